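ranking_fit <- function() {
  # 3 cells x 2 topics; topic 2 is new. Gene gA: phi_ref = 0.01,
  # phi_new = 0.3, so even the cell with theta = (0.9, 0.1) attributes gA
  # to the new topic (0.9 * 0.01 < 0.1 * 0.3).
  theta <- matrix(c(0.9, 0.1,
                    0.2, 0.8,
                    0.5, 0.5), 3, 2, byrow = TRUE,
                  dimnames = list(paste0("c", 1:3), c("ref", "new")))
  phi <- matrix(c(0.01, 0.3, 0.99, 0.7), 2, 2,
                dimnames = list(c("ref", "new"), c("gA", "gB")))
  structure(list(theta = theta, phi = phi, fixed_mask = c(TRUE, FALSE),
                 cell_ids = rownames(theta), gene_ids = colnames(phi)),
            class = "topic_fit")
}

test_that("support counts match the hand-computed example", {
  fit <- ranking_fit()
  cm <- count_matrix(matrix(c(1, 2, 3, 9, 9, 9), 3, 2),
                     paste0("c", 1:3), c("gA", "gB"))
  support <- count_topic_support(fit, cm)
  expect_equal(support$support[support$gene_id == "gA" &
                                 support$topic == "new"], 3L)
  # gB is argmaxed by the reference topic in cells 1 and 3
  expect_false("gB" %in%
                 support$gene_id[support$topic == "new" &
                                   support$support >= 2])
})

test_that("zero-count genes are absent from the support map", {
  fit <- ranking_fit()
  cm <- count_matrix(matrix(c(0, 0, 0, 5, 5, 5), 3, 2),
                     paste0("c", 1:3), c("gA", "gB"))
  support <- count_topic_support(fit, cm, all_topics = TRUE)
  expect_false("gA" %in% support$gene_id)
})

test_that("per-gene support over all topics partitions expressing cells", {
  set.seed(23)
  phi <- matrix(rgamma(3 * 15, 0.5), 3, 15)
  phi <- phi / rowSums(phi)
  theta <- matrix(rgamma(12 * 3, 0.7), 12, 3)
  theta <- theta / rowSums(theta)
  dimnames(phi) <- list(paste0("t", 1:3), paste0("g", 1:15))
  dimnames(theta) <- list(paste0("c", 1:12), paste0("t", 1:3))
  fit <- structure(list(theta = theta, phi = phi,
                        fixed_mask = c(TRUE, FALSE, FALSE),
                        cell_ids = rownames(theta),
                        gene_ids = colnames(phi)), class = "topic_fit")
  cm <- count_matrix(matrix(rpois(12 * 15, 1), 12, 15),
                     rownames(theta), colnames(phi))
  support <- count_topic_support(fit, cm, all_topics = TRUE)
  per_gene <- tapply(support$support, support$gene_id, sum)
  expressing <- Matrix::colSums(cm$counts > 0)
  for (g in names(per_gene))
    expect_equal(unname(per_gene[g]), unname(expressing[g]))
})

test_that("support agrees with a brute-force recomputation", {
  set.seed(24)
  phi <- matrix(rgamma(4 * 30, 0.4), 4, 30)
  phi <- phi / rowSums(phi)
  theta <- matrix(rgamma(20 * 4, 0.6), 20, 4)
  theta <- theta / rowSums(theta)
  dimnames(phi) <- list(paste0("t", 1:4), paste0("g", 1:30))
  dimnames(theta) <- list(paste0("c", 1:20), paste0("t", 1:4))
  fit <- structure(list(theta = theta, phi = phi,
                        fixed_mask = c(TRUE, TRUE, FALSE, FALSE),
                        cell_ids = rownames(theta),
                        gene_ids = colnames(phi)), class = "topic_fit")
  cm <- count_matrix(matrix(rpois(20 * 30, 0.8), 20, 30),
                     rownames(theta), colnames(phi))
  support <- count_topic_support(fit, cm)
  oracle <- support_oracle(fit, cm, new_idx = 3:4)
  expect_equal(nrow(support), length(oracle))
  for (i in seq_len(nrow(support))) {
    key <- paste(support$topic[i], support$gene_id[i], sep = "\r")
    expect_equal(support$support[i], oracle[[key]])
  }
})

test_that("support is invariant to cell and gene order", {
  fit <- ranking_fit()
  cm <- count_matrix(matrix(c(1, 2, 3, 9, 9, 9), 3, 2),
                     paste0("c", 1:3), c("gA", "gB"))
  s1 <- count_topic_support(fit, cm)
  cm2 <- count_matrix(as.matrix(cm$counts)[c(3, 1, 2), ],
                      cm$cell_ids[c(3, 1, 2)], cm$gene_ids)
  s2 <- count_topic_support(fit, cm2)
  expect_equal(dplyr::arrange(s1, topic, gene_id),
               dplyr::arrange(s2, topic, gene_id))
})

test_that("rank_genes applies the support threshold and tie rules", {
  support <- tibble::tibble(
    topic = rep("new01", 4),
    gene_id = c("gB", "gA", "gC", "gD"),
    support = c(12L, 12L, 9L, 30L))
  r <- rank_genes(support, min_cells = 10)
  expect_identical(r$gene_id, c("gD", "gA", "gB"))
  expect_identical(r$rank, 1:3)
  # gene with 9 supporting cells excluded at the default threshold
  expect_false("gC" %in% r$gene_id)
  r1 <- rank_genes(support, min_cells = 1)
  expect_identical(sort(r1$gene_id), sort(support$gene_id))
})

test_that("raising min_cells never adds a gene", {
  set.seed(25)
  support <- tibble::tibble(
    topic = sample(c("new01", "new02"), 40, replace = TRUE),
    gene_id = paste0("g", 1:40),
    support = sample(1:30, 40, replace = TRUE))
  prev <- rank_genes(support, 1)
  for (mc in c(5, 10, 20)) {
    cur <- rank_genes(support, mc)
    expect_true(all(paste(cur$topic, cur$gene_id) %in%
                      paste(prev$topic, prev$gene_id)))
    prev <- cur
  }
})

test_that("top_genes unions per-topic heads with stable order", {
  support <- tibble::tibble(
    topic = c("new01", "new01", "new01", "new02", "new02"),
    gene_id = c("gA", "gB", "gC", "gB", "gD"),
    support = c(30L, 20L, 15L, 25L, 10L))
  r <- rank_genes(support, 1)
  expect_identical(top_genes(r, 1), c("gA", "gB"))
  expect_identical(top_genes(r, 2), c("gA", "gB", "gD"))
  expect_lte(length(top_genes(r, 2)), 2 * 2)
  expect_identical(top_genes(r, 100), c("gA", "gB", "gC", "gD"))
})
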