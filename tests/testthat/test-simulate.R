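test_that("singlet draws match multinomial moments", {
  topics <- matrix(1 / 10, 1, 10)
  spec <- population_spec(60, topics, "pop", depth_meanlog = log(1000),
                          depth_sdlog = 0)
  cm <- generate_singlets(spec, seed = 5)
  depths <- Matrix::rowSums(cm$counts)
  expect_true(all(depths == 1000))
  means <- Matrix::colSums(cm$counts) / 60
  se <- sqrt(1000 * 0.1 * 0.9 / 60)
  expect_true(all(abs(means - 100) < 3 * se))
})

test_that("empty populations and determinism behave", {
  topics <- matrix(1 / 5, 1, 5)
  spec0 <- population_spec(0, topics, "pop")
  expect_equal(dim(generate_singlets(spec0)), c(0L, 5L))
  spec <- population_spec(10, topics, "pop")
  a <- generate_singlets(spec, seed = 3)
  b <- generate_singlets(spec, seed = 3)
  d <- generate_singlets(spec, seed = 4)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_false(identical(as.matrix(a$counts), as.matrix(d$counts)))
})

test_that("fitting the model on two disjoint populations recovers the topics", {
  topics <- two_block_topics(60)
  specA <- population_spec(80, topics[1, , drop = FALSE], "A",
                           depth_meanlog = log(400), depth_sdlog = 0.1)
  specB <- population_spec(80, topics[2, , drop = FALSE], "B",
                           depth_meanlog = log(400), depth_sdlog = 0.1)
  cmA <- generate_singlets(specA, seed = 6)
  cmB <- generate_singlets(specB, seed = 7)
  cm <- count_matrix(rbind(cmA$counts, cmB$counts),
                     c(cmA$cell_ids, cmB$cell_ids), cmA$gene_ids)
  fit <- fit_lda(cm, K = 2, seed = 1)
  expect_true(all(best_match_cosines(fit$phi, topics) >= 0.95))
})

test_that("doublet mixing respects ratio and target depth", {
  topics <- two_block_topics(40)
  specA <- population_spec(50, topics[1, , drop = FALSE], "A",
                           depth_meanlog = log(1000), depth_sdlog = 0)
  specB <- population_spec(50, topics[2, , drop = FALSE], "B",
                           depth_meanlog = log(1000), depth_sdlog = 0)
  cmA <- generate_singlets(specA, seed = 8)
  cmB <- generate_singlets(specB, seed = 9)
  db <- make_doublets(cmA, cmB, ratio = 0.3, n_doublets = 500, seed = 10,
                      target_depth = 1000)
  tot <- Matrix::rowSums(db$counts)
  expect_lt(stats::sd(tot) / mean(tot), 0.05)
  # expected per-gene proportion = ratio * pA + (1 - ratio) * pB;
  # block 1 carries pA mass, block 2 pB mass
  props <- Matrix::colSums(db$counts) / sum(db$counts)
  expect_equal(sum(props[1:20]), 0.3, tolerance = 0.02)
  expect_equal(sum(props[21:40]), 0.7, tolerance = 0.02)
  expect_error(make_doublets(cmA, cmB, ratio = 1.2, 10),
               class = "pictopics_validation_error")
})

test_that("a ratio near 1 reduces to a thinned parent A", {
  topics <- two_block_topics(40)
  specA <- population_spec(20, topics[1, , drop = FALSE], "A",
                           depth_meanlog = log(500), depth_sdlog = 0)
  specB <- population_spec(20, topics[2, , drop = FALSE], "B",
                           depth_meanlog = log(500), depth_sdlog = 0)
  cmA <- generate_singlets(specA, seed = 11)
  cmB <- generate_singlets(specB, seed = 12)
  db <- make_doublets(cmA, cmB, ratio = 0.999, n_doublets = 100, seed = 13)
  fracA <- sum(db$counts[, 1:20]) / sum(db$counts)
  expect_gt(fracA, 0.99)
})

test_that("injection changes only the listed entries and records truth", {
  cm <- toy_counts()
  out <- inject_upregulation(cm, c("g1", "g3"), 1.5, cells = c("c1", "c3"),
                             scenario_name = "demo")
  delta <- as.matrix(out$counts$counts) - as.matrix(cm$counts)
  expect_equal(delta[c(1, 3), c(1, 3)], matrix(1.5, 2, 2),
               ignore_attr = TRUE)
  delta[c(1, 3), c(1, 3)] <- 0
  expect_true(all(delta == 0))
  expect_identical(out$truth$injected_genes, c("g1", "g3"))
  expect_identical(out$truth$affected_cells, c("c1", "c3"))

  zero <- inject_upregulation(cm, "g1", 0)
  expect_equal(as.matrix(zero$counts$counts), as.matrix(cm$counts))
  expect_length(zero$truth$injected_genes, 0)

  expect_error(inject_upregulation(cm, "nope", 1),
               class = "pictopics_validation_error")
})

test_that("fraction mode selects a seeded subset of the right size", {
  cm <- count_matrix(matrix(1, 40, 3))
  out <- inject_upregulation(cm, "gene1", 10, cells = 0.1, seed = 4)
  expect_length(out$truth$affected_cells, 4)
  again <- inject_upregulation(cm, "gene1", 10, cells = 0.1, seed = 4)
  expect_identical(out$truth$affected_cells, again$truth$affected_cells)
})

test_that("scenarios are reproducible and validate their config", {
  a <- build_scenario("null", n_cells_per_pop = 30, n_genes = 120,
                      n_doublets = 10, depth_meanlog = log(300), seed = 2)
  b <- build_scenario("null", n_cells_per_pop = 30, n_genes = 120,
                      n_doublets = 10, depth_meanlog = log(300), seed = 2)
  expect_identical(as.matrix(a$reference$counts),
                   as.matrix(b$reference$counts))
  expect_identical(as.matrix(a$interacting$counts),
                   as.matrix(b$interacting$counts))
  expect_length(a$truth$injected_genes, 0)
  expect_error(build_scenario("null", n_cells_per_pop = 0),
               class = "pictopics_validation_error")
})

test_that("injection presets mark the expected gene sets in the truth", {
  scen <- build_scenario("subpop_10", n_cells_per_pop = 60, n_genes = 200,
                         n_doublets = 40, depth_meanlog = log(400), seed = 3)
  expect_identical(scen$truth$injected_genes, subpopulation_gene_set())
  expect_length(scen$truth$affected_cells, 4)
  expect_true(all(subpopulation_gene_set() %in% scen$reference$gene_ids))
  expect_identical(scen$reference$gene_ids, scen$interacting$gene_ids)
})
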