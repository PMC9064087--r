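test_that("K = 1 gives a degenerate profile and pooled topic", {
  cm <- toy_counts()
  fit <- fit_lda(cm, K = 1, beta = 1e-6, seed = 1)
  expect_equal(unname(fit$theta[, 1]), rep(1, 3))
  pooled <- Matrix::colSums(cm$counts) / sum(cm$counts)
  expect_equal(unname(fit$phi[1, ]), unname(pooled), tolerance = 1e-4)
  expect_true(elbo_nondecreasing(fit))
})

test_that("well-separated topics are recovered with high cosine", {
  phi_true <- two_block_topics(100)
  theta <- matrix(0, 200, 2)
  theta[1:100, 1] <- 1
  theta[101:200, 2] <- 1
  cm <- sample_lda_counts(phi_true, theta, depth = 300, seed = 42)
  fit <- fit_lda(cm, K = 2, seed = 3)
  expect_true(all(best_match_cosines(fit$phi, phi_true) >= 0.95))
  expect_true(elbo_nondecreasing(fit))
})

test_that("fits are stable across seeds", {
  phi_true <- two_block_topics(60)
  theta <- matrix(rgamma(160 * 2, 0.5), 160, 2)
  theta <- theta / rowSums(theta)
  cm <- sample_lda_counts(phi_true, theta, depth = 250, seed = 5)
  f1 <- fit_lda(cm, K = 2, seed = 11)
  f2 <- fit_lda(cm, K = 2, seed = 99)
  e1 <- tail(f1$elbo_trace, 1)
  e2 <- tail(f2$elbo_trace, 1)
  expect_lt(abs(e1 - e2) / abs(e1), 0.01)
  # align topics by best cosine and compare
  m <- vapply(1:2, function(k) max(cosine(f2$phi[1, ], f1$phi[k, ]),
                                   cosine(f2$phi[2, ], f1$phi[k, ])),
              numeric(1))
  expect_true(all(m >= 0.99))
})

test_that("identical seeds reproduce the fit exactly", {
  cm <- toy_counts()
  f1 <- fit_lda(cm, K = 2, seed = 7)
  f2 <- fit_lda(cm, K = 2, seed = 7)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
})

test_that("the engine with an all-false mask is exactly fit_lda", {
  cm <- toy_counts()
  set.seed(7)
  phi0 <- matrix(rgamma(2 * 4, 1), 2, 4)
  phi0 <- phi0 / rowSums(phi0)
  via_engine <- pictopics:::lda_engine(cm, phi0, rep(FALSE, 2),
                                       alpha = 0.5, beta = 0.01, tol = 1e-6,
                                       max_iter = 500, inner_tol = 1e-3,
                                       inner_max = 20)
  via_fit <- fit_lda(cm, K = 2, seed = 7)
  expect_equal(unname(via_fit$phi), unname(via_engine$phi))
  expect_identical(via_fit$elbo_trace, via_engine$elbo_trace)
})

test_that("fixed reference rows survive stage 2 bit-identically", {
  phi_true <- two_block_topics(40)
  theta <- matrix(0.5, 60, 2)
  cm_ref <- sample_lda_counts(phi_true, theta, depth = 200, seed = 2)
  ref <- fit_lda(cm_ref, K = 2, seed = 1)
  cm_new <- sample_lda_counts(phi_true, theta[1:30, ], depth = 200, seed = 3)
  fit <- fit_lda_fixed(cm_new, ref, K_new = 2, seed = 4)
  expect_identical(unname(fit$phi[1:2, ]), unname(ref$phi))
  expect_identical(fit$fixed_mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(elbo_nondecreasing(fit))
})

test_that("null data gives new topics negligible weight", {
  phi_true <- two_block_topics(40)
  theta <- matrix(rgamma(200 * 2, 0.5), 200, 2)
  theta <- theta / rowSums(theta)
  cm_ref <- sample_lda_counts(phi_true, theta, depth = 800, seed = 6)
  ref <- fit_lda(cm_ref, K = 2, seed = 1)
  cm_null <- sample_lda_counts(phi_true, theta[1:100, ], depth = 800,
                               seed = 8)
  fit <- fit_lda_fixed(cm_null, ref, K_new = 2, seed = 5)
  new_mass <- rowSums(fit$theta[, !fit$fixed_mask, drop = FALSE])
  expect_lt(mean(new_mass), 0.05)
})

test_that("genes unseen in the reference are captured by a new topic", {
  phi_true <- two_block_topics(40)
  theta <- matrix(rgamma(80 * 2, 0.5), 80, 2)
  theta <- theta / rowSums(theta)
  cm_ref <- sample_lda_counts(phi_true, theta, depth = 300, seed = 6)
  ref <- fit_lda(cm_ref, K = 2, seed = 1)
  # interacting data: same process plus 10 previously-silent genes with
  # large counts (the reference rows renormalize over the shared axis, so
  # keep the gene universe identical and plant counts on zero-prob genes)
  cm_int <- sample_lda_counts(phi_true, theta[1:40, ], depth = 300, seed = 9)
  m <- as.matrix(cm_int$counts)
  m <- cbind(m, matrix(rpois(40 * 10, 30), 40, 10))
  colnames(m) <- c(cm_int$gene_ids, paste0("extra", 1:10))
  cm_int <- count_matrix(m)
  ref_padded <- ref
  # extend reference vocabulary with (near) zero-probability entries so the
  # planted genes are unexplainable by fixed rows
  phi_ext <- cbind(ref$phi, matrix(1e-12, 2, 10))
  phi_ext <- phi_ext / rowSums(phi_ext)
  colnames(phi_ext) <- colnames(m)
  ref_padded$phi <- phi_ext
  ref_padded$gene_ids <- colnames(m)
  fit <- fit_lda_fixed(cm_int, ref_padded, K_new = 2, seed = 5)
  new_phi <- fit$phi[!fit$fixed_mask, , drop = FALSE]
  top10 <- lapply(seq_len(2), function(k)
    colnames(new_phi)[order(new_phi[k, ], decreasing = TRUE)[1:10]])
  hits <- vapply(top10, function(g) sum(grepl("^extra", g)), numeric(1))
  expect_gte(max(hits), 8)
})

test_that("fractional counts are accepted and fit cleanly", {
  cm <- toy_counts()
  m <- as.matrix(cm$counts) + 0.5
  cmf <- count_matrix(m)
  fit <- fit_lda(cmf, K = 2, seed = 1)
  expect_true(all(abs(rowSums(fit$phi) - 1) < 1e-8))
  expect_true(all(abs(rowSums(fit$theta) - 1) < 1e-8))
  expect_true(elbo_nondecreasing(fit))
})

test_that("token posterior matches hand calculations and normalizes", {
  fit <- structure(list(
    phi = matrix(c(0.2, 0.1, 0.8, 0.9), 2, 2,
                 dimnames = list(c("t1", "t2"), c("gA", "gB"))),
    theta = matrix(c(1, 0.5, 0, 0.5), 2, 2,
                   dimnames = list(c("c1", "c2"), c("t1", "t2"))),
    fixed_mask = c(FALSE, FALSE), cell_ids = c("c1", "c2"),
    gene_ids = c("gA", "gB")), class = "topic_fit")
  expect_equal(token_posterior(fit, "c1", "gA")$posterior, c(1, 0))
  expect_equal(token_posterior(fit, "c2", "gA")$posterior, c(2 / 3, 1 / 3))
  set.seed(10)
  for (i in 1:50) {
    K <- sample(2:6, 1)
    th <- rgamma(K, 1); th <- th / sum(th)
    ph <- rgamma(K, 1)
    f2 <- structure(list(
      phi = matrix(ph, K, 1, dimnames = list(paste0("t", 1:K), "g")),
      theta = matrix(th, 1, K, dimnames = list("c", paste0("t", 1:K))),
      fixed_mask = rep(FALSE, K), cell_ids = "c", gene_ids = "g"),
      class = "topic_fit")
    expect_equal(sum(token_posterior(f2, 1, 1)$posterior), 1)
  }
})

test_that("degenerate tokens return a flagged uniform posterior", {
  fit <- structure(list(
    phi = matrix(c(0, 0, 1, 1), 2, 2,
                 dimnames = list(c("t1", "t2"), c("gA", "gB"))),
    theta = matrix(c(1, 0), 1, 2, dimnames = list("c1", c("t1", "t2"))),
    fixed_mask = c(FALSE, FALSE), cell_ids = "c1",
    gene_ids = c("gA", "gB")), class = "topic_fit")
  tp <- token_posterior(fit, "c1", "gA")
  expect_equal(tp$posterior, c(0.5, 0.5))
  expect_true(all(tp$degenerate))
})

test_that("perplexity has its closed-form values and prefers the true K", {
  cm <- toy_counts()
  fit <- fit_lda(cm, K = 2, seed = 1)
  fit$phi[] <- 1 / ncol(fit$phi)
  expect_equal(perplexity(fit, cm, newdata = FALSE), ncol(fit$phi))

  one <- count_matrix(matrix(4, 1, 1), "c1", "g1")
  f1 <- fit_lda(one, K = 1, seed = 1)
  expect_equal(perplexity(f1, one, newdata = FALSE), 1, tolerance = 1e-6)

  phi_true <- two_block_topics(60)
  theta <- matrix(0, 120, 2)
  theta[1:60, 1] <- 1
  theta[61:120, 2] <- 1
  cm2 <- sample_lda_counts(phi_true, theta, depth = 250, seed = 12)
  p2 <- perplexity(fit_lda(cm2, 2, seed = 1), cm2, newdata = FALSE)
  p1 <- perplexity(fit_lda(cm2, 1, seed = 1), cm2, newdata = FALSE)
  expect_lt(p2, p1)
})

test_that("fit errors are informative", {
  cm <- toy_counts()
  expect_error(fit_lda(cm, K = 10), "exceed")
  empty <- count_matrix(matrix(0, 2, 2))
  expect_error(fit_lda(empty, K = 1), "no nonzero")
})
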