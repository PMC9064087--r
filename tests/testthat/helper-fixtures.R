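# Small fixtures and independent oracles shared across test files.

toy_counts <- function() {
  m <- matrix(c(5, 0, 1, 2,
                0, 3, 0, 1,
                4, 4, 2, 0), nrow = 3, byrow = TRUE)
  count_matrix(m, paste0("c", 1:3), paste0("g", 1:4),
               cell_labels = setNames(c("A", "A", "B"), paste0("c", 1:3)))
}

# Draw counts directly from the topic-model generative process (independent
# of the package's simulator): theta fixed per cell, counts multinomial
# with probabilities theta %*% phi.
sample_lda_counts <- function(phi, theta, depth, seed = 1) {
  set.seed(seed)
  probs <- theta %*% phi
  counts <- t(vapply(seq_len(nrow(theta)),
                     function(d) rmultinom(1, depth, probs[d, ])[, 1],
                     numeric(ncol(phi))))
  count_matrix(counts)
}

# Two well-separated topics over disjoint gene blocks.
two_block_topics <- function(n_genes = 100) {
  half <- n_genes / 2
  rbind(c(rep(1 / half, half), rep(0, half)),
        c(rep(0, half), rep(1 / half, half)))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Counts drawn from K_true disjoint-support topics (for elbow checks).
make_k_topic_data <- function(K_true, genes_per_topic = 40,
                              cells = 60 * K_true, depth = 400, seed = 21) {
  V <- K_true * genes_per_topic
  phi <- matrix(0, K_true, V)
  for (k in seq_len(K_true))
    phi[k, (k - 1) * genes_per_topic + seq_len(genes_per_topic)] <-
      1 / genes_per_topic
  set.seed(seed)
  theta <- matrix(rgamma(cells * K_true, 0.2), cells, K_true)
  theta <- theta / rowSums(theta)
  sample_lda_counts(phi, theta, depth = depth, seed = seed + 1)
}

# Best-match cosine per true topic (greedy over fitted rows).
best_match_cosines <- function(phi_fit, phi_true) {
  vapply(seq_len(nrow(phi_true)), function(k) {
    max(apply(phi_fit, 1, cosine, b = phi_true[k, ]))
  }, numeric(1))
}

elbo_nondecreasing <- function(fit, rel_tol = 1e-6) {
  tr <- fit$elbo_trace
  if (length(tr) < 2) return(TRUE)
  all(diff(tr) >= -rel_tol * abs(tr[-length(tr)]))
}

# Step-up Benjamini-Hochberg written out directly, as an oracle for the
# packaged wrapper.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  crit <- ranked <= alpha * seq_len(m) / m
  k <- if (any(crit)) max(which(crit)) else 0
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  adj_sorted <- rev(cummin(rev(ranked * m / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[ord] <- pmin(adj_sorted, 1)
  list(adjusted = adjusted, reject = reject)
}

# Mixture binomial tail by explicit pmf summation (oracle for n <= 20).
mixture_tail_oracle <- function(x, n, probs, weights) {
  if (x <= 0) return(1)
  tail_one <- function(p) sum(vapply(x:n, function(i) dbinom(i, n, p),
                                     numeric(1)))
  sum(weights * vapply(probs, tail_one, numeric(1)))
}

# Argmax support counts by direct looping (oracle for count_topic_support).
support_oracle <- function(fit, cm, new_idx) {
  out <- list()
  for (d in seq_len(nrow(cm$counts))) {
    for (g in which(cm$counts[d, ] > 0)) {
      scores <- fit$theta[d, ] * fit$phi[, g]
      if (sum(scores) <= 0) next
      win <- which.max(scores)   # ties: lowest index, same as max.col "first"
      if (win %in% new_idx) {
        key <- paste(rownames(fit$phi)[win], cm$gene_ids[g], sep = "\r")
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
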