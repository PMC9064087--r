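#' Injected-gene sets used by the packaged benchmark scenarios
#'
#' Three named gene sets drive the packaged scenarios: a 13-gene set of
#' immune / adhesion genes upregulated across a whole doublet population, a
#' 20-gene set used for the random-gene experiment, and a 5-gene set used
#' for the subpopulation experiment. In the synthetic scenarios these names
#' are attached to simulated genes chosen by expression level (see
#' [build_scenario()]); the symbols make simulator output legible, they
#' carry no biology of their own here.
#' @name injection_sets
NULL

#' @rdname injection_sets
#' @export
interaction_gene_set <- function() {
  c("Sell", "Mif", "Bcl2l1", "Cd40", "Myc", "Ncl", "Cst3", "Ly6a", "Ctla4",
    "Ccl22", "Cd69", "Dll4", "Lgals1")
}

#' @rdname injection_sets
#' @export
random_gene_set <- function() {
  c("Gcfc2", "Wdsub1", "AU040320", "Pank3", "Dcaf12", "Gm26669", "Ehd2",
    "Bag3", "Rpl10-ps2", "Notch1", "Ppm1g", "Oxsr1", "Nrarp", "Ppp3ca",
    "Rpl28-ps1", "Stbd1", "Srgap2", "Cpped1", "Gm10420", "St6galnac3")
}

#' @rdname injection_sets
#' @export
subpopulation_gene_set <- function() {
  c("Gbp4", "Gbp7", "Gzmb", "Il2ra", "Psma4")
}

#' Specify a singlet population for simulation
#'
#' A population is defined by its topic-gene rows (each row a probability
#' distribution over the shared gene universe), a symmetric Dirichlet
#' parameter for per-cell topic weights, and a log-normal distribution of
#' per-cell sequencing depth.
#'
#' @param n_cells Number of cells to simulate.
#' @param topics Topics x genes matrix; rows must sum to 1.
#' @param label Population label attached to every cell.
#' @param theta_alpha Symmetric Dirichlet parameter for per-cell topic
#'   weights. Default 0.5.
#' @param depth_meanlog,depth_sdlog Log-normal depth parameters; defaults
#'   give a mean depth around 2100 counts per cell (plate-protocol scale).
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_cells, topics, label,
                            theta_alpha = 0.5,
                            depth_meanlog = log(2000), depth_sdlog = 0.3) {
  topics <- as.matrix(topics)
  if (nrow(topics) < 1) abort("Need at least one topic.")
  if (any(topics < 0) || any(abs(rowSums(topics) - 1) > 1e-8))
    abort("Topic rows must be probability vectors.")
  stopifnot(n_cells >= 0, theta_alpha > 0, depth_sdlog >= 0)
  structure(list(n_cells = n_cells, topics = topics, label = label,
                 theta_alpha = theta_alpha, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog),
            class = "population_spec")
}

#' Draw singlet cells from a known topic model
#'
#' Per cell: depth from the log-normal, topic weights from the symmetric
#' Dirichlet, then counts from a single multinomial with gene probabilities
#' `theta %*% topics` (the exact marginal of drawing a topic per token and
#' then a gene from that topic).
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @param prefix Prefix for generated cell ids; defaults to the label.
#' @return A [count_matrix()] with the population label on every cell.
#' @export
generate_singlets <- function(spec, seed = 1, prefix = spec$label) {
  stopifnot(inherits(spec, "population_spec"))
  V <- ncol(spec$topics)
  K <- nrow(spec$topics)
  n <- spec$n_cells
  gene_ids <- colnames(spec$topics) %||% sprintf("g%04d", seq_len(V))
  if (n == 0) {
    m <- Matrix::Matrix(0, 0, V, sparse = TRUE)
    return(count_matrix(m, character(0), gene_ids))
  }
  set.seed(as.integer(seed))
  depths <- pmax(1, round(rlnorm(n, spec$depth_meanlog, spec$depth_sdlog)))
  theta <- matrix(rgamma(n * K, spec$theta_alpha), n, K)
  theta <- theta / rowSums(theta)
  probs <- theta %*% spec$topics
  counts <- matrix(0, n, V)
  for (d in seq_len(n))
    counts[d, ] <- rmultinom(1, depths[d], probs[d, ])
  cell_ids <- sprintf("%s_%04d", prefix, seq_len(n))
  count_matrix(counts, cell_ids, gene_ids,
               cell_labels = setNames(rep(spec$label, n), cell_ids))
}

#' Build synthetic doublets as ratio mixtures of singlets
#'
#' Each doublet pairs one random cell from population A with one from B.
#' Each parent profile is multinomially thinned (downsampled with
#' replacement from its count profile) to `ratio * T` and
#' `(1 - ratio) * T` counts respectively, where the target depth `T`
#' defaults to the mean of the two parents' totals, and the thinned
#' profiles are summed. Thinning keeps doublet depth comparable to singlet
#' depth, so depth alone does not give doublets away.
#'
#' @param cmA,cmB [count_matrix()] objects over the same gene axis.
#' @param ratio Fraction of the doublet contributed by population A, in
#'   (0, 1).
#' @param n_doublets Number of doublets to build.
#' @param seed Integer seed.
#' @param target_depth Fixed total per doublet; `NULL` (default) uses the
#'   mean of each pair's parent totals.
#' @return A [count_matrix()] of doublets labelled `"doublet"`, with the
#'   parent cell ids in attribute `"parents"`.
#' @export
make_doublets <- function(cmA, cmB, ratio, n_doublets, seed = 1,
                          target_depth = NULL) {
  if (!identical(cmA$gene_ids, cmB$gene_ids))
    abort("Populations must share an identical gene axis.")
  if (ratio <= 0 || ratio >= 1)
    abort("`ratio` must lie strictly inside (0, 1).",
          class = "pictopics_validation_error")
  if (nrow(cmA$counts) < 1 || nrow(cmB$counts) < 1)
    abort("Both populations need at least one cell.")
  set.seed(as.integer(seed))
  pa <- sample.int(nrow(cmA$counts), n_doublets, replace = TRUE)
  pb <- sample.int(nrow(cmB$counts), n_doublets, replace = TRUE)
  totA <- Matrix::rowSums(cmA$counts)
  totB <- Matrix::rowSums(cmB$counts)
  V <- ncol(cmA$counts)
  counts <- matrix(0, n_doublets, V)
  for (d in seq_len(n_doublets)) {
    Td <- if (is.null(target_depth)) mean(c(totA[pa[d]], totB[pb[d]]))
          else target_depth
    nA <- round(ratio * Td)
    nB <- round((1 - ratio) * Td)
    profA <- cmA$counts[pa[d], ]
    profB <- cmB$counts[pb[d], ]
    if (nA > 0 && sum(profA) > 0)
      counts[d, ] <- counts[d, ] + rmultinom(1, nA, profA)
    if (nB > 0 && sum(profB) > 0)
      counts[d, ] <- counts[d, ] + rmultinom(1, nB, profB)
  }
  cell_ids <- sprintf("doublet_%04d", seq_len(n_doublets))
  out <- count_matrix(counts, cell_ids, cmA$gene_ids,
                      cell_labels = setNames(rep("doublet", n_doublets),
                                             cell_ids))
  attr(out, "parents") <- tibble(doublet = cell_ids,
                                 parent_a = cmA$cell_ids[pa],
                                 parent_b = cmB$cell_ids[pb])
  out
}

#' Inject upregulation into selected genes
#'
#' Adds a constant to the listed genes' counts in the affected cells —
#' the ground-truth perturbation the benchmarks try to recover. Fractional
#' increments are stored exactly (the model accepts fractional counts; the
#' binomial diagnostic ceils them). All other entries are untouched.
#'
#' @param cm A [count_matrix()].
#' @param genes Gene ids to upregulate.
#' @param increment Constant added to each listed gene in each affected
#'   cell (`>= 0`).
#' @param cells `"all"`, a fraction in (0, 1) (a seeded subset of cells of
#'   that size), or an explicit character vector of cell ids.
#' @param seed Seed for fraction mode.
#' @param scenario_name Stored in the truth manifest.
#' @return A list with the modified `counts` ([count_matrix()]) and
#'   `truth` (a `simulation_truth` manifest: injected genes, increment,
#'   affected cells, seed, scenario name).
#' @export
inject_upregulation <- function(cm, genes, increment, cells = "all",
                                seed = 1, scenario_name = "custom") {
  missing <- setdiff(genes, cm$gene_ids)
  if (length(missing))
    abort(paste0("Unknown gene: ", missing[[1]]),
          class = "pictopics_validation_error")
  stopifnot(increment >= 0)
  if (is.numeric(cells)) {
    stopifnot(cells > 0, cells <= 1)
    set.seed(as.integer(seed))
    affected <- sort(sample(cm$cell_ids, round(cells * length(cm$cell_ids))))
  } else if (identical(cells, "all")) {
    affected <- cm$cell_ids
  } else {
    missing_cells <- setdiff(cells, cm$cell_ids)
    if (length(missing_cells))
      abort(paste0("Unknown cell: ", missing_cells[[1]]),
            class = "pictopics_validation_error")
    affected <- cells
  }
  counts <- cm$counts
  if (increment > 0 && length(genes) && length(affected)) {
    ci <- match(affected, cm$cell_ids)
    gi <- match(genes, cm$gene_ids)
    counts[ci, gi] <- as.matrix(counts[ci, gi, drop = FALSE]) + increment
  }
  truth <- structure(list(
    injected_genes = if (increment > 0) genes else character(0),
    increment = increment,
    affected_cells = if (increment > 0) affected else character(0),
    seeds = c(injection = as.integer(seed)),
    scenario_name = scenario_name), class = "simulation_truth")
  list(counts = count_matrix(counts, cm$cell_ids, cm$gene_ids,
                             cell_labels = cm$cell_labels),
       truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> scenario '%s': %d genes +%g in %d cells\n",
              x$scenario_name, length(x$injected_genes), x$increment,
              length(x$affected_cells)))
  invisible(x)
}

#' @method tidy simulation_truth
#' @export
tidy.simulation_truth <- function(x, ...) {
  tibble(gene_id = x$injected_genes,
         increment = rep_len(x$increment, length(x$injected_genes)),
         scenario = x$scenario_name)
}

# Place the three conventional symbol sets on simulated genes, chosen by
# expression in the reference: the 13- and 5-gene sets on genes of typical
# expression (pooled mean count per cell in [0.5, 3], widened to
# [0.25, 6] when the band is too small), the 20-gene "random" set
# uniformly among genes detected in more than 10 reference cells (the
# post-filter universe). A set whose candidate pool is too small at the
# current scale is skipped.
assign_symbol_sets <- function(reference, seed) {
  mean_per_cell <- Matrix::colSums(reference$counts) / nrow(reference$counts)
  detected <- Matrix::colSums(reference$counts > 0)
  typical <- which(mean_per_cell >= 0.5 & mean_per_cell <= 3)
  if (length(typical) < length(interaction_gene_set()) +
        length(subpopulation_gene_set()))
    typical <- which(mean_per_cell >= 0.25 & mean_per_cell <= 6)
  new_ids <- reference$gene_ids
  taken <- integer(0)
  set.seed(as.integer(seed))
  place <- function(symbols, pool) {
    pool <- setdiff(pool, taken)
    if (length(pool) < length(symbols)) return(invisible(NULL))
    chosen <- sort(sample(pool, length(symbols)))
    new_ids[chosen] <<- symbols
    taken <<- c(taken, chosen)
    invisible(NULL)
  }
  place(interaction_gene_set(), typical)
  place(subpopulation_gene_set(), typical)
  place(random_gene_set(), which(detected > 10))
  new_ids
}

#' Build a complete benchmark scenario
#'
#' Composes the synthetic benchmark end to end: two singlet populations
#' drawn from a known topic model (private topics per population plus
#' shared ones), doublets as ratio mixtures, and injected upregulation
#' with a ground-truth manifest. Everything is reproducible from `seed`.
#'
#' Presets:
#' \describe{
#'   \item{`ratio_50_50`, `ratio_60_40`, `ratio_30_70`}{13 genes of typical
#'     expression upregulated by +1.5 in every doublet, at mixing ratios
#'     0.5, 0.6 and 0.3.}
#'   \item{`random_genes`}{20 genes sampled uniformly from those detected
#'     in more than 10 reference cells, +1.5, ratio 0.5.}
#'   \item{`subpop_50`, `subpop_25`, `subpop_10`}{5 typical-expression
#'     genes upregulated by +10 in 50/25/10 percent of the doublets,
#'     ratio 0.5.}
#'   \item{`null`}{No injection; the truth manifest is empty.}
#' }
#'
#' "Typical expression" means a pooled mean count per reference cell in
#' `[0.5, 3]` — the count scale the +1.5 increment is calibrated to.
#' Injected genes are renamed to the conventional symbols of
#' [interaction_gene_set()] and friends so scenario outputs are legible.
#'
#' @param preset Scenario name, see above.
#' @param n_cells_per_pop Singlet cells per population. Default 1000.
#' @param n_genes Gene universe size. Default 2500.
#' @param n_doublets Doublets per scenario. Default 200.
#' @param n_private,n_shared Private topics per population and shared
#'   topics. Defaults 4 and 2 (10 distinct topics in total).
#' @param topic_concentration Symmetric Dirichlet concentration for
#'   topic-gene rows. Default 0.1 (sparse, well-separated topics).
#' @param theta_alpha,depth_meanlog,depth_sdlog See [population_spec()].
#' @param ratio,inject_genes,increment,inject_cells Override the preset's
#'   values (`inject_genes` may be a count — sampled from the typical band
#'   — or explicit gene ids).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list with `reference` (combined singlets, labelled
#'   `popA`/`popB`), `interacting` (doublets after injection), `truth`
#'   (the manifest, including all stage seeds) and `topics` (the true
#'   topic-gene matrix).
#' @export
build_scenario <- function(preset = c("ratio_50_50", "ratio_60_40",
                                      "ratio_30_70", "random_genes",
                                      "subpop_50", "subpop_25", "subpop_10",
                                      "null"),
                           n_cells_per_pop = 1000, n_genes = 2500,
                           n_doublets = 200, n_private = 4, n_shared = 2,
                           topic_concentration = 0.1, theta_alpha = 0.5,
                           depth_meanlog = log(2000), depth_sdlog = 0.3,
                           ratio = NULL, inject_genes = NULL,
                           increment = NULL, inject_cells = NULL, seed = 1) {
  preset <- match.arg(preset)
  bad <- c(n_cells_per_pop < 1, n_genes < 10, n_doublets < 1,
           n_private < 1, n_shared < 0)
  names(bad) <- c("n_cells_per_pop", "n_genes", "n_doublets", "n_private",
                  "n_shared")
  if (any(bad))
    abort(paste0("Invalid scenario fields: ",
                 paste(names(bad)[bad], collapse = ", ")),
          class = "pictopics_validation_error")
  seed <- as.integer(seed)
  seeds <- c(topics = seed * 13L + 1L, popA = seed * 13L + 2L,
             popB = seed * 13L + 3L, doublets = seed * 13L + 4L,
             genes = seed * 13L + 5L, injection = seed * 13L + 6L)
  seeds <- seeds %% .Machine$integer.max

  defaults <- switch(preset,
    ratio_50_50 = list(ratio = 0.5, genes = interaction_gene_set(),
                       increment = 1.5, cells = "all", rule = "typical"),
    ratio_60_40 = list(ratio = 0.6, genes = interaction_gene_set(),
                       increment = 1.5, cells = "all", rule = "typical"),
    ratio_30_70 = list(ratio = 0.3, genes = interaction_gene_set(),
                       increment = 1.5, cells = "all", rule = "typical"),
    random_genes = list(ratio = 0.5, genes = random_gene_set(),
                        increment = 1.5, cells = "all", rule = "detected"),
    subpop_50 = list(ratio = 0.5, genes = subpopulation_gene_set(),
                     increment = 10, cells = 0.5, rule = "typical"),
    subpop_25 = list(ratio = 0.5, genes = subpopulation_gene_set(),
                     increment = 10, cells = 0.25, rule = "typical"),
    subpop_10 = list(ratio = 0.5, genes = subpopulation_gene_set(),
                     increment = 10, cells = 0.1, rule = "typical"),
    null = list(ratio = 0.5, genes = character(0), increment = 0,
                cells = "all", rule = "typical"))
  ratio <- ratio %||% defaults$ratio
  increment <- increment %||% defaults$increment
  inject_cells <- inject_cells %||% defaults$cells

  # true topics: popA private, popB private, shared
  K_true <- 2 * n_private + n_shared
  set.seed(seeds[["topics"]])
  topics <- matrix(rgamma(K_true * n_genes, topic_concentration),
                   K_true, n_genes)
  topics <- topics / rowSums(topics)
  colnames(topics) <- sprintf("g%04d", seq_len(n_genes))
  idxA <- c(seq_len(n_private), 2 * n_private + seq_len(n_shared))
  idxB <- c(n_private + seq_len(n_private), 2 * n_private + seq_len(n_shared))

  specA <- population_spec(n_cells_per_pop, topics[idxA, , drop = FALSE],
                           "popA", theta_alpha, depth_meanlog, depth_sdlog)
  specB <- population_spec(n_cells_per_pop, topics[idxB, , drop = FALSE],
                           "popB", theta_alpha, depth_meanlog, depth_sdlog)
  singA <- generate_singlets(specA, seed = seeds[["popA"]])
  singB <- generate_singlets(specB, seed = seeds[["popB"]])

  reference <- count_matrix(rbind(singA$counts, singB$counts),
                            c(singA$cell_ids, singB$cell_ids),
                            singA$gene_ids,
                            cell_labels = c(singA$cell_labels,
                                            singB$cell_labels))

  doublets <- make_doublets(singA, singB, ratio = ratio,
                            n_doublets = n_doublets,
                            seed = seeds[["doublets"]])

  # Attach the conventional injection symbols to simulated genes. All
  # three symbol sets are placed for every preset (same seed, same
  # populations => identical gene universe across presets), so a single
  # reference fit can serve every scenario.
  new_ids <- assign_symbol_sets(reference, seeds[["genes"]])
  if (!identical(new_ids, reference$gene_ids)) {
    reference <- count_matrix(reference$counts, reference$cell_ids, new_ids,
                              cell_labels = reference$cell_labels)
    parents <- attr(doublets, "parents")
    doublets <- count_matrix(doublets$counts, doublets$cell_ids, new_ids,
                             cell_labels = doublets$cell_labels)
    attr(doublets, "parents") <- parents
    colnames(topics) <- new_ids
  }
  target_names <- inject_genes %||% defaults$genes
  truth_genes <- character(0)
  if (increment > 0 && length(target_names)) {
    missing <- setdiff(target_names, reference$gene_ids)
    if (length(missing))
      abort(paste0("Too few candidate genes to place injection target: ",
                   missing[[1]]),
            class = "pictopics_validation_error")
    truth_genes <- target_names
  }

  if (increment > 0 && length(truth_genes) &&
      !all(truth_genes %in% doublets$gene_ids))
    abort("Injection targets missing from the doublet gene axis.")

  inj <- inject_upregulation(doublets, truth_genes, increment,
                             cells = inject_cells,
                             seed = seeds[["injection"]],
                             scenario_name = preset)
  inj$truth$mixing_ratio <- ratio
  inj$truth$seeds <- seeds
  list(reference = reference, interacting = inj$counts, truth = inj$truth,
       topics = topics)
}
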