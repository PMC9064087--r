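---
title: "Detecting cell-cell interaction genes with two-stage topic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-cell interaction genes with two-stage topic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Protocols that capture physically interacting cells (PICs) sequence pairs of
attached cells as single observations. Genes that change their expression
*because* the cells interact — adhesion molecules, co-stimulatory receptors,
cytokines — are mixed into a profile that is mostly just the sum of the two
partners. The question this package answers is: which genes in the
interacting population cannot be explained as a mixture of the
non-interacting reference states?

`pictopics` answers it with latent Dirichlet allocation (LDA). Cells play
the role of documents and genes of words: each cell `d` draws topic weights
$\theta_d \sim \mathrm{Dir}(\alpha)$, each topic `k` is a distribution over
genes $\phi_k \sim \mathrm{Dir}(\beta)$, each transcript picks a topic from
$\theta_d$ and then a gene from $\phi_k$. Topics are groups of co-varying
genes: cell-type programs, temporal programs, housekeeping.

The two-stage workflow:

1. **Reference stage.** Fit LDA with `K` topics on a population known not
   to interact (sorted cells, mono-cultures, labelled singlets). These
   topics describe every non-interacting state available to a cell.
2. **Interaction stage.** Freeze the reference topic-gene rows and fit
   `K_new` additional free topics on the interacting population
   (`fit_lda_fixed()`). Cell-topic weights are re-estimated over all
   topics. Whatever the reference topics cannot explain — and only that —
   is absorbed by the new topics.
3. **Ranking.** For every (cell, gene) with nonzero count, compute the
   token posterior over topics ($r_k \propto \theta_{dk}\phi_{kg}$) and
   take its argmax over *all* topics. A gene's support for a new topic is
   the number of cells whose argmax lands there; genes are ranked per new
   topic by support (`count_topic_support()`, `rank_genes()`). Interaction
   candidates are genes many cells can only explain with new topics.

A binomial diagnostic (`compare_models_for_gene()`) motivates the new
topics: for a gene with count `x` out of a cell total `n`, compare
$\sum_k w_k P(\mathrm{Bin}(n, \phi_{kg}) \ge x)$ under the full weights
($w = \theta$) versus the reference-only weights ($w = \Delta$, new-topic
entries zeroed and the rest renormalized). Genes upregulated by
interaction are observed with visibly higher probability under $\theta$;
unaffected genes look the same under both.

## Fitting machinery and its numerical choices

The model is fitted by mean-field variational EM with point-estimate topic
rows. Per cell, the Dirichlet variational parameters $\gamma_d$ and the
token responsibilities are updated by coordinate ascent in compiled code;
the M-step sets each free row to the normalized sufficient statistics plus
the smoothing pseudocount $\beta$. Because the $\beta$ pseudocount is part
of the tracked objective ($\beta \sum_{kg} \log \phi_{kg}$ over free rows),
every E- and M-step is an exact ascent and the reported ELBO trace is
non-decreasing up to floating point — a property the test suite enforces on
every fit.

Parameters that matter, with their defaults and the reasoning:

* `alpha = 1/K`, `beta = 0.01`: symmetric, sparse priors of the kind used
  throughout the topic-modelling literature. `beta` only smooths the
  M-step; `alpha < 1` encourages cells to use few topics.
* `tol = 1e-6` (relative ELBO change): immediately after a flat random
  initialization the fit sits on a near-symmetric plateau where the ELBO
  moves slowly; a looser tolerance (we tried `1e-4`) stops there and
  returns topics collapsed onto the pooled gene frequencies. `1e-6`
  reliably walks off the plateau (two-block recovery cosine goes from
  ~0.6 to 0.999).
* `inner_tol = 1e-3`, `inner_max = 20`: the per-cell coordinate ascent is
  truncated rather than run to convergence; the M-step makes most of the
  progress, and truncation does not affect the ascent property.
* `n_starts`: variational EM finds local optima. The pipeline wrappers fit
  three random restarts and keep the highest final ELBO — selection by the
  model's own criterion. On the packaged benchmark a poor single-start
  optimum is visible directly in the bound (differences of order 1e5 on a
  bound of -2.9e7) and in noisier second-stage topics.
* Initialization is a seeded Dirichlet(1) draw per free topic row, so every
  fit is reproducible from its seed; serialized models
  (`write_topic_fit()`) are byte-identical across reruns.
* Degenerate tokens (posterior normalizer 0) return a flagged uniform
  posterior and are skipped by the ranking; cells whose weight sits
  entirely on new topics have no reference-only explanation and are
  excluded from the binomial diagnostic.
* Gene-axis alignment in stage 2 intersects gene ids and renormalizes the
  frozen rows over the shared vocabulary (a no-op when the axes already
  match, keeping the rows bit-identical).

`perplexity()` is the exponentiated negative per-token log-likelihood
using the fitted cell-topic weights,
$\exp(-\sum x \log(\hat\theta\phi) / \sum x)$. This plug-in form has two
useful exact identities — a uniform topic-gene model scores exactly the
vocabulary size, and a saturated single-gene model scores 1 — which the
full variational bound (with its Dirichlet KL terms) does not satisfy; the
bound is still what drives fitting and convergence.

## Choosing the number of topics

`selection_curve()` fits a grid of `K` and records perplexity plus the
mean pairwise cosine and Jensen-Shannon divergence between topic-gene
rows (all unordered pairs, averaged). Perplexity falls steeply while
genuine structure remains unexplained and flattens once `K` reaches the
generative complexity; `suggest_K()` returns the smallest `K` whose
relative improvement to the next grid point drops below `flatten_frac`
(default 0.02) — a thresholded version of reading the elbow off the plot,
invariant to rescaling the curve. Under-specifying the reference `K` is
the more dangerous direction: reference programs (e.g. housekeeping) that
get no topic of their own reappear as "new" topics in stage 2. The
second-stage topic-gene rows should be inspected for genes highly
expressed in the reference before interpreting them as interaction.

## What the simulator emulates — and what it does not

`build_scenario()` builds the whole benchmark without any external data:

* Two singlet populations (default 1000 cells each, 2500 genes) drawn
  from a known topic model with 4 private topics per population and 2
  shared topics, topic rows drawn from a sparse Dirichlet (concentration
  0.1). Depths are log-normal around 2000 counts per cell — plate-protocol
  scale, matching the sequencing depths at which PIC experiments are run.
* Doublets (default 200) pair a random cell from each population,
  multinomially thin each parent to `ratio * T` and `(1 - ratio) * T`
  (target depth `T` = mean of the parents' totals) and sum. Thinning keeps
  doublet depth in the singlet range, so depth alone cannot give doublets
  away.
* Upregulation adds a constant to selected genes in selected cells, with
  a truth manifest for scoring. The packaged scenarios mirror the standard
  validation design: +1.5 into 13 genes of typical expression (mixing
  ratios 50/50, 60/40, 30/70), +1.5 into 20 genes sampled from the
  post-filter universe, and +10 into 5 genes confined to 50/25/10 percent
  of the doublets. "Typical expression" is implemented as a pooled mean
  count per cell in [0.5, 3], the count scale to which a +1.5 increment is
  calibrated.

The simulator deliberately omits ambient RNA, empty droplets, UMI
collisions, batch effects and — most relevantly — within-population
substructure such as timepoints. Real co-culture references span multiple
timepoints, which decorrelates the orderings of the second-stage topics;
with a homogeneous injection into homogeneous doublets, all new topics
tend to agree on a single ordering of the injected genes. Passing the
packaged benchmarks therefore demonstrates sensitivity and ranking
fidelity, not robustness to the full noise structure of real data.

## Benchmark scale and design choices

The packaged benchmark and the acceptance checks run at 2 x 1000 reference
cells, 2500 genes, 200 doublets per scenario, reference `K = 10` (the
generative number of topics), `K_new = 5`, ranking threshold
`min_cells = 10` — sizes chosen to mirror the co-culture experiments the
scenarios emulate while remaining a desk-scale computation. The number of
new topics is not a settled quantity for real data; 5 is the package
default, and a perplexity sweep on the interacting population is the
recommended way to revisit it.

Choices that were genuinely open, and how they were made:

* **Threshold conventions.** Published filter descriptions mix "fewer
  than n" (inclusive keep) and "more than n" (strict keep); both are
  implemented and named per profile (`preprocess_counts()`), with gene
  filtering before cell filtering by default (the order is switchable, and
  neither publication states it).
* **Sidedness of the association test.** Two-sided Mann-Whitney with a
  `direction` column, so cell-type-specific (higher) topics remain
  identifiable; correction is Benjamini-Hochberg jointly over all
  (topic, label) hypotheses — the more conservative of the options.
* **Argmax scope in the ranking.** The token-posterior argmax runs over
  all topics, and only wins by new topics count; a tie between a reference
  and a new topic goes to the reference. Restricting the argmax to new
  topics would inflate support for genes the reference explains perfectly
  well.
* **Fractional counts.** Injection increments such as +1.5 are stored
  exactly; the variational updates only need non-negativity. The binomial
  diagnostic ceils counts (a conservative tail). In the diagnostic, `n` is
  the cell's total count including the gene itself, with an exclude-self
  variant available.
* **FPR universe.** Recovery curves take the genes surviving
  preprocessing in the interacting matrix as the negative universe, and
  support an exclusion list for nominal false positives that are plausibly
  real interaction genes.

## Known limitations

* Topic-number misspecification in stage 1 contaminates stage 2 (see
  above); the package warns about nothing automatically — inspect the
  association table and the new-topic gene lists.
* The ranking is a support count, not a calibrated test; there is no
  p-value attached to "needs a new topic in `s` cells".
* The binomial diagnostic is motivational QC and does not feed the
  ranking.
* With a homogeneous injected signature, per-topic rankings are strongly
  correlated, so the union-of-top-N recovery cutoff saturates near the
  size of the injected set (visible in the 20-gene scenario).
* Droplet data without a clean reference population (labelled singlets)
  violates the core assumption; upstream doublet calling is treated as an
  external step, and a contaminated reference absorbs interaction signal
  into the frozen topics.
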