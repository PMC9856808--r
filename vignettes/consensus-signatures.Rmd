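---
title: "Consensus random-forest signatures: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus random-forest signatures: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what is being estimated, under which assumptions, which knobs matter, and
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The estimation problem

Given a gene × sample abundance matrix over many tumor entities and one
query ("target") gene, we want a ranked gene list that is *entity
independent* and characteristic of target overexpression — a transcriptional
fingerprint of the microenvironment in which the target is high, usable for
any target without retuning.

The pipeline decomposes into: dichotomization (per-entity z-scores),
consensus random-forest feature selection, validation (aggregated confusion
matrix, leave-target-out overlap), and characterization (correlation
panels, direction splitting, over-representation analysis).

## 2. Dichotomization

For target gene $g$ and entity $e$, sample $j$'s score is

$$ z_j = \frac{t(x_{gj}) - \bar t_e}{s_e}, \qquad t(x) = \log_2(x + 1), $$

with mean and **sample** standard deviation ($n-1$) taken over entity $e$'s
samples, and the label is *high* iff $z_j \ge 1.5$ (inclusive).

Open choices fixed here, all exposed in `zscore_config()`:

* **Transform.** Public cohort browsers compute mRNA z-scores on
  log-transformed values; that is the default, with `transform = "none"`
  available. The z-definition is a documented assumption, not a claim about
  any specific external service.
* **Reference population.** All samples of the entity (not a diploid
  subset); copy-number-aware referencing is a stated non-goal.
* **Boundary.** $z = 1.5$ exactly is *high*: a cut-off needs a fixed
  boundary convention for determinism.
* **Degenerate entities.** A single-sample entity, or zero spread, yields
  $z = 0$ for all its samples (never *high*) with a warning: no
  overexpression signal is definable there.

Under the generator below, within-entity z-scores of the target are
approximately standard normal, so the expected high fraction is
$1 - \Phi(1.5) \approx 6.7\%$ — the same few-percent positive class the
real pan-cancer analysis produced, and the regime in which accuracy alone
is misleading and F1/MCC are needed.

## 3. Consensus random forest

`rf_config()` defaults reproduce the published procedure: $M = 100$
models, each a 1000-tree forest trained on a random half of the cohort on
**raw unlogged abundance** (trees are invariant to monotone per-feature
transforms, so not logging loses nothing and preserves the stated input
scale), evaluated on the other half; per model the $K = 200$ genes with the
largest importances are kept; genes are ranked by occurrence across the
$M$ per-model lists. The signature is the top $K$ of that ranking.

### The forest implementation

No random-forest learner is available in the supported dependency set, and
the procedure is the package's core, so the forest is implemented in
`src/forest.cpp`:

* bagged classification trees, Gini impurity, grown to purity
  (`min_samples_split = 2`), `mtry = ⌊√p⌋` features per node;
* **importances** are mean-decrease-in-impurity: per tree, each split's
  node-mass-weighted impurity decrease is credited to its feature and the
  per-tree vector is normalized to sum 1; the forest importance is the
  per-tree average — the same semantics as the toolkit the original
  procedure used;
* **histogram splits**: each feature is quantile-binned (≤ 64 bins) on the
  training half once per model, and split search scans bin boundaries.
  This is the standard gradient-boosting-style acceleration; with ~500
  training samples per model, 64 quantile bins are effectively lossless
  for split quality, and thresholds are stored as raw values so prediction
  does not depend on the binning. Exactness of split *location* within a
  bin is the one approximation relative to an exhaustive CART scan;
* all randomness (bootstrap, feature subsampling) comes from an internal
  splitmix64 generator seeded per model, so a fit is bit-reproducible
  across platforms independent of R's RNG state.

### Open choices

* **Stratification.** The 50/50 splits are stratified by class by default.
  With 4–8 % positives an unstratified half can lose the positive class
  entirely; `stratify = FALSE` preserves the literal unstratified reading
  (with re-drawing on degenerate halves).
* **Seeds.** Model $i$ uses `seed + i`: reproducible, independent streams.
* **Ties.** At the per-model top-$K$ boundary, ties break by gene id; in
  the consensus ranking, by mean importance then gene id. Pure determinism
  conventions.
* **No class weighting.** The imbalanced fit is reported as-is; the
  accuracy ≈ class prior behaviour is part of the phenomenon the F1/MCC
  discussion addresses, not something to correct away silently.

### Validation

* **Aggregated confusion matrix.** Each sample is held out by roughly half
  the models; its final prediction is the majority vote over those models,
  ties to *rest* (the conservative call for a positive-minority problem).
  Majority voting is the only symmetric, model-count-independent
  aggregation when the underlying per-model matrix is not published.
  $F1$ and MCC follow their closed forms; degenerate conventions:
  $F1 = 1$ when $TP = FP = FN = 0$ (with warning), MCC $= 0$ on any zero
  denominator factor.
* **Leave-target-out overlap.** The label-defining gene trivially tops its
  own signature; deleting it from the feature matrix and re-running
  measures how much of the signature was genuine co-expression structure
  rather than self-selection. Reported as
  $|\text{original} \cap \text{rerun}| / K$.

## 4. The synthetic cohort: what it emulates, and what a green test means

`simulate_cohort()` draws, per sample $j$ with latent factor
$f_j \sim N(0,1)$,

$$ \log_2 x_{gj} = \mu + b_{e(j),g} + \lambda_g f_j + \varepsilon_{gj}, $$

exponentiated to the raw scale. $\lambda_g$ is `target_loading` (1.0) for
the target, `loading` (0.8) for the planted module, 0 for noise genes;
$b \sim N(0, \texttt{entity\_shift\_sd})$ once per (entity, gene);
$\varepsilon \sim N(0, \texttt{noise\_sd})$.

Default calibration cohort (fixed for acceptance, chosen so the full
pipeline runs in minutes on one CPU): 4 entities × 250 samples, 2000
genes, module 100, loading 0.8, noise sd 0.5. Parameters the source
material does not state were chosen once, on field realism, and not
revisited:

* `entity_shift_sd = 1.0` (log2): per-entity baselines spread by a factor
  of ~2 on average, exceeding within-entity noise (0.5) — the
  heteroscedastic "entity effects dominate" structure a pan-cancer
  consensus must see through;
* `base_log_mean = 4`: raw values around $2^4$, an FPKM-like scale on
  which $\log_2(x+1) \approx \log_2 x$, keeping the z-scores close to the
  generative model;
* miR arm: 300 features, planted module 20, same latent factor — a second,
  smaller feature space over identical samples.

The closed form used for testing follows from the single-factor model:
within an entity,
$r(\text{target}, \text{module gene}) = a\lambda / \sqrt{(a^2+\sigma^2)(\lambda^2+\sigma^2)}$.

**What the generator does *not* emulate:** count noise and library-size
effects, over-dispersion, batch effects, correlated noise between
non-module genes, copy-number confounding, multiple overlapping modules,
missing data. A green recovery/overlap test therefore establishes that the
machinery correctly extracts a planted single-factor module from
entity-structured log-normal data — not that it would recover biology from
any real cohort, which is exactly why the published headline numbers are
documentation examples rather than acceptance targets here.

## 5. Characterization stages

* **Correlation panels** (`entity_panel()`): per (entity, panel gene)
  Pearson (default) or Spearman correlation of the target, on raw values
  by default with a `log2p1` flag — published scatter axes suggest raw
  scale but never state it, so it is configuration. BH adjustment is
  applied jointly across all rows of a panel (the most conservative
  reading of per-entity significance claims); p-values use the two-sided
  $t_{n-2}$ form, Spearman via mid-ranks. Entities with $n < 3$ or zero
  variance yield flagged rows, not errors.
* **Direction split** (`split_signature_by_direction()`): *up* requires
  both a strictly larger mean in the high group and Kruskal–Wallis
  $p < 0.05$; mean-equal genes fall to *down*, keeping the partition
  exhaustive and deterministic.
* **Two-group tables** (`group_mean_test()`, `mir_group_table()`): raw
  group means ± sd with a Kruskal–Wallis p-value by default
  (Mann–Whitney and Welch available — the published tables do not name
  their test). An all-constant feature is defined to $p = 1$.
* **ORA** (`ora_table()`): upper-tail hypergeometric $P(X \ge k)$ per set,
  universe = the measured transcriptome (overridable) — the hypothesis is
  about genes the assay could have selected, not about a database's
  vocabulary. BH across sets with non-zero overlap only, matching common
  ORA tooling. Web-service enrichment scores are a stated non-goal; no
  external enrichment value is asserted anywhere.

## 6. Numerical and degenerate-input conventions

* Expression matrices reject missing, non-finite or negative cells at
  construction; no imputation rule exists downstream, so none is offered.
* TSV round-trips write 17 significant digits (value-identical reload).
* $p = 0$ from a perfect correlation is tolerated by `bh_adjust()` (the
  two-sided t tail underflows at $|r| = 1$).
* MCC is computed in double precision with the denominator in log space;
  counts near $10^4$ would overflow 32-bit intermediate products otherwise.
* Entity filtering (`align_cohort()`) is inclusive at the threshold
  ("at least 60 samples") and idempotent.

## 7. Known limitations

* The forest's histogram split search can pick a marginally different
  threshold than an exhaustive scan; importance *rankings* are the object
  of interest and are insensitive to this at the tested scales, but exact
  per-split equivalence with other implementations is not claimed.
* Majority-vote aggregation is one defensible reading of "one confusion
  matrix over all samples from 100 half-cohort models"; other readings
  (pooling all votes, averaging per-model matrices) would shift F1/MCC.
* The leave-target-out overlap depends on how stably the tail of the
  ranking (genes beyond the planted structure) reproduces; it rises with
  the number of models, so comparisons should fix `n_models`.
* Survival analysis, immune deconvolution, network clustering and
  identifier mapping are deliberately out of scope.
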