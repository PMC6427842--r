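---
title: "Models and methods in iltx"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in iltx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`iltx` analyses factorial transcriptome-and-phenotype experiments on
*C. elegans* introgression lines (ILs): panels in which a transgene —
the motivating case is α-synuclein::YFP in body-wall muscle — has been
introgressed from the reference strain N2 into several wild-isolate
backgrounds. This vignette documents the statistical models, the
assumptions behind them, every tunable default, and the choices made
where the design was genuinely open. It deliberately states no empirical
result beyond what the package's own test suite and
`scripts/acceptance.R` compute.

## The gene-wise factorial model

For each gene the package fits, by ordinary least squares,

$$ y = \beta_0 + \beta_{\mathrm{age}}\,(a - \bar a) + \beta_{aS}\,x_{aS}
   + \sum_g \beta_g\,x_g + \sum_g \gamma_g\,x_{aS} x_g + \varepsilon $$

with treatment coding against a declared reference (default N2, no
transgene), a centred continuous age covariate $a$, and $G-1$ genotype
and interaction dummies. The design matrix therefore has
$3 + 2(G-1)$ columns and `build_design_matrix()` refuses rank-deficient
designs (an empty genotype × transgene cell, a single transgene state,
or an age covariate without variation), naming the offending cell.

Per-term significance uses **Type II sums of squares**: each main effect
is tested by comparing the main-effects model with and without that term,
the interaction by comparing the full model to the main-effects model,
and every F uses the full model's residual mean square. On the balanced
default design Type I, II and III coincide (the suite asserts this on a
balanced fixture); Type II remains well defined for the unbalanced
tables that phenotype censoring produces, which is why it is also used in
`two_way_anova()`. The original tooling for such microarray designs could
have moderated variances empirically; `iltx` deliberately fits plain OLS
per gene, and the difference is that its F tests carry fewer residual
degrees of freedom but no shrinkage assumptions.

Degenerate inputs: a constant gene yields p = 1 for all terms with a
warning; in the zero-residual limit an effect with positive sum of
squares gets p = 0 (−log10 p = ∞) and one without gets p = 1, so
noiseless structural effects are recovered with overwhelming, not
undefined, significance.

## Permutation-derived significance threshold

The significance cutoff is chosen from the data. Each permutation
reassigns whole expression columns to the fixed sample metadata — one
shared permutation per iteration, so each gene's value multiset and all
gene–gene correlation are preserved while the sample-to-metadata link
(genotype, transgene, batch *and* the age covariate) is broken wholesale.
The model is refitted per permutation, and for each term and candidate
threshold $\tau$ (the sorted unique observed $-\log_{10} p$),

$$ \mathrm{ratio}(\tau) = \frac{\mathrm{FP}(\tau)}{\mathrm{TP}(\tau)}, $$

with FP the mean permuted exceedance count — the standard plug-in
empirical-FDR estimate (a median option exists for heavy-tailed nulls).
`select_threshold()` takes the smallest grid $\tau$ with ratio at or
below the target (default 0.05), either per term or as one global
threshold that must satisfy all terms simultaneously; both modes exist
because a single shared "for convenience" threshold and per-term
thresholds are equally faithful readings of common practice. Thresholds
where TP = 0 are skipped (the ratio is undefined), ties move together
because membership uses ≥, and "no qualifying τ" is an explicit result,
not an error. Defaults: 100 permutations, unrestricted scheme (a
within-batch scheme is available when batch structure must be respected).

`classify_genes()` then forms the four per-term significance sets and the
**aS-specific** set: transgene-significant genes that are neither age-
nor genotype-significant. Whether interaction-significant genes should
also be excluded from that set is ambiguous in the underlying designs;
the default keeps them and a flag flips the behaviour.

## Developmental age estimation

Class-I age-responsive marker genes increase linearly in log2 expression
during development inside a 46–54 h window; each marker's calibration is
a slope (log2/h, strictly positive) and an intercept at 46 h. The marker
list itself comes from prior literature and is treated as an input file;
the generator ships a synthetic stand-in. A sample's age is the
closed-form least-squares inversion across its markers,

$$ \hat a = 46 + \frac{\sum_m s_m (x_m - b_m)}{\sum_m s_m^2}, $$

i.e. unweighted inverse regression — the estimator is exact on noiseless
in-window samples and first-order unbiased under additive marker noise
(both checked by simulation). The regression direction and weighting of
the original procedure are not pinned down anywhere; this closed form is
one faithful reading, and inverse-variance weighting is the natural
extension if per-marker noise estimates exist. The standard error is the
marker-residual spread divided by $\sqrt{\sum s_m^2}$. Estimates outside
the open window are reported but flagged, since linearity is only
asserted inside it; fewer than 10 available markers triggers a warning.

Estimated age (not chronological time) feeds the expression model by
default, matching a design where all samples share one chronological age
and all age signal is developmental. Genes used as age markers are
retained in the differential tests by default — excluding them guards
against circularity and is available via the marker list.

## Introgression mapping

"A wild-isolate marker gene is missing in an IL" is operationalised as a
nearest-centroid rule: for marker $m$ and IL line $L$, compare the IL
mean to the wild-type centroid of its own background and to the N2
centroid; the score is the difference of the two distances and calls
within `margin_factor` (default 0.5) × centroid separation of the
midpoint are *ambiguous*. The underlying wording gives no numeric rule;
nearest-centroid with a margin is the minimal formalisation that still
leaves an explicit uncertainty class.

Intervals are maximal runs of at least `min_run` (default 3, guarding
against isolated miscalls) N2-like markers, ordered by genome position;
ambiguous calls neither break a run nor count toward its length, so runs
separated only by ambiguity merge deterministically and reported
intervals never overlap. Bounds are the outermost N2-like marker
positions, in 1-based Mb; flanking distances to the nearest
background-like markers quantify the uncertainty zone. The PCR-panel
variant (`interval_from_pcr_markers()`) spans first-to-last N2 call with
the uncertainty zone extended to the flanking background calls — the
panels cannot pin precise introgression boundaries, and the
representation makes that explicit rather than hiding it.

## Enrichment

Groups are defined by $-\log_{10} p$ > threshold (default 2) for a chosen
term. The enrichment p-value is the upper-tail hypergeometric probability
$P(X \ge k)$ computed directly from the distribution's definition with
log-binomial coefficients; the suite verifies exact agreement with
exhaustive enumeration for every configuration with $N \le 20$ and with
an independent library implementation at scale. The universe defaults to
all array genes carrying at least one annotation (the alternative, all
array genes, is exposed — which one the original analyses used is
unknowable from the outside, and the choice shifts every K and N).
Adjustment defaults to Benjamini–Hochberg; terms overlapping the group in
fewer than `min_overlap` (default 5) genes are excluded from the ranked
report but retained in the output. Enrichment only — no depletion — and
no GO-graph ancestor propagation: annotations are taken as given flat
sets.

## Phenotype and survival statistics

`two_way_anova()` fits `value ~ aS * genotype` with the same Type II
machinery as the expression model. `tukey_within_genotype()` runs Tukey
HSD over all genotype × transgene groups (studentized-range family) and
extracts the within-genotype wild-type vs transgenic contrasts — the
family is all pairs, so the adjusted p's are conservative for the five
contrasts of interest.

Survival uses the product-limit estimator and the log-rank test from the
`survival` package (the field-standard implementation), wrapped so that
bagging (matricidal hatching) and crawl-off are right-censoring events.
Mean lifespan is computed over death events only, matching the assay
bookkeeping in which censored worms leave the lifespan result. A
time-restricted log-rank ("first 20 days") is implemented as
administrative censoring at the bound — risk sets are preserved, deaths
after the bound become censorings — rather than subsetting deaths, which
would bias the risk sets. Whether a mean-lifespan comparison should run
as a t-test or within the Tukey family is left to the caller; both paths
exist. Bagging rates are compared by two-sided Fisher exact test on the
2×2 table (no test is canonical here; exact beats asymptotic at n = 100
per line), reporting the difference in percentage points.

## The synthetic-data generator

`simulate_expression_experiment()` realizes exactly the structural model
the analysis assumes: baseline + age slope × (age − 46) + background
offsets + transgene shift + background-specific transgene shifts +
i.i.d. Gaussian noise on the log2 scale. Defaults, chosen once to mirror
the emulated study design:

* 5 backgrounds (N2 + four wild isolates) × ± transgene × 3 replicates
  = 30 arrays, batches assigned replicate-wise; sampling at 48 h.
* Transgenic cells developmentally delayed 0.3–1.75 h (N2 least, JU1941
  most, JU1931 smallest among isolates), plus a deterministic
  replicate-level spread of ±0.25 h. The jitter reflects batch-wise
  growth differences and is also what identifies the age coefficient
  within cells: with purely cell-level ages the age covariate is an
  exact linear combination of the transgene and interaction dummies.
  All true ages stay inside the 46–54 h window where marker linearity
  holds; steeper delays (the emulated study reports up to ~2.5 h
  spread) are available by raising the sampling time.
* `noise_sd` 0.25 log2 units — a standard scale for log-intensity
  microarray data; no empirical noise estimate exists to copy.
* Effect sets: 300 age genes (slopes 0.1–0.5 log2/h in magnitude, the
  50 calibration markers strictly positive), 200 genotype genes
  (offsets N(0,1) per background), 100 transgene genes (±1 log2 = 4
  noise sd), 60 interaction genes (N(0,1) per background). Sets are
  disjoint so the truth table is unambiguous.
* Wild-isolate marker genes every 0.5 Mb along chromosomes IV and V,
  2 log2 units below their N2 level in wild backgrounds, reset to the
  N2 level inside each IL's introgressed block (IV: 4.2–13.2 Mb in
  every IL; an extra block V: 2–6 Mb in JU1931). Marker genes are
  thereby *genuinely* transgene-responsive in the ILs — calibration
  runs that need a pure "5% aS effects" truth exclude them.

Phenotypes are genotype mean + transgene shift + interaction shift, with
development time Gaussian and pumping/thrashing counts Poisson around the
structural mean (hence integer and non-negative by construction);
lifespans are Weibull per cell with per-genotype transgene scale ratios,
bagging with configurable probability and times drawn from the
reproductive window, crawl-off likewise. The phenotype and survival
variance defaults are **placeholders** — no empirical estimates exist in
the underlying material — with the qualitative pattern (strongest
transgene effects in JU1941/JU1926, weakest in N2/JU1931, elevated
bagging in transgenic wild isolates) wired into the default shift
vectors.

What the generator does *not* emulate: probe-level and dye/channel
structure, spatial array artefacts, heavy-tailed or gene-dependent noise,
correlated gene modules beyond the shared design, linkage between the
phenotype and expression layers beyond shared design parameters, and
age-dependent censoring competition. Passing tests therefore show the
pipeline is correct and calibrated *under its own structural
assumptions*; they cannot show robustness to the ways real arrays
violate them.

## Numerical choices

* Negative sums of squares from floating-point cancellation are clamped
  at 0; p-values are computed on the log scale (`pf(log.p = TRUE)`) so
  −log10 p is accurate far beyond `.Machine$double.xmin`.
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive; scores are otherwise
  sign-indeterminate. PCA requires the mean-ratio scale, enforced by a
  double-centring guard on `mean_ratio_transform()`.
* Result TSVs serialise doubles with 17 significant digits, so
  write → read is value-identical.
* Every stochastic stage takes an explicit seed and restores the
  caller's RNG state; the pipeline derives all stage seeds from one
  run seed, making end-to-end output byte-identical under a fixed seed.

## Problem sizes in the test suite

The calibration checks run at the study's design scale: empirical-FDR
calibration over 50 simulated experiments of 2000 genes × 30 samples
with 100 permutations each; null uniformity on 1000 pure-noise genes;
effect recovery over 100 seeds; age recovery over 100 seeds with 50
markers; introgression recovery over 100 seeds at 0.5 Mb marker spacing;
log-rank size over 500 simulated assays of 100 worms per group with 15%
bagging. Module tests use smaller instances of the same generators.

## Known limitations

* One expression row per gene is assumed; probe-to-gene collapsing and
  array normalization are upstream of this package.
* The aS main-effect test averages over backgrounds, so a
  background-specific response with zero mean loads on the interaction
  term only; interpret the aS and interaction sets jointly.
* The FP/TP ratio is a plug-in FDR estimate; at very small TP it is
  noisy, which is why ratios are only evaluated on the observed grid and
  undefined-TP thresholds are skipped.
* Cox models, frailty, and competing-risk treatments of bagging are out
  of scope; bagging is censoring for lifespan and a phenotype in its own
  right, nothing more.
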