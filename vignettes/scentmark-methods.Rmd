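---
title: "Methods: attributing and discriminating individual nest scent marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing and discriminating individual nest scent marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentmark)
```

## The scientific problem

Solitary cavity-nesting bees such as *Osmia cornuta* mark their nest
entrance with a volatile bouquet and use that smell to verify the nest on
every return flight. The raw observations are GC/MS peak-area tables: for
each nest, two sequentially collected entrance sleeves ("marks"), one head
extract (cuticular hydrocarbons plus head-gland secretions) and one
Dufour's gland extract, together with control sleeves that were exposed to
ambient conditions but never nested. Three questions drive the analysis:

1. **Which substances in a mark come from the bee?** Marks mix Dufour's
   gland secretion, compounds rubbed off the body surface, and substances
   picked up from the environment (nest material, floral residues).
2. **Are marks individually distinctive?** Marks from the same nest should
   be more similar than marks from different nests.
3. **Do marks resemble their maker?** A bee's gland extract, or an
   estimated "total bee bouquet", should be closer to its own marks than to
   foreign ones.

`scentmark` implements the full analysis as a reusable, seeded pipeline,
plus a generative model of the whole study design so every statistical
property of the pipeline can be exercised without any instrument data.

## Data model and preprocessing

Peak areas are arbitrary-unit, strictly positive quantities spanning
several orders of magnitude, and only relative proportions carry meaning
(compositional data). The pipeline therefore:

* **filters substances** (`filter_substances()`): a compound must be
  present (area above a threshold, default "any positive area") in *every*
  sample of the analysis set, and must not be background. Background is
  operationalized through the control sleeves: a compound whose mean area
  in control/blank samples reaches its mean in the analysis samples is
  dropped. The original study exposes control sleeves without stating how
  they entered the analysis; the mean-comparison screen is our
  conservative operationalization, and every drop is logged per compound.
* **screens for private substances** (`detect_private_substances()`): a
  compound seen in only one bee's samples would make individual
  recognition trivial; the screen reports any such compound per bee. With
  a single bee in a table every present compound is trivially "private" —
  a documented degenerate case.
* **quantile-normalizes** samples (`quantile_normalize()`): rank-based
  replacement by mean order statistics removes non-linear per-sample
  intensity bias (extract amount, body size). Ties receive the mean of the
  reference values at the tied ranks. On continuous data the procedure is
  idempotent and equalizes the sorted value multisets of all samples; with
  ties the group-mean convention can leave multisets slightly unequal — a
  property of any tie-averaging variant.
* **applies the centered log-ratio transform** (`clr_transform()`):
  `clr(Y_ij) = ln(Y_ij / g(Y_j))` with `g` the per-sample geometric mean.
  Rows sum to zero and the result is invariant to per-sample scaling,
  which (together with quantile normalization) neutralizes the simulated
  intensity factor exactly. Zeros are a hard error by design: positivity
  must come from the substance filter, and no pseudo-count is ever applied
  silently.

The fixed order — filter, then quantile-normalize, then clr — follows from
clr's positivity requirement. Normalization is applied jointly across all
samples of the set being compared (marks only; gland extracts plus marks;
bouquets plus marks). Whether joint or per-source normalization is more
appropriate when two sources enter one comparison is genuinely open; joint
is the default because the subsequent distance computation assumes one
common scale.

## Source attribution

Attribution works on the compound universe "present in marks and in at
least one bee extract", with every involved sample scaled to the same
peak-area sum (`total_sum_scale()`). Total-sum scaling, not quantile
normalization, is used here deliberately: it preserves mixing proportions
exactly, so a mark that truly is a weighted sum of bee sources remains one
after normalization (this exactness is also what the synthetic recovery
tests assert).

Three rules, all thresholds exposed as parameters:

* **Kovats band** (`dufour_band_selection()`, `band_k = 2`): the log
  quotient of mean mark area over mean gland area is regressed on the
  compound's Kovats retention index (a volatility proxy — more volatile
  compounds deplete faster from marks, giving a slowly ascending line).
  Compounds whose internally studentized residual exceeds the band were
  enriched by other sources and leave the gland-related analysis. The
  single-pass ±2 band on the log scale is our operationalization; log
  because quotients are ratios, single-pass to keep the rule transparent.
* **Exogenous filter** (`exogenous_filter()`, threshold 2): a compound
  more than two-fold enriched in marks relative to the *sum* of its head
  and gland means is discarded as environmental. The inequality is strict
  ("more than two-fold" verbatim); compounds with no bee source at all are
  discarded with an explicit `no_bee_source` reason.
* **Contribution factors** (`contribution_factors()`, threshold 2): for
  each retained compound the larger-to-smaller ratio of head and gland
  means decides between a proportional contribution of both sources
  (ratio ≤ 2, factors (1, 1)) and a dominant single source (factor 1 for
  the larger, 0 for the smaller). The proportional case is implemented as
  plain summation because no weighting scheme is defined anywhere;
  r-dependent weights would be an alternative but are not implemented.
  The empirical ratio distribution is exported (`source_ratio`) so users
  can check the expected sharp peak between one and two.

The estimated individual bouquet of a bee is then
`factor_head * head + factor_gland * gland` per compound
(`estimate_bee_bouquet()`).

## Similarity analysis

The compound space is collapsed by PCA on the correlation matrix,
retaining every eigenvalue strictly greater than 1 (Kaiser rule; if none
qualifies the largest is kept with a warning). Factor scores are
standardized to unit variance — for full principal components the
regression-method score estimator coincides with standardized component
scores, which is the reading implemented. Dissimilarity is the squared
Euclidean distance (SED) between score vectors; small values mean similar
samples.

Pairs are labelled same/different by nest identity: all within-group pairs
for mark-vs-mark (for 25 nests × 2 sleeves: 1225 pairs, 25 same-nest),
all cross-group pairs for gland-vs-mark and bouquet-vs-mark (25 × 50 =
1250 pairs, 50 same-bee). Extreme isolated SED values are pruned at the
conventional extreme-outlier fence Q3 + 3·IQR (type-7 quartiles, pooled
over classes) before testing; the pruning rule in the original analysis is
unstated, so fence and quartile convention are explicit parameters here.

The test is a binomial-logit GLM of the pair label on SED, fitted by
maximum likelihood (IRLS, convergence 1e-12), reporting the Wald
chi-square for the SED coefficient. Complete separation — possible on toy
data that is "too clean" — is detected and refused rather than reported as
a huge meaningless Wald value.

## The synthetic data generator

`simulate_dataset()` draws the exact study design: per bee a latent gland
and a latent head bouquet (panel source means times per-compound
log-normal deviations, SD `sigma_individual = 0.40`), marks mixed as
`0.30·gland + 0.15·head + 0.55·environment`, a second sleeve additionally
perturbed by temporal drift (`sigma_drift = 0.15`), per-sample log-normal
intensity factors (`sigma_intensity = 0.50`) and per-cell measurement
noise (`sigma_noise = 0.10`). Control sleeves carry the environment
profile at a low ambient level (`control_level = 0.05` of the profile).
All noise is multiplicative because observed peak areas span five orders
of magnitude; log-normal noise keeps positive support and a scale-free
coefficient of variation.

The 59-compound panel (`default_compound_panel()`) is calibrated so the
class proportions per source match the reported chemistry: gland extracts
dominated by alkenes (~78.7%), head extracts ~37.1% alkanes / ~60.0%
alkenes, and marks ~44.7% alkanes, ~39.8% alkenes (double bonds mostly in
position 7, 7-pentacosene dominant), ~9.1% aldehydes, ~0.5% esters.
The environment profile is *defined* as the residual a mark mixed at the
reference weights needs to hit the mark targets exactly — mostly
plant-wax-like alkanes plus the mark-only aldehydes (and two mark-only
alcohols) that carry an `environment` ground-truth label. Ten compounds
are environmental by this construction, so the default estimated bouquet
has 49 compounds. Mixing weights and variance defaults are fixed study
conditions of the generator, chosen once as realistic for cuticular
hydrocarbon data (among-individual coefficients of variation of roughly
30–50% are typical); `sigma_drift` in particular is a free parameter —
no quantitative drift magnitude is available to estimate it from.

What the generator deliberately does **not** emulate: chromatographic
reality (co-elution, retention-time jitter, detector saturation),
compound-compound correlation beyond the class structure, seasonal or
age effects, and any non-multiplicative noise. Passing recovery tests
therefore show that the pipeline's statistics behave correctly under the
generative assumptions, not that real data satisfies those assumptions.

## Numerical choices and degenerate inputs

* CSV areas are written with 15 significant digits so write→read
  round-trips agree to well below 1e-12 relative error.
* UPGMA (`upgma_cluster()`) is average linkage on raw distances; merge
  heights equal the average pairwise distance between the merged clusters,
  and labels are pre-sorted so ties break deterministically.
  `sort_dendrogram()` places the subtree with the smaller minimum merge
  height first (bare leaves count as height 0), ties by smallest leaf
  label — one fixed convention out of several possible dendrogram
  seriation rules.
* Heatmap distance between samples is the Euclidean distance on the
  normalized clr values (the named heatmap tool's default metric).
* Under an exact null (`sigma_individual = 0`) quantile normalization can
  quantize a compound's ranks to a constant column, making the correlation
  matrix undefined; PCA then stops with an error naming the compound
  rather than silently dropping it.

## A worked example

```{r example, eval = FALSE}
res <- run_pipeline(pipeline_config(
  simulation = simulation_config(seed = 11),
  out_dir = "scentmark_run"))
print(res)
```

On the default design this reports 59 of 59 substances retained, no
private substances, the 1225/25/1200 mark-pair design, same-nest median
SED below the different-nest median with a Wald p-value far below 0.05,
and 49 bouquet compounds after the exogenous filter discards the ten
environmental ones.

## Validation strategy and known limitations

The test suite checks every statistic against an independent oracle
(brute-force SED, direct eigendecomposition for the PCA, a hand-rolled
Newton–Raphson maximum-likelihood fit for the Wald GLM, brute-force
average distances for UPGMA), verifies the transform invariants over
hundreds of random instances, and runs replicate studies on synthetic
ground truth: exogenous-compound recovery (sensitivity and specificity
1.0 at five-fold enrichment over 50 replicates at the default noise
level) and discrimination recovery (the same-nest-more-similar finding
with Wald p < 0.05 in 100% of 100 replicates at default signal). Replicate
studies use the full 25-bee design; oracle and invariant tests use small
matrices (6–20 samples) where brute force is exact.

Two limitations deserve emphasis:

* **The pairwise GLM is not a calibrated test.** All C(50, 2) = 1225 SED
  values derive from 50 samples, and the GLM treats them as independent
  observations. Under a true null (no individual signal) the Wald test
  rejects in about 0–1% of replicates instead of the nominal 5% — strongly
  conservative, so the *positive* findings are not inflated by the
  pseudo-replication, but reported p-values should not be read as
  calibrated error rates. A permutation test over bee labels would be the
  calibrated alternative; it is out of scope here because the package
  reproduces the published analysis.
* **Attribution thresholds are conventions.** The two-fold rules and the
  ±2 residual band are transparent but arbitrary cut-offs; all are
  parameters, and the exported ratio/residual distributions let users
  judge their placement on real data.
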