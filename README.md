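# scentmark

Source attribution and individual discrimination of solitary-bee nest
scent marks from GC/MS peak-area tables.

Female cavity-nesting bees (e.g. the mason bee *Osmia cornuta*) mark
their nest entrance with a volatile bouquet and re-identify the nest by
its smell. The raw data of such a study are wide-format GC/MS peak-area
tables over compounds (long-chain alkanes, alkenes, esters, aldehydes,
alcohols, methyl-branched alkanes) for several sample types per nest: two
sequential entrance-sleeve extracts ("marks"), a head extract
(cuticle + head glands), a Dufour's gland extract, and unnested control
sleeves. `scentmark` implements the complete analysis chain for these
data, plus a generative model of the whole study design so the pipeline
can be exercised and validated end-to-end without instrument data.

## The analysis

For compositional peak-area data `Y` (samples × compounds) the pipeline
computes, in order:

1. **Substance filter** — keep compound *i* iff `Y_ji > t` for every
   analysis sample *j* (default `t = 0`) and the compound is not
   attributable to background (control-sleeve mean ≥ analysis mean), with
   a per-compound screen for "private" substances seen in a single bee
   only (`filter_substances()`, `detect_private_substances()`).
2. **Quantile normalization** — rank-based replacement by mean order
   statistics across samples, removing per-sample intensity bias
   (`quantile_normalize()`).
3. **Centered log-ratio transform** — `clr(Y_ij) = ln(Y_ij / g(Y_j))`,
   `g` the per-sample geometric mean (`clr_transform()`).
4. **Source attribution** — on samples scaled to equal peak-area sums:
   OLS of `ln(mark mean / gland mean)` on the Kovats retention index with
   a ±2 studentized-residual band (`dufour_band_selection()`); discard of
   compounds more than two-fold enriched in marks over head + gland
   (`exogenous_filter()`); head/gland contribution factors from the
   larger-to-smaller source ratio *r* — proportional `(1, 1)` for
   `r ≤ 2`, dominant-source otherwise — and per-bee estimated bouquets
   `f_h·head + f_g·gland` (`contribution_factors()`,
   `estimate_bee_bouquet()`, all wrapped by `attribute_sources()`).
5. **Similarity analysis** — PCA on the correlation matrix keeping
   eigenvalues > 1, unit-variance factor scores; squared Euclidean
   distances `SED(a,b) = Σ_f (s_af − s_bf)²`; same/different-nest pair
   labelling; pruning of extreme SED values beyond `Q3 + 3·IQR`; and a
   binomial-logit GLM of pair label on SED with the Wald chi-square
   `W = (β₁/se₁)²` (`pca_factor_scores()`, `sed_matrix()`,
   `label_pairs()`, `prune_outliers()`, `wald_glm()`).
6. **Reporting** — UPGMA (average-linkage) clustered heatmaps with
   smallest-first sorted dendrograms and the count of nests whose two
   tags sit on adjacent leaves (`upgma_cluster()`, `sort_dendrogram()`,
   `tag_adjacency()`, `render_heatmap()`).

`simulate_dataset()` generates the default study design — 25 bees × {2
mark sleeves, head, gland} + 3 control sleeves over a 59-compound panel —
with per-bee log-normal individual signatures, between-sleeve drift,
intensity factors, measurement noise, and ground-truth source labels for
every compound (`default_compound_panel()`, `truth_source_labels()`).

## Worked example

```r
library(scentmark)
res <- run_pipeline(pipeline_config(
  simulation = simulation_config(seed = 11),
  out_dir = "scentmark_run"))   # out_dir optional
print(res)
```

```
scentmark pipeline run
  samples: 103  compounds retained: 59 / 59
  marks: 20 factors (83.15%), n = 1225, W = 21.485, p = 3.566e-06
    median SED same = 27.159 (n = 25), different = 40.326 (n = 1200)
  gland-vs-marks: 12 factors (78.39%), n = 1250, W = 52.420, p = 4.481e-13
    median SED same = 20.427 (n = 50), different = 31.327 (n = 1200)
  bouquet-vs-marks: 16 factors (78.65%), n = 1250, W = 68.934, p = 1.018e-16
    median SED same = 24.451 (n = 50), different = 38.008 (n = 1200)
  nests with adjacent tags in the mark dendrogram: 5
```

Reading the output: all 59 panel compounds pass the substance filter (no
private substances); the 50 mark sleeves form 1225 pairs of which the 25
same-nest pairs have a clearly lower median SED than the 1200
different-nest pairs (marks are individually distinctive, Wald p ≪ 0.05);
gland extracts and estimated bee bouquets are likewise closer to their own
bee's marks than to foreign ones; and, as in real data, same-nest tags
only occasionally end up as neighbouring dendrogram leaves. The
attribution stage (in `res$attribution`) discards the ten
environment-derived compounds, leaving a 49-compound estimated bouquet.
With `out_dir` set, the run directory holds the input CSVs + ground
truth, the filter report, SED matrices, the clustered heatmap with its
leaf-order TSV, a summary JSON and a run log.

A thin command-line wrapper is installed at
`inst/cli/scentmark.R` (`Rscript .../scentmark.R simulate|run --seed 42
--out DIR [--config sim.yaml]`).

The methods vignette (`vignettes/scentmark-methods.Rmd`) documents the
model assumptions, parameter conventions, what the generator does and
does not emulate, and known limitations of the pairwise-GLM design.

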