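# gmetkit

Quality-control-driven processing of untargeted (global) LC-MS
metabolomics feature tables, for analysts running large plate-based plasma
studies — cohort or clinical — where two things routinely go wrong before
any biology is measured: the instrument's per-feature sensitivity drifts
within and between 96-well plates, and whole-blood specimens sit at
ambient temperature before plasma separation, reshaping the metabolome.

The package provides, end to end:

* **RQC drift normalization** — a reference plasma (RQC) brackets every
  block of eight study injections; between two *reliable* RQCs (fewer than
  1,000 undetectable features each) the sensitivity is assumed to drift
  linearly and every intensity is corrected by

  `y = x_n * M1 / ( n (M2 - M1) / (S + 1) + M1 )`

  with `M1`, `M2` the feature's intensities in the flanking RQCs, `n` the
  position between them and `S + 1 = 9` for the canonical 8-study block.
  A `literal` mode applies the equation verbatim per segment; the default
  `anchored` mode additionally rescales every segment to the first
  reliable RQC, making intensities comparable across segments and plates.
* **QC feature filtering** — SQC (pooled study sample) repeatability CV
  over 30% eliminates a feature; the dQC dilution series (2/4/8/16-fold)
  must respond inversely and reproducibly; C18 features above m/z 950 and
  HILIC features above m/z 700 are discarded. Every removal is accounted
  for with reason codes.
* **Plasma quality scoring** — a packaged panel of 40 storage-time marker
  metabolites (lysophospholipids, dipeptides, fatty acids, succinic acid,
  amino acids, glucose, uric acid, ...) with power / linear / logarithmic
  trendlines over hours at 25 °C. Each marker scores
  `P_k = (100/40) * (NLA_k(48h) - NLA_k(sample)) / NLA_k(48h)` and the
  summed score triages samples at the 85-point threshold.
* **OPLS-DA marker discovery** — two-class orthogonal projections to
  latent structures, S-plot covariance/correlation loadings, selection at
  `|p(corr)[1]| > 0.7`, and t-test / fold-change candidate ranking.
* **A synthetic-data generator** — plate layouts, QC-intercalated run
  orders, piecewise-linear multiplicative drift with plate jumps,
  lognormal noise and donor effects, dilution-responsive QCs and
  trendline-driven storage series, all with ground truth, so every claim
  above is testable.

## Worked example

```r
library(gmetkit)

# three plates, 3 donors x 8 replicates each, 30% drift + plate jumps,
# 5% multiplicative noise
cfg <- sim_config(n_plates = 3, n_study_per_plate = 24, n_features = 100,
                  n_donors = 3, drift_amplitude = 0.3, plate_jump = 0.3,
                  noise_cv = 0.05, seed = 1)
sim <- simulate_intensities(cfg)
sim$table
#> feature_table: 100 features x 118 injections
#>   roles: dQC=12, RQC=12, SQC=22, study=72
#>   plates: P1, P2, P3
#>   missing cells: 0 (0.0%)

norm <- normalize_table(sim$table, threshold = 0.5, mode = "anchored")
norm$report
#> normalization_report (anchored mode): 11 segment(s)
#>   unreliable RQCs: 0; fallback (segment, feature) pairs: 0; raw pairs: 0
#>   uncovered injections: 25

filt <- apply_all_filters(norm$table, filter_config())
filt$report
#> filter_report: 100 of 100 features retained
#>   removal reasons: sqc_cv=0, dqc_cv=0, dqc_monotonicity=0, mz_cap=0
```

The 25 uncovered injections are the ten conditioning SQCs and the closing
dilution series, which lie outside the RQC-bracketed part of the sequence
and pass through unchanged. After anchored normalization the median
replicate CV collapses from ~23% (drift-dominated) to ~6%, just above the
injected 5% noise.

Scoring a simulated whole-blood storage series (6 donors, 4 °C vs 25 °C,
0–48 h) with the packaged marker panel:

```r
storage <- simulate_storage_series(sim_config(seed = 2), load_marker_table(),
                                   n_null_features = 50)
nt <- normalize_table(storage$table, threshold = 0.5)$table
scores <- score_samples(nt, mode = "direction_aware")
aggregate(scores$score, list(condition = sub("^D[0-9]+_", "", scores$sample_id)),
          function(x) round(mean(x), 1))
#>  condition    x
#>      4C_3h 64.4
#>     4C_12h 64.3
#>     4C_24h 64.3
#>         T0 64.3
#>     4C_48h 64.2
#>      4C_6h 64.2
#>     25C_3h 56.2
#>      25C_6h 49.4
#>    25C_12h 37.7
#>    25C_24h 24.8
#>    25C_48h -4.3
```

Properly handled samples (immediate processing or 4 °C storage) score
alike regardless of storage time, while 25 °C exposure degrades the score
monotonically — by 48 h the sample sits at the degraded reference and
scores near zero.

A thin command-line wrapper is installed as `exec/gmet`
(`gmet simulate|normalize|filter|fit-trendlines|score|select|run ...`),
and `run_pipeline()` drives the whole chain from a YAML configuration.

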