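---
title: "QC-driven processing of untargeted LC-MS metabolomics data with gmetkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC-driven processing of untargeted LC-MS metabolomics data with gmetkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmetkit)
```

## The problem

Untargeted ("global") LC-MS metabolomics quantifies thousands of features —
(m/z, retention-time) pairs with one intensity per injection — without
preselecting targets. Two pre-analytical problems dominate data quality in
large plate-based studies:

1. **Instrument sensitivity drift.** The per-feature response of the
   instrument changes over a sequence of injections, within a 96-well plate
   and abruptly between plates. Uncorrected, plate-of-origin rather than
   biology dominates the first principal components.
2. **Specimen handling.** Whole-blood EDTA specimens left at ambient
   temperature before plasma separation change composition rapidly —
   lysophospholipids, dipeptides and fatty acids accumulate while glucose,
   uric acid and some amino acids are consumed — so a plasma sample's
   metabolome reflects its handling history as much as its donor.

`gmetkit` implements a QC-centred processing protocol for both problems,
plus a synthetic-data generator that reproduces the statistical structure
the protocol assumes, so every step can be exercised with known ground
truth.

## QC design

Three kinds of quality-control injections are intercalated with the study
samples of each 96-well plate (wells A1–H11 carry up to 88 study samples):

* **SQC** (study QC): a pooled mixture of all study samples on the plate.
  Ten consecutive SQC injections condition the column at the head of the
  sequence; one SQC follows every block of eight study injections.
* **dQC** (dilution QC): 2-, 4-, 8- and 16-fold dilutions of the SQC,
  injected three times each at the end of the sequence (order d16, d8, d4,
  d2, then a closing SQC triplet).
* **RQC** (reference QC): a commercial reference plasma, injected so that
  every block of eight study injections is bracketed by two RQCs.

`make_plate_layout()` and `make_run_order()` emit exactly this design.

## Drift normalization

An RQC injection is *reliable* when fewer than 1,000 of the features are
undetectable in it (missing or zero; the absolute threshold can be given
as a fraction of the feature count for small tables). Between two
neighbouring reliable RQCs the per-feature sensitivity is assumed to drift
linearly, and every intensity in between is corrected by

$$ y = x_n \, M_1 \left( \frac{n\,(M_2 - M_1)}{S + 1} + M_1 \right)^{-1} $$

where $x_n$ is the intensity at position $n$ after the left RQC, $M_1$ and
$M_2$ are the feature's intensities in the left and right RQC, and $S$ is
the number of injections between them — the canonical block of eight study
injections gives the divisor 9. `normalize_table()` interpolates in
run-index space, so the divisor generalizes automatically to segments
lengthened by the exclusion of an unreliable RQC, and a sensitivity that
really is piecewise linear in run order is removed *exactly* (the test
suite asserts agreement with the algebraic ground truth to a relative
$10^{-9}$).

Two output scales are provided, because the correction equation alone
leaves a per-segment anchor ambiguity:

* **literal** — each segment is anchored to its own left RQC, the equation
  verbatim;
* **anchored** (default) — each segment is additionally rescaled per
  feature by $M_1^{\mathrm{first}}/M_1^{\mathrm{segment}}$, putting every
  segment and plate on the scale of the first reliable RQC of the
  sequence. After anchored normalization every reliable RQC equals the
  first RQC per feature, which the package uses as a self-test. Anchored
  is the default because the protocol's purpose is correcting intra- *and*
  inter-plate variation.

When a feature is unquantified in a flanking RQC, the nearest reliable RQC
on the same side in which it *is* quantified is substituted as the
interpolation node; if no such RQC exists on one side, the feature is left
raw for that segment. Both events are counted in the normalization report.
Injections before the first or after the last reliable RQC (the
conditioning SQCs and the closing dQC series) pass through unchanged and
are flagged as uncovered. Missing cells stay missing, and no negative
intensity can be produced.

## Feature filtering

`apply_all_filters()` composes three pure predicates and accounts for
every removal with reason codes:

* `sqc_cv` — the CV (sample standard deviation over mean) across the
  eligible SQC injections exceeds 30%. The rule is strict ("over 30%"): a
  feature exactly at the threshold survives. The ten conditioning SQCs are
  excluded, since repeatability stabilizes only over the serial initial
  injections.
* `dqc_cv` / `dqc_monotonicity` — the dilution series must respond: the
  CV within each fold's replicate triplet must not exceed 30%, and the
  mean intensity must decrease strictly over folds 1, 2, 4, 8, 16 (fold 1
  is the closing SQC triplet). A Spearman-correlation variant
  (`monotonicity_rule = "spearman"`, requiring $\rho = -1$) is equivalent
  on five complete levels and provided for symmetry with practice.
* `mz_cap` — features above m/z 950 (C18 assays) or m/z 700 (HILIC
  assays) are treated as probable noise or column contaminants. Both caps
  are exclusive and configurable; the HILIC cap in particular is reported
  inconsistently in practice (700 vs 900), so it is a plain parameter.

Filters run on normalized intensities (filtering follows normalization in
the pipeline) and are order-independent; the report satisfies
retained + removed = total with at least one reason per removal.

## Storage-time trendlines and the quality score

Forty plasma metabolites whose abundance changes systematically with
whole-blood storage time at 25 °C are packaged with their fitted
trendlines — power $y = ax^b$, linear $y = ax + b$, or logarithmic
$y = a\ln x + b$ — as `load_marker_table()`: 10 HILIC-positive, 15
HILIC-negative, 10 C18-positive and 5 C18-negative markers; 30 increase
with storage and 10 decrease. `fit_trendline()` fits each law by ordinary
least squares (the power law in log–log space, back-transformed), always
reporting $R^2$ in the original y space so the kinds are comparable;
`select_trendline()` picks the best kind, breaking near-ties in the order
linear < logarithmic < power.

Two transcription quirks of the source panel are preserved explicitly: the
Uric acid row pairs a "logarithmic" label with a linear-form equation, and
the Ribonic acid row a "linear" label with a log-form equation. Numerical
evaluation always follows the equation's form; the `variant` argument
selects whether the reported kind keeps the original labels
(`"as_printed"`) or matches the equations (`"swap_corrected"`). Refitting
noiseless points from every packaged equation therefore recovers all 40
coefficient pairs to six significant figures but the *labelled* kind for
only 38 of 40 — exactly the two quirk rows.

Each marker contributes points

$$ P_k = \frac{100}{40} \cdot
   \frac{\mathrm{NLA}_k(48\,\mathrm{h}) - \mathrm{NLA}_k(\mathrm{sample})}
        {\mathrm{NLA}_k(48\,\mathrm{h})} $$

relative to the 48-h degraded reference, and the quality score sums them
over the four assay groups; a sample passes at **85 points or more** (the
boundary is inclusive at 85, since the published wording leaves the exact
point undefined). A sample sitting exactly at the 48-h reference scores 0;
a sample in which every marker is absent scores 100. When fewer than 40
markers are matched, the factor rescales to $100/n$. Each $P_k$ is clamped
to $[-100/n, +100/n]$.

Decisions taken where the design was genuinely open:

* The literal $P_k$ (the published rule) is the default. It penalizes
  *fresh* samples on decreasing markers — glucose above its 48-h level
  drives $P_k$ negative — which conflicts with the intent that high scores
  mean high quality. `mode = "direction_aware"` flips the sign for
  decreasing markers; on simulated storage series the direction-aware
  score is monotonically non-increasing in storage time, which is asserted
  over 20 seeded replicates.
* The default reference $\mathrm{NLA}_k(48\,\mathrm{h})$ is the trendline
  value at 48 h, floored at 1 intensity unit: one marker's steep linear
  decline (Tetradecanedioic acid) extrapolates past zero well before 48 h,
  and a measured abundance reference cannot be negative. A measured mean
  may always be supplied instead.
* Control (0 h) points are excluded from power and logarithmic fits, where
  $\ln 0$ is undefined.
* The score treats sample NLAs on whatever scale the references are on;
  the published panel is described "in the log scale" in one place and
  used linearly in another, and the package does not second-guess the
  caller's scale.
* The four assay-group sums are taken from the panel's block sizes
  (HP = 10, HN = 15, CP = 10, CN = 5); the published score formula labels
  two different sums with the same group abbreviation, which is treated as
  a typographical slip.

## Marker discovery

`pca()` (via `stats::prcomp`) visualizes run structure; `opls_da()`
implements two-class orthogonal projections to latent structures: the
orthogonal-projection step deflates y-orthogonal variation before a single
predictive component is extracted, so with zero orthogonal components the
model reduces exactly to PLS1 (the test suite checks the predictive score
against an independent PLS implementation). Pareto scaling — mean
centering and division by the square root of the standard deviation — is
the default, the convention of the commercial multivariate tools used in
this field; unit-variance and centre-only scaling are available.

`s_plot()` computes, per feature, the covariance $p[1]$ and Pearson
correlation $p(\mathrm{corr})[1]$ between the (scaled, centred) feature
vector and the predictive score; `select_by_pcorr()` keeps features with
$|p(\mathrm{corr})[1]| > 0.7$ (strictly; 0.55 is the relaxed variant for
weaker contrasts). No $p[1]$ magnitude cut is applied by default — the
repeatability and dilution filters have already removed unreliable
features, which is what makes the pure-correlation rule workable; an
optional cut can be imposed by the caller on the returned points.
`rank_candidates()` orders features by two-sample t-test p-value (Welch by
default; pooled-variance Student's available for faithfulness to the
published analysis), then by descending |log fold change|.

## The synthetic-data generator

`simulate_intensities()` and `simulate_storage_series()` emit the exact
plate layout and run order above, with:

* per-feature multiplicative sensitivity surfaces, piecewise linear in run
  index between RQC nodes, with node-to-node changes up to
  `drift_amplitude` (default 30%) and an extra `plate_jump` (default 30%)
  discontinuity at plate boundaries — the drift model the normalization
  assumes, which is what makes the exact oracle possible;
* multiplicative lognormal noise (`noise_cv`, default 5%) and lognormal
  between-donor effects (`donor_cv`, default 20%);
* SQC truth equal to the pooled mean of the study samples, dQC truth equal
  to the pool over the dilution fold, RQC truth equal to the per-feature
  baseline;
* optional RQC degradation (random with `rqc_failure_prob`, or
  deterministic via `degrade_rqc_index`) that knocks out enough features
  to fail the reliability rule;
* for the storage series: six donors, one control and one sample per
  temperature (4/25 °C) and time (3–48 h) each — 66 study samples — with
  25 °C marker truths following the packaged trendlines (floored at 1),
  4 °C and control truths at baseline, and annotated marker features among
  time-independent nulls. The baseline convention is the trendline at
  $x = 0$ for linear markers and at $x = 1$ h for power/logarithmic
  markers, whose curves do not extend to 0. All assay modes are combined
  in one table, with each feature carrying its own `assay_mode`.

Identical configurations (including the seed) give bit-identical output.

What the generator does **not** emulate: chromatographic peak shapes, raw
spectra, retention-time drift, isotope patterns, feature-feature
correlation (optional in principle, off by default), nonlinear or
non-multiplicative drift, and matrix effects in the dilution series.
Passing tests on this generator therefore demonstrate that the
implementation honours its own model assumptions and recovers planted
structure — not that the model captures every behaviour of a real
instrument.

## Numerical choices and problem sizes

* Interpolation factors are formed as a single ratio, so that equal RQC
  intensities make normalization the *bit-exact* identity.
* CVs use the sample (n−1) standard deviation; fewer than two present
  values or a nonpositive mean makes a feature unevaluable (and removable)
  rather than an error.
* Trendline near-ties are resolved with a $10^{-12}$ tolerance in $R^2$.
* Missing values are imputed feature-wise by half the minimum observed
  intensity before multivariate analysis.
* The test-suite and acceptance-script problem sizes — 3 plates × 24
  samples for the variance-collapse study, 40 markers + 400 nulls for
  recovery, 20 replicate storage series, 24 × 500 noise matrices for the
  false-positive control — were chosen so the whole suite completes in
  well under a minute while keeping every stochastic bound comfortably
  away from its threshold.

## A short tour

```{r tour, eval = FALSE}
library(gmetkit)

# simulate a three-plate replicate study with drift and noise
cfg <- sim_config(n_plates = 3, n_study_per_plate = 24, n_features = 100,
                  n_donors = 3, drift_amplitude = 0.3, plate_jump = 0.3,
                  noise_cv = 0.05, seed = 1)
sim <- simulate_intensities(cfg)

# correct the drift and filter the features
norm <- normalize_table(sim$table, threshold = 0.5, mode = "anchored")
filt <- apply_all_filters(norm$table, filter_config())
print(filt$report)

# storage series -> per-sample quality scores and candidate markers
storage <- simulate_storage_series(sim_config(seed = 2), load_marker_table())
scores <- score_samples(normalize_table(storage$table, 0.5)$table,
                        mode = "direction_aware")
head(scores)
```

## Known limitations

* The normalization model is strictly multiplicative and piecewise linear;
  LOESS/spline QC-RLSC-style correction, total-intensity and quantile
  normalization, and retention-time alignment are out of scope.
* Blank subtraction, isotope/adduct collapsing and annotation-based
  filtering are not implemented.
* The quality score presumes sample NLAs comparable to the packaged 48-h
  references; cross-instrument transfer of the panel requires re-measured
  references.
* OPLS-DA component counts are not cross-validated (no $Q^2$/VIP); the
  number of orthogonal components defaults to 1.
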