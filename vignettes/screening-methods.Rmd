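---
title: "Screening obstructive sleep apnea from wakeful tracheal breathing sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening obstructive sleep apnea from wakeful tracheal breathing sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Obstructive sleep apnea (OSA) — repetitive pharyngeal collapse during
sleep — is quantified by the apnea/hypopnea index (AHI, events per hour
of sleep), with AHI ≥ 15 the common clinical threshold for
moderate-to-severe disease in need of treatment. Diagnosis requires an
overnight polysomnography; a screener that works during *wakefulness*,
from a few minutes of deliberate breathing recorded over the trachea,
sidesteps the overnight study entirely. The premise is physiological:
the airway deformities that predispose to collapse during sleep (a
narrowed pharynx, reduced muscle tone, a thick soft palate) also shape
the acoustics of breathing while awake.

The difficulty is heterogeneity. Age, sex, body habitus and pharyngeal
anatomy all shift breathing-sound spectra independently of OSA, so no
single feature set predicts severity across the whole population. The
pipeline implemented here addresses that by *subgrouping*: features are
selected and classifiers trained separately inside anthropometric
subsets (BMI < 35, age > 50, age ≤ 50, male, neck circumference > 40 cm,
Mallampati score ≤ 2), and the per-subset votes are fused with a
weighted average.

## The pipeline

`awakeosa()` runs the stages below and returns a classed model object
with `print`, `summary`, `predict` and `plot` methods.

**Segmentation and screening.** Each recording holds five deep breath
cycles through one route (nose, then mouth) and a terminal breath hold
(the *silent period*, a background-noise reference). A short-time-energy
envelope (50 ms frames, 10 ms hop, threshold midway in dB between the
quiet and loud frame populations) finds the bursts; labels alternate
starting with inspiration, which the recording protocol fixes. The
original study segmented by manual audio/visual inspection; an energy
envelope replaces the human so results are reproducible, and a manual
boundary table can override it. A phase is rejected below 10 dB SNR
against the silent period or above 1% clipped samples (the study states
only a qualitative "low SNR"; these are this package's defaults), and a
subject must keep at least two clean cycles per maneuver and phase type.

**Spectral summaries.** Per phase, power spectra come from Welch's
method (Hann window of 1024 samples, 50% overlap — 10 Hz resolution at
the 10240 Hz default rate) and are averaged across a subject's clean
cycles. Bispectra use the indirect estimator: an unbiased third-order
cumulant sequence on demeaned 1024-sample records pooled across cycles
(cumulant averaging *is* the cycle aggregation), a Parzen lag window in
product form, and a 2-D DFT. The default maximum lag of 128 gives a
40 Hz bispectral grid; coarser than the PSD grid, but every analysis
band keeps at least two line samples, and the cumulant stage is the
single most expensive computation in the pipeline — lag 256 would
quadruple it for no change in any downstream decision. At most 8 evenly
spaced records enter each estimate for the same reason.

**Bands and features.** Four fixed bands (100–300, 350–600, 1000–1700,
2100–2400 Hz) are augmented by bands *discovered* per maneuver/phase
where the two severity groups' 95% confidence envelopes (normal
approximation, mean ± 1.96 SE on the dB scale, computed across
subjects) fail to overlap for at least 100 Hz. Discovery uses only
training subjects with unambiguous severity (AHI ≤ 10 or ≥ 20). Over
each band the catalog evaluates PSD statistics (band mean, mean slope,
geometric mean, centroid, spectral spread, peak frequencies) and
bispectral line statistics (mean, weight centre, first and second
moments along the main diagonal, anti-diagonal, f/2 and 2f lines), plus
three time-domain fractal features (Katz, Higuchi, rescaled-range Hurst
with the Anis–Lloyd–Peters correction) — about 280 features across the
four maneuver/phase combinations. Mean/slope/difference operators work
in dB, centroid- and frequency-valued operators on linear power.
"Weight centre" is the normalised centroid Σf·m/Σm while "first/second
moment" are unnormalised (Σfᵏ·m/N); the two families are deliberately
distinct statistics. All features are min–max scaled to [0, 1] with
parameters learned on training rows only (leakage-safe; test rows are
clipped).

**Feature reduction, per subset.** Four stages, in order, on the
feature-extraction rows of the subset: (1) Welch two-sample t-test,
keep p ≤ 0.05; (2) a robustness score — per round, each severity group
is randomly partitioned into subgroups of 15 (shrunk to the smaller
group when a subset cannot fill 15), and a feature earns a point for
every cross-group subgroup pair where the t-test holds *and* both
subgroups pass the Lilliefors normality check; after 20 rounds features
scoring above 0.6 of the maximum survive; (3) redundancy removal —
features correlated at |r| ≥ 0.9 are clustered transitively and only
the best single-feature linear-SVM training accuracy survives per
cluster; (4) an effect-size filter keeping |Glass's Δ| > 0.8 (Δ =
group-mean difference over the non-OSA SD). The pipeline keeps at most
`max_keep` features (strongest |Δ| first) — the study worked from
roughly 15 per subset; the acceptance-scale configuration uses 10,
which bounds the combination search without touching any earlier
stage — and at least 3 so a combination exists.

**Training.** Per subset, boxplot fences (type-7 quartiles; adjacent
values within 1.5 IQR, merged across severity groups by taking the
outermost) mark outliers missing. All 3- and 4-feature combinations are
enumerated — neck circumference joins the pool in every subset except
its own — and each is trained 3 times as a random forest (1200 trees by
default; bootstrap resampling leaves ~2/3 of rows in-bag; Gini
splitting; class weights n/(2·n_k) compensating the group imbalance),
yielding out-of-bag accuracy, sensitivity and specificity.
Combinations with any repetition value below 0.7 are dropped; among
survivors the shortlist keeps averages within max(max observed
repetition spread, 2%) of the best. The shortlist is re-validated 5
times and the highest mean OOB accuracy wins (ties: sensitivity +
specificity, then lexicographic ids). Selection is validation-only: the
original protocol also consulted blind-test accuracy at this step,
which leaks test information, so the default here is the leakage-safe
variant. The "interaction-curvature" predictor-selection heuristic of
the original MATLAB routine has no equivalent in the forest backend
used here; standard random predictor subsetting replaces it.

**Voting.** Each subset model votes on *every* subject (+1 OSA / −1
non-OSA), weighted by its own OOB sensitivity (positive votes) or
specificity (negative votes); a subject whose combination features were
fenced out abstains from that model rather than contributing a zero.
The final decision d is the mean of non-abstaining weighted votes:
d > 0 calls OSA, d = 0 is called non-OSA with an explicit tie flag, and
|d| > 0.7 flags a high-confidence call. With every model at 100%
sensitivity and specificity, unanimous votes reach d = ±1 exactly.
Supporting analyses: leave-one-subset-out ablation, and the multiple
correlation of a combination with AHI or log(AHI).

## The synthetic cohort

No recordings are deposited with the study, so `generate_cohort()`
emulates the *statistical structure the pipeline assumes* — nothing
more; it is not an airway-acoustics model. Defaults mirror the clinical
cohort: 109 non-OSA / 90 OSA subjects; AHI drawn from truncated normals
with the published group moments (3.59 ± 3.95 below 15, 42.85 ± 32.72
above — used as parameters of the parent normal, so realised moments
shift slightly under truncation); BMI, neck circumference and
Mallampati coupled to AHI through a Gaussian copula whose latent
correlations are inflated (on a quadrature grid) to undo the
attenuation of the non-linear AHI marginal, targeting the published
r = 0.44/0.43/0.26; sex and age drawn per group with the published
enrichment. The train/test split is stratified 113/86.

Audio is shaped Gaussian noise through a group-dependent dB envelope:
the defining contrast is the 250–350 Hz slope — negative for non-OSA,
positive for OSA (±0.06 dB/Hz, between-subject SD 0.022, plus a mild
log-AHI gradient) — with OSA resonances shifted up 70 Hz and a small
group tilt in 2100–2400 Hz, so all four fixed bands carry information.
Five amplitude-modulated breath cycles precede a 2 s breath hold at a
−35 dB noise floor. What passing tests show is therefore that the
pipeline recovers *designed* contrasts of realistic magnitude through
the full audio path; they say nothing about microphone transfer,
ambient artifacts, or the breath-to-breath nonstationarity of real
tracheal sounds.

## Numerical choices and degenerate inputs

* Bands are closed intervals; a grid point belongs iff f₁ ≤ f ≤ f₂.
  Bispectral lines sample the magnitude at nearest grid bins, dropping
  points outside the stored quadrant.
* PSD band statistics require ≥ 3 grid points, bispectral lines ≥ 2.
* Peak operators demand 3 dB prominence; absent peaks yield missing
  values, and features constant on training rows are dropped at
  scaling.
* A constant signal has Katz dimension 1 by convention and a flagged
  missing Hurst exponent.
* The ambiguous shortlist window ("maximum difference or 2%") is read
  as lower bound = best − max(max repetition spread, 0.02), which keeps
  the window non-degenerate.
* Repetition r of any stochastic stage uses seed + r; every public
  entry point takes an explicit integer seed, and fits are
  reproducible bit-for-bit given one.
* Robustness subgroups shrink to the smaller severity group (floor 10)
  so mildly undersized subsets degrade gracefully instead of erroring;
  a subset that still cannot train is skipped with a warning and the
  ensemble continues.

## Problem sizes used by the shipped checks

The test suite validates the full pipeline on the default 199-subject
cohort with 300-tree forests and a 10-feature combination pool — the
configuration this package treats as its reference desk scale — and the
component checks use 1024-sample bispectral signals, 8192-sample fractal
series (50 seeds for the Hurst calibration), and 100-run reduction
simulations at n = 30/20. Forest size and feature-pool caps trade
variance against runtime and are the two knobs to raise for a
production fit (`awakeosa_control(n_trees = 1200)`,
`reduction_control(max_keep = 15)`).

## Known limitations

* The synthetic envelope is stationary within a breath; real tracheal
  sounds are flow-modulated within each phase.
* The robustness stage substitutes for multiple-testing correction, as
  in the original protocol; no FDR control is applied or claimed.
* Universal voting (every model votes on every subject) follows the
  published decision scheme; `membership_only` voting is available but
  not the default.
* The |d| > 0.7 high-confidence flag is reported without any
  calibration claim.
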