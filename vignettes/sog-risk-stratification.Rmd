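---
title: "Volumetry-based growth biomarkers for smoldering multiple myeloma: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetry-based growth biomarkers for smoldering multiple myeloma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Smoldering multiple myeloma (SMM) is an asymptomatic precursor of multiple
myeloma with a very heterogeneous prognosis: roughly a fifth of patients
progress to symptomatic disease within two years while a quarter are still
progression-free after ten. The IMWG therefore defines *biomarkers of
malignancy*: a marker qualifies if the high-risk group it isolates shows at
least 80% progression within the next two years (the "2yrPR >= 80%"
criterion). The established MRI marker — more than one focal lesion (FL)
larger than 5 mm — has repeatedly missed that bar.

Whole-body MRI volumetry offers richer candidates. Segmenting every focal
lesion at every MRI gives, per visit,

* **TTV** (total tumor volume): the sum of all focal-lesion volumes, in
  mm^3;
* **SOG** (speed of growth): the change of TTV between two consecutive
  MRIs divided by the elapsed time, in mm^3/month;
* **nFL**: the number of focal lesions;
* **dev-nFL**: newly appearing focal lesions per year.

This package implements the full evaluation chain for these biomarkers —
volumetry rules, biomarker-event detection, competing-risk survival
estimation, cutoff optimization with familywise error control — together
with a synthetic cohort generator so that every stage is testable without
patient data.

## Volumetry rules

`visit_volumes()` turns raw per-lesion measurements into per-visit TTV and
nFL:

1. **Modality averaging.** Lesions measured in both T1- and T2-weighted
   images use the arithmetic mean of the two volumes; if only one modality
   was measured, that value is used. The single-modality fallback is our
   choice — the convention "measured in both if possible" leaves the
   fallback open, and discarding a valid measurement would bias TTV
   downward.
2. **Carry-forward correction.** A lesion that is no longer delimitable
   (for example because diffuse infiltration intensified) keeps the
   corrected volume of its most recent measurable visit; the rule
   propagates across consecutive unmeasurable visits and ends as soon as
   the lesion is measured again. Volumes are never carried backward in
   time: a lesion that is unmeasurable at its very first appearance has no
   predecessor volume and is dropped from that visit with a warning rather
   than imputed.
3. **Focal-lesion rule.** A lesion counts as an FL when its equivalent
   sphere diameter `d = (6V/pi)^(1/3)` is strictly greater than 5 mm
   (65.45 mm^3). The rule is applied to the corrected volume because
   segmentation-time diameters are not available in tabular input.
4. **Time unit.** All times are real months from each patient's first MRI;
   dates are converted at 365.25/12 days per month.

MRI visits at which a patient has no detectable lesion are carried through
the lesion table as placeholder rows (`lesion_id = NA`), so a patient with
TTV = 0 still contributes visits — without this, lesion-free patients would
silently vanish from the analysis.

## Biomarker series and events

`biomarker_series()` aligns five tracks per patient-visit. The dynamic
tracks (SOG, new FL/year) are undefined at each patient's first MRI, so
single-MRI patients are excluded from dynamic-biomarker analyses (their
static tracks remain). Two conventions matter:

* **New FL/year counts appearances only.** A lesion that shrinks below
  5 mm or becomes undetectable does not produce a negative count; growth
  and new-lesion appearance are deliberately separable contributions.
* **log10(TTV).** TTV is log10-transformed for prognostic modelling. TTV
  = 0 is mapped to half the minimum positive TTV observed in the cohort (a
  pseudo-volume floor); any fixed floor below the detection volume would
  do, and this one adapts to the cohort's scale.

A *biomarker event* (`detect_event()`) is the first MRI at which a track
satisfies its comparator — `>` for the IMWG ">1 FL" criterion, `>=` for
the volumetry cutoffs; both comparators are first-class.

## Survival estimators

All estimators are implemented in the package and validated in the test
suite against closed forms, brute-force oracles and the independent
implementations in `survival` and `cmprsk`.

* **Aalen-Johansen** (`aalen_johansen()`): cumulative incidence of
  progression with death before progression as competing event,
  `CIF_k(t) = sum_{t_i <= t} S(t_i-) d_k(t_i)/n(t_i)` with `S` the
  all-cause Kaplan-Meier. Without competing deaths this reduces exactly to
  `1 - KM`.
* **Cause-specific Cox regression** (`cox_cause_specific()`): partial
  likelihood on counting-process rows `(start, stop, cause, covariates)`
  so biomarkers assessed during follow-up enter as time-dependent
  covariates; competing events are censored at their time. Ties use the
  Efron correction by default (better behaved than Breslow when tied
  event times occur; the choice is isolated behind a flag). Newton-Raphson
  with step-halving converges when the score's maximum absolute component
  falls below 1e-8 (at most 50 iterations, plus a negligible-step exit at
  1e-10); non-convergence or monotone likelihood is flagged, never
  silent. Reported p-values are Wald — one p per covariate, matching the
  usual multivariable-table layout.
* **Harrell's c for time-dependent markers** (`harrell_c_td()`): at each
  progression time the failing patient's current marker value is compared
  with every at-risk patient's current value; marker ties count 0.5,
  patients failing at the same time are not compared with each other.
* **Time-dependent sensitivity and FPR** (`td_sensitivity_fpr()`): the
  cumulative/dynamic estimator composed by Bayes' rule,
  `Sens(t) = p F1(t)/F(t)`, `FPR(t) = p (1 - F1(t))/(1 - F(t))`, with `p`
  the marker-positive fraction and `F1`, `F` Aalen-Johansen progression
  incidences among marker-positives and overall. With no censoring before
  the horizon this reduces exactly to the raw proportions. Which clock
  anchors the published variant of this estimator is not stated in the
  source material, so both are provided: marker status at the 2nd-MRI
  landmark with time measured from that landmark (default — the clock
  dynamic biomarkers live on), or whole-follow-up status on the first-MRI
  clock (`marker_clock = "any-time"`).
* **Holm step-down** (`holm_adjust()`) and **Spearman correlation**
  (`spearman_cor()`, midranks, t-approximation p, pairwise-complete with
  reported n) complete the toolbox.

## Cutoff analysis

`sweep_cutoffs()` implements the headline procedure. The candidate set is
*all distinct observed values* of a track — on a finite sample this is
exactly "all possible cutoffs". Per candidate:

1. detect first-crossing events;
2. anchor the outcome clock at the event MRI; event-free patients are
   anchored at their last MRI (so their event-free follow-up counts
   against the marker, not for it);
3. estimate the 2-year progression rate of the event-positive group as
   the Aalen-Johansen progression incidence at 24 months on the anchored
   clock;
4. compute a raw p-value from the cause-specific Cox model on the
   time-dependent binary event indicator (a score/log-rank variant is
   available behind `test = "logrank"`; the Cox Wald p is the default
   because it matches the modelling used everywhere else);
5. compute time-dependent sensitivity/FPR at the horizon.

Holm correction is applied across the candidate set per biomarker.
`select_cutoff()` returns the *smallest* candidate with 2yrPR >= 80% and
Holm-adjusted p < 0.05: the 80% criterion is the stated requirement, and
among qualifying cutoffs the smallest maximizes sensitivity, which is the
point of a screening biomarker. `biomarker_comparison_report()` assembles
the comparison table (fixed ">1 FL" row plus selected cutoffs, with group
sizes: all patients for static markers, patients with >= 2 MRIs for
dynamic ones) and a companion cutoff-free Harrell-c table computed on all
longitudinal values.

Internally the sweep shares one counting-process skeleton and per-event
risk-set order statistics across all candidates, so the per-candidate Cox
fit reduces to scalar Newton-Raphson on risk-set counts; a test pins this
fast path to the general fitter.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a retrospective
longitudinal SMM imaging cohort:

* 63 patients, first MRI at month 0, log-normal inter-MRI gaps with
  median 13 months, scheduled visit counts `1 + Poisson(4)` truncated at
  the outcome (about 200 observed MRIs, about 55 patients with >= 2
  MRIs);
* zero-inflated Poisson baseline lesion counts with log-normal volumes;
  one patient-level exponential growth rate drawn from a two-component
  normal mixture (a stable/shrinking and a growing component — the
  per-lesion growth-rate distribution of SMM focal lesions is not
  published, so these defaults are conventions and are documented as
  such); new lesions arrive as a Poisson process and enter at the 5 mm
  detection boundary with a small jitter, keeping "growth" and "new
  lesion" contributions to SOG separable;
* a cause-specific progression hazard driven by the **observed**
  step-function biomarker path on the visit grid,
  `h(t) = lambda0 exp(b_sog SOG(t)/100 + b_ttv log10(TTV(t)+1) +
  b_event 1[SOG event])`, sampled by inversion of the piecewise-constant
  cumulative hazard; death is an independent constant hazard and
  administrative censoring closes follow-up. The hazard deliberately sees
  what the analysis sees (the visit-grid path), not the latent continuous
  path, so planted coefficients are recoverable by the estimators under
  correct specification.

Default effect sizes are 37% extra progression risk per 100 mm^3/month of
SOG and 65% per tenfold TTV. The baseline progression hazard
(0.0020/month), death hazard (0.0005/month) and administrative window (56
months) were fixed once so that the simulated cohort reproduces the
target cohort-level two-year progression of about 20% (measured band
0.15–0.25 averaged over seeds) together with plausible progression/death
counts; they were not revisited afterwards.

What the generator does **not** emulate: diffuse bone-marrow
infiltration, MRI intensities (masks are geometric voxelized spheres),
missing laboratory values and their imputation, and mid-follow-up
treatment dropouts — simulated progression counts therefore run somewhat
higher than a clinic would record over the same window. Passing tests
demonstrate correctness of the estimators and of the recovery machinery
under the stated generative assumptions, not clinical validity on real
cohorts.

Unmeasurable flags are independent across lesion-visits, so a lesion can
become measurable again — exercising the carry-forward rule in both
directions. Labs are normal/log-normal draws whose correlation with the
latent growth rate is configurable (default 0) for correlation analyses.

Mask mode voxelizes each lesion by taking exactly `round(V / voxel
volume)` voxels nearest the lesion center, which guarantees the mask
volume matches the simulated volume within one voxel — a naive sphere
threshold does not. Lesion identity across visits is the shared integer
label, and the visit time is encoded in the file name
(`<patient>_m<months>.nii.gz`).

## Numerical and reproducibility choices

* All randomness of a cohort flows from `cohort_config(seed = ...)`; the
  caller's RNG state is restored afterwards. Identical config + seed
  yields byte-identical CSV/JSON artifacts (numeric columns are
  serialized at fixed 6-decimal precision for this reason).
* Degenerate inputs are defined, not errors: zero-dispersion schedules
  give exact 13-month grids, zero hazards give pure administrative
  censoring, a constant biomarker track yields an empty sweep with a
  warning, groups without events are flagged rather than fitted.
* Validation problem sizes, chosen to make Monte-Carlo error small while
  keeping the suite quick: closed-form checks at n = 4,000–10,000 draws;
  planted hazard-ratio recovery (true HR 8.42 on the SOG > 0 event
  indicator) on 200 replicate cohorts of n = 500, where the fitted 95% CI
  covers the truth in about 95% of replicates; cutoff recovery on one
  n = 500 cohort whose hazard steps sharply at SOG > 114 mm^3/month. The
  cutoff-recovery fixture uses deterministic growth components and an
  exact 13-month grid so that observed SOG values form point masses
  around the planted threshold; with continuous growth distributions the
  smallest-qualifying-cutoff rule drifts below the planted value, since
  mildly diluted candidate groups can stay above the 80% bar.

## Limitations

* The estimators assume one record per patient per analysis clock and
  noninformative censoring; frailty, stratified baselines and
  time-varying coefficients are out of scope.
* Multiple imputation of missing labs is out of scope (synthetic cohorts
  are generated complete).
* The sweep's Holm correction controls the familywise error of the
  cutoff search per biomarker; it does not correct across biomarkers.
* c-index values are in-sample; no optimism correction is applied.
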