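---
title: "Detecting occlusion MI from early ED data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting occlusion MI from early ED data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Occlusion myocardial infarction (OMI) — acute MI with a culprit lesion and
TIMI flow 0–1 — benefits from immediate angiography, but in emergency
departments where obvious STEMI is diverted prehospitalically, the OMI that
remains is mostly ECG-subtle: the guideline ST-elevation criteria detect
only a minority, and median time to angiography is measured in hours.
`omipipe` implements, on synthetic data, the full study design used to
quantify this gap and to test whether a learned ECG representation fused
with early tabular data can close it: rule-based outcome annotation from
registry facts, a rule-based STEMI comparator, a convolutional ECG encoder
feeding a logistic risk model, and a matched-specificity bootstrap
evaluation.

This vignette documents the models, the tunable parameters, and the design
decisions taken where the design was genuinely open. Every empirical claim
below is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted from memory.

## The synthetic cohort generator

The generator (`cohort_config()`, `generate_cohort()`) defines the study
conditions; its defaults are fixed, not tuning knobs.

**Latent classes and tabular structure.** Each visit draws a latent class —
OMI (1.9%), NOMI (4.6%), or no AMI — and class-conditional demographics,
history/medication flags, POC labs (hemoglobin, creatinine, glucose), and
initial hs-cTnT. The per-class flag prevalences, age/sex distributions, and
troponin log-normals (medians 7 / 105 / 51 ng/L with matching IQRs for
no-AMI / OMI / NOMI, clipped at a 3 ng/L assay floor) reproduce the pattern
reported for Swedish ED chest-pain cohorts: OMI patients are predominantly
male and carry *fewer* comorbidities than NOMI patients, which is why the
history-only model discriminates poorly. Lab values are masked
missing-at-random at per-lab rates between 0.8% (hs-cTnT) and 5% (glucose);
a property test confirms the missingness indicator is uncorrelated with the
latent class (|r| < 0.03 at n = 10,000).

**Registry outcomes.** Constructed per class so that (a) every latent OMI
satisfies at least one branch of the annotation tree (91% receive
angiography with a culprit lesion and TIMI 0–1, 80% also carry a registered
ACO; the no-angiography remainder is forced onto the troponin + wall-motion
/ arrest branch), (b) no latent NO_AMI satisfies any branch, and (c) latent
NOMI is kept off the OMI branches by construction (troponin above 1000 ng/L
is truncated when revascularization was drawn, occlusive TIMI grades are
never drawn). A small fraction of NOMI angiographies has `unclear` TIMI
flow, which the tree routes to `NEEDS_REVIEW` — the machine stand-in for
the human adjudication step in the original process. Mortality and
angiography-delay distributions (median 6 h to angiography for OMI, 28 h
for NOMI) follow the published cohort table.

**Waveforms.** One beat is a sum of five Gaussians (P, Q, R, S, T) on a
common time base, projected onto the 8 independent channels (I, II, V1–V6)
by a fixed 5×8 amplitude matrix; the 4 remaining limb leads are derived via
the Einthoven/Goldberger identities *after* noise is added, so the
identities hold to numerical precision on every record (tested at
10⁻⁹ mV). The RR interval is constant within a record (sinus regularity);
phase and rate vary across records, so beat detection and alignment are
still exercised. ST deviation is a smooth plateau from the end of the S
wave to the T-wave onset, which makes the level measured at J + 60 ms equal
the configured per-channel offset — the generator is its own measurement
oracle. LBBB and ventricular pacing widen the QRS Gaussians (×2.5), LVH
scales the R amplitude (×1.8). Sampling is 500 Hz for 10 s (the common
clinical rate; the rate is configurable because source systems differ).

**Difficulty structure.** Subtle OMI is defined as maximal ST elevation
between 0.05 mV and the applicable sex/age threshold; 60% of OMI is subtle
by default, so the STEMI rule's sensitivity is structurally ≈ 0.4 (verified
on a noiseless cohort within binomial error). Three ingredients keep the
ECG channel informative but imperfect, mirroring the reported real-data
behavior (ECG-only AUC well below the troponin-augmented model): benign
per-patient ST variation (iid N(0, 0.03 mV) per channel), white noise of
0.05 mV, and baseline wander of 0.05 mV. A 2.5% "early-repolarization"
fraction of non-OMI patients carries above-threshold elevation, which sets
the comparator's false-positive rate and hence the matched operating point
near 97% specificity. Extra ECGs (50% of visits) share the visit's
morphology with a new noise draw and a later timestamp.

**What the generator does not emulate.** Physiologic beat-to-beat
variability, rhythm disorders, reciprocal ST depression, hyperacute T
waves, electrode misplacement, and the correlation structure of real
comorbidity profiles. Tests passing on this cohort therefore demonstrate
that the pipeline's machinery is correct and that its comparative protocol
behaves as designed — not that the trained encoder would transfer to real
ECGs.

## Outcome annotation

`annotate_omi()` evaluates four branches in fixed order with
first-match-wins: R1 registered ACO; R2 24 h-max hs-cTnT strictly above
1000 ng/L with urgent PCI or CABG; R3 angiographic culprit lesion with TIMI
flow 0–1 (flow `unclear` → `NEEDS_REVIEW`); R4, for AMI without
angiography, hs-cTnT above 1000 ng/L with a new regional wall-motion
abnormality, or a STEMI-indicative ECG with cardiac arrest before
angiography. AMI with no branch is NOMI; no AMI diagnosis is NO_AMI. The
branches are mutually compatible, so order affects only which rule is
*reported*, never the status; a randomized property test checks totality
and determinism, and a monotonicity test checks that raising troponin never
demotes an OMI. "Urgent" revascularization is operationalized as within 7
days of the index visit (configurable). Exclusions mirror the study flow:
no ECG, poor-quality index ECG, or an undecidable outcome (AMI diagnosis
with every branch-relevant field absent); a STEMI discharge diagnosis never
excludes, to reflect normal patient flow. `NEEDS_REVIEW` is terminal for
the machine: those visits are dropped from model training and evaluation
and counted in the report.

## The STEMI rule engine

The comparator measures, then decides.

*Median beat*: R peaks detected on lead II (amplitude threshold with a
300 ms refractory), beats stacked on a −300…+500 ms window, per-sample
median across beats (≥ 3 beats required), per-lead baseline from the PR
segment (−80…−20 ms before QRS onset).

*J point*: the QRS offset, found where the cross-lead RMS slope of the
median beat stays below 6% of its intra-QRS maximum for 16 ms. The RMS
trace is smoothed (22 ms running mean) and differentiated over ±10 ms so
residual noise on the median beat cannot mask the plateau.

*Measurement offset*: ST deviation is read at **J + 60 ms** by default
(configurable: 0/40/80). With Gaussian beat morphology the S-wave tail
still contributes up to ~0.09 mV at the detected QRS offset in deep-S leads
(V1–V3), so a J + 0 reading cannot be accurate to the 0.02 mV the package
tests against; J + 60 sits mid-plateau and matches a common vendor
convention. This is the one place the implementation prefers measurement
accuracy over the guideline's nominal J + 0 sampling point.

*Decision*: positive when ≥ 2 leads within one contiguous group reach their
threshold — 0.1 mV everywhere except V2–V3 (0.25 mV men < 40 y, 0.2 mV men
≥ 40 y, 0.15 mV women; 1 mm = 0.1 mV). Contiguity groups are the clinical
conventions — inferior {II, III, aVF}, anterior {V1–V4}, lateral {I, aVL,
V5, V6} — plus adjacent precordial pairs so that combinations such as
V4+V5 count; the group list is a function argument. Records flagged LBBB,
LVH or paced are `not_applicable`: the criteria are undefined there. At
cohort level, measurement failures abstain (negative), matching how an
automated rule engine behaves in production.

## The ECG encoder

No deep-learning framework is available to this package's dependency
closure, so the residual 1-D convolutional network is implemented directly:
im2col convolutions and explicit backpropagation in RcppArmadillo, Adam in
R, with *all* randomness (initialization, shuffling, crop positions) drawn
from R's seeded RNG so training is reproducible bit for bit. Analytic
gradients are verified against central finite differences in the test
suite (relative error < 10⁻⁴).

Architecture: stem convolution (kernel 7, stride 2) → residual blocks
(kernel-5 stride-2 conv, ReLU, kernel-5 conv, 1×1 stride-2 skip, ReLU) →
global average pooling → a linear 50-dimensional embedding bottleneck → a
binary head. The embedding is an explicit bottleneck rather than a
penultimate classifier layer, so "feature extraction" is unambiguous. The
default is deliberately small (stem 16, blocks 24→32) so CPU training on
synthetic cohorts takes minutes; depth and width are configuration, not
architecture constants.

Training uses the 8 linearly independent leads only (V1–V6, I, II — the
limb leads III, aVR, aVL, aVF are exact linear combinations of I and II, a
fact both tested and exploited), random 2.5 s crops each epoch, extra
same-visit ECGs with the index visit's label (≈ +50% training pairs;
never used at feature-extraction time), weighted binary cross-entropy
(positive weight = negative:positive ratio, countering the ~2% prevalence),
and early stopping on tuning-set AUC with patience 5, keeping the
best-epoch weights. Per-epoch tuning AUC is computed on a single centered
crop for speed; final evaluation averages over 10 evenly spaced overlapping
crops (stride rounded to the nearest sample, first window at 0, last
flush with the record end). Crop averaging is applied to *embeddings* for
feature extraction and to head *probabilities* for encoder-only
evaluation — the natural reading of "averaging the results" for each use.

## Feature fusion

Features concatenate in fixed block order — history (age, sex, 23 binary
diagnosis/medication flags), ECG embedding (50), POC labs (3 values + 3
missingness indicators), troponin (1 + 1) — with registry-derived fields
statically rejected by name. Missingness indicators are included as
features: their correlation with the outcome is negligible by construction,
including them is the conservative superset, and they are removable via the
mask machinery.

Preprocessing is fitted on training rows only: maximum-likelihood
Yeo-Johnson for the four lab features (`car::powerTransform`), then
standardization to zero mean/unit variance for everything; missing entries
are imputed with the training mean of the transformed feature (zero on the
standardized scale). Zero-variance features pass through with a warning. A
test asserts the stored statistics equal the training-row statistics and
differ from global ones — the leakage check as an executable property.

The classifier is L2-regularized logistic regression (`glmnet`, alpha = 0)
with the penalty chosen on tuning-set AUC over a log-spaced 25-point grid
from 10² to 10⁻⁴ — AUC because the downstream comparison is
discrimination at a matched operating point. `ablation_grid()` fits any
subset of the 15 non-empty feature-group combinations; the five cumulative
ones (history; +ECG; +POC; +troponin; all) are flagged for the headline
table.

## Evaluation protocol

Patients are split 50/25/25 (train/tune/validate) stratified on the
outcome by largest-remainder allocation, so each split's OMI proportion is
exact to one patient. The comparator's operating point is its specificity
on the *tuning* set, computed on the cohort where the criteria are defined
(no LBBB/LVH/VP); the model's threshold is then the smallest cut-off whose
tuning specificity is at least that target (exact equality is generally
unattainable on finite data; the achieved specificity is reported
alongside). Raising the target can never lower the threshold — a tested
invariant.

Confidence intervals are percentile bootstrap over patients (B = 1000
default, 95%), the simplest method consistent with "bootstrapping to
approximate a CI"; resamples where a metric is undefined are skipped and
counted. Paired comparisons compute both metrics on the same resample and
take the percentile interval of the difference. AUC is the midrank
Mann-Whitney estimator, verified against exhaustive pair counting and an
independent library implementation. Joint resampling is used for all
metrics within a report (one index draw per replicate). Subgroup reports
(sex; the no-confounder cohort) reuse the global threshold — thresholds are
never refitted per subgroup. When the comparator must emit a binary verdict
on the full cohort, `not_applicable` counts as negative; in the reduced
cohort those patients are excluded. Rule comparators carry no AUC, which is
only meaningful for nonbinary predictions.

## Problem sizes, determinism, numerical choices

The package's own study runs use n = 3000 visits with the 2-block encoder
and 6 epochs — large enough that the qualitative orderings (history < +ECG
< +troponin validation AUC; fused sensitivity above rule sensitivity at
matched specificity, as medians over 3 seeds) are stable, small enough to
run in a few minutes on one CPU; coverage of the bootstrap CI is checked
with 200 known-truth repetitions at n = 400. One master seed derives
per-stage seeds (cohort, missingness, split, encoder, fusion, bootstrap),
and per-record waveform seeds, so tabular-only generation
(`waveforms = FALSE`) is byte-identical to the full run. Ties in the
threshold scan break toward the smallest qualifying threshold; percentage
formatting rounds halves away from zero to one decimal, matching clinical
table conventions (5.35 → 5.4); degenerate inputs (flatline records,
single-class subgroups, empty strata) error or abstain explicitly rather
than return silent values.

## Known limitations

The encoder is a scaled-down stand-in for a full ResNet: it demonstrates
the protocol, not state-of-the-art ECG representation learning. The
generator's difficulty structure is parametric and honest but synthetic —
absolute metric values on it say nothing about real-data performance, only
the *relative* behavior of the pipeline's components is meaningful.
Transfer-learning initialization is exposed as a weights-loading hook but
no pre-trained weights ship with the package. Sgarbossa-type criteria for
LBBB, ST-depression/reciprocal rules, and decision-curve analyses are out
of scope.
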