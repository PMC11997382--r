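---
title: "Methods: detecting cognitive motor dissociation from fNIRS motor imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting cognitive motor dissociation from fNIRS motor imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmdnirs)
```

## The problem

A patient with a disorder of consciousness (DOC) who cannot produce any
behavioral response may nonetheless understand and covertly follow commands —
*cognitive motor dissociation* (CMD). `cmdnirs` implements an instrumental
test for command-following: during a spoken block paradigm (50 s baseline,
five blocks of 20 s hand-open-close motor imagery followed by 20 s rest, 50 s
post-baseline; 300 s total), continuous-wave fNIRS measures cortical
hemodynamics over 63 channels at 703/808/850 nm and 11 Hz. If a behaviorally
unresponsive patient (VS/UWS or MCS−) shows a task-locked hemodynamic
response classified like that of healthy controls, the patient is flagged as
CMD — operationally, a *false positive* of the behavioral reference standard
(CRS-R diagnosis).

## Signal model and preprocessing

Neural activity is read through neurovascular coupling: motor imagery raises
oxyhemoglobin (HbO) and slightly lowers deoxyhemoglobin (HbR) over motor
cortex. The chain, in fixed order:

1. **Channel quality control.** Per channel and wavelength, the coefficient
   of variation of raw intensity, CV = σ/μ × 100% (sample SD over the whole
   series). A channel is dropped when CV strictly exceeds 15% at *any*
   wavelength; a recording with no surviving channel is rejected outright.
   CV is computed on raw intensities, before artifact correction — the
   screen is deliberately pessimistic, mirroring the exclusion of heavily
   contaminated recordings from analysis.
2. **Optical density.** OD(t) = −log10(I(t)/Ī), referencing each series to
   its temporal mean Ī (the continuous-wave convention; OD is then invariant
   to detector gain).
3. **Motion-artifact correction.** A centered 1 s sliding window yields a
   moving SD per series; samples are flagged where the moving SD exceeds 6×
   the *median* moving SD of that series (a robust multiplier — the absolute
   reading of "6 SD" would depend on channel gain) or where the
   sample-to-sample change exceeds 0.5 OD. Flags are dilated by one window,
   merged into segments; within each segment a near-interpolating cubic
   smoothing spline (`smooth.spline`, λ = 1e−8) is fitted and subtracted,
   the segment is re-leveled to the preceding clean data, and all subsequent
   data are shifted to preserve continuity — so both spikes and persistent
   baseline steps are corrected (spline-subtraction / MARA-style). Clean
   input passes through bit-identically, and a second pass on corrected
   fixtures flags nothing.
4. **Band-pass 0.01–0.1 Hz.** Removes cardiac (~1.1 Hz), respiratory
   (~0.25 Hz), residual Mayer-wave and drift energy while keeping the
   0.025 Hz block-design fundamental. No filter-design library is available
   in the supported environment, so the filter applies a third-order
   Butterworth *magnitude* response in the frequency domain to an
   even-reflection-padded series: exactly zero phase, DC removed exactly,
   and no edge transients from IIR state. Measured response: ≥95% gain at
   0.05 Hz, <0.1% at 1.1 Hz.
5. **Modified Beer–Lambert law.** Per sample, ΔOD(λ) =
   [ε_HbO(λ)ΔHbO + ε_HbR(λ)ΔHbR]·d·DPF is solved for (ΔHbO, ΔHbR) by least
   squares across the three wavelengths, with d = 3 cm and DPF = 6.0.
   The extinction table (703/808/850 nm) is compiled from the standard
   published hemoglobin spectra and shipped as a versioned constant; the
   synthetic generator uses the *same* table, so concentration round trips
   are exact by construction and the table choice only sets the absolute
   concentration scale (µmol/L).

## Features and classification

Channel series are averaged (unweighted) within ten anatomical ROIs; the
four motor ROIs (LPMC, RPMC, LM1, RM1) carry the classification. Each task
block is epoched from −5 s to +40 s around the task command
(`round(t × 11 Hz)` sample alignment, 496 samples), baseline-corrected by the
[−5, 0) s mean, and the five epochs are averaged pointwise. From the block
average, seven features — mean, peak, variance, median, peak-to-peak,
skewness, kurtosis — are extracted per chromophore in the imagery window
(5–20 s after the task command, epoch time [5, 20)) and the rest window
(5–20 s after the rest command, i.e. [25, 40)). Windows are half-open to
avoid double-counting boundary samples. Conventions, centralized in
`window_features()`: variance is the n−1 sample variance; skewness and
(non-excess) kurtosis use 1/n central moments; a zero-variance window yields
skewness = kurtosis = 0; *peak means maximum for both chromophores* — an
interpretive choice, flagged because HbR responses are negative-going.
Features default to the block average (one imagery + one rest vector per
subject and ROI); a per-block mode (5 + 5 vectors) is available via
`subject_features(mode = "per_block")` but is not the default analysis
path: block averaging precedes feature extraction, so each subject
contributes one exemplar per condition.

An RBF-kernel C-SVC is trained per ROI on healthy controls only (imagery
label 1, rest label 0). Because no SVM library ships with the supported
environment, the package carries its own small sequential-minimal-
optimization solver (maximal-violating-pair working-set selection, Rcpp).
Feature scaling is min–max to [0, 1], fitted on training data only; folds are
grouped by subject (both condition samples of a subject stay together — they
are statistically dependent) and the default cross-validation is 20-fold.
All 120 feature subsets of size 2–7 can be searched; for each subset a
real-valued genetic algorithm (population 20, 50 generations, tournament
selection, arithmetic crossover 0.7, Gaussian mutation 0.05, elitism 1)
searches C, γ ∈ (0.01, 10] for the best cross-validated accuracy, with the
fold partition drawn once per seed and held fixed so the search is
deterministic. Combinations are an outer loop around the GA (the GA
optimizes parameters *for each* combination). Ties between combinations are
broken toward fewer features, then lexicographically.

A patient *shows an fNIRS response* under the strict rule when the imagery
sample is labeled 1 **and** the rest sample 0; a lenient rule (imagery label
alone) is available since two defensible readings of the two-label decision
exist. All four motor ROIs are evaluated; the ROI with the highest
patient-level sensitivity against the behavioral reference is designated
the reporting ROI (for hand motor imagery this is typically the left
premotor cortex). Note this rule conditions ROI choice on the
patient set, which is defensible for reporting but would be leakage if the
sensitivity itself were the claimed performance — the planted-recovery tests
therefore evaluate recovery *at* the designated ROI rather than the best ROI
per truth.

## Statistics

Against the CRS-R reference (MCS+ positive, VS/UWS and MCS− negative), the
fNIRS response yields TP/FN/TN/FP and TPR/FNR/TNR/FPR as percentages.
Behavioral false positives are the CMD patients; the remaining
reference-negatives are true DOC. Six-month GOS-E is dichotomized at ≥4
(favorable); subjects lost to follow-up leave the prognosis tables only,
never the confusion matrix. Group comparisons use the package's own
two-sided Fisher exact test: full enumeration over the feasible cell range,
summing hypergeometric point probabilities ≤ that of the observed table
(relative tolerance 1e−7 for floating-point ties) — the point-probability
convention of mainstream statistical software (e.g. 3/4 vs 1/31 gives
P = 0.014, 0/20 vs 3/4 gives P = 0.012); the tail-doubling alternative
yields different values and is not used. Degenerate tables (a zero margin)
return p = 1 with a message. The
three pairwise prognosis comparisons are tested against the Bonferroni
threshold 0.05/3 = 0.0167.

## The synthetic cohort generator

Real patient recordings are not redistributable, so `simulate_cohort()`
builds virtual cohorts with known ground truth. Per subject:

- **Response.** Responders (all HC and MCS+; a `cmd_fraction` share of
  VS/UWS and MCS−, the planted CMD cases) receive ΔHbO = 0.5 µmol/L ×
  (task boxcar ⊛ canonical double-gamma HRF, peak 6 s, undershoot 16 s,
  ratio 1/6, normalized to unit peak) on every motor-ROI channel, and
  ΔHbR = −0.3 × ΔHbO delayed 1 s. The HRF form and HbO:HbR ratio are
  standard canonical choices consistent with the expected morphology
  (HbO up, HbR slightly down); no functional form is pinned down by data.
- **Physiological noise**, added in concentration space per channel:
  cardiac 1.1 Hz (2.2 µmol/L), respiratory 0.25 Hz (0.8), Mayer 0.1 Hz
  (0.5), 1/f drift (SD 0.8); HbR noise at 0.4× with independent phases.
  Each oscillation carries a random phase walk (diffusion 0.04 rad²/s,
  coherence ≈ 1 min). The phase walk matters: a *fixed-phase* 0.1 Hz
  sinusoid is exactly paradigm-locked (40 s block = 4 Mayer periods) and
  would survive block averaging undiminished, which contradicts both
  physiology (Mayer waves are quasi-periodic) and the premise that block
  averaging raises SNR. The amplitude budget is calibrated to two stated
  operating points: raw-intensity channel CV ≈ 5–10% (measured quantiles
  4.8–9.5%), and planted-responder recovery ≥ 0.8 sensitivity/specificity
  at the reporting ROI — the defaults are explicitly calibrated to make the
  pipeline's operating characteristics testable, not to match any clinical
  effect size, which no reference value pins down.
- **Artifacts.** Poisson-timed events (default 0.5/min), each hitting a
  random ~20% of channels (loose optodes): one-sample spikes of 0.5–2.0 OD
  or persistent baseline shifts of 0.2–1.0 OD. Events are channel-subset
  rather than whole-head because a persistent whole-head shift of this size
  would push *every* channel past the CV screen and void the recording —
  the regime handled in practice by excluding the subject outright.
- **Bad channels** get an 8× noise multiplier, guaranteeing CV > 15%.
- **Forward model.** Concentrations map to OD through the same extinction
  table, DPF and distance the inverse uses, then to strictly positive
  intensities I₀·10^(−OD) with per-channel random gains. All randomness
  flows from one seed through per-subject derived seeds; simulation without
  an explicit seed is refused.
- **Outcomes.** Patient responders draw a favorable 6-month GOS-E (≥4) with
  probability 0.45, non-responders 0.05 — covert command-following carries a
  markedly better prognosis, at odds of the order of 3-in-7 vs 1-in-30;
  10% of patients are lost to follow-up.

What the generator does *not* emulate: photon transport and partial-volume
effects, scalp/systemic physiology shared across channels, short-separation
regression, inter-subject amplitude variability in patients, and real
optode geometry. A green planted-recovery test therefore establishes that
the pipeline recovers command-following under the stated noise model — not
that the clinical sensitivity/specificity (68.4%/84.1%) would reproduce.

## Numerical and design choices

- Sample alignment uses one rule everywhere: index = `round(t × fs) + 1`
  (11 Hz gives non-integer sample times for most onsets).
- Channels 21, 28, 49 belong to no ROI; they pass preprocessing but never
  enter an ROI average.
- The paper's per-channel optode pairings are not published; the montage
  stores opaque source/detector labels with no geometric meaning.
- GA bounds (0.01, 10] comfortably contain the C and γ optima such searches
  settle on for this task family (≈0.2–9.8); the kernel is fixed to RBF.
- Reported rates are rounded to one decimal, p-values to three, the
  Bonferroni threshold to four; unrounded values are retained in objects.
- The noise-free round-trip test disables the motion corrector: with zero
  noise the median moving SD degenerates toward zero and the robust
  threshold flags smooth task transitions. The corrector's behaviour is
  specified and tested on spike/step fixtures instead.

## Limitations

Training sets of tens of subjects with 20-fold grouped CV leave the GA's
CV-accuracy estimate optimistically biased (the search selects on the same
folds); the planted-recovery tests score patients never seen in training, so
that bias does not inflate them. The strict two-label rule compounds
per-sample errors (≈ p² for sensitivity), which is why per-sample accuracy
must be high before patient-level recovery clears 0.8. Fisher enumeration
is exact but O(range) per table; fine for clinical table sizes.
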