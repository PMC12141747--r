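---
title: "Methods: phase-amplitude coupling as an EEG biomarker in ALS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-amplitude coupling as an EEG biomarker in ALS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Amyotrophic lateral sclerosis requires evidence of upper-motor-neuron
degeneration, which is clinically elusive. Cortical excitation/inhibition
imbalance precedes degeneration and should leave a trace in the coupling
between slow and fast EEG rhythms: the phase of slow oscillations
(theta 4–8 Hz, alpha 8–13 Hz, beta 13–30 Hz) modulates the amplitude of
gamma (30–60 Hz) activity, and that modulation depends on intact local
inhibitory circuits. `thetapac` implements an analysis in which theta–gamma
phase–amplitude coupling (PAC) at the central electrode over the
handedness-dominant sensorimotor cortex (Cd; C3 in right-handers, C4 in
left-handers) is compared between patients and controls, with band powers
as the control analysis, clinical phenotype and diffusion-MRI asymmetry as
companions, and ROC stratification as the payoff.

## The modulation index

For a candidate (phase frequency, amplitude frequency) cell, the signal is
band-passed in each band and the analytic signal gives the instantaneous
phase φ(t) of the slow band and the envelope A(t) of the fast band. Phases
are partitioned into N equal, left-closed bins over [−π, π); the
phase-conditioned amplitude profile

$$P_j = \frac{\langle A \rangle_j}{\sum_k \langle A \rangle_k}, \qquad
\mathrm{MI} = \frac{\log N - H(P)}{\log N}, \qquad
H(P) = -\sum_j P_j \log P_j$$

is the normalized Kullback–Leibler divergence of P from uniform. MI is 0
under phase-independence, 1 when all amplitude sits in one bin, invariant
to positive rescaling of A, and invariant to the logarithm base (natural
logs used internally).

Numerical choices:

- **N = 18 phase bins** (20° each), the standard for this estimator. The
  "100 evenly spaced bins per band" resolution is interpreted as the
  *comodulogram axis* resolution (100 frequency centers per axis in
  `pac_grid(fine = TRUE)`), not the phase-bin count; both are arguments.
- **Empty phase bins are a hard error** ("insufficient phase coverage"),
  never smoothed over: with the required ≥ 10·N samples of continuous
  phase, an empty bin can only come from a broken decomposition, and
  imputing it would bias MI toward 0.
- **Band edges are half-open** [lo, hi) everywhere (8 Hz is alpha,
  13 Hz is beta), consistently between the spectral and PAC modules.
- The default comodulogram grid is desk-scale (2-Hz phase steps, 5-Hz
  amplitude steps, bandwidths 2 and 10 Hz); `fine = TRUE` gives the
  100×100 map. `band_grid()` is the degenerate one-cell-per-band-pair grid
  whose mean MI is the direct band-level MI; the Monte-Carlo studies use
  it because it is ~25× cheaper and averages the same physical quantity.

### Filters

Preprocessing uses zero-phase forward–backward IIR filters (2nd-order
notch at 50 Hz with Q = 30; the 2–60 Hz band-pass as a cascade of
4th-order Butterworth high- and low-pass, which is numerically stable at
the very low normalized high-pass edge where a single band-pass design is
not). Filter transients (first/last second) are excluded via the
bad-segment mechanism.

The per-cell PAC decompositions instead use an exactly zero-phase
frequency-domain band-pass: the spectrum is multiplied by a raised-cosine
gain (transition width `min(2, max(0.5, 0.15·bandwidth))` Hz, clipped to
stay above DC) restricted to positive frequencies and doubled, so one
inverse FFT yields the band-limited analytic signal directly. This choice
is made because narrow IIR band-passes at normalized frequencies of ~0.01
are fragile under forward–backward filtering, FIR designs cost hundreds of
taps per cell, and a comodulogram needs one decomposition per axis center
— the FFT route makes the fine 100×100 map tractable while being exactly
linear-phase. Its circular wrap-around artifacts are confined to the
trimmed first/last second.

## The synthetic cohort generator

No raw recordings ship with the analysis (the study data are not publicly
available), so the generator is a first-class module that defines the
study conditions every downstream stage is tested against. Per channel:

- **aperiodic background**: spectrally shaped Gaussian noise with power
  ∝ 1/f^β, β = 1 by default, RMS 5 µV;
- **oscillations**: one narrowband cosine per band (theta 5 µV, alpha
  8 µV — the eyes-closed posterior-dominant rhythm is the largest —
  beta 3 µV, gamma 2 µV), with small per-subject frequency jitter
  (±0.5 Hz; ±1 Hz for gamma) and random initial phase. The cosine
  convention makes the emitted oscillation's analytic phase equal the
  phase that drives the coupling;
- **coupling**: the gamma carrier's envelope is multiplied by
  `1 − χ + χ·(1 + cos φ)/2` per coupling spec, which keeps the envelope
  in [(1−χ)·A, A] — non-negative for every depth χ ∈ [0, 1].

Defaults are the emulated study conditions: 5-minute recordings at
400 Hz, the five analysis electrodes (C3, C4, Cz, Fz, Pz), 26 subjects
per group, 23/26 right-handed, and the group coupling structure
control-Cd θ–γ = 0.6, ALS-Cd θ–γ = 0.2, Cn = 0.35 in both groups (Cd/Cn
resolved to C3/C4 per subject by handedness). Handedness affects
generation only through that resolution.

**Depth calibration.** Per-subject realized depth is drawn from a normal
centred on the spec depth, truncated to [0, 1], with SD 0.3 (specs at
exactly 0 stay uncoupled). The study's reported quantity is not an
absolute MI but an effect size — the Cd theta–gamma group contrast of
d ≈ 1.13 — so the generator was calibrated once against it: without
between-subject depth variability the MI estimator at 300 s is so precise
that d ≈ 7, which no real cohort shows; SD 0.3 puts the mean recovered d
at ≈ 1.15 at the full scale (n = 26/group, 300 s, 400 Hz), and the value
was then frozen.

**What the generator does not emulate**: eye-blink/EMG/ECG artifacts
(only optional amplitude bursts for testing rejection), volume conduction
and channel correlation, non-stationary coupling, 74-channel montage
realism. Passing tests therefore certify the estimator and inference
chain, not robustness to real-world artifact regimes.

## Preprocessing and artifact handling

Resample to 400 Hz (polyphase), average reference, notch, band-pass, then
artifact screening: 1-s windows of cross-channel RMS are z-scored robustly
(median/MAD) and windows above z = 5 become bad segments, merged with the
transient margins. The original analysis used ICA plus visual inspection;
that is deliberately out of scope here (the synthetic data carry no
physiological artifacts), and the deterministic RMS rule is the
configurable stand-in. A recording retaining less than `min_clean_s`
(default 60 s) of clean data is rejected with an explicit error rather
than analysed silently.

## Spectral control analysis

Band power can confound PAC, so the pipeline fits the same group model to
Welch band powers first. Welch: Hann windows of 2 s, 50% overlap, windows
confined to clean segments, one-sided density in µV²/Hz. Band power is the
mean of 10·log10(PSD) over in-band bins (the dB/Hz plotting convention);
whether one averages log-power or logs the average power is not fixed by
convention — the mean-log choice is implemented and the raw PSD is
returned for anyone wanting the alternative.

## Cohort statistics

Repeated-measures linear mixed models via `lmer` (REML), sum-coded
factors, type-III F-tests with Satterthwaite denominator degrees of
freedom (the reference analyses show fractional df; exact df replication
is not a goal — error rates and decisions are). Random structure: subject
intercept, optionally one random slope over a single within-subject
factor; a singular or unidentifiable slope fit falls back to the
intercept-only structure and is flagged. With one observation per subject
the mixed model is unidentifiable and an ordinary linear model (type-III
F) is used, flagged. Post hoc pairwise contrasts of marginal means are
Student t-tests, **unadjusted** for multiplicity to mirror the reference
reporting style (Holm is available but off). Effect sizes: pooled-SD
Cohen's d, local f² from R² of full vs term-deleted fits, Cramér's V.
IQR outliers use type-7 (linear interpolation) quartiles per
variable×condition cell — the flag set depends on the quantile convention,
hence it is pinned and documented.

## Clinical phenotyping

ECAS cut-offs: a score strictly greater than 77/100 (ALS-specific) or
105/136 (total) means *no* impairment, so boundary scores are impaired —
one packaged patient sits exactly on the 77 boundary and exercises the
rule. Missing ECAS (one patient) yields an undefined classification
excluded from contingency denominators only. Staging: onset ≤ 12 months =
early. Progression rate is the standard ΔFS construction
(48 − ALSFRS-r)/duration-in-months; the source analysis cites but does not
print its formula, and its published 5/7 early-slow/early-fast split is
not reproducible from the printed table under either median scope (all
patients or early-only — both are implemented behind a switch), so the
package reports its own split and never asserts the published one.
Similarly, Cramér's V for the form × impairment table computes to ≈ 0.21
from the printed counts, not the published 0.11; the chi-square (1.08)
does reproduce and is the asserted quantity.

## DTI asymmetry

Tabular analysis only (no image processing): per subject, level and
metric, the dominant − nondominant difference; group models on the raw
values (group × hemisphere × level, random intercept) and on the caudal
deltas (group × level). Levels are an ordered categorical factor — no
numeric rostro-caudal trend is fitted, matching the factor treatment of
the reference analysis. The synthetic generator injects caudal-only
asymmetry (FA +0.03/+0.04 at peduncle/brainstem in controls, attenuated
to +0.015/+0.01 in ALS, with matching small diffusivity offsets), a
subject×level random effect shared by both hemispheres, and measurement
noise; FA outside [0, 1] is re-drawn, never clipped.

## ROC stratification

AUC is computed by the rank (Mann–Whitney) statistic with tie correction,
which equals trapezoidal integration of the empirical curve. The operating
point maximizes Youden's J. Confidence intervals are stratified-bootstrap
percentiles (resampling within class, 2000 resamples by default, seeded);
bootstrap means of AUC/sensitivity/specificity at the per-resample Youden
point are reported alongside, since the reference analysis reports "mean"
operating characteristics without stating its procedure. Predictor
combination is a logistic model on standardized predictors; the combined
score is the linear predictor, each predictor is tested by a
likelihood-ratio chi-square (full vs deleted, df = 1), and perfect
separation triggers a flagged L2-penalized Newton fit rather than a
silent non-converged estimate.

## Monte-Carlo study design and problem sizes

The replicate studies keep the cohort sizes of the emulated study but
shrink the per-subject signal, a deliberate trade: the tested properties
are sign-recovery and error *rates*, which depend on the effect size
actually realized at the simulated scale, not on matching absolute MI.

- **Coupling recovery/specificity** (`coupling_recovery_study`): 100
  replicates × 26/group, 20-s recordings at 250 Hz, full preprocess + PAC
  path, cell-wise Student t-tests (the post hoc construction). At this
  scale the realized Cd θ–γ d ≈ 0.6, giving a sign-recovery rate ≥ 95%
  while keeping the study inside a test-suite-friendly budget; the
  specificity criterion is evaluated per off-target cell (each of the 14
  cells non-significant in ≥ 90% of replicates).
- **Null calibration** (`null_calibration_study`): summary tables drawn
  directly from the null mixed model (subject intercept + noise,
  n = 26/group) and pushed through the same `fit_rm_lmm` inference; 200
  replicates are used because at 100 the Monte-Carlo SD of a 5% rejection
  rate (2.2%) makes a ±3% band a coin-flip-prone check — 200 replicates
  test the same calibration property more stringently.
- **ROC ordering** (`roc_ordering_study`): Gaussian markers calibrated to
  population AUCs 0.86 (strong, EEG-like) and 0.64 (weak, DTI-like);
  the combined-versus-best comparison uses n = 100/group because the
  population AUC gap between combined (≈ 0.873) and strong marker is
  only ≈ 0.015, far below the in-sample AUC noise at n = 26.
- **DTI asymmetry** (`dti_asymmetry_study`): 100 replicates × 25/group,
  per-level pooled one-sample t on FA deltas (caudal detection; rostral
  false-positive control) and two-sample group contrast at brainstem.

All studies derive every random draw from a single master seed through a
32-bit-safe child-seed scheme, so every number is exactly reproducible.

## Known limitations

- The synthetic cohort is far cleaner than clinical EEG; real-data
  performance of the artifact rule and of PAC itself is not certified by
  these tests.
- Published F/df/p/AUC values from the real cohort are not reproduction
  targets — the underlying recordings are unavailable; only the printed
  clinical table supports exact worked examples.
- The random-slope structure for crossed within-subject factors is
  underdetermined; the implemented default (intercept + one slope factor,
  with singular-fit fallback) is one defensible choice among several.
- EDF I/O is not provided; the documented CSV + JSON container is the
  exchange format.
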