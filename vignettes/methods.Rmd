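---
title: "Methods: EEG grading, quantitative features and ICANS risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG grading, quantitative features and ICANS risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`icanseeg` analyses serial routine EEGs (a baseline recording 15–20 days
before CAR T-cell infusion, then post-infusion recordings on days 1, 3, 7
and 14) as predictors of ICANS, an encephalopathy whose EEG correlate is
background slowing. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic data generator
does and does not emulate.

## The qualitative arm: a rule-based grading scale

A visual read is captured on a structured form: predominant background
frequency (PBF: beta/alpha/theta/delta), symmetry, posterior dominant
rhythm, continuity, reactivity, voltage, state changes
(absent/physiological/pathological), the prevalence of diffuse theta and
delta slowing, and the prevalence and type of epileptiform abnormalities
(EA). Prevalence is classified from event rates: low < 1/min, moderate
≥ 1/min but < 1 per 10 s, high ≥ 1 per 10 s (`classify_prevalence()`).

`grade_record()` evaluates four rule sets and returns the **maximum**
triggered grade together with the fired rules. The maximum convention
follows the clinical principle that the worst finding drives severity, and
it is what makes the scale monotone: worsening any single descriptor can
only add rules, never remove them, so the grade never decreases. The test
suite verifies totality and this monotonicity exhaustively over the full
finite descriptor space (1536 grade-relevant combinations).

Two boundary completions the scale's tabular form does not pin down were
decided as follows:

* *Normal PBF* means alpha **or** beta background.
* *High-prevalence theta with a normal PBF* maps to grade 2 — the scale
  lists "+++" theta in its grade-2 row, and treating abundant theta as only
  slightly abnormal would break monotonicity against the moderate-theta
  grade-1 rule.

Dual-rater agreement is quantified by unweighted Cohen's kappa
(`cohens_kappa()`). Adjudication of disagreements is a human step and out
of computational scope; the package only flags them.

## The quantitative arm

### Preprocessing

Records are read from EDF (`read_edf()`; a minimal reader/writer is built
in, with labels normalized to plain 10-20 names). `apply_filters()` applies,
zero-phase, a 0.5–40 Hz bandpass (2nd-order Butterworth high-pass cascaded
with a 4th-order low-pass) and a comb of IIR notches (Q = 30) at the
powerline frequency (default 50 Hz) and its multiples below Nyquist.
Zero-phase (forward–backward) filtering is the routine-EEG convention and
avoids phase distortion that would bias phase-based connectivity.

Numerically, zero-phase filtering uses mirror padding (3 s per edge) with
steady-state initialization. The 0.5 Hz high-pass has a double pole at
radius ≈ 0.991, so naive forward–backward filtering leaves large edge
transients; mirror padding keeps the pad's band content identical to the
signal's and adds no offset, and the residual junction ringing decays
inside the pad. For a finite pure tone some ringing at the record edges is
unavoidable under any padding scheme; filter-response checks in the tests
therefore measure the steady-state response away from a 1 s settling margin.

`assemble_epoch()` excises annotated artifact intervals (half-open
`[onset, onset + duration)` in seconds) and concatenates the clean segments
directly, without tapering or crossfading — per-window tapering downstream
controls leakage at the seams, and windows are allowed to span seams.
Records with under 20 s of clean signal are rejected rather than analysed.
`make_windows()` then places 2.0 s windows every 0.25 s, giving
`floor((L − 2)/0.25) + 1` windows per epoch.

### Spectral and complexity features

* **PSD** (`window_psd()`): FFT periodogram with a Hann taper and
  power-consistent scaling (the integral over [0, Nyquist] recovers the
  window's mean power). The taper is a deliberate choice beyond a bare FFT:
  it bounds leakage across artifact seams.
* **Band energies** (`band_energy()`): trapezoidal integrals over δ=[2,4],
  θ=[4,8], α=[8,14], β=[14,30] Hz, plus the 0.5–40 Hz total. With 2 s
  windows the FFT grid step is 0.5 Hz, so band edges fall exactly on grid
  points.
* **Amplitude entropy** (`signal_entropy()`): differential entropy of the
  sample-amplitude histogram with Freedman–Diaconis bins, in nats. The
  complexity of the phase dimension is captured separately by PTE, so
  entropy is defined on amplitudes alone; a constant window returns a
  flagged `-Inf` sentinel. The estimator is validated against the Gaussian
  closed form ½ln(2πe) and the scaling law H(aX) = H(X) + ln|a|.
* **Higuchi fractal dimension** (`higuchi_fd()`): the standard curve-length
  construction with `kmax = 10` (conventional for 2 s windows at routine
  sampling rates; configurable), clipped to [1, 2] with a warning when
  estimator noise pushes it past the white-noise limit.

`summarize_record()` takes the **median jointly over all
(window, channel) pairs** for each feature — one scalar per feature per
record — and derives DTAR from the summarized energies. Channel-wise-first
aggregation would be an alternative; the joint median was chosen because
the risk models consume one scalar per record, and it is invariant to
channel ordering. Post-infusion records are normalized to the patient's
baseline by **ratio** (`normalize_to_baseline()`): ratios are scale-free
and comparable across patients, and a difference normalization would keep
the microvolt² scale that varies strongly between subjects. Baselines with
non-positive features refuse to normalize rather than emit infinities.

### Connectivity

Phase transfer entropy is computed on the **broadband** filtered signal
(no band selection bias) from analytic-signal phases
(`instantaneous_phase()`):

$$PTE_{x \to y} = \sum p(y_{t+\delta}, y_t, x_t)\,
  \log\frac{p(y_{t+\delta} \mid y_t, x_t)}{p(y_{t+\delta} \mid y_t)}$$

estimated by a triple histogram over the whole assembled epoch. Estimator
choices (all configurable, defaults are standard conventions): the delay
δ is the pooled samples-per-phase-sign-change of the channels; the number
of phase bins is `round(exp(0.626 + 0.4 ln(N − δ − 1)))`. PTE is computed
per epoch, not per 2 s window — a 2 s window provides too few phase samples
for a stable triple histogram. The implementation is checked to 1e-10
against an independent counting oracle.

`graph_metrics()` treats the PTE matrix as a weighted digraph. Path-based
measures (betweenness, eccentricity, diameter) use edge length
**1/weight** — stronger coupling, shorter distance; eigenvector centrality
is the Perron vector of the transposed weight matrix (incoming influence),
normalized to unit maximum; no edge thresholding is applied (thresholding
would add a free parameter with no principled default). Graphs that are
not strongly connected get `Inf` eccentricities/diameter, flagged rather
than raised. Note that eigenvector centrality is only well defined on
primitive (aperiodic, strongly connected) weight matrices; estimated PTE
matrices are strictly positive off the diagonal and always qualify.

## The risk layer

`expand_counting_process()` builds the long `(start, stop]` format with
time zero at infusion. The covariate is carried forward from the most
recent EEG at or before each interval start and updated at each
post-infusion EEG day; EEGs recorded on or after ICANS onset are excluded
from updates (they reflect the event, not its prediction). Patients with
only post-infusion EEGs enter at their first recording (delayed entry).

`fit_cox()` wraps `survival::coxph` with **Efron** tie handling — onsets
recorded at daily resolution make ties common — and reports HR, Wald 95%
CI and p per covariate. `stepwise_select()` does forward selection by
likelihood-ratio test at α = 0.05 with a backward check after each entry,
deterministic under lexicographic tie-breaking. `tertile_analysis()` uses
the linear-interpolation percentile convention (type 7) for the 33.3/66.7
cut-offs and fits the "above upper tertile" indicator. `group_compare()`
provides Mann-Whitney (continuous) and Pearson chi-square without
continuity correction (categorical). No multiple-testing correction is
applied across the feature family, mirroring the analysis design this
package implements; reports should state this.

## The synthetic cohort generator

`simulate_eeg()` builds each channel as a sum of band-limited sinusoidal
oscillators (frequency drawn uniformly inside the band with a 10% edge
margin, random phase) plus 1/f pink noise (spectral shaping of white
noise), with optional lagged, scaled couplings between channels and
artifact bursts (0.5–3 s, ten-fold amplitude) covering a configurable
fraction of the record. This exercises every downstream code path —
band-energy extraction, seam assembly, PTE directionality — without
claiming neurophysiological realism.

`simulate_cohort()` draws, per patient, a latent slowing severity
trajectory on the EEG schedule: a baseline value from the configured grade
mix (~88% normal, ~9% grade 1, ~3% grade 2, matching the reported
fraction of abnormal baseline recordings) plus a Gaussian per-timepoint
drift (mean 0.25, sd 0.5) clamped to [0, 3.5). The severity drives all
three observable layers coherently: the integer grade is its floor, the
paired evaluation form is sampled uniformly among descriptor combinations
consistent with that grade (so the grader round-trips exactly), and the
EEG spec's theta/delta amplitudes rise — and alpha falls — linearly with
it. ICANS onset is sampled from the piecewise-exponential hazard
`baseline_hazard · exp(β · x(t))` with the covariate constant between EEG
days, matching the counting-process formulation the risk module fits.

Default conditions emulate the serial-EEG study design: 68 patients,
baseline day uniform in [−20, −15], β = log 2 per severity unit, hazard
active in a 0–15 day post-infusion risk window (observed onsets fall in
that range), administrative censoring at day 30, and
`baseline_hazard = 0.0105`/day, calibrated once so cumulative incidence is
approximately 32%. The log-linear covariate-to-hazard link is an
assumption for testing, not a claim about ICANS biology; the generator
also does not model CRS dynamics, competing risks from early deaths,
realistic artifact morphology, or inter-channel volume conduction. Passing
tests therefore demonstrate correctness of the estimators and the
direction-recovery of the pipeline under the assumed generating model —
not clinical validity on real recordings.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; identical spec + seed
reproduces cohorts and signals bit for bit. The test suite uses: the full
1536-combination form space (exhaustive grading checks); 1000 two-second
windows for spectral ratios; 200 windows for the white-noise fractal limit;
100 seeds of 60 s two-channel epochs for PTE directionality; 100 random
digraphs of ≤ 6 nodes against exhaustive path enumeration; 200 replicate
cohorts of n = 1000 with a binary covariate (true HR 2) for estimate and
coverage checks; and one n = 1000 cohort with 4-channel, 22 s records for
the end-to-end dual-arm integration run. The binary-covariate cohort mode
skips form and signal generation, which parameter-recovery experiments do
not need.

## Known limitations

* The entropy estimator, normalization convention, aggregation order and
  PTE estimator details are reasonable standard choices where the analysis
  design leaves them open; all are configurable, and alternatives (e.g.
  difference normalization, per-window PTE) would change feature scales.
* Hazard constant within the risk window: simulated onset times are
  somewhat later on average than a front-loaded clinical hazard would give.
* The EDF implementation covers the plain EDF profile used here (equal
  sampling rates, 1 s records, integer Hz); it is not a general EDF+
  reader.
* Eccentricity/diameter are infinite on non-strongly-connected graphs;
  downstream medians propagate that honestly rather than imputing.
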