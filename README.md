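# icanseeg

EEG biomarkers of CAR T-cell neurotoxicity risk: a dual qualitative /
quantitative analysis pipeline with a synthetic serial-EEG cohort generator.

## The problem

Immune effector cell-associated neurotoxicity syndrome (ICANS) is an
encephalopathy that complicates CAR T-cell therapy in roughly a third of
treated lymphoma patients, with onset in the first two weeks after infusion.
Because encephalopathy has an EEG signature — background slowing from alpha
toward theta and delta — serial routine EEGs recorded before and after
infusion are a candidate early-warning biomarker. `icanseeg` implements both
arms of that analysis for neurophysiologists and biostatisticians working
with serial-EEG cohort designs:

* **Qualitative arm** — a rule-based 0–3 grading scale applied to structured
  visual-read evaluation forms (predominant background frequency,
  theta/delta/epileptiform abnormality prevalence, state changes,
  reactivity), plus Cohen's kappa for inter-rater agreement.
* **Quantitative arm** — band energies \(E_\delta, E_\theta, E_\alpha,
  E_\beta\) as PSD integrals over δ=[2,4], θ=[4,8], α=[8,14], β=[14,30] Hz,
  the slowing ratio DTAR \(= (E_\delta + E_\theta)/E_\alpha\), amplitude
  entropy \(H\), Higuchi fractal dimension \(F\), broadband phase transfer
  entropy \(PTE_{x\to y}\) between channels, and directed-graph measures
  (in/out-degree, betweenness and eigenvector centrality, eccentricity,
  diameter) on the PTE graph.
* **Risk layer** — fixed and time-dependent Cox proportional-hazards models
  in counting-process format \((start, stop]\) with covariates carried
  forward from the most recent pre-onset EEG, stepwise likelihood-ratio
  model selection, tertile cut-off analysis, and Mann-Whitney / chi-square
  group comparisons.
* **Synthetic cohort generator** — band-structured multichannel EEG
  (oscillators + pink noise + lagged couplings + artifact bursts, EDF I/O)
  and full patient timelines on the baseline / T1 / T3 / T7 / T14 schedule,
  with ICANS onsets drawn from a piecewise-exponential proportional-hazards
  model whose covariate is a latent slowing severity that also drives the
  simulated grades and theta/delta amplitudes — so every stage of the
  pipeline is testable without patient data.

## The grading scale

The maximum grade over all triggered rules is assigned:

| Grade | Rules |
|---|---|
| 0 normal | normal PBF (alpha/beta), ± low-prevalence theta, ± physiological state changes |
| 1 slightly abnormal | normal PBF + moderate theta and/or low delta and/or pathological state changes |
| 2 moderately abnormal | theta PBF, and/or high theta, and/or absent reactivity, and/or moderate delta, and/or low-prevalence epileptiform abnormalities |
| 3 severely abnormal | delta PBF, and/or high delta, and/or moderate/high-prevalence epileptiform abnormalities |

Prevalence classes: low < 1/min; moderate ≥ 1/min but < 1 per 10 s;
high ≥ 1 per 10 s.

## Worked example

```r
library(icanseeg)

# grade a visual read: theta background with moderate diffuse delta
form <- eeg_eval_form(pbf = "theta", delta_prevalence = "moderate")
grade_record(form)
#> EEG grade: 2 (moderately abnormal)
#>   rules fired: theta_pbf, delta_moderate

# a synthetic 120-patient serial-EEG cohort and the dual risk analysis
spec <- cohort_sim_spec(n_patients = 120, eeg_channels = 2,
                        eeg_duration = 22, seed = 41)
co <- simulate_cohort(spec)
co
#> Synthetic EEG cohort: 120 patients, 37 ICANS events (30.8%)

res <- run_risk_analysis(co, feature = "med_E_theta")
res$qualitative
#> Cox model (time_dependent covariates, 37 events)
#>   abnormal_eeg             HR 2.94 [95% CI 1.42-6.10]  p = 0.003758
res$quantitative
#> Cox model (time_dependent covariates, 37 events)
#>   med_E_theta              HR 1.12 [95% CI 1.02-1.23]  p = 0.02138
```

Both arms point the same way on the simulated cohort: EEGs graded abnormal
(grade ≥ 1) nearly triple the ICANS hazard, and each unit of
baseline-normalized median theta energy raises it by ~12%. The hazard ratios
quantify relative event rates per day at risk; the time-dependent model
updates each patient's covariate at every EEG day before onset.

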