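#' Quantitative features for one simulated EEG
#'
#' Convenience wrapper chaining simulation, filtering, epoch assembly,
#' windowing and feature summarization for a single [eeg_sim_spec()].
#'
#' @param spec An [eeg_sim_spec()].
#' @param features Feature groups for [window_features()].
#' @param connectivity Whether to add PTE/graph summaries (slower).
#' @param powerline Powerline frequency for [apply_filters()].
#' @return A `record_features` object, or an `epoch_rejection` if the clean
#'   signal is too short.
#' @export
features_from_sim <- function(spec, features = "energy",
                              connectivity = FALSE, powerline = 50) {
  sim <- simulate_eeg(spec)
  rec <- apply_filters(sim$record, powerline = powerline)
  ep <- assemble_epoch(rec, sim$artifacts)
  if (inherits(ep, "epoch_rejection")) return(ep)
  ws <- make_windows(ep)
  wf <- window_features(ws, features = features)
  conn <- if (connectivity) connectivity_summary(pte_matrix(ep)) else NULL
  summarize_record(wf, connectivity = conn)
}

#' Per-EEG quantitative feature table for a simulated cohort
#'
#' Simulates every non-excluded EEG in the cohort from its stored spec, runs
#' the quantitative pipeline, and returns one measurement row per EEG for the
#' requested summary feature, optionally normalized to each patient's
#' baseline record.
#'
#' @param cohort An `eeg_cohort` from [simulate_cohort()].
#' @param feature Name of the `record_features` entry to tabulate (e.g.
#'   `"med_E_theta"`, `"DTAR"`).
#' @param normalize Normalize post-infusion values to baseline via
#'   [normalize_to_baseline()] (default TRUE; patients without a usable
#'   baseline are dropped).
#' @param features Feature groups to compute (default energies only).
#' @return Data frame `patient_id`, `day`, `timepoint`, `value` suitable for
#'   [expand_counting_process()].
#' @export
cohort_feature_table <- function(cohort, feature = "med_E_theta",
                                 normalize = TRUE, features = "energy") {
  out <- list()
  for (p in cohort) {
    keep <- which(!p$excluded)
    if (length(keep) == 0) next
    rf <- lapply(keep, function(j) features_from_sim(p$eeg_specs[[j]],
                                                     features = features))
    ok <- !vapply(rf, inherits, logical(1), "epoch_rejection")
    keep <- keep[ok]; rf <- rf[ok]
    if (length(keep) == 0) next
    if (normalize) {
      b <- which(p$timepoints[keep] == "baseline")
      if (length(b) != 1) next
      base <- rf[[b]]
      vals <- vapply(seq_along(rf), function(k) {
        if (k == b) return(1)
        normalize_to_baseline(rf[[k]], base)[[feature]]
      }, numeric(1))
    } else {
      vals <- vapply(rf, function(r) r[[feature]], numeric(1))
    }
    out[[length(out) + 1]] <- data.frame(
      patient_id = p$patient_id, day = p$eeg_days[keep],
      timepoint = p$timepoints[keep], value = vals)
  }
  if (length(out) == 0) stop("no usable EEGs in the cohort")
  do.call(rbind, out)
}

#' Run the dual qualitative/quantitative ICANS risk analysis on a cohort
#'
#' The end-to-end pipeline: grades every evaluation form with the 0-3 scale
#' and fits a time-dependent Cox model for the "any EEG abnormality"
#' indicator (grade >= 1); extracts the requested quantitative feature from
#' the simulated signals, fits a time-dependent Cox model on the continuous
#' value, and runs the upper-tertile cut-off analysis.
#'
#' @param cohort An `eeg_cohort`.
#' @param feature Quantitative summary feature (default `"med_E_theta"`).
#' @param normalize Normalize features to baseline (default TRUE).
#' @return List with `qualitative` (grade-indicator [fit_cox()] table),
#'   `quantitative` (continuous-feature fit), `tertile`
#'   ([tertile_analysis()] output) and the underlying survival row tables.
#' @export
run_risk_analysis <- function(cohort, feature = "med_E_theta",
                              normalize = TRUE) {
  outcomes <- cohort_outcomes(cohort)

  grades <- cohort_measurements(cohort, what = function(p, j)
    grade_record(p$forms[[j]])$value)
  grades$value <- as.numeric(grades$value >= 1)
  qual_rows <- expand_counting_process(grades, outcomes, name = "abnormal_eeg")
  qual <- fit_cox(qual_rows, "abnormal_eeg")

  feats <- cohort_feature_table(cohort, feature = feature,
                                normalize = normalize)
  quant_rows <- expand_counting_process(feats, outcomes, name = feature)
  quant <- fit_cox(quant_rows, feature)
  tert <- tertile_analysis(quant_rows, feature)

  list(qualitative = qual, quantitative = quant, tertile = tert,
       qualitative_rows = qual_rows, quantitative_rows = quant_rows)
}
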