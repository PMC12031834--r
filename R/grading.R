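# Controlled vocabularies for the visual-read evaluation form. Prevalence
# levels are ordered none < low < moderate < high; "low" is < 1/min,
# "moderate" is >= 1/min but < 1 per 10 s, "high" is >= 1 per 10 s.
.pbf_levels        <- c("beta", "alpha", "theta", "delta")
.prevalence_levels <- c("none", "low", "moderate", "high")
.state_levels      <- c("absent", "physiological", "pathological")
.symmetry_levels   <- c("symmetric", "mild_asymmetry", "marked_asymmetry")
.continuity_levels <- c("continuous", "nearly_continuous", "discontinuous",
                        "burst_suppression")
.voltage_levels    <- c("normal", "attenuated", "suppressed")
.ea_type_levels    <- c("sporadic", "rhythmic_periodic", "seizure", "status")

#' Construct a structured EEG visual-read evaluation form
#'
#' Bundles the descriptors a reader records for a routine EEG: predominant
#' background frequency (PBF), background symmetry/continuity/voltage,
#' posterior dominant rhythm, reactivity, state changes, the prevalence of
#' non-epileptiform slowing in the theta and delta ranges, and the prevalence
#' and type of epileptiform abnormalities (EA). The form is the sole input to
#' [grade_record()].
#'
#' @param pbf Predominant background frequency: `"beta"`, `"alpha"`,
#'   `"theta"` or `"delta"`. Alpha and beta count as a normal background.
#' @param theta_prevalence,delta_prevalence Prevalence class of diffuse
#'   theta / delta slowing: `"none"`, `"low"` (< 1/min), `"moderate"`
#'   (>= 1/min but < 1 per 10 s) or `"high"` (>= 1 per 10 s). Delta
#'   prevalence covers both polymorphic and rhythmic delta activity.
#' @param state_changes `"absent"`, `"physiological"` (gradual alpha
#'   attenuation with emerging theta in relaxed wakefulness) or
#'   `"pathological"` (alpha rapidly replaced by long-lasting diffuse delta
#'   after eye closure, indicating somnolence).
#' @param reactivity_present Logical; background reactivity to stimulation.
#' @param ea_prevalence Prevalence class of epileptiform abnormalities.
#' @param ea_type Type of epileptiform abnormality; required when
#'   `ea_prevalence != "none"`, must be `NA` otherwise.
#' @param symmetry,pdr_present,continuity,voltage,iic_flag Remaining
#'   descriptive fields; recorded on the form but not used by the grading
#'   rules.
#' @return An object of class `eeg_eval_form`.
#' @seealso [grade_record()], [simulate_eval_form()]
#' @examples
#' f <- eeg_eval_form(pbf = "alpha", theta_prevalence = "moderate")
#' grade_record(f)
#' @export
eeg_eval_form <- function(pbf = "alpha",
                          theta_prevalence = "none",
                          delta_prevalence = "none",
                          state_changes = "absent",
                          reactivity_present = TRUE,
                          ea_prevalence = "none",
                          ea_type = NA_character_,
                          symmetry = "symmetric",
                          pdr_present = TRUE,
                          continuity = "continuous",
                          voltage = "normal",
                          iic_flag = FALSE) {
  pbf <- match.arg(pbf, .pbf_levels)
  theta_prevalence <- match.arg(theta_prevalence, .prevalence_levels)
  delta_prevalence <- match.arg(delta_prevalence, .prevalence_levels)
  state_changes <- match.arg(state_changes, .state_levels)
  ea_prevalence <- match.arg(ea_prevalence, .prevalence_levels)
  symmetry <- match.arg(symmetry, .symmetry_levels)
  continuity <- match.arg(continuity, .continuity_levels)
  voltage <- match.arg(voltage, .voltage_levels)
  stopifnot(is.logical(reactivity_present), length(reactivity_present) == 1,
            is.logical(pdr_present), is.logical(iic_flag))
  if (ea_prevalence == "none") {
    if (!is.na(ea_type))
      stop("ea_type must be NA when no epileptiform abnormalities are present")
  } else {
    if (is.na(ea_type))
      stop("ea_type is required when ea_prevalence != \"none\"")
    ea_type <- match.arg(ea_type, .ea_type_levels)
  }
  structure(list(
    pbf = pbf,
    theta_prevalence = theta_prevalence,
    delta_prevalence = delta_prevalence,
    state_changes = state_changes,
    reactivity_present = reactivity_present,
    ea_prevalence = ea_prevalence,
    ea_type = ea_type,
    symmetry = symmetry,
    pdr_present = pdr_present,
    continuity = continuity,
    voltage = voltage,
    iic_flag = iic_flag
  ), class = "eeg_eval_form")
}

#' @export
print.eeg_eval_form <- function(x, ...) {
  cat("EEG evaluation form\n")
  cat("  PBF:", x$pbf, "| reactivity:",
      if (x$reactivity_present) "present" else "absent", "\n")
  cat("  prevalence  theta:", x$theta_prevalence,
      " delta:", x$delta_prevalence, " EA:", x$ea_prevalence,
      if (!is.na(x$ea_type)) paste0("(", x$ea_type, ")") else "", "\n")
  cat("  state changes:", x$state_changes, "\n")
  invisible(x)
}

#' Classify abnormality prevalence from an event rate
#'
#' Maps a per-minute rate of EEG abnormalities (epileptiform or not) to the
#' three prevalence classes used on the evaluation form: low for < 1/min,
#' moderate for >= 1/min but less than 1 per 10 s, high for >= 1 per 10 s
#' (i.e. >= 6/min).
#'
#' @param rate Events per minute; non-negative.
#' @return `"low"`, `"moderate"` or `"high"`.
#' @examples
#' classify_prevalence(0.5)  # low
#' classify_prevalence(3)    # moderate
#' classify_prevalence(6)    # high
#' @export
classify_prevalence <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0))
    stop("rate must be a finite non-negative events-per-minute value")
  out <- ifelse(rate < 1, "low", ifelse(rate < 6, "moderate", "high"))
  out
}

# The four rule sets of the grading scale. Each rule: predicate on the form
# and the grade it triggers. The final grade is the maximum triggered grade.
.grading_rules <- list(
  list(id = "normal_background",   grade = 0L,
       test = function(f) f$pbf %in% c("alpha", "beta")),
  list(id = "theta_moderate",      grade = 1L,
       test = function(f) f$pbf %in% c("alpha", "beta") &&
         f$theta_prevalence == "moderate"),
  list(id = "delta_low",           grade = 1L,
       test = function(f) f$pbf %in% c("alpha", "beta") &&
         f$delta_prevalence == "low"),
  list(id = "pathological_state_changes", grade = 1L,
       test = function(f) f$state_changes == "pathological"),
  list(id = "theta_pbf",           grade = 2L,
       test = function(f) f$pbf == "theta"),
  list(id = "theta_high",          grade = 2L,
       test = function(f) f$theta_prevalence == "high"),
  list(id = "reactivity_absent",   grade = 2L,
       test = function(f) !f$reactivity_present),
  list(id = "delta_moderate",      grade = 2L,
       test = function(f) f$delta_prevalence == "moderate"),
  list(id = "ea_low",              grade = 2L,
       test = function(f) f$ea_prevalence == "low"),
  list(id = "delta_pbf",           grade = 3L,
       test = function(f) f$pbf == "delta"),
  list(id = "delta_high",          grade = 3L,
       test = function(f) f$delta_prevalence == "high"),
  list(id = "ea_moderate_high",    grade = 3L,
       test = function(f) f$ea_prevalence %in% c("moderate", "high"))
)

#' Grade an EEG evaluation form on the 0-3 encephalopathy scale
#'
#' Applies the rule-based grading scale to a visual-read form and returns the
#' maximum triggered grade together with the identifiers of all rules that
#' fired. The rule sets are:
#'
#' * **0 (normal)** — normal PBF (alpha or beta), with at most low-prevalence
#'   theta activity and/or physiological state changes;
#' * **1 (slightly abnormal)** — normal PBF with moderate-prevalence theta
#'   and/or low-prevalence delta and/or pathological state changes;
#' * **2 (moderately abnormal)** — theta PBF, and/or high-prevalence theta,
#'   and/or absent reactivity, and/or moderate-prevalence delta, and/or
#'   low-prevalence epileptiform abnormalities;
#' * **3 (severely abnormal)** — delta PBF, and/or high-prevalence delta,
#'   and/or moderate- or high-prevalence epileptiform abnormalities.
#'
#' Conflicting rule hits resolve to the maximum grade, following the clinical
#' convention that the worst finding drives severity.
#'
#' @param form An [eeg_eval_form()].
#' @return An object of class `eeg_grade`: list with integer `value` (0-3)
#'   and character `triggered_rules`.
#' @examples
#' grade_record(eeg_eval_form(pbf = "alpha", theta_prevalence = "low",
#'                            state_changes = "physiological"))  # grade 0
#' grade_record(eeg_eval_form(pbf = "delta", ea_prevalence = "high",
#'                            ea_type = "sporadic"))             # grade 3
#' @export
grade_record <- function(form) {
  if (!inherits(form, "eeg_eval_form"))
    stop("form must be an eeg_eval_form")
  fired <- Filter(function(r) isTRUE(r$test(form)), .grading_rules)
  # an abnormal PBF always fires its own rule, so `fired` is never empty
  grades <- vapply(fired, function(r) r$grade, integer(1))
  structure(list(
    value = max(grades),
    triggered_rules = vapply(fired, function(r) r$id, character(1))
  ), class = "eeg_grade")
}

#' @export
print.eeg_grade <- function(x, ...) {
  labels <- c("normal", "slightly abnormal", "moderately abnormal",
              "severely abnormal")
  cat("EEG grade:", x$value, sprintf("(%s)", labels[x$value + 1L]), "\n")
  cat("  rules fired:", paste(x$triggered_rules, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the grade-relevant evaluation-form space
#'
#' Returns a data frame with one row per combination of the descriptors the
#' grading rules consult (PBF, theta/delta/EA prevalence, state changes,
#' reactivity), plus the grade each combination maps to. Used for exhaustive
#' totality and monotonicity checks, and to sample forms consistent with a
#' target grade.
#'
#' @return Data frame with descriptor columns and an integer `grade` column.
#' @keywords internal
#' @export
enumerate_form_space <- function() {
  grid <- expand.grid(
    pbf = .pbf_levels,
    theta_prevalence = .prevalence_levels,
    delta_prevalence = .prevalence_levels,
    state_changes = .state_levels,
    reactivity_present = c(TRUE, FALSE),
    ea_prevalence = .prevalence_levels,
    stringsAsFactors = FALSE,
    KEEP.OUT.ATTRS = FALSE
  )
  grid$grade <- vapply(seq_len(nrow(grid)), function(i) {
    f <- eeg_eval_form(
      pbf = grid$pbf[i],
      theta_prevalence = grid$theta_prevalence[i],
      delta_prevalence = grid$delta_prevalence[i],
      state_changes = grid$state_changes[i],
      reactivity_present = grid$reactivity_present[i],
      ea_prevalence = grid$ea_prevalence[i],
      ea_type = if (grid$ea_prevalence[i] == "none") NA_character_
                else "sporadic"
    )
    grade_record(f)$value
  }, integer(1))
  grid
}

#' Cohen's kappa for inter-rater agreement on EEG grades
#'
#' Unweighted Cohen's kappa between two raters' grade sequences:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} where \eqn{p_o} is observed
#' agreement and \eqn{p_e} chance agreement from the marginal distributions.
#'
#' @param ratings_a,ratings_b Equal-length vectors of grades (0-3).
#' @return Kappa as a single number; 1 for perfect agreement, about 0 for
#'   independent raters, negative for worse-than-chance agreement.
#' @examples
#' cohens_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3))  # 1
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop("rating vectors must have equal length")
  n <- length(ratings_a)
  if (n < 2) stop("need at least 2 paired ratings")
  if (!all(ratings_a %in% 0:3) || !all(ratings_b %in% 0:3))
    stop("grades must be integers in 0..3")
  lev <- 0:3
  tab <- table(factor(ratings_a, levels = lev), factor(ratings_b, levels = lev))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)  # both raters constant and identical
  (po - pe) / (1 - pe)
}
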