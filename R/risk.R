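#' Expand serial EEG measurements into counting-process survival rows
#'
#' Builds the long (start, stop] format for time-dependent Cox regression.
#' Time zero is the infusion day. The covariate is carried forward from the
#' most recent EEG on or before each interval's start; it is updated at every
#' post-infusion EEG day. Measurements taken on or after ICANS onset are
#' excluded from covariate updates. Patients with a baseline (pre-infusion)
#' measurement enter at day 0; patients with only post-infusion measurements
#' enter at their first measurement day (delayed entry).
#'
#' @param measurements Data frame with columns `patient_id`, `day` (relative
#'   to infusion; negative = baseline) and `value`.
#' @param outcomes Data frame with columns `patient_id`, `icans_day` (`NA`
#'   for no event) and `censor_day`.
#' @param name Name for the covariate column in the output.
#' @return Data frame with `patient_id`, `start`, `stop`, `event` and the
#'   covariate column; rows per patient partition their at-risk time.
#' @export
expand_counting_process <- function(measurements, outcomes,
                                    name = "value") {
  stopifnot(all(c("patient_id", "day", "value") %in% names(measurements)),
            all(c("patient_id", "icans_day", "censor_day") %in%
                  names(outcomes)))
  if (any(measurements$day < -Inf) || any(!is.finite(measurements$day)))
    stop("measurement days must be finite")
  meas_by_pid <- split(measurements[c("day", "value")],
                       measurements$patient_id)
  acc_pid <- list(); acc_start <- list(); acc_stop <- list()
  acc_event <- list(); acc_val <- list()
  for (i in seq_len(nrow(outcomes))) {
    pid <- outcomes$patient_id[i]
    onset <- outcomes$icans_day[i]
    cens <- outcomes$censor_day[i]
    if (!is.na(cens) && cens < 0) stop("negative censor_day for ", pid)
    has_event <- !is.na(onset)
    end <- if (has_event) onset else cens
    m <- meas_by_pid[[as.character(pid)]]
    if (is.null(m)) next
    # EEGs recorded during clinical ICANS carry no predictive value here
    if (has_event) m <- m[m$day < onset, , drop = FALSE]
    if (nrow(m) == 0) next
    m <- m[order(m$day), , drop = FALSE]
    has_baseline <- any(m$day <= 0)
    entry <- if (has_baseline) 0 else min(m$day)
    if (end <= entry) {
      # event essentially at entry: one short immediate-event row
      end <- entry + 1e-3
    }
    cuts <- sort(unique(m$day[m$day > entry & m$day < end]))
    bounds <- c(entry, cuts, end)
    nk <- length(bounds) - 1
    starts <- bounds[-length(bounds)]
    vals <- m$value[findInterval(starts, m$day)]
    if (!has_baseline) vals[1] <- m$value[1]
    acc_pid[[i]] <- rep(pid, nk)
    acc_start[[i]] <- starts
    acc_stop[[i]] <- bounds[-1]
    acc_event[[i]] <- c(rep(0L, nk - 1), as.integer(has_event))
    acc_val[[i]] <- vals
  }
  if (length(acc_pid) == 0) stop("no usable patients in the input")
  out <- data.frame(
    patient_id = unlist(acc_pid), start = unlist(acc_start),
    stop = unlist(acc_stop), event = unlist(acc_event),
    value = unlist(acc_val)
  )
  names(out)[names(out) == "value"] <- name
  rownames(out) <- NULL
  validate_survival_rows(out)
  out
}

#' Validate counting-process survival rows
#'
#' Checks the structural invariants of the long format: positive-length
#' intervals, at most one event per patient, per-patient rows contiguous and
#' non-overlapping.
#'
#' @param rows Data frame with `patient_id`, `start`, `stop`, `event`.
#' @return `rows`, invisibly; stops on violation.
#' @export
validate_survival_rows <- function(rows) {
  if (any(rows$start >= rows$stop))
    stop("survival rows must have start < stop")
  o <- order(rows$patient_id, rows$start)
  pid <- rows$patient_id[o]
  ev_per_pid <- tapply(rows$event[o], pid, sum)
  if (any(ev_per_pid > 1))
    stop("more than one event row for patient ",
         names(ev_per_pid)[which(ev_per_pid > 1)[1]])
  same <- pid[-1] == pid[-length(pid)]
  gap <- abs(rows$start[o][-1] - rows$stop[o][-length(o)]) > 1e-9
  if (any(same & gap))
    stop("rows for patient ", pid[-1][which(same & gap)[1]],
         " overlap or leave gaps")
  invisible(rows)
}

#' Fit a Cox proportional-hazards model to EEG-derived covariates
#'
#' Partial-likelihood fit with Efron tie handling (onsets recorded at daily
#' resolution make ties common). Accepts either counting-process rows
#' (`start`, `stop`, `event`) for time-dependent covariates or simple
#' per-patient rows (`time`, `event`) for fixed baseline covariates.
#'
#' @param rows Data frame in either format, with one column per covariate.
#' @param covariates Character vector of covariate column names; defaults to
#'   every non-reserved column.
#' @param model_type `"time_dependent"` or `"fixed"`; recorded in the
#'   results and used to pick the expected input format.
#' @param min_events Minimum number of events required (default 5).
#' @return Data frame of class `cox_results`, one row per covariate:
#'   `covariate`, `hr`, `ci_low`, `ci_high` (Wald 95%), `p_value`,
#'   `n_events`, `model_type`, `adjusted` (TRUE when more than one covariate
#'   is in the model). The `survival::coxph` fit is attached as attribute
#'   `"fit"`.
#' @export
fit_cox <- function(rows, covariates = NULL,
                    model_type = c("time_dependent", "fixed"),
                    min_events = 5) {
  model_type <- match.arg(model_type)
  reserved <- c("patient_id", "start", "stop", "time", "event")
  if (is.null(covariates)) covariates <- setdiff(names(rows), reserved)
  if (length(covariates) == 0) stop("no covariates to fit")
  n_events <- sum(rows$event)
  if (n_events == 0) stop("degenerate fit: no events in the data")
  if (n_events < min_events)
    stop("too few events (", n_events, ") for a stable fit")
  for (cv in covariates) {
    if (!cv %in% names(rows)) stop("covariate not found: ", cv)
    if (length(unique(rows[[cv]])) < 2)
      stop("degenerate fit: covariate ", cv, " is constant across rows")
  }
  if (model_type == "time_dependent") {
    validate_survival_rows(rows)
    surv <- "survival::Surv(start, stop, event)"
  } else {
    if (!"time" %in% names(rows))
      stop("fixed-covariate fits need a `time` column")
    surv <- "survival::Surv(time, event)"
  }
  fml <- stats::as.formula(paste(surv, "~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = rows, ties = "efron")
  converged <- is.null(fit$info) ||
    isTRUE(fit$info[["convergence"]] == 0)
  if (!converged || any(is.na(stats::coef(fit))))
    stop("Cox fit failed to converge or produced undefined coefficients")
  s <- summary(fit)
  co <- s$coefficients
  res <- data.frame(
    covariate = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(co[, "Pr(>|z|)"]),
    n_events = n_events,
    model_type = model_type,
    adjusted = length(covariates) > 1,
    row.names = NULL
  )
  class(res) <- c("cox_results", "data.frame")
  attr(res, "fit") <- fit
  res
}

#' @export
print.cox_results <- function(x, ...) {
  cat(sprintf("Cox model (%s covariates, %d events)%s\n",
              x$model_type[1], x$n_events[1],
              if (x$adjusted[1]) ", adjusted" else ""))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-24s HR %.2f [95%% CI %.2f-%.2f]  p = %.4g\n",
                x$covariate[i], x$hr[i], x$ci_low[i], x$ci_high[i],
                x$p_value[i]))
  invisible(x)
}

# log partial likelihood of a fitted coxph
.cox_ll <- function(fit) fit$loglik[length(fit$loglik)]

#' Stepwise Cox model selection by likelihood-ratio test
#'
#' Forward selection over candidate covariates with a likelihood-ratio entry
#' test at `alpha`, followed after each entry by a backward check removing
#' covariates whose LRT p-value has risen above `alpha`. Ties between
#' candidates with equal p-values break lexicographically, making the
#' procedure deterministic.
#'
#' @param rows Survival rows as for [fit_cox()].
#' @param candidates Character vector of candidate covariate names.
#' @param alpha LRT significance threshold (default 0.05).
#' @param model_type Passed to [fit_cox()].
#' @return List with `selected` (character vector, possibly empty),
#'   `results` (the [fit_cox()] table of the final model, or `NULL`) and
#'   `trace` (data frame of entry/removal steps).
#' @export
stepwise_select <- function(rows, candidates, alpha = 0.05,
                            model_type = c("time_dependent", "fixed")) {
  model_type <- match.arg(model_type)
  candidates <- sort(candidates)
  selected <- character(0)
  trace <- list()
  ll_of <- function(vars) {
    if (length(vars) == 0) return(NULL)
    attr(fit_cox(rows, vars, model_type = model_type), "fit")
  }
  current_ll <- NULL  # NULL = null model; loglik[1] of any fit is its ll
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    ps <- vapply(remaining, function(cv) {
      fit1 <- tryCatch(ll_of(c(selected, cv)), error = function(e) NULL)
      if (is.null(fit1)) return(NA_real_)
      ll0 <- if (length(selected) == 0) fit1$loglik[1]
             else .cox_ll(ll_of(selected))
      stats::pchisq(2 * (.cox_ll(fit1) - ll0), df = 1, lower.tail = FALSE)
    }, numeric(1))
    ps <- ps[!is.na(ps)]
    if (length(ps) == 0 || min(ps) >= alpha) break
    best <- names(ps)[which(ps == min(ps))][1]  # lexicographic tie-break
    selected <- sort(c(selected, best))
    trace[[length(trace) + 1]] <- data.frame(step = "add", covariate = best,
                                             p = min(ps))
    # backward check
    repeat {
      if (length(selected) < 2) break
      drop_ps <- vapply(setdiff(selected, best), function(cv) {
        full <- ll_of(selected)
        red <- ll_of(setdiff(selected, cv))
        ll_red <- if (is.null(red)) full$loglik[1] else .cox_ll(red)
        stats::pchisq(2 * (.cox_ll(full) - ll_red), df = 1,
                      lower.tail = FALSE)
      }, numeric(1))
      if (length(drop_ps) == 0 || max(drop_ps) <= alpha) break
      worst <- names(drop_ps)[which(drop_ps == max(drop_ps))][1]
      selected <- setdiff(selected, worst)
      trace[[length(trace) + 1]] <- data.frame(step = "drop",
                                               covariate = worst,
                                               p = max(drop_ps))
    }
  }
  list(
    selected = selected,
    results = if (length(selected)) fit_cox(rows, selected,
                                            model_type = model_type)
              else NULL,
    trace = if (length(trace)) do.call(rbind, trace)
            else data.frame(step = character(0), covariate = character(0),
                            p = numeric(0))
  )
}

#' Tertile cut-off analysis of a quantitative EEG feature
#'
#' Identifies the empirical tertile cut-offs (33.3rd and 66.7th percentiles,
#' linear-interpolation convention) of a feature and fits a Cox model for the
#' indicator "above the upper-tertile cut-off".
#'
#' @param rows Survival rows containing the feature column.
#' @param feature Name of the feature column.
#' @param model_type Passed to [fit_cox()].
#' @return List with `cutoffs` (length 2), `results` (a [fit_cox()] table
#'   for the dichotomized covariate, `NULL` when degenerate) and `degenerate`
#'   flag. Heavy ties that collapse the tertiles raise a warning.
#' @export
tertile_analysis <- function(rows, feature,
                             model_type = c("time_dependent", "fixed")) {
  model_type <- match.arg(model_type)
  values <- rows[[feature]]
  if (is.null(values)) stop("feature not found: ", feature)
  if (length(values) < 9) stop("tertile analysis needs at least 9 values")
  cutoffs <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  ind <- as.numeric(values > cutoffs[2])
  if (cutoffs[1] == cutoffs[2] || length(unique(ind)) < 2) {
    warning("degenerate tertile cut-offs for ", feature,
            " (heavy ties); no dichotomized fit")
    return(list(cutoffs = cutoffs, results = NULL, degenerate = TRUE))
  }
  rows2 <- rows
  rows2[[paste0(feature, "_upper_tertile")]] <- ind
  res <- fit_cox(rows2, paste0(feature, "_upper_tertile"),
                 model_type = model_type)
  list(cutoffs = cutoffs, results = res, degenerate = FALSE)
}

#' Two-group comparison of cohort characteristics
#'
#' Mann-Whitney (Wilcoxon rank-sum) test for continuous variables, Pearson
#' chi-square (without continuity correction) for categorical ones; both
#' two-sided.
#'
#' @param values Numeric vector (continuous) or category labels
#'   (categorical).
#' @param groups Two-level grouping vector of the same length.
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `statistic`, `p_value` and `method`.
#' @export
group_compare <- function(values, groups,
                          kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("group_compare requires exactly two groups")
  if (kind == "continuous") {
    g <- levels(droplevels(groups))
    ht <- stats::wilcox.test(values[groups == g[1]], values[groups == g[2]],
                             exact = FALSE, correct = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Mann-Whitney U")
  } else {
    tab <- table(values, droplevels(groups))
    if (any(suppressWarnings(stats::chisq.test(tab,
                                               correct = FALSE))$expected < 5))
      warning("chi-square expected counts below 5; interpret with caution")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Pearson chi-square")
  }
}
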