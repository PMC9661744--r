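# Molecular response calls from longitudinal ctDNA concentration, their
# agreement with radiographic response, and survival contrasts.

TIMEPOINT_ORDER <- c(baseline = 1L, week8 = 2L, progression = 3L)

#' Call molecular (ctDNA) response
#'
#' A ctDNA response is a reduction of at least 50% in ctDNA concentration
#' (hGE/mL) from baseline to follow-up.  Patients whose baseline sample is
#' ctDNA-negative are not evaluable (there is no concentration to fall
#' from) and are flagged accordingly.  A follow-up-negative sample with a
#' positive baseline is a response (100% reduction).
#'
#' @param baseline,followup [sample_profile()] objects for the same
#'   patient and compartment, with `baseline$timepoint` preceding
#'   `followup$timepoint`.
#' @return A one-row data.frame (`response_call`): `patient_id`,
#'   `compartment`, `baseline_conc`, `followup_conc`, `pct_change`
#'   (negative = decrease; `NA` when not evaluable), `evaluable`,
#'   `responder`.
#' @export
call_response <- function(baseline, followup) {
  if (baseline$patient_id != followup$patient_id ||
      baseline$compartment != followup$compartment) {
    stop("baseline and follow-up must share patient and compartment")
  }
  if (TIMEPOINT_ORDER[baseline$timepoint] >=
      TIMEPOINT_ORDER[followup$timepoint]) {
    stop("baseline timepoint must precede follow-up timepoint")
  }
  b <- baseline$ctdna_hge_per_ml
  f <- followup$ctdna_hge_per_ml
  evaluable <- baseline$is_positive && b > 0
  data.frame(
    patient_id = baseline$patient_id,
    compartment = baseline$compartment,
    baseline_conc = b, followup_conc = f,
    pct_change = if (evaluable) 100 * (f - b) / b else NA_real_,
    evaluable = evaluable,
    responder = evaluable && f <= 0.5 * b,
    stringsAsFactors = FALSE
  )
}

#' Call responses across a cohort
#'
#' @param profiles A list of [sample_profile()] objects.
#' @param compartment Compartment to evaluate.
#' @param baseline_tp,followup_tp Timepoints compared.
#' @return A data.frame of response calls, one row per patient with both
#'   samples present; patients missing either sample are skipped and
#'   counted in the `n_missing_followup` attribute.
#' @export
cohort_responses <- function(profiles, compartment = "CSF",
                             baseline_tp = "baseline",
                             followup_tp = "week8") {
  pts <- unique(vapply(profiles, `[[`, character(1), "patient_id"))
  rows <- list()
  n_missing <- 0L
  for (pt in pts) {
    b <- find_profile(profiles, pt, compartment, baseline_tp)
    f <- find_profile(profiles, pt, compartment, followup_tp)
    if (is.null(b)) next
    if (is.null(f)) { n_missing <- n_missing + 1L; next }
    rows[[pt]] <- call_response(b, f)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), compartment = character(0),
               baseline_conc = numeric(0), followup_conc = numeric(0),
               pct_change = numeric(0), evaluable = logical(0),
               responder = logical(0))
  rownames(out) <- NULL
  attr(out, "n_missing_followup") <- n_missing
  out
}

#' Agreement between molecular and radiographic response
#'
#' Binarizes RECIST-style labels (by default CR/PR = responder, SD/PD =
#' non-responder), pairs them with evaluable molecular response calls, and
#' summarizes agreement as a 2x2 table with Cohen's kappa.
#'
#' @param calls A data.frame of response calls (see [call_response()]).
#' @param labels A data.frame with `patient_id` and
#'   `radiographic_response` (RECIST category or an already-binarized
#'   label present in `mapping`).
#' @param mapping Named character vector mapping each radiographic label
#'   to `"responder"` or `"nonresponder"`.
#' @return A `contingency_2x2` (molecular call as A, radiographic as B).
#' @export
response_vs_radiology <- function(calls, labels,
                                  mapping = c(CR = "responder",
                                              PR = "responder",
                                              SD = "nonresponder",
                                              PD = "nonresponder")) {
  calls <- calls[calls$evaluable, , drop = FALSE]
  if (nrow(calls) == 0L) stop("no evaluable response calls")
  m <- merge(calls, labels, by = "patient_id")
  if (nrow(m) == 0L) stop("no patients shared between calls and labels")
  unmapped <- setdiff(unique(m$radiographic_response), names(mapping))
  if (length(unmapped) > 0L) {
    stop("radiographic labels without a responder mapping: ",
         paste(unmapped, collapse = ", "))
  }
  rad <- unname(mapping[m$radiographic_response]) == "responder"
  mol <- m$responder
  contingency_table(sum(mol & rad), sum(mol & !rad),
                    sum(!mol & rad), sum(!mol & !rad))
}

validate_survival_records <- function(records) {
  needed <- c("time_months", "event")
  if (!all(needed %in% names(records))) {
    stop("survival records need columns time_months and event")
  }
  if (any(records$time_months <= 0)) stop("non-positive survival time")
  records$event <- as.logical(records$event)
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimate of the survival function, with
#' the median read off as the earliest event time at which the estimated
#' survival drops to 0.5 or below (undefined -- `NA` -- when survival
#' never reaches 0.5).
#'
#' @param records A data.frame with `time_months` (positive) and `event`
#'   (`TRUE` = event observed, `FALSE` = censored).
#' @return An object of class `km_estimate`: a `table` data.frame (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `median` and `n`.
#' @export
km_fit <- function(records) {
  records <- validate_survival_records(records)
  if (nrow(records) == 0L) stop("no survival records")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  ev <- tab[tab$n_event > 0, , drop = FALSE]
  median_t <- if (any(ev$surv <= 0.5)) min(ev$time[ev$surv <= 0.5])
              else NA_real_
  structure(list(table = tab, median = median_t, n = nrow(records)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, events = %d, median = %s\n",
              x$n, sum(x$table$n_event),
              if (is.na(x$median)) "not reached" else
                format(x$median, digits = 4)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with 1 degree of freedom and
#' its upper-tail p-value.  When neither group has an event the statistic
#' is 0 and p = 1.
#'
#' @param group_a,group_b Survival record data.frames (see [km_fit()]).
#' @return A list with `statistic`, `p_value`, `n_events`.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- validate_survival_records(group_a)
  group_b <- validate_survival_records(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  df <- rbind(
    data.frame(time_months = group_a$time_months, event = group_a$event,
               grp = "a"),
    data.frame(time_months = group_b$time_months, event = group_b$event,
               grp = "b"))
  if (sum(df$event) == 0L) {
    return(list(statistic = 0, p_value = 1, n_events = 0L))
  }
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ grp, data = df, rho = 0)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n_events = sum(df$event))
}

#' Univariate hazard ratio between two groups
#'
#' Fits a single-covariate proportional-hazards model (partial
#' likelihood, Efron ties) with group B as reference, and returns the
#' hazard ratio of group A relative to group B with its Wald 95%
#' confidence interval.  Swapping the groups inverts the ratio.
#'
#' @param group_a,group_b Survival record data.frames (see [km_fit()]).
#' @return A list with `hr`, `ci95` (length-2 vector), `log_hr`,
#'   `se_log_hr` and the Wald `p_value`.
#' @export
univariate_hr <- function(group_a, group_b) {
  group_a <- validate_survival_records(group_a)
  group_b <- validate_survival_records(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (sum(group_a$event) + sum(group_b$event) == 0L) {
    stop("hazard ratio is not estimable without events")
  }
  df <- rbind(
    data.frame(time_months = group_a$time_months, event = group_a$event,
               x = 1),
    data.frame(time_months = group_b$time_months, event = group_b$event,
               x = 0))
  fit <- survival::coxph(survival::Surv(time_months, event) ~ x, data = df)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(hr = exp(beta),
       ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       log_hr = beta, se_log_hr = se,
       p_value = 2 * stats::pnorm(-abs(beta / se)))
}

#' Read a clinical table
#'
#' TSV with columns `patient_id`, `endpoint` (`icPFS`, `ecPFS` or `OS`),
#' `time_months`, `event` (0/1) and `radiographic_response` (RECIST
#' string).
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "endpoint", "time_months", "event",
              "radiographic_response")
  missing_cols <- setdiff(needed, names(cl))
  if (length(missing_cols) > 0L) {
    stop("clinical table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(cl$time_months <= 0)) stop("non-positive survival time")
  cl$event <- as.logical(cl$event)
  cl
}

#' Survival contrast between molecular response groups
#'
#' Splits patients by a grouping variable (typically the ctDNA responder
#' flag), restricts the clinical table to one endpoint, and runs the
#' Kaplan-Meier / log-rank / hazard-ratio battery.
#'
#' @param clinical A clinical table (see [read_clinical_table()]).
#' @param groups A data.frame with `patient_id` and logical `in_group_a`;
#'   patients absent from `groups` are excluded.
#' @param endpoint Endpoint label to analyze.
#' @return A list with `km_a`, `km_b`, `logrank`, `hr`, `n_a`, `n_b`.
#' @export
survival_contrast <- function(clinical, groups, endpoint = "icPFS") {
  cl <- clinical[clinical$endpoint == endpoint, , drop = FALSE]
  m <- merge(cl, groups, by = "patient_id")
  a <- m[m$in_group_a, , drop = FALSE]
  b <- m[!m$in_group_a, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("both response groups must be non-empty for endpoint ", endpoint)
  }
  list(km_a = km_fit(a), km_b = km_fit(b),
       logrank = logrank_test(a, b), hr = univariate_hr(a, b),
       n_a = nrow(a), n_b = nrow(b))
}
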