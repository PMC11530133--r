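#' Impute survival events from insurance-claims gaps
#'
#' Real-world overall survival runs from day 0 (e.g. treatment initiation) to
#' death or last contact in the claims repository. Death is assumed for any
#' patient whose last claim is followed by a silence of strictly more than
#' `gap_days` before the repository cutoff; otherwise the patient is censored
#' at the last claim. The event (or censoring) date is the last claim date;
#' months are days / 30.44.
#'
#' @param claims List of `Date` vectors (one per patient, strictly
#'   increasing) or a single `Date` vector for one patient.
#' @param day0 `Date` vector (or scalar) of per-patient day-0 anchors; claims
#'   must not precede it.
#' @param gap_days Claims-gap threshold in days (default 100; the rule is a
#'   strict inequality).
#' @param data_cutoff Repository cutoff `Date`, at or after every last claim.
#' @return `data.frame` with `os_months` and `event` (1 = imputed death).
#' @export
impute_events_from_claims <- function(claims, day0, gap_days = 100L, data_cutoff) {
  if (inherits(claims, "Date")) claims <- list(claims)
  n <- length(claims)
  day0 <- rep(as.Date(day0), length.out = n)
  data_cutoff <- as.Date(data_cutoff)
  os <- numeric(n)
  ev <- integer(n)
  for (i in seq_len(n)) {
    cl <- as.Date(claims[[i]])
    if (!length(cl)) stop("patient ", i, " has an empty claim list")
    if (any(cl < day0[i])) stop("patient ", i, " has claims before day 0")
    last <- max(cl)
    if (data_cutoff < last) stop("data_cutoff precedes last claim of patient ", i)
    gap <- as.numeric(data_cutoff - last)
    ev[i] <- as.integer(gap > gap_days)
    os[i] <- as.numeric(last - day0[i]) / 30.44
  }
  data.frame(os_months = os, event = ev)
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator. The median is the first observed time at which
#' the survival curve drops to 0.5 or below; it is `NA` ("not reached") when
#' the curve never does.
#'
#' @param t Non-negative survival times.
#' @param e Event indicators (1 = event, 0 = censored).
#' @return List with `curve` (`data.frame`: `time`, `n_risk`, `n_event`,
#'   `survival`) and `median_os`.
#' @export
km_estimate <- function(t, e) {
  if (!length(t)) stop("empty input")
  if (any(t < 0)) stop("times must be >= 0")
  if (!all(e %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "none")
  curve <- data.frame(
    time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, survival = fit$surv
  )
  crossing <- curve$time[curve$survival <= 0.5 & curve$n_event > 0]
  median_os <- if (length(crossing)) min(crossing) else NA_real_
  list(curve = curve, median_os = median_os)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with 1 degree of freedom.
#'
#' @param t,e Survival times and event indicators.
#' @param group Two-level grouping vector.
#' @return List with `chi2` and `p`.
#' @export
logrank <- function(t, e, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("log-rank needs exactly 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(t, e) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary covariate
#'
#' Partial-likelihood estimate with Efron handling of tied event times
#' (Breslow available by flag); the hazard ratio is for the second factor
#' level relative to the first, with `exp(beta +/- 1.96 se)` as the 95% CI.
#'
#' @param t,e Survival times and event indicators.
#' @param group Two-level covariate.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List with `hr`, `ci95` (length-2), `p` (Wald), `beta`, `se`.
#' @export
cox_hr <- function(t, e, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("cox_hr needs exactly 2 non-empty groups")
  ev_per_group <- tapply(e, group, sum)
  if (any(ev_per_group == 0)) {
    stop(
      "no events in group(s): ",
      paste(names(ev_per_group)[ev_per_group == 0], collapse = ", "),
      " (monotone likelihood)"
    )
  }
  fit <- survival::coxph(survival::Surv(t, e) ~ group, ties = ties)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(
    hr = exp(beta),
    ci95 = exp(beta + c(-1.96, 1.96) * se),
    p = summary(fit)$coefficients[1, "Pr(>|z|)"],
    beta = beta, se = se
  )
}

#' Compare overall survival between expression-defined groups
#'
#' For each requested contrast (pair of group labels), fits Kaplan-Meier
#' curves, a two-group log-rank test and a univariate Cox model (hazard of
#' the first label relative to the second). With `strata`, the comparison is
#' repeated within each stratum level (subset and refit), matching per-site
#' survival panels.
#'
#' @param clin Clinical `data.frame` with `sample_id`, `os_months`, `event`.
#' @param labels Named vector mapping sample ids to group labels.
#' @param contrasts List of length-2 character vectors (or a single pair),
#'   e.g. `list(c("APUC6hi_ARlo", "APUC6lo_ARhi"))`.
#' @param strata Optional name of a `clin` column to stratify by
#'   (`"biopsy_site"`, `"histology"`, `"hormone_status"`).
#' @return `data.frame` with one row per contrast (x stratum): `contrast`,
#'   `stratum`, `n_a`, `n_b`, `hr`, `ci_lo`, `ci_hi`, `logrank_chi2`,
#'   `logrank_p`, `median_a`, `median_b` (`NA` = not reached).
#' @export
compare_groups_os <- function(clin, labels, contrasts, strata = NULL) {
  validate_clinical(clin)
  if (is.character(contrasts) && length(contrasts) == 2L) contrasts <- list(contrasts)
  lab <- labels[clin$sample_id]
  strata_vals <- if (is.null(strata)) {
    rep("all", nrow(clin))
  } else {
    if (!strata %in% colnames(clin)) stop("no clinical column '", strata, "'")
    as.character(clin[[strata]])
  }
  rows <- list()
  for (ct in contrasts) {
    if (length(ct) != 2L) stop("each contrast must be a pair of labels")
    if (!all(ct %in% lab)) {
      stop("contrast label(s) absent from cohort: ", paste(setdiff(ct, lab), collapse = ", "))
    }
    for (lev in unique(strata_vals)) {
      sel <- strata_vals == lev & lab %in% ct
      t <- clin$os_months[sel]
      e <- clin$event[sel]
      g <- factor(lab[sel], levels = rev(ct)) # hazard of ct[1] vs ct[2]
      if (nlevels(droplevels(g)) != 2L) next
      cx <- cox_hr(t, e, g)
      lr <- logrank(t, e, g)
      km_a <- km_estimate(t[g == ct[1]], e[g == ct[1]])
      km_b <- km_estimate(t[g == ct[2]], e[g == ct[2]])
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(ct, collapse = ":"),
        stratum = lev,
        n_a = sum(g == ct[1]), n_b = sum(g == ct[2]),
        hr = cx$hr, ci_lo = cx$ci95[1], ci_hi = cx$ci95[2],
        logrank_chi2 = lr$chi2, logrank_p = lr$p,
        median_a = km_a$median_os, median_b = km_b$median_os,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no contrast could be evaluated")
  do.call(rbind, rows)
}
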