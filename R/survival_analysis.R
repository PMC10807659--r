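## Overall-survival analysis by mutation status: Kaplan-Meier estimation
## with log-rank testing, and univariate / multivariate Cox
## proportional-hazards models.  Model fitting is delegated to the
## `survival` package (Efron tie handling); this module owns covariate
## encoding, degenerate-input detection and result shaping.

#' Kaplan-Meier estimate per group with a log-rank test
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicator (1 = death, 0 = censored).
#' @param groups Group label per subject (any atomic type; >= 2 levels for
#'   the log-rank test).
#' @return A list with `curves` (a data frame of per-group step functions:
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `logrank_chisq`,
#'   `logrank_df`, `logrank_p` and the underlying [survival::survfit()]
#'   object in `fit`.
#' @export
km_estimate <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 1L)
    stop_format("every group must contain at least one subject")
  if (sum(events) < 1L)
    stop_format("log-rank test needs at least one event")
  dat <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           data = dat)
  sf <- summary(fit, censored = TRUE)
  strata <- if (is.null(sf$strata)) rep(levels(groups)[1], length(sf$time))
            else sub("^groups=", "", as.character(sf$strata))
  curves <- data.frame(group = strata, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  logrank_chisq <- logrank_p <- NA_real_
  logrank_df <- NA_integer_
  if (nlevels(groups) >= 2L) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups,
                             data = dat)
    logrank_chisq <- sd$chisq
    logrank_df <- length(sd$n) - 1L
    logrank_p <- stats::pchisq(sd$chisq, df = logrank_df,
                               lower.tail = FALSE)
  }
  list(curves = curves, logrank_chisq = logrank_chisq,
       logrank_df = logrank_df, logrank_p = logrank_p, fit = fit)
}

## Encode a clinical/biomarker data frame into numeric Cox covariates.
## sex -> indicator male; stage -> ordinal numeric (or factor when
## stage_as_factor); msi -> indicator of MSI status; tmb -> log2(tmb + 1).
encode_covariates <- function(records, covariates, stage_as_factor = FALSE) {
  enc <- list()
  for (cv in covariates) {
    enc[[cv]] <- switch(cv,
      sex = as.numeric(records$sex == "male"),
      stage = if (stage_as_factor) factor(records$stage)
              else as.numeric(records$stage),
      msi = as.numeric(records$msi_status == "MSI"),
      tmb = tmb_log2(records$tmb),
      {
        v <- records[[cv]]
        if (is.null(v)) stop_format("unknown covariate '%s'", cv)
        if (is.logical(v)) as.numeric(v) else v
      })
  }
  as.data.frame(enc, optional = TRUE)
}

fit_one_cox <- function(df) {
  const <- vapply(df[-(1:2)], function(v)
    length(unique(v[!is.na(v)])) < 2L, logical(1))
  if (any(const))
    stop_format("covariate '%s' is constant across subjects",
                names(const)[const][1])
  fit <- survival::coxph(
    survival::Surv(os_time, os_event) ~ .,
    data = df, ties = "efron")
  s <- summary(fit)
  converged <- is.null(fit$info) && all(is.finite(fit$coefficients))
  warn_flag <- !is.null(fit$coefficients) &&
    any(abs(fit$coefficients) > 15)  # symptom of complete separation
  data.frame(
    term = rownames(s$coefficients),
    log_hr = s$coefficients[, "coef"],
    hazard_ratio = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    ci95_low = s$conf.int[, "lower .95"],
    ci95_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    n = s$n, n_events = s$nevent,
    log_likelihood = fit$loglik[2],
    converged = converged & !warn_flag,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cox proportional-hazards model of overall survival
#'
#' Fits either one joint multivariate model over all requested covariates,
#' or (with `univariate = TRUE`) a sequence of single-covariate models.
#' Recognised covariate names with built-in encodings: `focal_mutated`
#' (logical), `sex` (indicator of male), `age` (years), `stage` (ordinal
#' numeric by default), `msi` (indicator of MSI status), `tmb` (entered as
#' `log2(tmb + 1)`).  Any other name is looked up as a column of
#' `records`.  Ties are handled with the Efron approximation.  A constant
#' covariate is an error; suspected complete separation (|log HR| > 15) is
#' flagged via `converged = FALSE`, never silently.
#'
#' @param records Data frame with `os_time`, `os_event` and the covariate
#'   source columns.
#' @param covariates Character vector of covariate names.
#' @param univariate Fit one model per covariate instead of a joint model.
#' @param stage_as_factor Enter stage as a categorical factor instead of
#'   ordinal numeric.
#' @return A data frame with one row per model term: `log_hr`,
#'   `hazard_ratio`, `se`, `ci95_low`, `ci95_high`, `p_value`, model `n`,
#'   `n_events`, `log_likelihood`, `converged`; univariate results carry a
#'   `model` column naming the covariate.
#' @export
cox_fit <- function(records, covariates, univariate = FALSE,
                    stage_as_factor = FALSE) {
  if (!all(c("os_time", "os_event") %in% names(records)))
    stop_format("records must contain os_time and os_event")
  n_events <- sum(records$os_event, na.rm = TRUE)
  if (!univariate && n_events < length(covariates) + 1L)
    stop_format("too few events (%d) for %d covariates",
                n_events, length(covariates))
  base <- records[c("os_time", "os_event")]
  if (univariate) {
    out <- lapply(covariates, function(cv) {
      df <- cbind(base, encode_covariates(records, cv, stage_as_factor))
      res <- fit_one_cox(df)
      res$model <- cv
      res
    })
    do.call(rbind, out)
  } else {
    df <- cbind(base, encode_covariates(records, covariates,
                                        stage_as_factor))
    fit_one_cox(df)
  }
}

#' Kaplan-Meier curves stratified by two genes' mutation status
#'
#' Forms the four strata mut/mut, mut/wt, wt/mut, wt/wt from two mutation
#' status flags, drops empty strata with a warning, and reports per-stratum
#' curves plus the overall log-rank test across the remaining strata.
#'
#' @param times,events Follow-up times and event indicators.
#' @param status_a,status_b Logical mutation status for genes A and B.
#' @param labels Length-2 character vector naming the genes.
#' @return As [km_estimate()], with strata labelled
#'   `"<A>_mut/<B>_wt"` etc.
#' @export
stratified_km <- function(times, events, status_a, status_b,
                          labels = c("A", "B")) {
  lab <- paste0(labels[1], ifelse(status_a, "_mut/", "_wt/"),
                labels[2], ifelse(status_b, "_mut", "_wt"))
  all_levels <- as.vector(outer(
    paste0(labels[1], c("_mut", "_wt")),
    paste0(labels[2], c("_mut", "_wt")), paste, sep = "/"))
  empty <- setdiff(all_levels, unique(lab))
  if (length(empty))
    warning(sprintf("dropping empty stratum(s): %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  km_estimate(times, events, factor(lab))
}
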