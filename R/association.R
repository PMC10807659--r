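## Group comparisons between focal-gene mutated and wild-type samples:
## Mann-Whitney U for continuous readouts (age, TMB, CIN, MSI fraction,
## cell scores), Fisher's exact test for sex proportions, Pearson
## chi-square for the stage distribution.

comparison_result <- function(variable, test_name, statistic = NA_real_,
                              p_value = NA_real_, effect_summary = list(),
                              n_mut = NA_integer_, n_wt = NA_integer_,
                              evaluable = TRUE, note = NULL) {
  structure(list(variable = variable, test_name = test_name,
                 statistic = statistic, p_value = p_value,
                 effect_summary = effect_summary,
                 n_mut = n_mut, n_wt = n_wt,
                 evaluable = evaluable, note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g (n_mut = %d, n_wt = %d)%s\n",
              x$variable, x$test_name, x$statistic, x$p_value,
              x$n_mut, x$n_wt,
              if (x$evaluable) "" else " [not evaluable]"))
  invisible(x)
}

## Mann-Whitney U statistic of the "mutated" group, midranks for ties.
mann_whitney_u <- function(values, groups) {
  r <- rank(values)
  n1 <- sum(groups)
  sum(r[groups]) - n1 * (n1 + 1) / 2
}

## Exact two-sided permutation p-value for the Mann-Whitney U statistic:
## enumerate all assignments of group labels and count those whose U is at
## least as far from the null mean n1*n2/2 as the observed one.  Valid with
## ties (the midrank multiset is fixed across assignments).
mann_whitney_exact_p <- function(values, groups) {
  n <- length(values)
  n1 <- sum(groups)
  r <- rank(values)
  offset <- n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[groups]) - offset
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - offset
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Compare a continuous readout between mutated and wild-type groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test.  For a total sample
#' size of at most `exact_max` the p-value is exact, from full enumeration
#' of all group-label assignments (valid under ties); beyond that the
#' normal approximation with tie and continuity correction is used.
#'
#' @param values Numeric readout, one value per sample.
#' @param groups Logical vector, `TRUE` for mutated samples.
#' @param variable Readout name for reporting.
#' @param exact_max Largest total n for the exact enumeration path.
#' @return A `comparison_result` with the U statistic of the mutated group,
#'   p-value and group medians.
#' @export
compare_continuous <- function(values, groups, variable = "value",
                               exact_max = 12) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.logical(groups[keep])
  n1 <- sum(groups); n0 <- sum(!groups)
  if (n1 == 0L || n0 == 0L)
    return(comparison_result(variable, "mann_whitney",
                             n_mut = n1, n_wt = n0, evaluable = FALSE,
                             note = "a group is empty"))
  u <- mann_whitney_u(values, groups)
  if (diff(range(values)) == 0) {
    p <- 1  # every observation tied: no evidence either way
  } else if (length(values) <= exact_max) {
    p <- mann_whitney_exact_p(values, groups)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values[groups], values[!groups],
                         exact = FALSE, correct = TRUE))$p.value
  }
  comparison_result(variable, "mann_whitney", statistic = u,
                    p_value = p,
                    effect_summary = list(
                      median_mut = stats::median(values[groups]),
                      median_wt = stats::median(values[!groups])),
                    n_mut = n1, n_wt = n0)
}

#' Compare a binary trait (e.g. sex) between groups
#'
#' Two-sided Fisher's exact test on the 2 x 2 table of trait by group.
#'
#' @param flags Logical per-sample trait (e.g. `sex == "male"`).
#' @param groups Logical vector, `TRUE` for mutated samples.
#' @param variable Trait name for reporting.
#' @return A `comparison_result` with the conditional-MLE odds ratio as
#'   statistic, p-value and group proportions.
#' @export
compare_proportion <- function(flags, groups, variable = "proportion") {
  keep <- !is.na(flags) & !is.na(groups)
  flags <- as.logical(flags[keep]); groups <- as.logical(groups[keep])
  n1 <- sum(groups); n0 <- sum(!groups)
  tab <- matrix(c(sum(flags & groups), sum(!flags & groups),
                  sum(flags & !groups), sum(!flags & !groups)), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(comparison_result(variable, "fisher_exact",
                             n_mut = n1, n_wt = n0, evaluable = FALSE,
                             note = "an empty table margin"))
  ft <- stats::fisher.test(tab)
  comparison_result(variable, "fisher_exact",
                    statistic = unname(ft$estimate), p_value = ft$p.value,
                    effect_summary = list(
                      prop_mut = tab[1, 1] / n1, prop_wt = tab[1, 2] / n0),
                    n_mut = n1, n_wt = n0)
}

#' Compare the stage distribution between groups
#'
#' Pearson chi-square test on the 2 x k contingency table of group by stage
#' (df = k - 1), without continuity correction.  A warning note is attached
#' when any expected cell count is below 5.
#'
#' @param stages Ordinal stage per sample (1-4; `NA` dropped).
#' @param groups Logical vector, `TRUE` for mutated samples.
#' @param variable Name for reporting.
#' @return A `comparison_result` with the chi-square statistic and p-value;
#'   not evaluable when fewer than two stage levels are present.
#' @export
compare_stage <- function(stages, groups, variable = "stage") {
  keep <- !is.na(stages) & !is.na(groups)
  stages <- stages[keep]; groups <- as.logical(groups[keep])
  n1 <- sum(groups); n0 <- sum(!groups)
  levels_present <- sort(unique(stages))
  if (length(levels_present) < 2L || n1 == 0L || n0 == 0L)
    return(comparison_result(variable, "chi_square",
                             n_mut = n1, n_wt = n0, evaluable = FALSE,
                             note = "fewer than two stage levels"))
  tab <- table(factor(groups, levels = c(TRUE, FALSE)),
               factor(stages, levels = levels_present))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  note <- if (any(ct$expected < 5))
    "expected cell count < 5; chi-square approximation may be poor"
  comparison_result(variable, "chi_square",
                    statistic = unname(ct$statistic),
                    p_value = ct$p.value,
                    effect_summary = list(table = tab),
                    n_mut = n1, n_wt = n0, note = note)
}

#' Compare cell-type scores between groups
#'
#' One Mann-Whitney comparison per score row (cell type or aggregate
#' score), with Benjamini-Hochberg adjustment across rows and significance
#' tiers matching the usual star convention (< 0.001, < 0.01, < 0.05).
#'
#' @param cell_scores Numeric matrix, score rows x samples.
#' @param groups Logical vector aligned with the matrix columns, `TRUE`
#'   for mutated samples.
#' @return A data frame with one row per score: medians, U statistic,
#'   `p_value`, `q_value` and a `stars` column.
#' @export
compare_cell_scores <- function(cell_scores, groups) {
  groups <- as.logical(groups)
  rows <- rownames(cell_scores)
  res <- lapply(rows, function(ct)
    compare_continuous(cell_scores[ct, ], groups, variable = ct))
  out <- data.frame(
    cell_type = rows,
    median_mut = vapply(res, function(r)
      r$effect_summary$median_mut %||% NA_real_, numeric(1)),
    median_wt = vapply(res, function(r)
      r$effect_summary$median_wt %||% NA_real_, numeric(1)),
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    p_value = vapply(res, function(r) r$p_value, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$stars <- cut(out$q_value, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""), right = FALSE)
  out$stars <- as.character(out$stars)
  out
}

#' All mutation-status group comparisons for a cohort
#'
#' Runs the standard comparison battery against the focal mutation status:
#' Mann-Whitney for age, TMB, CIN and MSI fraction; Fisher's exact for sex;
#' chi-square for stage.
#'
#' @param clinical Clinical data frame with a logical `focal_mutated`
#'   column.
#' @param biomarkers Per-sample biomarker data frame from
#'   [compute_biomarkers()] (rows matched to `clinical` by `sample`).
#' @return A data frame, one row per comparison, with test name, statistic,
#'   p-value, group medians/proportions and group sizes.
#' @export
compare_groups <- function(clinical, biomarkers = NULL) {
  groups <- clinical$focal_mutated
  res <- list(compare_continuous(clinical$age, groups, "age"),
              compare_proportion(clinical$sex == "male", groups, "sex_male"),
              compare_stage(clinical$stage, groups))
  if (!is.null(biomarkers)) {
    bm <- biomarkers[match(clinical$sample, biomarkers$sample), ]
    res <- c(res, list(
      compare_continuous(bm$tmb, groups, "tmb"),
      compare_continuous(bm$msi_fraction, groups, "msi_fraction"),
      compare_continuous(bm$cin, groups, "cin")))
  }
  data.frame(
    variable = vapply(res, function(r) r$variable, character(1)),
    test_name = vapply(res, function(r) r$test_name, character(1)),
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    p_value = vapply(res, function(r) r$p_value, numeric(1)),
    summary_mut = vapply(res, function(r)
      (r$effect_summary$median_mut %||% r$effect_summary$prop_mut) %||%
        NA_real_, numeric(1)),
    summary_wt = vapply(res, function(r)
      (r$effect_summary$median_wt %||% r$effect_summary$prop_wt) %||%
        NA_real_, numeric(1)),
    n_mut = vapply(res, function(r) r$n_mut, integer(1)),
    n_wt = vapply(res, function(r) r$n_wt, integer(1)),
    evaluable = vapply(res, function(r) r$evaluable, logical(1)),
    stringsAsFactors = FALSE
  )
}
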