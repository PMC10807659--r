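## Per-sample instability biomarkers: tumor mutational burden (TMB),
## microsatellite instability (MSI) from paired tumor/normal repeat-length
## histograms, and the chromosomal instability (CIN) score from copy-number
## segments.

#' Tumor mutational burden for one sample
#'
#' Counts somatic coding substitutions and indels, excluding synonymous
#' calls and (optionally) known driver mutations, divided by the panel
#' footprint in megabases.  Input calls are assumed to be already filtered.
#'
#' @param calls Filtered variant calls for one sample (data frame).
#' @param panel_mb Megabases of genome examined by the panel; must be > 0.
#' @param exclude_drivers Drop calls flagged `is_known_driver` before
#'   counting (default `TRUE`).
#' @param eligible_classes Variant classes that count toward the burden;
#'   defaults to the nonsynonymous coding classes.
#' @return Mutations per megabase (non-negative scalar).
#' @export
compute_tmb <- function(calls, panel_mb, exclude_drivers = TRUE,
                        eligible_classes = NONSYNONYMOUS_CLASSES) {
  assert_positive(panel_mb, "panel_mb")
  if (is.null(calls) || !nrow(calls)) return(0)
  eligible <- calls$variant_class %in% eligible_classes
  if (exclude_drivers && "is_known_driver" %in% names(calls))
    eligible <- eligible & !calls$is_known_driver
  sum(eligible) / panel_mb
}

## Merge adjacent length bins of a 2 x k tumor/normal table until every
## expected count is >= 5 (or no further merge is possible).  Keeps the
## chi-square approximation honest on sparse repeat-length histograms.
merge_sparse_bins <- function(tab, min_expected = 5) {
  repeat {
    if (ncol(tab) <= 1L) return(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(expected, 2, min) < min_expected)
    if (!length(bad)) return(tab)
    j <- bad[1]
    # merge into the smaller neighbour
    target <- if (j == 1L) 2L
      else if (j == ncol(tab)) j - 1L
      else if (sum(tab[, j - 1]) <= sum(tab[, j + 1])) j - 1L else j + 1L
    tab[, target] <- tab[, target] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
}

#' Test one microsatellite site for instability
#'
#' Compares the tumor read-length distribution against the matched normal.
#' A site with fewer than `min_reads` total reads in either histogram is
#' `not_evaluable`.  Otherwise the two distributions are compared with a
#' chi-square test on pooled length bins (bins with expected count < 5
#' merged into a neighbour) or, alternatively, a two-sample
#' Kolmogorov-Smirnov test; the site is `unstable` iff the test is
#' significant at `alpha`.
#'
#' @param obs An [msi_site_observation()].
#' @param alpha Significance level for the site-level test.
#' @param min_reads Minimum total reads per histogram for the site to be
#'   evaluable.
#' @param method `"chisq"` (default) or `"ks"`.
#' @return One of `"unstable"`, `"stable"`, `"not_evaluable"`.
#' @export
test_site_instability <- function(obs, alpha = 0.05, min_reads = 20,
                                  method = c("chisq", "ks")) {
  method <- match.arg(method)
  tum <- obs$tumor_hist
  nor <- obs$normal_hist
  if (sum(tum) < min_reads || sum(nor) < min_reads) return("not_evaluable")
  lengths_all <- sort(unique(as.numeric(c(names(tum), names(nor)))))
  t_cnt <- n_cnt <- numeric(length(lengths_all))
  t_cnt[match(as.numeric(names(tum)), lengths_all)] <- tum
  n_cnt[match(as.numeric(names(nor)), lengths_all)] <- nor
  if (method == "chisq") {
    tab <- rbind(tumor = t_cnt, normal = n_cnt)
    tab <- merge_sparse_bins(tab)
    if (ncol(tab) <= 1L) return("stable")
    p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  } else {
    x <- rep(lengths_all, times = t_cnt)
    y <- rep(lengths_all, times = n_cnt)
    p <- suppressWarnings(stats::ks.test(x, y))$p.value
  }
  if (is.na(p)) return("stable")
  if (p < alpha) "unstable" else "stable"
}

#' Classify a sample's microsatellite status from site verdicts
#'
#' The sample-level MSI fraction is the number of unstable sites over the
#' number of evaluated (unstable + stable) sites; `not_evaluable` sites are
#' excluded from the denominator.  The sample is called MSI iff the fraction
#' is strictly greater than `threshold` (default "more than 40%").
#'
#' @param verdicts Character vector of per-site verdicts from
#'   [test_site_instability()].
#' @param threshold Strict lower bound on the unstable-site fraction for an
#'   MSI call.
#' @return A list with `msi_fraction` (NA when no site is evaluable) and
#'   `msi_status` (`"MSI"`, `"MSS"` or `"not_evaluable"`).
#' @export
classify_msi <- function(verdicts, threshold = 0.40) {
  evaluable <- verdicts[verdicts %in% c("unstable", "stable")]
  if (!length(evaluable))
    return(list(msi_fraction = NA_real_, msi_status = "not_evaluable"))
  frac <- sum(evaluable == "unstable") / length(evaluable)
  list(msi_fraction = frac,
       msi_status = if (frac > threshold) "MSI" else "MSS")
}

#' Chromosomal instability score from copy-number segments
#'
#' The proportion of segments whose log2 ratio lies strictly outside the
#' symmetric cutoff around zero (default 0.2): a segment with ratio exactly
#' at +/- cutoff is not aberrant.  With `weighting = "length"` the
#' proportion is weighted by segment length in base pairs.
#'
#' @param segments Data frame of segments with columns `start`, `end`,
#'   `log2_ratio` (1-based closed intervals).
#' @param cutoff Symmetric log2-ratio cutoff (> 0).
#' @param weighting `"count"` (default) or `"length"`.
#' @return Fraction in `[0, 1]`, or `NA` for an empty segment list.
#' @export
compute_cin <- function(segments, cutoff = 0.2,
                        weighting = c("count", "length")) {
  weighting <- match.arg(weighting)
  assert_positive(cutoff, "cutoff")
  if (is.null(segments) || !nrow(segments)) return(NA_real_)
  aberrant <- segments$log2_ratio > cutoff | segments$log2_ratio < -cutoff
  if (weighting == "count") {
    mean(aberrant)
  } else {
    w <- segments$end - segments$start + 1
    sum(w * aberrant) / sum(w)
  }
}

#' Compute all per-sample biomarkers for a cohort
#'
#' Runs TMB, MSI and CIN for every sample in the bundle's clinical table.
#' Calls should already be filtered (see [filter_calls()]); stages whose
#' inputs are absent from the bundle yield `NA` columns.
#'
#' @param bundle A [cohort_bundle()] whose `variants` are filtered calls.
#' @param panel_mb Panel footprint in megabases (for TMB).
#' @param exclude_drivers Passed to [compute_tmb()].
#' @param msi_threshold,msi_alpha,msi_min_reads,msi_test MSI parameters
#'   (see [test_site_instability()] and [classify_msi()]).
#' @param cin_cutoff,cin_weighting CIN parameters (see [compute_cin()]).
#' @return A data frame with one row per sample: `sample`, `tmb`,
#'   `msi_fraction`, `msi_status`, `cin`.
#' @export
compute_biomarkers <- function(bundle, panel_mb,
                               exclude_drivers = TRUE,
                               msi_threshold = 0.40, msi_alpha = 0.05,
                               msi_min_reads = 20, msi_test = "chisq",
                               cin_cutoff = 0.2, cin_weighting = "count") {
  samples <- bundle$clinical$sample
  calls_by_sample <- if (!is.null(bundle$variants) && nrow(bundle$variants))
    split(bundle$variants, bundle$variants$sample) else list()
  res <- data.frame(sample = samples,
                    tmb = NA_real_, msi_fraction = NA_real_,
                    msi_status = NA_character_, cin = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(samples)) {
    smp <- samples[i]
    res$tmb[i] <- compute_tmb(calls_by_sample[[smp]], panel_mb,
                              exclude_drivers = exclude_drivers)
    if (!is.null(bundle$msi_observations)) {
      obs <- bundle$msi_observations[[smp]]
      if (!is.null(obs)) {
        verdicts <- vapply(obs, test_site_instability, character(1),
                           alpha = msi_alpha, min_reads = msi_min_reads,
                           method = msi_test)
        msi <- classify_msi(verdicts, threshold = msi_threshold)
        res$msi_fraction[i] <- msi$msi_fraction
        res$msi_status[i] <- msi$msi_status
      }
    }
    if (!is.null(bundle$segments)) {
      seg <- bundle$segments[[smp]]
      if (!is.null(seg))
        res$cin[i] <- compute_cin(seg, cutoff = cin_cutoff,
                                  weighting = cin_weighting)
    }
  }
  res
}

#' Reporting transform for TMB
#'
#' TMB is computed and stored raw (mutations per megabase); plots and model
#' covariates use `log2(tmb + 1)`.
#' @param tmb Raw TMB values.
#' @return `log2(tmb + 1)`.
#' @export
tmb_log2 <- function(tmb) log2(tmb + 1)
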