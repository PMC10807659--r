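## Gene-set enrichment analysis between two phenotypes: signal-to-noise
## ranking, weighted Kolmogorov-Smirnov running-sum enrichment score,
## phenotype-permutation null, sign-separated normalized enrichment scores
## (NES) and FDR q-values.

## Signal-to-noise ratio per gene: (mean_mut - mean_wt) / (sd_mut + sd_wt),
## with each group's sd floored at 0.2 * |group mean| (and at 0.2 when the
## mean is 0) so that low-variance genes do not dominate the ranking.
row_sd <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(0, (rowSums(m * m) - n * mu * mu) / (n - 1)))
}

signal_to_noise <- function(expression, groups) {
  g1 <- expression[, groups, drop = FALSE]
  g0 <- expression[, !groups, drop = FALSE]
  m1 <- rowMeans(g1); m0 <- rowMeans(g0)
  s1 <- row_sd(g1); s0 <- row_sd(g0)
  floor_sd <- function(s, m) {
    s <- pmax(s, 0.2 * abs(m))
    s[s == 0] <- 0.2
    s
  }
  (m1 - m0) / (floor_sd(s1, m1) + floor_sd(s0, m0))
}

#' Rank genes by a two-phenotype differential metric
#'
#' Computes the signal-to-noise ratio for every gene (mutated minus
#' wild-type group mean over the sum of the floored group standard
#' deviations) and returns the genes in descending metric order.  Ties are
#' broken deterministically by gene identifier.
#'
#' @param expression Numeric genes x samples matrix.
#' @param groups Logical vector aligned with columns, `TRUE` = mutated
#'   phenotype.  Each group needs at least 3 samples for the variance
#'   estimates.
#' @param log2_transform Apply `log2(x + 1)` to the matrix first (for raw
#'   abundance input).
#' @return A named numeric vector of metric values, sorted descending.
#' @export
rank_genes <- function(expression, groups, log2_transform = FALSE) {
  groups <- as.logical(groups)
  if (sum(groups) < 3L || sum(!groups) < 3L)
    stop_format(paste("each phenotype needs >= 3 samples for the",
                      "signal-to-noise metric; use gene-set permutation",
                      "for smaller groups"))
  if (log2_transform) expression <- log2(expression + 1)
  score <- signal_to_noise(expression, groups)
  names(score) <- rownames(expression)
  score[order(-score, names(score))]
}

## ES from the ranked weight vector and sorted hit positions only.  The
## running sum is linear between hits, so its extrema occur immediately
## after a hit increment or just before the next hit; checking those 2*Nh
## candidate values reproduces the full running sum's extremum.
es_from_positions <- function(w_abs, hit_idx, n_genes) {
  nh <- length(hit_idx)
  if (!nh) return(NA_real_)
  denom_hit <- sum(w_abs[hit_idx])
  if (denom_hit == 0) denom_hit <- 1  # all-zero metric: flat hit increments
  n_miss <- n_genes - nh
  phit <- cumsum(w_abs[hit_idx]) / denom_hit
  if (n_miss == 0) return(1)
  pmiss_after <- (hit_idx - seq_len(nh)) / n_miss
  after <- phit - pmiss_after
  before <- c(0, phit[-nh]) - (hit_idx - seq_len(nh)) / n_miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Weighted running-sum enrichment score for one gene set
#'
#' Walks the ranked gene list; set members ("hits") increment the running
#' sum by their weighted metric share `|r|^p / sum(|r_hits|^p)`, non-members
#' decrement it by `1 / (N - N_hits)`.  The enrichment score is the running
#' sum value of largest magnitude, and the leading edge is the set members
#' at or before (positive ES) / at or after (negative ES) that extremum.
#' With `p = 0` this is the classical unweighted Kolmogorov-Smirnov
#' statistic up to sign.
#'
#' @param ranked Named numeric vector of metric values in ranked (descending)
#'   order, as from [rank_genes()].
#' @param gene_set Character vector of member gene identifiers.
#' @param p Weighting exponent (default 1).
#' @return A list with `es`, the full `running_sum` vector, the
#'   `leading_edge` gene vector and the hit count `size`.  A set with no
#'   overlap yields `es = NA`; a set covering the whole list is degenerate
#'   and flagged with a warning (`es = 1`).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  n <- length(ranked)
  if (nh == 0L)
    return(list(es = NA_real_, running_sum = NULL,
                leading_edge = character(0), size = 0L))
  w <- abs(ranked)^p
  denom_hit <- sum(w[hit])
  if (denom_hit == 0) {
    w[] <- 1  # zero metric everywhere: fall back to flat increments
    denom_hit <- nh
  }
  if (nh == n) {
    warning("gene set covers the entire ranked list; ES degenerate at 1",
            call. = FALSE)
    rs <- cumsum(w / denom_hit)
    return(list(es = 1, running_sum = rs, leading_edge = genes, size = nh))
  }
  increments <- ifelse(hit, w / denom_hit, -1 / (n - nh))
  rs <- cumsum(increments)
  peak <- which.max(abs(rs))
  es <- rs[peak]
  leading <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
             else genes[peak:n][hit[peak:n]]
  list(es = es, running_sum = rs, leading_edge = leading, size = nh)
}

## Observed and permuted signal-to-noise rankings -> ES matrix
## (sets x (1 + n_perm)); column 1 is the observed phenotype.
es_null_matrix <- function(expression, groups, gene_sets, n_perm, weight,
                           seed) {
  n <- ncol(expression)
  n1 <- sum(groups)
  genes <- rownames(expression)
  set_idx <- lapply(gene_sets, function(s) which(genes %in% s))
  perm_labels <- with_seed(seed, replicate(n_perm, {
    z <- logical(n); z[sample.int(n, n1)] <- TRUE; z
  }))
  es <- matrix(NA_real_, nrow = length(gene_sets), ncol = n_perm + 1L,
               dimnames = list(names(gene_sets), NULL))
  for (k in 0:n_perm) {
    grp <- if (k == 0L) groups else perm_labels[, k]
    score <- signal_to_noise(expression, grp)
    ord <- order(-score, genes)
    w_abs <- abs(score[ord])^weight
    rank_of <- integer(length(genes))
    rank_of[ord] <- seq_along(ord)
    for (s in seq_along(set_idx)) {
      pos <- sort(rank_of[set_idx[[s]]])
      es[s, k + 1L] <- es_from_positions(w_abs, pos, length(genes))
    }
  }
  es
}

## Sign-separated normalization: ES divided by the mean magnitude of the
## same-sign null ES of its own gene set.  Each null ES is normalized
## leaving itself out of that mean: including it shrinks extreme null NES
## (a null value inflates its own divisor) while the observed NES has no
## such term, which makes the observed tail anti-conservative against the
## null extrema.  Leave-one-out restores the symmetry.
normalize_es <- function(es_obs, null_mat) {
  nes_obs <- rep(NA_real_, length(es_obs))
  null_nes <- matrix(NA_real_, nrow = nrow(null_mat), ncol = ncol(null_mat))
  safe_div <- function(e, divisor) {
    ifelse(is.na(e) | is.na(divisor) | divisor <= 0, NA_real_, e / divisor)
  }
  for (s in seq_along(es_obs)) {
    null_s <- null_mat[s, ]
    pos <- !is.na(null_s) & null_s >= 0
    neg <- !is.na(null_s) & null_s < 0
    sum_pos <- sum(null_s[pos]); n_pos <- sum(pos)
    sum_neg <- sum(abs(null_s[neg])); n_neg <- sum(neg)
    mean_pos <- if (n_pos > 0) sum_pos / n_pos else NA_real_
    mean_neg <- if (n_neg > 0) sum_neg / n_neg else NA_real_
    e <- es_obs[s]
    nes_obs[s] <- if (is.na(e)) NA_real_
      else if (e >= 0) safe_div(e, mean_pos) else safe_div(e, mean_neg)
    loo_pos <- if (n_pos > 1) (sum_pos - null_s) / (n_pos - 1) else NA_real_
    loo_neg <- if (n_neg > 1) (sum_neg - abs(null_s)) / (n_neg - 1)
               else NA_real_
    null_nes[s, pos] <- safe_div(null_s[pos], loo_pos[pos])
    null_nes[s, neg] <- safe_div(null_s[neg], loo_neg[neg])
  }
  list(nes_obs = nes_obs, null_nes = null_nes)
}

#' Phenotype-permutation gene-set enrichment analysis
#'
#' For every gene set: the observed enrichment score on the signal-to-noise
#' ranking; a null distribution of enrichment scores from `n_perm` random
#' relabellings of the sample phenotypes (re-ranking genes each time); the
#' nominal p-value from the same-sign tail of the set's own null; the
#' normalized enrichment score NES = ES / mean(|same-sign null ES|); and an
#' FDR q-value comparing the observed NES against the pooled null NES
#' distribution, positive and negative sides normalized and evaluated
#' separately.  Results are deterministic given `seed`.
#'
#' @param expression Numeric genes x samples matrix.
#' @param groups Logical phenotype vector aligned with columns (`TRUE` =
#'   mutated).
#' @param gene_sets Named list of gene identifier vectors.
#' @param n_perm Number of phenotype permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param weight Running-sum weighting exponent (default 1).
#' @param log2_transform Apply `log2(x + 1)` to the matrix first.
#' @param min_size Sets with fewer overlapping genes are dropped.
#' @return A data frame with one row per retained set: `set_name`, `size`,
#'   `es`, `nes`, `nominal_p`, `fdr_q`, `fwer_p` (family-wise p against the
#'   per-permutation extremum of the null NES over all sets, for claims
#'   about a single selected set), `leading_edge` (comma-joined).
#' @export
gsea <- function(expression, groups, gene_sets, n_perm = 1000, seed = 1,
                 weight = 1, log2_transform = FALSE, min_size = 2) {
  groups <- as.logical(groups)
  if (log2_transform) expression <- log2(expression + 1)
  genes <- rownames(expression)
  overlap <- vapply(gene_sets, function(s) sum(s %in% genes), integer(1))
  keep <- overlap >= min_size
  if (!any(keep)) stop_format("no gene set overlaps the expression matrix")
  gene_sets <- gene_sets[keep]

  ranked <- rank_genes(expression, groups)
  obs <- lapply(gene_sets, function(s)
    enrichment_score(ranked, s, p = weight))
  es_all <- es_null_matrix(expression, groups, gene_sets, n_perm, weight,
                           seed)
  es_obs <- es_all[, 1]
  null_mat <- es_all[, -1, drop = FALSE]

  nominal_p <- vapply(seq_along(gene_sets), function(s) {
    e <- es_obs[s]; null_s <- null_mat[s, ]
    if (is.na(e)) return(NA_real_)
    if (e >= 0) {
      same <- null_s[null_s >= 0]
      if (!length(same)) return(NA_real_)
      mean(same >= e)
    } else {
      same <- null_s[null_s < 0]
      if (!length(same)) return(NA_real_)
      mean(same <= e)
    }
  }, numeric(1))

  norm <- normalize_es(es_obs, null_mat)
  nes_obs <- norm$nes_obs
  null_nes <- as.vector(norm$null_nes)
  null_nes <- null_nes[!is.na(null_nes)]

  # family-wise error p for the claim "this set is enriched", correcting
  # for selection across sets and across both signs: |NES| is compared
  # against the per-permutation maximum of |null NES| over all sets
  perm_absmax <- suppressWarnings(
    apply(abs(norm$null_nes), 2, max, na.rm = TRUE))
  perm_absmax[!is.finite(perm_absmax)] <- NA_real_
  fwer_p <- vapply(nes_obs, function(nes) {
    if (is.na(nes)) return(NA_real_)
    mean(perm_absmax >= abs(nes), na.rm = TRUE)
  }, numeric(1))

  fdr_q <- vapply(seq_along(nes_obs), function(s) {
    nes <- nes_obs[s]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_frac <- if (sum(null_nes >= 0))
        sum(null_nes >= nes) / sum(null_nes >= 0) else NA_real_
      obs_frac <- sum(nes_obs >= nes, na.rm = TRUE) /
        sum(nes_obs >= 0, na.rm = TRUE)
    } else {
      null_frac <- if (sum(null_nes < 0))
        sum(null_nes <= nes) / sum(null_nes < 0) else NA_real_
      obs_frac <- sum(nes_obs <= nes, na.rm = TRUE) /
        sum(nes_obs < 0, na.rm = TRUE)
    }
    if (is.na(null_frac) || obs_frac == 0) return(NA_real_)
    min(1, null_frac / obs_frac)
  }, numeric(1))

  data.frame(
    set_name = names(gene_sets),
    size = vapply(obs, function(o) o$size, integer(1)),
    es = es_obs,
    nes = nes_obs,
    nominal_p = nominal_p,
    fdr_q = fdr_q,
    fwer_p = fwer_p,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
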