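## Gene-level mutation landscape: oncoprint matrix, per-gene mutation
## frequencies, and pairwise co-occurrence / mutual-exclusivity statistics.

#' Binary gene x sample mutation matrix (oncoprint semantics)
#'
#' Entry is 1 iff the sample carries at least one retained nonsynonymous
#' call in the gene; multiple calls collapse to 1.  Samples listed in
#' `samples` but absent from the calls appear as all-zero columns, so the
#' matrix denominators reflect the whole cohort.
#'
#' @param calls Filtered variant calls (data frame).
#' @param samples Character vector of all cohort sample identifiers.
#' @param classes Variant classes that count as mutated; defaults to the
#'   nonsynonymous coding classes (synonymous calls never mark a gene).
#' @return An integer matrix, genes in rows, samples in columns.
#' @export
mutation_matrix <- function(calls, samples,
                            classes = NONSYNONYMOUS_CLASSES) {
  calls <- calls[calls$variant_class %in% classes, , drop = FALSE]
  genes <- sort(unique(calls$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(calls)) {
    keep <- calls$sample %in% samples
    idx <- cbind(match(calls$gene[keep], genes),
                 match(calls$sample[keep], samples))
    m[idx] <- 1L
  }
  m
}

#' Per-gene mutation frequency
#'
#' @param matrix Binary gene x sample matrix from [mutation_matrix()].
#' @return Named numeric vector: fraction of samples mutated per gene.
#' @export
gene_frequencies <- function(matrix) {
  if (!nrow(matrix) || !ncol(matrix))
    stop_format("mutation matrix must be non-empty")
  rowMeans(matrix)
}

#' Pairwise gene co-occurrence / mutual exclusivity
#'
#' For every pair of genes mutated in at least `min_mutated` samples, a
#' 2 x 2 table (both mutated, A only, B only, neither) is tested with a
#' two-sided Fisher's exact test.  Odds ratio < 1 indicates mutual
#' exclusivity, > 1 co-occurrence; q-values are Benjamini-Hochberg adjusted
#' across all tested pairs and a direction is called only when
#' `q <= sig_level`.
#'
#' @param matrix Binary gene x sample matrix from [mutation_matrix()].
#' @param min_mutated Minimum mutated-sample count for a gene to be tested.
#' @param correction Multiple-testing method (passed to [stats::p.adjust()]).
#' @param sig_level q-value threshold for calling a direction.
#' @return A data frame with one row per tested pair: `gene_a`, `gene_b`,
#'   counts `n_both`, `n_a_only`, `n_b_only`, `n_neither`, `odds_ratio`
#'   (conditional MLE, possibly 0 or Inf), `p_value`, `q_value`,
#'   `direction` in {co-occurring, mutually_exclusive, none}.
#' @export
pairwise_association <- function(matrix, min_mutated = 5,
                                 correction = "BH", sig_level = 0.05) {
  counts <- rowSums(matrix)
  genes <- rownames(matrix)[counts >= min_mutated]
  if (length(genes) < 2L)
    stop_format("need >= 2 genes mutated in >= %d samples", min_mutated)
  pairs <- utils::combn(genes, 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    n_both = NA_integer_, n_a_only = NA_integer_,
                    n_b_only = NA_integer_, n_neither = NA_integer_,
                    odds_ratio = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, direction = "none",
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    a <- matrix[pairs[1, k], ] > 0
    b <- matrix[pairs[2, k], ] > 0
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                  nrow = 2)
    ft <- stats::fisher.test(tab)
    out$n_both[k] <- tab[1, 1]; out$n_a_only[k] <- tab[2, 1]
    out$n_b_only[k] <- tab[1, 2]; out$n_neither[k] <- tab[2, 2]
    out$odds_ratio[k] <- unname(ft$estimate)
    out$p_value[k] <- ft$p.value
  }
  out$q_value <- stats::p.adjust(out$p_value, method = correction)
  sig <- out$q_value <= sig_level
  out$direction[sig & out$odds_ratio > 1] <- "co-occurring"
  out$direction[sig & out$odds_ratio < 1] <- "mutually_exclusive"
  out
}
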