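#' Filter somatic calls by allele frequency, read support and artifact list
#'
#' Retention rule for panel somatic calls: a call is kept iff its variant
#' allele frequency is at least `min_vaf` (default 2%), it has at least
#' `min_alt_reads` supporting reads (default 5), it does not match the
#' positional artifact list, and its `is_artifact` flag is not set.  Both
#' thresholds are inclusive ("at least" / "or more").  Input order is
#' preserved and the operation is idempotent.
#'
#' Matched-normal subtraction is assumed to have been applied upstream; the
#' artifact flag/list is how previously identified recurrent sequencing
#' artifacts are removed here.
#'
#' @param calls Data frame of variant calls (see [read_mutations()]).
#' @param min_vaf Minimum variant allele frequency, inclusive.
#' @param min_alt_reads Minimum alt-supporting read count, inclusive.
#' @param artifact_list Optional data frame with columns `chrom`, `pos`,
#'   `ref`, `alt` of known artifact sites to remove.
#' @return The retained subset of `calls`, same columns, original order.
#' @examples
#' calls <- data.frame(sample = "S1", gene = "TP53", chrom = "17",
#'                     pos = 1:3, ref = "C", alt = "T",
#'                     variant_class = "missense",
#'                     alt_depth = c(5, 4, 50), total_depth = 250,
#'                     vaf = c(0.02, 0.05, 0.019),
#'                     is_known_driver = FALSE, is_artifact = FALSE)
#' filter_calls(calls)  # keeps only the first call
#' @export
filter_calls <- function(calls, min_vaf = 0.02, min_alt_reads = 5,
                         artifact_list = NULL) {
  if (min_vaf < 0 || min_alt_reads < 0)
    stop_format("thresholds must be >= 0")
  if (is.null(calls) || !nrow(calls)) return(calls)
  keep <- calls$vaf >= min_vaf &
    calls$alt_depth >= min_alt_reads &
    !calls$is_artifact
  if (!is.null(artifact_list) && nrow(artifact_list)) {
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
    keep <- keep & !(key(calls) %in% key(artifact_list))
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
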