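## Independent brute-force oracles used to freeze expected values.  These
## deliberately share no code with the package implementations.

## Build a minimal variant-call data frame.
make_calls <- function(n, sample = "S1", gene = "TP53",
                       variant_class = "missense",
                       alt_depth = 10, total_depth = 100,
                       vaf = alt_depth / total_depth,
                       is_known_driver = FALSE, is_artifact = FALSE) {
  data.frame(sample = rep_len(sample, n), gene = rep_len(gene, n),
             chrom = rep_len("chr1", n), pos = seq_len(n),
             ref = rep_len("A", n), alt = rep_len("C", n),
             variant_class = rep_len(variant_class, n),
             alt_depth = rep_len(alt_depth, n),
             total_depth = rep_len(total_depth, n),
             vaf = rep_len(vaf, n),
             is_known_driver = rep_len(is_known_driver, n),
             is_artifact = rep_len(is_artifact, n),
             stringsAsFactors = FALSE)
}

## Two-sided Fisher exact p by full hypergeometric enumeration: sum the
## probabilities of all tables with the observed margins whose probability
## does not exceed the observed table's.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exact two-sided Mann-Whitney p by bitmask enumeration of every group
## assignment: P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|).
mw_enum_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals)
  n1 <- length(x)
  r <- rank(vals)
  mu <- n1 * (n - n1) / 2
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  count <- total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
    if (length(idx) != n1) next
    total <- total + 1L
    if (abs(u_of(idx) - mu) >= abs(u_obs - mu) - 1e-9)
      count <- count + 1L
  }
  count / total
}

## GSEA enrichment score by position-by-position running-sum evaluation.
es_brute <- function(ranked, gene_set, p = 1) {
  hit <- names(ranked) %in% gene_set
  n <- length(ranked)
  nh <- sum(hit)
  w <- abs(ranked)^p
  denom <- sum(w[hit])
  rs <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) w[i] / denom else -1 / (n - nh)
    rs[i] <- acc
  }
  rs[which.max(abs(rs))]
}

## Two-group log-rank chi-square by hand: observed-minus-expected events in
## group 1 at every distinct event time, hypergeometric variance.
logrank_brute <- function(times, events, group1) {
  event_times <- sort(unique(times[events == 1]))
  o_minus_e <- v <- 0
  for (t in event_times) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group1)
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & group1)
    e <- d_t * n1_t / n_t
    o_minus_e <- o_minus_e + d1_t - e
    if (n_t > 1)
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  o_minus_e^2 / v
}

## Small deterministic MSI site fixture: explicit paired histograms.
fixed_site <- function(tumor_counts, normal_counts,
                       lengths = seq_along(tumor_counts) + 10) {
  panelmarkers::msi_site_observation(
    "fix",
    stats::setNames(tumor_counts, lengths),
    stats::setNames(normal_counts, lengths))
}
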