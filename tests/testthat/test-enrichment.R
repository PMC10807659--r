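ranked_fixture <- function(n = 10, seed = 2) {
  set.seed(seed)
  r <- sort(rnorm(n, 0, 1.5), decreasing = TRUE)
  names(r) <- sprintf("g%02d", seq_len(n))
  r
}

test_that("signal-to-noise metric: equal means give 0, the sd floor tames
           constant genes, ordering matches hand computation", {
  x <- rbind(
    gA = c(5, 6, 7, 5, 6, 7),        # identical groups -> 0
    gB = c(9, 9, 9, 4, 4, 4),        # constant in both groups: floor kicks in
    gC = c(8, 9, 10, 3, 4, 5),
    gD = c(2, 3, 4, 7, 8, 9))
  colnames(x) <- sprintf("s%d", 1:6)
  grp <- rep(c(TRUE, FALSE), each = 3)
  r <- rank_genes(x, grp)
  expect_equal(r[["gA"]], 0)
  # gB: sd floored at 0.2*|mean| per group -> (9-4)/(1.8+0.8)
  expect_equal(r[["gB"]], 5 / 2.6)
  # gC: the floor binds only in the high group (sd 1 < 0.2*9)
  expect_equal(r[["gC"]], 5 / 2.8)
  expect_equal(names(r), c("gB", "gC", "gA", "gD"))
  expect_error(rank_genes(x[, 1:5], grp[1:5]), ">= 3 samples")
})

test_that("enrichment score equals the brute-force running sum", {
  r <- ranked_fixture(10)
  set.seed(3)
  for (i in 1:20) {
    gene_set <- sample(names(r), sample(2:5, 1))
    for (p in c(0, 1, 2)) {
      es <- enrichment_score(r, gene_set, p = p)
      expect_equal(es$es, es_brute(r, gene_set, p = p), tolerance = 1e-12)
    }
  }
})

test_that("a set packed at the top of the list maximises the positive ES", {
  r <- ranked_fixture(20)
  top <- enrichment_score(r, names(r)[1:4])
  expect_gt(top$es, 0.8)
  expect_equal(top$leading_edge, names(r)[1:4])
  set.seed(5)
  for (i in 1:10) {
    other <- enrichment_score(r, sample(names(r), 4))
    expect_lte(abs(other$es), 1)
    expect_lte(other$es, top$es + 1e-12)
  }
})

test_that("degenerate sets are flagged", {
  r <- ranked_fixture(8)
  none <- enrichment_score(r, c("absent1", "absent2"))
  expect_true(is.na(none$es))
  expect_warning(all_in <- enrichment_score(r, names(r)), "degenerate")
  expect_equal(all_in$es, 1)
})

test_that("with p = 0 the |ES| equals the unweighted two-sample KS
           statistic between hit and miss rank distributions", {
  r <- ranked_fixture(30, seed = 9)
  set.seed(10)
  for (i in 1:10) {
    gene_set <- sample(names(r), 8)
    es <- enrichment_score(r, gene_set, p = 0)
    hit_pos <- which(names(r) %in% gene_set)
    miss_pos <- setdiff(seq_along(r), hit_pos)
    grid <- seq_along(r)
    d <- max(abs(vapply(grid, function(t)
      mean(hit_pos <= t) - mean(miss_pos <= t), numeric(1))))
    expect_equal(abs(es$es), d, tolerance = 1e-12)
  }
})

test_that("gsea observed ES agrees with enrichment_score and fgsea on the
           same ranking", {
  skip_if_not_installed("fgsea")
  cfg <- simulation_config(n_samples = 40, n_genes = 120, n_gene_sets = 6,
                           set_size = 10, seed = 13, focal_frequency = 0.4,
                           components = "expression")
  b <- simulate_cohort(cfg)
  grp <- b$clinical$focal_mutated
  res <- gsea(b$expression, grp, b$gene_sets, n_perm = 10, seed = 1,
              log2_transform = TRUE)
  ranked <- rank_genes(b$expression, grp, log2_transform = TRUE)
  for (s in res$set_name) {
    mine <- enrichment_score(ranked, b$gene_sets[[s]])$es
    expect_equal(res$es[res$set_name == s], mine, tolerance = 1e-12)
    ref <- fgsea::calcGseaStat(ranked,
                               which(names(ranked) %in% b$gene_sets[[s]]),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("same seed gives bitwise identical results; different seeds
           differ", {
  cfg <- simulation_config(n_samples = 30, n_genes = 80, n_gene_sets = 4,
                           set_size = 8, seed = 29, focal_frequency = 0.4,
                           components = "expression")
  b <- simulate_cohort(cfg)
  grp <- b$clinical$focal_mutated
  g1 <- gsea(b$expression, grp, b$gene_sets, n_perm = 50, seed = 7,
             log2_transform = TRUE)
  g2 <- gsea(b$expression, grp, b$gene_sets, n_perm = 50, seed = 7,
             log2_transform = TRUE)
  expect_identical(g1, g2)
  g3 <- gsea(b$expression, grp, b$gene_sets, n_perm = 50, seed = 8,
             log2_transform = TRUE)
  expect_false(identical(g1$nominal_p, g3$nominal_p))
})

test_that("nominal p is stable under doubling the permutation count", {
  cfg <- simulation_config(n_samples = 40, n_genes = 100, n_gene_sets = 5,
                           set_size = 10, seed = 43, focal_frequency = 0.4,
                           components = "expression")
  b <- simulate_cohort(cfg)
  grp <- b$clinical$focal_mutated
  g_small <- gsea(b$expression, grp, b$gene_sets, n_perm = 200, seed = 3,
                  log2_transform = TRUE)
  g_big <- gsea(b$expression, grp, b$gene_sets, n_perm = 400, seed = 3,
                log2_transform = TRUE)
  expect_true(all(abs(g_small$nominal_p - g_big$nominal_p) <
                    2 / sqrt(200), na.rm = TRUE))
})

test_that("a downshifted set comes out with negative NES and small q", {
  cfg <- simulation_config(n_samples = 80, n_genes = 200, n_gene_sets = 8,
                           set_size = 15, seed = 51, focal_frequency = 0.3,
                           components = "expression")
  b <- simulate_cohort(cfg)
  res <- gsea(b$expression, b$clinical$focal_mutated, b$gene_sets,
              n_perm = 100, seed = 2, log2_transform = TRUE)
  ifn <- res[grepl("INTERFERON", res$set_name), ]
  expect_true(all(ifn$nes < 0))
  expect_true(all(ifn$fdr_q < 0.1, na.rm = TRUE))
})
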