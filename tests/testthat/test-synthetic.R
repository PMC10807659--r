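small_cfg <- function(...) {
  simulation_config(n_samples = 40, n_msi_sites = 6, site_depth = 60,
                    n_genes = 60, n_gene_sets = 4, set_size = 6,
                    n_segments = 10, ...)
}

test_that("the same seed reproduces the bundle exactly; seeds differ", {
  b1 <- simulate_cohort(small_cfg(seed = 5))
  b2 <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(b1, b2)
  b3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(b1$variants, b3$variants))
})

test_that("components draw from independent sub-streams", {
  full <- simulate_cohort(small_cfg(seed = 9))
  lean <- simulate_cohort(small_cfg(
    seed = 9, components = c("variants", "survival")))
  expect_identical(lean$clinical, full$clinical)
  expect_identical(lean$variants, full$variants)
  expect_null(lean$expression)
})

test_that("simulate_cohort does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cohort(small_cfg(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("focal mutation count at full cohort scale matches the
           configured frequency", {
  cfg <- simulation_config(n_samples = 3702, seed = 424,
                           components = character(0))
  b <- simulate_cohort(cfg)
  n_mut <- sum(b$truth$focal_mutated)
  # 424/3702 with binomial noise: +/- 4 sd ~ 77
  expect_gt(n_mut, 424 - 77)
  expect_lt(n_mut, 424 + 77)
  # reproducible exactly under the same seed
  expect_equal(sum(simulate_cohort(cfg)$truth$focal_mutated), n_mut)
})

test_that("generated TMB and CIN moments converge to configured values", {
  cfg <- simulation_config(n_samples = 5000, seed = 50,
                           components = c("variants", "segments"),
                           n_segments = 40)
  b <- simulate_cohort(cfg)
  kept <- filter_calls(b$variants)
  bm <- compute_biomarkers(
    cohort_bundle(kept, b$clinical, segments = b$segments),
    panel_mb = cfg$panel_mb)
  mut <- b$truth$focal_mutated
  expect_equal(mean(bm$tmb[!mut]), cfg$tmb_base, tolerance = 0.05)
  expect_equal(mean(bm$tmb[mut]), cfg$tmb_base * cfg$tmb_fold,
               tolerance = 0.05)
  expect_equal(mean(bm$cin[!mut]), cfg$cin_mean_wt, tolerance = 0.05)
  expect_equal(mean(bm$cin[mut]), cfg$cin_mean_mut, tolerance = 0.05)
})

test_that("every mutated driver gene leaves at least one retained call and
           decoys are all removed by the filter", {
  cfg <- small_cfg(seed = 61, components = "variants")
  b <- simulate_cohort(cfg)
  kept <- filter_calls(b$variants)
  expect_true(all(kept$vaf >= 0.02 & kept$alt_depth >= 5))
  # every truth-mutated TP53 sample has a retained TP53 call
  tp53_samples <- b$truth$sample[b$truth$TP53]
  expect_setequal(unique(kept$sample[kept$gene == "TP53"]), tp53_samples)
  # decoy calls (below either threshold, or artifact-flagged) all vanish
  decoys <- b$variants[b$variants$vaf < 0.02 | b$variants$alt_depth < 5 |
                         b$variants$is_artifact, ]
  expect_gt(nrow(decoys), 0)
  key <- function(d) paste(d$sample, d$chrom, d$pos)
  expect_false(any(key(decoys) %in% key(kept)))
})

test_that("stable sites match the normal distribution; unstable deep sites
           are detected nearly always", {
  set.seed(71)
  flags <- replicate(400, test_site_instability(
    simulate_msi_site(500, unstable = TRUE, shift = 3)))
  expect_gte(mean(flags == "unstable"), 0.99)
  set.seed(72)
  null_flags <- replicate(400, test_site_instability(
    simulate_msi_site(500, unstable = FALSE)))
  # false-positive rate at most around alpha
  expect_lte(mean(null_flags == "unstable"), 0.08)
})

test_that("MSI samples carry a majority of shifted sites, MSS few", {
  cfg <- simulation_config(n_samples = 60, n_msi_sites = 20,
                           site_depth = 150, seed = 81,
                           msi_prob_wt = 0.5, msi_prob_mut = 0.5,
                           components = "msi")
  b <- simulate_cohort(cfg)
  frac <- vapply(b$clinical$sample, function(s) {
    v <- vapply(b$msi_observations[[s]], test_site_instability,
                character(1))
    classify_msi(v)$msi_fraction
  }, numeric(1))
  expect_gt(min(frac[b$truth$msi_true]), 0.4)
  expect_lt(max(frac[!b$truth$msi_true]), 0.3)
})

test_that("survival generation recovers the configured hazard ratio", {
  cfg <- simulation_config(n_samples = 500, os_hr = 2.0, seed = 91,
                           components = "survival")
  b <- simulate_cohort(cfg)
  fit <- cox_fit(b$clinical, c("focal_mutated", "age", "stage"))
  row <- fit[fit$term == "focal_mutatedTRUE" |
               fit$term == "focal_mutated", ][1, ]
  expect_lt(abs(row$log_hr - log(2)), 3 * row$se)
  # censoring close to the configured administrative fraction
  expect_equal(mean(b$clinical$os_event == 0), cfg$censor_rate,
               tolerance = 0.07)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(focal_frequency = 1.2), "probability")
  expect_error(simulation_config(os_hr = -1), "> 0")
  expect_error(simulation_config(n_msi_sites = 0), ">= 1")
  expect_error(simulate_msi_site(0), ">= 1")
})
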