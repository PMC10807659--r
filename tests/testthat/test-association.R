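test_that("complete separation gives U = 0 for the mutated group", {
  r <- compare_continuous(c(1, 2, 3, 4, 5, 6),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$statistic, 0)
  expect_equal(r$effect_summary$median_mut, 2)
})

test_that("identical multisets in both groups give exact p = 1", {
  vals <- c(1, 2, 2, 7, 1, 2, 2, 7)
  grp <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- compare_continuous(vals, grp)
  expect_equal(r$p_value, 1)
})

test_that("exact Mann-Whitney p agrees with bitmask enumeration, ties
           included", {
  set.seed(14)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n0 <- sample(2:(12 - n1), 1)
    # integer draws force ties regularly
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n0, replace = TRUE)
    r <- compare_continuous(c(x, y), c(rep(TRUE, n1), rep(FALSE, n0)))
    expect_equal(r$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("an empty group is reported as not evaluable", {
  r <- compare_continuous(1:5, rep(TRUE, 5))
  expect_false(r$evaluable)
  expect_true(is.na(r$p_value))
})

test_that("Fisher proportion test matches enumeration and handles
           degenerate margins", {
  r <- compare_proportion(c(rep(TRUE, 20), rep(FALSE, 20)),
                          rep(c(TRUE, FALSE), 20))
  expect_equal(r$p_value, 1)  # perfectly balanced 10/10/10/10
  flags <- c(rep(TRUE, 9), rep(FALSE, 1), rep(TRUE, 1), rep(FALSE, 9))
  grp <- c(rep(TRUE, 10), rep(FALSE, 10))
  r <- compare_proportion(flags, grp)
  expect_equal(r$p_value, fisher_enum_p(9, 1, 1, 9), tolerance = 1e-10)
  # a trait constant in everyone leaves an empty margin
  r <- compare_proportion(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_false(r$evaluable)
})

test_that("stage chi-square matches the hand-computed statistic", {
  stages <- c(rep(1, 10), rep(2, 25), rep(3, 40), rep(4, 25))
  grp <- rep(FALSE, 100)
  grp[c(1:6, 11:22, 36:45, 76:80)] <- TRUE
  r <- compare_stage(stages, grp)
  tab <- table(grp, stages)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_hand <- sum((tab - expected)^2 / expected)
  expect_equal(unname(r$statistic), chisq_hand, tolerance = 1e-12)
  expect_equal(r$p_value,
               pchisq(chisq_hand, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical stage distributions give statistic 0 and p = 1", {
  stages <- rep(c(1, 2, 3, 4), each = 10)
  grp <- rep(c(TRUE, FALSE), 20)  # same composition in both groups
  r <- compare_stage(stages, grp)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)
  expect_false(compare_stage(rep(2, 20), rep(c(TRUE, FALSE), 10))$evaluable)
})

test_that("a 2-level stage collapse agrees with Fisher on direction", {
  stages <- c(rep(1, 30), rep(2, 30))
  grp <- c(rep(TRUE, 24), rep(FALSE, 6), rep(TRUE, 6), rep(FALSE, 24))
  chi <- compare_stage(stages, grp)
  fis <- compare_proportion(stages == 1, grp)
  expect_lt(chi$p_value, 0.01)
  expect_lt(fis$p_value, 0.01)
  expect_gt(fis$statistic, 1)  # early stage enriched in mutated group
})

test_that("cell-score comparison returns one adjusted row per score", {
  set.seed(17)
  cfg <- simulation_config(n_samples = 120, seed = 17,
                           components = "cell_scores")
  b <- simulate_cohort(cfg)
  res <- compare_cell_scores(b$cell_scores, b$clinical$focal_mutated)
  expect_equal(nrow(res), 12L)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(all(res$stars %in% c("***", "**", "*", "")))
  # constant scores give p = 1
  cs <- rbind(flat = rep(0.5, 10))
  colnames(cs) <- sprintf("s%d", 1:10)
  flat <- compare_cell_scores(cs, rep(c(TRUE, FALSE), 5))
  expect_equal(flat$p_value, 1)
})

test_that("tests are invariant to sample ordering", {
  set.seed(18)
  vals <- rnorm(40)
  stages <- sample(1:4, 40, replace = TRUE)
  flags <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  grp <- c(rep(TRUE, 12), rep(FALSE, 28))
  perm <- sample(40)
  expect_equal(compare_continuous(vals, grp)$p_value,
               compare_continuous(vals[perm], grp[perm])$p_value)
  expect_equal(compare_proportion(flags, grp)$p_value,
               compare_proportion(flags[perm], grp[perm])$p_value)
  expect_equal(compare_stage(stages, grp)$p_value,
               compare_stage(stages[perm], grp[perm])$p_value)
})

test_that("compare_groups assembles the full battery against focal status", {
  cfg <- simulation_config(n_samples = 80, n_msi_sites = 6, site_depth = 60,
                           n_segments = 10, seed = 23,
                           components = c("variants", "msi", "segments",
                                          "survival"))
  b <- simulate_cohort(cfg)
  b$variants <- filter_calls(b$variants)
  bm <- compute_biomarkers(b, panel_mb = 1.6)
  res <- compare_groups(b$clinical, bm)
  expect_setequal(res$variable,
                  c("age", "sex_male", "stage", "tmb", "msi_fraction",
                    "cin"))
  expect_equal(unique(res$n_mut + res$n_wt), 80L)
})
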