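test_that("TMB is eligible-call count over panel megabases", {
  expect_equal(compute_tmb(make_calls(12), panel_mb = 1.5), 8.0)
  # driver exclusion
  calls <- make_calls(10)
  calls$is_known_driver[c(3, 7)] <- TRUE
  expect_equal(compute_tmb(calls, panel_mb = 1.0), 8.0)
  expect_equal(compute_tmb(calls, panel_mb = 1.0, exclude_drivers = FALSE),
               10.0)
  # synonymous calls never count
  calls$variant_class[1:4] <- "synonymous"
  expect_equal(compute_tmb(calls, panel_mb = 1.0, exclude_drivers = FALSE),
               6.0)
  expect_equal(compute_tmb(make_calls(0), panel_mb = 2), 0.0)
  expect_error(compute_tmb(make_calls(3), panel_mb = 0), "> 0")
})

test_that("TMB scales exactly inversely with the panel footprint", {
  set.seed(3)
  calls <- make_calls(40)
  calls$variant_class <- sample(VARIANT_CLASSES, 40, replace = TRUE)
  for (mb in c(0.5, 1, 1.6, 3.2))
    expect_equal(compute_tmb(calls, mb) * mb, compute_tmb(calls, 1))
})

test_that("identical tumor and normal histograms are stable", {
  h <- c(`16` = 50, `17` = 120, `18` = 200, `19` = 90, `20` = 40)
  obs <- msi_site_observation("s", h, h)
  expect_equal(test_site_instability(obs), "stable")
  expect_equal(test_site_instability(obs, method = "ks"), "stable")
})

test_that("a shifted tumor histogram is called unstable, matching a hand
           chi-square on the same table", {
  # all expected counts >= 5, so no bin merging: the verdict must agree
  # with the plain Pearson statistic computed by hand
  tumor <- c(120, 180, 90, 40, 20)
  normal <- c(30, 90, 200, 110, 50)
  obs <- fixed_site(tumor, normal)
  tab <- rbind(tumor, normal)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - expected)^2 / expected)
  p_hand <- pchisq(chisq, df = ncol(tab) - 1, lower.tail = FALSE)
  expect_lt(p_hand, 0.05)
  expect_equal(test_site_instability(obs), "unstable")
})

test_that("low-coverage sites are not evaluable", {
  obs <- fixed_site(c(1, 2, 0), c(30, 40, 30))
  expect_equal(test_site_instability(obs, min_reads = 20), "not_evaluable")
  # depth-1 degenerate histogram from the simulator
  set.seed(1)
  one_read <- simulate_msi_site(1, unstable = TRUE)
  expect_equal(test_site_instability(one_read, min_reads = 20),
               "not_evaluable")
})

test_that("sample MSI classification uses a strict >40% rule", {
  v <- function(unstable, stable, ne = 0)
    c(rep("unstable", unstable), rep("stable", stable),
      rep("not_evaluable", ne))
  r <- classify_msi(v(21, 31))           # 21/52 = 0.4038 -> MSI
  expect_equal(r$msi_status, "MSI")
  expect_equal(r$msi_fraction, 21 / 52)
  expect_equal(classify_msi(v(20, 32))$msi_status, "MSS")  # 0.3846
  expect_equal(classify_msi(v(20, 30))$msi_status, "MSS")  # exactly 40%
  # not-evaluable sites leave the denominator
  expect_equal(classify_msi(v(20, 29, 3))$msi_fraction, 20 / 49)
  ne <- classify_msi(v(0, 0, 5))
  expect_equal(ne$msi_status, "not_evaluable")
  expect_true(is.na(ne$msi_fraction))
})

test_that("flipping one stable site to unstable never lowers the fraction", {
  set.seed(8)
  for (i in 1:20) {
    n_u <- sample(0:30, 1); n_s <- sample(1:30, 1)
    v <- sample(c(rep("unstable", n_u), rep("stable", n_s)))
    f0 <- classify_msi(v)$msi_fraction
    flip <- which(v == "stable")[1]
    v[flip] <- "unstable"
    expect_gte(classify_msi(v)$msi_fraction, f0)
  }
})

test_that("CIN is the fraction of segments strictly outside the cutoff", {
  seg <- function(r) data.frame(start = rep(1, length(r)),
                                end = rep(1000, length(r)), log2_ratio = r)
  expect_equal(compute_cin(seg(c(0.3, -0.1, -0.25, 0.05))), 0.5)
  expect_equal(compute_cin(seg(c(0.1, -0.19, 0.05))), 0.0)
  # boundary value exactly at the cutoff is not aberrant
  expect_equal(compute_cin(seg(c(0.2, -0.2, 0.21))), 1 / 3)
  expect_true(is.na(compute_cin(seg(numeric(0)))))
})

test_that("CIN equals a brute-force indicator mean; length weighting
           weights by base pairs", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    segs <- data.frame(start = cumsum(sample(1e4:1e6, n)),
                       log2_ratio = rnorm(n, 0, 0.25))
    segs$end <- segs$start + sample(1e4:1e7, n)
    brute <- mean(abs(segs$log2_ratio) > 0.2)
    expect_equal(compute_cin(segs), brute)
    w <- segs$end - segs$start + 1
    brute_len <- sum(w * (abs(segs$log2_ratio) > 0.2)) / sum(w)
    expect_equal(compute_cin(segs, weighting = "length"), brute_len)
  }
})

test_that("compute_biomarkers fills one row per sample and tolerates
           missing components", {
  cfg <- simulation_config(n_samples = 10, n_msi_sites = 5, site_depth = 60,
                           n_segments = 8, seed = 3,
                           components = c("variants", "segments"))
  b <- simulate_cohort(cfg)
  b$variants <- filter_calls(b$variants)
  bm <- compute_biomarkers(b, panel_mb = 1.6)
  expect_equal(bm$sample, b$clinical$sample)
  expect_true(all(is.na(bm$msi_fraction)))   # msi component disabled
  expect_true(all(bm$cin >= 0 & bm$cin <= 1))
  expect_true(all(bm$tmb >= 0))
})
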