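## Synthetic-cohort generator.  Emulates the statistical structure of a
## targeted-panel colon cancer cohort -- per-sample somatic calls with
## depth/VAF evidence, paired tumor/normal repeat-length histograms for
## microsatellite sites, copy-number segments, clinical and overall-survival
## data, expression and cell-type scores -- with a programmable effect of one
## focal gene's mutation status on every downstream readout.  Ground-truth
## labels are emitted alongside the bundle so parameter recovery is
## measurable.

#' Simulation configuration
#'
#' Defaults emulate a large colon-cancer panel cohort: 3702 samples with the
#' focal gene (PKHD1) mutated at frequency 424/3702, background driver
#' frequencies matching the commonly mutated colorectal genes (TP53 73%,
#' APC 57%, KRAS 40%, SMAD4 19%, PIK3CA 20%), 52 mononucleotide-repeat MSI
#' sites of at least 15 bp, and a 1.6 Mb panel footprint.  Focal-mutation
#' effects default to the qualitative directions expected for this kind of
#' cohort: higher TMB, higher MSI probability, lower CIN, worse overall
#' survival, and down-shifted interferon-response expression sets.
#'
#' @param n_samples Cohort size.
#' @param gene_frequencies Named mutation probabilities for background
#'   driver genes.
#' @param focal_gene,focal_frequency The focal gene and its mutation
#'   probability.
#' @param tmb_base Mean TMB-eligible (nonsynonymous, non-driver) mutations
#'   per megabase in wild-type samples.
#' @param tmb_fold Multiplicative TMB effect in focal-mutated samples.
#' @param panel_mb Panel footprint in megabases.
#' @param msi_prob_wt,msi_prob_mut Probability that a wild-type / mutated
#'   sample is truly microsatellite-instable.
#' @param n_msi_sites Number of repeat sites assayed per sample.
#' @param site_depth Mean reads per site histogram.
#' @param instability_shift Mean repeat-length displacement (bp) of the
#'   tumor distribution at a truly unstable site.
#' @param site_unstable_prob_msi,site_unstable_prob_mss Per-site
#'   probability of true instability in MSI / MSS samples.
#' @param cin_mean_wt,cin_mean_mut Expected fraction of aberrant
#'   copy-number segments by focal status.
#' @param n_segments Copy-number segments per sample.
#' @param os_hr Hazard ratio of the focal mutation on overall survival.
#' @param age_hr_per_year,stage_hr Covariate hazard ratios (per year of age
#'   centred at 60; per stage step centred at stage 2).
#' @param median_os_months Baseline median overall survival (reference
#'   covariates), months.
#' @param censor_rate Target fraction of administratively censored samples.
#' @param shifted_sets Named numeric vector: expression gene sets whose
#'   log2 mean is shifted by the given amount in focal-mutated samples
#'   (negative = down-regulated).  `NULL` for no expression effect.
#' @param n_genes,n_gene_sets,set_size Expression matrix size and gene-set
#'   collection layout (sets are disjoint gene blocks).
#' @param n_cell_types,n_shifted_cell_types,cell_shift Cell-score rows, how
#'   many are shifted in mutated samples, and the shift in SD units.
#' @param male_frequency,mean_age,sd_age,stage_probs Clinical marginals.
#' @param stage2_enrichment Multiplier on the stage-2 probability for
#'   focal-mutated samples (early-stage enrichment; 1 = none).
#' @param decoy_frac Sub-threshold decoy calls (fail the VAF or read-support
#'   filter) per sample, as a fraction of the eligible mutation count.
#' @param components Which bundle components to generate; omitting a
#'   component leaves it `NULL` (the matching pipeline stage is skipped).
#' @param seed Root seed; every component derives its own sub-stream from
#'   it, so generating fewer components never perturbs the others.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_samples = 3702,
    gene_frequencies = c(TP53 = 0.73, APC = 0.57, KRAS = 0.40,
                         SMAD4 = 0.19, PIK3CA = 0.20),
    focal_gene = "PKHD1",
    focal_frequency = 424 / 3702,
    tmb_base = 6, tmb_fold = 2.5, panel_mb = 1.6,
    msi_prob_wt = 0.10, msi_prob_mut = 0.35,
    n_msi_sites = 52, site_depth = 200, instability_shift = 3,
    site_unstable_prob_msi = 0.7, site_unstable_prob_mss = 0.01,
    cin_mean_wt = 0.30, cin_mean_mut = 0.20, n_segments = 40,
    os_hr = 2.0, age_hr_per_year = 1.03, stage_hr = 1.6,
    median_os_months = 36, censor_rate = 0.3,
    shifted_sets = c(HALLMARK_INTERFERON_ALPHA_RESPONSE = -1,
                     HALLMARK_INTERFERON_GAMMA_RESPONSE = -1),
    n_genes = 1200, n_gene_sets = 50, set_size = 20,
    n_cell_types = 12, n_shifted_cell_types = 7, cell_shift = 0.8,
    male_frequency = 0.59, mean_age = 60, sd_age = 10,
    stage_probs = c(0.15, 0.25, 0.35, 0.25), stage2_enrichment = 1.5,
    decoy_frac = 0.3,
    components = c("variants", "msi", "segments", "survival",
                   "expression", "cell_scores"),
    seed = 1) {
  cfg <- as.list(environment())
  assert_prob(c(focal_frequency, msi_prob_wt, msi_prob_mut,
                site_unstable_prob_msi, site_unstable_prob_mss,
                cin_mean_wt, cin_mean_mut, censor_rate, male_frequency),
              "probabilities")
  assert_prob(gene_frequencies, "gene_frequencies")
  assert_positive(c(tmb_fold, os_hr, age_hr_per_year, stage_hr,
                    panel_mb, median_os_months), "folds and hazard ratios")
  if (n_msi_sites < 1) stop_format("n_msi_sites must be >= 1")
  if (n_samples < 1) stop_format("n_samples must be >= 1")
  if (abs(sum(stage_probs) - 1) > 1e-8)
    stop_format("stage_probs must sum to 1")
  if (!is.null(shifted_sets) && is.null(names(shifted_sets)))
    stop_format("shifted_sets must be a named numeric vector")
  structure(cfg, class = "simulation_config")
}

#' Null simulation configuration
#'
#' The same cohort structure with every focal-mutation effect switched off:
#' no TMB fold change, equal MSI probabilities, equal CIN means, hazard
#' ratio 1, no expression or cell-score shifts, no stage enrichment.
#' Downstream tests on such a cohort should reject at the nominal rate.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_simulation_config <- function(...) {
  over <- list(...)
  base <- list(tmb_fold = 1, os_hr = 1, msi_prob_mut = 0.10,
               msi_prob_wt = 0.10, cin_mean_mut = 0.30, cin_mean_wt = 0.30,
               shifted_sets = NULL, cell_shift = 0, stage2_enrichment = 1)
  do.call(simulation_config, utils::modifyList(base, over))
}

#' Simulate one microsatellite site observation
#'
#' The normal histogram is drawn from a discretised normal distribution
#' centred on the site's reference repeat length.  A stable tumor histogram
#' is drawn from the same distribution; an unstable one is displaced
#' shorter by `shift` bp and over-dispersed by 50%, the classic deletion
#' stutter of replication slippage.  Uses the current RNG stream.
#'
#' @param depth Reads per histogram (>= 1).
#' @param unstable Is the site truly unstable in the tumor?
#' @param shift Length displacement in bp for unstable sites.
#' @param ref_length Reference repeat length in bp (>= 15 for a qualifying
#'   site).
#' @param dispersion SD of the read-length distribution in bp.
#' @param site_id Identifier for the observation.
#' @return An [msi_site_observation()].
#' @export
simulate_msi_site <- function(depth, unstable = FALSE, shift = 3,
                              ref_length = 18, dispersion = 1.2,
                              site_id = "site") {
  if (depth < 1) stop_format("depth must be >= 1")
  draw_hist <- function(centre, disp) {
    lens <- pmax(1, round(stats::rnorm(depth, centre, disp)))
    tab <- table(lens)
    h <- as.numeric(tab)
    names(h) <- names(tab)
    h
  }
  normal <- draw_hist(ref_length, dispersion)
  tumor <- if (unstable) draw_hist(ref_length - shift, dispersion * 1.5)
           else draw_hist(ref_length, dispersion)
  msi_site_observation(site_id, tumor, normal)
}

random_base_pair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample.int(4, n, replace = TRUE)
  alt <- ((ref - 1 + sample.int(3, n, replace = TRUE)) %% 4) + 1
  list(ref = bases[ref], alt = bases[alt])
}

## One block of variant-call rows with guaranteed filter fate.
## kind "driver"/"passenger": VAF >= 4.5% and alt reads >= 5 (always pass);
## "decoy_vaf": VAF < 2% (always fails the VAF floor);
## "decoy_reads": 1-4 alt reads (always fails read support);
## "artifact": passes thresholds but carries the artifact flag.
make_calls <- function(sample_id, gene, variant_class, kind,
                       is_known_driver = FALSE) {
  n <- length(sample_id)
  if (!n) return(NULL)
  if (kind %in% c("driver", "passenger")) {
    depth <- 100 + stats::rpois(n, 400)
    vaf_t <- stats::runif(n, 0.05, 0.6)
    alt <- pmax(5, round(vaf_t * depth))
  } else if (kind == "decoy_vaf") {
    depth <- rep(1000L, n)
    alt <- sample(2:19, n, replace = TRUE)
  } else if (kind == "decoy_reads") {
    depth <- 300 + stats::rpois(n, 100)
    alt <- sample(1:4, n, replace = TRUE)
  } else { # artifact
    depth <- 100 + stats::rpois(n, 400)
    alt <- pmax(5, round(stats::runif(n, 0.05, 0.3) * depth))
  }
  bp <- random_base_pair(n)
  data.frame(
    sample = sample_id, gene = gene,
    chrom = paste0("chr", sample.int(22, n, replace = TRUE)),
    pos = sample.int(1e8, n, replace = TRUE),
    ref = bp$ref, alt = bp$alt,
    variant_class = variant_class,
    alt_depth = as.numeric(alt), total_depth = as.numeric(depth),
    vaf = alt / depth,
    is_known_driver = rep(is_known_driver, n),
    is_artifact = rep(kind == "artifact", n),
    stringsAsFactors = FALSE
  )
}

sample_classes <- function(n) {
  sample(NONSYNONYMOUS_CLASSES, n, replace = TRUE,
         prob = c(0.66, 0.09, 0.13, 0.04, 0.08))
}

simulate_clinical <- function(cfg, focal) {
  n <- cfg$n_samples
  sex <- ifelse(stats::runif(n) < cfg$male_frequency, "male", "female")
  age <- round(pmin(95, pmax(25, stats::rnorm(n, cfg$mean_age, cfg$sd_age))))
  probs_wt <- cfg$stage_probs
  probs_mut <- probs_wt
  probs_mut[2] <- probs_mut[2] * cfg$stage2_enrichment
  probs_mut <- probs_mut / sum(probs_mut)
  stage <- integer(n)
  stage[!focal] <- sample(1:4, sum(!focal), replace = TRUE, prob = probs_wt)
  stage[focal] <- sample(1:4, sum(focal), replace = TRUE, prob = probs_mut)
  data.frame(sample = sprintf("S%05d", seq_len(n)),
             sex = sex, age = age, stage = stage,
             os_time = NA_real_, os_event = NA_integer_,
             focal_mutated = focal, stringsAsFactors = FALSE)
}

simulate_variants <- function(cfg, samples, focal) {
  n <- length(samples)
  blocks <- list()
  # one call per mutated driver gene (incl. the focal gene), flagged as a
  # known driver so it is excluded from the TMB numerator
  driver_status <- cbind(
    vapply(cfg$gene_frequencies, function(f)
      stats::runif(n) < f, logical(n)),
    focal)
  colnames(driver_status) <- c(names(cfg$gene_frequencies), cfg$focal_gene)
  hit <- which(driver_status, arr.ind = TRUE)
  if (nrow(hit)) {
    blocks$driver <- make_calls(samples[hit[, 1]],
                                colnames(driver_status)[hit[, 2]],
                                sample_classes(nrow(hit)), "driver",
                                is_known_driver = TRUE)
  }
  # TMB-eligible passengers: Poisson(tmb_base * panel_mb [* tmb_fold])
  lambda <- cfg$tmb_base * cfg$panel_mb *
    ifelse(focal, cfg$tmb_fold, 1)
  n_pass <- stats::rpois(n, lambda)
  smp <- rep(samples, n_pass)
  total_pass <- sum(n_pass)
  if (total_pass) {
    blocks$passenger <- make_calls(
      smp, sprintf("PSG%03d", sample.int(300, total_pass, replace = TRUE)),
      sample_classes(total_pass), "passenger")
  }
  # synonymous passengers (never counted in TMB or the landscape)
  n_syn <- stats::rpois(n, 0.25 * lambda)
  if (sum(n_syn)) {
    blocks$syn <- make_calls(
      rep(samples, n_syn),
      sprintf("PSG%03d", sample.int(300, sum(n_syn), replace = TRUE)),
      rep("synonymous", sum(n_syn)), "passenger")
  }
  # decoys guaranteed to fail exactly one retention rule, plus flagged
  # artifact calls that pass both thresholds
  for (kind in c("decoy_vaf", "decoy_reads", "artifact")) {
    n_k <- stats::rpois(n, cfg$decoy_frac * lambda / 3)
    if (sum(n_k)) {
      blocks[[kind]] <- make_calls(
        rep(samples, n_k),
        sprintf("PSG%03d", sample.int(300, sum(n_k), replace = TRUE)),
        sample_classes(sum(n_k)), kind)
    }
  }
  calls <- do.call(rbind, blocks)
  rownames(calls) <- NULL
  list(calls = calls, driver_status = driver_status)
}

simulate_msi_component <- function(cfg, samples, msi_true) {
  ref_lengths <- 15 + (seq_len(cfg$n_msi_sites) - 1) %% 11
  site_ids <- sprintf("MSI_%02d", seq_len(cfg$n_msi_sites))
  out <- vector("list", length(samples))
  names(out) <- samples
  for (i in seq_along(samples)) {
    p_unstable <- if (msi_true[i]) cfg$site_unstable_prob_msi
                  else cfg$site_unstable_prob_mss
    unstable <- stats::runif(cfg$n_msi_sites) < p_unstable
    depth <- pmax(2, stats::rpois(cfg$n_msi_sites, cfg$site_depth))
    obs <- vector("list", cfg$n_msi_sites)
    for (j in seq_len(cfg$n_msi_sites)) {
      obs[[j]] <- simulate_msi_site(depth[j], unstable[j],
                                    shift = cfg$instability_shift,
                                    ref_length = ref_lengths[j],
                                    site_id = site_ids[j])
    }
    names(obs) <- site_ids
    out[[i]] <- obs
  }
  out
}

simulate_segments <- function(cfg, samples, focal) {
  n <- length(samples)
  k <- cfg$n_segments
  cin_mean <- ifelse(focal, cfg$cin_mean_mut, cfg$cin_mean_wt)
  total <- n * k
  aberrant <- stats::runif(total) < rep(cin_mean, each = k)
  magnitude <- 0.201 + stats::rexp(total, rate = 4)
  ratio <- ifelse(aberrant,
                  magnitude * sample(c(-1, 1), total, replace = TRUE),
                  stats::runif(total, -0.19, 0.19))
  start <- sample.int(1e8, total, replace = TRUE)
  len <- pmax(1e4, round(stats::rlnorm(total, log(5e6), 0.5)))
  seg <- data.frame(
    sample = rep(samples, each = k),
    chrom = paste0("chr", sample.int(22, total, replace = TRUE)),
    start = start, end = start + len - 1L,
    log2_ratio = ratio, stringsAsFactors = FALSE)
  split(seg[setdiff(names(seg), "sample")], seg$sample)[samples]
}

## Administrative censoring horizon: C ~ Uniform(0, t_max) with t_max
## solved so that the expected censored fraction over the realised hazards
## equals censor_rate.
censor_horizon <- function(hazard, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  f <- function(t_max)
    mean((1 - exp(-hazard * t_max)) / (hazard * t_max)) - censor_rate
  stats::uniroot(f, interval = c(1e-9, 1e9), tol = 1e-10)$root
}

simulate_survival <- function(cfg, clinical) {
  base_hazard <- log(2) / cfg$median_os_months
  hazard <- base_hazard *
    cfg$os_hr^clinical$focal_mutated *
    cfg$age_hr_per_year^(clinical$age - 60) *
    cfg$stage_hr^(clinical$stage - 2)
  t_event <- stats::rexp(nrow(clinical), rate = hazard)
  t_max <- censor_horizon(hazard, cfg$censor_rate)
  t_censor <- if (is.finite(t_max))
    stats::runif(nrow(clinical), 0, t_max) else Inf
  list(os_time = pmin(t_event, t_censor),
       os_event = as.integer(t_event <= t_censor),
       hazard = hazard)
}

simulate_expression <- function(cfg, samples, focal) {
  g <- cfg$n_genes
  if (cfg$n_gene_sets * cfg$set_size > g)
    stop_format("n_genes too small for %d disjoint sets of size %d",
                cfg$n_gene_sets, cfg$set_size)
  genes <- sprintf("G%04d", seq_len(g))
  shifted_names <- names(cfg$shifted_sets)
  generic <- sprintf("HALLMARK_SET_%02d",
                     seq_len(cfg$n_gene_sets - length(shifted_names)))
  set_names <- c(shifted_names, generic)
  gene_sets <- split(genes[seq_len(cfg$n_gene_sets * cfg$set_size)],
                     rep(seq_len(cfg$n_gene_sets), each = cfg$set_size))
  names(gene_sets) <- set_names
  n <- length(samples)
  mu <- stats::runif(g, 3, 8)
  x_log <- matrix(stats::rnorm(g * n, 0, 1), nrow = g) + mu
  if (length(shifted_names)) {
    for (s in shifted_names) {
      idx <- match(gene_sets[[s]], genes)
      x_log[idx, focal] <- x_log[idx, focal] + cfg$shifted_sets[[s]]
    }
  }
  expr <- 2^x_log
  dimnames(expr) <- list(genes, samples)
  list(expression = expr, gene_sets = gene_sets)
}

CELL_TYPE_NAMES <- c(
  "B cell plasma", "B cell", "Common lymphoid progenitor", "Immune score",
  "Macrophage", "T cell CD4+ naive", "T cell CD8+ central memory",
  "Microenvironment score", "T cell CD4+ memory", "Monocyte", "NK cell",
  "Neutrophil")

simulate_cell_scores <- function(cfg, samples, focal) {
  k <- cfg$n_cell_types
  names_k <- if (k <= length(CELL_TYPE_NAMES)) CELL_TYPE_NAMES[seq_len(k)]
             else c(CELL_TYPE_NAMES,
                    sprintf("Cell type %02d", seq_len(k - 12)))
  n <- length(samples)
  m <- matrix(pmax(0, stats::rnorm(k * n, 0.25, 0.08)), nrow = k,
              dimnames = list(names_k, samples))
  shifted <- seq_len(min(cfg$n_shifted_cell_types, k))
  if (cfg$cell_shift != 0 && length(shifted))
    m[shifted, focal] <- m[shifted, focal] + cfg$cell_shift * 0.08
  m
}

#' Simulate a complete cohort bundle
#'
#' Deterministic given the configuration seed: each component (clinical,
#' variants, MSI histograms, segments, survival, expression, cell scores)
#' draws from its own sub-stream derived from the root seed, so disabling a
#' component leaves the others byte-identical.  Ground truth (focal status,
#' true MSI status, per-sample hazard) is attached as `$truth`.
#'
#' @param cfg A [simulation_config()].
#' @return A [cohort_bundle()] with a `truth` data frame.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config"))
    stop_format("cfg must be a simulation_config")
  focal <- with_seed(derive_seed(cfg$seed, "focal"),
                     stats::runif(cfg$n_samples) < cfg$focal_frequency)
  clinical <- with_seed(derive_seed(cfg$seed, "clinical"),
                        simulate_clinical(cfg, focal))
  samples <- clinical$sample

  variants <- NULL
  driver_status <- NULL
  if ("variants" %in% cfg$components) {
    v <- with_seed(derive_seed(cfg$seed, "variants"),
                   simulate_variants(cfg, samples, focal))
    variants <- v$calls
    driver_status <- v$driver_status
  }

  msi_true <- with_seed(derive_seed(cfg$seed, "msi_status"),
                        stats::runif(cfg$n_samples) <
                          ifelse(focal, cfg$msi_prob_mut, cfg$msi_prob_wt))
  msi_obs <- NULL
  if ("msi" %in% cfg$components) {
    msi_obs <- with_seed(derive_seed(cfg$seed, "msi_sites"),
                         simulate_msi_component(cfg, samples, msi_true))
  }

  segments <- NULL
  if ("segments" %in% cfg$components) {
    segments <- with_seed(derive_seed(cfg$seed, "segments"),
                          simulate_segments(cfg, samples, focal))
  }

  hazard <- rep(NA_real_, cfg$n_samples)
  if ("survival" %in% cfg$components) {
    surv <- with_seed(derive_seed(cfg$seed, "survival"),
                      simulate_survival(cfg, clinical))
    clinical$os_time <- surv$os_time
    clinical$os_event <- surv$os_event
    hazard <- surv$hazard
  }

  expression <- NULL
  gene_sets <- NULL
  if ("expression" %in% cfg$components && cfg$n_genes > 0) {
    e <- with_seed(derive_seed(cfg$seed, "expression"),
                   simulate_expression(cfg, samples, focal))
    expression <- e$expression
    gene_sets <- e$gene_sets
  }

  cell_scores <- NULL
  if ("cell_scores" %in% cfg$components && cfg$n_cell_types > 0) {
    cell_scores <- with_seed(derive_seed(cfg$seed, "cell_scores"),
                             simulate_cell_scores(cfg, samples, focal))
  }

  truth <- data.frame(sample = samples, focal_mutated = focal,
                      msi_true = msi_true, hazard = hazard,
                      stringsAsFactors = FALSE)
  if (!is.null(driver_status))
    truth <- cbind(truth, as.data.frame(driver_status)[
      setdiff(colnames(driver_status), cfg$focal_gene)])
  attr(truth, "config") <- cfg

  cohort_bundle(variants = variants, clinical = clinical,
                msi_observations = msi_obs, segments = segments,
                expression = expression, cell_scores = cell_scores,
                gene_sets = gene_sets, truth = truth)
}

#' Write a cohort bundle to disk in the package's file formats
#'
#' Emits `mutations.tsv`, `clinical.tsv`, `segments.seg`,
#' `msi_histograms.tsv`, `expression.tsv`, `cell_scores.tsv`,
#' `gene_sets.gmt` and `truth.tsv` (those whose component is present).
#'
#' @param bundle A [cohort_bundle()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(bundle$variants))
    write_result_table(bundle$variants, p("mutations.tsv"))
  clin <- bundle$clinical
  write_result_table(clin, p("clinical.tsv"))
  if (!is.null(bundle$segments)) {
    seg <- do.call(rbind, lapply(names(bundle$segments), function(s)
      cbind(sample = s, bundle$segments[[s]])))
    write_result_table(seg, p("segments.seg"))
  }
  if (!is.null(bundle$msi_observations)) {
    rows <- list()
    for (smp in names(bundle$msi_observations)) {
      for (obs in bundle$msi_observations[[smp]]) {
        for (src in c("tumor", "normal")) {
          h <- obs[[paste0(src, "_hist")]]
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, site_id = obs$site_id, source = src,
            length = as.numeric(names(h)), read_count = as.numeric(h),
            stringsAsFactors = FALSE)
        }
      }
    }
    write_result_table(do.call(rbind, rows), p("msi_histograms.tsv"))
  }
  if (!is.null(bundle$expression))
    write_matrix_tsv(bundle$expression, p("expression.tsv"), "gene")
  if (!is.null(bundle$cell_scores))
    write_matrix_tsv(bundle$cell_scores, p("cell_scores.tsv"), "cell_type")
  if (!is.null(bundle$gene_sets)) {
    lines <- vapply(names(bundle$gene_sets), function(nm)
      paste(c(nm, "synthetic", bundle$gene_sets[[nm]]), collapse = "\t"),
      character(1))
    writeLines(lines, p("gene_sets.gmt"))
  }
  if (!is.null(bundle$truth))
    write_result_table(bundle$truth, p("truth.tsv"))
  invisible(dir)
}
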