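## End-to-end orchestration: simulate (or read) a cohort, filter calls,
## compute biomarkers, mutation landscape, group comparisons, survival
## models and gene-set enrichment, with a run manifest recording every
## stage, row counts and the thresholds actually applied.

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x[order(names(x))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a cohort bundle from the paths in a run configuration
#'
#' Mandatory paths: `mutations`, `clinical`.  Optional: `segments`,
#' `msi_histograms`, `expression`, `cell_scores`, `gene_sets`; pipeline
#' stages whose inputs are absent are skipped, not errors.
#'
#' @param paths Named list of file paths.
#' @return A [cohort_bundle()].
#' @export
load_cohort <- function(paths) {
  need <- function(key) {
    if (is.null(paths[[key]]))
      stop_format("run config paths must include '%s'", key)
    paths[[key]]
  }
  opt <- function(key, reader) {
    if (is.null(paths[[key]])) NULL else reader(paths[[key]])
  }
  cohort_bundle(
    variants = read_mutations(need("mutations")),
    clinical = read_clinical(need("clinical")),
    segments = opt("segments", read_segments),
    msi_observations = opt("msi_histograms", read_msi_histograms),
    expression = opt("expression", read_expression),
    cell_scores = opt("cell_scores", read_cell_scores),
    gene_sets = opt("gene_sets", read_gene_sets))
}

## Qualitative direction summary of the five focal-mutation readouts:
## TMB, MSI fraction, CIN (group medians + Mann-Whitney), overall survival
## (Cox log-HR of the focal status), and expression enrichment (the gene
## set with the smallest FDR q).  The four test p-values are BH-adjusted
## together; the enrichment row keeps its own permutation FDR q.
direction_report <- function(comparisons, cox_focal, gsea_res,
                             sig_level = 0.05) {
  pick <- function(var) comparisons[comparisons$variable == var, ]
  rows <- list()
  for (var in c("tmb", "msi_fraction", "cin")) {
    r <- pick(var)
    if (!nrow(r) || !r$evaluable) next
    # U above its null mean means the mutated group tends to rank higher
    u_mid <- r$n_mut * r$n_wt / 2
    rows[[var]] <- data.frame(
      readout = var,
      direction = if (r$statistic > u_mid) "up" else "down",
      p_value = r$p_value, stringsAsFactors = FALSE)
  }
  if (!is.null(cox_focal)) {
    rows$os <- data.frame(
      readout = "os_hazard",
      direction = if (cox_focal$log_hr > 0) "up" else "down",
      p_value = cox_focal$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(gsea_res) && nrow(gsea_res)) {
    ok <- !is.na(gsea_res$nes)
    best <- gsea_res[ok, ][which.max(abs(gsea_res$nes[ok])), ]
    if (nrow(best)) {
      # the selection-corrected FWER p is the right single-claim p-value
      # for "the most extreme set is enriched"
      out <- rbind(out, data.frame(
        readout = paste0("enrichment:", best$set_name),
        direction = if (best$nes >= 0) "up" else "down",
        p_value = best$fwer_p, stringsAsFactors = FALSE))
    }
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < sig_level
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages, in dependency order: filter, biomarkers, landscape, association,
#' survival, enrichment, report.  A stage whose inputs are missing from the
#' bundle is skipped with a logged reason.  All thresholds come from the
#' run configuration (see [read_run_config()]); every value actually
#' applied is recorded in the manifest.
#'
#' @param bundle A [cohort_bundle()]; alternatively `NULL` with
#'   `sim_config` supplied, in which case the cohort is simulated first.
#' @param config Run configuration list from [read_run_config()].
#' @param sim_config Optional [simulation_config()] used when `bundle` is
#'   `NULL`.
#' @param out_dir Optional directory: result tables are written there as
#'   TSV, plus `manifest.json`.
#' @return A list with `results` (named list of stage outputs, including
#'   the `report` direction table) and `manifest`.
#' @export
run_pipeline <- function(bundle = NULL, config = read_run_config(),
                         sim_config = NULL, out_dir = NULL) {
  stages <- list()
  log_stage <- function(name, status, n_rows = NA_integer_,
                        reason = "") {
    stages[[name]] <<- data.frame(stage = name, status = status,
                                  n_rows = n_rows, reason = reason,
                                  stringsAsFactors = FALSE)
  }
  if (is.null(bundle)) {
    if (is.null(sim_config))
      stop_format("either a bundle or a sim_config is required")
    bundle <- simulate_cohort(sim_config)
    log_stage("simulate", "complete", nrow(bundle$clinical))
  }
  results <- list()

  kept <- filter_calls(bundle$variants, min_vaf = config$min_vaf,
                       min_alt_reads = config$min_alt_reads)
  results$filtered_calls <- kept
  log_stage("filter", "complete", if (is.null(kept)) 0L else nrow(kept))
  filtered_bundle <- bundle
  filtered_bundle$variants <- kept

  bm <- compute_biomarkers(filtered_bundle, panel_mb = config$panel_mb,
                           exclude_drivers = config$exclude_drivers,
                           msi_threshold = config$msi_threshold,
                           msi_alpha = config$msi_alpha,
                           msi_min_reads = config$msi_min_reads,
                           msi_test = config$msi_test,
                           cin_cutoff = config$cin_cutoff,
                           cin_weighting = config$cin_weighting)
  results$biomarkers <- bm
  log_stage("biomarkers", "complete", nrow(bm))

  if (!is.null(kept) && nrow(kept)) {
    mat <- mutation_matrix(kept, bundle$clinical$sample)
    results$mutation_matrix <- mat
    results$gene_frequencies <- gene_frequencies(mat)
    # pairwise testing is restricted to the most recurrently mutated genes
    # (oncoprint depth), not the whole passenger tail
    top <- utils::head(order(rowSums(mat), decreasing = TRUE),
                       config$landscape_top_genes)
    results$pairwise <- tryCatch(
      pairwise_association(mat[top, , drop = FALSE],
                           min_mutated = config$min_mutated),
      error = function(e) NULL)
    log_stage("landscape", "complete", nrow(mat))
  } else {
    log_stage("landscape", "skipped", reason = "no retained calls")
  }

  clinical <- bundle$clinical
  if (is.null(clinical$focal_mutated) &&
      !is.null(results$mutation_matrix) &&
      config$focal_gene %in% rownames(results$mutation_matrix)) {
    clinical$focal_mutated <-
      results$mutation_matrix[config$focal_gene, clinical$sample] > 0
  }
  if (!is.null(clinical$focal_mutated)) {
    results$comparisons <- compare_groups(clinical, bm)
    log_stage("association", "complete", nrow(results$comparisons))
    if (!is.null(bundle$cell_scores)) {
      grp <- clinical$focal_mutated[
        match(colnames(bundle$cell_scores), clinical$sample)]
      results$cell_score_comparisons <-
        compare_cell_scores(bundle$cell_scores, grp)
      log_stage("cell_scores", "complete",
                nrow(results$cell_score_comparisons))
    } else {
      log_stage("cell_scores", "skipped", reason = "no cell score matrix")
    }
  } else {
    log_stage("association", "skipped", reason = "no focal status")
  }

  cox_focal <- NULL
  if (!is.null(clinical$focal_mutated) &&
      !all(is.na(clinical$os_time)) && sum(clinical$os_event, na.rm = TRUE)) {
    records <- clinical
    records$msi_status <- bm$msi_status[match(records$sample, bm$sample)]
    records$tmb <- bm$tmb[match(records$sample, bm$sample)]
    results$km <- km_estimate(records$os_time, records$os_event,
                              ifelse(records$focal_mutated, "mutated",
                                     "wild_type"))
    covars <- "focal_mutated"
    for (cv in c("sex", "age", "stage")) {
      if (length(unique(stats::na.omit(records[[cv]]))) > 1L)
        covars <- c(covars, cv)
    }
    if (!all(is.na(records$msi_status)) &&
        length(unique(stats::na.omit(records$msi_status))) > 1L)
      covars <- c(covars, "msi")
    if (!all(is.na(records$tmb)) &&
        length(unique(stats::na.omit(records$tmb))) > 1L)
      covars <- c(covars, "tmb")
    results$cox_univariate <- cox_fit(records, covars, univariate = TRUE)
    results$cox_multivariate <- cox_fit(records, covars)
    cox_focal <- results$cox_univariate[
      results$cox_univariate$model == "focal_mutated", ][1, ]
    log_stage("survival", "complete", nrow(results$cox_multivariate))
  } else {
    log_stage("survival", "skipped",
              reason = "no survival data or focal status")
  }

  if (!is.null(bundle$expression) && !is.null(bundle$gene_sets) &&
      !is.null(clinical$focal_mutated)) {
    grp <- clinical$focal_mutated[
      match(colnames(bundle$expression), clinical$sample)]
    results$gsea <- gsea(bundle$expression, grp, bundle$gene_sets,
                         n_perm = config$gsea_nperm,
                         seed = config$seed,
                         weight = config$gsea_weight,
                         log2_transform = config$gsea_log2)
    log_stage("enrichment", "complete", nrow(results$gsea))
  } else {
    log_stage("enrichment", "skipped",
              reason = "no expression matrix or gene sets")
  }

  if (!is.null(results$comparisons)) {
    results$report <- direction_report(results$comparisons, cox_focal,
                                       results$gsea)
    log_stage("report", "complete", nrow(results$report))
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    thresholds = config[c("min_vaf", "min_alt_reads", "msi_threshold",
                          "msi_alpha", "msi_min_reads", "msi_test",
                          "cin_cutoff", "cin_weighting", "panel_mb",
                          "gsea_nperm", "gsea_weight", "min_mutated")],
    stages = do.call(rbind, c(stages, list(make.row.names = FALSE))),
    version = as.character(utils::packageVersion("panelmarkers")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) if (!is.null(x) && is.data.frame(x))
      write_result_table(x, file.path(out_dir, f))
    wt(results$filtered_calls, "filtered_calls.tsv")
    wt(results$biomarkers, "biomarkers.tsv")
    if (!is.null(results$mutation_matrix))
      write_matrix_tsv(results$mutation_matrix,
                       file.path(out_dir, "mutation_matrix.tsv"), "gene")
    if (!is.null(results$gene_frequencies))
      wt(data.frame(gene = names(results$gene_frequencies),
                    frequency = unname(results$gene_frequencies)),
         "gene_frequencies.tsv")
    wt(results$pairwise, "pairwise_association.tsv")
    wt(results$comparisons, "comparisons.tsv")
    wt(results$cell_score_comparisons, "cell_score_comparisons.tsv")
    wt(results$cox_univariate, "cox_univariate.tsv")
    wt(results$cox_multivariate, "cox_multivariate.tsv")
    if (!is.null(results$km)) wt(results$km$curves, "km_curves.tsv")
    wt(results$gsea, "gsea.tsv")
    wt(results$report, "report.tsv")
    jsonlite::write_json(
      list(config_hash = manifest$config_hash, seed = manifest$seed,
           thresholds = manifest$thresholds,
           stages = manifest$stages, version = manifest$version),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(results = results, manifest = manifest)
}
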