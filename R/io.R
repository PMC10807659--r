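## Readers and writers for the external table formats.  Every other module
## consumes only the in-memory objects produced here: plain data frames for
## row-oriented tables, numeric matrices for expression / cell scores, named
## lists for gene sets and per-site repeat-length histograms.
##
## Coordinate convention: mutation and segment tables are 1-based, fully
## closed intervals (MAF / SEG convention).

#' Column dialect for a mutation table
#'
#' Maps the canonical column names used internally to the column names found
#' in the file, so MAF-like tables with arbitrary headers can be read without
#' rewriting them.
#'
#' @param sample,gene,chrom,pos,ref,alt,variant_class,alt_depth,total_depth
#'   Column names in the file for each mandatory field.
#' @param vaf Column name for variant allele frequency; when the column is
#'   absent VAF is derived as `alt_depth / total_depth`.
#' @param is_known_driver,is_artifact Optional flag columns; missing columns
#'   default to `FALSE` for every row.
#' @return A named list of column names.
#' @export
mutation_dialect <- function(sample = "sample", gene = "gene",
                             chrom = "chrom", pos = "pos",
                             ref = "ref", alt = "alt",
                             variant_class = "variant_class",
                             alt_depth = "alt_depth",
                             total_depth = "total_depth",
                             vaf = "vaf",
                             is_known_driver = "is_known_driver",
                             is_artifact = "is_artifact") {
  list(sample = sample, gene = gene, chrom = chrom, pos = pos, ref = ref,
       alt = alt, variant_class = variant_class, alt_depth = alt_depth,
       total_depth = total_depth, vaf = vaf,
       is_known_driver = is_known_driver, is_artifact = is_artifact)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

#' Read somatic mutation calls from a MAF-like tab-separated table
#'
#' One call per row.  Rows with zero total depth are rejected (dropped with a
#' warning naming the offending line numbers); non-numeric depths are an
#' error naming the line.  When no VAF column is present it is derived as
#' `alt_depth / total_depth`.
#'
#' @param path Path to the tab-separated file (header row required).
#' @param dialect Column-name mapping from [mutation_dialect()].
#' @return A data frame of variant calls with canonical columns `sample`,
#'   `gene`, `chrom`, `pos`, `ref`, `alt`, `variant_class`, `alt_depth`,
#'   `total_depth`, `vaf`, `is_known_driver`, `is_artifact`, in file order.
#' @export
read_mutations <- function(path, dialect = mutation_dialect()) {
  raw <- read_tsv_raw(path)
  mandatory <- c("sample", "gene", "chrom", "pos", "ref", "alt",
                 "variant_class", "alt_depth", "total_depth")
  for (fld in mandatory) {
    if (!dialect[[fld]] %in% names(raw))
      stop_format("mutation table %s is missing mandatory column '%s'",
                  path, dialect[[fld]])
  }
  n <- nrow(raw)
  num_col <- function(fld) {
    v <- raw[[dialect[[fld]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & nzchar(trimws(as.character(v))))
    if (length(bad))
      stop_format("non-numeric '%s' in %s at line %d (value '%s')",
                  dialect[[fld]], path, bad[1] + 1L, v[bad[1]])
    out
  }
  calls <- data.frame(
    sample = as.character(raw[[dialect$sample]]),
    gene = as.character(raw[[dialect$gene]]),
    chrom = as.character(raw[[dialect$chrom]]),
    pos = as.integer(num_col("pos")),
    ref = as.character(raw[[dialect$ref]]),
    alt = as.character(raw[[dialect$alt]]),
    variant_class = as.character(raw[[dialect$variant_class]]),
    alt_depth = num_col("alt_depth"),
    total_depth = num_col("total_depth"),
    stringsAsFactors = FALSE
  )
  zero <- which(calls$total_depth <= 0)
  if (length(zero)) {
    warning(sprintf("rejected %d row(s) with total_depth = 0 in %s (line %s)",
                    length(zero), path,
                    paste(zero + 1L, collapse = ", ")), call. = FALSE)
  }
  if (dialect$vaf %in% names(raw)) {
    calls$vaf <- num_col("vaf")
  } else {
    calls$vaf <- calls$alt_depth / calls$total_depth
  }
  flag_col <- function(fld) {
    if (dialect[[fld]] %in% names(raw)) {
      v <- raw[[dialect[[fld]]]]
      if (is.logical(v)) v
      else as.logical(toupper(as.character(v)) %in% c("TRUE", "T", "1", "YES"))
    } else rep(FALSE, n)
  }
  calls$is_known_driver <- flag_col("is_known_driver")
  calls$is_artifact <- flag_col("is_artifact")
  calls <- calls[setdiff(seq_len(n), zero), , drop = FALSE]
  rownames(calls) <- NULL
  bad_vaf <- calls$vaf < 0 | calls$vaf > 1
  if (any(bad_vaf, na.rm = TRUE))
    stop_format("VAF outside [0, 1] in %s", path)
  calls
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are removed; a line with fewer than three
#' fields (i.e. an empty set) is a format error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene identifiers.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop_format("GMT line %d in %s has fewer than 3 fields", i, path)
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Read copy-number segments (SEG-like table)
#'
#' Accepts the common SEG header aliases (`ID`/`sample`, `loc.start`/`start`,
#' `loc.end`/`end`, `seg.mean`/`seg_mean`/`log2_ratio`).  Coordinates are
#' 1-based closed.
#'
#' @param path Path to the tab-separated segment file.
#' @return A data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `log2_ratio`.
#' @export
read_segments <- function(path) {
  raw <- read_tsv_raw(path)
  pick <- function(aliases, what) {
    hit <- aliases[aliases %in% names(raw)]
    if (!length(hit))
      stop_format("segment table %s is missing column '%s'", path, what)
    raw[[hit[1]]]
  }
  seg <- data.frame(
    sample = as.character(pick(c("sample", "ID", "Sample"), "sample")),
    chrom = as.character(pick(c("chrom", "chromosome", "Chromosome"), "chrom")),
    start = as.integer(pick(c("start", "loc.start", "Start"), "start")),
    end = as.integer(pick(c("end", "loc.end", "End"), "end")),
    log2_ratio = as.numeric(
      pick(c("log2_ratio", "seg_mean", "seg.mean", "Segment_Mean"),
           "seg_mean")),
    stringsAsFactors = FALSE
  )
  if (any(seg$start > seg$end))
    stop_format("segment with start > end in %s", path)
  seg
}

## Roman or free-text stage labels to ordinal 1-4; sub-stages (IIIA) collapse
## to their major stage.  Unrecognised labels become NA.
normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  out <- rep(NA_integer_, length(s))
  out[grepl("^IV", s) | s == "4"] <- 4L
  out[grepl("^III", s) | s == "3"] <- 3L
  out[grepl("^II($|[AB])", s) | s == "2"] <- 2L
  out[grepl("^I($|[AB])", s) | s == "1"] <- 1L
  out
}

#' Read a clinical table
#'
#' Expects columns `sample`, `sex`, `age`, `stage`, `os_time`, `os_event`;
#' an optional `focal_mutated` flag column is honoured.  Stage is normalised
#' to an ordinal 1-4 (Roman numerals and sub-stages such as "IIIA" accepted).
#'
#' @param path Path to the tab-separated clinical file.
#' @return A data frame, one row per sample.
#' @export
read_clinical <- function(path) {
  raw <- read_tsv_raw(path)
  mandatory <- c("sample", "sex", "age", "stage", "os_time", "os_event")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop_format("clinical table %s is missing column '%s'",
                path, missing_cols[1])
  clin <- data.frame(
    sample = as.character(raw$sample),
    sex = tolower(as.character(raw$sex)),
    age = as.numeric(raw$age),
    stage = normalize_stage(raw$stage),
    os_time = as.numeric(raw$os_time),
    os_event = as.integer(raw$os_event),
    stringsAsFactors = FALSE
  )
  if (!all(clin$sex %in% c("male", "female", NA)))
    stop_format("sex values must be 'male'/'female' in %s", path)
  if (any(clin$os_time < 0, na.rm = TRUE))
    stop_format("negative os_time in %s", path)
  if (!all(clin$os_event %in% c(0L, 1L, NA)))
    stop_format("os_event must be 0/1 in %s", path)
  if ("focal_mutated" %in% names(raw))
    clin$focal_mutated <- as.logical(raw$focal_mutated)
  clin
}

## Generic genes-x-samples (or celltypes-x-samples) matrix reader: first
## column holds row identifiers, remaining columns are samples.
read_matrix_tsv <- function(path, what) {
  raw <- read_tsv_raw(path)
  if (ncol(raw) < 2L)
    stop_format("%s matrix %s needs an id column plus >= 1 sample", what, path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop_format("duplicate row identifiers in %s matrix %s", what, path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a gene-expression matrix (genes x samples TSV)
#'
#' First column is the gene identifier; remaining columns are samples.
#' Gene identifiers must be unique and abundances non-negative.
#'
#' @param path Path to the tab-separated matrix.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  m <- read_matrix_tsv(path, "expression")
  if (any(m < 0, na.rm = TRUE))
    stop_format("negative abundance values in expression matrix %s", path)
  m
}

#' Read a cell-type score matrix (cell types x samples TSV)
#'
#' @param path Path to the tab-separated matrix (e.g. xCell output).
#' @return A numeric matrix, cell types in rows, samples in columns.
#' @export
read_cell_scores <- function(path) read_matrix_tsv(path, "cell score")

#' Read paired tumor/normal repeat-length histograms for MSI sites
#'
#' Long format: one row per (sample, site, source, read length) with columns
#' `sample`, `site_id`, `source` (`tumor` or `normal`), `length`,
#' `read_count`.
#'
#' @param path Path to the tab-separated histogram file.
#' @return A named list (by sample) of lists of site observations; each
#'   observation is a list with `site_id`, `tumor_hist` and `normal_hist`,
#'   the histograms being read counts named by repeat length in bp.
#' @export
read_msi_histograms <- function(path) {
  raw <- read_tsv_raw(path)
  mandatory <- c("sample", "site_id", "source", "length", "read_count")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop_format("MSI histogram table %s is missing column '%s'",
                path, missing_cols[1])
  if (!all(raw$source %in% c("tumor", "normal")))
    stop_format("source must be 'tumor' or 'normal' in %s", path)
  if (any(raw$read_count < 0))
    stop_format("negative read_count in %s", path)
  out <- list()
  for (smp in unique(as.character(raw$sample))) {
    rows_s <- raw[raw$sample == smp, , drop = FALSE]
    obs <- list()
    for (site in unique(as.character(rows_s$site_id))) {
      rows <- rows_s[rows_s$site_id == site, , drop = FALSE]
      hist_of <- function(src) {
        r <- rows[rows$source == src, , drop = FALSE]
        h <- as.numeric(r$read_count)
        names(h) <- as.character(r$length)
        h[order(as.numeric(names(h)))]
      }
      obs[[site]] <- msi_site_observation(site, hist_of("tumor"),
                                          hist_of("normal"))
    }
    out[[smp]] <- obs
  }
  out
}

#' Construct a single MSI site observation
#'
#' @param site_id Site identifier.
#' @param tumor_hist,normal_hist Read counts named by repeat length (bp).
#' @param min_repeat_bp Minimum repeat length for a qualifying site.
#' @return A list of class `msi_site_observation`.
#' @export
msi_site_observation <- function(site_id, tumor_hist, normal_hist,
                                 min_repeat_bp = 15) {
  if (any(tumor_hist < 0) || any(normal_hist < 0))
    stop_format("histogram counts must be non-negative (site %s)", site_id)
  structure(list(site_id = site_id,
                 tumor_hist = tumor_hist,
                 normal_hist = normal_hist,
                 min_repeat_bp = min_repeat_bp),
            class = "msi_site_observation")
}

#' Write a result table as TSV
#'
#' Real values are written with 15 significant digits so that a write/read
#' round trip reproduces integers bit-identically and reals to at least 12
#' significant digits.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- formatC(y[[j]], digits = 15, format = "g")
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as TSV (row ids in the first column)
#' @param m A numeric matrix with row and column names.
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  write_result_table(df, path)
}

#' Read the run configuration (YAML)
#'
#' Unspecified keys fall back to the package defaults: VAF floor 0.02,
#' minimum alt-read support 5, MSI fraction threshold 0.40, CIN log2 cutoff
#' 0.2, site-level test `chisq` at alpha 0.05 with 20-read minimum.
#'
#' @param path Path to a YAML configuration file (or `NULL` for defaults).
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    min_vaf = 0.02, min_alt_reads = 5,
    msi_threshold = 0.40, msi_test = "chisq", msi_alpha = 0.05,
    msi_min_reads = 20,
    cin_cutoff = 0.2, cin_weighting = "count",
    panel_mb = 1.6, exclude_drivers = TRUE,
    gsea_nperm = 1000, gsea_weight = 1, gsea_log2 = TRUE,
    min_mutated = 5, landscape_top_genes = 25, seed = 1,
    focal_gene = "PKHD1",
    paths = list()
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}

#' Assemble and validate a cohort bundle
#'
#' The in-memory container consumed by every analysis stage.  Validation
#' enforces that every sample identifier appearing in any component also
#' appears in the clinical table, that expression gene identifiers are
#' unique, and that gene sets are non-empty and deduplicated.
#'
#' @param variants Data frame of variant calls (see [read_mutations()]).
#' @param clinical Clinical data frame (see [read_clinical()]).
#' @param msi_observations Optional named list (by sample) of site
#'   observation lists.
#' @param segments Optional named list (by sample) of segment data frames,
#'   or one long data frame with a `sample` column.
#' @param expression Optional genes x samples matrix.
#' @param cell_scores Optional cell types x samples matrix.
#' @param gene_sets Optional named list of gene identifier vectors.
#' @param truth Optional ground-truth data frame (synthetic cohorts only).
#' @return A list of class `cohort_bundle`.
#' @export
cohort_bundle <- function(variants, clinical, msi_observations = NULL,
                          segments = NULL, expression = NULL,
                          cell_scores = NULL, gene_sets = NULL,
                          truth = NULL) {
  known <- clinical$sample
  check_samples <- function(ids, what) {
    extra <- setdiff(ids, known)
    if (length(extra))
      stop_format("%s mentions sample(s) absent from clinical: %s",
                  what, paste(utils::head(extra, 5), collapse = ", "))
  }
  if (!is.null(variants) && nrow(variants))
    check_samples(unique(variants$sample), "variant table")
  if (is.data.frame(segments))
    segments <- split(segments[setdiff(names(segments), "sample")],
                      segments$sample)
  if (!is.null(segments)) check_samples(names(segments), "segment list")
  if (!is.null(msi_observations))
    check_samples(names(msi_observations), "MSI observation list")
  if (!is.null(expression)) {
    check_samples(colnames(expression), "expression matrix")
    if (anyDuplicated(rownames(expression)))
      stop_format("expression matrix has duplicate gene identifiers")
  }
  if (!is.null(cell_scores)) check_samples(colnames(cell_scores),
                                           "cell score matrix")
  if (!is.null(gene_sets)) {
    if (any(!lengths(gene_sets)))
      stop_format("gene sets must be non-empty")
    gene_sets <- lapply(gene_sets, unique)
  }
  structure(list(variants = variants, clinical = clinical,
                 msi_observations = msi_observations, segments = segments,
                 expression = expression, cell_scores = cell_scores,
                 gene_sets = gene_sets, truth = truth),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", nrow(x$clinical), "samples\n")
  cat("  variants:    ", if (is.null(x$variants)) 0 else nrow(x$variants),
      "calls\n")
  cat("  msi sites:   ",
      if (is.null(x$msi_observations)) "absent"
      else paste0(length(x$msi_observations[[1]]), " per sample"), "\n")
  cat("  segments:    ",
      if (is.null(x$segments)) "absent" else "present", "\n")
  cat("  expression:  ",
      if (is.null(x$expression)) "absent"
      else paste(dim(x$expression), collapse = " x "), "\n")
  cat("  cell scores: ",
      if (is.null(x$cell_scores)) "absent"
      else paste(dim(x$cell_scores), collapse = " x "), "\n")
  cat("  gene sets:   ",
      if (is.null(x$gene_sets)) 0 else length(x$gene_sets), "\n")
  invisible(x)
}
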