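#' Construct a sample design table
#'
#' Describes the layout of a proximity-labelling experiment: each labelling
#' dataset couples one active-bait sample with one non-binding (R97A mutant)
#' control sample, and is identified by its multimer format and biological
#' replicate.
#'
#' @param sample_id Character vector of unique sample identifiers (one LFQ
#'   intensity column per sample in the quantification table).
#' @param dataset_id Character vector; the labelling experiment each sample
#'   belongs to. Every dataset must contain exactly one bait and one control
#'   sample.
#' @param bait Character vector, `"ACTIVE_SN"` or `"CONTROL_R97A"`.
#' @param multimer Character vector, `"IN_SOLUTION"` or `"ON_BEAD"`.
#' @param replicate Positive integer vector of biological replicate numbers.
#'
#' @return A `data.frame` of class `sample_design`.
#' @export
sample_design <- function(sample_id, dataset_id, bait, multimer, replicate) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    dataset_id = as.character(dataset_id),
    bait = as.character(bait),
    multimer = as.character(multimer),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_design(d)
  class(d) <- c("sample_design", "data.frame")
  d
}

validate_sample_design <- function(d) {
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (!all(d$bait %in% c("ACTIVE_SN", "CONTROL_R97A")))
    stop("bait must be ACTIVE_SN or CONTROL_R97A")
  if (!all(d$multimer %in% c("IN_SOLUTION", "ON_BEAD")))
    stop("multimer must be IN_SOLUTION or ON_BEAD")
  if (any(d$replicate < 1L))
    stop("replicate must be a positive integer")
  for (ds in unique(d$dataset_id)) {
    b <- d$bait[d$dataset_id == ds]
    if (sum(b == "ACTIVE_SN") != 1L || sum(b == "CONTROL_R97A") != 1L)
      stop("dataset ", ds, " must have exactly one ACTIVE_SN and one CONTROL_R97A sample")
  }
  key <- unique(data.frame(dataset_id = d$dataset_id,
                           mk = paste(d$multimer, d$replicate)))
  if (anyDuplicated(key$dataset_id) || anyDuplicated(key$mk))
    stop("(multimer, replicate) pairs must identify datasets uniquely")
  invisible(d)
}

#' Construct a protein quantification table
#'
#' The pipeline's raw input: one row per protein group with an LFQ intensity
#' per sample. Missing values (`NA`) are distinct from measured zeros and are
#' preserved through round-trip I/O.
#'
#' @param proteins `data.frame` with columns `protein_id` (unique accessions),
#'   `gene_name`, and optionally `mw_kda` (molecular weight, kilodaltons).
#' @param intensities Numeric matrix, rows matching `proteins$protein_id`,
#'   one column per sample; `NA` marks a value that was not quantified.
#'
#' @return An object of class `quant_table`: a list with elements `proteins`
#'   and `intensities`.
#' @export
quant_table <- function(proteins, intensities) {
  stopifnot(is.data.frame(proteins), is.matrix(intensities))
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  if (nrow(proteins) != nrow(intensities))
    stop("proteins and intensities row counts differ")
  bad <- !is.na(intensities) & (!is.finite(intensities) | intensities < 0)
  if (any(bad))
    stop("intensities must be finite and non-negative")
  if (is.null(proteins$gene_name)) proteins$gene_name <- proteins$protein_id
  rownames(intensities) <- proteins$protein_id
  structure(list(proteins = proteins, intensities = intensities),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table:", nrow(x$proteins), "proteins x",
      ncol(x$intensities), "samples;",
      sum(is.na(x$intensities)), "missing intensities\n")
  invisible(x)
}

#' Read a protein quantification table from TSV
#'
#' Expects a tab-separated file (UTF-8, `.` decimal separator, header
#' required) shaped like a MaxQuant `proteinGroups` export: an id column, an
#' optional gene-name and molecular-weight column, and one intensity column
#' per sample in the design. Following the LFQ convention that a reported
#' zero means "not quantified", zero and empty cells become missing values
#' unless `zero_as_missing = FALSE`.
#'
#' @param path Path to the TSV file.
#' @param design A [sample_design()] table; one intensity column per
#'   `sample_id` must be present.
#' @param id_col,gene_col,mw_col Column names for protein accession, gene
#'   name and molecular weight (kDa). `gene_col`/`mw_col` are optional in
#'   the file.
#' @param zero_as_missing Treat intensity cells equal to 0 as missing
#'   (default `TRUE`).
#'
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, design, id_col = "protein_id",
                             gene_col = "gene_name", mw_col = "mw_kda",
                             zero_as_missing = TRUE) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!id_col %in% names(tab))
    stop("id column '", id_col, "' not found in ", path)
  missing_cols <- setdiff(design$sample_id, names(tab))
  if (length(missing_cols))
    stop("sample column(s) missing from quant table: ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate protein_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  proteins <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  proteins$gene_name <- if (gene_col %in% names(tab))
    as.character(tab[[gene_col]]) else ids
  if (mw_col %in% names(tab)) proteins$mw_kda <- as.numeric(tab[[mw_col]])
  m <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(m) <- "double"
  if (zero_as_missing) m[!is.na(m) & m == 0] <- NA_real_
  quant_table(proteins, m)
}

#' Write a protein quantification table to TSV
#'
#' Missing intensities are written as empty cells, so that missingness (as
#' opposed to a measured zero) survives a round trip through
#' [read_quant_table()] with `zero_as_missing = FALSE`.
#'
#' @param x A [quant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  out <- cbind(x$proteins,
               as.data.frame(x$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Construct / validate a protein annotation table
#'
#' Per-protein metadata driving the annotation filter and characterization:
#' a flat cellular-component class, a plasma-membrane flag, the number of
#' predicted N-glycosylation sequons, and the Ig-like domain count. When a
#' sequence is supplied, `n_sequons` must equal the output of
#' [find_sequons()] on it (or is filled in from it when `NA`).
#'
#' @param df `data.frame` with columns `protein_id`, `cc_class` (one of
#'   `MEMBRANE`, `CYTOPLASM`, `NUCLEUS`, `OTHER`), `plasma_membrane`
#'   (logical), `n_sequons`, `n_ig_domains`, and optionally `sequence`.
#'
#' @return A `data.frame` of class `annotation_table`.
#' @export
annotation_table <- function(df) {
  req <- c("protein_id", "cc_class", "plasma_membrane", "n_sequons",
           "n_ig_domains")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein_id in annotation table")
  if (!all(df$cc_class %in% c("MEMBRANE", "CYTOPLASM", "NUCLEUS", "OTHER")))
    stop("cc_class must be one of MEMBRANE, CYTOPLASM, NUCLEUS, OTHER")
  df$plasma_membrane <- as.logical(df$plasma_membrane)
  if (any(df$plasma_membrane & df$cc_class != "MEMBRANE"))
    stop("plasma_membrane = TRUE requires cc_class = MEMBRANE")
  if (any(df$n_sequons < 0, na.rm = TRUE) || any(df$n_ig_domains < 0, na.rm = TRUE))
    stop("n_sequons and n_ig_domains must be >= 0")
  if (!is.null(df$sequence)) {
    for (i in which(!is.na(df$sequence) & nzchar(df$sequence))) {
      n <- length(find_sequons(df$sequence[i]))
      if (is.na(df$n_sequons[i])) {
        df$n_sequons[i] <- n
      } else if (df$n_sequons[i] != n) {
        stop("n_sequons for ", df$protein_id[i],
             " (", df$n_sequons[i], ") does not match its sequence (", n, ")")
      }
    }
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read a protein annotation table from TSV
#'
#' @param path Path to a TSV with the columns of [annotation_table()].
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  annotation_table(df)
}

#' Read the packaged counter-receptor reference table
#'
#' Returns the packaged 49-row reference list of counter-receptors (gene
#' name, log2 fold change over the R97A control, p value), with the printed
#' decimal values preserved verbatim. p values are stored as published,
#' without interpretation as raw or adjusted.
#'
#' @return A `data.frame` with columns `gene_name`, `log2_fold_change`,
#'   `p_value`.
#' @export
read_table1_fixture <- function() {
  path <- system.file("extdata", "table1_counter_receptors.tsv",
                      package = "proxiglyco", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df), c("gene_name", "log2_fold_change", "p_value")) ||
      anyDuplicated(df$gene_name) ||
      any(!is.finite(df$log2_fold_change)) ||
      any(df$p_value <= 0 | df$p_value >= 1))
    stop("packaged counter-receptor table is corrupt")
  df
}

#' Read a centroided MALDI peak list from TSV
#'
#' Two numeric columns (m/z in Da, intensity); a header line is detected and
#' skipped. Peaks are sorted by m/z on load.
#'
#' @param path Path to the TSV file.
#' @param condition_label Free-text label for the spectrum's condition.
#' @return A `data.frame` of class `peak_list` with columns `mz`,
#'   `intensity` and attribute `condition_label`.
#' @export
read_peaklist <- function(path, condition_label = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(lines[1], "\t")[[1]]
  if (length(lines) && any(is.na(suppressWarnings(as.numeric(first)))))
    lines <- lines[-1]
  parts <- strsplit(lines, "\t")
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(v) != 2L || anyNA(v))
      stop("peak list ", path, ": non-numeric or malformed entry at line ", i)
    if (v[1] <= 0) stop("peak list ", path, ": non-positive m/z at line ", i)
    if (v[2] < 0 || !is.finite(v[2]))
      stop("peak list ", path, ": invalid intensity at line ", i)
  }
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p)))
  pl <- peak_list(mz = m[, 1], intensity = m[, 2],
                  condition_label = condition_label)
  pl
}

#' Construct a peak list
#'
#' @param mz Positive m/z values (Da).
#' @param intensity Non-negative intensities.
#' @param condition_label Free-text spectrum label.
#' @return A sorted `peak_list` data frame.
#' @export
peak_list <- function(mz, intensity, condition_label = "") {
  if (any(mz <= 0) || any(!is.finite(mz))) stop("m/z must be positive and finite")
  if (any(intensity < 0) || any(!is.finite(intensity)))
    stop("intensities must be non-negative and finite")
  o <- order(mz)
  df <- data.frame(mz = mz[o], intensity = intensity[o])
  attr(df, "condition_label") <- condition_label
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Write a peak list to TSV
#'
#' @param x A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  utils::write.table(data.frame(mz = x$mz, intensity = x$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write an analysis report as JSON
#'
#' Serializes a report (any list of scalars, vectors and nested lists) to
#' JSON with a `schema_version` field, at full numeric precision.
#'
#' @param report A named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  report$schema_version <- REPORT_SCHEMA_VERSION
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON analysis report
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The report as a named list (the `schema_version` field retained).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rep$schema_version))
    stop("report ", path, " has no schema_version field")
  rep
}
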