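# TSV dialect used throughout: tab-separated, UTF-8, Unix newlines, header
# row, empty cell = missing.  Numeric columns are parsed strictly so a typo
# is reported with its line number instead of silently becoming NA.

parse_numeric_cols <- function(df, cols, path) {
  for (cl in intersect(cols, names(df))) {
    raw <- df[[cl]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !is.na(raw) & nzchar(trimws(raw))
    if (any(bad))
      stop("malformed numeric cell in ", path, ", column '", cl, "', line ",
           which(bad)[1] + 1L, ": '", raw[which(bad)[1]], "'")
    df[[cl]] <- v
  }
  df
}

#' Read a cohort phenotype table
#'
#' One row per individual: `id`, the ECG intervals (`qrs_ms`, `qt_ms`,
#' `pr_ms`), `heart_rate_bpm`, `qrs_axis_deg`, covariates (`age`, `sex`,
#' `bmi`, `height`), 24 amplitude columns (`R_`/`S_` per lead) and the eight
#' exclusion-flag columns.  Missing values are empty cells.
#'
#' @param path TSV file.
#' @param pedigree optional [pedigree()]; ids present in the phenotype table
#'   but absent from it raise an error.
#' @return data.frame.
#' @export
read_cohort <- function(path, pedigree = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = "")
  if (!"id" %in% names(df)) stop("cohort table lacks an 'id' column")
  num_cols <- setdiff(names(df), "id")
  df <- parse_numeric_cols(df, num_cols, path)
  if (anyDuplicated(df$id)) stop("duplicated id(s) in ", path)
  if (!is.null(pedigree)) {
    extra <- setdiff(df$id, pedigree$id)
    if (length(extra))
      stop("id(s) present in phenotypes but absent from the pedigree: ",
           paste(utils::head(extra, 10), collapse = ", "))
  }
  df
}

#' Read a SNP dosage matrix
#'
#' TSV with an `id` column followed by one column per SNP; dosages must lie
#' in `[0, 2]`.
#'
#' @inheritParams read_cohort
#' @return numeric matrix, rownames = ids.
#' @export
read_dosages <- function(path, pedigree = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = "")
  if (!"id" %in% names(df)) stop("dosage table lacks an 'id' column")
  snps <- setdiff(names(df), "id")
  df <- parse_numeric_cols(df, snps, path)
  for (cl in snps) {
    v <- df[[cl]]
    bad <- !is.na(v) & (v < 0 | v > 2)
    if (any(bad))
      stop("dosage outside [0, 2] in ", path, ", column '", cl, "', line ",
           which(bad)[1] + 1L, ": ", v[which(bad)[1]])
  }
  if (!is.null(pedigree)) {
    extra <- setdiff(df$id, pedigree$id)
    if (length(extra))
      stop("id(s) present in dosages but absent from the pedigree: ",
           paste(utils::head(extra, 10), collapse = ", "))
  }
  m <- as.matrix(df[snps])
  rownames(m) <- df$id
  m
}

#' Read a raw SNP catalog
#'
#' TSV with columns `id`, `source_trait`, `locus`, `pvalue`; feed the result
#' to [select_index_snps()].
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, na.strings = "")
  need <- c("id", "source_trait", "locus", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  parse_numeric_cols(df, "pvalue", path)
}

# atomic write: assemble under a .tmp name, rename into place on success
write_tsv_atomic <- function(df, path, digits = NULL) {
  tmp <- paste0(path, ".tmp")
  out <- df
  if (!is.null(digits))
    for (cl in names(out)) if (is.numeric(out[[cl]]) && cl != "n")
      out[[cl]] <- round(out[[cl]], digits)
  utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a heritability report
#'
#' Emits `report.tsv` (numbers rounded to 2 decimals, the table's customary
#' precision) and `report.json` (full precision, plus run metadata: package
#' version and the seed when supplied).  Files are written under a `.tmp`
#' name and renamed on completion, so an interrupted run never clobbers a
#' finished report.
#'
#' @param report a `herit_report` (or any data.frame).
#' @param dir output directory (created if needed).
#' @param seed optional integer recorded in the metadata.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_atomic(as.data.frame(report), file.path(dir, "report.tsv"),
                   digits = 2)
  meta <- list(package = "ecgherit",
               version = as.character(utils::packageVersion("ecgherit")),
               seed = seed)
  obj <- list(metadata = meta, report = as.data.frame(report))
  tmp <- file.path(dir, "report.json.tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  file.rename(tmp, file.path(dir, "report.json"))
  invisible(dir)
}

#' Write a simulated cohort bundle to disk
#'
#' Writes the same formats the pipeline reads: `pedigree.fam`, `cohort.tsv`,
#' `dosages.tsv`, `catalog.tsv` and `truth.json`.
#'
#' @param bundle output of [simulate_ecg_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fam(bundle$pedigree, file.path(dir, "pedigree.fam"))
  write_tsv_atomic(bundle$cohort, file.path(dir, "cohort.tsv"))
  dos <- data.frame(id = rownames(bundle$dosages), bundle$dosages,
                    check.names = FALSE)
  write_tsv_atomic(dos, file.path(dir, "dosages.tsv"))
  write_tsv_atomic(bundle$catalog, file.path(dir, "catalog.tsv"))
  truth <- bundle$truth
  for (tr in names(truth)) truth[[tr]]$components <- NULL
  jsonlite::write_json(list(seed = bundle$seed, truth = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
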