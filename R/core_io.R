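#' Construct a validated FPKM expression matrix
#'
#' An expression matrix holds non-negative FPKM values with genes in rows and
#' samples in columns. It is the input to the transcriptome screening stage.
#'
#' @param values Numeric matrix with row names (gene ids) and column names
#'   (sample ids). All values must be finite and non-negative, identifiers
#'   unique, and at least 2 samples present (per-gene variation statistics are
#'   undefined otherwise).
#' @return A numeric matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  .check_ids(rownames(values), colnames(values))
  if (ncol(values) < 2L)
    stop_shape("an expression matrix needs at least 2 samples")
  bad <- !is.finite(values)
  if (any(bad))
    stop_domain(sprintf("non-finite FPKM value(s) in gene(s): %s",
                        paste(unique(rownames(values)[row(values)[bad]]),
                              collapse = ", ")))
  if (any(values < 0))
    stop_domain(sprintf("negative FPKM value(s) in gene(s): %s",
                        paste(unique(rownames(values)[row(values)[values < 0]]),
                              collapse = ", ")))
  structure(values, class = c("expression_matrix", class(matrix())))
}

#' Construct a validated Ct matrix
#'
#' Holds quantification-cycle (Ct) values, genes in rows and samples in
#' columns, after any technical replicates have been collapsed by their
#' arithmetic mean. Retained Ct values must be finite and in (0, 45]; missing
#' cells are kept as explicit `NA` (never silently zero) and are only allowed
#' when `allow_missing = TRUE` — downstream algorithms apply their own
#' missing-data policy.
#'
#' @param ct Numeric matrix with gene row names and sample column names.
#' @param replicate_depth Integer >= 1, the number of technical replicates that
#'   were averaged into each cell.
#' @param allow_missing Allow `NA` cells (flagged, never imputed).
#' @return A numeric matrix of class `ct_matrix` with a `replicate_depth`
#'   attribute.
#' @export
ct_matrix <- function(ct, replicate_depth = 1L, allow_missing = FALSE) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  .check_ids(rownames(ct), colnames(ct))
  replicate_depth <- as.integer(replicate_depth)
  if (is.na(replicate_depth) || replicate_depth < 1L)
    stop_domain("replicate_depth must be an integer >= 1")
  miss <- is.na(ct)
  if (any(miss) && !allow_missing) {
    i <- which(miss, arr.ind = TRUE)[1L, ]
    stop_missing_data(sprintf("missing Ct for gene '%s', sample '%s'",
                              rownames(ct)[i[1L]], colnames(ct)[i[2L]]))
  }
  ok <- !miss
  if (any(!is.finite(ct[ok])) || any(ct[ok] <= 0 | ct[ok] > 45))
    stop_domain("Ct values must be finite and in (0, 45]")
  structure(ct, replicate_depth = replicate_depth,
            class = c("ct_matrix", class(matrix())))
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("Ct matrix: %d genes x %d samples (replicate depth %d)\n",
              nrow(x), ncol(x), attr(x, "replicate_depth")))
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a sample design table
#'
#' Maps each sample to one level of one or more experimental factors (e.g.
#' development stage, hair-follicle cycle time-point, breed, sampling site).
#' Stored long: one row per (sample, factor) with its level label.
#'
#' @param df Data frame with columns `sample`, `factor`, `level` (a fourth
#'   optional column `subject` identifies the animal for paired tests).
#' @return A data frame of class `study_design`.
#' @export
study_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample", "factor", "level")
  if (!all(need %in% names(df)))
    stop_shape("a study design needs columns sample, factor, level")
  for (nm in intersect(c(need, "subject"), names(df)))
    df[[nm]] <- trimws(as.character(df[[nm]]))
  dup <- duplicated(df[c("sample", "factor")])
  if (any(dup))
    stop_design_mismatch(
      sprintf("sample(s) assigned more than one level of a factor: %s",
              paste(unique(df$sample[dup]), collapse = ", ")))
  class(df) <- c("study_design", class(df))
  df
}

.check_ids <- function(genes, samples) {
  if (is.null(genes) || is.null(samples))
    stop_shape("gene and sample identifiers are required (dimnames)")
  if (anyDuplicated(genes)) stop_duplicate_id(genes[duplicated(genes)], "gene")
  if (anyDuplicated(samples)) stop_duplicate_id(samples[duplicated(samples)], "sample")
  invisible(TRUE)
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_delim_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          colClasses = "character", comment.char = "",
                          fileEncoding = "UTF-8")
  genes <- trimws(df[[1L]])
  df <- df[-1L]
  names(df) <- trimws(names(df))
  body <- vapply(df, function(col) {
    col <- trimws(col)
    col[col == ""] <- NA_character_
    suppressWarnings(as.numeric(col))
  }, numeric(nrow(df)))
  body <- matrix(body, nrow = nrow(df),
                 dimnames = list(genes, names(df)))
  raw_blank <- vapply(df, function(col) trimws(col) == "", logical(nrow(df)))
  list(values = body,
       unparseable = is.na(body) & !matrix(raw_blank, nrow = nrow(df)))
}

#' Read an FPKM expression matrix from delimited text
#'
#' Expects gene ids in the first column and sample ids in the header row;
#' tab or comma delimiter is auto-detected from the header, decimal separator
#' is `"."`, identifiers are whitespace-trimmed and case-sensitive.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  parsed <- .read_delim_matrix(path, sep)
  if (any(parsed$unparseable | is.na(parsed$values))) {
    bad <- is.na(parsed$values)
    stop_domain(sprintf("non-numeric cell(s) in gene row(s): %s",
                        paste(unique(rownames(parsed$values)[row(parsed$values)[bad]]),
                              collapse = ", ")))
  }
  expression_matrix(parsed$values)
}

#' Read a Ct table from delimited text
#'
#' Two layouts are supported. `"wide"` is gene x sample with gene ids in the
#' first column. `"long"` has columns `gene`, `sample`, `replicate`, `ct`, one
#' row per technical replicate; replicates are collapsed by their arithmetic
#' mean and the collapsed depth is recorded.
#'
#' @param path Path to a TSV/CSV file.
#' @param layout `"wide"` or `"long"`.
#' @param sep Field separator; `NULL` auto-detects.
#' @param allow_missing Keep empty wide-layout cells as flagged `NA` instead of
#'   raising a missing-data error.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, layout = c("wide", "long"), sep = NULL,
                          allow_missing = FALSE) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    parsed <- .read_delim_matrix(path, sep)
    if (any(parsed$unparseable))
      stop_domain("non-numeric Ct cell(s) present")
    miss <- is.na(parsed$values)
    if (any(miss) && !allow_missing) {
      i <- which(miss, arr.ind = TRUE)[1L, ]
      stop_missing_data(sprintf("missing Ct for gene '%s', sample '%s'",
                                rownames(parsed$values)[i[1L]],
                                colnames(parsed$values)[i[2L]]))
    }
    return(ct_matrix(parsed$values, replicate_depth = 1L,
                     allow_missing = allow_missing))
  }
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(df) <- tolower(trimws(names(df)))
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop_shape("long layout needs columns gene, sample, replicate, ct")
  df$gene <- trimws(as.character(df$gene))
  df$sample <- trimws(as.character(df$sample))
  df$ct <- as.numeric(df$ct)
  collapse_replicates(df, allow_missing = allow_missing)
}

#' Collapse technical replicates of a long Ct table
#'
#' Arithmetic mean per (gene, sample); no outlier rejection is applied. The
#' operation is idempotent: collapsing an already collapsed table (one
#' replicate per cell) changes nothing.
#'
#' @param long Data frame with columns `gene`, `sample`, `ct` (and optionally
#'   `replicate`).
#' @param allow_missing Permit (gene, sample) pairs with zero replicates.
#' @return A [ct_matrix()] with `replicate_depth` set to the largest number of
#'   replicates collapsed into any cell.
#' @export
collapse_replicates <- function(long, allow_missing = FALSE) {
  genes <- unique(long$gene)
  samples <- unique(long$sample)
  if (any(!is.finite(long$ct)))
    stop_domain("non-finite Ct value(s) in replicate table")
  counts <- table(factor(long$gene, genes), factor(long$sample, samples))
  if (any(counts == 0) && !allow_missing) {
    i <- which(counts == 0, arr.ind = TRUE)[1L, ]
    stop_missing_data(sprintf("no Ct replicate for gene '%s', sample '%s'",
                              genes[i[1L]], samples[i[2L]]))
  }
  sums <- tapply(long$ct, list(factor(long$gene, genes),
                               factor(long$sample, samples)), mean)
  ct_matrix(sums, replicate_depth = max(counts), allow_missing = allow_missing)
}

#' Read a sample design table
#'
#' @param path TSV/CSV file with columns `sample`, `factor`, `level` and
#'   optionally `subject`.
#' @param sep Field separator; `NULL` auto-detects.
#' @return A [study_design()].
#' @export
read_study_design <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- .detect_sep(path)
  study_design(utils::read.table(path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"))
}

#' Partition the samples of a Ct matrix by one design factor
#'
#' @param ct A [ct_matrix()] (or any matrix with sample column names).
#' @param design A [study_design()].
#' @param factor Name of the factor whose levels define the partition.
#' @return Named list, level -> character vector of sample ids. The subsets
#'   are disjoint and jointly cover the Ct matrix's samples.
#' @export
group_samples <- function(ct, design, factor) {
  rows <- design[design$factor == factor, , drop = FALSE]
  absent <- setdiff(colnames(ct), rows$sample)
  if (length(absent))
    stop_design_mismatch(
      sprintf("sample(s) not assigned a '%s' level: %s", factor,
              paste(absent, collapse = ", ")))
  rows <- rows[rows$sample %in% colnames(ct), , drop = FALSE]
  split(rows$sample, rows$level)
}

#' Write a gene x sample matrix as tab-delimited text
#'
#' Round-trips through [read_expression_matrix()] / [read_ct_table()]
#' value-identically at the written precision (values are written with full
#' double precision by default).
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_column Header label of the identifier column.
#' @param digits Significant digits to write; `NA` writes full precision.
#' @export
write_matrix_tsv <- function(m, path, id_column = "gene", digits = NA) {
  vals <- if (is.na(digits)) format(m, digits = 17, trim = TRUE, scientific = FALSE)
          else format(round(m, digits), trim = TRUE, scientific = FALSE)
  df <- data.frame(rownames(m), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
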