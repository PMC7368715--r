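.series_matrix <- function(series, strict_missing = FALSE) {
  if (length(series) < 2L)
    stop_shape("aggregation needs at least 2 stability series")
  if (!all(vapply(series, inherits, logical(1L), "stability_series")))
    stop_shape("inputs must be stability_series objects")
  bad <- !vapply(series, `[[`, logical(1L), "lower_is_stable")
  if (any(bad))
    stop_orientation(sprintf(
      "series oriented higher-is-stabler must be negated by the caller: %s",
      paste(vapply(series[bad], `[[`, character(1L), "algorithm"),
            collapse = ", ")))
  genes <- names(series[[1L]]$values)
  for (s in series[-1L])
    if (!setequal(names(s$values), genes))
      stop_gene_set(sprintf("gene set of series '%s' differs", s$algorithm))
  if (length(genes) < 2L) stop_shape("aggregation needs at least 2 genes")
  m <- vapply(series, function(s) s$values[genes], numeric(length(genes)))
  labels <- vapply(series, `[[`, character(1L), "algorithm")
  labels <- make.unique(labels)
  dimnames(m) <- list(genes, labels)
  incomplete <- rownames(m)[rowSums(is.na(m)) > 0L]
  if (length(incomplete)) {
    if (strict_missing)
      stop_missing_data(sprintf("missing stability value(s) for gene(s): %s",
                                paste(incomplete, collapse = ", ")))
    warning(sprintf("dropping gene(s) with missing stability values: %s",
                    paste(incomplete, collapse = ", ")), call. = FALSE)
    m <- m[!rownames(m) %in% incomplete, , drop = FALSE]
    if (nrow(m) < 2L) stop_shape("fewer than 2 complete genes left to aggregate")
  }
  m
}

#' ComprFinder composite stability score
#'
#' Each algorithm's stability column is min-max standardized onto [0, 1]
#' (range `delta = max - min`; standardized value `(x - min) / delta`) and the
#' final score of a gene is the arithmetic mean of its standardized values
#' over the n supplied algorithms. Genes are ranked by ascending final score
#' (lower = more stable; ties broken lexicographically by gene id). Because
#' min-max standardization is invariant to strictly increasing affine
#' transforms of a column, the composite is insensitive to the very different
#' native scales of the underlying algorithms. n is not fixed at 4: any >= 2
#' identically oriented series over the same gene set can be aggregated.
#'
#' A column with zero range (an algorithm that does not discriminate at all)
#' is standardized to all zeros and flagged with a warning, so it cannot
#' separate genes.
#'
#' @param series List of >= 2 [stability_series()] over the identical gene
#'   set, all oriented lower-is-more-stable. A gene with a missing value in
#'   any series is dropped with a warning (`strict_missing = TRUE` errors
#'   instead).
#' @param strict_missing Error on missing values instead of dropping genes.
#' @return List of class `comprfinder_result`: `values` (gene x algorithm
#'   input matrix), `standardized`, `fs` (named final scores), `ranking`
#'   (named integer ranks), `n_algorithms`, `constant_columns`.
#' @export
comprfinder <- function(series, strict_missing = FALSE) {
  m <- .series_matrix(series, strict_missing)
  rng <- apply(m, 2L, range)
  delta <- rng[2L, ] - rng[1L, ]
  constant <- delta == 0
  if (any(constant))
    warning(sprintf("constant stability column(s) standardized to 0: %s",
                    paste(colnames(m)[constant], collapse = ", ")),
            call. = FALSE)
  std <- sweep(m, 2L, rng[1L, ])
  std[, !constant] <- sweep(std[, !constant, drop = FALSE], 2L,
                            delta[!constant], "/")
  std[, constant] <- 0
  fs <- rowMeans(std)
  ord <- order(fs, rownames(m))
  ranking <- stats::setNames(seq_len(nrow(m)),
                             rownames(m)[ord])[rownames(m)]
  names(ranking) <- rownames(m)
  structure(list(values = m, standardized = std, fs = fs, ranking = ranking,
                 n_algorithms = ncol(m),
                 constant_columns = colnames(m)[constant]),
            class = "comprfinder_result")
}

#' @export
print.comprfinder_result <- function(x, digits = 3, ...) {
  cat(sprintf("ComprFinder composite over %d algorithms, %d genes\n",
              x$n_algorithms, nrow(x$values)))
  ord <- order(x$ranking)
  print(data.frame(gene = names(x$fs)[ord],
                   FS = round(x$fs[ord], digits),
                   rank = x$ranking[ord], row.names = NULL), ...)
  invisible(x)
}

#' @export
as.data.frame.comprfinder_result <- function(x, ...) {
  ord <- order(x$ranking)
  data.frame(gene = names(x$fs)[ord], fs = unname(x$fs[ord]),
             rank = unname(x$ranking[ord]), stringsAsFactors = FALSE)
}

#' RefFinder-style geometric mean of ranks
#'
#' Each series is first converted to integer ranks (average ranks on ties);
#' a gene's score is the geometric mean of its n ranks. This is the
#' rank-based comparator the composite score is designed to replace: ranking
#' first discards the spacing of the underlying stability values.
#'
#' @inheritParams comprfinder
#' @return Data frame (`gene`, `score`, `rank`) sorted by ascending score,
#'   with the gene x algorithm rank matrix in attribute `"ranks"`.
#' @export
reffinder_score <- function(series, strict_missing = FALSE) {
  m <- .series_matrix(series, strict_missing)
  ranks <- apply(m, 2L, rank, ties.method = "average")
  ranks <- matrix(ranks, nrow = nrow(m), dimnames = dimnames(m))
  score <- exp(rowMeans(log(ranks)))
  ord <- order(score, rownames(m))
  out <- data.frame(gene = rownames(m)[ord], score = unname(score[ord]),
                    rank = seq_len(nrow(m)), stringsAsFactors = FALSE)
  attr(out, "ranks") <- ranks
  out
}

#' Side-by-side comparison of the composite and rank-based aggregates
#'
#' @inheritParams comprfinder
#' @return Data frame with one row per gene: final score and rank under the
#'   composite (ComprFinder) and under the geometric-mean-of-ranks comparator
#'   (RefFinder-style), sorted by composite rank.
#' @export
compare_aggregators <- function(series, strict_missing = FALSE) {
  cf <- comprfinder(series, strict_missing)
  rf <- reffinder_score(series, strict_missing)
  rf_rank <- stats::setNames(rf$rank, rf$gene)
  rf_score <- stats::setNames(rf$score, rf$gene)
  ord <- order(cf$ranking)
  genes <- names(cf$fs)[ord]
  data.frame(gene = genes,
             comprfinder_fs = unname(cf$fs[genes]),
             comprfinder_rank = unname(cf$ranking[genes]),
             reffinder_score = unname(rf_score[genes]),
             reffinder_rank = unname(rf_rank[genes]),
             stringsAsFactors = FALSE)
}
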