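#' Remove zero-expression genes before screening
#'
#' @param m An [expression_matrix()].
#' @param zero_policy `"any-zero"` removes a gene if any sample has FPKM 0
#'   (default; screening statistics such as MFC are undefined at 0);
#'   `"all-zero"` removes only genes with FPKM 0 everywhere.
#' @return The filtered matrix, with attributes `removed` (gene ids) and
#'   `n_removed`.
#' @export
prefilter_genes <- function(m, zero_policy = c("any-zero", "all-zero")) {
  zero_policy <- match.arg(zero_policy)
  drop <- if (zero_policy == "any-zero") apply(m == 0, 1L, any)
          else apply(m == 0, 1L, all)
  if (all(drop)) stop_empty_set("prefilter removed every gene")
  out <- m[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(m)[drop]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Per-gene screening statistics
#'
#' For each gene across samples: mean FPKM; coefficient of variation in
#' percent, `100 * sd / mean` (sample standard deviation, n-1 denominator);
#' maximum fold change `max / min` (flagged undefined when the minimum is 0);
#' a per-sample specificity measure SPM and its dispersion DPM.
#'
#' Two DPM normalizations are available. The default `"spm-sd"` uses
#' `SPM_i = x_i^2 / sum(x^2)` and `DPM = sd(SPM) * sqrt(n)`, which maps a
#' constant non-zero gene to exactly 0 and a one-hot gene to exactly 1 for
#' every n >= 2. The alternative `"cv-rms"` is `DPM = cv / sqrt(1 + cv^2)`
#' (cv as a fraction), the calibration that agrees with published
#' housekeeping-gene screening tables in which DPM tracks the CV; it also maps
#' constants to 0 but approaches 1 only asymptotically for one-hot genes.
#'
#' @param m An [expression_matrix()] (no all-zero gene rows).
#' @param dpm_method `"spm-sd"` (default) or `"cv-rms"`.
#' @return Data frame with columns `gene`, `mean_fpkm`, `cv_pct`, `mfc`
#'   (`NA` where undefined), `mfc_defined`, `dpm`; the SPM vectors are
#'   attached as a gene x sample matrix in attribute `"spm"`.
#' @export
gene_summary <- function(m, dpm_method = c("spm-sd", "cv-rms")) {
  dpm_method <- match.arg(dpm_method)
  if (ncol(m) < 2L) stop_shape("gene summaries need at least 2 samples")
  if (any(rowSums(m) == 0))
    stop_domain(sprintf("all-zero gene(s) reached gene_summary: %s",
                        paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
  n <- ncol(m)
  mean_fpkm <- rowMeans(m)
  sd_fpkm <- apply(m, 1L, stats::sd)
  cv_pct <- 100 * sd_fpkm / mean_fpkm
  mins <- apply(m, 1L, min)
  maxs <- apply(m, 1L, max)
  mfc_defined <- mins > 0
  mfc <- ifelse(mfc_defined, maxs / mins, NA_real_)
  spm <- m^2 / rowSums(m^2)
  dpm <- switch(dpm_method,
    "spm-sd" = apply(spm, 1L, stats::sd) * sqrt(n),
    "cv-rms" = {
      cv <- cv_pct / 100
      cv / sqrt(1 + cv^2)
    })
  out <- data.frame(gene = rownames(m), mean_fpkm = mean_fpkm,
                    cv_pct = cv_pct, mfc = mfc, mfc_defined = mfc_defined,
                    dpm = dpm, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "spm") <- spm
  attr(out, "dpm_method") <- dpm_method
  out
}

#' Screening thresholds for candidate housekeeping genes
#'
#' Exactly one FPKM rule is active: the absolute cutoff (default,
#' `mean FPKM >= min_mean_fpkm`) or the percentile rule
#' (`mean FPKM >=` the `fpkm_percentile`-th percentile of all gene means).
#' FPKM and CV thresholds are inclusive; DPM and MFC are strict.
#'
#' @param min_mean_fpkm Inclusive lower bound on mean FPKM (default 10).
#' @param max_cv_pct Inclusive upper bound on CV percent (default 20).
#' @param max_dpm Strict upper bound on DPM (default 0.2).
#' @param max_mfc Strict upper bound on MFC (default 2.5).
#' @param fpkm_rule `"absolute"` or `"percentile"`.
#' @param fpkm_percentile Percentile (0-100) used by the percentile rule.
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_mean_fpkm = 10, max_cv_pct = 20,
                              max_dpm = 0.2, max_mfc = 2.5,
                              fpkm_rule = c("absolute", "percentile"),
                              fpkm_percentile = 80) {
  fpkm_rule <- match.arg(fpkm_rule)
  vals <- c(min_mean_fpkm, max_cv_pct, max_dpm, max_mfc, fpkm_percentile)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_domain("all screening thresholds must be positive")
  structure(list(min_mean_fpkm = min_mean_fpkm, max_cv_pct = max_cv_pct,
                 max_dpm = max_dpm, max_mfc = max_mfc,
                 fpkm_rule = fpkm_rule, fpkm_percentile = fpkm_percentile),
            class = "screen_thresholds")
}

#' Select candidate housekeeping genes by thresholded intersection
#'
#' Builds the four criterion gene sets (high FPKM, low CV, low DPM, low MFC)
#' and their 4-way intersection; genes whose MFC is undefined (minimum FPKM 0)
#' are excluded from the MFC set. Counts are reported for Venn-style display.
#'
#' @param summaries Output of [gene_summary()].
#' @param thresholds A [screen_thresholds()].
#' @return List with elements `sets` (list fpkm/cv/dpm/mfc of gene id
#'   vectors), `intersection`, `counts` (named integer vector incl.
#'   `intersection`) and `thresholds`.
#' @export
screen_candidates <- function(summaries, thresholds = screen_thresholds()) {
  t <- thresholds
  fpkm_cut <- if (t$fpkm_rule == "absolute") t$min_mean_fpkm
              else stats::quantile(summaries$mean_fpkm,
                                   t$fpkm_percentile / 100, names = FALSE)
  sets <- list(
    fpkm = summaries$gene[summaries$mean_fpkm >= fpkm_cut],
    cv = summaries$gene[summaries$cv_pct <= t$max_cv_pct],
    dpm = summaries$gene[summaries$dpm < t$max_dpm],
    mfc = summaries$gene[summaries$mfc_defined & summaries$mfc < t$max_mfc])
  intersection <- Reduce(intersect, sets)
  counts <- c(vapply(sets, length, integer(1L)),
              intersection = length(intersection))
  list(sets = sets, intersection = intersection, counts = counts,
       thresholds = t)
}

#' Rank genes by ascending coefficient of variation
#'
#' Ties are broken lexicographically by gene id.
#'
#' @param summaries Output of [gene_summary()].
#' @return `summaries` reordered by CV with an added integer `cv_rank` column.
#' @export
rank_by_cv <- function(summaries) {
  ord <- order(summaries$cv_pct, summaries$gene)
  out <- summaries[ord, , drop = FALSE]
  out$cv_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
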