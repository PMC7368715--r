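#' A labelled per-gene stability series
#'
#' Container used by the aggregation stage. All four bundled algorithms are
#' oriented lower-is-more-stable; the orientation is recorded so aggregation
#' can refuse to mix directions.
#'
#' @param algorithm Label, e.g. `"geNorm"`.
#' @param values Named numeric vector, one finite value per gene (`NA` allowed
#'   only to mark a gene an algorithm could not evaluate).
#' @param lower_is_stable Orientation flag; all bundled algorithms use `TRUE`.
#' @return A list of class `stability_series`.
#' @export
stability_series <- function(algorithm, values, lower_is_stable = TRUE) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop_gene_set("stability values need unique gene names")
  if (any(is.infinite(values)))
    stop_domain("stability values must be finite")
  structure(list(algorithm = algorithm, values = values,
                 lower_is_stable = isTRUE(lower_is_stable)),
            class = "stability_series")
}

#' @export
print.stability_series <- function(x, ...) {
  cat(sprintf("%s stability (%s = more stable)\n", x$algorithm,
              if (x$lower_is_stable) "lower" else "higher"))
  print(sort(x$values), ...)
  invisible(x)
}

#' @export
as.data.frame.stability_series <- function(x, ...) {
  data.frame(gene = names(x$values), algorithm = x$algorithm,
             stability = unname(x$values),
             rank = rank(x$values, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Convert Ct values to anchored relative quantities
#'
#' Per gene, `Q = E^(Ct_min - Ct)` where `Ct_min` is that gene's minimum Ct,
#' so the highest-expression sample of each gene gets `Q = 1` and
#' `0 < Q <= 1` throughout. The amplification base E defaults to 2 (perfect
#' doubling) and may be supplied per gene from a dilution-series estimate;
#' plausible bases are restricted to [1.6, 2.1]. geNorm/NormFinder results are
#' invariant to the anchor because both work on ratios / log differences.
#'
#' @param ct A [ct_matrix()] without missing cells.
#' @param efficiencies Scalar base E, or a named vector with one base per gene.
#' @return Gene x sample matrix of relative quantities with attribute
#'   `"efficiencies"`.
#' @export
ct_to_quantity <- function(ct, efficiencies = 2) {
  if (any(is.na(ct)))
    stop_missing_data("Ct matrix has missing cells; apply a missing-data policy first")
  E <- .gene_efficiencies(efficiencies, rownames(ct))
  q <- E^(apply(ct, 1L, min) - unclass(ct))
  structure(q, efficiencies = E)
}

.gene_efficiencies <- function(efficiencies, genes) {
  if (length(efficiencies) == 1L && is.null(names(efficiencies)))
    efficiencies <- stats::setNames(rep(efficiencies, length(genes)), genes)
  if (!all(genes %in% names(efficiencies)))
    stop_gene_set(sprintf("no amplification base for gene(s): %s",
                          paste(setdiff(genes, names(efficiencies)),
                                collapse = ", ")))
  E <- efficiencies[genes]
  if (any(!is.finite(E)) || any(E < 1.6 | E > 2.1))
    stop_domain("amplification base E must lie in [1.6, 2.1]")
  E
}

.sd_cols <- function(x) apply(x, 1L, stats::sd)

# mean over k != j of SD_samples(log2(q_j / q_k)), for each gene j
.genorm_m <- function(logq) {
  g <- nrow(logq)
  vapply(seq_len(g), function(j) {
    v <- vapply(setdiff(seq_len(g), j), function(k)
      stats::sd(logq[j, ] - logq[k, ]), numeric(1L))
    mean(v)
  }, numeric(1L))
}

#' geNorm expression-stability analysis
#'
#' The stability of gene j is `M_j`, the average over all other genes k of the
#' standard deviation across samples of `log2(Q_j / Q_k)`. Genes are excluded
#' stepwise (highest M first, M recomputed each round) until two remain; the
#' exclusion order defines the ranking and the final indistinguishable pair is
#' ordered by its M at the 3-gene stage so downstream rank aggregation gets
#' distinct ranks 1 and 2. Pairwise variation `V_n` is the standard deviation
#' across samples of `log2(NF_n / NF_(n+1))`, where `NF_n` is the per-sample
#' geometric mean of the top-n genes' quantities; `V_n < 0.15` is the
#' conventional signal that the (n+1)-th gene adds nothing.
#'
#' @param q Relative quantity matrix from [ct_to_quantity()] (>= 3 genes,
#'   >= 2 samples, all quantities positive).
#' @return List of class `genorm_result`: `m` (full-panel M per gene),
#'   `ranking` (named integer ranks, 1 = most stable), `exclusion_order`
#'   (least stable first), `v` (named vector, `"V2/V3"` ...), `series`
#'   (a [stability_series()] of the full-panel M values).
#' @export
genorm <- function(q) {
  if (nrow(q) < 3L) stop_shape("geNorm needs at least 3 genes")
  if (ncol(q) < 2L) stop_shape("geNorm needs at least 2 samples")
  if (any(q <= 0)) stop_domain("quantities must be positive")
  logq <- log2(unclass(q))
  genes <- rownames(q)

  m_full <- stats::setNames(.genorm_m(logq), genes)

  active <- genes
  exclusion <- character(0)
  final_pair_m <- NULL
  while (length(active) > 2L) {
    m <- stats::setNames(.genorm_m(logq[active, , drop = FALSE]), active)
    worst <- names(which.max(m))[1L]
    if (length(active) == 3L)
      final_pair_m <- m[setdiff(active, worst)]
    exclusion <- c(exclusion, worst)
    active <- setdiff(active, worst)
  }
  # rank: excluded last = least stable; final pair ordered by 3-gene-stage M
  pair_sorted <- names(sort(final_pair_m))
  ranking_order <- c(pair_sorted, rev(exclusion)) # most stable first
  ranking <- stats::setNames(seq_along(ranking_order), ranking_order)[genes]
  names(ranking) <- genes

  top <- ranking_order
  nf <- vapply(seq_along(top), function(n)
    colMeans(logq[top[seq_len(n)], , drop = FALSE]), numeric(ncol(q)))
  # nf[, n] = per-sample log2 geometric mean of top-n genes
  v <- vapply(2:(length(top) - 1L), function(n)
    stats::sd(nf[, n] - nf[, n + 1L]), numeric(1L))
  names(v) <- sprintf("V%d/V%d", 2:(length(top) - 1L), 3:length(top))

  structure(list(m = m_full, ranking = ranking,
                 exclusion_order = exclusion, v = v,
                 series = stability_series("geNorm", m_full)),
            class = "genorm_result")
}

#' NormFinder model-based stability
#'
#' Implements the variance-decomposition model of Andersen and colleagues on
#' log2 quantities. With a grouping factor, per-gene/per-group intragroup
#' variances are estimated from sample-centred values (each sample's gene
#' average subtracted), bias-corrected for the centring and truncated at 0,
#' and intergroup deviations (constrained to sum to zero over genes within a
#' group) are shrunken toward 0 by their estimated signal/noise ratio; the
#' stability of a gene in a group is `|d| + SE(d)` and the reported value is
#' its average over groups. Without a design the ungrouped variant returns the
#' bias-corrected variance of each gene's deviation from the per-sample mean
#' profile.
#'
#' @param q Relative quantity matrix (positive; >= 3 genes).
#' @param design Optional [study_design()]; with it, `factor` selects the
#'   grouping and every level needs >= 2 samples.
#' @param factor Grouping factor name (required with a design).
#' @param log_base Logarithm base for the transform (default 2).
#' @return A [stability_series()] labelled `"NormFinder"`, with attribute
#'   `"truncated"` naming (gene, group) variance estimates truncated at 0.
#' @export
normfinder <- function(q, design = NULL, factor = NULL, log_base = 2) {
  if (nrow(q) < 3L) stop_shape("NormFinder needs at least 3 genes")
  if (any(q <= 0)) stop_domain("quantities must be positive")
  y <- log(unclass(q), base = log_base)
  genes <- rownames(q)
  k <- nrow(y)

  groups <- if (is.null(design)) {
    list(all = colnames(q))
  } else {
    if (is.null(factor)) stop_config("a grouping factor is required with a design")
    group_samples(q, design, factor)
  }
  sizes <- lengths(groups)
  if (!is.null(design)) {
    if (length(groups) < 2L)
      stop_design_mismatch("grouped NormFinder needs at least 2 groups")
    if (any(sizes < 2L))
      stop_design_mismatch(sprintf("group(s) with fewer than 2 samples: %s",
                                   paste(names(groups)[sizes < 2L], collapse = ", ")))
  }

  z <- sweep(y, 2L, colMeans(y)) # remove per-sample level
  zbar <- vapply(groups, function(s) rowMeans(z[, s, drop = FALSE]),
                 numeric(k))                        # gene x group
  s2 <- vapply(groups, function(s) apply(z[, s, drop = FALSE], 1L, stats::var),
               numeric(k))
  zbar <- matrix(zbar, nrow = k, dimnames = list(genes, names(groups)))
  s2 <- matrix(s2, nrow = k, dimnames = list(genes, names(groups)))

  # bias correction for the per-sample centring:
  # E[s2_ig] = sigma2_ig (1 - 2/k) + mean_l(sigma2_lg)/k
  correct <- function(s2g) {
    if (k > 2L) (s2g - sum(s2g) / (k * (k - 1L))) * k / (k - 2L) else s2g
  }
  sigma2 <- apply(s2, 2L, correct)
  sigma2 <- matrix(sigma2, nrow = k, dimnames = dimnames(s2))
  truncated <- sigma2 < 0
  sigma2[truncated] <- 0

  if (is.null(design)) {
    vals <- stats::setNames(sigma2[, 1L], genes)
    out <- stability_series("NormFinder", vals)
    attr(out, "truncated") <- which(truncated, arr.ind = TRUE)
    return(out)
  }

  G <- length(groups)
  d <- zbar - rowMeans(zbar) # intergroup deviation; colSums(d) == 0
  var_d <- sweep(sigma2, 2L, sizes, "/")
  gamma2 <- max(0, sum(d^2) / ((G - 1L) * (k - 1L)) - mean(var_d))
  shrink <- ifelse(gamma2 + var_d > 0, gamma2 / (gamma2 + var_d), 0)
  d_tilde <- d * shrink
  se <- sqrt(var_d * shrink)
  rho <- abs(d_tilde) + se
  vals <- stats::setNames(rowMeans(rho), genes)
  out <- stability_series("NormFinder", vals)
  attr(out, "truncated") <- which(truncated, arr.ind = TRUE)
  attr(out, "gamma2") <- gamma2
  out
}

#' BestKeeper descriptive Ct statistics
#'
#' Works on raw Ct values. Per gene: geometric and arithmetic mean, range, the
#' std-value (mean absolute deviation of Ct about a central Ct; arithmetic-mean
#' centring by default, geometric-mean centring selectable) and the coefficient
#' of variation of Ct. The per-sample BestKeeper index is the geometric mean
#' over genes, and each gene is correlated (Pearson) against the index.
#'
#' @param ct A [ct_matrix()] with positive Ct; missing cells are dropped
#'   sample-listwise when `missing = "drop-sample"`, otherwise they error.
#' @param center `"arithmetic"` (default) or `"geometric"` centring of the
#'   std-value.
#' @param missing `"error"` or `"drop-sample"`.
#' @return List of class `bestkeeper_result`: `gene_stats` data frame
#'   (`gene`, `geo_mean`, `arith_mean`, `min`, `max`, `std_value`, `cv_pct`,
#'   `r`, `p_value`), `index` (per-sample geometric mean), `series`
#'   (std-values as a [stability_series()]).
#' @export
bestkeeper <- function(ct, center = c("arithmetic", "geometric"),
                       missing = c("error", "drop-sample")) {
  center <- match.arg(center)
  missing <- match.arg(missing)
  ct <- .apply_missing_policy(ct, missing)
  if (ncol(ct) < 2L) stop_shape("BestKeeper needs at least 2 samples")
  x <- unclass(ct)
  geo <- exp(rowMeans(log(x)))
  ari <- rowMeans(x)
  centre <- if (center == "arithmetic") ari else geo
  std_value <- rowMeans(abs(x - centre))
  index <- exp(colMeans(log(x)))
  cors <- lapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(index) == 0)
      return(list(estimate = NA_real_, p.value = NA_real_))
    stats::cor.test(x[i, ], index, alternative = "two.sided")
  })
  stats_df <- data.frame(
    gene = rownames(x), geo_mean = geo, arith_mean = ari,
    min = apply(x, 1L, min), max = apply(x, 1L, max),
    std_value = std_value, cv_pct = 100 * std_value / ari,
    r = vapply(cors, function(ct.) unname(ct.$estimate), numeric(1L)),
    p_value = vapply(cors, function(ct.) ct.$p.value, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(gene_stats = stats_df, index = index, center = center,
                 series = stability_series(
                   "BestKeeper", stats::setNames(std_value, rownames(x)))),
            class = "bestkeeper_result")
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) the per-sample difference
#' `Ct_j - Ct_k` is formed; the stability of gene j is the mean over all
#' other genes k of the standard deviation across samples of that difference.
#' Lower values indicate more stable expression. Adding a per-sample constant
#' to all genes (a global loading shift) cancels out.
#'
#' @param ct A [ct_matrix()] (>= 2 genes, >= 2 samples).
#' @param missing `"error"` or `"drop-sample"`.
#' @return A [stability_series()] labelled `"deltaCt"`.
#' @export
delta_ct_stability <- function(ct, missing = c("error", "drop-sample")) {
  missing <- match.arg(missing)
  ct <- .apply_missing_policy(ct, missing)
  if (nrow(ct) < 2L) stop_shape("the delta-Ct method needs at least 2 genes")
  if (ncol(ct) < 2L) stop_shape("the delta-Ct method needs at least 2 samples")
  x <- unclass(ct)
  g <- nrow(x)
  vals <- vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j), function(k)
      stats::sd(x[j, ] - x[k, ]), numeric(1L)))
  }, numeric(1L))
  stability_series("deltaCt", stats::setNames(vals, rownames(x)))
}

.apply_missing_policy <- function(ct, missing) {
  if (!any(is.na(ct))) return(ct)
  if (missing == "error")
    stop_missing_data("Ct matrix has missing cells (use missing = 'drop-sample')")
  keep <- colSums(is.na(ct)) == 0L
  if (!any(keep)) stop_missing_data("every sample has at least one missing Ct")
  ct[, keep, drop = FALSE]
}

#' Run all four stability algorithms
#'
#' Applies geNorm, NormFinder, BestKeeper and the delta-Ct method to the same
#' Ct matrix (optionally restricted to one design factor's samples) and
#' returns four identically oriented [stability_series()] over the identical
#' gene set, ready for [comprfinder()] / [reffinder_score()].
#'
#' @param ct A [ct_matrix()].
#' @param design Optional [study_design()] for grouped NormFinder.
#' @param factor Grouping factor name used by NormFinder (ignored without a
#'   design).
#' @param efficiencies Amplification base(s) for [ct_to_quantity()].
#' @param bestkeeper_center Centring for the BestKeeper std-value.
#' @param samples Optional sample subset to analyse.
#' @return List of class `stability_bundle`: `series` (named list of 4
#'   [stability_series()]), `genorm`, `bestkeeper` (full results).
#' @export
stability_all <- function(ct, design = NULL, factor = NULL, efficiencies = 2,
                          bestkeeper_center = c("arithmetic", "geometric"),
                          samples = NULL) {
  bestkeeper_center <- match.arg(bestkeeper_center)
  if (!is.null(samples)) {
    unknown <- setdiff(samples, colnames(ct))
    if (length(unknown))
      stop_design_mismatch(sprintf("unknown sample(s): %s",
                                   paste(unknown, collapse = ", ")))
    ct <- ct[, samples, drop = FALSE]
    ct <- ct_matrix(ct, replicate_depth = 1L)
  }
  q <- ct_to_quantity(ct, efficiencies)
  gn <- genorm(q)
  nf <- normfinder(q, design = design, factor = factor)
  bk <- bestkeeper(ct, center = bestkeeper_center)
  dc <- delta_ct_stability(ct)
  structure(list(series = list(geNorm = gn$series, NormFinder = nf,
                               BestKeeper = bk$series, deltaCt = dc),
                 genorm = gn, bestkeeper = bk),
            class = "stability_bundle")
}
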