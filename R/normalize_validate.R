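#' Multi-gene normalization factor
#'
#' Per sample, the geometric mean of the member housekeeping genes' Ct values
#' (default, `NF_s = (prod Ct_g,s)^(1/|hkgs|)`, in Ct units) or of their
#' unanchored relative quantities `2^-Ct` (`"quantity-geomean"`, the geNorm
#' convention). A single-gene scheme's NF equals that gene's Ct, and the NF
#' always lies within the member genes' per-sample Ct range.
#'
#' @param ct A [ct_matrix()] containing the housekeeping genes.
#' @param hkgs Character vector of member gene ids (length >= 1).
#' @param mode `"ct-geomean"` (default) or `"quantity-geomean"`.
#' @return Named per-sample numeric vector.
#' @export
normalization_factor <- function(ct, hkgs, mode = c("ct-geomean", "quantity-geomean")) {
  mode <- match.arg(mode)
  unknown <- setdiff(hkgs, rownames(ct))
  if (length(unknown))
    stop_gene_set(sprintf("unknown housekeeping gene(s): %s",
                          paste(unknown, collapse = ", ")))
  x <- unclass(ct)[hkgs, , drop = FALSE]
  if (any(is.na(x)))
    stop_missing_data("missing Ct among the housekeeping genes")
  if (mode == "ct-geomean") exp(colMeans(log(x)))
  else exp(colMeans(log(2^-x)))
}

#' A named normalization scheme
#'
#' @param label Scheme label (defaults to the member genes joined by `+`).
#' @param hkgs Member housekeeping gene ids.
#' @return List of class `normalization_scheme`.
#' @export
normalization_scheme <- function(hkgs, label = paste(hkgs, collapse = "+")) {
  if (length(hkgs) < 1L) stop_gene_set("a scheme needs at least one gene")
  structure(list(label = label, hkgs = hkgs), class = "normalization_scheme")
}

#' Relative expression of target genes, 2^-deltaCt
#'
#' `deltaCt = Ct_target - NF` per sample, relative expression `2^-deltaCt`
#' (for the quantity-geomean NF mode the equivalent ratio
#' `2^-Ct_target / NF` is used). Values are strictly positive; adding one
#' cycle to a target everywhere halves its values.
#'
#' @param target_ct A [ct_matrix()] of target-gene Ct values.
#' @param hkg_ct A [ct_matrix()] of housekeeping-gene Ct values over the same
#'   samples.
#' @param scheme A [normalization_scheme()] (or character vector of gene ids).
#' @param mode NF mode, see [normalization_factor()].
#' @return Target x sample matrix of class `relative_expression` with
#'   attributes `scheme` (label) and `nf`.
#' @export
relative_expression <- function(target_ct, hkg_ct, scheme,
                                mode = c("ct-geomean", "quantity-geomean")) {
  mode <- match.arg(mode)
  if (is.character(scheme)) scheme <- normalization_scheme(scheme)
  if (!setequal(colnames(target_ct), colnames(hkg_ct)))
    stop_design_mismatch("target and housekeeping Ct tables cover different samples")
  hkg_ct <- hkg_ct[, colnames(target_ct), drop = FALSE]
  nf <- normalization_factor(hkg_ct, scheme$hkgs, mode)
  tx <- unclass(target_ct)
  expr <- if (mode == "ct-geomean") 2^-sweep(tx, 2L, nf)
          else sweep(2^-tx, 2L, nf, "/")
  structure(expr, scheme = scheme$label, nf = nf,
            class = c("relative_expression", class(matrix())))
}

#' Paired comparison of relative expression between stages
#'
#' Classical two-sided paired t-test per target gene and level pair of the
#' chosen factor; samples are paired across levels by a subject key (the same
#' animal measured at each time-point). Significance stars follow the usual
#' convention: `*` for p < 0.05, `**` for p < 0.01.
#'
#' @param expr A [relative_expression()] matrix.
#' @param design A [study_design()] whose rows for `factor` cover all samples
#'   of `expr` and that carries a `subject` column (or pass `pairing`, a named
#'   vector sample -> subject).
#' @param factor Factor whose levels are compared.
#' @param pairing Optional named vector sample -> subject overriding the
#'   design's `subject` column.
#' @param levels Optional character vector restricting/ordering the levels.
#' @return Data frame: `target`, `level_a`, `level_b`, `n_pairs`,
#'   `mean_diff`, `t`, `p_value`, `stars`.
#' @export
stage_comparison <- function(expr, design, factor, pairing = NULL,
                             levels = NULL) {
  groups <- group_samples(expr, design, factor)
  if (!is.null(levels)) {
    missing_lv <- setdiff(levels, names(groups))
    if (length(missing_lv))
      stop_design_mismatch(sprintf("unknown level(s): %s",
                                   paste(missing_lv, collapse = ", ")))
    groups <- groups[levels]
  }
  if (is.null(pairing)) {
    rows <- design[design$factor == factor, , drop = FALSE]
    if (is.null(rows$subject))
      stop_design_mismatch("no pairing: design lacks a subject column")
    pairing <- stats::setNames(rows$subject, rows$sample)
  }
  unpaired <- setdiff(colnames(expr), names(pairing))
  if (length(unpaired))
    stop_design_mismatch(sprintf("sample(s) without a pairing key: %s",
                                 paste(unpaired, collapse = ", ")))
  combos <- utils::combn(names(groups), 2L, simplify = FALSE)
  res <- list()
  for (target in rownames(expr)) {
    for (cmb in combos) {
      a <- groups[[cmb[1L]]]
      b <- groups[[cmb[2L]]]
      subj <- intersect(pairing[a], pairing[b])
      loose <- c(setdiff(pairing[a], subj), setdiff(pairing[b], subj))
      if (length(loose))
        stop_design_mismatch(sprintf(
          "unpaired subject(s) between levels %s and %s: %s",
          cmb[1L], cmb[2L], paste(loose, collapse = ", ")))
      if (length(subj) < 2L)
        stop_design_mismatch(sprintf(
          "fewer than 2 paired subjects between levels %s and %s",
          cmb[1L], cmb[2L]))
      a <- a[match(subj, pairing[a])]
      b <- b[match(subj, pairing[b])]
      d <- expr[target, a] - expr[target, b]
      if (stats::sd(d) == 0) {
        tt <- if (mean(d) == 0) list(statistic = 0, p.value = 1)
              else list(statistic = sign(mean(d)) * Inf, p.value = 0)
      } else {
        ht <- stats::t.test(expr[target, a], expr[target, b], paired = TRUE)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      res[[length(res) + 1L]] <- data.frame(
        target = target, level_a = cmb[1L], level_b = cmb[2L],
        n_pairs = length(subj), mean_diff = mean(d),
        t = tt$statistic, p_value = tt$p.value,
        stars = if (tt$p.value < 0.01) "**"
                else if (tt$p.value < 0.05) "*" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Correlation between normalization schemes
#'
#' Each relative-expression table is flattened to one vector (all targets and
#' samples pooled, in identical cell order) and schemes are compared pairwise
#' by Pearson correlation with two-sided p-values. Two schemes whose NFs
#' differ by a constant number of cycles give proportional expression values
#' and hence r = 1 exactly.
#'
#' @param tables Named list of [relative_expression()] matrices over identical
#'   target x sample cells (names default to the scheme labels).
#' @param per_target Also return per-target correlation matrices.
#' @return List with symmetric unit-diagonal matrices `r` and `p_value` (and
#'   `per_target` when requested).
#' @export
scheme_correlation <- function(tables, per_target = FALSE) {
  if (length(tables) < 2L) stop_shape("need at least 2 schemes to correlate")
  ref <- tables[[1L]]
  for (tb in tables[-1L])
    if (!identical(dim(tb), dim(ref)) ||
        !identical(dimnames(tb), dimnames(ref)))
      stop_shape("all expression tables must cover identical target x sample cells")
  labels <- names(tables)
  if (is.null(labels))
    labels <- vapply(tables, function(tb) {
      lb <- attr(tb, "scheme")
      if (is.null(lb)) "" else lb
    }, character(1L))
  labels <- make.unique(labels)
  corr_pair <- function(x, y) {
    ht <- stats::cor.test(as.vector(x), as.vector(y), alternative = "two.sided")
    c(unname(ht$estimate), ht$p.value)
  }
  k <- length(tables)
  r <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rp <- corr_pair(tables[[i]], tables[[j]])
    r[i, j] <- r[j, i] <- rp[1L]
    p[i, j] <- p[j, i] <- rp[2L]
  }
  out <- list(r = r, p_value = p)
  if (per_target) {
    out$per_target <- lapply(stats::setNames(rownames(ref), rownames(ref)),
      function(tg) {
        rt <- diag(1, k); dimnames(rt) <- list(labels, labels)
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
          rt[i, j] <- rt[j, i] <- stats::cor(tables[[i]][tg, ],
                                             tables[[j]][tg, ])
        rt
      })
  }
  out
}

#' Amplification efficiency from a dilution series
#'
#' Least-squares fit of Ct against log10 template input over a serial
#' dilution; the slope gives the per-cycle amplification rate,
#' `efficiency % = 100 * (10^(-1/slope) - 1)` (slope -3.3219 corresponds to
#' perfect doubling, 100%). R-squared of the fit is reported.
#'
#' @param log10_dilution Numeric vector, log10 of relative template input.
#' @param ct Matching Ct values (>= 3 points).
#' @return List: `slope`, `intercept`, `efficiency_pct`, `base`
#'   (`10^(-1/slope)`), `r_squared`.
#' @export
efficiency_from_dilutions <- function(log10_dilution, ct) {
  if (length(log10_dilution) != length(ct))
    stop_shape("dilution and Ct vectors differ in length")
  if (length(ct) < 3L) stop_shape("need at least 3 dilution points")
  fit <- stats::lm(ct ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop_domain("non-negative standard-curve slope: no amplification")
  base <- 10^(-1 / slope)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       efficiency_pct = 100 * (base - 1), base = base,
       r_squared = 1 - ss_res / ss_tot)
}
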