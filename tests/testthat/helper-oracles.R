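# Independent naive-loop oracles. These re-derive every statistic with
# explicit loops and textbook formulas, sharing no code with the package.

osd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_genorm_m <- function(q) {
  g <- nrow(q)
  out <- numeric(g)
  for (j in seq_len(g)) {
    vs <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      vs <- c(vs, osd(log2(q[j, ] / q[k, ])))
    }
    out[j] <- mean(vs)
  }
  names(out) <- rownames(q)
  out
}

oracle_delta_ct <- function(ct) {
  g <- nrow(ct)
  out <- numeric(g)
  for (j in seq_len(g)) {
    vs <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      vs <- c(vs, osd(ct[j, ] - ct[k, ]))
    }
    out[j] <- mean(vs)
  }
  names(out) <- rownames(ct)
  out
}

oracle_bestkeeper <- function(ct, center = "arithmetic") {
  g <- nrow(ct); n <- ncol(ct)
  std <- ar <- ge <- numeric(g)
  for (j in seq_len(g)) {
    ar[j] <- sum(ct[j, ]) / n
    ge[j] <- prod(ct[j, ])^(1 / n)
    cen <- if (center == "arithmetic") ar[j] else ge[j]
    std[j] <- sum(abs(ct[j, ] - cen)) / n
  }
  idx <- numeric(n)
  for (s in seq_len(n)) idx[s] <- prod(ct[, s])^(1 / g)
  r <- p <- numeric(g)
  for (j in seq_len(g)) {
    x <- ct[j, ]; y <- idx
    r[j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r[j] * sqrt((n - 2) / (1 - r[j]^2))
    p[j] <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(arith = ar, geo = ge, std = std, index = idx, r = r, p = p)
}

# literal transcription of the model-based variance-decomposition estimators
oracle_normfinder <- function(q, groups = NULL, log_base = 2) {
  y <- log(q, base = log_base)
  k <- nrow(y)
  if (is.null(groups)) groups <- list(all = colnames(y))
  G <- length(groups)
  z <- y
  for (s in seq_len(ncol(y))) z[, s] <- y[, s] - mean(y[, s])
  zbar <- s2 <- matrix(0, k, G)
  for (g in seq_len(G)) {
    cols <- groups[[g]]
    for (i in seq_len(k)) {
      zi <- z[i, cols]
      zbar[i, g] <- mean(zi)
      s2[i, g] <- sum((zi - mean(zi))^2) / (length(zi) - 1)
    }
  }
  sigma2 <- matrix(0, k, G)
  for (g in seq_len(G)) for (i in seq_len(k)) {
    v <- if (k > 2) (s2[i, g] - sum(s2[, g]) / (k * (k - 1))) * k / (k - 2)
         else s2[i, g]
    sigma2[i, g] <- max(0, v)
  }
  if (G == 1) return(stats::setNames(sigma2[, 1], rownames(y)))
  n_g <- sapply(groups, length)
  d <- zbar - rowMeans(zbar)
  vard <- sigma2
  for (g in seq_len(G)) vard[, g] <- sigma2[, g] / n_g[g]
  gamma2 <- max(0, sum(d^2) / ((G - 1) * (k - 1)) - mean(vard))
  rho <- matrix(0, k, G)
  for (g in seq_len(G)) for (i in seq_len(k)) {
    shr <- if (gamma2 + vard[i, g] > 0) gamma2 / (gamma2 + vard[i, g]) else 0
    rho[i, g] <- abs(d[i, g] * shr) + sqrt(vard[i, g] * shr)
  }
  stats::setNames(rowMeans(rho), rownames(y))
}

oracle_comprfinder <- function(m) {
  std <- m
  for (j in seq_len(ncol(m))) {
    lo <- min(m[, j]); hi <- max(m[, j])
    std[, j] <- if (hi > lo) (m[, j] - lo) / (hi - lo) else 0
  }
  fs <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) fs[i] <- sum(std[i, ]) / ncol(m)
  names(fs) <- rownames(m)
  fs
}

oracle_reffinder <- function(m) {
  rk <- m
  for (j in seq_len(ncol(m))) rk[, j] <- rank(m[, j])
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) out[i] <- prod(rk[i, ])^(1 / ncol(m))
  names(out) <- rownames(m)
  out
}

oracle_nf <- function(ct, hkgs) {
  out <- numeric(ncol(ct))
  for (s in seq_len(ncol(ct))) out[s] <- prod(ct[hkgs, s])^(1 / length(hkgs))
  stats::setNames(out, colnames(ct))
}

oracle_rel_expr <- function(target_ct, nf) {
  out <- target_ct
  for (i in seq_len(nrow(target_ct))) for (s in seq_len(ncol(target_ct)))
    out[i, s] <- 2^-(target_ct[i, s] - nf[s])
  out
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (osd(d) / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), n - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}
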