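test_that("normalization factors are geometric means of member Ct values", {
  ct <- ct_matrix(matrix(c(24.2, 23.1,
                           20.0, 21.0,
                           22.0, 25.0), nrow = 3, byrow = TRUE,
                         dimnames = list(c("h1", "h2", "h3"), c("a", "b"))))
  expect_equal(unname(normalization_factor(ct, "h1")),
               c(24.2, 23.1)) # single-gene scheme: the gene's own Ct
  expect_equal(unname(normalization_factor(ct, c("h2", "h3"))[1]),
               sqrt(440), tolerance = 1e-12)
  expect_equal(unname(normalization_factor(ct, c("h2", "h3"))[1]),
               20.9762, tolerance = 1e-4)

  same <- ct_matrix(matrix(26, 3, 2, dimnames = list(c("x", "y", "z"),
                                                     c("a", "b"))))
  expect_equal(unname(normalization_factor(same, c("x", "y", "z"))),
               c(26, 26))

  expect_error(normalization_factor(ct, c("h1", "nope")),
               class = "refstab_gene_set_error")

  # NF bounded by the member genes' per-sample range, and oracle agreement
  for (seed in 1:4) {
    r <- rand_ct(4, 6, seed = seed)
    nf <- normalization_factor(r, rownames(r)[1:3])
    expect_true(all(nf >= apply(unclass(r)[1:3, ], 2, min) - 1e-12))
    expect_true(all(nf <= apply(unclass(r)[1:3, ], 2, max) + 1e-12))
    expect_equal(nf, oracle_nf(unclass(r), rownames(r)[1:3]),
                 tolerance = 1e-9)
  }
})

test_that("relative expression follows 2^-deltaCt exactly", {
  hkg <- ct_matrix(matrix(c(20, 21, 22, 23), nrow = 2, byrow = TRUE,
                          dimnames = list(c("h1", "h2"), c("a", "b"))))
  tgt <- ct_matrix(matrix(c(25, 21.9773), nrow = 1,
                          dimnames = list("t1", c("a", "b"))))
  expr <- relative_expression(tgt, hkg, c("h1", "h2"))
  nf <- normalization_factor(hkg, c("h1", "h2"))
  expect_equal(unname(expr["t1", "a"]), 2^-(25 - nf[["a"]]))
  expect_equal(unname(expr["t1", "a"]), 0.0615, tolerance = 2e-3)
  # Ct equal to the NF gives exactly 1
  expect_equal(unname(expr["t1", "b"]), 2^-(21.9773 - nf[["b"]]))
  at_nf <- ct_matrix(matrix(nf, nrow = 1, dimnames = list("t", names(nf))))
  expect_equal(unname(relative_expression(at_nf, hkg, c("h1", "h2"))["t", ]),
               c(1, 1), tolerance = 1e-9)

  # one extra cycle everywhere halves every value
  plus1 <- ct_matrix(unclass(tgt) + 1)
  expect_equal(unclass(relative_expression(plus1, hkg, c("h1", "h2"))),
               unclass(expr) / 2, tolerance = 1e-12, ignore_attr = TRUE)

  # shifting target and every member gene by the same constant is exactly
  # neutral in quantity-geomean mode (the Ct-geomean NF only shifts
  # approximately by the constant, so there it is neutral to first order)
  hkg_s <- ct_matrix(unclass(hkg) + 1.7)
  tgt_s <- ct_matrix(unclass(tgt) + 1.7)
  q0 <- relative_expression(tgt, hkg, c("h1", "h2"), mode = "quantity-geomean")
  q1 <- relative_expression(tgt_s, hkg_s, c("h1", "h2"),
                            mode = "quantity-geomean")
  expect_equal(unclass(q1), unclass(q0), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single-gene schemes are exactly neutral in Ct mode too
  expect_equal(unclass(relative_expression(tgt_s, hkg_s, "h1")),
               unclass(relative_expression(tgt, hkg, "h1")),
               tolerance = 1e-12, ignore_attr = TRUE)

  other <- ct_matrix(matrix(c(25, 26), nrow = 1,
                            dimnames = list("t1", c("a", "zzz"))))
  expect_error(relative_expression(other, hkg, c("h1", "h2")),
               class = "refstab_design_mismatch_error")
  expect_equal(unclass(expr),
               oracle_rel_expr(unclass(tgt), oracle_nf(unclass(hkg),
                                                       c("h1", "h2"))),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("paired stage comparisons reproduce the textbook t-test", {
  # 3 subjects measured at two stages
  expr <- matrix(c(1.0, 1.1, 0.9, 2.0, 2.2, 1.8), nrow = 1,
                 dimnames = list("tgt", sprintf("s%d", 1:6)))
  class(expr) <- c("relative_expression", class(matrix()))
  design <- study_design(data.frame(
    sample = sprintf("s%d", 1:6), factor = "stage",
    level = rep(c("T1", "T2"), each = 3),
    subject = rep(c("an1", "an2", "an3"), 2)))
  res <- stage_comparison(expr, design, "stage")
  want <- oracle_paired_t(c(1.0, 1.1, 0.9), c(2.0, 2.2, 1.8))
  expect_equal(res$t, want$t, tolerance = 1e-9)
  expect_equal(res$p_value, want$p, tolerance = 1e-9)
  expect_equal(res$n_pairs, 3L)
  expect_identical(res$stars, "**") # p ~ 0.0033

  # identical paired values: t = 0, p = 1, no star
  same <- matrix(rep(c(1.3, 0.8, 1.1), 2), nrow = 1,
                 dimnames = list("tgt", sprintf("s%d", 1:6)))
  res0 <- stage_comparison(same, design, "stage")
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  expect_identical(res0$stars, "")

  unpaired <- design
  unpaired$subject[6] <- "an9"
  expect_error(stage_comparison(expr, unpaired, "stage"),
               class = "refstab_design_mismatch_error")
})

test_that("a planted 2-fold stage effect is detected in >= 95% of replicates", {
  # 6 paired subjects, one-cycle (2-fold) shift, 0.25-cycle biological noise
  set.seed(2024)
  hits <- 0L
  n_rep <- 120L
  for (r in seq_len(n_rep)) {
    base <- stats::rnorm(6, 28, 0.5)
    ct_t1 <- base + stats::rnorm(6, 0, 0.25)
    ct_t2 <- base - 1 + stats::rnorm(6, 0, 0.25)
    hkg <- ct_matrix(matrix(rep(c(24, 25), each = 12), nrow = 2, byrow = TRUE,
                            dimnames = list(c("h1", "h2"),
                                            sprintf("s%d", 1:12))))
    tgt <- ct_matrix(matrix(c(ct_t1, ct_t2), nrow = 1,
                            dimnames = list("tgt", sprintf("s%d", 1:12))))
    design <- study_design(data.frame(
      sample = sprintf("s%d", 1:12), factor = "stage",
      level = rep(c("T1", "T2"), each = 6), subject = rep(1:6, 2)))
    expr <- relative_expression(tgt, hkg, c("h1", "h2"))
    res <- stage_comparison(expr, design, "stage")
    if (res$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("scheme correlations are symmetric, unit-diagonal and exact on toys", {
  set.seed(6)
  tgt <- ct_matrix(matrix(stats::runif(3 * 6, 24, 30), nrow = 3,
                          dimnames = list(c("t1", "t2", "t3"),
                                          sprintf("s%d", 1:6))))
  hkg <- rand_ct(3, 6, seed = 8)
  e1 <- relative_expression(tgt, hkg, rownames(hkg)[1])
  e2 <- relative_expression(tgt, hkg, rownames(hkg)[1:2])
  # a scheme whose NF differs by a constant cycle count correlates at exactly 1
  shifted <- ct_matrix(unclass(hkg) + 0.8)
  e3 <- relative_expression(tgt, shifted, rownames(hkg)[1])
  cors <- scheme_correlation(list(A = e1, B = e2, C = e3))
  expect_equal(cors$r, t(cors$r))
  expect_equal(unname(diag(cors$r)), c(1, 1, 1))
  expect_true(all(cors$r >= -1 & cors$r <= 1 + 1e-12))
  expect_equal(cors$r["A", "C"], 1, tolerance = 1e-12)
  want <- oracle_pearson(as.vector(unclass(e1)), as.vector(unclass(e2)))
  expect_equal(cors$r["A", "B"], want$r, tolerance = 1e-9)
  expect_equal(cors$p_value["A", "B"], want$p, tolerance = 1e-9)

  bad <- e1[, 1:5]
  expect_error(scheme_correlation(list(e1, bad)), class = "refstab_shape_error")
})

test_that("hand vectors reproduce the direct Pearson formula", {
  x <- matrix(c(1, 2, 3, 4), 1, dimnames = list("t", sprintf("s%d", 1:4)))
  y <- matrix(c(2, 3, 5, 9), 1, dimnames = list("t", sprintf("s%d", 1:4)))
  cors <- scheme_correlation(list(X = x, Y = y))
  want <- oracle_pearson(c(1, 2, 3, 4), c(2, 3, 5, 9))
  expect_equal(cors$r["X", "Y"], want$r, tolerance = 1e-12)
  expect_equal(want$r, 11.5 / sqrt(5 * 28.75), tolerance = 1e-12)
  expect_equal(want$r, 0.9592, tolerance = 1e-4)
})

test_that("dilution-series slopes convert to amplification efficiencies", {
  dil <- c(-3, -4, -5, -6)
  perfect <- efficiency_from_dilutions(dil, 35 + 3.3219 * dil * -1)
  expect_equal(perfect$slope, -3.3219, tolerance = 1e-9)
  expect_equal(perfect$efficiency_pct, 100, tolerance = 0.01)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-9)

  e94 <- efficiency_from_dilutions(dil, 35 - 3.45 * dil)
  expect_equal(e94$slope, -3.45, tolerance = 1e-9)
  expect_equal(e94$efficiency_pct, 94.9, tolerance = 0.05)

  expect_error(efficiency_from_dilutions(dil, c(23, 22, 21, 20)),
               class = "refstab_domain_error")
  expect_error(efficiency_from_dilutions(c(-3, -4), c(20, 23)),
               class = "refstab_shape_error")
})
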