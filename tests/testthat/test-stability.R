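test_that("the quantity transform anchors each gene at its minimum Ct", {
  ct <- ct_matrix(matrix(c(20, 23, 21.5,
                           30, 28, 29), nrow = 2, byrow = TRUE,
                         dimnames = list(c("g1", "g2"), c("a", "b", "c"))))
  q <- ct_to_quantity(ct)
  expect_equal(unname(q["g1", "a"]), 1)
  expect_equal(unname(q["g2", "b"]), 1)
  expect_equal(unname(q["g1", "b"]), 0.125) # 2^-3
  expect_true(all(q > 0 & q <= 1))

  # log-quantity differences are negated Ct differences
  set.seed(3)
  for (i in 1:5) {
    ctr <- rand_ct(5, 7, seed = i)
    E <- 1.9
    qr <- ct_to_quantity(ctr, efficiencies = E)
    expect_equal(log(qr[, 2] / qr[, 5], base = E),
                 -(ctr[, 2] - ctr[, 5]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  expect_error(ct_to_quantity(ct, efficiencies = 2.5),
               class = "refstab_domain_error")
  holed <- ct_matrix(matrix(c(20, NA, 25, 26), 2, 2,
                            dimnames = list(c("g1", "g2"), c("a", "b"))),
                     allow_missing = TRUE)
  expect_error(ct_to_quantity(holed), class = "refstab_missing_data_error")
})

test_that("geNorm reproduces the hand-computed toy panel", {
  gn <- genorm(toy_quantities())
  expect_equal(gn$m, c(g1 = 0.5, g2 = 0.5, g3 = 1.0))
  expect_identical(gn$exclusion_order, "g3")
  expect_identical(gn$ranking[["g3"]], 3L)
  expect_setequal(names(gn$ranking[gn$ranking <= 2]), c("g1", "g2"))
})

test_that("a gene proportional to the others keeps pairwise variation at zero", {
  base <- c(1, 3, 2, 5)
  q <- rbind(g1 = base, g2 = 2 * base, g3 = 0.5 * base)
  colnames(q) <- sprintf("s%d", 1:4)
  gn <- genorm(q)
  expect_equal(unname(gn$v), 0, tolerance = 1e-12)
  expect_equal(unname(gn$m), c(0, 0, 0), tolerance = 1e-12)
})

test_that("geNorm is invariant to per-gene Ct offsets", {
  for (seed in 1:4) {
    ct <- rand_ct(5, 8, seed = seed)
    shifted <- ct_matrix(unclass(ct) + c(3, -2, 0, 1.5, -4))
    a <- genorm(ct_to_quantity(ct))
    b <- genorm(ct_to_quantity(shifted))
    expect_equal(a$m, b$m, tolerance = 1e-10)
    expect_identical(a$ranking, b$ranking)
    expect_equal(a$v, b$v, tolerance = 1e-10)
  }
})

test_that("NormFinder collapses to zero on perfectly uniform panels", {
  q <- matrix(rep(c(1, 0.5, 0.25, 0.125), each = 3), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  expect_equal(unname(normfinder(q)$values), c(0, 0, 0), tolerance = 1e-12)
  design <- study_design(data.frame(sample = colnames(q), factor = "f",
                                    level = c("a", "a", "b", "b")))
  expect_equal(unname(normfinder(q, design, "f")$values), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("NormFinder matches a literal transcription of the estimators", {
  set.seed(14)
  for (seed in 1:5) {
    q <- rand_quantity(genes = 3 + seed %% 3, samples = 6, seed = seed)
    design <- study_design(data.frame(
      sample = colnames(q), factor = "grp",
      level = rep(c("g1", "g2"), each = 3)))
    got <- normfinder(q, design, "grp")
    want <- oracle_normfinder(unclass(q),
                              groups = split(colnames(q),
                                             rep(c("g1", "g2"), each = 3)))
    expect_equal(got$values, want, tolerance = 1e-9)
    got_u <- normfinder(q)
    expect_equal(got_u$values, oracle_normfinder(unclass(q)),
                 tolerance = 1e-9)
  }
})

test_that("NormFinder rejects degenerate groupings", {
  q <- rand_quantity(4, 5, seed = 2)
  design <- study_design(data.frame(
    sample = colnames(q), factor = "grp",
    level = c("a", "a", "a", "a", "b")))
  expect_error(normfinder(q, design, "grp"),
               class = "refstab_design_mismatch_error")
  one_group <- study_design(data.frame(sample = colnames(q), factor = "grp",
                                       level = "a"))
  expect_error(normfinder(q, one_group, "grp"),
               class = "refstab_design_mismatch_error")
})

test_that("BestKeeper descriptive statistics match both centring options", {
  ct <- ct_matrix(matrix(c(20, 21, 22), 1, 3,
                         dimnames = list("g1", c("a", "b", "c"))))
  # single-gene BestKeeper is legal for the descriptive part
  arith <- bestkeeper(ct)$gene_stats
  expect_equal(arith$arith_mean, 21)
  expect_equal(arith$std_value, 2 / 3)
  geo <- bestkeeper(ct, center = "geometric")$gene_stats
  expect_equal(geo$geo_mean, 9240^(1 / 3), tolerance = 1e-9)
  expect_equal(geo$geo_mean, 20.984, tolerance = 1e-3)
  expect_equal(geo$std_value, 0.672, tolerance = 1e-3)

  flat <- bestkeeper(ct_matrix(matrix(25, 2, 3,
    dimnames = list(c("g1", "g2"), c("a", "b", "c")))))$gene_stats
  expect_equal(flat$std_value, c(0, 0))
  expect_equal(flat$cv_pct, c(0, 0))
})

test_that("BestKeeper invariants: ordering of means and MAD below SD", {
  for (seed in 1:6) {
    ct <- rand_ct(5, 8, seed = seed)
    bk <- bestkeeper(ct)$gene_stats
    expect_true(all(bk$min <= bk$geo_mean + 1e-12))
    expect_true(all(bk$geo_mean <= bk$arith_mean + 1e-12))
    expect_true(all(bk$arith_mean <= bk$max + 1e-12))
    sds <- apply(unclass(ct), 1, stats::sd)
    expect_true(all(bk$std_value <= sds + 1e-12))
  }
})

test_that("the delta-Ct method reproduces the hand-computed toy panel", {
  s <- delta_ct_stability(toy_delta_ct())
  expect_equal(s$values,
               c(g1 = (1 + 2 / sqrt(3)) / 2,
                 g2 = (1 + 1 / sqrt(3)) / 2,
                 g3 = (2 / sqrt(3) + 1 / sqrt(3)) / 2),
               tolerance = 1e-9)
  expect_equal(unname(s$values), c(1.0774, 0.7887, 0.8660), tolerance = 1e-4)

  # two genes with constant offset: both stabilities zero
  ct2 <- ct_matrix(matrix(c(20, 22, 24, 25, 27, 29), nrow = 2, byrow = TRUE,
                          dimnames = list(c("g1", "g2"), c("a", "b", "c"))))
  expect_equal(unname(delta_ct_stability(ct2)$values), c(0, 0))
})

test_that("delta-Ct stabilities ignore per-sample Ct offsets", {
  for (seed in 1:4) {
    ct <- rand_ct(4, 7, seed = seed)
    offs <- stats::runif(7, -2, 2)
    shifted <- ct_matrix(sweep(unclass(ct), 2, -offs))
    expect_equal(delta_ct_stability(ct)$values,
                 delta_ct_stability(shifted)$values, tolerance = 1e-10)
  }
})

test_that("with two genes the delta-Ct stability is the pair SD and geNorm agrees", {
  ct <- rand_ct(2, 6, seed = 31)
  s <- delta_ct_stability(ct)
  pair_sd <- stats::sd(ct[1, ] - ct[2, ])
  expect_equal(unname(s$values), c(pair_sd, pair_sd), tolerance = 1e-12)
  # geNorm needs >= 3 genes by contract
  expect_error(genorm(ct_to_quantity(ct)), class = "refstab_shape_error")
})

test_that("all four algorithms match naive-loop oracles on random panels", {
  for (seed in 1:6) {
    g <- 3 + seed %% 4 # 3..6 genes
    n <- 4 + seed %% 5 # 4..8 samples
    ct <- rand_ct(g, n, seed = 100 + seed)
    q <- ct_to_quantity(ct)
    expect_equal(genorm(q)$m, oracle_genorm_m(unclass(q)), tolerance = 1e-9)
    expect_equal(delta_ct_stability(ct)$values, oracle_delta_ct(unclass(ct)),
                 tolerance = 1e-9)
    bk <- bestkeeper(ct)
    want <- oracle_bestkeeper(unclass(ct))
    expect_equal(bk$gene_stats$std_value, want$std, tolerance = 1e-9)
    expect_equal(bk$gene_stats$geo_mean, want$geo, tolerance = 1e-9)
    expect_equal(unname(bk$index), want$index, tolerance = 1e-9)
    expect_equal(bk$gene_stats$r, want$r, tolerance = 1e-9)
    expect_equal(bk$gene_stats$p_value, want$p, tolerance = 1e-9)
    expect_equal(normfinder(q)$values, oracle_normfinder(unclass(q)),
                 tolerance = 1e-9)
  }
})

test_that("run-all returns four aligned series and demotes a planted noisy gene", {
  spec <- ct_sim_spec(
    genes = data.frame(gene = sprintf("G%02d", 1:12),
                       baseline = seq(22, 30, length.out = 12),
                       sigma = c(rep(0.1, 11), 1.0)),
    factors = list(grp = 13L), seed = 5)
  sim <- simulate_ct(spec)
  expect_identical(dim(sim$ct), c(12L, 39L))
  bundle <- stability_all(sim$ct)
  expect_named(bundle$series,
               c("geNorm", "NormFinder", "BestKeeper", "deltaCt"))
  for (s in bundle$series) {
    expect_length(s$values, 12L)
    expect_true(s$lower_is_stable)
    expect_identical(names(which.max(s$values)), "G12")
  }
})

test_that("a panel of identical samples degenerates toward zero stability", {
  spec <- ct_sim_spec(genes = data.frame(gene = c("a", "b", "c", "d"),
                                         baseline = c(20, 22, 24, 26),
                                         sigma = 0),
                      factors = list(grp = 2L), samples_per_level = 3,
                      replicate_sd = 0, seed = 1)
  sim <- simulate_ct(spec)
  bundle <- stability_all(sim$ct)
  for (s in bundle$series)
    expect_equal(unname(s$values), rep(0, 4), tolerance = 1e-12)
})

test_that("missing-Ct policy drops samples listwise, never imputes", {
  ct <- ct_matrix(matrix(c(20, 21, NA, 22,
                           25, 26, 25, 27,
                           30, 29, 31, 30), nrow = 3, byrow = TRUE,
                         dimnames = list(c("g1", "g2", "g3"),
                                         c("a", "b", "c", "d"))),
                  allow_missing = TRUE)
  expect_error(delta_ct_stability(ct), class = "refstab_missing_data_error")
  s <- delta_ct_stability(ct, missing = "drop-sample")
  keep <- unclass(ct)[, c("a", "b", "d")]
  expect_equal(s$values, oracle_delta_ct(keep), tolerance = 1e-12)
})
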