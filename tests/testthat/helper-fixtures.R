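# Shared fixture builders (all fixtures are generated in code).

rand_ct <- function(genes = 4, samples = 6, seed = 1, lo = 18, hi = 32) {
  set.seed(seed)
  m <- matrix(stats::runif(genes * samples, lo, hi), nrow = genes,
              dimnames = list(sprintf("g%d", seq_len(genes)),
                              sprintf("s%d", seq_len(samples))))
  ct_matrix(m)
}

rand_quantity <- function(genes = 4, samples = 6, seed = 1) {
  ct_to_quantity(rand_ct(genes, samples, seed))
}

toy_delta_ct <- function() {
  ct_matrix(matrix(c(20, 21, 22,
                     25, 25, 25,
                     30, 31, 30), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("s1", "s2", "s3"))))
}

toy_quantities <- function() {
  matrix(c(1, 2, 4,
           2, 4, 8,
           1, 1, 1), nrow = 3, byrow = TRUE,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

series_from_matrix <- function(m) {
  lapply(colnames(m), function(cn)
    stability_series(cn, stats::setNames(m[, cn], rownames(m))))
}
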