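#' Specification of a simulated qPCR Ct experiment
#'
#' The generative model is Gaussian noise in cycle space (log-expression
#' space, the standard qPCR noise model): for biological sample s of level l
#' of its factor, `Ct_gs = baseline_g + shift_g(l) + N(0, sigma_g)`, and each
#' technical replicate adds independent `N(0, replicate_sd)` jitter around the
#' sample's value. Level shifts are additive in Ct (multiplicative in
#' expression), so "regulated" genes that stability algorithms must demote can
#' be planted.
#'
#' The default design mirrors a determination-stage qPCR study on goat skin:
#' 12 genes and four experimental factors (development stage, hair-follicle
#' cycle time-point, breed, body site) with 4/3/4/5 levels, 3 biological
#' samples per level and 3 technical replicates. Baseline Ct values span the
#' low-20s to high-20s and per-gene noise SDs span 0.4 to 1.0 cycles, the
#' range of per-gene Ct dispersions such panels report.
#'
#' @param genes Data frame with columns `gene`, `baseline` (Ct cycles) and
#'   `sigma` (per-gene biological noise SD, cycles, >= 0).
#' @param factors Named list, factor -> character vector of level labels (or a
#'   single integer level count).
#' @param samples_per_level Biological samples per level.
#' @param replicates Technical replicates per sample (>= 1).
#' @param replicate_sd Technical jitter SD in cycles.
#' @param shifts Named list factor -> (named list level -> named numeric gene
#'   shifts in cycles); absent entries are 0.
#' @param seed Integer seed; a fixed seed makes [simulate_ct()] byte-identical.
#' @return List of class `ct_sim_spec`.
#' @export
ct_sim_spec <- function(genes = NULL,
                        factors = list(stage = 4L, cycle = 3L,
                                       breed = 4L, site = 5L),
                        samples_per_level = 3L, replicates = 3L,
                        replicate_sd = 0.1, shifts = list(), seed = 1L) {
  if (is.null(genes)) {
    n <- 12L
    genes <- data.frame(
      gene = sprintf("G%02d", seq_len(n)),
      baseline = seq(23, 29, length.out = n),
      sigma = seq(0.4, 1.0, length.out = n),
      stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(c("gene", "baseline", "sigma") %in% names(genes)))
    stop_spec("genes needs columns gene, baseline, sigma")
  if (anyDuplicated(genes$gene)) stop_spec("duplicate gene ids in spec")
  if (any(genes$sigma < 0) || any(!is.finite(genes$sigma)))
    stop_spec("per-gene noise SDs must be finite and >= 0")
  if (any(genes$baseline <= 0 | genes$baseline > 45))
    stop_spec("baseline Ct must lie in (0, 45]")
  factors <- lapply(factors, function(f)
    if (is.numeric(f)) sprintf("L%d", seq_len(f)) else as.character(f))
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop_spec("factors must be named")
  if (replicates < 1L) stop_spec("replicates must be >= 1")
  if (samples_per_level < 1L) stop_spec("samples_per_level must be >= 1")
  if (replicate_sd < 0) stop_spec("replicate_sd must be >= 0")
  structure(list(genes = genes, factors = factors,
                 samples_per_level = as.integer(samples_per_level),
                 replicates = as.integer(replicates),
                 replicate_sd = replicate_sd, shifts = shifts,
                 seed = as.integer(seed)),
            class = "ct_sim_spec")
}

#' Simulate a Ct experiment with planted stability structure
#'
#' @param spec A [ct_sim_spec()].
#' @return List: `ct` (collapsed [ct_matrix()]), `long` (replicate-level data
#'   frame `gene,sample,replicate,ct`), `design` ([study_design()]), `truth`
#'   (data frame `gene`, `baseline`, `sigma`, `expected_rank` — ascending
#'   sigma, the planted stability order).
#' @export
simulate_ct <- function(spec = ct_sim_spec()) {
  if (!inherits(spec, "ct_sim_spec")) stop_spec("spec must be a ct_sim_spec")
  set.seed(spec$seed)
  genes <- spec$genes$gene
  design_rows <- list()
  sample_ids <- character(0)
  true_ct <- NULL
  for (f in names(spec$factors)) {
    for (lv in spec$factors[[f]]) {
      for (b in seq_len(spec$samples_per_level)) {
        sid <- sprintf("%s_%s_s%d", f, lv, b)
        sample_ids <- c(sample_ids, sid)
        shift <- rep(0, length(genes))
        sh <- spec$shifts[[f]][[lv]]
        if (!is.null(sh)) {
          idx <- match(names(sh), genes)
          if (anyNA(idx)) stop_spec("shift refers to unknown gene")
          shift[idx] <- sh
        }
        ct_s <- spec$genes$baseline + shift +
          stats::rnorm(length(genes), 0, spec$genes$sigma)
        true_ct <- cbind(true_ct, ct_s)
        design_rows[[length(design_rows) + 1L]] <-
          data.frame(sample = sid, factor = f, level = lv,
                     subject = sprintf("subj_%s_%d", f, b),
                     stringsAsFactors = FALSE)
      }
    }
  }
  dimnames(true_ct) <- list(genes, sample_ids)
  long <- expand.grid(replicate = seq_len(spec$replicates),
                      sample = sample_ids, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- long[, c("gene", "sample", "replicate")]
  long$ct <- true_ct[cbind(long$gene, long$sample)] +
    stats::rnorm(nrow(long), 0, spec$replicate_sd)
  ct <- collapse_replicates(long)
  design <- study_design(do.call(rbind, design_rows))
  truth <- data.frame(gene = genes, baseline = spec$genes$baseline,
                      sigma = spec$genes$sigma,
                      expected_rank = rank(spec$genes$sigma,
                                           ties.method = "average"),
                      stringsAsFactors = FALSE)
  list(ct = ct, long = long, design = design, truth = truth)
}

#' Specification of a simulated FPKM screening matrix
#'
#' Three planted gene classes: housekeeping-like genes (high mean, low
#' variability — lognormal with small log-SD, chosen so the default screening
#' thresholds are met with high probability), variable genes (wide lognormal)
#' and all-zero genes. Defaults emulate a 39-sample transcriptome screen.
#'
#' @param n_hkg,n_variable,n_zero Class counts (>= 0).
#' @param n_samples Number of samples (>= 2).
#' @param hkg_meanlog,hkg_sdlog Lognormal parameters of the housekeeping-like
#'   class (defaults: median ~50 FPKM, ~8% CV).
#' @param var_meanlog,var_sdlog Parameters of the variable class.
#' @param seed Integer seed.
#' @return List of class `fpkm_sim_spec`.
#' @export
fpkm_sim_spec <- function(n_hkg = 3L, n_variable = 100L, n_zero = 5L,
                          n_samples = 39L,
                          hkg_meanlog = log(50), hkg_sdlog = 0.08,
                          var_meanlog = log(8), var_sdlog = 0.9,
                          seed = 1L) {
  counts <- c(n_hkg, n_variable, n_zero)
  if (any(counts < 0L) || sum(counts) < 1L)
    stop_spec("class counts must be >= 0 with at least one gene")
  if (n_samples < 2L) stop_spec("need at least 2 samples")
  if (hkg_sdlog < 0 || var_sdlog < 0) stop_spec("sdlog must be >= 0")
  structure(list(n_hkg = as.integer(n_hkg), n_variable = as.integer(n_variable),
                 n_zero = as.integer(n_zero), n_samples = as.integer(n_samples),
                 hkg_meanlog = hkg_meanlog, hkg_sdlog = hkg_sdlog,
                 var_meanlog = var_meanlog, var_sdlog = var_sdlog,
                 seed = as.integer(seed)),
            class = "fpkm_sim_spec")
}

#' Simulate an FPKM matrix with planted housekeeping-like genes
#'
#' @param spec An [fpkm_sim_spec()].
#' @return List: `fpkm` (an [expression_matrix()]), `truth` (data frame
#'   `gene`, `class` in hkg/variable/zero).
#' @export
simulate_fpkm <- function(spec = fpkm_sim_spec()) {
  if (!inherits(spec, "fpkm_sim_spec")) stop_spec("spec must be an fpkm_sim_spec")
  set.seed(spec$seed)
  ns <- spec$n_samples
  rows <- list(); classes <- character(0); ids <- character(0)
  if (spec$n_hkg > 0L)
    for (i in seq_len(spec$n_hkg)) {
      rows[[length(rows) + 1L]] <- stats::rlnorm(ns, spec$hkg_meanlog,
                                                 spec$hkg_sdlog)
      ids <- c(ids, sprintf("hkg_%03d", i)); classes <- c(classes, "hkg")
    }
  if (spec$n_variable > 0L)
    for (i in seq_len(spec$n_variable)) {
      rows[[length(rows) + 1L]] <- stats::rlnorm(ns, spec$var_meanlog,
                                                 spec$var_sdlog)
      ids <- c(ids, sprintf("var_%03d", i)); classes <- c(classes, "variable")
    }
  if (spec$n_zero > 0L)
    for (i in seq_len(spec$n_zero)) {
      rows[[length(rows) + 1L]] <- rep(0, ns)
      ids <- c(ids, sprintf("zero_%03d", i)); classes <- c(classes, "zero")
    }
  fpkm <- do.call(rbind, rows)
  dimnames(fpkm) <- list(ids, sprintf("S%02d", seq_len(ns)))
  list(fpkm = expression_matrix(fpkm),
       truth = data.frame(gene = ids, class = classes,
                          stringsAsFactors = FALSE))
}
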