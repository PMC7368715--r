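#' Assemble and validate a pipeline configuration
#'
#' A configuration enables stages by supplying their inputs; at least one
#' stage must be enabled. Inputs may be in-memory objects or file paths to
#' the delimited formats of the reader functions.
#'
#' @param expression FPKM matrix (or path): enables the screening stage.
#' @param ct Ct table (or path): enables the stability + aggregation stages.
#' @param ct_layout Layout for a Ct path, `"wide"` or `"long"`.
#' @param design Study design (or path); optional, used for per-factor
#'   stability runs and grouped NormFinder.
#' @param factors Factor names to analyse per group (defaults to all factors
#'   in the design); the pooled all-samples run uses factor membership as the
#'   NormFinder grouping when a design is present.
#' @param thresholds A [screen_thresholds()].
#' @param zero_policy Prefilter policy for screening.
#' @param dpm_method DPM normalization, see [gene_summary()].
#' @param efficiencies Amplification base(s), see [ct_to_quantity()].
#' @param bestkeeper_center BestKeeper std-value centring.
#' @param aggregate_input Bare gene x algorithm table of stability values (or
#'   path to one; first column gene ids): enables aggregation-only runs for
#'   users of other algorithms.
#' @param aggregate_method `"comprfinder"`, `"reffinder"` or `"both"`.
#' @param strict_missing Error on missing values during aggregation.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when simulated inputs are produced
#'   upstream).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, ct = NULL,
                            ct_layout = c("wide", "long"), design = NULL,
                            factors = NULL,
                            thresholds = screen_thresholds(),
                            zero_policy = c("any-zero", "all-zero"),
                            dpm_method = c("spm-sd", "cv-rms"),
                            efficiencies = 2,
                            bestkeeper_center = c("arithmetic", "geometric"),
                            aggregate_input = NULL,
                            aggregate_method = c("both", "comprfinder", "reffinder"),
                            strict_missing = FALSE, seed = NULL) {
  cfg <- list(expression = expression, ct = ct,
              ct_layout = match.arg(ct_layout), design = design,
              factors = factors, thresholds = thresholds,
              zero_policy = match.arg(zero_policy),
              dpm_method = match.arg(dpm_method),
              efficiencies = efficiencies,
              bestkeeper_center = match.arg(bestkeeper_center),
              aggregate_input = aggregate_input,
              aggregate_method = match.arg(aggregate_method),
              strict_missing = strict_missing, seed = seed)
  for (field in c("expression", "ct", "design", "aggregate_input")) {
    x <- cfg[[field]]
    if (is.character(x) && length(x) == 1L && !file.exists(x))
      stop_config(sprintf("%s file not found: %s", field, x))
  }
  if (is.null(expression) && is.null(ct) && is.null(aggregate_input))
    stop_config("no stage enabled: supply expression, ct or aggregate_input")
  structure(cfg, class = "pipeline_config")
}

.load_input <- function(x, reader) if (is.character(x)) reader(x) else x

.read_aggregate_table <- function(path) {
  parsed <- .read_delim_matrix(path)
  if (any(parsed$unparseable)) stop_domain("non-numeric stability value(s)")
  parsed$values
}

#' Run the screening / stability / aggregation pipeline
#'
#' Executes every enabled stage and collects its tables into a report bundle:
#' screening summary and Venn counts; per-algorithm stability tables with one
#' column per design factor plus the pooled all-samples run; geNorm pairwise
#' variation sequence; composite (ComprFinder) and rank-based (RefFinder)
#' aggregation tables and their side-by-side comparison. A run log records
#' package version, seed and the decision flags in effect.
#'
#' @param config A [pipeline_config()].
#' @return List of class `report_bundle`: `tables` (named list of data
#'   frames), `log` (character vector).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  tables <- list()
  log <- c(sprintf("refstab %s", as.character(utils::packageVersion("refstab"))),
           sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
           sprintf("zero_policy=%s dpm_method=%s bestkeeper_center=%s aggregate_method=%s",
                   config$zero_policy, config$dpm_method,
                   config$bestkeeper_center, config$aggregate_method))

  design <- if (!is.null(config$design))
    .load_input(config$design, read_study_design)

  if (!is.null(config$expression)) {
    m <- .load_input(config$expression, read_expression_matrix)
    m <- prefilter_genes(m, config$zero_policy)
    log <- c(log, sprintf("screening: %d gene(s) removed by prefilter",
                          attr(m, "n_removed")))
    summ <- gene_summary(m, dpm_method = config$dpm_method)
    tables$screening_summary <- rank_by_cv(summ)
    sc <- screen_candidates(summ, config$thresholds)
    tables$screening_counts <- data.frame(
      criterion = names(sc$counts), n_genes = as.integer(sc$counts),
      stringsAsFactors = FALSE)
    tables$screening_candidates <- data.frame(gene = sc$intersection,
                                              stringsAsFactors = FALSE)
  }

  series_for_aggregation <- NULL
  if (!is.null(config$ct)) {
    ct <- .load_input(config$ct, function(p) read_ct_table(p, config$ct_layout))
    runs <- list()
    if (!is.null(design)) {
      factors <- if (is.null(config$factors)) unique(design$factor)
                 else config$factors
      for (f in factors) {
        rows <- design[design$factor == f & design$sample %in% colnames(ct), ,
                       drop = FALSE]
        if (!nrow(rows))
          stop_config(sprintf("no sample of the Ct table has factor '%s'", f))
        runs[[f]] <- stability_all(
          ct, design = design, factor = f,
          efficiencies = config$efficiencies,
          bestkeeper_center = config$bestkeeper_center,
          samples = unique(rows$sample))
      }
      # pooled run grouped by factor membership
      pooled_design <- study_design(data.frame(
        sample = design$sample, factor = "pooled", level = design$factor,
        stringsAsFactors = FALSE))
      pooled_design <- pooled_design[!duplicated(pooled_design$sample), ,
                                     drop = FALSE]
      runs[["all_samples"]] <- stability_all(
        ct, design = pooled_design, factor = "pooled",
        efficiencies = config$efficiencies,
        bestkeeper_center = config$bestkeeper_center)
    } else {
      runs[["all_samples"]] <- stability_all(
        ct, efficiencies = config$efficiencies,
        bestkeeper_center = config$bestkeeper_center)
    }
    for (alg in c("geNorm", "NormFinder", "BestKeeper", "deltaCt")) {
      tab <- data.frame(gene = rownames(ct), stringsAsFactors = FALSE)
      for (rn in names(runs)) {
        s <- runs[[rn]]$series[[alg]]
        tab[[rn]] <- .value_rank(s$values[tab$gene])
      }
      tables[[paste0("stability_", tolower(alg))]] <- tab
    }
    tables$genorm_v <- do.call(rbind, lapply(names(runs), function(rn)
      data.frame(run = rn, step = names(runs[[rn]]$genorm$v),
                 v = unname(runs[[rn]]$genorm$v), stringsAsFactors = FALSE)))
    series_for_aggregation <- runs[["all_samples"]]$series
    per_run_series <- lapply(runs, `[[`, "series")
    agg <- lapply(per_run_series, function(sr)
      compare_aggregators(sr, config$strict_missing))
    tables$aggregation <- do.call(rbind, lapply(names(agg), function(rn)
      cbind(run = rn, agg[[rn]], stringsAsFactors = FALSE)))
  }

  if (!is.null(config$aggregate_input)) {
    vals <- if (is.character(config$aggregate_input))
      .read_aggregate_table(config$aggregate_input)
    else as.matrix(config$aggregate_input)
    series <- lapply(colnames(vals), function(cn)
      stability_series(cn, stats::setNames(vals[, cn], rownames(vals))))
    cmp <- compare_aggregators(series, config$strict_missing)
    tables$aggregation_external <- switch(config$aggregate_method,
      both = cmp,
      comprfinder = cmp[c("gene", "comprfinder_fs", "comprfinder_rank")],
      reffinder = cmp[order(cmp$reffinder_rank),
                      c("gene", "reffinder_score", "reffinder_rank")])
  }

  structure(list(tables = tables, log = log), class = "report_bundle")
}

# "value (rank)" formatting used by the stability report tables
.value_rank <- function(values) {
  sprintf("%.3f (%d)", values,
          as.integer(rank(values, ties.method = "first")))
}

#' Write a report bundle to disk
#'
#' File naming is deterministic (`<table>.tsv` per table plus `run_log.txt`,
#' or a single `bundle.json`); numeric columns are written at 3 decimals in
#' TSV mode. Writing the same bundle twice produces identical bytes.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!length(bundle$tables)) stop_config("empty report bundle: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) refstab_error("refstab_io_error",
                                      sprintf("cannot create directory %s", dir))
  paths <- character(0)
  if (format == "json") {
    path <- file.path(dir, "bundle.json")
    jsonlite::write_json(list(tables = bundle$tables, log = bundle$log),
                         path, dataframe = "columns", digits = NA,
                         pretty = TRUE)
    paths <- path
  } else {
    for (nm in names(bundle$tables)) {
      tab <- bundle$tables[[nm]]
      num <- vapply(tab, is.numeric, logical(1L))
      tab[num] <- lapply(tab[num], function(x) sprintf("%.3f", x))
      path <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
      paths <- c(paths, path)
    }
    log_path <- file.path(dir, "run_log.txt")
    writeLines(bundle$log, log_path)
    paths <- c(paths, log_path)
  }
  invisible(paths)
}

#' Read back a JSON report bundle
#'
#' @param path Path to a `bundle.json` written by [write_report()].
#' @return A `report_bundle`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tables = lapply(raw$tables, as.data.frame), log = raw$log),
            class = "report_bundle")
}
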