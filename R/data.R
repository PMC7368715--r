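#' Bundled example: goat skin housekeeping-gene panel summaries
#'
#' Two small tables describing a 12-gene candidate housekeeping panel assayed
#' across 39 goat (*Capra hircus*) skin tissue samples, shipped as worked-
#' example input for the aggregation stage.
#'
#' `stability` holds the all-samples per-gene stability values and ranks of
#' three Ct-based algorithms (NormFinder, BestKeeper std-value, delta-Ct mean
#' pair SD), the geNorm rank where known (the top-3 and bottom-3 of the geNorm
#' exclusion order; middle ranks are `NA` because only the figure-level order
#' is available, not the M values), and the reported composite final score and
#' rank for comparison. `screening` holds the transcriptome screening
#' statistics of the same genes (mean FPKM, CV% with its rank among 15,853
#' genes, MFC, DPM).
#'
#' These are reported summary statistics, not raw measurements: the per-sample
#' Ct and FPKM matrices behind them are not redistributed here, so the tables
#' support rank-based aggregation examples but not re-running the stability
#' algorithms themselves.
#'
#' @return List with data frames `stability` and `screening`.
#' @export
goat_skin_tables <- function() {
  read1 <- function(f)
    utils::read.csv(system.file("extdata", f, package = "refstab",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  list(stability = read1("goat_skin_stability_all_samples.csv"),
       screening = read1("goat_skin_screening.csv"))
}
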