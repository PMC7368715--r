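#' @keywords internal
#' @noRd
refstab_error <- function(class, message, ...) {
  stop(errorCondition(message,
                      class = c(class, "refstab_error"),
                      ...))
}

# condition classes used across the package:
#   refstab_duplicate_id_error  duplicate gene/sample identifiers
#   refstab_domain_error        values outside their domain (negative FPKM,
#                               Ct outside (0,45], efficiency outside [1.6,2.1],
#                               non-negative dilution slope, ...)
#   refstab_shape_error         too few genes/samples or mismatched dimensions
#   refstab_missing_data_error  absent Ct cells / zero-replicate pairs
#   refstab_design_mismatch_error  samples absent from a design / unpaired
#   refstab_gene_set_error      unknown genes or mismatched gene sets
#   refstab_orientation_error   stability series oriented higher-is-stabler
#   refstab_empty_set_error     a filter removed every gene
#   refstab_spec_error          invalid simulation spec
#   refstab_config_error        invalid pipeline configuration

stop_duplicate_id <- function(ids, what = "gene") {
  refstab_error("refstab_duplicate_id_error",
                sprintf("duplicate %s identifier(s): %s", what,
                        paste(unique(ids), collapse = ", ")))
}

stop_domain <- function(message) refstab_error("refstab_domain_error", message)
stop_shape <- function(message) refstab_error("refstab_shape_error", message)
stop_missing_data <- function(message) refstab_error("refstab_missing_data_error", message)
stop_design_mismatch <- function(message) refstab_error("refstab_design_mismatch_error", message)
stop_gene_set <- function(message) refstab_error("refstab_gene_set_error", message)
stop_orientation <- function(message) refstab_error("refstab_orientation_error", message)
stop_empty_set <- function(message) refstab_error("refstab_empty_set_error", message)
stop_spec <- function(message) refstab_error("refstab_spec_error", message)
stop_config <- function(message) refstab_error("refstab_config_error", message)
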