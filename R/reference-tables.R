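#' Packaged reference tables
#'
#' Three small plain-text tables ship with the package and parameterize
#' the synthetic-data generators and the worked examples:
#'
#' * `soil_variogram_table()` — fitted variogram parameters (model kind,
#'   nugget, sill, range, SDI class, fit diagnostics, log-transform flag)
#'   for 24 soil attributes of a 100-point sugarcane field-reform survey.
#' * `soil_summary_table()` — descriptive statistics (mean, SE, SD,
#'   min, max, CV, skewness, kurtosis) for the same attributes.
#' * `microbiology_reference()` — two-region (R1/R2) group means and
#'   standard errors for nine microbiological variables (marker-gene
#'   copy numbers, enzyme activities, microbial biomass carbon, C/N).
#'   The group means are reported survey values except cellulase, whose
#'   means are synthetic plausible values; all SEs are synthetic
#'   plausible values chosen on each assay's scale (the originals are
#'   available only graphically). Provenance is flagged per row in the
#'   `mean_source`/`se_source` columns.
#'
#' @return A data frame.
#' @name reference_tables
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "soilspatial",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
soil_variogram_table <- function() read_extdata("soil_variogram_table.csv")

#' @rdname reference_tables
#' @export
soil_summary_table <- function() read_extdata("soil_summary_table.csv")

#' @rdname reference_tables
#' @export
microbiology_reference <- function() {
  read_extdata("region_microbiology_means_synthetic_se.csv")
}
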