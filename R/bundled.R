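#' Path to the bundled reduced model table
#' @return path to the reaction TSV shipped with the package.
#' @export
bundled_model_path <- function() {
  system.file("extdata", "reduced_cardiomyocyte.tsv", package = "mitoflux",
              mustWork = TRUE)
}

#' Load the bundled reduced model from its shipped table
#'
#' Reads the TSV fixture under `inst/extdata` (identical to the network
#' returned by [build_reduced_model()] under default parameters) and applies
#' an uptake configuration.
#'
#' @param config uptake configuration, or `NULL` to keep the bounds stored in
#'   the table.
#' @return a `mito_model`.
#' @export
load_bundled_model <- function(config = default_uptake_config()) {
  model <- read_table(bundled_model_path())
  if (!is.null(config)) model <- apply_uptake_config(model, config)
  model
}
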