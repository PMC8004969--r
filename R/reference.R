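#' Reference tables for rabbit ALOX15 and its interface mutants
#'
#' Small bundled tables of reference values for the rabbit ALOX15 system:
#'
#' * `alox15_kinetics_table()` — steady-state Michaelis-Menten constants
#'   (kcat in s^-1 with standard error, KM in uM with standard error) for
#'   linoleic (LA) and arachidonic (AA) acid oxygenation by the wild-type
#'   enzyme and the His585Glu / Trp181Glu interface mutants.
#' * `alox15_geometry_table()` — trajectory-averaged reactive distances
#'   (Angstrom) and well-oriented / pre-catalytic percentages for the
#'   wild-type and Trp181Glu substrate complexes.
#'
#' These are inputs for the arithmetic comparisons (catalytic efficiencies,
#' pre-catalytic enrichment folds, mean-distance shifts); the underlying
#' trajectories are not redistributable.
#'
#' @return data.frame.
#' @export
alox15_kinetics_table <- function() {
  utils::read.csv(system.file("extdata", "alox15_kinetics.csv",
                              package = "loxtraj"),
                  stringsAsFactors = FALSE)
}

#' @rdname alox15_kinetics_table
#' @export
alox15_geometry_table <- function() {
  utils::read.csv(system.file("extdata", "alox15_reactive_geometry.csv",
                              package = "loxtraj"),
                  stringsAsFactors = FALSE)
}
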