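#' Path to a shipped model file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path (or vector of file names).
#' @export
choflux_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "choflux")))
  }
  path <- system.file("extdata", file, package = "choflux")
  if (path == "") stop("no shipped file called ", file, call. = FALSE)
  path
}

#' Shipped reference CHO network
#'
#' The reconstructed reference model of mAb-producing CHO central carbon and
#' amino acid metabolism (glycolysis, TCA cycle, pentose phosphate pathway,
#' glutaminolysis and transaminases, oxidative phosphorylation, adenylate
#' kinase, growth and mAb synthesis). Reactions whose exact published rate
#' equations were not available carry grammar-consistent minimal forms and a
#' `reconstructed` flag.
#'
#' @return `MetabolicNetwork`.
#' @export
reference_network <- function() load_network(choflux_file("cho_network.yaml"))

#' Shipped reference parameter table
#' @return `ParameterSet` data frame; the `sensitive_flag` column marks the
#'   20-parameter calibration subset.
#' @export
reference_parameters <- function() load_parameters(choflux_file("cho_parameters.csv"))

#' The four reference culture experiments
#'
#' Batch and fed-batch cultures on each of two media, inoculated at
#' 0.2e6 cells/mL: the Biogro-CHO batch (25 mM glucose, 4 mM glutamine) and
#' fed-batch (10 mM glucose, 2.4 mM glutamine; concentrate 130 mM glucose,
#' 25 mM glutamine) and the PowerCHO-2 batch and fed-batch (6.5 mM glutamine;
#' concentrate at 100 mM glucose, 16 mM glutamine plus 2.5x base amino acids).
#'
#' @return Named list of four `CultureExperiment` objects.
#' @export
reference_experiments <- function() {
  files <- c(biogro_batch = "experiment_biogro_batch.yaml",
             biogro_fedbatch = "experiment_biogro_fedbatch.yaml",
             powercho_batch = "experiment_powercho_batch.yaml",
             powercho_fedbatch = "experiment_powercho_fedbatch.yaml")
  lapply(files, function(f) load_experiment(choflux_file(f)))
}

#' Published full-model sensitivity screening table
#'
#' Mean and standard deviation of the elementary effect for the 20 parameters
#' retained for calibration in the original full-model screening; used as a
#' fixture for the subset-selection rule.
#'
#' @return Data frame with `parameter`, `mean_ee`, `sd_ee`.
#' @export
reference_sensitivity <- function() {
  utils::read.csv(choflux_file("reference_sensitivity.csv"),
                  stringsAsFactors = FALSE)
}

#' Toy uptake-conversion network for fast oracle tests
#' @return `MetabolicNetwork` with three reactions (uptake, product-inhibited
#'   conversion, degradation).
#' @export
toy_network <- function() load_network(choflux_file("toy_network.yaml"))

#' @rdname toy_network
#' @export
toy_parameters <- function() load_parameters(choflux_file("toy_parameters.csv"))

#' @rdname toy_network
#' @export
toy_experiment <- function() load_experiment(choflux_file("toy_experiment.yaml"))
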