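# Shared fixtures. Reference objects are loaded once per test run; small
# networks are built in code.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

ref_net <- function() memo("net", reference_network())
ref_par <- function() memo("par", reference_parameters())
ref_exps <- function() memo("exps", reference_experiments())
ref_traj <- function() memo(
  "traj", simulate_culture(ref_net(), ref_par(), ref_exps()$biogro_batch))

toy_net <- function() memo("toy_net", toy_network())
toy_par <- function() memo("toy_par", toy_parameters())
toy_exp <- function() memo("toy_exp", toy_experiment())

# minimal culture scaffold: extracellular substrate S, per-cell pool P,
# cells and volume, with caller-supplied reactions
tiny_mets <- function(extra = list()) {
  c(list(list(id = "S", compartment = "extracellular"),
         list(id = "P", compartment = "intracellular"),
         list(id = "Xv", compartment = "cells"),
         list(id = "V", compartment = "volume")),
    extra)
}

tiny_state <- function(S = 10, P = 1e-7, Xv = 1, V = 1, ...) {
  c(S = S, P = P, Xv = Xv, V = V, ...)
}

# constant-specific-growth-rate model: mu ~= Vmax_g (substrate saturating,
# negligible consumption), used for the exponential closed-form checks
constant_growth_network <- function() {
  metabolic_network(
    tiny_mets(),
    list(list(id = "V_growth",
              stoichiometry = c(S = -1e-30, Xv = 1),
              rate_law = list(Vmax = "Vmax_g",
                              substrates = list(list(species = "S",
                                                     Km = "Km_g"))))))
}

batch_experiment <- function(initial, duration = 48, name = "tiny",
                             sampling = 12) {
  as_exp <- list(name = name, medium = "synthetic", mode = "batch",
                 duration = duration, sampling_interval = sampling,
                 initial = as.list(initial))
  choflux:::as_experiment(as_exp)
}
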