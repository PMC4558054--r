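# Batch / fed-batch culture simulator. The ODE system couples per-cell kinetic
# fluxes to culture-scale balances:
#   dXv/dt   = mu * Xv
#   dS/dt    = 1000 * Xv * sum(stoich * flux)    extracellular species and mAb
#   dC/dt    = sum(stoich * flux) - mu * C       intracellular per-cell pools
#   dV/dt    = 0 between feed events
# Feed events are exact discontinuities: integration stops, the bolus is mixed
# in, and integration restarts from the post-bolus state.

#' Load a culture experiment definition
#'
#' YAML file with fields `name`, `medium`, `mode` (`batch` or `fed-batch`),
#' `duration` (h), `initial` (map species to initial value; must cover every
#' species in the network), and for fed-batch a `feed` block with
#' `composition` (mM in the concentrate) and `policy` (`interval`, `start`,
#' `glucose_floor`, `set_point`, `conditional`).
#'
#' @param path YAML path.
#' @return A `CultureExperiment` list.
#' @export
load_experiment <- function(path) {
  if (!file.exists(path)) stop("experiment file not found: ", path, call. = FALSE)
  ex <- yaml::read_yaml(path)
  as_experiment(ex)
}

as_experiment <- function(ex) {
  stopifnot(!is.null(ex$mode), !is.null(ex$duration), !is.null(ex$initial))
  if (!ex$mode %in% c("batch", "fed-batch")) {
    stop("mode must be 'batch' or 'fed-batch'", call. = FALSE)
  }
  ex$initial <- unlist(ex$initial)
  if (ex$mode == "fed-batch") {
    if (is.null(ex$feed)) stop("fed-batch experiment needs a feed block", call. = FALSE)
    ex$feed$composition <- unlist(ex$feed$composition)
    pol <- ex$feed$policy %||% list()
    pol$interval <- pol$interval %||% 24
    pol$start <- pol$start %||% 24
    pol$glucose_floor <- pol$glucose_floor %||% 10
    pol$set_point <- pol$set_point %||% unname(ex$initial["GLC"])
    pol$conditional <- isTRUE(pol$conditional)
    gf <- ex$feed$composition["GLC"]
    if (!is.na(gf) && !(pol$glucose_floor < pol$set_point && pol$set_point < gf)) {
      stop("feed policy requires floor < set-point < feed glucose concentration",
           call. = FALSE)
    }
    ex$feed$policy <- pol
  } else {
    ex$feed <- NULL
  }
  class(ex) <- "CultureExperiment"
  ex
}

#' Mix a feed bolus into the culture
#'
#' Instantaneous, mass-conserving mixing: volume increases by `volume`, every
#' extracellular concentration (and the mAb titre) is the volume-weighted mean
#' of broth and concentrate, the cell density is diluted, and intracellular
#' per-cell pools are unchanged.
#'
#' @param network `MetabolicNetwork` (supplies compartments).
#' @param state Named state vector (must include `V`).
#' @param volume Bolus volume in L, >= 0.
#' @param feed Named vector of concentrate concentrations (mM); species absent
#'   from `feed` are treated as 0 (pure dilution).
#' @return Post-bolus named state vector.
#' @export
apply_bolus <- function(network, state, volume, feed) {
  if (!is.numeric(volume) || length(volume) != 1L || is.na(volume) || volume < 0) {
    stop("bolus volume must be a single non-negative number", call. = FALSE)
  }
  if (volume == 0) return(state)
  mets <- if (is.list(network) && !is.null(network$kin)) {
    data.frame(id = network$species, compartment = network$compartment)
  } else network$metabolites
  V <- unname(state["V"])
  Vp <- V + volume
  out <- state
  dilute <- mets$id[mets$compartment %in% c("extracellular", "product")]
  for (sp in dilute) {
    cf <- if (sp %in% names(feed)) feed[[sp]] else 0
    out[sp] <- (state[[sp]] * V + cf * volume) / Vp
  }
  out["Xv"] <- state[["Xv"]] * V / Vp
  out["V"] <- Vp
  out
}

#' Feed volume that restores glucose to a target concentration
#'
#' Solves the mixing balance for the bolus volume `v` such that the post-bolus
#' glucose equals `target`: `v = V * (target - G) / (G_feed - target)`.
#' Returns 0 when glucose is already at or above the target.
#'
#' @param state Named state vector with `GLC` and `V`.
#' @param feed Named concentrate vector with `GLC`.
#' @param target Post-bolus glucose concentration (mM).
#' @return Bolus volume in L.
#' @export
feed_volume_for_target <- function(state, feed, target) {
  gfeed <- feed[["GLC"]]
  if (target >= gfeed) {
    stop("feed target (", target, " mM) must be below the concentrate glucose (",
         gfeed, " mM)", call. = FALSE)
  }
  G <- unname(state["GLC"])
  if (G >= target) return(0)
  unname(state["V"]) * (target - G) / (gfeed - target)
}

default_atol <- function(comp, x0, floor_scale = c(
  extracellular = 1, intracellular = 1e-7, cells = 0.1, product = 1, volume = 1)) {
  typ <- pmax(abs(x0), floor_scale[comp$compartment])
  unname(typ * 1e-10)
}

#' Simulate a culture experiment
#'
#' Stiff adaptive integration (\code{deSolve::lsoda}) between feed events.
#' At each daily trigger time of a fed-batch experiment the bolus volume is
#' computed from the glucose set-point rule (unconditionally by default, or
#' only when glucose has fallen below the policy floor when
#' `policy$conditional` is TRUE), the bolus is mixed in exactly, and
#' integration restarts. Deterministic: no randomness is involved.
#'
#' @param network `MetabolicNetwork` or compiled network.
#' @param params `ParameterSet` or named numeric vector.
#' @param experiment `CultureExperiment`.
#' @param output_times Optional extra times (h) that must appear on the grid;
#'   all within `[0, duration]`.
#' @param dense_dt Spacing of the dense output grid (h).
#' @param rtol,atol Solver tolerances. `atol` defaults to 1e-10 of each
#'   species' typical magnitude.
#' @param dilution Apply the `-mu*C` division-dilution term to intracellular
#'   per-cell pools (default TRUE).
#' @return A `SimulationTrajectory`: list with `times`, `states` (matrix,
#'   species in columns), `fluxes` (matrix, reactions in columns),
#'   `feed_events` (data frame), `species`, `reaction_ids`.
#' @export
simulate_culture <- function(network, params, experiment, output_times = NULL,
                             dense_dt = 1, rtol = 1e-8, atol = NULL,
                             dilution = TRUE) {
  comp <- as_compiled(network, params)
  pv <- unname(param_values(params)[comp$param_names])
  dur <- experiment$duration
  if (!is.null(output_times) &&
      (min(output_times) < 0 || max(output_times) > dur)) {
    stop("output_times must lie within [0, ", dur, "]", call. = FALSE)
  }
  init <- experiment$initial
  miss <- setdiff(comp$species, names(init))
  if (length(miss)) {
    stop("experiment is missing initial condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x0 <- unname(init[comp$species])
  if (is.null(atol)) atol <- default_atol(comp, x0)

  species <- comp$species
  f <- comp$flat
  stoich <- comp$stoich
  rhs_fn <- function(t, y, parms) {
    d <- .rhs_cpp(y, pv, f$vmax_idx, f$sub_off, f$sub_type, f$sub_i1,
                  f$sub_i2, f$sub_k, f$reg_off, f$reg_kind, f$reg_e1,
                  f$reg_e2, f$reg_k, f$reg_alpha, f$reg_beta,
                  stoich, f$comp_code, f$i_cells0, f$i_growth0, dilution)
    if (any(!is.finite(d))) {
      bad <- species[!is.finite(d)]
      stop("non-finite derivative at t = ", signif(t, 6), " for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    list(d)
  }

  event_times <- if (!is.null(experiment$feed)) {
    pol <- experiment$feed$policy
    tt <- seq(pol$start, dur, by = pol$interval)
    tt[tt > 0 & tt < dur]
  } else numeric()

  grid <- sort(unique(c(seq(0, dur, by = dense_dt), dur, output_times,
                        event_times)))
  seg_bounds <- c(0, event_times, dur)
  times <- c(); states <- NULL
  feed_log <- list()
  x <- x0
  for (si in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[si]; t1 <- seg_bounds[si + 1L]
    seg_times <- grid[grid >= t0 & grid <= t1]
    if (length(seg_times) < 2L) seg_times <- c(t0, t1)
    sol <- tryCatch(
      deSolve::lsoda(y = x, times = seg_times, func = rhs_fn, parms = NULL,
                     rtol = rtol, atol = atol, maxsteps = 50000),
      warning = function(w) stop("solver failed in [", t0, ", ", t1, "] h (",
                                 conditionMessage(w), "); last valid time ",
                                 max(times, 0), call. = FALSE))
    st <- sol[, -1, drop = FALSE]
    keep <- if (length(times)) -1L else seq_len(nrow(st))  # drop duplicated knot
    times <- c(times, sol[keep, 1])
    states <- rbind(states, st[keep, , drop = FALSE])
    x <- st[nrow(st), ]
    if (t1 %in% event_times) {
      names(x) <- species
      pol <- experiment$feed$policy
      fc <- experiment$feed$composition
      vol <- if (pol$conditional && x[["GLC"]] >= pol$glucose_floor) 0
             else feed_volume_for_target(x, fc, pol$set_point)
      if (vol > 0) {
        x <- apply_bolus(comp, x, vol, fc)
        feed_log[[length(feed_log) + 1L]] <-
          data.frame(time = t1, volume = vol, glucose_after = x[["GLC"]])
        # concentrations at feed instants are reported post-bolus
        states[nrow(states), ] <- unname(x)
      }
      x <- unname(x)
    }
  }
  colnames(states) <- species
  fluxes <- flux_matrix_along(comp, states, pv)
  structure(list(
    times = times, states = states, fluxes = fluxes,
    feed_events = if (length(feed_log)) do.call(rbind, feed_log) else
      data.frame(time = numeric(), volume = numeric(), glucose_after = numeric()),
    species = species, reaction_ids = comp$reaction_ids,
    experiment = experiment$name %||% "experiment"),
    class = "SimulationTrajectory")
}

#' @export
print.SimulationTrajectory <- function(x, ...) {
  cat("SimulationTrajectory:", x$experiment, "\n ",
      length(x$times), "time points over", max(x$times), "h;",
      nrow(x$feed_events), "feed events\n")
  invisible(x)
}

#' Default observable set
#'
#' The 32 model outputs used for sensitivity screening and calibration:
#' cells, mAb, the measured extracellular species, key intracellular pools,
#' the AMP/ATP and NAD/NADH ratios, ATP, and the culture oxygen uptake rate
#' (`OUR = V_resp * Xv * 1000`, mmol O2 per L per h).
#'
#' @return Character vector of observable names.
#' @export
default_outputs <- function() {
  c("Xv", "mAb", "GLC", "LAC", "GLN", "GLU", "NH4", "ALA", "ASP", "ASN",
    "SER", "GLY", "HIS", "ARG", "ILE", "VAL", "THR", "LYS", "MET", "PHE",
    "TYR", "G6P", "F6P", "PYR", "CIT", "AKG", "MAL", "R5P", "ATP",
    "AMP/ATP", "NAD/NADH", "OUR")
}

#' Evaluate observables from a trajectory
#'
#' Linear-in-time interpolation of the dense solution. Observables are species
#' names, pool ratios written `"A/B"`, or `"OUR"` (oxygen uptake rate,
#' `V_resp * Xv * 1000`).
#'
#' @param trajectory `SimulationTrajectory`.
#' @param outputs Character vector of observable names.
#' @param times Times (h) within the trajectory range.
#' @return Numeric matrix, `length(times)` rows by `length(outputs)` columns.
#' @export
observe <- function(trajectory, outputs = default_outputs(), times) {
  tr <- trajectory
  if (min(times) < min(tr$times) - 1e-9 || max(times) > max(tr$times) + 1e-9) {
    stop("requested times outside the simulated range [",
         min(tr$times), ", ", max(tr$times), "] h", call. = FALSE)
  }
  series_for <- function(out) {
    if (out %in% tr$species) return(tr$states[, out])
    if (out == "OUR") return(tr$fluxes[, "V_resp"] * tr$states[, "Xv"] * 1000)
    if (grepl("/", out, fixed = TRUE)) {
      parts <- strsplit(out, "/", fixed = TRUE)[[1]]
      if (all(parts %in% tr$species)) {
        den <- tr$states[, parts[2]]
        return(ifelse(den > 0, tr$states[, parts[1]] / den, NA_real_))
      }
    }
    stop("unknown observable: ", out, call. = FALSE)
  }
  cols <- lapply(outputs, function(out) {
    stats::approx(tr$times, series_for(out), xout = times, ties = "ordered")$y
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(NULL, outputs)
  m
}
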