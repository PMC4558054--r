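# Dynamic metabolic flux analysis: flux trajectories along a simulated
# culture, the derived flux sums and ratios (ammonia production, TCA influx,
# net ATP production and the contribution fractions), inhibition-term time
# courses, and delta-method confidence bands on fluxes propagated from the
# calibration covariance.

#' Derived flux definitions
#'
#' Data-driven definitions of the derived flux sums and ratios. Sums are
#' linear combinations over reaction fluxes (e.g. ammonia production
#' `V_GLDH + V_GlnT + V_SDHH + V_ASN + V_HISARGTA`; TCA influx
#' `V_GLDH + V_PDH + V_AlaTA + V_PC + 5*V_AAtoSUC`; net ATP production
#' `V_PGK + V_PK + V_AKGDH + V_PC + V_GlnT + 2*2.5*V_resp`). Ratios divide a
#' sum (or single flux) by another. Note the net-ATP convention counts
#' `V_GlnT` and `V_PC` as written in the source figure definitions even
#' though this is biochemically surprising; the definitions are data, so
#' alternative conventions are a file edit away.
#'
#' @param path Optional YAML path; defaults to the shipped definitions.
#' @return List with `sums` (named coefficient maps) and `ratios` (named
#'   `num`/`den` pairs).
#' @export
derived_flux_definitions <- function(path = NULL) {
  if (is.null(path)) path <- choflux_file("derived_fluxes.yaml")
  defs <- yaml::read_yaml(path)
  defs$sums <- lapply(defs$sums, unlist)
  defs
}

#' Re-evaluate fluxes along a trajectory
#'
#' Recomputes every reaction rate from the stored states, independently of the
#' flux series the simulator recorded, and checks both agree.
#'
#' @param trajectory `SimulationTrajectory`.
#' @param network,params Model and parameters used for the simulation.
#' @param tol Consistency tolerance (relative).
#' @return A `FluxTrajectory`: list with `times` and `fluxes` (matrix,
#'   reactions in columns).
#' @export
evaluate_fluxes <- function(trajectory, network, params, tol = 1e-12) {
  comp <- as_compiled(network, params)
  pv <- unname(param_values(params)[comp$param_names])
  fl <- flux_matrix_along(comp, trajectory$states, pv)
  if (!is.null(trajectory$fluxes)) {
    rel <- abs(fl - trajectory$fluxes) / pmax(abs(trajectory$fluxes), 1e-300)
    if (max(rel) > tol) {
      warning("re-evaluated fluxes deviate from stored fluxes (max rel ",
              format(max(rel), digits = 3), ")")
    }
  }
  structure(list(times = trajectory$times, fluxes = fl),
            class = "FluxTrajectory")
}

flux_matrix <- function(fluxes) {
  if (is.matrix(fluxes)) return(fluxes)
  if (!is.null(fluxes$fluxes)) return(fluxes$fluxes)
  stop("cannot extract a flux matrix", call. = FALSE)
}

#' Evaluate a derived flux sum
#'
#' @param fluxes Flux matrix (reactions in columns), `SimulationTrajectory`
#'   or `FluxTrajectory`.
#' @param definition Named coefficient vector over reaction ids, or the name
#'   of a shipped sum definition.
#' @param defs Definitions list (defaults to the shipped file).
#' @return Numeric series (one value per trajectory time).
#' @export
derived_flux <- function(fluxes, definition, defs = derived_flux_definitions()) {
  fl <- flux_matrix(fluxes)
  co <- if (is.character(definition) && length(definition) == 1L) {
    if (definition %in% colnames(fl)) {
      stats::setNames(1, definition)
    } else {
      d <- defs$sums[[definition]]
      if (is.null(d)) stop("unknown derived flux: ", definition, call. = FALSE)
      d
    }
  } else definition
  miss <- setdiff(names(co), colnames(fl))
  if (length(miss)) stop("derived flux references unknown reaction(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  as.numeric(fl[, names(co), drop = FALSE] %*% unname(co))
}

#' Ammonia production flux series
#'
#' `V_GLDH + V_GlnT + V_SDHH + V_ASN + V_HISARGTA`.
#' @inheritParams derived_flux
#' @return Numeric series.
#' @export
ammonia_production <- function(fluxes) derived_flux(fluxes, "ammonia_production")

#' Total TCA-cycle influx series
#'
#' `V_GLDH + V_PDH + V_AlaTA + V_PC + 5*V_AAtoSUC`.
#' @inheritParams derived_flux
#' @return Numeric series.
#' @export
tca_influx <- function(fluxes) derived_flux(fluxes, "tca_influx")

#' Net ATP production series
#'
#' `V_PGK + V_PK + V_AKGDH + V_PC + V_GlnT + 2*2.5*V_resp`.
#' @inheritParams derived_flux
#' @return Numeric series.
#' @export
net_atp_production <- function(fluxes) derived_flux(fluxes, "net_atp_production")

#' Derived flux ratio series
#'
#' Evaluates the shipped ratio definitions (amino-acid / PDH / PC
#' contributions to the TCA influx, glycolytic and respiratory shares of net
#' ATP production, and the PDH/PK and LDH/PK ratios). Time points with a
#' non-positive denominator are reported as `NA` (undefined), never as 0.
#'
#' @inheritParams derived_flux
#' @return Data frame, one column per ratio.
#' @export
flux_ratios <- function(fluxes, defs = derived_flux_definitions()) {
  fl <- flux_matrix(fluxes)
  out <- lapply(defs$ratios, function(r) {
    num <- derived_flux(fl, r$num, defs)
    den <- derived_flux(fl, r$den, defs)
    ifelse(den > 0, num / den, NA_real_)
  })
  as.data.frame(out)
}

#' Inhibition-term time course
#'
#' Evaluates the non-competitive inhibition factor `1/(1 + I(t)/K)` of an
#' effector along a trajectory — e.g. the lactate term on phosphofructokinase
#' or the ammonia term in the growth rate.
#'
#' @param trajectory `SimulationTrajectory`.
#' @param effector Species id whose concentration drives the term.
#' @param K Inhibition constant, or the name of a parameter in `params`.
#' @param params Parameter set (needed when `K` is a name).
#' @return Numeric series in `(0, 1]`.
#' @export
inhibition_term_course <- function(trajectory, effector, K, params = NULL) {
  if (is.character(K)) {
    pv <- param_values(params)
    if (!K %in% names(pv)) stop("unknown inhibition constant: ", K, call. = FALSE)
    K <- pv[[K]]
  }
  if (!effector %in% colnames(trajectory$states)) {
    stop("unknown inhibition effector: ", effector, call. = FALSE)
  }
  inhibition_factor(trajectory$states[, effector], K)
}

#' Delta-method confidence bands for fluxes and derived quantities
#'
#' Propagates the calibration covariance of the free parameters to any flux
#' or derived quantity: `value +/- t * sqrt(g' Sigma g)` with `g` the central
#' finite-difference gradient of the quantity with respect to the free
#' parameters (each simulation re-run at the perturbed parameter vector).
#'
#' @param network,params Model and calibrated parameter values.
#' @param experiment Culture to simulate.
#' @param times Evaluation times (h), default 48 and 96.
#' @param covariance Free-parameter covariance (from a `CalibrationResult`).
#' @param free Free-parameter names (order matching `covariance`).
#' @param quantities Reaction ids and/or derived sum/ratio names; default all
#'   reactions plus all derived sums and ratios.
#' @param df Degrees of freedom for the t quantile.
#' @param level Confidence level.
#' @param rel_step Relative finite-difference step.
#' @param ... Passed to the simulator.
#' @return Tidy data frame: `time`, `quantity`, `value`, `ci_low`, `ci_high`.
#' @export
flux_confidence <- function(network, params, experiment, covariance, free,
                            times = c(48, 96), quantities = NULL, df = Inf,
                            level = 0.95, rel_step = 1e-4, ...) {
  defs <- derived_flux_definitions()
  comp <- as_compiled(network, params)
  if (is.null(quantities)) {
    quantities <- c(comp$reaction_ids, names(defs$sums), names(defs$ratios))
  }
  pv <- param_values(params)
  eval_quantities <- function(p) {
    tr <- simulate_culture(comp, p, experiment, output_times = times, ...)
    idx <- vapply(times, function(tt) which.min(abs(tr$times - tt)), 1L)
    fl <- tr$fluxes[idx, , drop = FALSE]
    m <- vapply(quantities, function(q) {
      if (q %in% names(defs$ratios)) {
        r <- defs$ratios[[q]]
        num <- derived_flux(fl, r$num, defs)
        den <- derived_flux(fl, r$den, defs)
        ifelse(den > 0, num / den, NA_real_)
      } else derived_flux(fl, q, defs)
    }, numeric(length(times)))
    if (length(times) == 1L) m <- matrix(m, 1L,
                                         dimnames = list(NULL, quantities))
    m
  }
  base <- eval_quantities(pv)
  grads <- array(NA_real_, c(length(times), length(quantities), length(free)))
  for (i in seq_along(free)) {
    h <- rel_step * max(abs(pv[[free[i]]]), 1e-300)
    pp <- pv; pp[free[i]] <- pp[free[i]] + h
    pm <- pv; pm[free[i]] <- max(pm[free[i]] - h, 0)
    vp <- eval_quantities(pp); vm <- eval_quantities(pm)
    grads[, , i] <- (vp - vm) / (pp[free[i]] - pm[free[i]])
  }
  tcrit <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df)
  else stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  singular <- !all(is.finite(covariance))
  for (ti in seq_along(times)) {
    for (qi in seq_along(quantities)) {
      g <- grads[ti, qi, ]
      half <- if (singular || any(!is.finite(g))) Inf
      else tcrit * sqrt(max(drop(t(g) %*% covariance %*% g), 0))
      rows[[length(rows) + 1L]] <- data.frame(
        time = times[ti], quantity = quantities[qi],
        value = base[ti, qi],
        ci_low = base[ti, qi] - half, ci_high = base[ti, qi] + half)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
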