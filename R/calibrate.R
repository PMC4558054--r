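# Weighted nonlinear least-squares calibration of the sensitive-parameter
# subset. The objective is the sigma-weighted sum of squared residuals over
# all cultures and sampling times; free parameters are normalized to their
# order of magnitude, bounded below by 0, and optimized with bounded
# Levenberg-Marquardt. Confidence intervals are linearized (Wald):
# covariance s^2 (J'J)^{-1} at the optimum.

#' Restrict measurements to the usable data window
#'
#' Keeps records from 24 h after inoculation up to the last time each
#' culture's viability is still at or above 95%; the model does not describe
#' the decline phase, so later data are excluded. Optional phase schemes
#' further restrict to before or after the 72 h mid-exponential split.
#' Censored records (below the limit of detection) are dropped.
#'
#' @param measurements Measurement table (`culture`, `output`, `time_h`,
#'   `value`, `sd`, optional `censored`).
#' @param viability Viability table (`culture`, `time_h`, `viability_pct`);
#'   every culture in `measurements` must appear.
#' @param phase `"all"`, `"phase1"` (< 72 h) or `"phase2"` (>= 72 h).
#' @param start_h,viability_cutoff,phase_split_h Window rule constants.
#' @return Filtered measurement table.
#' @export
window_measurements <- function(measurements, viability,
                                phase = c("all", "phase1", "phase2"),
                                start_h = 24, viability_cutoff = 95,
                                phase_split_h = 72) {
  phase <- match.arg(phase)
  keep <- logical(nrow(measurements))
  for (cu in unique(measurements$culture)) {
    vb <- viability[viability$culture == cu, ]
    if (!nrow(vb)) stop("no viability series for culture ", cu, call. = FALSE)
    below <- vb$time_h[vb$viability_pct < viability_cutoff]
    t_end <- if (length(below)) min(below) else Inf
    rows <- measurements$culture == cu
    keep[rows] <- measurements$time_h[rows] >= start_h &
      measurements$time_h[rows] <= t_end
  }
  if (!is.null(measurements$censored)) keep <- keep & !measurements$censored
  if (phase == "phase1") keep <- keep & measurements$time_h < phase_split_h
  if (phase == "phase2") keep <- keep & measurements$time_h >= phase_split_h
  measurements[keep, , drop = FALSE]
}

#' Weighted sum-of-squares calibration objective
#'
#' `sum(((y_exp - y_model)/sigma)^2)` over every measurement record. A
#' simulation failure returns the penalty value (default 1e12) with a
#' `failed` attribute instead of raising, so the optimizer stays alive.
#'
#' @param params Full named parameter vector (or `ParameterSet`).
#' @param network,experiments,measurements As in [predict_measurements()].
#' @param penalty Value returned on simulation failure.
#' @param ... Passed to the simulator.
#' @return Scalar weighted SSR.
#' @export
calibration_objective <- function(params, network, experiments, measurements,
                                  penalty = 1e12, ...) {
  pred <- tryCatch(
    predict_measurements(network, param_values(params), experiments,
                         measurements, ...),
    error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) {
    return(structure(penalty, failed = TRUE))
  }
  sum(((measurements$value - pred) / measurements$sd)^2)
}

#' Order-of-magnitude parameter normalization
#'
#' Scales each value by `10^-n` using its magnitude exponent so every free
#' parameter is O(1) during optimization; `denormalize_params()` inverts it
#' exactly.
#'
#' @param values Named numeric vector.
#' @param exponents Named integer vector of magnitude exponents `n` (covering
#'   `names(values)`).
#' @return Scaled vector.
#' @export
normalize_params <- function(values, exponents) {
  values / 10^exponents[names(values)]
}

#' @rdname normalize_params
#' @param scaled Scaled vector to map back to the natural scale.
#' @export
denormalize_params <- function(scaled, exponents) {
  scaled * 10^exponents[names(scaled)]
}

magnitude_exponents <- function(params, free) {
  if (is.data.frame(params)) {
    stats::setNames(params$magnitude_exponent, params$name)[free]
  } else {
    stats::setNames(floor(log10(abs(param_values(params)[free]))), free)
  }
}

#' Fit the sensitive-parameter subset
#'
#' Bounded Levenberg-Marquardt least squares (\code{minpack.lm::nls.lm}) on
#' the normalized free parameters, all other parameters frozen at their
#' supplied values. Lower bounds are 0 throughout. Returns the estimates on
#' the natural scale together with the residuals, the finite-difference
#' Jacobian at the optimum and the linearized covariance.
#'
#' @param network Model network.
#' @param experiments Named list of `CultureExperiment`s.
#' @param measurements Windowed measurement table.
#' @param params `ParameterSet` (start values, magnitude exponents, bounds).
#' @param free Character vector of free parameter names; defaults to the
#'   table's `sensitive_flag` subset.
#' @param start Optional named start values overriding the table (e.g. the
#'   all-data estimates when fitting subsets).
#' @param maxiter Optimizer iteration cap.
#' @param penalty Objective value substituted on simulation failure.
#' @param ... Passed to the simulator (tolerances etc.).
#' @return A `CalibrationResult` list: `estimates`, `free`, `ssr`,
#'   `residuals`, `jacobian` (normalized scale), `covariance` (natural
#'   scale), `df`, `converged`, `n_obs`, `exponents`, `params_full`.
#' @export
fit_parameters <- function(network, experiments, measurements, params,
                           free = NULL, start = NULL, maxiter = 50L,
                           penalty = 1e6, ...) {
  pv <- param_values(params)
  if (is.null(free)) {
    if (!is.data.frame(params)) {
      stop("free parameter subset required when params is not a table",
           call. = FALSE)
    }
    free <- params$name[params$sensitive_flag == 1]
  }
  stopifnot(all(free %in% names(pv)))
  if (!is.null(start)) pv[names(start)] <- start
  expo <- magnitude_exponents(params, free)
  lower <- if (is.data.frame(params)) {
    stats::setNames(params$lower_bound, params$name)[free]
  } else rep(0, length(free))
  upper <- if (is.data.frame(params)) {
    stats::setNames(params$upper_bound, params$name)[free]
  } else rep(Inf, length(free))
  comp <- as_compiled(network, pv)
  dots <- list(...)
  n_obs <- nrow(measurements)

  resid_fn <- function(theta) {
    full <- pv
    full[free] <- denormalize_params(stats::setNames(theta, free), expo)
    pred <- tryCatch(
      do.call(predict_measurements,
              c(list(comp, full, experiments, measurements), dots)),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(sqrt(penalty / n_obs), n_obs))
    }
    (measurements$value - pred) / measurements$sd
  }

  theta0 <- unname(normalize_params(pv[free], expo))
  # the iteration-cap notice is recorded in `converged`/`info`, not raised
  opt <- withCallingHandlers(
    minpack.lm::nls.lm(
      par = theta0, lower = unname(normalize_params(lower, expo)),
      upper = unname(ifelse(is.finite(upper),
                            normalize_params(upper, expo), Inf)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
    warning = function(w) {
      if (grepl("maxiter", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  theta_hat <- stats::setNames(opt$par, free)
  est <- denormalize_params(theta_hat, expo)
  resid <- resid_fn(opt$par)
  ssr <- sum(resid^2)
  J <- numeric_jacobian(resid_fn, opt$par)
  df <- n_obs - length(free)
  cov_norm <- tryCatch({
    JtJ <- crossprod(J)
    s2 <- ssr / df
    s2 * solve(JtJ)
  }, error = function(e) NULL)
  cov_nat <- if (!is.null(cov_norm)) {
    sc <- 10^expo
    cov_norm * tcrossprod(sc)
  }
  full <- pv
  full[free] <- est
  structure(list(estimates = est, free = free, ssr = ssr,
                 residuals = resid, jacobian = J,
                 covariance = cov_nat, df = df,
                 converged = opt$info %in% 1:4,
                 info = opt$message, n_obs = n_obs,
                 exponents = expo, params_full = full),
            class = "CalibrationResult")
}

# central finite-difference Jacobian (relative step) of a residual function
numeric_jacobian <- function(fn, theta, rel_step = 1e-4) {
  f0 <- fn(theta)
  J <- matrix(NA_real_, length(f0), length(theta))
  for (i in seq_along(theta)) {
    h <- rel_step * max(abs(theta[i]), 1e-8)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- max(tm[i] - h, 0)
    J[, i] <- (fn(tp) - fn(tm)) / (tp[i] - tm[i])
  }
  J
}

#' Linearized parameter confidence intervals
#'
#' Wald intervals from the Jacobian at the least-squares optimum:
#' `estimate +/- t(1 - (1-level)/2, N - k) * se` with
#' `se^2 = diag(s^2 (J'J)^{-1})`, `s^2 = SSR/(N - k)`. Rank-deficient
#' Jacobians flag the affected parameters with infinite intervals.
#'
#' @param result A `CalibrationResult`.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `parameter`, `estimate`, `ci_low`, `ci_high`, `se`,
#'   `identifiable`.
#' @export
confidence_intervals <- function(result, level = 0.95) {
  est <- result$estimates
  k <- length(est)
  tcrit <- stats::qt(1 - (1 - level) / 2, result$df)
  J <- result$jacobian
  rank_ok <- qr(J)$rank == k
  if (!is.null(result$covariance) && rank_ok) {
    se_nat <- sqrt(pmax(diag(result$covariance), 0))
    ident <- rep(TRUE, k)
  } else {
    se_nat <- rep(Inf, k)
    ident <- rep(FALSE, k)
    if (rank_ok && is.null(result$covariance)) ident[] <- FALSE
  }
  data.frame(parameter = names(est), estimate = unname(est),
             ci_low = unname(est - tcrit * se_nat),
             ci_high = unname(est + tcrit * se_nat),
             se = unname(se_nat), identifiable = ident,
             row.names = NULL)
}

#' Do two confidence intervals overlap?
#' @param a,b Length-2 numeric vectors `(low, high)`.
#' @return Logical.
#' @export
ci_overlap <- function(a, b) max(a[1], b[1]) <= min(a[2], b[2])

#' Compare calibrations across data subsets
#'
#' Reproduces the subset-comparison scheme: the all-data fit is run first and
#' its estimates seed the subset fits (by culture mode, by medium, or by
#' growth phase). For every parameter and subset pair, interval overlap
#' decides whether the estimates differ significantly.
#'
#' @param network,experiments,params As in [fit_parameters()].
#' @param measurements Un-windowed measurement table.
#' @param viability Viability table used for windowing.
#' @param schemes Named list; each element selects a data subset, either a
#'   character vector of culture names or a list with `cultures` and/or
#'   `phase`. The special name `all` (always run first) uses every culture.
#' @param free Free-parameter subset (default: table's sensitive flags).
#' @param level Confidence level for the overlap verdicts.
#' @param ... Passed through to [fit_parameters()].
#' @return List with `fits` (per scheme `CalibrationResult`), `intervals`
#'   (long data frame with a `scheme` column), and `overlap` (pairwise
#'   verdicts per parameter).
#' @export
subset_comparison <- function(network, experiments, measurements, viability,
                              params, schemes = NULL, free = NULL,
                              level = 0.95, ...) {
  if (is.null(schemes)) {
    cultures <- names(experiments)
    is_fb <- grepl("fedbatch", cultures)
    is_biogro <- grepl("biogro", cultures)
    schemes <- list(all = cultures,
                    batch = cultures[!is_fb],
                    fedbatch = cultures[is_fb],
                    biogro = cultures[is_biogro],
                    powercho = cultures[!is_biogro])
  }
  if (!"all" %in% names(schemes)) {
    schemes <- c(list(all = unique(measurements$culture)), schemes)
  }
  fits <- list(); ivals <- list()
  seed_start <- NULL
  for (nm in c("all", setdiff(names(schemes), "all"))) {
    sch <- schemes[[nm]]
    cultures <- if (is.list(sch)) sch$cultures %||% unique(measurements$culture)
    else sch
    phase <- if (is.list(sch)) sch$phase %||% "all" else "all"
    mw <- window_measurements(
      measurements[measurements$culture %in% cultures, , drop = FALSE],
      viability, phase = phase)
    if (!nrow(mw)) {
      warning("scheme ", nm, " has no data after windowing; skipped")
      next
    }
    ft <- fit_parameters(network, experiments[cultures], mw, params,
                         free = free, start = seed_start, ...)
    fits[[nm]] <- ft
    ci <- confidence_intervals(ft, level)
    ci$scheme <- nm
    ivals[[nm]] <- ci
    if (nm == "all") seed_start <- ft$estimates
  }
  intervals <- do.call(rbind, ivals)
  rownames(intervals) <- NULL
  sch_names <- names(fits)
  pairs <- if (length(sch_names) > 1) utils::combn(sch_names, 2) else NULL
  overlap <- NULL
  if (!is.null(pairs)) {
    rows <- list()
    for (pc in seq_len(ncol(pairs))) {
      a <- ivals[[pairs[1, pc]]]; b <- ivals[[pairs[2, pc]]]
      for (prm in a$parameter) {
        ra <- a[a$parameter == prm, ]; rb <- b[b$parameter == prm, ]
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = prm, scheme_a = pairs[1, pc], scheme_b = pairs[2, pc],
          overlap = ci_overlap(c(ra$ci_low, ra$ci_high),
                               c(rb$ci_low, rb$ci_high)))
      }
    }
    overlap <- do.call(rbind, rows)
  }
  list(fits = fits, intervals = intervals, overlap = overlap)
}
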