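# Morris elementary-effects screening. Each parameter is perturbed on a
# 4-level grid spanning +/-25% of its nominal value (unit-scaled to [0,1] with
# step Delta = levels/(2*(levels-1)) = 2/3), along r randomised one-at-a-time
# trajectories. The mean of a parameter's elementary effects measures its
# global influence on the screening objective; the standard deviation flags
# nonlinearity/interaction.

#' Construct a Morris screening design
#'
#' @param parameters Character vector of parameter names to screen.
#' @param nominal Named numeric vector of nominal values (must cover
#'   `parameters`).
#' @param bound_fraction Half-width of the screening box as a fraction of the
#'   nominal value (default 0.25, i.e. +/-25%).
#' @param levels Number of grid levels (default 4).
#' @param delta Step on the unit-scaled grid; defaults to the canonical
#'   `levels / (2 * (levels - 1))` (2/3 for 4 levels).
#' @param reps Number of trajectories, one elementary effect per parameter
#'   each (default 35).
#' @param seed Integer seed; the design is fully reproducible from it.
#' @return A `MorrisDesign` list.
#' @export
morris_design <- function(parameters, nominal, bound_fraction = 0.25,
                          levels = 4L, delta = levels / (2 * (levels - 1)),
                          reps = 35L, seed = 1L) {
  nominal <- param_values(nominal)
  miss <- setdiff(parameters, names(nominal))
  if (length(miss)) stop("no nominal value for: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  structure(list(parameters = parameters,
                 nominal = nominal[parameters],
                 bound_fraction = bound_fraction, levels = as.integer(levels),
                 delta = delta, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "MorrisDesign")
}

#' Elementary effect of one parameter
#'
#' Finite-difference sensitivity `(f(p + delta * e_i) - f(p)) / delta` along
#' axis `i`. Both the base point and the stepped point must lie inside the
#' design region.
#'
#' @param f Scalar function of a parameter vector.
#' @param p Base point (on the scale `f` expects; unit scale within the
#'   screening design).
#' @param i Parameter index to step.
#' @param delta Signed step.
#' @param lower,upper Bounds of the design region (recycled).
#' @return The elementary effect value.
#' @export
elementary_effect <- function(f, p, i, delta, lower = 0, upper = 1) {
  p2 <- p
  p2[i] <- p2[i] + delta
  eps <- 1e-12
  if (any(p < lower - eps | p > upper + eps) ||
      p2[i] < lower - eps || p2[i] > upper + eps) {
    stop("elementary effect step leaves the design region", call. = FALSE)
  }
  (f(p2) - f(p)) / delta
}

# map unit-scale design point to natural parameter values
morris_unit_to_natural <- function(design, u) {
  design$nominal * (1 - design$bound_fraction + 2 * design$bound_fraction * u)
}

#' Build randomised Morris trajectories
#'
#' Each trajectory starts at a random grid point and steps each parameter
#' once, in random order and random direction, by `delta` on the unit-scaled
#' grid, giving `k + 1` model evaluations and one elementary effect per
#' parameter. Same seed, same design.
#'
#' @param design A `MorrisDesign`.
#' @return List of trajectories; each has `points` (a `(k+1) x k` matrix of
#'   unit-scale coordinates), `order` (parameter index stepped at each move)
#'   and `sign` (step direction).
#' @export
build_trajectories <- function(design) {
  k <- length(design$parameters)
  grid <- seq(0, 1, length.out = design$levels)
  d <- design$delta
  lowset <- grid[grid + d <= 1 + 1e-12]   # starts allowing a +delta step
  highset <- grid[grid - d >= -1e-12]     # starts allowing a -delta step
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(design$seed)
  lapply(seq_len(design$reps), function(rep) {
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    base <- vapply(sgn, function(s)
      sample(if (s > 0) lowset else highset, 1L), 1.0)
    ord <- sample.int(k)
    pts <- matrix(0, k + 1L, k)
    pts[1, ] <- base
    x <- base
    for (m in seq_len(k)) {
      x[ord[m]] <- x[ord[m]] + sgn[ord[m]] * d
      pts[m + 1L, ] <- x
    }
    list(points = pts, order = ord, sign = sgn)
  })
}

#' Elementary effects of an arbitrary scalar function
#'
#' Runs the Morris design against `f` (evaluated on the natural parameter
#' scale; effects are computed on the unit-scaled axis). Evaluation failures
#' (errors or non-finite values) skip the affected effects and are counted.
#'
#' @param f Scalar function of a full named parameter vector.
#' @param design A `MorrisDesign`.
#' @return A `MorrisResult` data frame: `parameter`, `mean_ee`, `sd_ee`,
#'   `n_ee`, `rank` (by `|mean_ee|`), with attributes `n_failures` and
#'   `design`.
#' @export
morris_ee <- function(f, design) {
  trajs <- build_trajectories(design)
  k <- length(design$parameters)
  ee <- matrix(NA_real_, design$reps, k)
  n_fail <- 0L
  for (r in seq_along(trajs)) {
    tr <- trajs[[r]]
    fx <- rep(NA_real_, k + 1L)
    for (m in seq_len(k + 1L)) {
      val <- tryCatch(f(morris_unit_to_natural(design, tr$points[m, ])),
                      error = function(e) NA_real_)
      if (!is.finite(val)) { n_fail <- n_fail + 1L; val <- NA_real_ }
      fx[m] <- val
    }
    for (m in seq_len(k)) {
      i <- tr$order[m]
      ee[r, i] <- (fx[m + 1L] - fx[m]) / (tr$sign[i] * design$delta)
    }
  }
  res <- data.frame(
    parameter = design$parameters,
    mean_ee = colMeans(ee, na.rm = TRUE),
    sd_ee = apply(ee, 2, stats::sd, na.rm = TRUE),
    n_ee = colSums(!is.na(ee)))
  res$rank <- rank(-abs(res$mean_ee), ties.method = "first")
  res <- res[order(res$rank), ]
  rownames(res) <- NULL
  attr(res, "n_failures") <- n_fail
  attr(res, "design") <- design
  class(res) <- c("MorrisResult", "data.frame")
  res
}

#' Model predictions aligned with a measurement table
#'
#' Simulates each culture present in `measurements` once and interpolates the
#' requested observables at the measured times.
#'
#' @param network,params Model and parameter values.
#' @param experiments Named list of `CultureExperiment`s (names match the
#'   `culture` column).
#' @param measurements Measurement data frame (`culture`, `output`, `time_h`,
#'   `value`, `sd`).
#' @param ... Passed to [simulate_culture()].
#' @return Numeric vector of model values, one per measurement row.
#' @export
predict_measurements <- function(network, params, experiments, measurements,
                                 ...) {
  pred <- rep(NA_real_, nrow(measurements))
  for (cu in unique(measurements$culture)) {
    ex <- experiments[[cu]]
    if (is.null(ex)) stop("no experiment definition for culture ", cu,
                          call. = FALSE)
    rows <- which(measurements$culture == cu)
    tt <- measurements$time_h[rows]
    outs <- unique(measurements$output[rows])
    tr <- simulate_culture(network, params, ex,
                           output_times = sort(unique(tt)), ...)
    m <- observe(tr, outs, sort(unique(tt)))
    ti <- match(tt, sort(unique(tt)))
    oi <- match(measurements$output[rows], outs)
    pred[rows] <- m[cbind(ti, oi)]
  }
  pred
}

#' Sensitivity screening objective
#'
#' The scalar output screened by Morris: the mean over all measured outputs
#' and sampling times of the absolute standard-deviation-weighted model value
#' `|y_model / sigma|` — the same weighting the calibration objective uses.
#'
#' @param predictions Model values aligned with `measurements` rows.
#' @param measurements Measurement table carrying the `sd` column.
#' @return Scalar objective value.
#' @export
scalar_objective <- function(predictions, measurements) {
  if (is.null(measurements$sd) || any(!is.finite(measurements$sd)) ||
      any(measurements$sd <= 0)) {
    stop("measurements must carry finite positive standard deviations",
         call. = FALSE)
  }
  mean(abs(predictions / measurements$sd))
}

#' Morris screening of the kinetic model
#'
#' Computes per-parameter elementary-effect means and standard deviations of
#' the screening objective ([scalar_objective()]) across the design, ranking
#' parameters by `|mean|`. Simulation failures at design points are skipped
#' and counted in the `n_failures` attribute.
#'
#' @param network Model network.
#' @param params `ParameterSet` (nominal values; design box is +/-25% around
#'   them).
#' @param experiments Named list of `CultureExperiment`s.
#' @param measurements Measurement table (defines outputs, times and sigma
#'   weights).
#' @param design `MorrisDesign`; defaults to screening every parameter with
#'   the standard settings.
#' @param ... Passed to [simulate_culture()] (e.g. solver tolerances).
#' @return `MorrisResult` (see [morris_ee()]).
#' @export
morris_screen <- function(network, params, experiments, measurements,
                          design = NULL, ...) {
  pv <- param_values(params)
  if (is.null(design)) design <- morris_design(names(pv), pv)
  comp <- as_compiled(network, params)
  dots <- list(...)
  f <- function(p_natural) {
    full <- pv
    full[names(p_natural)] <- p_natural
    pred <- do.call(predict_measurements,
                    c(list(comp, full, experiments, measurements), dots))
    scalar_objective(pred, measurements)
  }
  morris_ee(f, design)
}

#' Select the sensitive-parameter subset
#'
#' Parameters whose absolute mean elementary effect reaches `threshold`,
#' capped at `max_count` by rank. An empty selection falls back (with a
#' warning) to the top `max_count`.
#'
#' @param result `MorrisResult` (or any data frame with `parameter`,
#'   `mean_ee` and `rank`).
#' @param threshold Minimum `|mean_ee|` (default 0.6).
#' @param max_count Cap on the subset size (default 20).
#' @return Character vector of parameter names, ordered by rank.
#' @export
select_sensitive <- function(result, threshold = 0.6, max_count = 20L) {
  res <- result[order(result$rank), ]
  sel <- res$parameter[abs(res$mean_ee) >= threshold]
  if (!length(sel)) {
    warning("no parameter reaches |mean EE| >= ", threshold,
            "; returning the top ", max_count, " by rank")
    sel <- res$parameter
  }
  utils::head(sel, max_count)
}
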