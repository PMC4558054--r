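# Synthetic pseudo-experimental data with the statistical structure of the
# study cultures: daily (or 12-hourly) sampling, multiplicative measurement
# noise whose magnitude scales with the signal, per-class coefficients of
# variation, limit-of-detection censoring of low intracellular species, and a
# viability series that stays at 100% until a configurable decline onset so
# the data-window rule is exercised.

#' Measurement noise model
#'
#' Multiplicative truncated-Gaussian noise: `value = truth * (1 + cv * z)`,
#' `z ~ N(0,1)`, truncated at 0. The per-class coefficients of variation are
#' configurable; the reported standard deviation column is `cv * truth`
#' (floored at a small per-class assay scale so weights stay finite near
#' zero). Species with a limit of detection produce censored records when the
#' underlying value is below it.
#'
#' @param cv_extracellular,cv_intracellular,cv_cells CVs for extracellular
#'   species, intracellular pools/ratios, and cells/mAb (defaults 10%, 15%,
#'   10%).
#' @param lod Named vector of limits of detection per observable.
#' @return A `NoiseModel` list.
#' @export
noise_model <- function(cv_extracellular = 0.10, cv_intracellular = 0.15,
                        cv_cells = 0.10, lod = numeric(0)) {
  stopifnot(cv_extracellular >= 0, cv_intracellular >= 0, cv_cells >= 0,
            all(lod >= 0))
  structure(list(cv_extracellular = cv_extracellular,
                 cv_intracellular = cv_intracellular,
                 cv_cells = cv_cells, lod = lod),
            class = "NoiseModel")
}

# observable -> (cv, sd floor) classification
output_noise_class <- function(output, network, noise) {
  mets <- if (is.list(network) && !is.null(network$kin)) {
    data.frame(id = network$species, compartment = network$compartment)
  } else network$metabolites
  comp <- mets$compartment[match(output, mets$id)]
  if (!is.na(comp)) {
    switch(comp,
           extracellular = c(noise$cv_extracellular, 0.05),
           intracellular = c(noise$cv_intracellular, 1e-9),
           cells = c(noise$cv_cells, 0.02),
           product = c(noise$cv_cells, 0.5),
           c(noise$cv_extracellular, 1e-6))
  } else if (output == "OUR") {
    c(noise$cv_extracellular, 1e-5)
  } else if (grepl("/", output, fixed = TRUE)) {
    c(noise$cv_intracellular, 0.005)
  } else {
    stop("cannot classify observable for noise: ", output, call. = FALSE)
  }
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic measurement set for one culture
#'
#' Simulates the experiment, samples the observables on the schedule, applies
#' multiplicative noise and LOD censoring, and returns the noisy measurement
#' table together with the noiseless truth and the generating parameters.
#' Bitwise reproducible for a fixed seed.
#'
#' @param network,params Model and generating parameter values.
#' @param experiment `CultureExperiment`; its `sampling_interval` field (12 or
#'   24 h) sets the default schedule.
#' @param schedule Optional vector of sampling times (h), overriding the
#'   interval rule.
#' @param noise `NoiseModel`.
#' @param outputs Observables to sample (default [default_outputs()], toy
#'   networks: pass their species).
#' @param seed Integer seed.
#' @param ... Passed to the simulator.
#' @return List: `measurements` (culture, output, time_h, value, sd,
#'   censored), `truth` (same rows, noiseless value), `params`.
#' @export
generate_dataset <- function(network, params, experiment, schedule = NULL,
                             noise = noise_model(), outputs = default_outputs(),
                             seed = 1L, ...) {
  if (is.null(schedule)) {
    interval <- experiment$sampling_interval %||% 24
    schedule <- seq(0, experiment$duration, by = interval)
  }
  tr <- simulate_culture(network, params, experiment,
                         output_times = schedule, ...)
  truth <- observe(tr, outputs, schedule)
  cls <- vapply(outputs, output_noise_class, numeric(2),
                network = network, noise = noise)
  tab <- with_seed(seed, {
    rows <- list()
    for (oi in seq_along(outputs)) {
      cv <- cls[1, oi]; floor_sd <- cls[2, oi]
      tv <- truth[, oi]
      z <- stats::rnorm(length(schedule))
      val <- pmax(tv * (1 + cv * z), 0)
      if (cv == 0) val <- tv
      sdv <- if (cv > 0) cv * pmax(abs(tv), floor_sd) else rep(1, length(tv))
      lod <- noise$lod[outputs[oi]]
      cens <- if (!is.na(lod)) tv < lod else rep(FALSE, length(tv))
      rows[[oi]] <- data.frame(
        culture = experiment$name %||% "culture",
        output = outputs[oi], time_h = schedule,
        value = ifelse(cens, NA_real_, val),
        sd = sdv, censored = cens,
        value_true = tv)
    }
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  list(measurements = tab[, c("culture", "output", "time_h", "value", "sd",
                              "censored")],
       truth = tab[, c("culture", "output", "time_h", "value_true")],
       params = param_values(params))
}

#' Synthetic viability series
#'
#' 100% viability until `onset_h`, then a linear decline at `rate_pct_h`
#' percent per hour — enough structure to exercise the 95%-viability data
#' window without modelling death kinetics (which the model deliberately
#' excludes).
#'
#' @param experiment `CultureExperiment`.
#' @param onset_h Decline onset (default 65% of the culture duration).
#' @param rate_pct_h Decline rate (%/h).
#' @param interval Sampling interval (h).
#' @return Data frame: `culture`, `time_h`, `viability_pct`.
#' @export
generate_viability <- function(experiment, onset_h = NULL, rate_pct_h = 0.25,
                               interval = NULL) {
  if (is.null(interval)) interval <- experiment$sampling_interval %||% 24
  if (is.null(onset_h)) onset_h <- 0.65 * experiment$duration
  tt <- seq(0, experiment$duration, by = interval)
  vb <- pmax(100 - pmax(tt - onset_h, 0) * rate_pct_h, 0)
  data.frame(culture = experiment$name %||% "culture", time_h = tt,
             viability_pct = vb)
}

#' Generate the full four-culture synthetic study
#'
#' One measurement set and viability series per reference culture, with the
#' per-culture sampling rules (12 h for the Biogro batch, daily otherwise)
#' and LOD censoring of the species that were undetectable in the
#' corresponding cultures (alpha-ketoglutarate in the Biogro batch, pyruvate
#' in the Biogro fed-batch).
#'
#' @param network,params Model and generating parameters.
#' @param experiments Named experiment list (default the shipped four).
#' @param noise Base `NoiseModel`; per-culture LODs are layered on top.
#' @param seed Integer seed (fanned out per culture).
#' @param ... Passed to the simulator.
#' @return List: `measurements`, `viability` (row-bound tables), `truth`,
#'   `params`.
#' @export
generate_study <- function(network, params, experiments = reference_experiments(),
                           noise = noise_model(), seed = 1L, ...) {
  lods <- list(biogro_batch = c(AKG = 6e-8),
               biogro_fedbatch = c(PYR = 1.2e-7))
  meas <- list(); via <- list(); truth <- list()
  for (i in seq_along(experiments)) {
    nm <- names(experiments)[i]
    nz <- noise
    nz$lod <- c(noise$lod, lods[[nm]])
    ds <- generate_dataset(network, params, experiments[[i]], noise = nz,
                           seed = seed + i, ...)
    meas[[nm]] <- ds$measurements
    truth[[nm]] <- ds$truth
    via[[nm]] <- generate_viability(experiments[[i]])
  }
  list(measurements = do.call(rbind, meas), viability = do.call(rbind, via),
       truth = do.call(rbind, truth), params = param_values(params))
}

#' Parameter-recovery benchmark
#'
#' Repeatedly generates noisy synthetic data at known ground-truth parameters,
#' refits the free subset from a perturbed start, and summarises per-parameter
#' bias, relative RMSE and confidence-interval coverage. The acceptance
#' surface for the calibration machinery.
#'
#' @param network Model (typically the toy network).
#' @param params Generating `ParameterSet`.
#' @param experiment Culture to simulate.
#' @param free Free-parameter names.
#' @param outputs Observables to measure.
#' @param noise `NoiseModel` for the replicates.
#' @param n_replicates Number of replicates.
#' @param seed Base seed (replicate r uses `seed + r`).
#' @param start_factor Multiplicative perturbation of the start values.
#' @param level CI level for coverage.
#' @param ... Passed to [fit_parameters()].
#' @return List: `summary` (per parameter: bias, rmse_rel, coverage,
#'   n_converged) and `replicates` (long per-replicate table).
#' @export
recovery_benchmark <- function(network, params, experiment, free,
                               outputs, noise = noise_model(),
                               n_replicates = 20L, seed = 1L,
                               start_factor = 1.15, level = 0.95, ...) {
  truth <- param_values(params)[free]
  reps <- list()
  for (r in seq_len(n_replicates)) {
    ds <- generate_dataset(network, params, experiment, noise = noise,
                           outputs = outputs, seed = seed + r)
    mm <- ds$measurements[!ds$measurements$censored, , drop = FALSE]
    ft <- tryCatch(
      fit_parameters(network, stats::setNames(list(experiment),
                                              experiment$name %||% "culture"),
                     mm, params, free = free,
                     start = truth * start_factor, ...),
      error = function(e) NULL)
    if (is.null(ft)) {
      reps[[r]] <- data.frame(replicate = r, parameter = free,
                              estimate = NA_real_, truth = unname(truth),
                              covered = NA, converged = FALSE)
      next
    }
    ci <- confidence_intervals(ft, level)
    reps[[r]] <- data.frame(
      replicate = r, parameter = free, estimate = unname(ft$estimates),
      truth = unname(truth),
      covered = ci$ci_low <= unname(truth) & unname(truth) <= ci$ci_high,
      converged = ft$converged)
  }
  long <- do.call(rbind, reps)
  sm <- do.call(rbind, lapply(free, function(pn) {
    d <- long[long$parameter == pn & !is.na(long$estimate), ]
    rel_err <- (d$estimate - d$truth) / d$truth
    data.frame(parameter = pn,
               bias = mean(rel_err),
               rmse_rel = sqrt(mean(rel_err^2)),
               coverage = mean(d$covered),
               n_converged = sum(d$converged))
  }))
  list(summary = sm, replicates = long)
}
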