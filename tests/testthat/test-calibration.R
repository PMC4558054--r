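# Calibration: data windowing, weighted objective, normalization, bounded
# least squares, linearized confidence intervals, subset comparison.

toy_free <- c("Vmax_upt", "Vmax_conv", "KmS_upt")

test_that("data window keeps 24 h to the 95%-viability crossing", {
  meas <- data.frame(culture = "c1", output = "S",
                     time_h = c(12, 24, 72, 120, 132),
                     value = 1, sd = 1)
  via <- data.frame(culture = "c1", time_h = c(0, 96, 120, 144),
                    viability_pct = c(100, 97, 94, 80))
  w <- window_measurements(meas, via)
  expect_equal(w$time_h, c(24, 72, 120))   # 12 h too early, 132 h post-decline
  # always-viable culture keeps everything from 24 h on
  via2 <- data.frame(culture = "c1", time_h = c(0, 144), viability_pct = 100)
  expect_equal(window_measurements(meas, via2)$time_h, c(24, 72, 120, 132))
  # phase split at 72 h
  expect_equal(window_measurements(meas, via2, phase = "phase1")$time_h, 24)
  expect_equal(window_measurements(meas, via2, phase = "phase2")$time_h,
               c(72, 120, 132))
  # censored records never enter the objective
  meas$censored <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(window_measurements(meas, via2)$time_h, c(72, 120, 132))
  expect_error(window_measurements(meas, via[0, ]), "viability")
})

test_that("weighted SSR arithmetic and failure penalty", {
  # zero-Vmax toy model holds S constant at 20, so predictions are known
  pars <- param_values(toy_par())
  pars[c("Vmax_upt", "Vmax_conv", "Vmax_deg")] <- 0
  meas <- data.frame(culture = "toy_batch", output = "S",
                     time_h = c(12, 24), value = c(19, 20), sd = c(1, 1))
  exps <- list(toy_batch = toy_exp())
  expect_equal(calibration_objective(pars, toy_net(), exps, meas), 1)
  meas$sd <- c(0.5, 1)    # halving sigma quadruples that residual's weight
  expect_equal(calibration_objective(pars, toy_net(), exps, meas), 4)
  meas$value <- c(20, 20) # perfect fit
  expect_equal(calibration_objective(pars, toy_net(), exps, meas), 0)
  # simulation failure yields the finite penalty, flagged
  bad <- pars; bad[] <- NaN
  obj <- calibration_objective(bad, toy_net(), exps, meas)
  expect_equal(as.numeric(obj), 1e12)
  expect_true(attr(obj, "failed"))
})

test_that("magnitude normalization round-trips exactly", {
  expo <- c(a = -8, b = 0, c = 3)
  x <- c(a = 2.9e-8, b = 0, c = 4321)
  sc <- normalize_params(x, expo)
  expect_equal(unname(sc["a"]), 2.9)
  expect_equal(unname(sc["b"]), 0)
  expect_equal(denormalize_params(sc, expo), x)
})

test_that("noiseless data are recovered within 1% from a perturbed start", {
  ds <- generate_dataset(toy_net(), toy_par(), toy_exp(),
                         outputs = c("S", "P", "Q"),
                         noise = noise_model(0, 0, 0), seed = 1)
  truth <- param_values(toy_par())[toy_free]
  ft <- fit_parameters(toy_net(), list(toy_batch = toy_exp()),
                       ds$measurements, toy_par(), free = toy_free,
                       start = truth * 1.1)
  expect_true(ft$converged)
  expect_lt(max(abs(ft$estimates - truth) / truth), 0.01)
  # descent: objective at the estimate never exceeds the start
  exps <- list(toy_batch = toy_exp())
  p_start <- param_values(toy_par()); p_start[toy_free] <- truth * 1.1
  expect_lte(ft$ssr,
             calibration_objective(p_start, toy_net(), exps, ds$measurements))
  # bounds respected
  expect_true(all(ft$estimates >= 0))
  # essentially zero residual error at the optimum
  expect_lt(ft$ssr, 1e-6)
})

test_that("linearized CIs match the closed-form linear-model solution", {
  # y = a * t + eps observed at 5 points with known sigma: compare against lm()
  set.seed(9)
  t_obs <- 1:5
  sigma <- 0.3
  a_true <- 2
  y <- a_true * t_obs + rnorm(5, 0, sigma)
  resid_fn <- function(theta) (y - theta[1] * t_obs) / sigma
  a_hat <- sum(y * t_obs) / sum(t_obs^2)
  res <- list(estimates = c(a = a_hat), free = "a",
              residuals = resid_fn(a_hat),
              ssr = sum(resid_fn(a_hat)^2),
              jacobian = matrix(-t_obs / sigma, 5, 1),
              covariance = NULL, df = 4, exponents = c(a = 0))
  s2 <- res$ssr / res$df
  res$covariance <- matrix(s2 * solve(crossprod(res$jacobian)), 1, 1)
  class(res) <- "CalibrationResult"
  ci <- confidence_intervals(res)
  fit_lm <- lm(y ~ 0 + t_obs)
  ci_lm <- confint(fit_lm, level = 0.95)
  expect_equal(unname(ci$estimate), unname(coef(fit_lm)), tolerance = 1e-10)
  expect_equal(c(ci$ci_low, ci$ci_high), unname(c(ci_lm[1], ci_lm[2])),
               tolerance = 1e-10)
})

test_that("CI widths scale with sigma and collapse at zero residuals", {
  ds <- generate_dataset(toy_net(), toy_par(), toy_exp(),
                         outputs = c("S", "Q"),
                         noise = noise_model(0.05, 0.05, 0.05), seed = 4)
  mm <- ds$measurements
  exps <- list(toy_batch = toy_exp())
  ft1 <- fit_parameters(toy_net(), exps, mm, toy_par(), free = toy_free)
  mm2 <- mm; mm2$sd <- mm$sd * 2
  ft2 <- fit_parameters(toy_net(), exps, mm2, toy_par(), free = toy_free,
                        start = ft1$estimates)
  ci1 <- confidence_intervals(ft1); ci2 <- confidence_intervals(ft2)
  # doubling every sigma at (numerically) the same optimum rescales the
  # residual shape, leaving s^2 (J'J)^{-1} invariant only up to the refit;
  # widths must stay equal within a few percent
  expect_equal(ci2$ci_high - ci2$ci_low, ci1$ci_high - ci1$ci_low,
               tolerance = 0.05)
  # zero residuals, nonzero dof -> zero-width intervals
  ds0 <- generate_dataset(toy_net(), toy_par(), toy_exp(),
                          outputs = c("S", "Q"), noise = noise_model(0, 0, 0),
                          seed = 1)
  ft0 <- fit_parameters(toy_net(), exps, ds0$measurements, toy_par(),
                        free = toy_free)
  ci0 <- confidence_intervals(ft0)
  expect_lt(max((ci0$ci_high - ci0$ci_low) / pmax(ci0$estimate, 1e-12)), 1e-3)
})

test_that("interval overlap verdicts follow the pairwise rule", {
  expect_true(ci_overlap(c(1, 2), c(1.5, 3)))
  expect_false(ci_overlap(c(1, 2), c(2.1, 3)))
  expect_true(ci_overlap(c(1, 2), c(2, 3)))   # touching counts as overlap
})

test_that("identical data subsets give identical estimates that overlap", {
  ds <- generate_dataset(toy_net(), toy_par(), toy_exp(),
                         outputs = c("S", "Q"),
                         noise = noise_model(0.05, 0.05, 0.05), seed = 6)
  m1 <- ds$measurements; m1$culture <- "c1"
  m2 <- ds$measurements; m2$culture <- "c2"
  meas <- rbind(m1, m2)
  via <- rbind(data.frame(culture = "c1", time_h = c(0, 72),
                          viability_pct = 100),
               data.frame(culture = "c2", time_h = c(0, 72),
                          viability_pct = 100))
  exps <- list(c1 = toy_exp(), c2 = toy_exp())
  cmp <- subset_comparison(toy_net(), exps, meas, via, toy_par(),
                          schemes = list(all = c("c1", "c2"),
                                         first = "c1", second = "c2"),
                          free = toy_free, maxiter = 20)
  est1 <- cmp$fits$first$estimates
  est2 <- cmp$fits$second$estimates
  expect_equal(est1, est2, tolerance = 1e-10)
  expect_true(all(cmp$overlap$overlap[cmp$overlap$scheme_a == "first" &
                                        cmp$overlap$scheme_b == "second"]))
})

test_that("a planted parameter difference between subsets is detected", {
  # generate the two subsets from different Vmax_upt values
  par2 <- toy_par()
  par2$value[par2$name == "Vmax_upt"] <- 2e-4 * 1.8
  d1 <- generate_dataset(toy_net(), toy_par(), toy_exp(),
                         outputs = c("S", "Q"),
                         noise = noise_model(0.03, 0.03, 0.03), seed = 11)
  d2 <- generate_dataset(toy_net(), par2, toy_exp(),
                         outputs = c("S", "Q"),
                         noise = noise_model(0.03, 0.03, 0.03), seed = 12)
  m1 <- d1$measurements; m1$culture <- "c1"
  m2 <- d2$measurements; m2$culture <- "c2"
  via <- rbind(data.frame(culture = "c1", time_h = c(0, 72),
                          viability_pct = 100),
               data.frame(culture = "c2", time_h = c(0, 72),
                          viability_pct = 100))
  cmp <- subset_comparison(toy_net(), list(c1 = toy_exp(), c2 = toy_exp()),
                          rbind(m1, m2), via, toy_par(),
                          schemes = list(all = c("c1", "c2"),
                                         first = "c1", second = "c2"),
                          free = toy_free, maxiter = 25)
  ov <- cmp$overlap[cmp$overlap$scheme_a == "first" &
                      cmp$overlap$scheme_b == "second", ]
  expect_false(ov$overlap[ov$parameter == "Vmax_upt"])
})
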