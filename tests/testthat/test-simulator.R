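# Simulator: unit algebra of the balances, bolus mixing, feed policy,
# closed-form checks and reproducibility.

test_that("extracellular balance has the right unit algebra", {
  # single uptake flux v on S: dS/dt = -v * Xv * 1000
  net <- metabolic_network(
    tiny_mets(),
    list(list(id = "V_upt", stoichiometry = c(S = -1, P = 1),
              rate_law = list(Vmax = "Vm",
                              substrates = list(list(species = "S",
                                                     Km = "Km1"))))))
  pars <- c(Vm = 2e-4, Km1 = 1e-9)  # S >> Km: flux ~= Vmax
  ex <- batch_experiment(tiny_state(S = 10, Xv = 2), duration = 0.5)
  tr <- simulate_culture(net, pars, ex, dense_dt = 0.1)
  # derivative at t0: -2e-4 * 2 * 1000 = -0.4 mM/h
  dS <- diff(tr$states[1:2, "S"]) / diff(tr$times[1:2])
  expect_equal(dS, -0.4, tolerance = 1e-4)
})

test_that("clamped growth follows the exponential closed form", {
  net <- constant_growth_network()
  pars <- c(Vmax_g = 0.03, Km_g = 1e-9)
  ex <- batch_experiment(tiny_state(S = 1000, Xv = 0.2), duration = 24)
  tr <- simulate_culture(net, pars, ex)
  xv24 <- unname(tr$states[which(tr$times == 24), "Xv"])
  expect_equal(xv24, 0.2 * exp(0.03 * 24), tolerance = 1e-6)
})

test_that("frozen constant fluxes give the linear closed form", {
  # saturating substrate, no growth: S declines linearly at Vmax*Xv*1000
  net <- metabolic_network(
    tiny_mets(),
    list(list(id = "V_upt", stoichiometry = c(S = -1, P = 1),
              rate_law = list(Vmax = "Vm",
                              substrates = list(list(species = "S",
                                                     Km = "Km1"))))))
  pars <- c(Vm = 1e-4, Km1 = 1e-12)
  ex <- batch_experiment(tiny_state(S = 50, Xv = 3), duration = 20)
  tr <- simulate_culture(net, pars, ex)
  expect_equal(unname(tr$states[, "S"]), 50 - 1e-4 * 3 * 1000 * tr$times,
               tolerance = 1e-6)
})

test_that("bolus mixing follows the mixing formula and conserves mass", {
  net <- toy_net()
  st <- c(S = 10, Q = 2, P = 5e-7, Xv = 1.5, V = 1)
  names(st)[1] <- "S"
  out <- apply_bolus(net, st, 0.1, c(S = 130))
  expect_equal(out[["S"]], (10 * 1 + 130 * 0.1) / 1.1)  # 20.909... mM
  expect_equal(out[["S"]], 20.9090909090909, tolerance = 1e-12)
  # conservation of every species and of total cells to 1e-12 relative
  expect_equal(out[["S"]] * out[["V"]], 10 * 1 + 130 * 0.1, tolerance = 1e-12)
  expect_equal(out[["Q"]] * out[["V"]], 2 * 1, tolerance = 1e-12)
  expect_equal(out[["Xv"]] * out[["V"]], 1.5 * 1, tolerance = 1e-12)
  expect_equal(out[["P"]], 5e-7)      # per-cell pools unchanged
  # zero-volume bolus is the identity
  expect_identical(apply_bolus(net, st, 0, c(S = 130)), st)
  expect_error(apply_bolus(net, st, -0.1, c(S = 130)), "non-negative")
})

test_that("feed volume rule hits the glucose target exactly", {
  st <- c(GLC = 8, V = 1, Xv = 1)
  v <- feed_volume_for_target(st, c(GLC = 130), 15)
  expect_equal(v, 7 / 115)
  # round trip through the mixing balance
  expect_equal((8 * 1 + 130 * v) / (1 + v), 15, tolerance = 1e-12)
  expect_equal(feed_volume_for_target(c(GLC = 20, V = 1), c(GLC = 130), 15), 0)
  expect_error(feed_volume_for_target(st, c(GLC = 10), 15), "below")
})

test_that("zero-Vmax model holds all concentrations constant", {
  pars <- param_values(toy_par())
  pars[c("Vmax_upt", "Vmax_conv", "Vmax_deg")] <- 0
  tr <- simulate_culture(toy_net(), pars, toy_exp())
  for (sp in c("S", "P", "Q", "Xv")) {
    expect_equal(diff(range(tr$states[, sp])), 0, tolerance = 1e-12)
  }
})

test_that("conditional feed policy triggers nothing while glucose stays high", {
  ex <- ref_exps()$powercho_fedbatch
  ex$feed$policy$conditional <- TRUE
  ex$duration <- 72          # glucose still far above the 10 mM floor
  tr <- simulate_culture(ref_net(), ref_par(), ex)
  expect_equal(nrow(tr$feed_events), 0)
  # unconditional default does feed
  tr2 <- simulate_culture(ref_net(), ref_par(), ref_exps()$biogro_fedbatch)
  expect_gt(nrow(tr2$feed_events), 0)
  # feed events conserve cell count across the discontinuity
  ev <- tr2$feed_events[1, ]
  i <- max(which(tr2$times < ev$time))
  expect_equal(unname(tr2$states[i + 1, "GLC"]), ev$glucose_after,
               tolerance = 1e-6)
})

test_that("trajectories are reproducible and stay finite and non-negative", {
  tr1 <- ref_traj()
  tr2 <- simulate_culture(ref_net(), ref_par(), ref_exps()$biogro_batch)
  expect_identical(tr1$states, tr2$states)   # bitwise reproducible
  expect_true(all(is.finite(tr1$states)))
  expect_gt(min(tr1$states), -1e-12)         # non-negative up to solver noise
})

test_that("reference batch model stays finite and non-negative over 360 h", {
  ex <- ref_exps()$biogro_batch
  ex$duration <- 360
  tr <- simulate_culture(ref_net(), ref_par(), ex, dense_dt = 2)
  expect_true(all(is.finite(tr$states)))
  expect_gt(min(tr$states), -1e-10)
  expect_true(all(tr$fluxes >= 0))
})

test_that("tightening solver tolerances leaves observables unchanged", {
  ex <- toy_exp()
  t_obs <- seq(6, 72, by = 6)
  tr1 <- simulate_culture(toy_net(), toy_par(), ex, rtol = 1e-8)
  tr2 <- simulate_culture(toy_net(), toy_par(), ex, rtol = 5e-9,
                          atol = choflux:::default_atol(
                            choflux:::as_compiled(toy_net(), toy_par()),
                            unname(ex$initial[c("S", "Q", "P", "Xv", "V")])) / 2)
  m1 <- observe(tr1, c("S", "P", "Q"), t_obs)
  m2 <- observe(tr2, c("S", "P", "Q"), t_obs)
  scale <- matrix(apply(abs(m1), 2, max), nrow(m1), ncol(m1), byrow = TRUE)
  expect_lt(max(abs(m1 - m2) / scale), 1e-3)   # < 0.1% of each output's scale
})

test_that("observation interpolates linearly and rejects out-of-range times", {
  tr <- ref_traj()
  # on-grid time returns the stored value
  i <- which(tr$times == 48)
  expect_equal(unname(observe(tr, "GLC", 48)[1, 1]),
               unname(tr$states[i, "GLC"]))
  # midpoint of a linear segment is the mean of the endpoints
  t1 <- tr$times[10]; t2 <- tr$times[11]
  mid <- unname(observe(tr, "GLC", (t1 + t2) / 2)[1, 1])
  expect_equal(mid, mean(tr$states[10:11, "GLC"]), tolerance = 1e-12)
  expect_error(observe(tr, "GLC", 1e4), "outside")
  expect_error(observe(tr, "NOPE", 48), "unknown observable")
})

test_that("experiments demand complete initial conditions", {
  ex <- toy_exp()
  ex$initial <- ex$initial[setdiff(names(ex$initial), "P")]
  expect_error(simulate_culture(toy_net(), toy_par(), ex), "missing initial")
})
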