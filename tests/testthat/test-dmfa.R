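# Dynamic MFA: derived flux definitions (shipped as data), sums/ratios,
# inhibition-term courses, delta-method flux confidence.

test_that("shipped derived-flux definitions state the published formulas", {
  defs <- derived_flux_definitions()
  expect_equal(defs$sums$ammonia_production,
               c(V_GLDH = 1, V_GlnT = 1, V_SDHH = 1, V_ASN = 1,
                 V_HISARGTA = 1))
  expect_equal(defs$sums$tca_influx,
               c(V_GLDH = 1, V_PDH = 1, V_AlaTA = 1, V_PC = 1, V_AAtoSUC = 5))
  expect_equal(defs$sums$net_atp_production,
               c(V_PGK = 1, V_PK = 1, V_AKGDH = 1, V_PC = 1, V_GlnT = 1,
                 V_resp = 2 * 2.5))
  expect_equal(defs$sums$aa_to_tca,
               c(V_GLDH = 1, V_AlaTA = 1, V_AAtoSUC = 5))
  expect_equal(defs$sums$glycolytic_atp, c(V_HK = 1, V_PFK = 1))
  expect_equal(defs$ratios$aa_contribution_tca,
               list(num = "aa_to_tca", den = "tca_influx"))
  expect_equal(defs$ratios$pdh_to_pk, list(num = "V_PDH", den = "V_PK"))
  expect_equal(defs$ratios$ldh_to_pk, list(num = "V_LDH", den = "V_PK"))
})

all_ones <- function() {
  rids <- ref_traj()$reaction_ids
  matrix(1, 2, length(rids), dimnames = list(NULL, rids))
}

test_that("derived sums evaluate the all-ones identities", {
  fl <- all_ones()
  expect_equal(ammonia_production(fl), c(5, 5))
  expect_equal(tca_influx(fl), c(9, 9))            # 1+1+1+1+5
  expect_equal(net_atp_production(fl), c(10, 10))  # 5*1 + 2*2.5
  fl0 <- all_ones() * 0
  expect_equal(ammonia_production(fl0), c(0, 0))
  expect_equal(tca_influx(fl0), c(0, 0))
  expect_equal(net_atp_production(fl0), c(0, 0))
  # single components
  fl1 <- fl0; fl1[, "V_AAtoSUC"] <- 0.2
  expect_equal(tca_influx(fl1), c(1, 1))
  fl2 <- fl0; fl2[, "V_resp"] <- 1
  expect_equal(net_atp_production(fl2), c(5, 5))
  expect_error(derived_flux(fl, c(V_NOPE = 1)), "unknown reaction")
})

test_that("derived sums are linear in their components", {
  set.seed(13)
  rids <- ref_traj()$reaction_ids
  for (i in 1:20) {
    a <- matrix(runif(length(rids)), 1, dimnames = list(NULL, rids))
    b <- matrix(runif(length(rids)), 1, dimnames = list(NULL, rids))
    lam <- runif(1, -2, 2)
    for (q in c("ammonia_production", "tca_influx", "net_atp_production")) {
      expect_equal(derived_flux(a + lam * b, q),
                   derived_flux(a, q) + lam * derived_flux(b, q),
                   tolerance = 1e-12)
    }
  }
})

test_that("TCA influx contributions partition unity at every time point", {
  fr <- flux_ratios(ref_traj())
  tot <- fr$aa_contribution_tca + fr$pdh_contribution_tca +
    fr$pc_contribution_tca
  expect_equal(tot, rep(1, length(tot)), tolerance = 1e-9)
  # all-ones check: AA contribution 7/9, respiration ATP share on V_resp-only
  fl <- all_ones()
  expect_equal(flux_ratios(fl)$aa_contribution_tca, c(7, 7) / 9)
  fl2 <- fl * 0; fl2[, "V_resp"] <- 1
  expect_equal(flux_ratios(fl2)$atp_from_respiration, c(1, 1))
})

test_that("ratios with empty denominators are reported missing, not zero", {
  fl <- all_ones() * 0
  fr <- flux_ratios(fl)
  expect_true(all(is.na(fr$pdh_to_pk)))
  expect_true(all(is.na(fr$aa_contribution_tca)))
})

test_that("re-evaluated fluxes agree with the simulator's stored fluxes", {
  ft <- evaluate_fluxes(ref_traj(), ref_net(), ref_par())
  rel <- abs(ft$fluxes - ref_traj()$fluxes) /
    pmax(abs(ref_traj()$fluxes), 1e-300)
  expect_lt(max(rel), 1e-12)
  # zero-Vmax model gives a zero flux trajectory
  pars <- param_values(toy_par())
  pars[c("Vmax_upt", "Vmax_conv", "Vmax_deg")] <- 0
  tr <- simulate_culture(toy_net(), pars, toy_exp())
  expect_true(all(evaluate_fluxes(tr, toy_net(), pars)$fluxes == 0))
})

test_that("glucose uptake declines with glucose when regulators are held fixed", {
  # controlled sub-model: hexokinase alone on a decaying glucose pool
  net <- metabolic_network(
    tiny_mets(),
    list(list(id = "V_upt", stoichiometry = c(S = -1, P = 1),
              rate_law = list(Vmax = "Vm",
                              substrates = list(list(species = "S",
                                                     Km = "Km1"))))))
  pars <- c(Vm = 2e-4, Km1 = 5)
  tr <- simulate_culture(net, pars, batch_experiment(tiny_state(S = 20),
                                                     duration = 96))
  v <- evaluate_fluxes(tr, net, pars)$fluxes[, "V_upt"]
  expect_true(all(diff(v) <= 1e-12))
})

test_that("inhibition-term courses behave like 1/(1+I/K)", {
  tr <- ref_traj()
  term <- inhibition_term_course(tr, "LAC", "KdLAC_PFK", ref_par())
  expect_true(all(term > 0 & term <= 1))
  # lactate rises monotonically in this batch culture, so the term falls
  expect_lt(term[length(term)], term[1])
  expect_equal(inhibition_term_course(tr, "LAC", 1e300)[1], 1,
               tolerance = 1e-6)
  expect_error(inhibition_term_course(tr, "LAC", "KdNOPE", ref_par()),
               "unknown inhibition constant")
  expect_error(inhibition_term_course(tr, "NOPE", 1), "unknown inhibition effector")
})

test_that("delta-method flux bands collapse at zero covariance and match the
           single-parameter closed form", {
  free <- c("Vmax_upt", "Vmax_conv")
  cov0 <- matrix(0, 2, 2)
  fc0 <- flux_confidence(toy_net(), toy_par(), toy_exp(), cov0, free,
                         times = 48, quantities = c("V_upt", "V_conv"),
                         df = 20)
  expect_equal(fc0$ci_high - fc0$ci_low, c(0, 0), tolerance = 1e-9)
  # V_upt is exactly linear in Vmax_upt: gradient = V_upt/Vmax_upt, so the
  # half-width is t * sqrt(v) * V_upt / Vmax_upt
  v_var <- (0.05 * 2e-4)^2
  cov1 <- diag(c(v_var, 0))
  fc1 <- flux_confidence(toy_net(), toy_par(), toy_exp(), cov1, free,
                         times = 48, quantities = "V_upt", df = 20)
  tcrit <- qt(0.975, 20)
  expect_equal(fc1$ci_high - fc1$value,
               tcrit * sqrt(v_var) * fc1$value / 2e-4, tolerance = 1e-3)
})

test_that("delta-method bands agree with Monte-Carlo parameter resampling", {
  free <- c("Vmax_upt", "Vmax_conv")
  sds <- c(0.04 * 2e-4, 0.05 * 3e-4)
  Sigma <- diag(sds^2)
  fc <- flux_confidence(toy_net(), toy_par(), toy_exp(), Sigma, free,
                        times = 48, quantities = "V_conv", df = Inf)
  half_delta <- fc$ci_high - fc$value
  set.seed(21)
  pv <- param_values(toy_par())
  draws <- replicate(200, {
    p <- pv
    p[free] <- pmax(p[free] + rnorm(2, 0, sds), 0)
    tr <- simulate_culture(toy_net(), p, toy_exp(), output_times = 48)
    tr$fluxes[which.min(abs(tr$times - 48)), "V_conv"]
  })
  half_mc <- qnorm(0.975) * sd(draws)
  expect_lt(abs(half_delta - half_mc) / half_mc, 0.15)
})
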