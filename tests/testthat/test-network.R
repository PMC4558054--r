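# Network loading, validation and flux-vector properties.

test_that("shipped reference model validates clean and reports its size", {
  rep <- validate_network(ref_net(), ref_par())
  expect_true(rep$valid)
  expect_equal(nrow(rep$issues), 0)
  expect_gt(rep$n_reactions, 30)
  # full-model parameter count is reported (soft check, near the published 139)
  expect_gt(rep$n_parameters, 120)
  expect_lt(rep$n_parameters, 160)
})

test_that("biomass conversion factor is consistent with dry weight and molar mass", {
  bm <- ref_net()$biomass
  expect_equal(bm$dry_weight_g_per_1e6 / bm$protein_mw * 1000,
               bm$biomass_mmol_per_1e6, tolerance = 0.01)
})

test_that("validation flags undeclared species and missing parameters", {
  net <- metabolic_network(
    tiny_mets(),
    list(list(id = "V_upt", stoichiometry = c(S = -1, P = 1),
              rate_law = list(Vmax = "Vm",
                              substrates = list(list(species = "GHOST",
                                                     Km = "Km1"))))))
  rep <- validate_network(net, c(Vm = 1))
  expect_false(rep$valid)
  expect_true("unresolved_species" %in% rep$issues$type)
  expect_true("unresolved_parameter" %in% rep$issues$type)  # Km1 missing
})

test_that("non-mutual reversible pairs are reported", {
  net <- metabolic_network(
    tiny_mets(),
    list(list(id = "V_f", stoichiometry = c(S = -1, P = 1),
              reversible_pair = "V_r",
              rate_law = list(Vmax = "Vf",
                              substrates = list(list(species = "S", Km = "Kf")))),
         list(id = "V_r", stoichiometry = c(P = -1, S = 1),
              rate_law = list(Vmax = "Vr",
                              substrates = list(list(species = "P", Km = "Kr"))))))
  rep <- validate_network(net, c(Vf = 1, Vr = 1, Kf = 1, Kr = 1))
  expect_true("non_mutual_reversible_pair" %in% rep$issues$type)
})

test_that("reference evaluator and compiled kernel agree to machine precision", {
  comp <- choflux:::as_compiled(ref_net(), ref_par())
  pv <- unname(param_values(ref_par())[comp$param_names])
  set.seed(7)
  for (i in 1:20) {
    x <- unname(ref_exps()$biogro_batch$initial[comp$species]) *
      exp(stats::rnorm(length(comp$species), 0, 0.3))
    vr <- choflux:::eval_fluxes(comp, x, pv)
    vc <- choflux:::eval_fluxes_fast(comp, x, pv)
    expect_lt(max(abs(vr - vc) / pmax(abs(vr), 1e-300)), 1e-12)
  }
})

test_that("flux vector matches per-reaction rates and is linear in Vmax", {
  net <- ref_net(); par <- ref_par()
  state <- ref_exps()$biogro_batch$initial
  v <- flux_vector(net, state, par)
  expect_true(all(v >= 0))
  for (rid in c("V_HK", "V_PFK", "V_growth", "V_mAb", "V_resp")) {
    expect_equal(v[[rid]], reaction_rate(net, rid, state, par))
  }
  # zero Vmax everywhere -> all-zero vector
  pv <- param_values(par)
  vmax_names <- vapply(net$reactions, function(r) r$rate_law$Vmax, "")
  pv0 <- pv; pv0[vmax_names] <- 0
  expect_true(all(flux_vector(net, state, pv0) == 0))
  # scaling all Vmax by c scales all fluxes by c
  pv3 <- pv; pv3[vmax_names] <- pv[vmax_names] * 3
  expect_equal(unname(flux_vector(net, state, pv3)), unname(3 * v),
               tolerance = 1e-12)
})

test_that("rates rise with substrates and fall with inhibitors", {
  net <- ref_net(); par <- ref_par()
  set.seed(11)
  base <- ref_exps()$biogro_batch$initial
  for (i in 1:10) {
    state <- base
    jitter <- exp(stats::rnorm(length(state), 0, 0.2))
    state[] <- state * jitter
    v0 <- flux_vector(net, state, par)
    # substrate monotonicity: more glucose never slows hexokinase
    up <- state; up["GLC"] <- up["GLC"] * 1.05
    expect_gte(flux_vector(net, up, par)[["V_HK"]], v0[["V_HK"]])
    # inhibitor monotonicity: more lactate never speeds growth or PFK
    upI <- state; upI["LAC"] <- upI["LAC"] * 1.5 + 1
    vI <- flux_vector(net, upI, par)
    expect_lte(vI[["V_growth"]], v0[["V_growth"]])
    expect_lte(vI[["V_PFK"]], v0[["V_PFK"]])
    # ammonia inhibits growth
    upN <- state; upN["NH4"] <- upN["NH4"] + 2
    expect_lte(flux_vector(net, upN, par)[["V_growth"]], v0[["V_growth"]])
  }
})

test_that("growth rate follows the multiplicative precursor form", {
  net <- ref_net(); par <- ref_par()
  state <- ref_exps()$biogro_batch$initial
  mu <- growth_rate(net, state, par)
  expect_gt(mu, 0)
  # any single depleted precursor annihilates growth
  for (sp in c("GLN", "ILE", "G6P", "R5P")) {
    st0 <- state; st0[sp] <- 0
    expect_equal(growth_rate(net, st0, par), 0)
  }
  # half-inhibition by lactate at its growth affinity constant
  pv <- param_values(par)
  st <- state; st["LAC"] <- pv[["KdLACgrowth"]]; st["NH4"] <- 0
  st_ref <- state; st_ref["LAC"] <- 0; st_ref["NH4"] <- 0
  expect_equal(growth_rate(net, st, par), growth_rate(net, st_ref, par) / 2,
               tolerance = 1e-12)
})

test_that("mAb rate needs every amino-acid precursor and rises as Km falls", {
  net <- ref_net(); par <- ref_par()
  state <- ref_exps()$biogro_batch$initial
  q0 <- mab_rate(net, state, par)
  expect_gt(q0, 0)
  st0 <- state; st0["VAL"] <- 0
  expect_equal(mab_rate(net, st0, par), 0)
  pv <- param_values(par)
  pv["KmVALmAb"] <- pv[["KmVALmAb"]] / 2
  expect_gte(mab_rate(net, state, pv), q0)
})

test_that("activation-neutral identity: alpha = beta = 1 leaves fluxes unregulated", {
  net <- ref_net(); pv <- param_values(ref_par())
  state <- ref_exps()$biogro_batch$initial
  # set every activation to neutral; fluxes must equal the Michaelis-Menten
  # core with inhibitions only
  pv_neutral <- pv
  pv_neutral[c("alphaAMP_ATP", "betaAMP_ATP", "alphaF6P_PK", "betaF6P_PK")] <- 1
  v_neutral <- flux_vector(net, state, pv_neutral)
  # independently strip the activation terms from the model definition
  net_stripped <- net
  for (rid in names(net_stripped$reactions)) {
    rl <- net_stripped$reactions[[rid]]$rate_law
    rl$regulation <- Filter(function(g) g$kind != "nonessential_activation",
                            rl$regulation)
    net_stripped$reactions[[rid]]$rate_law <- rl
  }
  v_stripped <- flux_vector(net_stripped, state, pv)
  expect_equal(unname(v_neutral), unname(v_stripped), tolerance = 1e-12)
})
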