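test_that("exact_psi matches an independent hand summation on a tiny model", {
  sm <- two_wave_no_confounder_model()
  regs <- standard_regimes(2)
  for (a in regs) {
    for (ap in regs) {
      expect_equal(exact_psi(sm, a, ap), psi_by_hand(sm, a$values, ap$values),
                   tolerance = 1e-12)
    }
  }
})

test_that("an intercept-only outcome gives psi = plogis(b0) for any regimes", {
  b0 <- -0.9
  sm <- two_wave_no_confounder_model(outcome = c(`(Intercept)` = b0))
  regs <- standard_regimes(2)
  for (a in regs) {
    for (ap in regs) {
      expect_equal(exact_psi(sm, a, ap), plogis(b0), tolerance = 1e-12)
    }
  }
  ms <- as_model_set(sm)
  base <- data.frame(male = c(0, 1))
  psi <- simulate_psi(ms, base, regs$persistent, regs$never, 500, seed = 4)
  expect_equal(as.numeric(psi), plogis(b0), tolerance = 1e-12)
})

test_that("regimes equal except at the final wave share the mediator law exactly", {
  for (sm in list(toy_mediation_scenario(), no_direct_effect_scenario())) {
    inc <- regime_incident(2, 2)
    nev <- regime_never(2)
    expect_identical(exact_psi(sm, inc, inc), exact_psi(sm, inc, nev))
    eff <- exact_effects(sm)$effects
    rnie <- eff$estimate[eff$regime == "incident_w2" & eff$effect == "rNIE"]
    expect_identical(rnie, 1)
  }
})

test_that("mediator-trajectory probabilities integrate to one for every baseline", {
  # exercised internally with a 1e-10 guard; a wrong law would error here
  sm <- toy_mediation_scenario()
  expect_no_error(exact_psi(sm, regime_persistent(2), regime_never(2)))
})

test_that("null scenario has all effects exactly 1; pathway isolation is exact", {
  null_eff <- exact_effects(null_mediation_scenario())$effects
  expect_true(all(null_eff$estimate == 1))

  eff <- exact_effects(no_direct_effect_scenario())$effects
  p <- eff[eff$regime == "persistent", ]
  expect_identical(p$estimate[p$effect == "rNDE"], 1)
  expect_gt(p$estimate[p$effect == "rNIE"], 1)
  # decomposition identity is exact on shared psi values
  expect_equal(p$estimate[p$effect == "rTE"],
               p$estimate[p$effect == "rNDE"] * p$estimate[p$effect == "rNIE"],
               tolerance = 1e-14)
})

test_that("rNDE is non-decreasing in the direct exposure-outcome coefficient", {
  rnde <- vapply(c(0, 0.3, 0.6, 0.9, 1.2), function(b) {
    out <- c(`(Intercept)` = -1.2, obese_w1 = b, obese_w2 = b * 0.6,
             inactive_w1 = 0.5, inactive_w2 = 0.8, male = -0.3)
    sm <- two_wave_no_confounder_model(outcome = out)
    eff <- exact_effects(sm)$effects
    eff$estimate[eff$regime == "persistent" & eff$effect == "rNDE"]
  }, numeric(1))
  expect_true(all(diff(rnde) > 0))
})

test_that("the enumeration guard rejects oversized state spaces", {
  sm <- paper_like_scenario("nshd-like") # 4 baseline, 2 confounders, 4 waves
  expect_error(exact_psi(sm, regime_persistent(4), regime_never(4)),
               "2\\^22")
})

test_that("exact joint moments are coherent probabilities", {
  sm <- toy_mediation_scenario()
  em <- exact_marginals(sm)
  expect_equal(em$moment(character(0)), 1, tolerance = 1e-12)
  expect_equal(em$marginals[["male"]], 0.5, tolerance = 1e-12)
  # joint <= each marginal, conditional in [0,1]
  j <- em$moment(c("obese_w1", "obese_w2"))
  expect_lte(j, em$marginals[["obese_w1"]] + 1e-12)
  expect_gte(j / em$marginals[["obese_w1"]], 0)
})
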