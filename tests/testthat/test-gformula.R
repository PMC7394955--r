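test_that("wave models recover generating coefficients (generate-and-refit)", {
  sm <- paper_like_scenario("nshd-like")
  co <- derive_cohort(generate_cohort(sm, 50000, seed = 2024))
  ms <- fit_wave_models(co, outcome_col = "y")
  true_coef <- function(resp) {
    t <- as.integer(sub(".*_w", "", resp))
    stem <- sub("_w[0-9]+$", "", resp)
    if (stem == "inactive") sm$mediator[[t]] else sm$confounders[[stem]][[t]]
  }
  within3 <- integer(0)
  check <- function(m, truth) {
    for (nm in names(m$coef)) {
      tv <- if (nm %in% names(truth)) truth[[nm]] else 0
      within3 <<- c(within3, abs(m$coef[[nm]] - tv) <= 3 * m$se[[nm]])
    }
  }
  for (t in 1:4) {
    for (m in ms$confounder_models[[t]]) check(m, true_coef(m$response))
    check(ms$mediator_models[[t]], true_coef(ms$mediator_models[[t]]$response))
  }
  check(ms$outcome_model, sm$outcome)
  expect_gte(mean(within3), 0.95)
})

test_that("exposure coefficients in mediator models are null when truly null", {
  sm <- null_mediation_scenario()
  co <- derive_cohort(generate_cohort(sm, 30000, seed = 55))
  ms <- fit_wave_models(co, outcome_col = "y")
  m2 <- ms$mediator_models[[2]]
  expect_lte(abs(m2$coef[["obese_w1"]]), 3 * m2$se[["obese_w1"]])
  mo <- ms$outcome_model
  expect_lte(abs(mo$coef[["obese_w1"]]), 3 * mo$se[["obese_w1"]])
  expect_lte(abs(mo$coef[["obese_w2"]]), 3 * mo$se[["obese_w2"]])
})

test_that("degenerate and misspecified inputs raise named errors", {
  sm <- toy_mediation_scenario()
  co <- derive_cohort(generate_cohort(sm, 400, seed = 3))
  co$table$smoker_w1 <- 0
  expect_error(fit_wave_models(co), "smoker_w1")

  co2 <- derive_cohort(generate_cohort(sm, 400, seed = 3))
  ms <- fit_wave_models(co2)
  base <- co2$table[c("male", "low_social_class")]
  expect_error(simulate_psi(ms, base, regime_never(2), regime_never(2),
                            n_mc = 0, seed = 1), "n_mc")
  expect_error(simulate_psi(ms, base, regime_never(3), regime_never(3),
                            n_mc = 10, seed = 1), "regime length")
  expect_error(exposure_regime(c(1, 0)), "monotone")
})

test_that("Monte Carlo psi is deterministic given models, baselines, n_mc, seed", {
  sm <- toy_mediation_scenario()
  ms <- as_model_set(sm)
  base <- data.frame(male = c(0, 1, 1), low_social_class = c(0, 1, 0))
  a <- regime_persistent(2); ap <- regime_never(2)
  p1 <- simulate_psi(ms, base, a, ap, 5000, seed = 42)
  p2 <- simulate_psi(ms, base, a, ap, 5000, seed = 42)
  expect_identical(as.numeric(p1), as.numeric(p2))
  p3 <- simulate_psi(ms, base, a, ap, 5000, seed = 43)
  expect_false(identical(as.numeric(p1), as.numeric(p3)))
})

test_that("effect decomposition rTE = rNDE x rNIE is exact on shared psi", {
  sm <- toy_mediation_scenario()
  co <- derive_cohort(generate_cohort(sm, 3000, seed = 8))
  est <- estimate_randomized_effects(co, n_mc = 4000, seed = 12)
  e <- est$effects
  for (rg in unique(e$regime)) {
    rte <- e$estimate[e$regime == rg & e$effect == "rTE"]
    rnde <- e$estimate[e$regime == rg & e$effect == "rNDE"]
    rnie <- e$estimate[e$regime == rg & e$effect == "rNIE"]
    if (is.na(rnde)) next
    expect_lte(abs(rte - rnde * rnie) / rte, 1e-12)
  }
})

test_that("last-wave-only regimes report rTE only (no mediator follows onset)", {
  sm <- toy_mediation_scenario()
  co <- derive_cohort(generate_cohort(sm, 3000, seed = 8))
  est <- estimate_randomized_effects(co, n_mc = 4000, seed = 12)
  e <- est$effects[est$effects$regime == "incident_w2", ]
  expect_false(is.na(e$estimate[e$effect == "rTE"]))
  expect_true(all(is.na(e$estimate[e$effect %in% c("rNDE", "rNIE")])))
})

test_that("restricting waves_used refits only the early-wave models", {
  sm <- paper_like_scenario("nshd-like")
  co <- derive_cohort(generate_cohort(sm, 4000, seed = 21))
  d3 <- use_waves(co$design, 3)
  ms <- fit_wave_models(co, d3)
  expect_length(ms$mediator_models, 3)
  expect_false(any(grepl("_w4", names(ms$outcome_model$coef))))
  est <- estimate_randomized_effects(co, d3, n_mc = 3000, seed = 5)
  expect_setequal(unique(est$effects$regime),
                  c("incident_w2", "incident_w3", "persistent"))
})

test_that("bootstrap CIs are symmetric, reproducible, and count failures", {
  sm <- toy_mediation_scenario()
  co <- derive_cohort(generate_cohort(sm, 800, seed = 14))
  be <- bootstrap_effects(co, n_boot = 20, n_mc = 2000, seed = 77)
  ok <- !is.na(be$effects$estimate)
  expect_equal(be$effects$ci_high[ok] - be$effects$estimate[ok],
               be$effects$estimate[ok] - be$effects$ci_low[ok],
               tolerance = 1e-12)
  be2 <- bootstrap_effects(co, n_boot = 2, n_mc = 500, seed = 77)
  be3 <- bootstrap_effects(co, n_boot = 2, n_mc = 500, seed = 77)
  expect_identical(be2$effects, be3$effects)
  expect_equal(be$n_failed, 0L)
})

test_that("bootstrap errors out when more than 10% of replicates fail", {
  sm <- toy_mediation_scenario()
  co <- derive_cohort(generate_cohort(sm, 300, seed = 16))
  # let the point-estimate fit through, then fail every third replicate refit
  real_fit <- medgf:::fit_specs
  calls <- 0L
  local_mocked_bindings(
    fit_specs = function(...) {
      calls <<- calls + 1L
      if (calls > 1L && calls %% 3L == 0L) stop("resample degenerate")
      real_fit(...)
    },
    .package = "medgf")
  expect_error(
    bootstrap_effects(co, n_boot = 20, n_mc = 200, seed = 5),
    "of 20 bootstrap replicates failed")
})
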