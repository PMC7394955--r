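make_or_cohort <- function(tab) {
  d <- cohort_design("assoc", wave_labels = c("1", "2"),
                     baseline_vars = names(tab)[!names(tab) %in%
                       c("poor_pf", "trajectory")],
                     timevarying_confounder_vars = character(0),
                     mediator_var = "inactive", exposure_var = "obese",
                     outcome_var = "poor_pf", gender_var = "male")
  co <- structure(list(design = d, table = tab), class = "longitudinal_cohort")
  co
}

test_that("crude OR equals the 2x2 cross-product ratio to 6+ significant figures", {
  tab <- data.frame(
    male = rep(1, 200),
    exposed = rep(c(1, 0), each = 100),
    poor_pf = c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95)))
  co <- make_or_cohort(tab)
  r <- fit_adjusted_or(co, "exposed")
  crude <- (10 * 95) / (90 * 5)
  expect_equal(r$odds_ratio, crude, tolerance = 1e-7)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_true(all(c(r$odds_ratio, r$ci_low, r$ci_high) > 0))
})

test_that("a constant adjustment covariate leaves the OR unchanged", {
  tab <- data.frame(
    male = rep(1, 200),
    constant = rep(1, 200),
    exposed = rep(c(1, 0), each = 100),
    poor_pf = c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95)))
  co <- make_or_cohort(tab)
  r0 <- fit_adjusted_or(co, "exposed")
  r1 <- fit_adjusted_or(co, "exposed",
                        adjust = adjustment_set("plus_const", "constant"))
  expect_equal(r1$odds_ratio, r0$odds_ratio, tolerance = 1e-12)
})

test_that("adjusted OR recovers a true conditional log-odds of 0.7", {
  set.seed(2027)
  n <- 20000
  z <- rbinom(n, 1, 0.4)
  x <- rbinom(n, 1, plogis(-0.5 + 0.8 * z))
  y <- rbinom(n, 1, plogis(-1.5 + 0.7 * x + 0.6 * z))
  co <- make_or_cohort(data.frame(male = 1, z = z, x = x, poor_pf = y))
  r <- fit_adjusted_or(co, "x", adjust = adjustment_set("custom", "z"))
  expect_lt(abs(r$odds_ratio - exp(0.7)), 0.1)
})

test_that("trajectory ORs use never as reference and cover each class", {
  sm <- paper_like_scenario("ncds-like")
  co <- derive_cohort(generate_cohort(sm, 8000, seed = 4))
  r <- fit_adjusted_or(co, "trajectory",
                       adjust = adjustment_set("modelA", "male"))
  expect_setequal(r$level, c("incident_w2", "incident_w3", "persistent"))
  expect_true(all(r$odds_ratio > 0))

  co$table$trajectory[co$table$trajectory == "never"] <- "persistent"
  expect_error(fit_adjusted_or(co, "trajectory"), "reference level 'never'")
})

test_that("separation and non-convergence raise named errors", {
  tab <- data.frame(male = 1,
                    exposed = rep(c(1, 0), each = 50),
                    poor_pf = rep(c(1, 0), each = 50)) # perfectly separated
  co <- make_or_cohort(tab)
  expect_error(fit_adjusted_or(co, "exposed"), "separation|converge")
})

test_that("the association table has the full wave-by-model layout", {
  sm <- paper_like_scenario("ncds-like")
  co <- derive_cohort(generate_cohort(sm, 6000, seed = 17))
  tab <- association_table(co)
  expect_setequal(unique(tab$model),
                  c("model1", "model2", "modelA", "modelB", "reference"))
  # obesity and inactivity at each of 3 waves under model1 and model2
  expect_equal(sum(tab$term != "trajectory"), 3 * 2 * 2)
  # trajectory rows: 3 classes x 2 models + fixed reference
  expect_equal(sum(tab$term == "trajectory"), 3 * 2 + 1)
  ref <- tab[tab$model == "reference", ]
  expect_equal(ref$odds_ratio, 1)
  # obesity at each wave is positively associated with poor functioning here
  ob <- tab[tab$term %in% paste0("obese_w", 1:3) & tab$model == "model1", ]
  expect_true(all(ob$odds_ratio > 1))
})
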