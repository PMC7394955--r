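test_that("generator validates n and is deterministic in the seed", {
  sm <- toy_mediation_scenario()
  expect_error(generate_cohort(sm, 0), "positive")
  one <- generate_cohort(sm, 1, seed = 5)
  expect_equal(nrow(one$table), 1)
  a <- generate_cohort(sm, 500, seed = 7)
  b <- generate_cohort(sm, 500, seed = 7)
  expect_identical(a$table, b$table)
  c <- generate_cohort(sm, 500, seed = 8)
  expect_false(identical(a$table, c$table))
})

test_that("presets declare the documented wave structure", {
  expect_equal(paper_like_scenario("nshd-like")$n_waves, 4)
  expect_equal(paper_like_scenario("ncds-like")$n_waves, 3)
  expect_error(paper_like_scenario("mystery-cohort"), "unknown scenario")
})

test_that("preset obesity is effectively absorbing (persistence >= 0.95)", {
  for (id in c("nshd-like", "ncds-like")) {
    sm <- paper_like_scenario(id)
    em <- exact_marginals(sm)
    for (t in seq(2, sm$n_waves)) {
      prev <- paste0("obese_w", t - 1)
      pers <- em$moment(c(prev, paste0("obese_w", t))) / em$marginals[[prev]]
      expect_gte(pers, 0.95)
    }
  }
})

test_that("simulated prevalences match the enumerated preset marginals", {
  sm <- paper_like_scenario("nshd-like")
  em <- exact_marginals(sm)
  co <- derive_cohort(generate_cohort(sm, 200000, seed = 2))
  tab <- co$table
  for (t in 1:4) {
    for (v in c("obese", "inactive")) {
      nm <- paste0(v, "_w", t)
      expect_lt(abs(mean(tab[[nm]]) - em$marginals[[nm]]), 0.01)
    }
  }
  # gender-specific wave-1 obesity against the scenario's calibrated marginal
  f <- tab$male == 0
  target <- (em$marginals[["obese_w1"]] - em$moment(c("obese_w1", "male"))) /
    (1 - em$marginals[["male"]])
  expect_equal(target, 0.059, tolerance = 0.002) # calibration anchor
  expect_lt(abs(mean(tab$obese_w1[f]) - target), 0.01)
  # rising obesity, inactivity in the plausible band, higher among the obese
  ob <- vapply(1:4, function(t) mean(tab[[paste0("obese_w", t)]]), numeric(1))
  expect_true(all(diff(ob) > 0))
  for (t in 1:4) {
    m <- tab[[paste0("inactive_w", t)]]
    o <- tab[[paste0("obese_w", t)]]
    expect_true(mean(m) > 0.30 && mean(m) < 0.65)
    expect_gt(mean(m[o == 1]), mean(m[o == 0]))
  }
})

test_that("generated conditionals match the structural probabilities (GoF)", {
  sm <- paper_like_scenario("nshd-like")
  tab <- generate_cohort(sm, 200000, seed = 9)$table
  # group subjects by the full covariate pattern of a model; within each cell
  # the response is Bernoulli with the model probability
  gof_pvalue <- function(coef, resp) {
    covs <- setdiff(names(coef), "(Intercept)")
    key <- do.call(paste, c(tab[covs], sep = ":"))
    stat <- 0; df <- 0
    for (cell in unique(key)) {
      sel <- key == cell
      n <- sum(sel)
      p <- plogis(medgf:::eval_lp(coef, as.list(tab[sel, , drop = FALSE][1, ]), 1))
      if (n * p < 50 || n * (1 - p) < 50) next
      o <- sum(tab[[resp]][sel])
      stat <- stat + (o - n * p)^2 / (n * p * (1 - p))
      df <- df + 1
    }
    pchisq(stat, df, lower.tail = FALSE)
  }
  expect_gt(gof_pvalue(sm$mediator[[2]], "inactive_w2"), 0.001)
  expect_gt(gof_pvalue(sm$exposure[[2]], "obese_w2"), 0.001)
  expect_gt(gof_pvalue(sm$confounders$depressed[[3]], "depressed_w3"), 0.001)
})

test_that("the continuous score and BMI columns are coherent with the flags", {
  sm <- paper_like_scenario("ncds-like")
  co <- generate_cohort(sm, 5000, seed = 13)
  tab <- co$table
  expect_true(all(tab$pf_score >= 0 & tab$pf_score <= 100))
  expect_true(all(tab$pf_score == round(tab$pf_score)))
  for (t in 1:3) {
    expect_identical(as.integer(tab[[paste0("bmi_w", t)]] >= 30),
                     as.integer(tab[[paste0("obese_w", t)]]))
  }
  # derivation layer reproduces the generator's flags from BMI
  der <- derive_cohort(co)
  expect_equal(der$table$obese_w2, tab$obese_w2)
  # lower scores land in the poor-functioning tail, per gender
  for (g in 0:1) {
    sel <- der$table$male == g
    expect_gte(mean(der$table$poor_pf[sel]), 0.10)
    expect_lt(mean(der$table$poor_pf[sel]), 0.20)
  }
})
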