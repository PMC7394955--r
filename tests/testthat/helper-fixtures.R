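# Shared fixtures: tiny structural models and cohort tables built in code.

# two-wave model with no time-varying confounders; small enough that psi can
# be recomputed in tests by explicit nested summation, independent of the
# package's enumeration engine
two_wave_no_confounder_model <- function(outcome = c(`(Intercept)` = -1.2,
                                                     obese_w1 = 0.6,
                                                     obese_w2 = 0.4,
                                                     inactive_w1 = 0.5,
                                                     inactive_w2 = 0.8,
                                                     male = -0.3)) {
  structural_model(
    cohort_id = "tiny",
    wave_labels = c("1", "2"),
    baseline = c(male = 0.5),
    confounders = stats::setNames(list(), character(0)),
    mediator = list(
      c(`(Intercept)` = -0.5, male = -0.3),
      c(`(Intercept)` = -0.8, inactive_w1 = 1.2, obese_w1 = 0.7, male = -0.3)),
    exposure = list(
      c(`(Intercept)` = -1.0, inactive_w1 = 0.4),
      c(`(Intercept)` = -1.5, obese_w1 = 4.0, inactive_w2 = 0.3)),
    outcome = outcome)
}

# independent reference computation of psi(a, aprime) for the two-wave,
# no-confounder model above: explicit sums over the four mediator paths
psi_by_hand <- function(sm, a, aprime) {
  p <- 0
  for (male in 0:1) {
    pv <- if (male == 1) sm$baseline[["male"]] else 1 - sm$baseline[["male"]]
    for (m1 in 0:1) {
      pm1 <- stats::plogis(sm$mediator[[1]][["(Intercept)"]] +
                           sm$mediator[[1]][["male"]] * male)
      pm1 <- if (m1 == 1) pm1 else 1 - pm1
      for (m2 in 0:1) {
        pm2 <- stats::plogis(sm$mediator[[2]][["(Intercept)"]] +
                             sm$mediator[[2]][["inactive_w1"]] * m1 +
                             sm$mediator[[2]][["obese_w1"]] * aprime[1] +
                             sm$mediator[[2]][["male"]] * male)
        pm2 <- if (m2 == 1) pm2 else 1 - pm2
        co <- sm$outcome
        py <- stats::plogis(co[["(Intercept)"]] + co[["obese_w1"]] * a[1] +
                            co[["obese_w2"]] * a[2] + co[["inactive_w1"]] * m1 +
                            co[["inactive_w2"]] * m2 + co[["male"]] * male)
        p <- p + pv * pm1 * pm2 * py
      }
    }
  }
  p
}

# small wide-format cohort table with every analysis column, for IO tests
tiny_cohort_table <- function(n = 10) {
  set.seed(99)
  tab <- data.frame(
    male = rep_len(c(0, 1), n),
    low_social_class = rep_len(c(0, 0, 1), n),
    pf_score = seq(30, 30 + 5 * (n - 1), by = 5)[seq_len(n)]
  )
  for (t in 1:4) {
    tab[[paste0("smoker_w", t)]] <- rep_len(c(0, 1, 0), n)
    tab[[paste0("inactive_w", t)]] <- rep_len(c(1, 0), n)
    tab[[paste0("bmi_w", t)]] <- 24 + (seq_len(n) %% 5) * 2 + t
  }
  tab
}

tiny_design <- function() {
  cohort_design("tiny4",
                wave_labels = c("36", "43", "53", "60"),
                baseline_vars = c("male", "low_social_class"),
                timevarying_confounder_vars = "smoker",
                mediator_var = "inactive",
                exposure_var = "obese",
                bmi_var = "bmi",
                outcome_score_var = "pf_score",
                gender_var = "male")
}
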