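# Calibrate the shipped scenario presets and freeze them as YAML.
# Usage (from the repository root): Rscript scripts/calibrate_scenarios.R
suppressPackageStartupMessages(library(medgf))

lg <- function(p) log(p / (1 - p))

# ---- nshd-like: T = 4, confounders smoker + depressed ----------------------
make_nshd <- function(ob_int, in_int) {
  structural_model(
    cohort_id = "nshd-like",
    wave_labels = c("36", "43", "53", "60-64"),
    baseline = c(male = 0.48, low_social_class = 0.30, smoker_early = 0.35,
                 poor_mental_health = 0.15),
    confounders = list(
      smoker = list(
        c(`(Intercept)` = -2.2, smoker_early = 2.8, low_social_class = 0.4),
        c(`(Intercept)` = -2.8, smoker_w1 = 3.6, smoker_early = 0.8, low_social_class = 0.2),
        c(`(Intercept)` = -3.0, smoker_w2 = 3.6, smoker_early = 0.8, low_social_class = 0.2),
        c(`(Intercept)` = -3.2, smoker_w3 = 3.6, smoker_early = 0.8, low_social_class = 0.2)),
      depressed = list(
        c(`(Intercept)` = -2.3, poor_mental_health = 1.6, low_social_class = 0.3, male = -0.3),
        c(`(Intercept)` = -2.4, depressed_w1 = 1.8, poor_mental_health = 1.0, obese_w1 = 0.3, male = -0.3),
        c(`(Intercept)` = -2.4, depressed_w2 = 1.8, poor_mental_health = 1.0, obese_w2 = 0.3, male = -0.3),
        c(`(Intercept)` = -2.4, depressed_w3 = 1.8, poor_mental_health = 1.0, obese_w3 = 0.3, male = -0.3))),
    mediator = list(
      c(`(Intercept)` = in_int[1], male = -0.5, low_social_class = 0.4,
        poor_mental_health = 0.4, depressed_w1 = 0.3, smoker_w1 = 0.2),
      c(`(Intercept)` = in_int[2], inactive_w1 = 1.3, male = -0.35, obese_w1 = 0.5,
        depressed_w2 = 0.3, low_social_class = 0.2),
      c(`(Intercept)` = in_int[3], inactive_w2 = 1.4, male = -0.15, obese_w2 = 0.5,
        depressed_w3 = 0.3, low_social_class = 0.2),
      c(`(Intercept)` = in_int[4], inactive_w3 = 1.3, obese_w3 = 0.4,
        depressed_w4 = 0.3, low_social_class = 0.2)),
    exposure = list(
      c(`(Intercept)` = ob_int[1], male = -0.15, low_social_class = 0.4, inactive_w1 = 0.5),
      c(`(Intercept)` = ob_int[2], obese_w1 = 6.0, inactive_w2 = 0.4, low_social_class = 0.3),
      c(`(Intercept)` = ob_int[3], obese_w2 = 6.0, inactive_w3 = 0.4, low_social_class = 0.3),
      c(`(Intercept)` = ob_int[4], obese_w3 = 6.0, inactive_w4 = 0.4, low_social_class = 0.3)),
    outcome = c(`(Intercept)` = -3.3, obese_w1 = 0.35, obese_w2 = 0.2, obese_w3 = 0.2,
                obese_w4 = 0.3, inactive_w4 = 0.7, inactive_w3 = 0.25,
                inactive_w2 = 0.1, inactive_w1 = 0.1, depressed_w4 = 0.5,
                smoker_w4 = 0.4, low_social_class = 0.3, poor_mental_health = 0.3,
                male = -0.1),
    score = list(coef = c(`(Intercept)` = 55, obese_w1 = -2, obese_w2 = -1.5,
                          obese_w3 = -1.5, obese_w4 = -2.5, inactive_w4 = -5,
                          inactive_w3 = -2, depressed_w4 = -3, smoker_w4 = -2,
                          low_social_class = -2, poor_mental_health = -2,
                          male = 2),
                 sd = 8))
}

calibrate <- function(make, ob_int, in_int, ob_target_f, in_target_f,
                      gender = "male", iters = 4) {
  for (it in seq_len(iters)) {
    sm <- make(ob_int, in_int)
    em <- exact_marginals(sm)
    pf <- 1 - em$marginals[[gender]] # P(female)
    K <- sm$n_waves
    obs_f <- vapply(seq_len(K), function(t) {
      (em$marginals[[paste0("obese_w", t)]] -
         em$moment(c(paste0("obese_w", t), gender))) / pf
    }, numeric(1))
    in_f <- vapply(seq_len(K), function(t) {
      (em$marginals[[paste0("inactive_w", t)]] -
         em$moment(c(paste0("inactive_w", t), gender))) / pf
    }, numeric(1))
    cat(sprintf("iter %d: obese(f) %s | inactive(f) %s\n", it,
                paste(sprintf("%.3f", obs_f), collapse = " "),
                paste(sprintf("%.3f", in_f), collapse = " ")))
    ob_int <- ob_int + (lg(ob_target_f) - lg(obs_f))
    in_int <- in_int + (lg(in_target_f) - lg(in_f))
  }
  list(sm = make(ob_int, in_int), ob_int = ob_int, in_int = in_int)
}

cat("== nshd-like ==\n")
res_n <- calibrate(make_nshd,
                   ob_int = c(-3.3, -3.1, -2.1, -2.7),
                   in_int = c(-0.55, -0.6, -0.75, 0.0),
                   ob_target_f = c(0.059, 0.125, 0.248, 0.299),
                   in_target_f = c(0.402, 0.541, 0.471, 0.621))
sm_nshd <- res_n$sm
em <- exact_marginals(sm_nshd)
cat("final marginals:\n")
print(round(em$marginals, 4))
for (t in 2:4) {
  pers <- em$moment(paste0("obese_w", c(t - 1, t))) /
    em$marginals[[paste0("obese_w", t - 1)]]
  cat(sprintf("persistence w%d->w%d: %.3f\n", t - 1, t, pers))
}
for (t in 1:4) {
  ot <- paste0("obese_w", t); mt <- paste0("inactive_w", t)
  p1 <- em$moment(c(ot, mt)) / em$marginals[[ot]]
  p0 <- (em$marginals[[mt]] - em$moment(c(ot, mt))) / (1 - em$marginals[[ot]])
  cat(sprintf("inactivity w%d: obese %.3f vs non-obese %.3f\n", t, p1, p0))
}
cat("poor-PF (binary y) marginal:",
    round(mean(generate_cohort(sm_nshd, 200000, 7)$table$y), 4), "\n")
write_scenario(sm_nshd, "inst/extdata/scenarios/nshd-like.yml")

# ---- ncds-like: T = 3, confounders smoker + depressed + poor_srh -----------
make_ncds <- function(ob_int, in_int) {
  structural_model(
    cohort_id = "ncds-like",
    wave_labels = c("33", "42", "50"),
    baseline = c(male = 0.48, low_social_class = 0.30, smoker_early = 0.35,
                 poor_mental_health = 0.15),
    confounders = list(
      smoker = list(
        c(`(Intercept)` = -2.1, smoker_early = 2.8, low_social_class = 0.4),
        c(`(Intercept)` = -2.8, smoker_w1 = 3.6, smoker_early = 0.8, low_social_class = 0.2),
        c(`(Intercept)` = -3.0, smoker_w2 = 3.6, smoker_early = 0.8, low_social_class = 0.2)),
      depressed = list(
        c(`(Intercept)` = -2.3, poor_mental_health = 1.6, low_social_class = 0.3, male = -0.3),
        c(`(Intercept)` = -2.4, depressed_w1 = 1.8, poor_mental_health = 1.0, obese_w1 = 0.3, male = -0.3),
        c(`(Intercept)` = -2.4, depressed_w2 = 1.8, poor_mental_health = 1.0, obese_w2 = 0.3, male = -0.3)),
      poor_srh = list(
        c(`(Intercept)` = -2.2, poor_mental_health = 1.0, low_social_class = 0.4),
        c(`(Intercept)` = -2.3, poor_srh_w1 = 1.8, obese_w1 = 0.4, poor_mental_health = 0.6),
        c(`(Intercept)` = -2.3, poor_srh_w2 = 1.8, obese_w2 = 0.4, poor_mental_health = 0.6))),
    mediator = list(
      c(`(Intercept)` = in_int[1], low_social_class = 0.4, poor_mental_health = 0.3,
        depressed_w1 = 0.3, smoker_w1 = 0.2),
      c(`(Intercept)` = in_int[2], inactive_w1 = 1.4, obese_w1 = 0.5,
        depressed_w2 = 0.3, low_social_class = 0.2),
      c(`(Intercept)` = in_int[3], inactive_w2 = 1.5, obese_w2 = 0.5,
        depressed_w3 = 0.3, low_social_class = 0.2)),
    exposure = list(
      c(`(Intercept)` = ob_int[1], low_social_class = 0.4, inactive_w1 = 0.5),
      c(`(Intercept)` = ob_int[2], obese_w1 = 6.0, inactive_w2 = 0.4, low_social_class = 0.3),
      c(`(Intercept)` = ob_int[3], obese_w2 = 6.0, inactive_w3 = 0.4, low_social_class = 0.3)),
    outcome = c(`(Intercept)` = -3.2, obese_w1 = 0.2, obese_w2 = 0.15, obese_w3 = 0.2,
                inactive_w3 = 0.8, inactive_w2 = 0.2, inactive_w1 = 0.1,
                poor_srh_w3 = 0.6, depressed_w3 = 0.4, smoker_w3 = 0.3,
                low_social_class = 0.3, poor_mental_health = 0.2),
    score = list(coef = c(`(Intercept)` = 66, male = 4, obese_w1 = -1.5,
                          obese_w2 = -1.5, obese_w3 = -1.5, inactive_w3 = -5,
                          inactive_w2 = -2, poor_srh_w3 = -4, depressed_w3 = -3,
                          smoker_w3 = -2, low_social_class = -2,
                          poor_mental_health = -2),
                 sd = 8))
}

cat("\n== ncds-like ==\n")
res_c <- calibrate(make_ncds,
                   ob_int = c(-2.5, -2.9, -2.4),
                   in_int = c(-1.0, -1.35, -1.6),
                   ob_target_f = c(0.111, 0.148, 0.234),
                   in_target_f = c(0.297, 0.337, 0.302))
sm_ncds <- res_c$sm
em <- exact_marginals(sm_ncds)
print(round(em$marginals, 4))
for (t in 2:3) {
  pers <- em$moment(paste0("obese_w", c(t - 1, t))) /
    em$marginals[[paste0("obese_w", t - 1)]]
  cat(sprintf("persistence w%d->w%d: %.3f\n", t - 1, t, pers))
}
for (t in 1:3) {
  ot <- paste0("obese_w", t); mt <- paste0("inactive_w", t)
  p1 <- em$moment(c(ot, mt)) / em$marginals[[ot]]
  p0 <- (em$marginals[[mt]] - em$moment(c(ot, mt))) / (1 - em$marginals[[ot]])
  cat(sprintf("inactivity w%d: obese %.3f vs non-obese %.3f\n", t, p1, p0))
}
write_scenario(sm_ncds, "inst/extdata/scenarios/ncds-like.yml")

# ---- null-mediation: T = 2, all exposure coefficients zero -----------------
sm_null <- structural_model(
  cohort_id = "null-mediation",
  wave_labels = c("1", "2"),
  baseline = c(male = 0.5, low_social_class = 0.3),
  confounders = list(
    smoker = list(
      c(`(Intercept)` = -0.8, low_social_class = 0.5),
      c(`(Intercept)` = -1.5, smoker_w1 = 2.2, low_social_class = 0.3))),
  mediator = list(
    c(`(Intercept)` = -0.7, smoker_w1 = 0.4, low_social_class = 0.4, male = -0.3),
    c(`(Intercept)` = -1.2, inactive_w1 = 1.6, smoker_w2 = 0.4, male = -0.3)),
  exposure = list(
    c(`(Intercept)` = -1.1, low_social_class = 0.3, inactive_w1 = 0.3),
    c(`(Intercept)` = -2.0, obese_w1 = 4.5, inactive_w2 = 0.3)),
  outcome = c(`(Intercept)` = -1.0, inactive_w2 = 0.5, inactive_w1 = 0.2,
              smoker_w2 = 0.4, low_social_class = 0.3, male = -0.2))
write_scenario(sm_null, "inst/extdata/scenarios/null-mediation.yml")
cat("\nnull oracle effects (should all be exactly 1):\n")
print(exact_effects(sm_null)$effects)

# ---- no-direct-effect: exposure acts only via the mediator ----------------
sm_nde <- structural_model(
  cohort_id = "no-direct-effect",
  wave_labels = c("1", "2"),
  baseline = c(male = 0.5, low_social_class = 0.3),
  confounders = list(
    smoker = list(
      c(`(Intercept)` = -0.8, low_social_class = 0.5),
      c(`(Intercept)` = -1.5, smoker_w1 = 2.2, low_social_class = 0.3))),
  mediator = list(
    c(`(Intercept)` = -0.6, smoker_w1 = 0.4, male = -0.3),
    c(`(Intercept)` = -1.1, inactive_w1 = 1.4, obese_w1 = 1.0, smoker_w2 = 0.3, male = -0.3)),
  exposure = list(
    c(`(Intercept)` = -1.0, inactive_w1 = 0.4),
    c(`(Intercept)` = -1.8, obese_w1 = 4.5, inactive_w2 = 0.4)),
  outcome = c(`(Intercept)` = -1.3, inactive_w2 = 1.2, inactive_w1 = 0.6,
              smoker_w2 = 0.3, low_social_class = 0.3, male = -0.2))
write_scenario(sm_nde, "inst/extdata/scenarios/no-direct-effect.yml")
cat("\nno-direct oracle effects (rNDE must be exactly 1 for persistent):\n")
print(exact_effects(sm_nde)$effects)

# ---- toy-mediation: both pathways active, 2 waves, 1 confounder ------------
sm_toy <- structural_model(
  cohort_id = "toy-mediation",
  wave_labels = c("1", "2"),
  baseline = c(male = 0.5, low_social_class = 0.3),
  confounders = list(
    smoker = list(
      c(`(Intercept)` = -0.8, low_social_class = 0.5),
      c(`(Intercept)` = -1.5, smoker_w1 = 2.2, obese_w1 = 0.3, low_social_class = 0.3))),
  mediator = list(
    c(`(Intercept)` = -0.6, smoker_w1 = 0.4, male = -0.3),
    c(`(Intercept)` = -1.1, inactive_w1 = 1.4, obese_w1 = 0.8, smoker_w2 = 0.3, male = -0.3)),
  exposure = list(
    c(`(Intercept)` = -1.0, inactive_w1 = 0.4, low_social_class = 0.3),
    c(`(Intercept)` = -1.8, obese_w1 = 4.5, inactive_w2 = 0.4)),
  outcome = c(`(Intercept)` = -1.6, obese_w1 = 0.7, obese_w2 = 0.5,
              inactive_w2 = 0.9, inactive_w1 = 0.4, smoker_w2 = 0.3,
              low_social_class = 0.3, male = -0.2))
write_scenario(sm_toy, "inst/extdata/scenarios/toy-mediation.yml")
cat("\ntoy oracle effects:\n")
print(exact_effects(sm_toy)$effects)
cat("\ndone\n")
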