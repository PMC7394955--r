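#' Generate a complete synthetic cohort from a structural model
#'
#' Subjects are drawn by forward simulation in the declared causal order:
#' independent Bernoulli baseline covariates, then per wave the time-varying
#' confounders, the mediator (inactivity) and the exposure (obesity), then a
#' binary distal outcome \code{y} from the outcome model. When the model
#' carries a score specification, a continuous functioning score
#' \code{pf_score} (0-100, lower = worse, rounded to integers so realistic
#' ties occur) and per-wave BMI columns consistent with the obesity
#' indicators are also emitted, so the derivation layer
#' (\code{\link{derive_obesity}}, \code{\link{dichotomize_outcome}}) is
#' exercised end to end. Deterministic given \code{seed}.
#'
#' @param sm a \code{\link{structural_model}}.
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @param design optional \code{cohort_design}; defaults to
#'   \code{\link{as_cohort_design}(sm)}.
#' @return A \code{longitudinal_cohort}.
#' @export
generate_cohort <- function(sm, n, seed = 1, design = as_cohort_design(sm)) {
  stopifnot(inherits(sm, "structural_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  K <- sm$n_waves
  lnames <- names(sm$confounders)
  with_seed(seed, {
    env <- list()
    for (v in names(sm$baseline)) {
      env[[v]] <- as.numeric(stats::rbinom(n, 1L, sm$baseline[[v]]))
    }
    draw <- function(coef) {
      p <- stats::plogis(eval_lp(coef, env, n))
      as.numeric(stats::runif(n) < p)
    }
    for (t in seq_len(K)) {
      for (j in seq_along(lnames)) {
        env[[wname(lnames[j], t)]] <- draw(sm$confounders[[j]][[t]])
      }
      env[[wname(sm$mediator_var, t)]] <- draw(sm$mediator[[t]])
      env[[wname(sm$exposure_var, t)]] <- draw(sm$exposure[[t]])
    }
    env$y <- draw(sm$outcome)
    if (!is.null(sm$score)) {
      raw <- eval_lp(sm$score$coef, env, n) + stats::rnorm(n, 0, sm$score$sd)
      env$pf_score <- round(pmin(100, pmax(0, raw)))
      for (t in seq_len(K)) {
        ob <- env[[wname(sm$exposure_var, t)]]
        env[[wname("bmi", t)]] <- round(
          ob * (30 + stats::rgamma(n, shape = 2, rate = 0.55)) +
          (1 - ob) * pmax(16, 29.5 - stats::rgamma(n, shape = 3.5, rate = 0.75)),
          1)
      }
    }
    longitudinal_cohort(as.data.frame(env, check.names = FALSE), design)
  })
}

scenario_file <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(name, ".yml"),
                      package = "medgf")
  if (!nzchar(path)) {
    stop("unknown scenario '", name, "'", call. = FALSE)
  }
  path
}

#' Shipped preset emulating the wave structure of one of the two cohorts
#'
#' Presets are version-controlled YAML files (see
#' \code{system.file("extdata/scenarios", package = "medgf")}) calibrated so
#' that simulated marginals qualitatively match the published descriptive
#' tables: rising, effectively absorbing obesity (wave-1 about 5-11\%, final
#' wave about 23-30\%, persistence \eqn{P(A_t = 1 | A_{t-1} = 1) \ge 0.95}),
#' inactivity about 30-65\% and higher among the obese at every wave, and
#' both a direct and an inactivity-mediated positive pathway from obesity to
#' poor functioning. Baseline confounder prevalences use round documented
#' values. Presets match marginal structure only; they make no attempt to
#' reproduce the restricted cohorts' joint distributions or published effect
#' estimates.
#'
#' @param cohort_id \code{"nshd-like"} (4 waves, nominal ages 36, 43, 53,
#'   60-64) or \code{"ncds-like"} (3 waves, nominal ages 33, 42, 50).
#' @return A \code{structural_model}.
#' @export
paper_like_scenario <- function(cohort_id = c("nshd-like", "ncds-like")) {
  if (!is.character(cohort_id) || length(cohort_id) != 1L ||
      !cohort_id %in% c("nshd-like", "ncds-like")) {
    stop("unknown scenario label; use \"nshd-like\" or \"ncds-like\"",
         call. = FALSE)
  }
  read_scenario(scenario_file(cohort_id))
}

#' Null-mediation test scenario
#'
#' A two-wave, one-confounder preset in which every exposure coefficient is
#' zero in the confounder, mediator and outcome models: the exact oracle
#' effects are 1 for every regime, making it the canonical fixture for null
#' recovery of the fitted pipeline.
#'
#' @return A \code{structural_model}.
#' @export
null_mediation_scenario <- function() {
  read_scenario(scenario_file("null-mediation"))
}

#' Pathway-isolation test scenario (indirect effect only)
#'
#' Two-wave, one-confounder preset with a nonzero exposure-to-mediator and
#' mediator-to-outcome pathway but zero direct exposure-to-outcome and
#' exposure-to-confounder coefficients: the exact rNDE is 1 and the exact
#' rNIE exceeds 1 for the persistent regime.
#'
#' @return A \code{structural_model}.
#' @export
no_direct_effect_scenario <- function() {
  read_scenario(scenario_file("no-direct-effect"))
}

#' Small two-wave scenario with both direct and mediated effects
#'
#' Used for oracle-equivalence and bootstrap-coverage checks: the binary
#' state space is small enough for exact enumeration while both pathways are
#' active.
#'
#' @return A \code{structural_model}.
#' @export
toy_mediation_scenario <- function() {
  read_scenario(scenario_file("toy-mediation"))
}
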