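#' Define a generative structural model for a synthetic cohort
#'
#' A \code{structural_model} is the all-binary data-generating counterpart of
#' a fitted \code{model_set}: independent Bernoulli baseline covariates, then
#' per wave (in the fixed within-wave order confounders, mediator, exposure)
#' a logistic model per variable whose named coefficients may reference only
#' temporally prior variables, a logistic outcome model on the full history,
#' and a Gaussian continuous functioning score (0-100, lower = worse) used to
#' exercise the centile dichotomizer. It doubles as the exact specification
#' the enumeration oracle integrates over.
#'
#' @param cohort_id label for the scenario.
#' @param wave_labels character vector of wave names; length = number of
#'   waves T.
#' @param baseline named numeric vector of marginal probabilities of the
#'   independent binary baseline covariates; must include the gender
#'   variable.
#' @param confounders named list, one element per time-varying confounder
#'   stem; each element a list of T named coefficient vectors (element t is
#'   the logistic model of \code{<stem>_w<t>}).
#' @param mediator list of T coefficient vectors for the per-wave mediator
#'   (inactivity).
#' @param exposure list of T coefficient vectors for the per-wave exposure
#'   (obesity); used only when generating data, never when evaluating
#'   counterfactuals (regimes set the exposure deterministically).
#' @param outcome named coefficient vector for the binary distal outcome.
#' @param score list with \code{coef} (named vector, linear model of the
#'   continuous score on the full history, intercept on the 0-100 scale) and
#'   \code{sd} (residual standard deviation).
#' @param mediator_var,exposure_var,gender_var variable stems/names (defaults
#'   \code{"inactive"}, \code{"obese"}, \code{"male"}).
#' @return An object of class \code{structural_model}.
#' @export
structural_model <- function(cohort_id, wave_labels, baseline,
                             confounders, mediator, exposure, outcome,
                             score = NULL,
                             mediator_var = "inactive",
                             exposure_var = "obese",
                             gender_var = "male") {
  n_waves <- length(wave_labels)
  stopifnot(n_waves >= 2L, is.numeric(baseline), !is.null(names(baseline)))
  if (any(baseline <= 0 | baseline >= 1)) {
    stop("baseline probabilities must lie strictly in (0,1)", call. = FALSE)
  }
  if (!gender_var %in% names(baseline)) {
    stop("baseline must include the gender variable '", gender_var, "'",
         call. = FALSE)
  }
  sm <- structure(list(
    cohort_id = cohort_id,
    wave_labels = as.character(wave_labels),
    n_waves = n_waves,
    baseline = baseline,
    confounders = confounders,
    mediator = mediator,
    exposure = exposure,
    outcome = outcome,
    score = score,
    mediator_var = mediator_var,
    exposure_var = exposure_var,
    gender_var = gender_var
  ), class = "structural_model")
  validate_structural_model(sm)
  sm
}

# names of covariates a model at (kind, wave t, confounder index j) may use
allowed_history <- function(sm, kind, t, j = NULL) {
  lnames <- names(sm$confounders)
  prior <- seq_len(t - 1L)
  base <- names(sm$baseline)
  hist <- c(base,
            wname(lnames, prior),
            wname(sm$mediator_var, prior),
            wname(sm$exposure_var, prior))
  switch(kind,
    confounder = c(hist, if (!is.null(j) && j > 1L) wname(lnames[seq_len(j - 1L)], t)),
    mediator = c(hist, wname(lnames, t)),
    exposure = c(hist, wname(lnames, t), wname(sm$mediator_var, t)),
    outcome = c(base, wname(c(lnames, sm$mediator_var, sm$exposure_var),
                            seq_len(sm$n_waves))),
    stop("unknown model kind '", kind, "'", call. = FALSE))
}

validate_structural_model <- function(sm) {
  T <- sm$n_waves
  lnames <- names(sm$confounders)
  chk <- function(coef, kind, t, j = NULL, label) {
    if (is.null(coef) || is.null(names(coef))) {
      stop("missing or unnamed coefficients for ", label, call. = FALSE)
    }
    bad <- setdiff(setdiff(names(coef), "(Intercept)"),
                   allowed_history(sm, kind, t, j))
    if (length(bad)) {
      stop(label, " references non-prior variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (j in seq_along(sm$confounders)) {
    if (length(sm$confounders[[j]]) != T) {
      stop("confounder '", lnames[j], "' needs one model per wave",
           call. = FALSE)
    }
    for (t in seq_len(T)) {
      chk(sm$confounders[[j]][[t]], "confounder", t, j,
          paste0(lnames[j], "_w", t))
    }
  }
  stopifnot(length(sm$mediator) == T, length(sm$exposure) == T)
  for (t in seq_len(T)) {
    chk(sm$mediator[[t]], "mediator", t, label = wname(sm$mediator_var, t))
    chk(sm$exposure[[t]], "exposure", t, label = wname(sm$exposure_var, t))
  }
  chk(sm$outcome, "outcome", T, label = "outcome")
  if (!is.null(sm$score)) chk(sm$score$coef, "outcome", T, label = "score")
  invisible(sm)
}

#' @export
print.structural_model <- function(x, ...) {
  cat("<structural_model> ", x$cohort_id, ": ", x$n_waves, " waves, ",
      length(x$baseline), " baseline vars, ",
      length(x$confounders), " time-varying confounder(s)\n", sep = "")
  invisible(x)
}

#' Cohort design implied by a structural model
#'
#' @param sm a \code{structural_model}.
#' @param waves_used optional prefix of waves for analysis.
#' @return A \code{\link{cohort_design}} whose outcome is the generated
#'   continuous functioning score (with the binary structural outcome
#'   retained in column \code{y}).
#' @export
as_cohort_design <- function(sm, waves_used = NULL) {
  stopifnot(inherits(sm, "structural_model"))
  cohort_design(
    cohort_id = sm$cohort_id,
    wave_labels = sm$wave_labels,
    baseline_vars = names(sm$baseline),
    timevarying_confounder_vars = names(sm$confounders),
    mediator_var = sm$mediator_var,
    exposure_var = sm$exposure_var,
    bmi_var = if (!is.null(sm$score)) "bmi" else NULL,
    outcome_score_var = if (!is.null(sm$score)) "pf_score" else NULL,
    outcome_var = "y",
    gender_var = sm$gender_var,
    waves_used = waves_used
  )
}

#' Convert a structural model into a model set with the true coefficients
#'
#' Bypasses fitting: the resulting \code{model_set} carries the generative
#' coefficients for every time-varying confounder, the mediator and the
#' outcome, so the Monte Carlo g-computation can be checked against the
#' enumeration oracle without estimation noise.
#'
#' @param sm a \code{structural_model}; all waves are used.
#' @return A \code{model_set}.
#' @export
as_model_set <- function(sm) {
  stopifnot(inherits(sm, "structural_model"))
  T <- sm$n_waves
  lnames <- names(sm$confounders)
  conf <- lapply(seq_len(T), function(t) {
    ms <- lapply(seq_along(lnames), function(j) {
      list(response = wname(lnames[j], t), coef = sm$confounders[[j]][[t]])
    })
    names(ms) <- lnames
    ms
  })
  med <- lapply(seq_len(T), function(t) {
    list(response = wname(sm$mediator_var, t), coef = sm$mediator[[t]])
  })
  structure(list(
    design = as_cohort_design(sm),
    baseline_vars = names(sm$baseline),
    confounder_models = conf,
    mediator_models = med,
    outcome_model = list(response = "y", coef = sm$outcome),
    n = NA_integer_,
    diagnostics = list(converged = TRUE, source = "structural")
  ), class = "model_set")
}

# ---- scenario files (structured text, YAML) --------------------------------

coef_to_list <- function(coef) as.list(coef)
list_to_coef <- function(lst) {
  v <- vapply(lst, as.numeric, numeric(1))
  stats::setNames(v, names(lst))
}

#' Read a structural-model scenario from a YAML file
#'
#' @param path scenario file (see the files under
#'   \code{system.file("extdata/scenarios", package = "medgf")} for the
#'   format).
#' @return A \code{structural_model}.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  structural_model(
    cohort_id = y$cohort_id,
    wave_labels = y$wave_labels,
    baseline = list_to_coef(y$baseline),
    confounders = lapply(y$confounders, function(per_wave)
      lapply(per_wave, list_to_coef)),
    mediator = lapply(y$mediator, list_to_coef),
    exposure = lapply(y$exposure, list_to_coef),
    outcome = list_to_coef(y$outcome),
    score = if (!is.null(y$score))
      list(coef = list_to_coef(y$score$coef), sd = as.numeric(y$score$sd)),
    mediator_var = y$mediator_var %||% "inactive",
    exposure_var = y$exposure_var %||% "obese",
    gender_var = y$gender_var %||% "male"
  )
}

#' Write a structural-model scenario to a YAML file
#'
#' @param sm a \code{structural_model}.
#' @param path output file.
#' @export
write_scenario <- function(sm, path) {
  stopifnot(inherits(sm, "structural_model"))
  y <- list(
    cohort_id = sm$cohort_id,
    wave_labels = as.list(sm$wave_labels),
    mediator_var = sm$mediator_var,
    exposure_var = sm$exposure_var,
    gender_var = sm$gender_var,
    baseline = coef_to_list(sm$baseline),
    confounders = lapply(sm$confounders, function(per_wave)
      lapply(per_wave, coef_to_list)),
    mediator = lapply(sm$mediator, coef_to_list),
    exposure = lapply(sm$exposure, coef_to_list),
    outcome = coef_to_list(sm$outcome),
    score = if (!is.null(sm$score))
      list(coef = coef_to_list(sm$score$coef), sd = sm$score$sd)
  )
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}
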