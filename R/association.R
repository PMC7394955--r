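# Descriptive association stage: adjusted logistic odds ratios for obesity /
# inactivity at each wave and for trajectory classes, with configurable
# adjustment sets. This stage ignores time-varying confounding by design; the
# mediational g-formula is the causal stage.

#' Declare an adjustment set for the association stage
#'
#' Named covariate sets mirroring the published layout: \code{model1}
#' (baseline confounders) and \code{model2} (\code{model1} plus the same-wave
#' co-factor, obesity or inactivity as appropriate) for per-wave terms;
#' \code{modelA} (gender only) and \code{modelB} (gender plus baseline
#' confounders) for trajectory classes. Sets are config-driven: any covariate
#' list present in the cohort is accepted.
#'
#' @param name label (\code{model1}, \code{model2}, \code{modelA},
#'   \code{modelB} or custom).
#' @param terms character vector of covariate column names.
#' @return An object of class \code{adjustment_set}.
#' @export
adjustment_set <- function(name, terms) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, terms = unique(as.character(terms))),
            class = "adjustment_set")
}

# reference = most frequent level (stable under resampling)
freq_ref_factor <- function(x) {
  f <- as.factor(x)
  stats::relevel(f, ref = names(which.max(table(f))))
}

#' Adjusted odds ratio for one term by maximum-likelihood logistic regression
#'
#' Fits \code{outcome ~ term + adjustment terms} and returns
#' \code{OR = exp(coefficient)} with the 95\% Wald interval
#' \code{exp(coefficient +/- 1.96 SE)}. A categorical term (e.g. the
#' trajectory class) enters as indicator contrasts and yields one row per
#' non-reference level; for \code{trajectory} the reference is
#' \code{"never"}. Categorical adjustment covariates use their most frequent
#' level as reference. Non-convergence and separation raise named errors
#' rather than returning silently penalized estimates.
#'
#' @param cohort a derived \code{longitudinal_cohort}.
#' @param term covariate column whose odds ratio is wanted.
#' @param outcome binary outcome column (default \code{"poor_pf"}).
#' @param adjust an \code{\link{adjustment_set}} (possibly with no terms).
#' @param reference reference level when \code{term} is categorical
#'   (default \code{"never"} for \code{trajectory}, otherwise the most
#'   frequent level).
#' @return A data.frame with columns \code{term}, \code{level},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{n},
#'   \code{model}.
#' @export
fit_adjusted_or <- function(cohort, term, outcome = "poor_pf",
                            adjust = adjustment_set("crude", character(0)),
                            reference = NULL) {
  stopifnot(inherits(cohort, "longitudinal_cohort"),
            inherits(adjust, "adjustment_set"))
  tab <- cohort$table
  need <- c(outcome, term, adjust$terms)
  absent <- setdiff(need, names(tab))
  if (length(absent)) {
    stop("cohort lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  y <- tab[[outcome]]
  if (any(!(y %in% c(0, 1)))) {
    stop("outcome column '", outcome, "' must be binary 0/1", call. = FALSE)
  }
  dat <- data.frame(.y = y)
  tv <- tab[[term]]
  categorical <- is.character(tv) || is.factor(tv)
  if (categorical) {
    ref <- reference %||% if (term == "trajectory") "never" else
      names(which.max(table(tv)))
    if (!ref %in% tv) {
      stop("reference level '", ref, "' absent from term '", term, "'",
           call. = FALSE)
    }
    dat$.term <- stats::relevel(factor(tv), ref = ref)
  } else {
    dat$.term <- as.numeric(tv)
  }
  kept <- character(0)
  for (cv in setdiff(adjust$terms, term)) {
    v <- tab[[cv]]
    if (length(unique(v)) < 2L) next # constant covariate carries no adjustment
    dat[[cv]] <- if (is.character(v) || is.factor(v)) freq_ref_factor(v) else as.numeric(v)
    kept <- c(kept, cv)
  }
  form <- stats::as.formula(paste(
    ".y ~ .term",
    if (length(kept))
      paste("+", paste(sprintf("`%s`", kept), collapse = " + "))
    else ""))
  fit <- suppressWarnings(stats::glm(
    form, data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  if (!fit$converged) {
    stop("non-convergence estimating OR for '", term, "' (", adjust$name, ")",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear covariates estimating OR for '", term, "' (",
         adjust$name, ")", call. = FALSE)
  }
  if (max(abs(cf)) > 20) {
    stop("possible separation estimating OR for '", term, "' (",
         adjust$name, ")", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  sel <- grep("^\\.term", names(cf))
  lev <- if (categorical) sub("^\\.term", "", names(cf)[sel]) else term
  data.frame(
    term = term,
    level = lev,
    odds_ratio = exp(unname(cf[sel])),
    ci_low = exp(unname(cf[sel] - 1.96 * se[sel])),
    ci_high = exp(unname(cf[sel] + 1.96 * se[sel])),
    n = nrow(dat),
    model = adjust$name,
    stringsAsFactors = FALSE
  )
}

#' Adjusted odds-ratio table for all waves and trajectory classes
#'
#' The descriptive layout of the association stage: per wave the obesity and
#' inactivity odds ratios under \code{model1} (baseline confounders) and
#' \code{model2} (plus the same-wave co-factor), and the trajectory-class
#' odds ratios (reference \code{"never"}, whose OR is fixed at 1) under
#' \code{modelA} (gender only) and \code{modelB} (gender plus baseline
#' confounders).
#'
#' @param cohort a derived \code{longitudinal_cohort}.
#' @param design a \code{cohort_design}; defaults to the cohort's own.
#' @param baseline_terms covariates of \code{model1}/\code{modelB}; defaults
#'   to the design's baseline confounders.
#' @return A data.frame, one row per term and model.
#' @export
association_table <- function(cohort, design = cohort$design,
                              baseline_terms = design$baseline_vars) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  m1 <- adjustment_set("model1", baseline_terms)
  mA <- adjustment_set("modelA", design$gender_var)
  mB <- adjustment_set("modelB", unique(c(design$gender_var, baseline_terms)))
  out <- list()
  for (t in seq_len(design$n_waves)) {
    ob <- wname(design$exposure_var, t)
    mv <- wname(design$mediator_var, t)
    m2_ob <- adjustment_set("model2", c(baseline_terms, mv))
    m2_in <- adjustment_set("model2", c(baseline_terms, ob))
    out[[length(out) + 1L]] <- cbind(wave = t, fit_adjusted_or(cohort, ob, adjust = m1))
    out[[length(out) + 1L]] <- cbind(wave = t, fit_adjusted_or(cohort, ob, adjust = m2_ob))
    out[[length(out) + 1L]] <- cbind(wave = t, fit_adjusted_or(cohort, mv, adjust = m1))
    out[[length(out) + 1L]] <- cbind(wave = t, fit_adjusted_or(cohort, mv, adjust = m2_in))
  }
  out[[length(out) + 1L]] <- cbind(wave = NA_integer_,
                                   fit_adjusted_or(cohort, "trajectory", adjust = mA))
  out[[length(out) + 1L]] <- cbind(wave = NA_integer_,
                                   fit_adjusted_or(cohort, "trajectory", adjust = mB))
  ref <- data.frame(wave = NA_integer_, term = "trajectory", level = "never",
                    odds_ratio = 1, ci_low = NA_real_, ci_high = NA_real_,
                    n = nrow(cohort$table), model = "reference",
                    stringsAsFactors = FALSE)
  rbind(do.call(rbind, out), ref)
}
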