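# Parametric mediational g-formula: wave-sequential logistic models, Monte
# Carlo g-computation of counterfactual risks under paired exposure regimes
# with interventional mediator draws, multiplicative effect decomposition,
# and subject-resampling bootstrap confidence intervals.

# ordered model specifications for a design: one logistic model per
# time-varying confounder per wave, per mediator per wave, plus the outcome,
# each conditioning on the full measured history permitted by the fixed
# within-wave ordering (confounders -> mediator -> exposure), main effects
model_specs <- function(design, outcome_col = "poor_pf") {
  K <- max(design$waves_used)
  lnames <- design$timevarying_confounder_vars
  med <- design$mediator_var
  expv <- design$exposure_var
  base <- design$baseline_vars
  specs <- list()
  for (t in seq_len(K)) {
    prior <- seq_len(t - 1L)
    hist <- c(base, wname(lnames, prior), wname(med, prior), wname(expv, prior))
    for (j in seq_along(lnames)) {
      specs[[length(specs) + 1L]] <- list(
        kind = "confounder", wave = t, var = lnames[j],
        response = wname(lnames[j], t),
        covariates = c(hist, if (j > 1L) wname(lnames[seq_len(j - 1L)], t)))
    }
    specs[[length(specs) + 1L]] <- list(
      kind = "mediator", wave = t, var = med,
      response = wname(med, t),
      covariates = c(hist, wname(lnames, t)))
  }
  allw <- seq_len(K)
  specs[[length(specs) + 1L]] <- list(
    kind = "outcome", wave = K, var = outcome_col,
    response = outcome_col,
    covariates = c(base, wname(lnames, allw), wname(med, allw),
                   wname(expv, allw)))
  specs
}

# IRLS logistic fit on a prebuilt numeric matrix; errors are named after the
# model so non-convergence and separation surface, never pass silently
fit_logit <- function(X, y, label) {
  if (stats::var(y) == 0) {
    stop("degenerate model for '", label, "': response has zero variance",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  cf <- fit$coefficients
  if (anyNA(cf)) {
    stop("degenerate model for '", label,
         "': collinear or constant covariate", call. = FALSE)
  }
  if (!fit$converged) {
    stop("non-convergence in model for '", label, "'", call. = FALSE)
  }
  if (max(abs(cf)) > 20) {
    stop("possible separation in model for '", label, "'", call. = FALSE)
  }
  cf
}

# fit every spec on rows `idx` of the master matrix (bootstrap fast path)
fit_specs <- function(mat, specs, idx, design, want_se = FALSE) {
  K <- max(design$waves_used)
  lnames <- design$timevarying_confounder_vars
  conf <- rep(list(stats::setNames(vector("list", length(lnames)), lnames)), K)
  medm <- vector("list", K)
  outm <- NULL
  n <- length(idx)
  for (sp in specs) {
    X <- cbind(`(Intercept)` = 1, mat[idx, sp$covariates, drop = FALSE])
    y <- mat[idx, sp$response]
    cf <- fit_logit(X, y, sp$response)
    names(cf) <- colnames(X)
    m <- list(response = sp$response, coef = cf)
    if (want_se) {
      p <- stats::plogis(drop(X %*% cf))
      w <- p * (1 - p)
      xtx <- crossprod(X * sqrt(w))
      m$se <- stats::setNames(sqrt(diag(solve(xtx))), colnames(X))
    }
    if (sp$kind == "confounder") {
      conf[[sp$wave]][[sp$var]] <- m
    } else if (sp$kind == "mediator") {
      medm[[sp$wave]] <- m
    } else {
      outm <- m
    }
  }
  structure(list(
    design = design,
    baseline_vars = design$baseline_vars,
    confounder_models = conf,
    mediator_models = medm,
    outcome_model = outm,
    n = n,
    diagnostics = list(converged = TRUE, source = "fitted")
  ), class = "model_set")
}

# numeric master matrix of all columns any spec touches
spec_matrix <- function(table, specs) {
  cols <- unique(unlist(lapply(specs, function(s) c(s$response, s$covariates))))
  absent <- setdiff(cols, names(table))
  if (length(absent)) {
    stop("cohort lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  m <- vapply(cols, function(cl) as.numeric(table[[cl]]), numeric(nrow(table)))
  dimnames(m) <- list(NULL, cols)
  m
}

#' Fit the wave-sequential conditional models of the mediational g-formula
#'
#' One maximum-likelihood logistic regression per time-varying confounder per
#' wave, per mediator (inactivity) per wave, and one for the distal outcome;
#' each model conditions, with main effects, on the baseline covariates and
#' the full measured history allowed by the fixed within-wave ordering
#' (confounders before mediator before exposure). Only the waves in
#' \code{design$waves_used} are modelled, so restricting the design with
#' \code{\link{use_waves}} reproduces the omit-last-wave sensitivity
#' analysis without changing the algorithm.
#'
#' @param cohort a derived \code{longitudinal_cohort}.
#' @param design a \code{cohort_design}; defaults to the cohort's own.
#' @param outcome_col binary outcome column (default \code{"poor_pf"}).
#' @return A \code{model_set}.
#' @export
fit_wave_models <- function(cohort, design = cohort$design,
                            outcome_col = "poor_pf") {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  if (max(design$waves_used) < 2L) {
    stop("the mediation analysis needs at least 2 analysis waves", call. = FALSE)
  }
  specs <- model_specs(design, outcome_col)
  mat <- spec_matrix(cohort$table, specs)
  fit_specs(mat, specs, seq_len(nrow(mat)), design, want_se = TRUE)
}

#' @export
print.model_set <- function(x, ...) {
  K <- length(x$mediator_models)
  cat("<model_set> ", K, " waves, ",
      length(x$confounder_models[[1]]), " confounder model(s)/wave, n = ",
      x$n, " (", x$diagnostics$source, ")\n", sep = "")
  invisible(x)
}

#' Monte Carlo counterfactual risk under paired exposure regimes
#'
#' Estimates \eqn{\psi(\bar a, \bar a')} by forward simulation from a fitted
#' (or true) \code{model_set}. Baseline covariate rows are recycled in a
#' balanced cycle so that every subject's covariates enter equally often; for
#' each simulated trajectory two streams are run: the mediator-generating
#' stream draws confounders and the mediator forward under exposure history
#' \eqn{\bar a'}, recording the mediator trajectory; the outcome stream then
#' re-draws confounders under exposure \eqn{\bar a} with the mediator fixed
#' at the recorded trajectory, and the fitted outcome probability is
#' evaluated. The returned risk is the grand mean; because the interventional
#' mediator distribution is conditioned on baseline covariates only, this is
#' the randomized-interventional-analogue construction. Deterministic given
#' \code{(models, baselines, n_mc, seed)}.
#'
#' @param models a \code{model_set}.
#' @param baselines data.frame of observed baseline-covariate rows.
#' @param regime_a exposure regime for the outcome stream.
#' @param regime_aprime exposure regime generating the mediator trajectory.
#' @param n_mc total number of simulated trajectories (>= 1).
#' @param seed integer seed for this evaluation.
#' @param weights optional non-negative weights over baseline rows; when
#'   given, rows are sampled proportionally instead of cycled (used to pass
#'   an enumerated baseline distribution).
#' @return Risk in \code{[0, 1]}, with attribute \code{mc_se} (Monte Carlo
#'   standard error of the mean).
#' @export
simulate_psi <- function(models, baselines, regime_a, regime_aprime,
                         n_mc, seed, weights = NULL) {
  stopifnot(inherits(models, "model_set"),
            inherits(regime_a, "exposure_regime"),
            inherits(regime_aprime, "exposure_regime"))
  if (!is.numeric(n_mc) || length(n_mc) != 1L || n_mc < 1) {
    stop("n_mc must be a positive integer", call. = FALSE)
  }
  n_mc <- as.integer(n_mc)
  design <- models$design
  K <- length(models$mediator_models)
  if (length(regime_a$values) != K || length(regime_aprime$values) != K) {
    stop("regime length (", length(regime_a$values),
         ") must match the number of analysis waves (", K, ")", call. = FALSE)
  }
  bvars <- models$baseline_vars
  baselines <- as.data.frame(baselines)
  absent <- setdiff(bvars, names(baselines))
  if (length(absent)) {
    stop("baselines lack column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  nb <- nrow(baselines)
  lnames <- names(models$confounder_models[[1]])
  med <- design$mediator_var
  expv <- design$exposure_var

  with_seed(seed, {
    idx <- if (is.null(weights)) {
      rep_len(seq_len(nb), n_mc)
    } else {
      sample.int(nb, n_mc, replace = TRUE, prob = weights)
    }
    benv <- lapply(bvars, function(v) as.numeric(baselines[[v]])[idx])
    names(benv) <- bvars

    # stream 1: interventional mediator draw under regime a'
    env1 <- benv
    for (t in seq_len(K)) env1[[wname(expv, t)]] <- regime_aprime$values[t]
    for (t in seq_len(K)) {
      for (j in seq_along(lnames)) {
        m <- models$confounder_models[[t]][[j]]
        p <- stats::plogis(eval_lp(m$coef, env1, n_mc))
        env1[[m$response]] <- as.numeric(stats::runif(n_mc) < p)
      }
      m <- models$mediator_models[[t]]
      p <- stats::plogis(eval_lp(m$coef, env1, n_mc))
      env1[[m$response]] <- as.numeric(stats::runif(n_mc) < p)
    }

    # stream 2: outcome stream under regime a with the mediator fixed
    env2 <- benv
    for (t in seq_len(K)) {
      env2[[wname(expv, t)]] <- regime_a$values[t]
      env2[[wname(med, t)]] <- env1[[wname(med, t)]]
    }
    for (t in seq_len(K)) {
      for (j in seq_along(lnames)) {
        m <- models$confounder_models[[t]][[j]]
        p <- stats::plogis(eval_lp(m$coef, env2, n_mc))
        env2[[m$response]] <- as.numeric(stats::runif(n_mc) < p)
      }
    }
    py <- stats::plogis(eval_lp(models$outcome_model$coef, env2, n_mc))
    psi <- mean(py)
    attr(psi, "mc_se") <- stats::sd(py) / sqrt(n_mc)
    psi
  })
}

# point effects from a fitted model set; psi values are shared across the
# three ratios so the decomposition rTE = rNDE x rNIE holds to machine
# precision by construction
compute_effects <- function(models, baselines, regimes, n_mc, seed,
                            weights = NULL) {
  ref <- Filter(function(r) all(r$values == 0L), regimes)
  if (length(ref) != 1L) {
    stop("regimes must include exactly one never-obese reference", call. = FALSE)
  }
  ref <- ref[[1L]]
  others <- Filter(function(r) any(r$values == 1L), regimes)
  if (length(others) < 1L) stop("no non-reference regime given", call. = FALSE)

  p_ref <- simulate_psi(models, baselines, ref, ref, n_mc,
                        derive_seed(seed, paste0("psi:", ref$label, ":", ref$label)),
                        weights)
  psi_rows <- list(data.frame(regime_a = ref$label, regime_aprime = ref$label,
                              psi = as.numeric(p_ref), stringsAsFactors = FALSE))
  eff <- list()
  for (rg in others) {
    paa <- simulate_psi(models, baselines, rg, rg, n_mc,
                        derive_seed(seed, paste0("psi:", rg$label, ":", rg$label)),
                        weights)
    if (is_last_wave_only(rg)) {
      # no mediator is measured between final-wave obesity onset and the
      # outcome, so the effect is not partitioned: only rTE is defined
      est <- c(rTE = as.numeric(paa) / as.numeric(p_ref),
               rNDE = NA_real_, rNIE = NA_real_)
      psi_rows[[length(psi_rows) + 1L]] <- data.frame(
        regime_a = rg$label, regime_aprime = rg$label,
        psi = as.numeric(paa), stringsAsFactors = FALSE)
    } else {
      par <- simulate_psi(models, baselines, rg, ref, n_mc,
                          derive_seed(seed, paste0("psi:", rg$label, ":", ref$label)),
                          weights)
      est <- c(rTE = as.numeric(paa) / as.numeric(p_ref),
               rNDE = as.numeric(par) / as.numeric(p_ref),
               rNIE = as.numeric(paa) / as.numeric(par))
      psi_rows[[length(psi_rows) + 1L]] <- data.frame(
        regime_a = rg$label, regime_aprime = c(rg$label, ref$label),
        psi = c(as.numeric(paa), as.numeric(par)), stringsAsFactors = FALSE)
    }
    eff[[length(eff) + 1L]] <- data.frame(
      regime = rg$label, effect = names(est), estimate = unname(est),
      stringsAsFactors = FALSE)
  }
  list(effects = do.call(rbind, eff), psi = do.call(rbind, psi_rows))
}

#' Randomized-interventional-analogue natural effects (point estimates)
#'
#' Fits the wave-sequential models once, computes the counterfactual risks
#' \eqn{\psi(\bar a^*, \bar a^*)}, \eqn{\psi(\bar a, \bar a)} and
#' \eqn{\psi(\bar a, \bar a^*)} per non-reference regime by Monte Carlo
#' g-computation, and returns the risk-ratio effects
#' rTE, rNDE and rNIE. For a regime differing from the reference only at the
#' final analysis wave the effect is structurally unpartitioned (no mediator
#' follows the exposure onset): only rTE is returned, rNDE and rNIE are
#' \code{NA}.
#'
#' @inheritParams fit_wave_models
#' @param regimes list of \code{exposure_regime}s including the never-obese
#'   reference; defaults to \code{\link{standard_regimes}} on the design.
#' @param n_mc total simulated trajectories per counterfactual risk.
#' @param seed integer master seed; all Monte Carlo substreams derive from it.
#' @param models optional prefitted \code{model_set} (skips fitting).
#' @return An \code{effect_estimates} object.
#' @export
estimate_randomized_effects <- function(cohort, design = cohort$design,
                                        regimes = standard_regimes(design),
                                        n_mc = 10000, seed = 1,
                                        models = NULL) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  if (is.null(models)) models <- fit_wave_models(cohort, design)
  baselines <- cohort$table[design$baseline_vars]
  res <- compute_effects(models, baselines, regimes, n_mc, seed)
  structure(list(
    effects = res$effects,
    psi = res$psi,
    n_mc = as.integer(n_mc),
    n_boot = NA_integer_,
    seed = as.integer(seed),
    n = nrow(cohort$table),
    exact = FALSE
  ), class = "effect_estimates")
}

#' Bootstrap confidence intervals for the randomized natural effects
#'
#' Resamples subjects with replacement; per replicate the wave-sequential
#' models are refitted and all effects recomputed on an independent Monte
#' Carlo substream. The standard error of each effect is the standard
#' deviation of its replicate estimates and the 95\% confidence interval is
#' the symmetric normal interval (point estimate \eqn{\pm} 1.96 SE).
#' Replicates whose models fail to fit (non-convergence, separation,
#' degenerate resample) are dropped and counted; more than 10\% failures is
#' an error.
#'
#' @inheritParams estimate_randomized_effects
#' @param n_boot number of bootstrap replicates (>= 2; 500 in the headline
#'   analysis, scale down for quick runs).
#' @return An \code{effect_estimates} object with \code{se}, \code{ci_low},
#'   \code{ci_high} columns and failure diagnostics.
#' @export
bootstrap_effects <- function(cohort, design = cohort$design,
                              regimes = standard_regimes(design),
                              n_boot = 500, n_mc = 10000, seed = 1) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  if (!is.numeric(n_boot) || n_boot < 2) {
    stop("n_boot must be at least 2", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  specs <- model_specs(design)
  mat <- spec_matrix(cohort$table, specs)
  n <- nrow(mat)
  bmat <- cohort$table[design$baseline_vars]

  point_models <- fit_specs(mat, specs, seq_len(n), design)
  point <- compute_effects(point_models, bmat, regimes, n_mc,
                           derive_seed(seed, "mc:0"))

  eff_names <- paste(point$effects$regime, point$effects$effect, sep = ":")
  reps <- matrix(NA_real_, n_boot, length(eff_names),
                 dimnames = list(NULL, eff_names))
  n_failed <- 0L
  for (r in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, paste0("boot:", r)),
                     sample.int(n, n, replace = TRUE))
    est <- tryCatch({
      mr <- fit_specs(mat, specs, idx, design)
      compute_effects(mr, bmat[idx, , drop = FALSE], regimes, n_mc,
                      derive_seed(seed, paste0("mc:", r)))$effects$estimate
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else reps[r, ] <- est
  }
  if (n_failed > 0.1 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed to fit ",
         "(more than 10%)", call. = FALSE)
  }
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  out <- point$effects
  out$se <- unname(se)
  out$ci_low <- out$estimate - 1.96 * out$se
  out$ci_high <- out$estimate + 1.96 * out$se
  structure(list(
    effects = out,
    psi = point$psi,
    n_mc = as.integer(n_mc),
    n_boot = n_boot,
    n_failed = n_failed,
    seed = as.integer(seed),
    n = n,
    exact = FALSE
  ), class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, digits = 3, ...) {
  hdr <- if (isTRUE(x$exact)) "exact (enumeration oracle)" else
    paste0("n = ", x$n, ", n_mc = ", x$n_mc,
           if (!is.na(x$n_boot %||% NA)) paste0(", n_boot = ", x$n_boot,
                                                " (", x$n_failed %||% 0L,
                                                " failed)"))
  cat("<effect_estimates> ", hdr, "\n", sep = "")
  print(format(x$effects, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.effect_estimates <- function(x, ...) x$effects

#' Effects table in the regime-by-effect layout of the headline analysis
#'
#' @param x an \code{effect_estimates}.
#' @return A data.frame with one row per effect (rTE, rNDE, rNIE) and one
#'   column per regime, entries formatted as \code{"est (lo, hi)"} when CIs
#'   are available.
#' @export
effects_wide <- function(x) {
  stopifnot(inherits(x, "effect_estimates"))
  e <- x$effects
  fmt <- function(row) {
    if (is.na(row$estimate)) return("")
    if (!is.null(row$ci_low) && !is.na(row$ci_low)) {
      sprintf("%.2f (%.2f, %.2f)", row$estimate, row$ci_low, row$ci_high)
    } else {
      sprintf("%.3f", row$estimate)
    }
  }
  regimes <- unique(e$regime)
  effects <- c("rTE", "rNDE", "rNIE")
  out <- data.frame(effect = effects, stringsAsFactors = FALSE)
  for (rg in regimes) {
    out[[rg]] <- vapply(effects, function(ef) {
      row <- e[e$regime == rg & e$effect == ef, , drop = FALSE]
      if (nrow(row) == 0L) "" else fmt(as.list(row[1L, ]))
    }, character(1))
  }
  out
}
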