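# Exact enumeration over all-binary structural models. Binary configurations
# are indexed by the bits of an integer vector 0:(2^nbits - 1); any variable
# column is re-derived from its bit position on demand, so memory stays at a
# few numeric vectors even for 2^20 configurations.

# column of variable at bit position `pos` (0-based) for configuration ids `idx`
bitcol <- function(idx, pos) bitwAnd(bitwShiftR(idx, pos), 1L)

# linear predictor over an enumeration grid: names in `bitpos` are grid
# variables, anything else must be a scalar in `fixed` (baseline value,
# regime exposure, or a mediator fixed by the outcome stream)
enum_lp <- function(coef, bitpos, fixed, idx) {
  nms <- names(coef)
  i0 <- match("(Intercept)", nms)
  lp <- rep.int(if (is.na(i0)) 0 else coef[[i0]], length(idx))
  for (k in seq_along(coef)) {
    if (!is.na(i0) && k == i0) next
    nm <- nms[[k]]
    p <- bitpos[[nm]]
    if (!is.null(p)) {
      lp <- lp + coef[[k]] * bitcol(idx, p)
    } else if (!is.null(fixed[[nm]])) {
      lp <- lp + coef[[k]] * fixed[[nm]]
    } else {
      stop("model references unknown variable '", nm, "'", call. = FALSE)
    }
  }
  lp
}

# enumerate all baseline configurations of independent Bernoulli covariates:
# data.frame of 0/1 columns plus a probability column `.p`
baseline_grid <- function(baseline) {
  nv <- length(baseline)
  idx <- 0:(2^nv - 1L)
  g <- data.frame(row.names = seq_along(idx))
  p <- rep(1, length(idx))
  for (j in seq_len(nv)) {
    x <- bitcol(idx, j - 1L)
    g[[names(baseline)[j]]] <- x
    p <- p * ifelse(x == 1L, baseline[[j]], 1 - baseline[[j]])
  }
  g$.p <- p
  g
}

oracle_guard <- function(n_bits, what) {
  if (n_bits > 22L) {
    stop("state space too large for exact enumeration (", what, ": 2^",
         n_bits, " configurations exceeds the 2^22 guard)", call. = FALSE)
  }
}

#' Exact counterfactual risk by full enumeration
#'
#' Computes \eqn{\psi(\bar a, \bar a')} — the population risk of the outcome
#' when the exposure is set to trajectory \eqn{\bar a} while the mediator
#' trajectory is drawn from its interventional distribution under
#' \eqn{\bar a'} given baseline covariates — by exact summation over every
#' binary configuration of a \code{\link{structural_model}}: for each
#' baseline configuration, the mediator-trajectory law under \eqn{\bar a'}
#' is obtained by marginalizing confounder paths, and the expected outcome
#' under \eqn{\bar a} with the mediator fixed is obtained by marginalizing a
#' second, independent confounder stream. No sampling is involved; this is
#' the ground truth against which the Monte Carlo g-computation is tested.
#'
#' @param sm a \code{structural_model} (all-binary).
#' @param regime_a exposure regime for the outcome stream.
#' @param regime_aprime exposure regime generating the mediator trajectory.
#' @return The exact risk in \code{[0, 1]}.
#' @export
exact_psi <- function(sm, regime_a, regime_aprime) {
  stopifnot(inherits(sm, "structural_model"),
            inherits(regime_a, "exposure_regime"),
            inherits(regime_aprime, "exposure_regime"))
  K <- sm$n_waves
  if (length(regime_a$values) != K || length(regime_aprime$values) != K) {
    stop("regime length must equal the model's number of waves", call. = FALSE)
  }
  lnames <- names(sm$confounders)
  nL <- length(lnames)
  nV <- length(sm$baseline)
  oracle_guard(nV + 2L * K * nL + K, "baseline x confounder paths x mediator")

  # stream 1 grid: per wave the confounders then the mediator
  s1_vars <- as.vector(vapply(seq_len(K), function(t)
    c(wname(lnames, t), wname(sm$mediator_var, t)), character(nL + 1L)))
  bitpos1 <- stats::setNames(as.list(seq_along(s1_vars) - 1L), s1_vars)
  idx1 <- 0:(2^length(s1_vars) - 1L)
  mpos1 <- vapply(wname(sm$mediator_var, seq_len(K)),
                  function(v) bitpos1[[v]], integer(1))

  # stream 2 grid: mediator bits (weighted later by the stream-1 law)
  # followed by a fresh set of confounder bits
  s2_vars <- c(wname(sm$mediator_var, seq_len(K)),
               if (nL > 0L) as.vector(vapply(seq_len(K), function(t)
                 wname(lnames, t), character(nL))))
  bitpos2 <- stats::setNames(as.list(seq_along(s2_vars) - 1L), s2_vars)
  idx2 <- 0:(2^length(s2_vars) - 1L)

  vg <- baseline_grid(sm$baseline)
  exp_names <- wname(sm$exposure_var, seq_len(K))
  psi <- 0
  for (r in seq_len(nrow(vg))) {
    vfix <- as.list(vg[r, names(sm$baseline), drop = FALSE])
    pv <- vg$.p[r]

    # P(mbar | a', v): marginalize confounder paths under regime a'
    fixed1 <- c(vfix, stats::setNames(as.list(regime_aprime$values), exp_names))
    prob1 <- rep(1, length(idx1))
    for (t in seq_len(K)) {
      for (j in seq_len(nL)) {
        p <- stats::plogis(enum_lp(sm$confounders[[j]][[t]], bitpos1, fixed1, idx1))
        x <- bitcol(idx1, bitpos1[[wname(lnames[j], t)]])
        prob1 <- prob1 * (x * p + (1L - x) * (1 - p))
      }
      p <- stats::plogis(enum_lp(sm$mediator[[t]], bitpos1, fixed1, idx1))
      x <- bitcol(idx1, bitpos1[[wname(sm$mediator_var, t)]])
      prob1 <- prob1 * (x * p + (1L - x) * (1 - p))
    }
    mindex1 <- rep.int(0L, length(idx1))
    for (t in seq_len(K)) {
      mindex1 <- mindex1 + bitcol(idx1, mpos1[t]) * 2L^(t - 1L)
    }
    pm <- rep(0, 2^K)
    agg <- rowsum(prob1, mindex1)
    pm[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    if (abs(sum(pm) - 1) > 1e-10) {
      stop("internal: mediator-trajectory law does not sum to 1", call. = FALSE)
    }

    # E[Y | a, mbar, v]: marginalize a fresh confounder stream under regime a
    fixed2 <- c(vfix, stats::setNames(as.list(regime_a$values), exp_names))
    prob2 <- rep(1, length(idx2))
    for (t in seq_len(K)) {
      for (j in seq_len(nL)) {
        p <- stats::plogis(enum_lp(sm$confounders[[j]][[t]], bitpos2, fixed2, idx2))
        x <- bitcol(idx2, bitpos2[[wname(lnames[j], t)]])
        prob2 <- prob2 * (x * p + (1L - x) * (1 - p))
      }
    }
    ey <- stats::plogis(enum_lp(sm$outcome, bitpos2, fixed2, idx2))
    mindex2 <- rep.int(0L, length(idx2))
    for (t in seq_len(K)) {
      mindex2 <- mindex2 + bitcol(idx2, bitpos2[[wname(sm$mediator_var, t)]]) * 2L^(t - 1L)
    }
    eym <- rep(0, 2^K)
    agg2 <- rowsum(prob2 * ey, mindex2)
    eym[as.integer(rownames(agg2)) + 1L] <- agg2[, 1L]

    psi <- psi + pv * sum(pm * eym)
  }
  psi
}

#' Exact randomized-interventional effects by enumeration
#'
#' Exact rTE, rNDE and rNIE (risk ratios) per non-reference regime, with the
#' never-obese regime as reference \eqn{\bar a^*}:
#' \deqn{rTE = \psi(\bar a, \bar a)/\psi(\bar a^*, \bar a^*),\quad
#'       rNDE = \psi(\bar a, \bar a^*)/\psi(\bar a^*, \bar a^*),\quad
#'       rNIE = \psi(\bar a, \bar a)/\psi(\bar a, \bar a^*).}
#' Ground truth carries no confidence intervals.
#'
#' @param sm a \code{structural_model}.
#' @param regimes list of \code{exposure_regime}s including the never-obese
#'   reference; defaults to \code{\link{standard_regimes}}.
#' @return An \code{effect_estimates} object (exact, no CIs).
#' @export
exact_effects <- function(sm, regimes = standard_regimes(sm$n_waves)) {
  stopifnot(inherits(sm, "structural_model"))
  ref <- Filter(function(r) all(r$values == 0L), regimes)
  if (length(ref) != 1L) {
    stop("regimes must include exactly one never-obese reference", call. = FALSE)
  }
  ref <- ref[[1L]]
  others <- Filter(function(r) any(r$values == 1L), regimes)
  if (length(others) < 1L) stop("no non-reference regime given", call. = FALSE)

  p_ref <- exact_psi(sm, ref, ref)
  psi_rows <- list(data.frame(regime_a = ref$label, regime_aprime = ref$label,
                              psi = p_ref, stringsAsFactors = FALSE))
  eff <- list()
  for (rg in others) {
    paa <- exact_psi(sm, rg, rg)
    par <- exact_psi(sm, rg, ref)
    psi_rows[[length(psi_rows) + 1L]] <- data.frame(
      regime_a = rg$label, regime_aprime = c(rg$label, ref$label),
      psi = c(paa, par), stringsAsFactors = FALSE)
    eff[[length(eff) + 1L]] <- data.frame(
      regime = rg$label,
      effect = c("rTE", "rNDE", "rNIE"),
      estimate = c(paa / p_ref, par / p_ref, paa / par),
      stringsAsFactors = FALSE)
  }
  structure(list(
    effects = do.call(rbind, eff),
    psi = do.call(rbind, psi_rows),
    n_mc = NA_integer_, n_boot = NA_integer_, seed = NA_integer_,
    exact = TRUE
  ), class = "effect_estimates")
}

#' Exact marginal and joint moments of a structural model
#'
#' Enumerates the full joint distribution of a \code{structural_model}
#' (baseline covariates and every wave's confounders, mediator and exposure,
#' the exposure now drawn from its own generative model) and returns the
#' exact marginal prevalence of every binary variable. The returned closure
#' \code{moment(vars)} gives \eqn{E[\prod vars]} for any variable subset, so
#' conditional quantities (e.g. obesity persistence
#' \eqn{P(A_t = 1 \mid A_{t-1} = 1)} or gender-specific prevalences) can be
#' formed from exact joints. Used as the independent calibration check of
#' the synthetic generator.
#'
#' @param sm a \code{structural_model}.
#' @return A list with \code{marginals} (named numeric) and \code{moment}
#'   (function of a character vector of variable names).
#' @export
exact_marginals <- function(sm) {
  stopifnot(inherits(sm, "structural_model"))
  K <- sm$n_waves
  lnames <- names(sm$confounders)
  nL <- length(lnames)
  nV <- length(sm$baseline)
  n_bits <- nV + K * (nL + 2L)
  oracle_guard(n_bits, "full joint")

  vars <- c(names(sm$baseline),
            as.vector(vapply(seq_len(K), function(t)
              c(wname(lnames, t), wname(sm$mediator_var, t),
                wname(sm$exposure_var, t)), character(nL + 2L))))
  bitpos <- stats::setNames(as.list(seq_along(vars) - 1L), vars)
  idx <- 0:(2^n_bits - 1L)
  prob <- rep(1, length(idx))
  for (j in seq_len(nV)) {
    x <- bitcol(idx, bitpos[[names(sm$baseline)[j]]])
    pj <- sm$baseline[[j]]
    prob <- prob * (x * pj + (1L - x) * (1 - pj))
  }
  fixed <- list()
  for (t in seq_len(K)) {
    for (j in seq_len(nL)) {
      p <- stats::plogis(enum_lp(sm$confounders[[j]][[t]], bitpos, fixed, idx))
      x <- bitcol(idx, bitpos[[wname(lnames[j], t)]])
      prob <- prob * (x * p + (1L - x) * (1 - p))
    }
    p <- stats::plogis(enum_lp(sm$mediator[[t]], bitpos, fixed, idx))
    x <- bitcol(idx, bitpos[[wname(sm$mediator_var, t)]])
    prob <- prob * (x * p + (1L - x) * (1 - p))
    p <- stats::plogis(enum_lp(sm$exposure[[t]], bitpos, fixed, idx))
    x <- bitcol(idx, bitpos[[wname(sm$exposure_var, t)]])
    prob <- prob * (x * p + (1L - x) * (1 - p))
  }
  moment <- function(which_vars) {
    w <- prob
    for (v in which_vars) {
      p <- bitpos[[v]]
      if (is.null(p)) stop("unknown variable '", v, "'", call. = FALSE)
      w <- w * bitcol(idx, p)
    }
    sum(w)
  }
  marginals <- vapply(vars, function(v) moment(v), numeric(1))
  list(marginals = marginals, moment = moment)
}
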