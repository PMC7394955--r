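#' Deterministic obesity exposure regimes
#'
#' An exposure regime is a deterministic obesity trajectory
#' \eqn{\bar a = (a_1, \dots, a_K)} over the analysis waves: never obese
#' (all zeros), incident at wave \eqn{k} (zeros then ones from wave
#' \eqn{k}), or persistent (all ones). Regimes are monotone non-decreasing,
#' mirroring the effectively absorbing obesity process.
#'
#' @param values 0/1 vector over the analysis waves.
#' @param label optional label; inferred from the onset wave when omitted.
#' @return An object of class \code{exposure_regime} with fields
#'   \code{label} and \code{values}.
#' @examples
#' exposure_regime(c(0, 1, 1))          # incident_w2
#' regime_persistent(4)
#' @export
exposure_regime <- function(values, label = NULL) {
  values <- as.integer(values)
  if (length(values) < 1L || any(!(values %in% c(0L, 1L)))) {
    stop("regime values must be a non-empty 0/1 vector", call. = FALSE)
  }
  if (any(diff(values) < 0L)) {
    stop("regime must be monotone non-decreasing (never / incident / persistent)",
         call. = FALSE)
  }
  if (is.null(label)) label <- classify_trajectory(values)
  structure(list(label = label, values = values), class = "exposure_regime")
}

#' @rdname exposure_regime
#' @param k onset wave (\code{2 <= k <= n_waves}).
#' @param n_waves number of analysis waves.
#' @export
regime_never <- function(n_waves) exposure_regime(rep(0L, n_waves))

#' @rdname exposure_regime
#' @export
regime_persistent <- function(n_waves) exposure_regime(rep(1L, n_waves))

#' @rdname exposure_regime
#' @export
regime_incident <- function(k, n_waves) {
  k <- as.integer(k)
  if (k < 2L || k > n_waves) stop("onset wave must be in 2..n_waves", call. = FALSE)
  exposure_regime(as.integer(seq_len(n_waves) >= k))
}

#' All standard regimes for a design
#'
#' Never obese (the reference), incident obesity at each wave
#' \code{2..K}, and persistent obesity, over the design's analysis waves.
#'
#' @param design a \code{cohort_design} (or an integer number of waves).
#' @return A named list of \code{exposure_regime}s.
#' @export
standard_regimes <- function(design) {
  k <- if (inherits(design, "cohort_design")) max(design$waves_used) else as.integer(design)
  regs <- c(list(regime_never(k)),
            lapply(seq(2L, k), regime_incident, n_waves = k),
            list(regime_persistent(k)))
  stats::setNames(regs, vapply(regs, `[[`, "", "label"))
}

#' @export
print.exposure_regime <- function(x, ...) {
  cat("<exposure_regime> ", x$label, ": (",
      paste(x$values, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# a regime differing from the never-obese reference only at the final wave
# has no mediator measured after exposure onset, so its rNIE is structurally
# 1 (no partition is reported)
is_last_wave_only <- function(regime) {
  v <- regime$values
  length(v) >= 2L && v[length(v)] == 1L && all(v[-length(v)] == 0L)
}
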