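#' Derive a reproducible sub-seed from a user seed and a label
#'
#' All randomness in the package flows from one user-supplied seed. Named
#' substreams (e.g. \code{"mc"} for the Monte Carlo g-computation stream,
#' \code{"boot"} for bootstrap resampling) and per-replicate offsets are
#' derived with a small deterministic string hash, so results are
#' reproducible and independent of the order in which substreams are
#' consumed.
#'
#' @param seed integer user seed.
#' @param key character label of the substream (may include a replicate
#'   index, e.g. \code{"boot:17"}).
#' @return An integer in \code{[1, 2^31 - 2]} suitable for
#'   \code{\link[base]{set.seed}}.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

#' Evaluate a named-coefficient linear predictor over a variable environment
#'
#' Coefficient vectors are stored with names referring to columns of the
#' current simulation environment; \code{"(Intercept)"} is the intercept.
#' Values in \code{env} may be vectors or scalars (scalars are recycled),
#' which lets deterministic exposure regimes enter as constants.
#'
#' @param coef named numeric vector, first-class representation of a fitted
#'   or generative logistic model.
#' @param env named list of numeric vectors/scalars.
#' @param n length of the result.
#' @return Numeric vector of length \code{n} on the linear-predictor scale.
#' @keywords internal
eval_lp <- function(coef, env, n) {
  nms <- names(coef)
  i0 <- match("(Intercept)", nms)
  lp <- rep.int(if (is.na(i0)) 0 else coef[[i0]], n)
  for (k in seq_along(coef)) {
    if (!is.na(i0) && k == i0) next
    nm <- nms[[k]]
    v <- env[[nm]]
    if (is.null(v)) {
      stop("linear predictor references unknown variable '", nm, "'",
           call. = FALSE)
    }
    lp <- lp + coef[[k]] * v
  }
  lp
}

# run code with an isolated RNG state seeded at `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# wave-suffixed column name(s): wname("inactive", 2) -> "inactive_w2"
wname <- function(var, t) {
  if (length(var) == 0L || length(t) == 0L) return(character(0))
  as.vector(outer(var, t, function(v, tt) paste0(v, "_w", tt)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
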