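#' Declare the wave structure and variable roles of a longitudinal cohort
#'
#' A \code{cohort_design} states which columns of a wide-format cohort table
#' play which causal role, the number of waves, and which waves enter the
#' mediation analysis. Within every wave the causal ordering is fixed as
#' time-varying confounders, then the mediator (inactivity), then the
#' exposure (obesity): inactivity is assumed measured before obesity at the
#' same age, so wave-\eqn{t} obesity can influence wave-\eqn{t+1} inactivity
#' but not the concurrent one, and there is no mediator between final-wave
#' obesity and the outcome.
#'
#' Wide-column convention: per-wave variables are suffixed \code{_w<t>}
#' (\code{t = 1..n_waves}); baseline variables are unsuffixed. Binary
#' variables are coded 0/1 integers; the gender variable is 0/1 with the
#' mapping declared by the caller (the shipped presets use \code{male},
#' 1 = male).
#'
#' @param cohort_id label, e.g. \code{"nshd46"} or \code{"ncds58"}.
#' @param wave_labels character vector of wave names (typically nominal ages
#'   in years); its length sets the number of waves \code{n_waves >= 2}.
#' @param baseline_vars character vector of baseline confounder column names
#'   (all binary 0/1 in the shipped presets); must include \code{gender_var}.
#' @param timevarying_confounder_vars character vector of per-wave binary
#'   confounder stems (e.g. \code{c("smoker", "depressed")}).
#' @param mediator_var stem of the per-wave binary inactivity indicator.
#' @param exposure_var stem of the per-wave binary obesity indicator
#'   (derived column), or \code{NULL} if only \code{bmi_var} is supplied.
#' @param bmi_var stem of the per-wave continuous BMI column (kg/m^2), or
#'   \code{NULL} when the exposure arrives pre-derived as binary.
#' @param outcome_score_var name of the distal continuous functioning score
#'   column (0-100, lower = worse), or \code{NULL}.
#' @param outcome_var name of a pre-derived binary poor-functioning column,
#'   or \code{NULL}; at least one of \code{outcome_score_var},
#'   \code{outcome_var} must be given.
#' @param gender_var name of the 0/1 gender column.
#' @param waves_used integer vector, a non-empty prefix \code{1..K} of the
#'   waves entering the mediation analysis (default all waves); setting
#'   \code{K = n_waves - 1} reproduces the omit-last-wave sensitivity
#'   analysis.
#' @return An object of class \code{cohort_design}.
#' @examples
#' d <- cohort_design("demo", wave_labels = c("36", "43", "53"),
#'                    baseline_vars = c("male", "low_social_class"),
#'                    timevarying_confounder_vars = "smoker",
#'                    mediator_var = "inactive", exposure_var = "obese",
#'                    outcome_score_var = "pf_score", gender_var = "male")
#' d$n_waves
#' @export
cohort_design <- function(cohort_id,
                          wave_labels,
                          baseline_vars,
                          timevarying_confounder_vars,
                          mediator_var = "inactive",
                          exposure_var = "obese",
                          bmi_var = NULL,
                          outcome_score_var = "pf_score",
                          outcome_var = NULL,
                          gender_var = "male",
                          waves_used = NULL) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  wave_labels <- as.character(wave_labels)
  n_waves <- length(wave_labels)
  if (n_waves < 2L) stop("a cohort design needs at least 2 waves", call. = FALSE)
  baseline_vars <- as.character(baseline_vars)
  if (!gender_var %in% baseline_vars) {
    baseline_vars <- c(gender_var, baseline_vars)
  }
  if (is.null(exposure_var) && is.null(bmi_var)) {
    stop("one of exposure_var or bmi_var must be declared", call. = FALSE)
  }
  if (is.null(outcome_score_var) && is.null(outcome_var)) {
    stop("one of outcome_score_var or outcome_var must be declared",
         call. = FALSE)
  }
  waves_used <- if (is.null(waves_used)) seq_len(n_waves) else as.integer(waves_used)
  if (length(waves_used) < 1L || !identical(waves_used, seq_len(max(waves_used))) ||
      max(waves_used) > n_waves) {
    stop("waves_used must be a non-empty prefix 1..K of the waves",
         call. = FALSE)
  }
  structure(list(
    cohort_id = cohort_id,
    wave_labels = wave_labels,
    n_waves = n_waves,
    baseline_vars = unique(baseline_vars),
    timevarying_confounder_vars = as.character(timevarying_confounder_vars),
    mediator_var = mediator_var,
    exposure_var = exposure_var %||% "obese",
    bmi_var = bmi_var,
    outcome_score_var = outcome_score_var,
    outcome_var = outcome_var,
    gender_var = gender_var,
    waves_used = waves_used
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design> ", x$cohort_id, ": ", x$n_waves, " waves (",
      paste(x$wave_labels, collapse = ", "), ")\n", sep = "")
  cat("  baseline:   ", paste(x$baseline_vars, collapse = ", "), "\n", sep = "")
  cat("  confounders:", paste(x$timevarying_confounder_vars, collapse = ", "),
      "\n  mediator:   ", x$mediator_var,
      "\n  exposure:   ", x$exposure_var,
      if (!is.null(x$bmi_var)) paste0(" (from ", x$bmi_var, ")") else "",
      "\n  outcome:    ",
      if (!is.null(x$outcome_var)) x$outcome_var else
        paste0("10th-centile flag of ", x$outcome_score_var),
      "\n  waves used: 1..", max(x$waves_used), "\n", sep = "")
  invisible(x)
}

#' Restrict a design to the first K waves of analysis
#'
#' @param design a \code{cohort_design}.
#' @param k last wave to use (\code{2 <= k <= n_waves}).
#' @return The design with \code{waves_used = 1..k}.
#' @export
use_waves <- function(design, k) {
  stopifnot(inherits(design, "cohort_design"))
  k <- as.integer(k)
  if (k < 2L || k > design$n_waves) {
    stop("waves_used must keep at least 2 waves and at most n_waves",
         call. = FALSE)
  }
  design$waves_used <- seq_len(k)
  design
}

# all analysis columns a complete cohort table must contain
design_columns <- function(design, derived = FALSE) {
  tw <- seq_len(design$n_waves)
  cols <- c(design$baseline_vars,
            wname(design$timevarying_confounder_vars, tw),
            wname(design$mediator_var, tw))
  if (!is.null(design$bmi_var)) {
    cols <- c(cols, wname(design$bmi_var, tw))
  } else {
    cols <- c(cols, wname(design$exposure_var, tw))
  }
  if (!is.null(design$outcome_score_var)) cols <- c(cols, design$outcome_score_var)
  if (!is.null(design$outcome_var)) cols <- c(cols, design$outcome_var)
  if (derived) {
    cols <- c(cols, wname(design$exposure_var, tw), "trajectory", "poor_pf")
  }
  unique(cols)
}

# binary-typed columns among the design's analysis columns
design_binary_columns <- function(design) {
  tw <- seq_len(design$n_waves)
  cols <- c(design$baseline_vars,
            wname(design$timevarying_confounder_vars, tw),
            wname(design$mediator_var, tw))
  if (is.null(design$bmi_var)) cols <- c(cols, wname(design$exposure_var, tw))
  if (!is.null(design$outcome_var)) cols <- c(cols, design$outcome_var)
  unique(cols)
}
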