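#' Construct a longitudinal cohort from a wide table and a design
#'
#' @param table data.frame, one row per subject, columns as declared by the
#'   design (per-wave columns suffixed \code{_w<t>}).
#' @param design a \code{\link{cohort_design}}.
#' @param validate check column presence, binary coding and completeness.
#' @return An object of class \code{longitudinal_cohort}: a list with
#'   elements \code{design} and \code{table}.
#' @export
longitudinal_cohort <- function(table, design, validate = TRUE) {
  stopifnot(is.data.frame(table), inherits(design, "cohort_design"))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (validate) validate_cohort_table(table, design)
  structure(list(design = design, table = table),
            class = "longitudinal_cohort")
}

validate_cohort_table <- function(table, design) {
  need <- design_columns(design)
  absent <- setdiff(need, names(table))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  for (cl in need) {
    v <- table[[cl]]
    if (is.character(v) || is.factor(v)) {
      vv <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vv) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric value in column '", cl, "' at row ", bad[1],
             call. = FALSE)
      }
      v <- vv
    }
    if (anyNA(v)) {
      stop("missing value in analysis column '", cl, "' at row ",
           which(is.na(v))[1],
           " (complete data required; impute upstream)", call. = FALSE)
    }
  }
  for (cl in intersect(design_binary_columns(design), names(table))) {
    v <- as.numeric(table[[cl]])
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad)) {
      stop("non-binary value in declared binary column '", cl, "' at row ",
           bad[1], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a wide-format cohort CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and one row per
#' subject; lines starting with \code{#} (provenance comments written by
#' \code{\link{write_cohort}}) are ignored.
#'
#' @param path file path.
#' @inheritParams longitudinal_cohort
#' @return A \code{longitudinal_cohort}; derived columns are not computed
#'   (see \code{\link{derive_cohort}}).
#' @export
read_cohort <- function(path, design) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- design_columns(design)
  absent <- setdiff(need, names(tab))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  for (cl in need) {
    v <- tab[[cl]]
    if (is.character(v)) {
      vv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vv) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        stop("non-numeric value '", v[bad[1]], "' in column '", cl,
             "' at row ", bad[1], call. = FALSE)
      }
      tab[[cl]] <- vv
    }
  }
  longitudinal_cohort(tab, design)
}

#' Write a cohort table to CSV with a provenance comment
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param path output file path.
#' @param header optional named character vector written as leading
#'   \code{# key=value} comment lines (e.g. config hash and seed).
#' @export
write_cohort <- function(cohort, path, header = NULL) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", names(header), "=", unname(header)), con)
  }
  utils::write.csv(cohort$table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("<longitudinal_cohort> ", x$design$cohort_id, ": ",
      nrow(x$table), " subjects, ", x$design$n_waves, " waves, ",
      ncol(x$table), " columns\n", sep = "")
  if ("trajectory" %in% names(x$table)) {
    print(table(trajectory = x$table$trajectory))
  }
  invisible(x)
}

#' Flag obesity from BMI at every wave
#'
#' Obesity is defined as BMI at or above the threshold (default
#' 30 kg/m^2, boundary inclusive). When the design declares a pre-derived
#' binary exposure and no BMI columns, this is a checked pass-through.
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param threshold BMI cutoff in kg/m^2 (> 0).
#' @return The cohort with \code{obese_w<t>} columns (0/1) added or verified.
#' @export
derive_obesity <- function(cohort, threshold = 30) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive BMI in kg/m^2", call. = FALSE)
  }
  d <- cohort$design
  tw <- seq_len(d$n_waves)
  if (is.null(d$bmi_var)) {
    ob <- cohort$table[wname(d$exposure_var, tw)]
    if (any(vapply(ob, function(v) any(!(v %in% c(0, 1))), logical(1)))) {
      stop("pre-derived exposure columns must be 0/1", call. = FALSE)
    }
    return(cohort)
  }
  for (t in tw) {
    bmi <- cohort$table[[wname(d$bmi_var, t)]]
    if (any(bmi <= 0)) {
      stop("non-positive BMI at row ", which(bmi <= 0)[1], ", wave ", t,
           call. = FALSE)
    }
    cohort$table[[wname(d$exposure_var, t)]] <- as.integer(bmi >= threshold)
  }
  cohort
}

#' Classify an obesity sequence by wave of first onset
#'
#' Obesity behaves as an effectively absorbing state (reversion is rare), so
#' trajectories are defined solely by the wave of first onset: never obese at
#' any wave, first obese at wave 1 ("persistent"), or first obese at wave
#' \code{k > 1} ("incident_w<k>"). Reversions after onset are ignored.
#'
#' @param obese_sequence 0/1 vector, one entry per wave (length >= 1).
#' @return A character scalar: \code{"never"}, \code{"persistent"} or
#'   \code{"incident_w<k>"}.
#' @examples
#' classify_trajectory(c(0, 0, 1, 1))  # "incident_w3"
#' classify_trajectory(c(1, 0, 0, 0))  # "persistent" (onset rule governs)
#' @export
classify_trajectory <- function(obese_sequence) {
  if (length(obese_sequence) == 0L) {
    stop("empty obesity sequence", call. = FALSE)
  }
  if (any(!(obese_sequence %in% c(0, 1)))) {
    stop("obesity sequence entries must be 0/1", call. = FALSE)
  }
  k <- match(1, obese_sequence)
  if (is.na(k)) "never" else if (k == 1L) "persistent" else paste0("incident_w", k)
}

# vectorized over a subjects x waves 0/1 matrix
classify_trajectories <- function(obese_matrix) {
  if (is.null(dim(obese_matrix)) || ncol(obese_matrix) == 0L) {
    stop("empty obesity sequence", call. = FALSE)
  }
  if (any(!(obese_matrix %in% c(0, 1)))) {
    stop("obesity sequence entries must be 0/1", call. = FALSE)
  }
  onset <- apply(obese_matrix == 1, 1, function(z) {
    k <- which(z)[1]
    if (is.na(k)) 0L else k
  })
  ifelse(onset == 0L, "never",
         ifelse(onset == 1L, "persistent", paste0("incident_w", onset)))
}

#' Dichotomize a functioning score at a gender-specific low centile
#'
#' Within each gender stratum the threshold is the smallest observed score
#' \code{s} at which the cumulative proportion of scores \code{<= s} first
#' reaches the centile; subjects scoring at or below it are flagged. Under
#' ties the flagged proportion may exceed the centile (tie inflation), never
#' fall below it.
#'
#' @param scores numeric vector of finite functioning scores (lower = worse).
#' @param gender 0/1 vector of the same length.
#' @param centile percent in (0, 100); default 10.
#' @return A list: \code{flags} (0/1 integer vector) and \code{thresholds}
#'   (named numeric, per gender level).
#' @export
dichotomize_outcome <- function(scores, gender, centile = 10) {
  stopifnot(length(scores) == length(gender))
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!is.numeric(centile) || centile <= 0 || centile >= 100) {
    stop("centile must be in (0, 100)", call. = FALSE)
  }
  p <- centile / 100
  flags <- integer(length(scores))
  levels <- sort(unique(gender))
  thresholds <- stats::setNames(numeric(length(levels)), as.character(levels))
  for (g in levels) {
    i <- which(gender == g)
    if (length(i) == 0L) stop("empty gender stratum '", g, "'", call. = FALSE)
    if (length(i) < 10L) {
      warning("gender stratum '", g, "' has fewer than 10 subjects",
              call. = FALSE)
    }
    s <- sort(scores[i])
    cum <- seq_along(s) / length(s)
    thr <- s[which(cum >= p)[1]]
    thresholds[as.character(g)] <- thr
    flags[i] <- as.integer(scores[i] <= thr)
  }
  list(flags = flags, thresholds = thresholds)
}

#' Compute all derived analysis columns of a cohort
#'
#' Applies \code{\link{derive_obesity}}, classifies every subject's obesity
#' trajectory, and (when the design declares a continuous score)
#' dichotomizes the functioning score at the gender-specific centile into
#' \code{poor_pf}. When the design declares a pre-derived binary outcome it
#' is copied to \code{poor_pf}.
#'
#' @inheritParams derive_obesity
#' @param centile percent for the poor-functioning cutoff (default 10).
#' @return The cohort with columns \code{obese_w<t>}, \code{trajectory},
#'   \code{poor_pf}; per-gender score thresholds are kept in the
#'   \code{pf_threshold_by_gender} attribute of the cohort.
#' @export
derive_cohort <- function(cohort, threshold = 30, centile = 10) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  d <- cohort$design
  cohort <- derive_obesity(cohort, threshold)
  ob <- as.matrix(cohort$table[wname(d$exposure_var, seq_len(d$n_waves))])
  cohort$table$trajectory <- classify_trajectories(ob)
  if (!is.null(d$outcome_score_var)) {
    dd <- dichotomize_outcome(cohort$table[[d$outcome_score_var]],
                              cohort$table[[d$gender_var]], centile)
    cohort$table$poor_pf <- dd$flags
    attr(cohort, "pf_threshold_by_gender") <- dd$thresholds
  } else {
    cohort$table$poor_pf <- as.integer(cohort$table[[d$outcome_var]])
  }
  cohort
}

#' Prevalence summary of poor functioning, obesity, inactivity and trajectories
#'
#' Produces the descriptive layout of a cohort: per gender the number and
#' percentage with poor functioning; per wave the obesity and inactivity
#' prevalence, inactivity split by obesity status at the same wave, and the
#' trajectory-class distribution per gender.
#'
#' @param cohort a derived \code{longitudinal_cohort}
#'   (see \code{\link{derive_cohort}}).
#' @return A data.frame with columns \code{block}, \code{wave}, \code{group},
#'   \code{stratum}, \code{n}, \code{total}, \code{pct}.
#' @export
prevalence_summary <- function(cohort) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  d <- cohort$design
  tab <- cohort$table
  if (!all(c("trajectory", "poor_pf") %in% names(tab))) {
    stop("derived columns absent; run derive_cohort() first", call. = FALSE)
  }
  gvar <- d$gender_var
  rows <- list()
  add <- function(block, wave, group, stratum, x) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, wave = wave, group = group, stratum = stratum,
      n = sum(x), total = length(x), pct = round(100 * mean(x), 2),
      stringsAsFactors = FALSE)
  }
  for (g in sort(unique(tab[[gvar]]))) {
    sel <- tab[[gvar]] == g
    add("poor_pf", NA_integer_, paste0(gvar, "=", g), "all",
        tab$poor_pf[sel])
  }
  for (t in seq_len(d$n_waves)) {
    obt <- tab[[wname(d$exposure_var, t)]]
    mt <- tab[[wname(d$mediator_var, t)]]
    add("obesity", t, "all", "all", obt)
    add("inactivity", t, "all", "all", mt)
    add("inactivity", t, "all", "non-obese", mt[obt == 0])
    add("inactivity", t, "all", "obese", mt[obt == 1])
    for (g in sort(unique(tab[[gvar]]))) {
      sel <- tab[[gvar]] == g
      add("obesity", t, paste0(gvar, "=", g), "all", obt[sel])
      add("inactivity", t, paste0(gvar, "=", g), "all", mt[sel])
    }
  }
  for (g in sort(unique(tab[[gvar]]))) {
    sel <- tab[[gvar]] == g
    for (cls in trajectory_levels(d)) {
      add("trajectory", NA_integer_, paste0(gvar, "=", g), cls,
          tab$trajectory[sel] == cls)
    }
  }
  do.call(rbind, rows)
}

# ordered trajectory class labels for a design
trajectory_levels <- function(design) {
  k <- if (inherits(design, "cohort_design")) max(design$waves_used) else design
  c("never", if (k >= 2) paste0("incident_w", seq(2L, k)), "persistent")
}
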