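# Config-driven pipeline wiring the stages:
# simulate -> derive -> associations -> mediate (and an oracle check when the
# scenario's state space permits exact enumeration).

pipeline_schema <- list(
  scenario = "character: preset name or path to a scenario YAML (required)",
  cohort_csv = "character: optional path to an existing cohort CSV (skips simulation)",
  n = "integer >= 1: subjects to simulate (required unless cohort_csv given)",
  seed = "integer: master seed (required)",
  n_mc = "integer >= 1: total Monte Carlo trajectories per counterfactual risk",
  n_boot = "integer >= 2: bootstrap replicates (0 disables the bootstrap)",
  waves_used = "integer: last analysis wave (default all waves)",
  regimes = "character vector of regime labels or \"all\"",
  stages = "subset of simulate, derive, associations, mediate, oracle",
  stratify_by = "character: optional gender column for stratified runs",
  output_dir = "character: output directory (required)"
)

validate_config <- function(cfg) {
  bad <- function(field, why) {
    stop("config field '", field, "': ", why, " (expected ",
         pipeline_schema[[field]], ")", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(pipeline_schema))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$scenario)) bad("scenario", "missing")
  if (is.null(cfg$seed)) bad("seed", "missing")
  if (is.null(cfg$output_dir)) bad("output_dir", "missing")
  if (is.null(cfg$cohort_csv) && is.null(cfg$n)) bad("n", "missing")
  if (!is.null(cfg$n) && (!is.numeric(cfg$n) || cfg$n < 1)) bad("n", "not a positive integer")
  if (!is.null(cfg$n_boot) && (!is.numeric(cfg$n_boot) ||
      (cfg$n_boot != 0 && cfg$n_boot < 2))) bad("n_boot", "must be 0 or >= 2")
  cfg$n_mc <- cfg$n_mc %||% 10000
  if (!is.numeric(cfg$n_mc) || cfg$n_mc < 1) bad("n_mc", "not a positive integer")
  cfg$n_boot <- cfg$n_boot %||% 500
  cfg$stages <- cfg$stages %||% c("simulate", "derive", "associations", "mediate")
  bad_stage <- setdiff(cfg$stages,
                       c("simulate", "derive", "associations", "mediate", "oracle"))
  if (length(bad_stage)) bad("stages", paste("unknown stage", bad_stage[1]))
  cfg$regimes <- cfg$regimes %||% "all"
  cfg
}

write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(header), "=", unname(header)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_scenario <- function(label) {
  if (file.exists(label)) read_scenario(label) else
    switch(label,
      "null-mediation" = null_mediation_scenario(),
      "no-direct-effect" = no_direct_effect_scenario(),
      "toy-mediation" = toy_mediation_scenario(),
      paper_like_scenario(label))
}

# design with the gender covariate removed from the adjustment/baseline set,
# for per-stratum runs
drop_gender_covariate <- function(design) {
  design$baseline_vars <- setdiff(design$baseline_vars, design$gender_var)
  design
}

#' Run the full analysis pipeline from a config file
#'
#' Executes the requested stages in order — simulate a cohort from a
#' scenario (or read one from CSV), derive the analysis columns, fit the
#' adjusted odds-ratio table, estimate the randomized natural effects with
#' bootstrap confidence intervals, and (for scenarios small enough to
#' enumerate) compare against the exact oracle — and writes machine-readable
#' outputs: \code{cohort.csv}, \code{associations.csv}, \code{effects.csv},
#' \code{results.json} and \code{run.log}. Every output embeds the config
#' hash and seed. Identical config and seed give byte-identical results.
#'
#' @param config path to a YAML config file, or an equivalent named list
#'   (see the \code{medgf:::pipeline_schema} field descriptions).
#' @param output_dir optional override of the config's output directory.
#' @return Invisibly, a run report list (paths, effects, timings).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    cfg_hash <- unname(tools::md5sum(config))
  } else {
    cfg <- config
    tmp <- tempfile(fileext = ".yml")
    yaml::write_yaml(cfg, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(config_hash = cfg_hash, seed = cfg$seed)
  logf <- file.path(cfg$output_dir, "run.log")
  logmsg <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n",
        sep = "", file = logf, append = TRUE)
  }
  cat("", file = logf)
  logmsg("medgf ", as.character(utils::packageVersion("medgf")),
         " | R ", R.version.string)
  logmsg("config_hash=", cfg_hash, " seed=", cfg$seed)
  report <- list(config_hash = cfg_hash, seed = cfg$seed, outputs = list())

  fail_marker <- file.path(cfg$output_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  on_error <- function(e) {
    writeLines(conditionMessage(e), fail_marker)
    logmsg("FAILED: ", conditionMessage(e))
    stop(e)
  }

  tryCatch({
    sm <- resolve_scenario(cfg$scenario)
    design <- as_cohort_design(sm)
    if (!is.null(cfg$waves_used)) design <- use_waves(design, cfg$waves_used)

    if (!is.null(cfg$cohort_csv)) {
      cohort <- read_cohort(cfg$cohort_csv, design)
      logmsg("read cohort: ", nrow(cohort$table), " subjects from ",
             cfg$cohort_csv)
    } else {
      cohort <- generate_cohort(sm, cfg$n, derive_seed(cfg$seed, "simulate"),
                                design)
      logmsg("simulated cohort: ", cfg$n, " subjects from scenario '",
             cfg$scenario, "'")
    }

    if (any(c("derive", "associations", "mediate") %in% cfg$stages)) {
      cohort <- derive_cohort(cohort)
      path <- file.path(cfg$output_dir, "cohort.csv")
      write_cohort(cohort, path, hdr)
      report$outputs$cohort <- path
      prev <- prevalence_summary(cohort)
      ppath <- file.path(cfg$output_dir, "prevalence.csv")
      write_table_with_header(prev, ppath, hdr)
      report$outputs$prevalence <- ppath
      logmsg("derived columns + prevalence summary written")
    }

    if ("associations" %in% cfg$stages) {
      assoc <- association_table(cohort, design)
      path <- file.path(cfg$output_dir, "associations.csv")
      write_table_with_header(assoc, path, hdr)
      report$outputs$associations <- path
      logmsg("association table written (", nrow(assoc), " rows)")
    }

    results <- list(config_hash = cfg_hash, seed = cfg$seed,
                    package_version = as.character(utils::packageVersion("medgf")))
    if ("mediate" %in% cfg$stages) {
      regimes <- if (identical(cfg$regimes, "all")) standard_regimes(design) else {
        all_reg <- standard_regimes(design)
        missing <- setdiff(cfg$regimes, names(all_reg))
        if (length(missing)) {
          stop("unknown regime label(s): ", paste(missing, collapse = ", "),
               call. = FALSE)
        }
        all_reg[unique(c("never", cfg$regimes))]
      }
      run_one <- function(coh, dsn, tag) {
        est <- if (cfg$n_boot >= 2) {
          bootstrap_effects(coh, dsn, regimes, n_boot = cfg$n_boot,
                            n_mc = cfg$n_mc, seed = cfg$seed)
        } else {
          estimate_randomized_effects(coh, dsn, regimes, n_mc = cfg$n_mc,
                                      seed = cfg$seed)
        }
        logmsg("mediation [", tag, "]: ", nrow(est$effects), " effects, ",
               "n_boot=", est$n_boot, " n_mc=", est$n_mc)
        est
      }
      if (!is.null(cfg$stratify_by)) {
        gv <- cfg$stratify_by
        dsn <- drop_gender_covariate(design)
        ests <- lapply(sort(unique(cohort$table[[gv]])), function(g) {
          coh <- cohort
          coh$table <- coh$table[coh$table[[gv]] == g, , drop = FALSE]
          run_one(coh, dsn, paste0(gv, "=", g))
        })
        names(ests) <- paste0(gv, "=", sort(unique(cohort$table[[gv]])))
        eff <- do.call(rbind, lapply(names(ests), function(nm) {
          cbind(stratum = nm, ests[[nm]]$effects)
        }))
        results$effects <- eff
        results$psi <- do.call(rbind, lapply(names(ests), function(nm) {
          cbind(stratum = nm, ests[[nm]]$psi)
        }))
        results$diagnostics <- lapply(ests, function(e)
          list(n = e$n, n_boot = e$n_boot, n_failed = e$n_failed %||% 0L))
      } else {
        est <- run_one(cohort, design, "all")
        eff <- est$effects
        results$effects <- eff
        results$psi <- est$psi
        results$diagnostics <- list(n = est$n, n_boot = est$n_boot,
                                    n_failed = est$n_failed %||% 0L,
                                    n_mc = est$n_mc)
      }
      path <- file.path(cfg$output_dir, "effects.csv")
      write_table_with_header(eff, path, hdr)
      report$outputs$effects <- path
    }

    if ("oracle" %in% cfg$stages) {
      truth <- exact_effects(sm)
      results$oracle <- truth$effects
      path <- file.path(cfg$output_dir, "oracle.csv")
      write_table_with_header(truth$effects, path, hdr)
      report$outputs$oracle <- path
      logmsg("oracle effects written")
    }

    results$elapsed_sec <- round(proc.time()[["elapsed"]] - t0, 2)
    jpath <- file.path(cfg$output_dir, "results.json")
    jsonlite::write_json(results, jpath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    report$outputs$results <- jpath
    report$results <- results
    logmsg("done in ", results$elapsed_sec, " s")
  }, error = on_error)
  invisible(report)
}
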