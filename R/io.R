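#' Write / read session tables
#'
#' Sessions are stored as a long CSV with one row per trial
#' (`unit_id, size, trial, choice, reward, p_left, p_right`) plus an optional
#' units CSV (`unit_id, size, member_ids, test_id`, members separated by
#' `;`). `read_sessions()` validates on the way in: required columns present,
#' rewards in \{0, 1\}, trial indices 1..n without gaps — a violation is a
#' parse error naming the offending row. Write-then-read reproduces choices,
#' rewards and metadata exactly.
#'
#' @param sessions List of [session()]s or a `bandit_dataset`.
#' @param path Trials CSV path.
#' @param units_path Optional units CSV path.
#' @return `write_sessions()`: invisibly, the trials data frame.
#'   `read_sessions()`: list of [session()]s.
#' @export
write_sessions <- function(sessions, path, units_path = NULL) {
  ds <- if (inherits(sessions, "bandit_dataset")) sessions else NULL
  sessions <- sessions_of(sessions)
  trials <- sessions_to_trials(sessions)
  utils::write.csv(trials, path, row.names = FALSE)
  if (!is.null(units_path)) {
    units <- if (!is.null(ds)) ds$units else data.frame(
      unit_id = vapply(sessions, `[[`, character(1), "unit_id"),
      size = vapply(sessions, `[[`, integer(1), "size"),
      member_ids = vapply(sessions, function(s)
        paste(s$member_ids, collapse = ";"), character(1)),
      test_id = vapply(sessions, `[[`, character(1), "test_id"),
      stringsAsFactors = FALSE
    )
    utils::write.csv(units, units_path, row.names = FALSE)
  }
  invisible(trials)
}

sessions_to_trials <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    n <- length(s$choices)
    sch <- s$schedule
    data.frame(
      unit_id = s$unit_id, size = s$size, trial = seq_len(n),
      choice = ARM_LABELS[s$choices], reward = s$rewards,
      p_left = if (!is.null(sch)) unname(sch[, 1L]) else NA_real_,
      p_right = if (!is.null(sch)) unname(sch[, 2L]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  trials <- do.call(rbind, rows)
  if (is.null(trials)) {
    trials <- data.frame(unit_id = character(), size = integer(),
                         trial = integer(), choice = character(),
                         reward = integer(), p_left = numeric(),
                         p_right = numeric())
  }
  trials
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path, units_path = NULL) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("unit_id", "size", "trial", "choice", "reward")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop_config("missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(trials$reward %in% c(0L, 1L)))
  if (length(bad)) {
    stop_config("invalid reward %s at row %d", trials$reward[bad[1L]],
                bad[1L])
  }
  units <- if (!is.null(units_path)) {
    utils::read.csv(units_path, stringsAsFactors = FALSE,
                    colClasses = c(unit_id = "character",
                                   member_ids = "character",
                                   test_id = "character"))
  } else NULL
  trials$unit_id <- as.character(trials$unit_id)
  out <- lapply(split(seq_len(nrow(trials)), trials$unit_id), function(ix) {
    u <- trials[ix, ]
    u <- u[order(u$trial), ]
    if (!identical(as.integer(u$trial), seq_len(nrow(u)))) {
      gap <- which(as.integer(u$trial) != seq_len(nrow(u)))[1L]
      stop_config("trial index gap for unit %s near row %d",
                  u$unit_id[1L], ix[gap])
    }
    sch <- NULL
    if ("p_left" %in% names(u) && !anyNA(u$p_left)) {
      sch <- structure(cbind(left = u$p_left, right = u$p_right),
                       class = c("tab_schedule", "matrix"))
    }
    meta <- if (!is.null(units)) units[match(u$unit_id[1L], units$unit_id), ]
            else NULL
    session(
      unit_id = u$unit_id[1L],
      choices = u$choice,
      rewards = u$reward,
      size = u$size[1L],
      member_ids = if (!is.null(meta) && !is.na(meta$member_ids))
        strsplit(meta$member_ids, ";", fixed = TRUE)[[1L]]
        else rep(u$unit_id[1L], u$size[1L]),
      schedule = sch,
      test_id = if (!is.null(meta)) meta$test_id else NA_character_
    )
  })
  # preserve file order of first appearance
  out[unique(trials$unit_id)]
}

#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs: the task, the synthetic
#' design, priors, optimiser and MCMC settings, analysis options, the global
#' seed and the output directory. Stage seeds are derived from the global
#' seed (simulate: seed, fit: seed + 1, WBIC: seed + 2), so identical
#' config + seed reproduce identical outputs.
#'
#' @param design A [group_design()].
#' @param priors A [prior_spec()].
#' @param n_restarts MAP restarts per fit.
#' @param mcmc List with `n_samples` and `burn_in` for WBIC.
#' @param wbic Compute WBICs (can be turned off for speed).
#' @param regression_covariates,paired_contrasts Passed to
#'   [analysis_report()].
#' @param seed Global integer seed (required).
#' @param out_dir Output directory (created if absent).
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = group_design(),
                       priors = prior_spec(),
                       n_restarts = 10,
                       mcmc = list(n_samples = 5000, burn_in = 1000),
                       wbic = TRUE,
                       regression_covariates = TRUE,
                       paired_contrasts = FALSE,
                       seed,
                       out_dir) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop_config("a single integer seed is required")
  }
  if (missing(out_dir)) stop_config("out_dir is required")
  stopifnot(inherits(design, "group_design"), inherits(priors, "prior_spec"))
  structure(
    list(design = design, priors = priors, n_restarts = n_restarts,
         mcmc = mcmc, wbic = isTRUE(wbic),
         regression_covariates = isTRUE(regression_covariates),
         paired_contrasts = isTRUE(paired_contrasts),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain `task`, `design` (with nested `population`),
#' `priors`, `mcmc`, `n_restarts`, `wbic`, `seed` and `out_dir` blocks; every
#' field falls back to the package default. Format is chosen by extension
#' (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Config file path.
#' @param out_dir,seed Optional overrides of the file's values.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(fun, args) do.call(fun, as.list(args))
  task <- if (!is.null(raw$task)) build(task_config, raw$task)
          else task_config()
  pop <- if (!is.null(raw$design$population)) {
    build(population_spec, raw$design$population)
  } else population_spec()
  dargs <- raw$design
  dargs$population <- NULL
  dargs <- as.list(dargs)
  dargs$population <- pop
  dargs$task <- task
  design <- do.call(group_design, dargs)
  priors <- if (!is.null(raw$priors)) build(prior_spec, raw$priors)
            else prior_spec()
  run_config(
    design = design, priors = priors,
    n_restarts = if (!is.null(raw$n_restarts)) raw$n_restarts else 10,
    mcmc = utils::modifyList(list(n_samples = 5000, burn_in = 1000),
                             as.list(raw$mcmc)),
    wbic = if (!is.null(raw$wbic)) raw$wbic else TRUE,
    regression_covariates = if (!is.null(raw$regression_covariates))
      raw$regression_covariates else TRUE,
    paired_contrasts = isTRUE(raw$paired_contrasts),
    seed = if (!is.null(seed)) seed else raw$seed,
    out_dir = if (!is.null(out_dir)) out_dir else raw$out_dir
  )
}

out_file <- function(config, name) file.path(config$out_dir, name)

write_table <- function(df, config, name) {
  df$run_seed <- config$seed
  utils::write.csv(df, out_file(config, name), row.names = FALSE)
  invisible(df)
}

read_table <- function(config, name) {
  f <- out_file(config, name)
  if (!file.exists(f)) return(NULL)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  df$run_seed <- NULL
  df
}

with_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    stop_config("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Pipeline stages
#'
#' `pipeline_simulate()` generates the synthetic dataset and writes
#' `sessions.csv`, `units.csv` and `ground_truth.csv`;
#' `pipeline_fit()` reads the session files and writes MAP fit tables for
#' both models (`fits_simple.csv`, `fits_asymmetric.csv`);
#' `pipeline_wbic()` writes per-unit WBICs for both models (`wbic.csv`) and
#' the model-comparison t-test (`model_comparison.csv`);
#' `pipeline_analyze()` assembles [unit_records()] and writes the analysis
#' report tables plus `report.md`. [run_pipeline()] runs them in order.
#' Every written table carries the run seed in a `run_seed` column.
#'
#' @param config A [run_config()].
#' @return Each stage invisibly returns its main in-memory product.
#' @export
pipeline_simulate <- function(config) {
  with_stage("simulate", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    design <- config$design
    design$seed <- config$seed
    ds <- generate_dataset(design)
    write_table(sessions_to_trials(ds$sessions), config, "sessions.csv")
    write_table(ds$units, config, "units.csv")
    if (!is.null(ds$ground_truth)) {
      write_table(ds$ground_truth, config, "ground_truth.csv")
    }
    invisible(ds)
  })
}

#' @rdname pipeline_simulate
#' @export
pipeline_fit <- function(config) {
  with_stage("fit", {
    sess <- read_sessions(out_file(config, "sessions.csv"),
                          out_file(config, "units.csv"))
    fs <- fit_sessions(sess, "simple", config$priors, config$n_restarts,
                       seed = config$seed + 1L)
    fa <- fit_sessions(sess, "asymmetric", config$priors, config$n_restarts,
                       seed = config$seed + 1L)
    write_table(fs, config, "fits_simple.csv")
    write_table(fa, config, "fits_asymmetric.csv")
    invisible(list(simple = fs, asymmetric = fa))
  })
}

#' @rdname pipeline_simulate
#' @export
pipeline_wbic <- function(config) {
  with_stage("wbic", {
    sess <- read_sessions(out_file(config, "sessions.csv"),
                          out_file(config, "units.csv"))
    ws <- wbic_sessions(sess, "simple", config$priors,
                        config$mcmc$n_samples, config$mcmc$burn_in,
                        seed = config$seed + 2L)
    wa <- wbic_sessions(sess, "asymmetric", config$priors,
                        config$mcmc$n_samples, config$mcmc$burn_in,
                        seed = config$seed + 2L)
    write_table(rbind(ws, wa), config, "wbic.csv")
    write_table(compare_models(ws$wbic, wa$wbic), config,
                "model_comparison.csv")
    invisible(list(simple = ws, asymmetric = wa))
  })
}

#' @rdname pipeline_simulate
#' @export
pipeline_analyze <- function(config) {
  with_stage("analyze", {
    sess <- read_sessions(out_file(config, "sessions.csv"),
                          out_file(config, "units.csv"))
    fs <- read_table(config, "fits_simple.csv")
    fa <- read_table(config, "fits_asymmetric.csv")
    records <- unit_records(sess, fs, fa)
    write_table(records, config, "unit_records.csv")
    report <- analysis_report(
      records,
      regression_covariates = config$regression_covariates,
      paired_contrasts = config$paired_contrasts
    )
    for (nm in names(report)) {
      if (!is.null(report[[nm]])) {
        write_table(as.data.frame(report[[nm]]), config,
                    paste0(nm, ".csv"))
      }
    }
    write_report_md(report, config)
    invisible(report)
  })
}

write_report_md <- function(report, config) {
  con <- file(out_file(config, "report.md"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Group-size bandit analysis report")
  w("")
  w("Run seed: %d", config$seed)
  fmt_df <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    paste(utils::capture.output(print(df, row.names = FALSE)),
          collapse = "\n")
  }
  sections <- c(
    descriptives = "Descriptive statistics by group size",
    omnibus = "Kruskal-Wallis omnibus tests",
    pairwise = "Pairwise Wilcoxon rank-sum tests (Bonferroni-adjusted)",
    positivity_bias = "Positivity-bias tests",
    within_group = "Within-group contrasts vs member aggregates",
    regressions = "Poisson regressions of performance"
  )
  for (nm in names(sections)) {
    if (is.null(report[[nm]])) next
    w("")
    w("## %s", sections[nm])
    w("")
    w("```")
    writeLines(fmt_df(report[[nm]]), con)
    w("```")
  }
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Simulate, fit, (optionally) score WBICs, and analyze, writing all artifact
#' files plus a `log.txt` with the seed, package and R versions and per-stage
#' timings into `config$out_dir`. Identical config + seed produce
#' byte-identical data tables. Running the stages individually on the emitted
#' files gives the same results as this one-shot entry point, since each
#' stage reads its inputs back from the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dataset, fits, WBICs (or `NULL`) and
#'   the [analysis_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("banditgroups %s | R %s", as.character(utils::packageVersion("banditgroups")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  )
  stages <- list(
    simulate = pipeline_simulate,
    fit = pipeline_fit,
    wbic = if (config$wbic) pipeline_wbic else NULL,
    analyze = pipeline_analyze
  )
  out <- list()
  for (nm in names(stages)) {
    if (is.null(stages[[nm]])) next
    t0 <- proc.time()[["elapsed"]]
    out[[nm]] <- stages[[nm]](config)
    dt <- proc.time()[["elapsed"]] - t0
    n_units <- if (nm == "simulate") length(out[[nm]]$sessions) else NA
    log_lines <- c(log_lines,
                   sprintf("stage %-8s done in %.1fs%s", nm, dt,
                           if (!is.na(n_units))
                             sprintf(" (%d units)", n_units) else ""))
  }
  writeLines(log_lines, out_file(config, "log.txt"))
  invisible(out)
}
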