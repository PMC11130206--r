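## canonical CSV column sets
.dotprobe_cols <- c("subject_id", "session_id", "trial_index", "task",
                    "congruence", "probe_side", "rt_ms", "pair_id",
                    "width_diff", "is_repetition")
.preference_cols <- c("subject_id", "session_id", "trial_index", "phase",
                      "block", "order", "flanged_colour",
                      "flanged_dot_height", "choice")

#' Write a trial table to CSV in the package's canonical dialect
#'
#' Selects the canonical columns for the schema and writes plain CSV
#' (no row names), so a write/read round trip reproduces the table exactly.
#'
#' @param trials Trial table.
#' @param path Output file path.
#' @param schema `"dotprobe"` or `"preference"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, schema = c("dotprobe", "preference")) {
  schema <- match.arg(schema)
  cols <- if (schema == "dotprobe") .dotprobe_cols else .preference_cols
  missing <- setdiff(cols, names(trials))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(trials[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads a CSV of dot-probe or preference trials, optionally applying a
#' rename map first so externally deposited column names can be ingested
#' without hard-coding them. All schema columns must be present after
#' renaming; row-level violations (non-positive RT, out-of-range dot height,
#' non-binary choice, unknown factor levels) are collected and reported
#' together with their row numbers.
#'
#' @param path CSV file path.
#' @param schema `"dotprobe"` or `"preference"`.
#' @param rename_map Optional named character vector `c(external = canonical)`
#'   mapping the file's column names to the canonical ones.
#' @return Validated, typed data.frame.
#' @export
read_trials <- function(path, schema = c("dotprobe", "preference"),
                        rename_map = NULL) {
  schema <- match.arg(schema)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(rename_map)) {
    hit <- names(d) %in% names(rename_map)
    names(d)[hit] <- unname(rename_map[names(d)[hit]])
  }
  cols <- if (schema == "dotprobe") .dotprobe_cols else .preference_cols
  missing <- setdiff(cols, names(d))
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf(
        "%d row(s) with %s (rows %s)", length(rows), what,
        paste(utils::head(rows, 5L), collapse = ", ")))
    }
  }
  if (schema == "dotprobe") {
    flag(!is.finite(d$rt_ms) | d$rt_ms <= 0, "non-positive rt_ms")
    flag(!d$congruence %in% c("congruent", "incongruent"),
         "invalid congruence")
    flag(!d$probe_side %in% c("left", "right"), "invalid probe_side")
    d$is_repetition <- as.logical(d$is_repetition)
    flag(is.na(d$is_repetition), "invalid is_repetition")
  } else {
    flag(!d$phase %in% c("forced", "choice"), "invalid phase")
    flag(!d$flanged_colour %in% c("red", "green"), "invalid flanged_colour")
    flag(!d$order %in% c("red_first", "green_first"), "invalid order")
    flag(!is.finite(d$flanged_dot_height) |
           abs(d$flanged_dot_height) > 0.35 + 1e-9,
         "flanged_dot_height outside [-0.35, 0.35]")
    flag(!d$choice %in% c(0, 1), "non-binary choice")
  }
  if (length(problems) > 0)
    stop("validation failed for ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  d
}

#' Assemble a pipeline configuration
#'
#' Collects everything one run of the simulate/filter/fit/test pipeline
#' needs. Serialisable to/from YAML with [write_pipeline_config()] /
#' [read_pipeline_config()]. The seed is mandatory in `simulate` and `full`
#' modes; a [run_pipeline()] bundle plus its config reproduces every output
#' bit-identically.
#'
#' @param mode `"simulate"`, `"analyse"` or `"full"`.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed.
#' @param dotprobe_subjects,preference_subjects Subject identifier vectors.
#' @param dotprobe_params A [dotprobe_gen_params()] object.
#' @param choice_params A [choice_gen_params()] object.
#' @param sampler A [sampler_settings()] object.
#' @param switch_prior_a,switch_prior_b,switch_n_sims Switch-test settings.
#' @param input_dotprobe,input_preference Input CSV paths (analyse mode;
#'   default: the simulate-mode outputs inside `out_dir`).
#' @param rename_map Optional column rename map for external data.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("full", "simulate", "analyse"),
                            out_dir = tempfile("probepref_run_"),
                            seed = NULL,
                            dotprobe_subjects = c("subj1", "subj2", "subj3"),
                            preference_subjects = sprintf("subj%d", 1:6),
                            dotprobe_params = dotprobe_gen_params(),
                            choice_params = choice_gen_params(),
                            sampler = sampler_settings(),
                            switch_prior_a = 10, switch_prior_b = 10,
                            switch_n_sims = 10000,
                            input_dotprobe = NULL, input_preference = NULL,
                            rename_map = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("simulate", "full") && is.null(seed))
    stop("seed is mandatory in simulate/full modes")
  if (is.null(seed)) seed <- 1L
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 dotprobe_subjects = dotprobe_subjects,
                 preference_subjects = preference_subjects,
                 dotprobe_params = dotprobe_params,
                 choice_params = choice_params,
                 sampler = sampler,
                 switch_prior_a = switch_prior_a,
                 switch_prior_b = switch_prior_b,
                 switch_n_sims = switch_n_sims,
                 input_dotprobe = input_dotprobe,
                 input_preference = input_preference,
                 rename_map = rename_map),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$dotprobe_params <- unclass(x$dotprobe_params)
  x$choice_params <- unclass(x$choice_params)
  x$sampler <- unclass(x$sampler)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_pipeline_config()] (or hand-written
#'   with the same fields).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    mode = x$mode, out_dir = x$out_dir, seed = x$seed,
    dotprobe_subjects = unlist(x$dotprobe_subjects),
    preference_subjects = unlist(x$preference_subjects),
    dotprobe_params = do.call(dotprobe_gen_params, x$dotprobe_params),
    choice_params = do.call(choice_gen_params, x$choice_params),
    sampler = do.call(sampler_settings, x$sampler),
    switch_prior_a = x$switch_prior_a, switch_prior_b = x$switch_prior_b,
    switch_n_sims = x$switch_n_sims,
    input_dotprobe = x$input_dotprobe,
    input_preference = x$input_preference,
    rename_map = if (is.null(x$rename_map)) NULL else unlist(x$rename_map))
}

## simulate both experiments for all subjects under the study design
.simulate_stage <- function(config) {
  seed <- config$seed
  designs <- list(flange = list(pairs = stimulus_pairs(72, "flange"),
                                n_sessions = 6L, tps = 24L),
                  symmetry = list(pairs = stimulus_pairs(80, "symmetry"),
                                  n_sessions = 8L, tps = 20L))
  tabs <- list()
  k <- 0L
  for (task in names(designs)) {
    dg <- designs[[task]]
    for (s in seq_along(config$dotprobe_subjects)) {
      k <- k + 1L
      plan <- schedule_dotprobe(dg$pairs, dg$n_sessions, dg$tps,
                                seed = (seed + 1000L * k) %%
                                  .Machine$integer.max)
      tabs[[k]] <- simulate_dotprobe(plan, config$dotprobe_params,
                                     subject_id = config$dotprobe_subjects[s],
                                     seed = (seed + 1000L * k + 1L) %%
                                       .Machine$integer.max)
    }
  }
  dot <- do.call(rbind, tabs)
  plan_pref <- schedule_preference(config$preference_subjects,
                                   seed = (seed + 77L) %%
                                     .Machine$integer.max)
  pref <- simulate_choices(plan_pref, config$choice_params,
                           seed = (seed + 78L) %% .Machine$integer.max)
  list(dotprobe = dot, preference = pref)
}

#' Run the full simulate / filter / fit / test pipeline
#'
#' `simulate` mode generates and writes the two trial tables only.
#' `analyse` mode reads trial CSVs, filters the dot-probe RTs with one
#' repetition round (excluded trials are re-run by simulating their plan
#' under the configured generator; external datasets that already contain
#' repetition sessions should carry them as extra session levels instead),
#' fits the per-subject robust dot-probe regressions and
#' the pooled preference model, runs the per-session switch tests, and
#' writes all result CSVs plus a human-readable summary. `full` does both.
#' Every stage logs its wall time and the seed in use; a rerun with the same
#' config produces hash-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return A `report_bundle`: list with the filter reports, per-subject
#'   dot-probe summary table, preference summary tables, per-session switch
#'   results, diagnostics roll-up, and provenance (seed, config hash, file
#'   paths, package/backend versions).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    if (!quiet)
      message(sprintf("[%s] done in %.1f s (seed %d)", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      config$seed))
    res
  }
  paths <- list(dotprobe = file.path(config$out_dir, "dotprobe_trials.csv"),
                preference = file.path(config$out_dir,
                                       "preference_trials.csv"))
  bundle <- list(config = config)

  if (config$mode %in% c("simulate", "full")) {
    sim <- log_stage("simulate", .simulate_stage(config))
    write_trials(sim$dotprobe, paths$dotprobe, "dotprobe")
    write_trials(sim$preference, paths$preference, "preference")
    bundle$simulated <- sim
  }
  if (config$mode == "simulate") {
    bundle$provenance <- .provenance(config, paths)
    class(bundle) <- "report_bundle"
    return(bundle)
  }

  in_dot <- if (!is.null(config$input_dotprobe)) config$input_dotprobe
  else paths$dotprobe
  in_pref <- if (!is.null(config$input_preference)) config$input_preference
  else paths$preference
  dot <- read_trials(in_dot, "dotprobe", config$rename_map)
  pref <- read_trials(in_pref, "preference", config$rename_map)

  ## filtering, with one repetition round per task (re-simulated when the
  ## generator parameters are available, i.e. for simulated data)
  filt <- log_stage("filter", {
    out <- list()
    for (task in unique(dot$task)) {
      d <- dot[dot$task == task, , drop = FALSE]
      primary <- filter_trials(d)
      reps <- list()
      for (s in unique(primary$excluded$subject_id)) {
        exc <- primary$excluded[primary$excluded$subject_id == s, ,
                                drop = FALSE]
        plan <- repetition_plan(exc, session_id = "R1")
        reps[[s]] <- simulate_dotprobe(
          plan, config$dotprobe_params, subject_id = s,
          seed = (config$seed + 5000L + match(task, unique(dot$task))) %%
            .Machine$integer.max)
        reps[[s]]$is_repetition <- TRUE
        reps[[s]] <- reps[[s]][, .dotprobe_cols, drop = FALSE]
      }
      repetition <- filter_trials(do.call(rbind, c(reps, list(d[0, ]))))
      out[[task]] <- suppressWarnings(merge_repetitions(primary, repetition))
    }
    out
  })
  bundle$filtering <- filt

  bundle$dotprobe_fits <- log_stage("fit-dotprobe", {
    fits <- list()
    for (task in names(filt)) {
      d <- filt[[task]]$trials
      for (s in unique(d$subject_id)) {
        fits[[paste(task, s)]] <-
          fit_dotprobe_subject(d[d$subject_id == s, , drop = FALSE],
                               settings = config$sampler)
      }
    }
    fits
  })
  bundle$dotprobe_table <- dotprobe_results_table(bundle$dotprobe_fits)
  utils::write.csv(bundle$dotprobe_table,
                   file.path(config$out_dir, "dotprobe_results.csv"),
                   row.names = FALSE)

  bundle$preference_fit <- log_stage("fit-preference",
    fit_preference(pref, include_height = TRUE, settings = config$sampler))
  bundle$preference_table <- preference_results_table(bundle$preference_fit)
  utils::write.csv(bundle$preference_table,
                   file.path(config$out_dir, "preference_results.csv"),
                   row.names = FALSE)
  subj_prob <- per_subject_probability(bundle$preference_fit)
  bundle$subject_table <- do.call(rbind, lapply(names(subj_prob), function(s) {
    cbind(data.frame(subject_id = s), as.data.frame(subj_prob[[s]]))
  }))
  utils::write.csv(bundle$subject_table,
                   file.path(config$out_dir, "preference_subjects.csv"),
                   row.names = FALSE)

  bundle$switch_tests <- log_stage("switch-test",
    switch_test_sessions(pref, config$switch_prior_a, config$switch_prior_b,
                         config$switch_n_sims, seed = config$seed))
  utils::write.csv(bundle$switch_tests,
                   file.path(config$out_dir, "switch_tests.csv"),
                   row.names = FALSE)

  rhats <- c(vapply(bundle$dotprobe_fits,
                    function(f) .max_rhat(f$diagnostics), numeric(1)),
             preference = .max_rhat(bundle$preference_fit$diagnostics))
  bundle$diagnostics <- data.frame(model = names(rhats), rhat_max = rhats,
                                   row.names = NULL)
  bundle$all_converged <-
    all(vapply(bundle$dotprobe_fits, `[[`, logical(1), "converged")) &&
    bundle$preference_fit$converged

  summary_path <- file.path(config$out_dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con)
  cat("probepref pipeline summary (seed", config$seed, ")\n\n")
  for (task in names(filt)) {
    cat("==", task, "filtering ==\n"); print(filt[[task]])
  }
  cat("\n== dot-probe fits ==\n"); print(bundle$dotprobe_table)
  cat("\n== preference fit ==\n"); print(bundle$preference_table)
  cat("\n== switch tests ==\n")
  print(table(bundle$switch_tests$verdict))
  sink(); close(con)

  bundle$provenance <- .provenance(config, paths)
  class(bundle) <- "report_bundle"
  bundle
}

.provenance <- function(config, paths) {
  cfg_file <- tempfile(fileext = ".yaml")
  write_pipeline_config(config, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  list(seed = config$seed, config_hash = hash,
       out_dir = config$out_dir,
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("probepref")),
       backend = "JAGS via rjags")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("probepref report bundle (mode:", x$config$mode,
      ", seed:", x$provenance$seed, ")\n")
  cat("  outputs in:", x$provenance$out_dir, "\n")
  if (!is.null(x$dotprobe_table))
    cat("  dot-probe fits:", length(x$dotprobe_fits), "\n")
  if (!is.null(x$switch_tests))
    cat("  switch tests:", nrow(x$switch_tests), "sessions\n")
  invisible(x)
}
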