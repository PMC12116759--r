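# Run configuration, artifact and table I/O, end-to-end orchestration and
# the command-line interface.

#' Write / read a cohort as CSV or Parquet tables
#'
#' A cohort is stored as two files, `trajectories` (one row per
#' patient-hour) and `patients` (static covariates and flags), as plain CSV
#' by default or Parquet when the arrow package is installed.
#'
#' @param cohort A `cohort` list (`trajectories`, `patients`).
#' @param dir Directory to write into (created if needed).
#' @param format `"csv"` (default) or `"parquet"` (requires arrow).
#' @return `write_trajectories` returns the directory invisibly;
#'   `read_trajectories` returns a `cohort` list (the format is detected
#'   from the files present).
#' @export
write_trajectories <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required for parquet output", call. = FALSE)
    }
    arrow::write_parquet(cohort$trajectories,
                         file.path(dir, "trajectories.parquet"))
    arrow::write_parquet(cohort$patients, file.path(dir, "patients.parquet"))
  } else {
    utils::write.csv(cohort$trajectories, file.path(dir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(dir) {
  if (file.exists(file.path(dir, "trajectories.parquet"))) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required to read parquet input",
           call. = FALSE)
    }
    return(structure(list(
      trajectories = as.data.frame(
        arrow::read_parquet(file.path(dir, "trajectories.parquet"))),
      patients = as.data.frame(
        arrow::read_parquet(file.path(dir, "patients.parquet"))),
      config = NULL
    ), class = "cohort"))
  }
  tf <- file.path(dir, "trajectories.csv")
  pf <- file.path(dir, "patients.csv")
  for (f in c(tf, pf)) {
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
  }
  structure(list(
    trajectories = utils::read.csv(tf, stringsAsFactors = FALSE),
    patients = utils::read.csv(pf, stringsAsFactors = FALSE),
    config = NULL
  ), class = "cohort")
}

relist_dense <- function(x) {
  if (is.list(x) && !is.null(x$W)) {
    list(W = as.matrix(x$W), b = matrix(as.numeric(x$b), nrow = 1L))
  } else {
    lapply(x, relist_dense)
  }
}

#' Save / load a trained policy artifact
#'
#' The artifact (actor, critic and target-critic parameters, agent config,
#' normalization statistics, feature names and training log) is serialized
#' to a single JSON file at full numeric precision.
#'
#' @param artifact A `policy_artifact`.
#' @param path File path (conventionally `artifact.json`).
#' @return `save_artifact` returns `path` invisibly; `load_artifact` the
#'   restored `policy_artifact`.
#' @export
save_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "policy_artifact"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    actor = artifact$actor, critic = artifact$critic,
    target_critic = artifact$target_critic,
    config = unclass(artifact$config),
    norm_stats = list(min = as.list(artifact$norm_stats$min),
                      max = as.list(artifact$norm_stats$max),
                      features = artifact$norm_stats$features),
    feature_names = artifact$feature_names,
    log = if (is.null(artifact$log)) NULL else as.list(artifact$log)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) {
  if (!file.exists(path)) stop("no artifact at ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- raw$config
  cfg$hidden_layers <- as.numeric(cfg$hidden_layers)
  config <- do.call(agent_config, cfg[names(cfg) %in%
                                        names(formals(agent_config))])
  structure(list(
    actor = relist_dense(raw$actor),
    critic = relist_dense(raw$critic),
    target_critic = relist_dense(raw$target_critic),
    config = config,
    norm_stats = list(min = unlist(raw$norm_stats$min),
                      max = unlist(raw$norm_stats$max),
                      features = raw$norm_stats$features),
    feature_names = raw$feature_names,
    log = if (is.null(raw$log)) NULL else as.data.frame(raw$log)
  ), class = "policy_artifact")
}

# Serialize a transition dataset to JSON (episodes are rebuilt on read).
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "transition_dataset"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- unclass(dataset)
  payload$episodes <- NULL
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

read_dataset <- function(path) {
  if (!file.exists(path)) stop("no dataset at ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$states <- as.matrix(raw$states)
  raw$next_states <- as.matrix(raw$next_states)
  colnames(raw$states) <- colnames(raw$next_states) <- raw$feature_names
  raw$norm_stats <- list(min = unlist(raw$norm_stats$min),
                         max = unlist(raw$norm_stats$max),
                         features = raw$norm_stats$features)
  raw$episodes <- split(seq_along(raw$actions),
                        raw$patient_id)[unique(raw$patient_id)]
  structure(raw, class = "transition_dataset")
}

config_blocks <- function() {
  list(
    sim = setdiff(names(formals(sim_config)), "seed"),
    reward = names(formals(reward_params)),
    pipeline = c("train_frac", "threshold", "k", "horizon"),
    agent = setdiff(names(formals(agent_config)), "seed"),
    ope = c("n_models", "subsample_frac", "fqe_hidden", "fqe_lr",
            "fqe_steps", "fqe_batch_size", "fqe_target_update",
            "n_bootstrap"),
    analysis = c("n_bootstrap", "delta_breaks", "glucose_breaks")
  )
}

#' Assemble and validate a run configuration
#'
#' Builds the nested configuration of an end-to-end run from a YAML file or
#' a named list. Recognized blocks are `sim`, `reward`, `pipeline`, `agent`,
#' `ope` and `analysis`, plus top-level `seed` and `output_dir`; unknown
#' blocks or keys are rejected. Values not supplied fall back to each
#' module's defaults. One seed governs the run; per-model seeds are derived
#' from it.
#'
#' @param config Path to a YAML file, or a named list.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  blocks <- config_blocks()
  allowed_top <- c(names(blocks), "seed", "output_dir")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown)) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (blk in names(blocks)) {
    extra <- setdiff(names(config[[blk]]), blocks[[blk]])
    if (length(extra)) {
      stop(sprintf("unknown key(s) in '%s': %s", blk,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  seed <- as.integer(config$seed %||% 1L)
  sim <- do.call(sim_config, c(config$sim, list(seed = seed)))
  reward <- do.call(reward_params, config$reward %||% list())
  agent <- do.call(agent_config, c(config$agent, list(seed = seed)))
  pipeline <- utils::modifyList(
    list(train_frac = 0.85, threshold = 0.30, k = 5, horizon = 24),
    config$pipeline %||% list())
  ope <- utils::modifyList(
    list(n_models = 5, subsample_frac = 0.80, fqe_hidden = c(256, 256),
         fqe_lr = 3e-4, fqe_steps = 2000, fqe_batch_size = 256,
         fqe_target_update = 100, n_bootstrap = 10000),
    config$ope %||% list())
  analysis <- utils::modifyList(
    list(n_bootstrap = 1000, delta_breaks = NULL, glucose_breaks = NULL),
    config$analysis %||% list())
  structure(list(seed = seed, output_dir = config$output_dir %||% "runs/run1",
                 sim = sim, reward = reward, pipeline = pipeline,
                 agent = agent, ope = ope, analysis = analysis),
            class = "run_config")
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] %s (%.1f s)", format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full pipeline end to end
#'
#' Simulate a cohort, preprocess it into transition datasets, run the
#' multi-seed training/selection protocol, evaluate the selected policy and
#' the clinician behaviour, compute the descriptive analyses, and write all
#' results (resolved configuration, seeds, package version, per-model
#' leaderboard, analysis report, trained artifact) into the output
#' directory. Rerunning with the same configuration reproduces all outputs.
#'
#' @param config A [run_config()], or anything it accepts.
#' @param engine Training engine, see [train_dcql()].
#' @param verbose Log stage timings.
#' @return Invisibly, a list with the output directory and the in-memory
#'   results (`mdp`, `protocol`, `behavior`, `comparison`, `report`).
#' @export
run_end_to_end <- function(config = run_config(), engine = c("cpp", "r"),
                           verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  engine <- match.arg(engine)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  cohort <- simulate_cohort(config$sim)
  if (verbose) stage_log("simulate", t0)

  mdp <- build_mdp(cohort, train_frac = config$pipeline$train_frac,
                   seed = config$seed, params = config$reward,
                   threshold = config$pipeline$threshold,
                   k = config$pipeline$k, horizon = config$pipeline$horizon)
  if (verbose) stage_log("preprocess", t0)

  fqe_args <- list(hidden = config$ope$fqe_hidden, lr = config$ope$fqe_lr,
                   steps = config$ope$fqe_steps,
                   batch_size = config$ope$fqe_batch_size,
                   target_update = config$ope$fqe_target_update,
                   n_bootstrap = config$ope$n_bootstrap)
  protocol <- multiseed_protocol(mdp$train, mdp$test,
                                 n_models = config$ope$n_models,
                                 config = config$agent,
                                 subsample_frac = config$ope$subsample_frac,
                                 fqe_args = fqe_args, engine = engine,
                                 verbose = verbose)
  if (verbose) stage_log("train+select", t0)

  behavior <- behavior_returns(mdp$test, gamma = config$agent$discount,
                               n_bootstrap = config$ope$n_bootstrap,
                               seed = config$seed)
  comparison <- compare_policies(protocol$best, mdp$test)
  tir_tab <- do.call(tir_by_difference, c(
    list(comparison, n_bootstrap = config$analysis$n_bootstrap,
         seed = config$seed),
    if (!is.null(config$analysis$delta_breaks)) {
      list(breaks = config$analysis$delta_breaks)
    }))
  dose_tab <- do.call(dose_by_glucose, c(
    list(comparison, n_bootstrap = config$analysis$n_bootstrap,
         seed = config$seed),
    if (!is.null(config$analysis$glucose_breaks)) {
      list(breaks = config$analysis$glucose_breaks)
    }))
  if (verbose) stage_log("analyze", t0)

  best_fqe <- protocol$results[[protocol$best_index]]
  report <- list(
    package_version = as.character(utils::packageVersion("insulinrl")),
    seed = config$seed,
    model_seeds = protocol$leaderboard$seed,
    n_patients = config$sim$n_patients,
    exclusion_tally = as.list(mdp$exclusion_tally),
    dropped_features = mdp$dropped_features,
    selected_model = protocol$best_index,
    fqe_value = best_fqe$mean_value,
    fqe_ci = c(best_fqe$ci_low, best_fqe$ci_high),
    behavior_value = behavior$result$mean_value,
    behavior_ci = c(behavior$result$ci_low, behavior$result$ci_high),
    agreement_rate = agreement_rate(comparison$timesteps$model_dose,
                                    comparison$timesteps$observed_dose),
    mean_tir = mean(comparison$patients$tir)
  )
  utils::write.csv(protocol$leaderboard,
                   file.path(out_dir, "leaderboard.csv"), row.names = FALSE)
  utils::write.csv(tir_tab, file.path(out_dir, "tir_by_difference.csv"),
                   row.names = FALSE)
  utils::write.csv(dose_tab, file.path(out_dir, "dose_by_glucose.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  save_artifact(protocol$best, file.path(out_dir, "best_model",
                                         "artifact.json"))
  yaml::write_yaml(serialize_run_config(config),
                   file.path(out_dir, "config.yaml"))
  if (verbose) stage_log("write outputs", t0)

  invisible(list(output_dir = out_dir, mdp = mdp, protocol = protocol,
                 behavior = behavior, comparison = comparison,
                 tir_by_difference = tir_tab, dose_by_glucose = dose_tab,
                 report = report))
}

serialize_run_config <- function(config) {
  list(seed = config$seed, output_dir = config$output_dir,
       sim = unclass(config$sim)[setdiff(names(unclass(config$sim)), "seed")],
       reward = unclass(config$reward),
       pipeline = config$pipeline,
       agent = unclass(config$agent)[setdiff(names(unclass(config$agent)),
                                             "seed")],
       ope = config$ope, analysis = config$analysis)
}

# ---- command-line interface ------------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) {
      stop("unexpected argument: ", key, call. = FALSE)
    }
    key <- substring(key, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: insulinrl <command> [options]",
    "",
    "commands:",
    "  simulate   --n N --seed S --out DIR [--horizon H]",
    "  preprocess --data DIR --out DIR [--seed S] [--train-frac F]",
    "             [--threshold T] [--k K]",
    "  train      --data train.json --out DIR [--seed S] [--steps N]",
    "  evaluate   --policy DIR --data test.json [--bootstrap N] [--seed S]",
    "  analyze    --policy DIR --data test.json --out DIR [--seed S]",
    "  run        --config cfg.yaml [--engine cpp|r]",
    sep = "\n")
}

need_arg <- function(opts, key) {
  if (is.null(opts[[key]])) {
    stop("missing required option --", key, "\n", cli_usage(), call. = FALSE)
  }
  opts[[key]]
}

cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat(cli_usage(), "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  num <- function(x, default = NULL) {
    if (is.null(x)) default else as.numeric(x)
  }
  switch(
    cmd,
    simulate = {
      cfg <- sim_config(n_patients = num(need_arg(opts, "n")),
                        seed = num(opts$seed, 1),
                        horizon = num(opts$horizon, 24))
      dir <- write_trajectories(simulate_cohort(cfg), need_arg(opts, "out"))
      message("wrote cohort to ", dir)
    },
    preprocess = {
      cohort <- read_trajectories(need_arg(opts, "data"))
      mdp <- build_mdp(cohort, train_frac = num(opts[["train-frac"]], 0.85),
                       seed = num(opts$seed, 1),
                       threshold = num(opts$threshold, 0.30),
                       k = num(opts$k, 5))
      out <- need_arg(opts, "out")
      write_dataset(mdp$train, file.path(out, "train.json"))
      write_dataset(mdp$test, file.path(out, "test.json"))
      jsonlite::write_json(
        list(split = mdp$split, exclusion_tally = as.list(mdp$exclusion_tally),
             dropped_features = mdp$dropped_features),
        file.path(out, "preprocess.json"), auto_unbox = TRUE)
      message("wrote transition datasets to ", out)
    },
    train = {
      ds <- read_dataset(need_arg(opts, "data"))
      cfg <- agent_config(seed = num(opts$seed, 1),
                          gradient_steps = num(opts$steps, 5000))
      art <- train_dcql(ds, cfg)
      path <- file.path(need_arg(opts, "out"), "artifact.json")
      save_artifact(art, path)
      message("wrote artifact to ", path)
    },
    evaluate = {
      art <- load_artifact(file.path(need_arg(opts, "policy"),
                                     "artifact.json"))
      ds <- read_dataset(need_arg(opts, "data"))
      fqe <- fqe_evaluate(ds, art, gamma = art$config$discount,
                          n_bootstrap = num(opts$bootstrap, 10000),
                          seed = num(opts$seed, 1))
      print(fqe$result)
    },
    analyze = {
      art <- load_artifact(file.path(need_arg(opts, "policy"),
                                     "artifact.json"))
      ds <- read_dataset(need_arg(opts, "data"))
      comparison <- compare_policies(art, ds)
      out <- need_arg(opts, "out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      seed <- num(opts$seed, 1)
      utils::write.csv(tir_by_difference(comparison, seed = seed),
                       file.path(out, "tir_by_difference.csv"),
                       row.names = FALSE)
      utils::write.csv(dose_by_glucose(comparison, seed = seed),
                       file.path(out, "dose_by_glucose.csv"),
                       row.names = FALSE)
      utils::write.csv(comparison$patients,
                       file.path(out, "patients.csv"), row.names = FALSE)
      message("wrote analysis tables to ", out)
    },
    run = {
      cfg <- run_config(need_arg(opts, "config"))
      engine <- if (is.null(opts$engine)) "cpp" else opts$engine
      run_end_to_end(cfg, engine = engine)
    },
    stop("unknown command '", cmd, "'\n", cli_usage(), call. = FALSE)
  )
  invisible(0L)
}
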