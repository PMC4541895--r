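# Pipeline configuration and end-to-end orchestration.

#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults: membership slopes
#' (15, toe 50), smoothing coefficient 0.3, type-7 quantile calibration,
#' 22 retained PCA dimensions, six folds, 1200 training vectors per
#' activity and the simulator settings. The configuration round-trips
#' through YAML without loss; command-line flags override file values.
#'
#' @param ... Named overrides of the default entries.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter_coefficient = 0.3,
    quantile_type = calibration_quantile_type(),
    membership = list(fsr_heel = list(slope = 15, inflection = 0.5),
                      fsr_5th  = list(slope = 15, inflection = 0.5),
                      fsr_1st  = list(slope = 15, inflection = 0.5),
                      fsr_toe  = list(slope = 50, inflection = 0.5)),
    min_event_duration_ms = 0,
    feature_set = "mean_rms_domfreq",
    phase_foot = "left",
    n_components = 22L,
    folds = 6L,
    n_per_class = 1200L,
    simulator = list(cadence = 100, n_cycles = 20, noise_sd = 0.05,
                     transition_ramp_ms = 60),
    seed = 1L,
    out_dir = "insolegait-artifacts")
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- pipeline_config()
  doc <- yaml::read_yaml(path)
  cfg[names(doc)] <- doc
  cfg
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_membership_params <- function(config) {
  lapply(config$membership, function(m) {
    membership_params(slope = m$slope, inflection = m$inflection)
  })
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full monitoring pipeline on synthetic data
#'
#' Executes simulate -> calibrate -> detect -> featurize -> train ->
#' evaluate with the given configuration, writing every artifact (streams,
#' calibration profile, phase events, feature corpus, trained model,
#' evaluation report) under `config$out_dir`. Every artifact set is
#' stamped with the configuration hash and seed in `run_info.json`, and
#' identical configurations reproduce byte-identical CSVs.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of artifact paths plus the evaluation result.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[insolegait] ", ...)
  paths <- list()
  art <- function(name) file.path(config$out_dir, name)

  sim <- config$simulator
  params <- gait_sim_params(cadence = sim$cadence, n_cycles = sim$n_cycles,
                            noise_sd = sim$noise_sd,
                            transition_ramp_ms = sim$transition_ramp_ms,
                            seed = config$seed)
  mf <- config_membership_params(config)

  say("simulating calibration recordings and walking trial")
  cal <- simulate_calibration(seed = offset_seed(config$seed, 1000L))
  walk <- simulate_walk_forward(params)
  write_stream(walk[stream_columns()], paths$stream <- art("stream.csv"))

  say("calibrating")
  profile <- calibrate_profile(cal$unloaded, cal$loaded)
  write_profile(profile, paths$profile <- art("profile.json"))

  say("detecting gait phases")
  norm <- normalize_stream(
    low_pass_filter(walk[stream_columns()], config$filter_coefficient),
    profile)
  events <- do.call(rbind, lapply(c("left", "right"), function(s) {
    ev <- demarcate_phases(gpda_memberships(norm, s, params = mf),
                           config$min_event_duration_ms)
    ev$side <- s
    ev
  }))
  write_events(events, paths$phases <- art("phases.csv"))
  phase_diff <- phase_duration_differences(events[events$side == "left", ])
  utils::write.csv(data.frame(phase = names(phase_diff),
                              mean_diff_ms = as.numeric(phase_diff)),
                   paths$phase_report <- art("phase_differences.csv"),
                   row.names = FALSE)

  say("building training corpus (", config$n_per_class, " per class)")
  corpus <- build_training_corpus(params, n_per_class = config$n_per_class)
  write_features(as.data.frame(corpus),
                 paths$features <- art("features.csv"))

  say("training PCA + GNB model")
  model <- train_activity_model(corpus, n_components = config$n_components)
  write_model(model, paths$model <- art("model.json"))

  say("evaluating with ", config$folds, "-fold cross-validation")
  cv <- six_fold_cv(corpus, n_components = config$n_components,
                    folds = config$folds)
  report <- data.frame(metric = c("cv_accuracy_pct",
                                  paste0("fold", seq_along(cv$fold_accuracy),
                                         "_accuracy_pct")),
                       value = c(cv$accuracy, cv$fold_accuracy))
  utils::write.csv(report, paths$report <- art("report.csv"),
                   row.names = FALSE)

  info <- list(config_hash = config_hash(config), seed = config$seed,
               artifacts = lapply(paths, basename))
  jsonlite::write_json(info, art("run_info.json"), auto_unbox = TRUE)
  say(sprintf("done: cross-validated accuracy %.2f%%", cv$accuracy))
  invisible(c(paths, list(cv = cv, phase_differences = phase_diff)))
}

# ---- command-line interface -------------------------------------------------

#' Command-line entry point
#'
#' Dispatches the subcommands exposed by the `exec/insolegait` script:
#' simulate, calibrate, detect, featurize, train, classify, evaluate and
#' run-all. Each is a thin wrapper over the exported functions; flags are
#' `--name value` pairs.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: insolegait <command> [--flag value ...]",
    "",
    "commands:",
    "  simulate   --activity walking_forward --seconds 30 --seed 7 --out stream.csv",
    "  calibrate  --unloaded u.csv --loaded l.csv --out profile.json",
    "  detect     --in stream.csv --profile profile.json --out phases.csv",
    "  featurize  --in stream.csv --profile profile.json --out features.csv",
    "  train      --features features.csv --components 22 --out model.json",
    "  classify   --in stream.csv --profile profile.json --model model.json --out activities.csv",
    "  evaluate   --features features.csv --components 22 --folds 6",
    "  run-all    [--config config.yaml] [--out-dir DIR] [--seed N]",
    sep = "\n")
  if (length(args) == 0L || args[1L] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1L]
  opt <- parse_cli_flags(args[-1L])
  get_opt <- function(name, default = NULL) {
    if (!is.null(opt[[name]])) opt[[name]] else default %||%
      stop("missing required flag --", name, call. = FALSE)
  }
  switch(cmd,
    simulate = {
      seed <- as.integer(get_opt("seed", 1L))
      kind <- get_opt("activity", "walking_forward")
      secs <- as.numeric(get_opt("seconds", 30))
      stream <- simulate_activity(kind, secs,
                                  gait_sim_params(seed = seed))
      write_stream(stream[stream_columns()], get_opt("out"))
      labels_path <- opt[["labels"]]
      if (!is.null(labels_path)) {
        utils::write.csv(stream[c("time", "side", "phase", "activity")],
                         labels_path, row.names = FALSE)
      }
    },
    calibrate = {
      profile <- calibrate_profile(read_stream(get_opt("unloaded")),
                                   read_stream(get_opt("loaded")))
      write_profile(profile, get_opt("out"))
    },
    detect = {
      norm <- normalize_stream(read_stream(get_opt("in")),
                               read_profile(get_opt("profile")))
      events <- do.call(rbind, lapply(intersect(c("left", "right"),
                                                unique(norm$side)),
        function(s) {
          ev <- demarcate_phases(gpda_memberships(norm, s))
          ev$side <- s
          ev
        }))
      write_events(events, get_opt("out"))
    },
    featurize = {
      fv <- pipeline_features(read_stream(get_opt("in")),
                              read_profile(get_opt("profile")))
      write_features(fv, get_opt("out"))
    },
    train = {
      tab <- utils::read.csv(get_opt("features"))
      model <- train_activity_model(as.matrix(tab[feature_names()]),
                                    tab$label,
                                    n_components =
                                      as.integer(get_opt("components", 22L)))
      write_model(model, get_opt("out"))
    },
    classify = {
      out <- classify_stream(read_stream(get_opt("in")),
                             read_profile(get_opt("profile")),
                             read_model(get_opt("model")))
      utils::write.csv(out, get_opt("out"), row.names = FALSE)
    },
    evaluate = {
      tab <- utils::read.csv(get_opt("features"))
      cv <- six_fold_cv(as.matrix(tab[feature_names()]),
                        labels = tab$label,
                        n_components = as.integer(get_opt("components", 22L)),
                        folds = as.integer(get_opt("folds", 6L)))
      cat(sprintf("cross-validated accuracy: %.2f%%\n", cv$accuracy))
    },
    "run-all" = {
      cfg <- if (!is.null(opt[["config"]])) read_config(opt[["config"]])
             else pipeline_config()
      if (!is.null(opt[["out-dir"]])) cfg$out_dir <- opt[["out-dir"]]
      if (!is.null(opt[["seed"]])) cfg$seed <- as.integer(opt[["seed"]])
      run_pipeline(cfg)
    },
    {
      cat(usage, "\n")
      stop("unknown command: ", cmd, call. = FALSE)
    })
  invisible(0L)
}

parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i + 1L > length(args)) stop("flag ", a, " needs a value",
                                    call. = FALSE)
    opt[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
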