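# Configuration and end-to-end orchestration: simulate a cohort to disk,
# run the full pipeline, write machine-readable reports and manifests.

#' Run configuration
#'
#' A validated bag of every knob of an end-to-end run: the root seed, the
#' protocol script of the simulated cohort, the evaluation configuration,
#' and the output paths. Every run writes a manifest (config, seed, package
#' version) next to its outputs, from which the run is reproducible
#' bit-for-bit.
#'
#' @param seed Integer root seed.
#' @param data_dir Directory holding (or receiving) the cohort.
#' @param out_dir Directory receiving reports and manifests.
#' @param script A [protocol_script()].
#' @param eval An [eval_config()] (its seed is overridden by `seed`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, data_dir = "data", out_dir = "out",
                       script = protocol_script(), eval = eval_config()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  eval$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), data_dir = data_dir,
                 out_dir = out_dir, script = script, eval = eval),
            class = "run_config")
}

#' Read a run configuration from JSON (or YAML)
#'
#' Unknown fields are rejected with the offending name. YAML files are
#' accepted when the `yaml` package is available.
#'
#' @param path Config file; `.json`, `.yml` or `.yaml`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("seed", "data_dir", "out_dir", "script", "eval")
  bad <- setdiff(names(obj), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  script <- if (!is.null(obj$script)) {
    sk <- c("activities", "trials", "n_subjects", "capacity_g",
            "initial_fill_g")
    bad <- setdiff(names(obj$script), sk)
    if (length(bad)) stop("unknown script field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    do.call(protocol_script, lapply(obj$script, unlist))
  } else protocol_script()
  ev <- eval_config()
  if (!is.null(obj$eval)) {
    for (nm in names(obj$eval)) {
      if (nm %in% c("detector_window", "spotter_window")) {
        ev[[nm]] <- do.call(window_spec, as.list(unlist(obj$eval[[nm]])))
      } else if (nm %in% names(ev)) {
        ev[[nm]] <- obj$eval[[nm]]
      } else {
        stop("unknown eval field: ", nm, call. = FALSE)
      }
    }
  }
  run_config(seed = obj$seed %||% 1L, data_dir = obj$data_dir %||% "data",
             out_dir = obj$out_dir %||% "out", script = script, eval = ev)
}

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "fluidintake",
    version = as.character(utils::packageVersion("fluidintake")),
    seed = config$seed,
    script = unclass(config$script),
    eval = lapply(unclass(config$eval), function(v) {
      if (inherits(v, "window_spec")) unclass(v) else v
    })
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort and write it to disk
#'
#' Generates the synthetic cohort defined by the config's protocol script
#' and seed, writes it in the package's on-disk formats under
#' `config$data_dir`, together with a `manifest.json` listing the seed and
#' the drawn per-subject profile parameters.
#'
#' @param config A [run_config()].
#' @return The generated `intake_dataset`, invisibly.
#' @export
cmd_simulate <- function(config = run_config()) {
  profiles <- draw_subject_profiles(config$script$n_subjects,
                                    derive_seed(config$seed, 0L))
  ds <- generate_cohort(config$script, config$seed, profiles = profiles)
  write_dataset(ds, config$data_dir)
  write_manifest(config, file.path(config$data_dir, "manifest.json"),
                 extra = list(profiles = lapply(profiles, unclass)))
  invisible(ds)
}

#' Run the full pipeline end to end
#'
#' Loads the cohort from `config$data_dir` if present, otherwise simulates
#' it first, then runs the hierarchical leave-one-subject-out evaluation
#' (smoothing, detection, spotting, estimation) and writes
#' `report.json` plus `manifest.json` under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param simulate_if_missing Simulate the cohort when `data_dir` has none?
#' @return The `hier_eval_report`, invisibly.
#' @export
cmd_run_all <- function(config = run_config(), simulate_if_missing = TRUE) {
  ds <- if (file.exists(file.path(config$data_dir, "index.json"))) {
    read_dataset(config$data_dir)
  } else if (simulate_if_missing) {
    cmd_simulate(config)
  } else {
    stop("no dataset under ", config$data_dir, call. = FALSE)
  }
  report <- run_hierarchical_eval(ds, config$eval)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    detection = list(pooled = as.list(report$detection$pooled),
                     counts = report$detection$counts,
                     per_fold = report$detection$per_fold),
    gestures = list(per_gesture = report$gestures$per_gesture,
                    overall = as.list(report$gestures$overall)),
    amount_metrics = report$amount_metrics,
    event_accounting = report$event_accounting
  )
  jsonlite::write_json(out, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  # per-drink estimates: subject, trial, container, actual vs estimated
  utils::write.csv(report$amounts,
                   file.path(config$out_dir, "estimates.csv"),
                   row.names = FALSE)
  write_manifest(config, file.path(config$out_dir, "manifest.json"))
  invisible(report)
}
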