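#' Experiment manifest
#'
#' Bundles the three configuration blocks plus a root seed and output
#' directory into one reproducible description of a simulate-train-evaluate
#' run.
#'
#' @param simulation An [sim_config()].
#' @param architecture An [arch_config()].
#' @param training An [train_config()].
#' @param seed Root seed applied to all three stages.
#' @param out_dir Run directory for artifacts (`NULL` for none).
#' @return An object of class `ad_manifest`.
#' @export
experiment_manifest <- function(simulation = sim_config(),
                                architecture = arch_config(),
                                training = train_config(),
                                seed = 1L,
                                out_dir = NULL) {
  simulation$seed <- as.integer(seed)
  training$seed <- as.integer(seed)
  structure(list(simulation = simulation, architecture = architecture,
                 training = training, seed = as.integer(seed),
                 out_dir = out_dir, status = "pending"),
            class = "ad_manifest")
}

#' Read an experiment manifest from a YAML config file
#'
#' The file holds `simulation:`, `architecture:`, `training:` blocks whose
#' keys mirror the respective configuration constructors, plus optional
#' top-level `seed` and `out_dir`.
#'
#' @param path YAML file path.
#' @return An `ad_manifest`.
#' @export
read_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  build <- function(block, ctor) {
    args <- doc[[block]] %||% list()
    do.call(ctor, args)
  }
  experiment_manifest(simulation = build("simulation", sim_config),
                      architecture = build("architecture", arch_config),
                      training = build("training", train_config),
                      seed = doc$seed %||% 1L,
                      out_dir = doc$out_dir)
}

sim_config_hash <- function(config) {
  rlang::hash(config[c("dt", "range_D", "range_N", "range_B", "range_R",
                       "range_alpha", "range_Q", "n_per_class", "seed")])
}

.dataset_cache <- new.env(parent = emptyenv())

#' Run one simulate-train-evaluate experiment
#'
#' Generates (or reuses, by content hash of the simulation configuration)
#' the dataset, trains the configured network, evaluates it on the test
#' split, and - when `out_dir` is set - writes the history CSV, checkpoint
#' and JSON report under the run directory. Stage failures are recorded on
#' the returned manifest under `status`.
#'
#' @param manifest An [experiment_manifest()].
#' @return The completed manifest, with elements `fit`, `report`,
#'   `dataset_hash`, `metrics` added.
#' @export
run_experiment <- function(manifest) {
  stage <- "simulate"
  result <- tryCatch({
    key <- sim_config_hash(manifest$simulation)
    dataset <- .dataset_cache[[key]]
    if (is.null(dataset)) {
      dataset <- generate_dataset(manifest$simulation)
      .dataset_cache[[key]] <- dataset
    }
    stage <- "train"
    fit <- train(build_network(manifest$architecture), dataset,
                 manifest$training)
    stage <- "evaluate"
    report <- evaluate(fit, dataset, split = "test")
    stage <- "write"
    if (!is.null(manifest$out_dir)) {
      dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(fit$history, file.path(manifest$out_dir, "history.csv"),
                       progress = FALSE)
      save_network(fit$network, file.path(manifest$out_dir, "checkpoint.rds"))
      write_report_json(report, file.path(manifest$out_dir, "report.json"))
    }
    manifest$fit <- fit
    manifest$report <- report
    manifest$dataset_hash <- key
    manifest$metrics <- glance(report)
    manifest$status <- "completed"
    manifest
  }, error = function(e) {
    manifest$status <- sprintf("failed at stage '%s': %s", stage,
                               conditionMessage(e))
    manifest
  })
  result
}

write_report_json <- function(report, path) {
  obj <- list(confusion = unclass(report$confusion),
              metrics = report$metrics, macro = report$macro,
              accuracy = report$accuracy, n = report$n)
  writeLines(yaml::as.yaml(obj), sub("\\.json$", ".yaml", path))
  json <- paste0(
    "{\n",
    sprintf('  "accuracy": %.6f,\n', report$accuracy),
    sprintf('  "macro_f1": %.6f,\n', report$macro$f1),
    sprintf('  "n": %d,\n', report$n),
    sprintf('  "confusion": [%s]\n',
            paste(apply(report$confusion, 1, function(r)
              sprintf("[%s]", paste(r, collapse = ", "))), collapse = ", ")),
    "}\n")
  cat(json, file = path)
  invisible(path)
}

#' Run a one-axis ablation grid
#'
#' Repeats the base experiment with one configuration axis swept over the
#' given values and summarizes each run in one row mirroring the
#' depth/kernel/width study tables: configuration value, trainable-parameter
#' count, final training accuracy, best validation accuracy and best epoch.
#' Unsupported values are skipped with a warning and recorded.
#'
#' @param base An [experiment_manifest()].
#' @param axis One of `"depth"`, `"kernel"`, `"x0"`, `"aux_features"`,
#'   `"autocorrelation"`, `"selective"`, `"cost"`, `"activation"`,
#'   `"batch_size"`.
#' @param values Vector (or list, for `aux_features`) of axis values.
#' @return Tibble with one row per completed run.
#' @export
run_ablation_grid <- function(base, axis, values) {
  axes <- c("depth", "kernel", "x0", "aux_features", "autocorrelation",
            "selective", "cost", "activation", "batch_size")
  if (!axis %in% axes) {
    abort(sprintf("`axis` must be one of %s.", paste(axes, collapse = ", ")))
  }
  rows <- list()
  for (v in values) {
    m <- base
    ok <- tryCatch({
      switch(axis,
             depth = { m$architecture$depth <- as.integer(v) },
             kernel = { m$architecture$kernel <- as.integer(v) },
             x0 = { m$architecture$x0 <- as.integer(v) },
             aux_features = { m$architecture$aux_features <- unlist(v) },
             autocorrelation = {
               m$architecture$use_autocorrelation <- isTRUE(v)
               m$architecture$input_channels <- 1L + if (isTRUE(v)) 3L else 0L
             },
             selective = { m$training$selective_mode <- as.character(v) },
             cost = { m$training$cost <- as.character(v) },
             activation = { m$architecture$activation <- as.character(v) },
             batch_size = { m$training$batch_size <- as.integer(v) })
      m$architecture <- do.call(arch_config, m$architecture[setdiff(
        names(m$architecture), "input_channels")])
      TRUE
    }, error = function(e) {
      warn(sprintf("Skipping unsupported %s value '%s': %s", axis,
                   paste(v, collapse = ","), conditionMessage(e)))
      FALSE
    })
    if (!ok) next
    done <- run_experiment(m)
    if (!identical(done$status, "completed")) {
      warn(sprintf("%s = %s failed: %s", axis, paste(v, collapse = ","),
                   done$status))
      next
    }
    g <- glance(done$fit)
    rows[[length(rows) + 1L]] <- tibble(
      value = paste(v, collapse = ","),
      parameters = count_parameters(done$fit$network),
      train_accuracy = g$final_train_accuracy,
      validation_accuracy = g$best_validation_accuracy,
      best_epoch = g$best_epoch)
  }
  dplyr::bind_rows(rows)
}
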