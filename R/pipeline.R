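# End-to-end pipeline: synthesize (or read) silhouette sequences, preprocess,
# segment gait cycles, compute and fuse templates, train the classifier, and
# evaluate - writing every intermediate under one run directory with a
# manifest.

#' Pipeline configuration
#'
#' One nested list mirroring each stage's parameters, validated before any
#' work starts.  Any block can be omitted to use stage defaults.
#'
#' @param out_dir run directory to create.
#' @param synth list: `n_per_class`, `n_cycles`, `noise_rate`, `seed`.
#' @param prep list: `threshold`, `open_radius`, `close_radius`, `out_size`.
#' @param cycles list: `smooth_window`, `min_separation`, `prominence`.
#' @param fuse list: `target` (`"max"`/`"mean"`), `n_restarts`, `seed`.
#' @param model list passed to [model_config()].
#' @param train list passed to [train_config()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            synth = list(n_per_class = 10L, n_cycles = 2L,
                                         noise_rate = 0, seed = 1L),
                            prep = list(threshold = 127, open_radius = 1,
                                        close_radius = 1, out_size = 256L),
                            cycles = list(smooth_window = 3, min_separation = 5,
                                          prominence = 0.01),
                            fuse = list(target = "max", n_restarts = 5L,
                                        seed = 1L),
                            model = list(input_size = 256L, seed = 1L),
                            train = list(learning_rate = 1e-3, epochs = 15L,
                                         seed = 1L)) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  # validate every block against its stage's constructor up front
  wp <- walker_params(n_cycles = synth$n_cycles %||% 2L,
                      noise_rate = synth$noise_rate %||% 0,
                      seed = synth$seed %||% 1L)
  if ((synth$n_per_class %||% 10L) < 1L) stop("synth$n_per_class must be >= 1")
  if ((prep$threshold %||% 127) <= 0 || (prep$threshold %||% 127) >= 255) {
    stop("prep$threshold must lie in (0, 255)")
  }
  if ((cycles$smooth_window %||% 3) %% 2 == 0) stop("cycles$smooth_window must be odd")
  match.arg(fuse$target %||% "max", c("max", "mean"))
  mc <- do.call(model_config, model)
  tc <- do.call(train_config, train)
  structure(list(out_dir = out_dir, synth = synth, prep = prep,
                 cycles = cycles, fuse = fuse, model_config = mc,
                 train_config = tc, base_params = wp),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

#' Build a labeled FEI dataset from synthetic walkers, streaming
#'
#' Renders each planned walker, preprocesses it, segments gait cycles, and
#' fuses templates into FEIs one sequence at a time, so memory stays bounded
#' by a single sequence regardless of dataset size.
#'
#' @param n_per_class sequences per gait class.
#' @param base optional [walker_params()] carrying `n_cycles`/`noise_rate`.
#' @param seed dataset seed.
#' @param target,fuse_seed,n_restarts fusion options, see
#'   [optimize_fusion_weights()].
#' @param max_cycles_per_seq cap on cycles taken from one sequence (`Inf`
#'   for all).
#' @param verbose print progress.
#' @param on_sample optional callback `function(sample, seq_index, cycle_index)`
#'   invoked per FEI (e.g. to write artifacts).
#' @return List of samples `list(fei, label)` ready for [split_dataset()].
#' @export
synth_fei_dataset <- function(n_per_class, base = NULL, seed = 1L,
                              target = "max", fuse_seed = 1L, n_restarts = 5L,
                              max_cycles_per_seq = Inf, verbose = FALSE,
                              on_sample = NULL) {
  plan <- dataset_plan(n_per_class, base, seed)
  samples <- list()
  for (i in seq_along(plan)) {
    if (verbose && i %% 10L == 0L) message("  sequence ", i, "/", length(plan))
    s <- generate_walker_sequence(plan[[i]])
    pp <- prep_sequence(s)
    gcs <- find_gait_cycles(pp)
    take <- seq_len(min(length(gcs$cycles), max_cycles_per_seq))
    for (k in take) {
      r <- cycle_fei(gcs$cycles[[k]], target = target, seed = fuse_seed,
                     n_restarts = n_restarts)
      smp <- list(fei = unclass(r$fei), label = plan[[i]]$class_label,
                  weights = r$weights$weights)
      if (!is.null(on_sample)) on_sample(smp, i, k)
      samples[[length(samples) + 1L]] <- smp
    }
  }
  samples
}

#' Run the full pipeline
#'
#' Stages: synthesize labeled walker sequences, preprocess to normalized
#' binary silhouettes, detect and segment gait cycles, compute GEI/GEnI/AEI
#' per cycle, optimize fusion weights and build FEIs, split, train the
#' classifier, and evaluate - writing intermediates and a manifest under
#' `config$out_dir`.  The run directory is append-only: no stage mutates an
#' earlier stage's outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return The run directory path, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  manifest <- list(stages = list())
  stage <- function(name, code) {
    say(name)
    tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  samples <- stage("synth+prep+cycles+templates+fuse", {
    # one sequence at a time: render, write, preprocess, segment, fuse, drop
    plan <- dataset_plan(config$synth$n_per_class %||% 10L,
                         base = config$base_params,
                         seed = config$synth$seed %||% 1L)
    p <- config$prep; cyc <- config$cycles; fu <- config$fuse
    smp <- list(); wrec <- list()
    dir.create(file.path(out, "sequences"), showWarnings = FALSE)
    dir.create(file.path(out, "fei"), showWarnings = FALSE)
    for (i in seq_along(plan)) {
      s <- generate_walker_sequence(plan[[i]])
      write_walker_sequence(s, file.path(out, "sequences",
                                         sprintf("%03d_%s", i, plan[[i]]$class_label)))
      pp <- prep_sequence(s, threshold = p$threshold %||% 127,
                          open_radius = p$open_radius %||% 1,
                          close_radius = p$close_radius %||% 1,
                          out_size = p$out_size %||% 256L)
      gcs <- find_gait_cycles(pp, smooth_window = cyc$smooth_window %||% 3,
                              min_separation = cyc$min_separation %||% 5,
                              prominence = cyc$prominence %||% 0.01)
      for (k in seq_along(gcs$cycles)) {
        r <- cycle_fei(gcs$cycles[[k]], target = fu$target %||% "max",
                       n_restarts = fu$n_restarts %||% 5L,
                       seed = fu$seed %||% 1L)
        id <- sprintf("%03d_c%d_%s", i, k, plan[[i]]$class_label)
        write_energy_png(r$fei, file.path(out, "fei", paste0(id, ".png")))
        smp[[length(smp) + 1L]] <- list(fei = unclass(r$fei),
                                        label = plan[[i]]$class_label, id = id)
        wrec[[id]] <- list(weights = r$weights$weights, cost = r$weights$cost,
                           n_iter = r$weights$n_iter)
      }
    }
    jsonlite::write_json(wrec, file.path(out, "fusion_weights.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$synth <- list(status = "ok", n_sequences = length(plan))
    manifest$stages$fei <- list(status = "ok", n_samples = length(smp))
    attr(smp, "n_sequences") <- length(plan)
    smp
  })

  result <- stage("train+eval", {
    sp <- split_dataset(samples, config$train_config)
    model <- build_model(config$model_config)
    tr <- train_model(model, sp$train, config$train_config)
    utils::write.csv(tr$history, file.path(out, "training_log.csv"),
                     row.names = FALSE)
    ev <- evaluate_model(tr$model, sp$test)
    save_model(tr$model, file.path(out, "model.rds"))
    jsonlite::write_json(
      list(accuracy = ev$metrics$accuracy,
           macro_precision = ev$metrics$macro_precision,
           macro_sensitivity = ev$metrics$macro_sensitivity,
           macro_specificity = ev$metrics$macro_specificity,
           macro_f1 = ev$metrics$macro_f1,
           per_class = ev$metrics$per_class,
           confusion = unclass(ev$confusion)),
      file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$train <- list(status = "ok",
                                   n_train = length(sp$train),
                                   n_test = length(sp$test),
                                   test_accuracy = ev$metrics$accuracy)
    ev
  })

  manifest$n_sequences <- attr(samples, "n_sequences")
  manifest$n_fei <- length(samples)
  manifest$test_accuracy <- result$metrics$accuracy
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say(sprintf("done: %d sequences, %d FEIs, test accuracy %.2f%%",
              attr(samples, "n_sequences"), length(samples),
              result$metrics$accuracy))
  invisible(out)
}
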