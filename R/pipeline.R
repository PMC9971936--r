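#' Assemble a full run configuration
#'
#' Nested configuration for end-to-end runs, with every stage's constants
#' surfaced as named keys (delay `tau = 1`, image side 299, target rate
#' 300 Hz, 10 s segments, learning rate 0.001, batch 64, `k = 5` folds,
#' `alpha = 0.05`). Each stochastic stage derives its seed from the master
#' `seed`.
#'
#' @param path optional YAML file whose keys override the defaults.
#' @param ... named overrides (`synth`, `prep`, `rp`, `model`, `selection`,
#'   `n_per_class`, `leads`, `run_id`, `output_dir`, `seed`), applied after
#'   the file.
#' @return a list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  base <- list(
    run_id = "run1",
    output_dir = "rpafnet_runs",
    seed = 1L,
    n_per_class = 60L,
    leads = c("II", "V1"),
    synth = list(),
    prep = list(target_fs = 300, segment_len = 10),
    rp = list(size = 64L),
    model = list(profile = "desk"),
    selection = list(k_folds = 5L, alpha = 0.05)
  )
  if (!is.null(path)) {
    base <- utils::modifyList(base, yaml::read_yaml(path))
  }
  overrides <- list(...)
  if (length(overrides)) base <- utils::modifyList(base, overrides)
  structure(base, class = "run_config")
}

resolve_run <- function(cfg) {
  seed <- as.integer(cfg$seed)
  synth <- do.call(synth_config, utils::modifyList(list(seed = seed),
                                                   cfg$synth))
  prep <- do.call(prep_config,
                  utils::modifyList(list(seed = derive_seed(seed, 2L)),
                                    cfg$prep))
  rp <- do.call(rp_config, cfg$rp)
  margs <- cfg$model
  profile <- if (is.null(margs$profile)) "desk" else margs$profile
  margs$profile <- NULL
  margs$seed <- derive_seed(seed, 3L)
  model <- do.call(parnet_profile, c(list(profile = profile), margs))
  sel <- do.call(selection_config,
                 utils::modifyList(list(seed = derive_seed(seed, 4L)),
                                   cfg$selection))
  list(synth = synth, prep = prep, rp = rp, model = model, selection = sel,
       seed = seed)
}

manifest_add <- function(manifest, path) {
  rbind(manifest, data.frame(file = path,
                             md5 = unname(tools::md5sum(path)),
                             row.names = NULL))
}

#' Run the full pipeline end to end
#'
#' simulate -> prepare -> recurrence-plot conversion -> train -> evaluate,
#' writing every stage artifact (dataset summary, cached images, model
#' checkpoint, metrics report and a content-hash manifest) under
#' `output_dir/run_id`. The cached image stage is resumable: if the image
#' cache for this run already exists it is reused instead of recomputed.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return list with `metrics` (held-out `metrics_report`), `model`,
#'   `manifest`, `dir`.
#' @export
run_end_to_end <- function(cfg = run_config(), verbose = FALSE) {
  parts <- resolve_run(cfg)
  dir <- file.path(cfg$output_dir, cfg$run_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- data.frame(file = character(0), md5 = character(0))

  say("[simulate] %d records per class", cfg$n_per_class)
  records <- generate_dataset(parts$synth, cfg$n_per_class, parts$seed)
  split <- balance_and_split(records, parts$prep)

  rp_cache <- file.path(dir, "rp_images.rds")
  if (file.exists(rp_cache)) {
    say("[rp-convert] reusing cached images")
    cache <- readRDS(rp_cache)
    rp_train <- cache$train
    rp_test <- cache$test
  } else {
    say("[prep+rp-convert] leads %s", paste(cfg$leads, collapse = "+"))
    rp_train <- prepare_rp_dataset(split$train_val, parts$rp, parts$prep,
                                   cfg$leads)
    rp_test <- prepare_rp_dataset(split$test, parts$rp, parts$prep,
                                  cfg$leads)
    saveRDS(list(train = rp_train, test = rp_test), rp_cache)
  }
  manifest <- manifest_add(manifest, rp_cache)

  say("[train] profile input %dx%d", parts$model$input_size,
      parts$model$input_size)
  mcfg <- parts$model
  mcfg$in_channels <- 3L * length(cfg$leads)
  model <- train_model(build_model(mcfg),
                       stack_subset(rp_train, cfg$leads),
                       rp_train$labels)
  ckpt <- file.path(dir, "model.rds")
  save_model(model, ckpt)
  manifest <- manifest_add(manifest, ckpt)
  manifest <- manifest_add(manifest, file.path(dir, "model.json"))
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  manifest <- manifest_add(manifest, file.path(dir, "history.csv"))

  say("[evaluate] %d held-out records", length(rp_test$labels))
  pred <- predict_labels(model, stack_subset(rp_test, cfg$leads))
  rep <- metrics(confusion(rp_test$labels, pred))
  mpath <- file.path(dir, "metrics.json")
  jsonlite::write_json(
    list(f1 = rep$f1, precision = rep$precision, recall = rep$recall,
         specificity = rep$specificity, accuracy = rep$accuracy,
         counts = unclass(rep$counts)),
    mpath, auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- manifest_add(manifest, mpath)

  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  list(metrics = rep, model = model, manifest = manifest, dir = dir)
}

#' Sampling-frequency / segment-length grid experiment
#'
#' Trains and evaluates one classifier per (sampling rate, segment length)
#' cell on the same synthetic record set: records are generated once at
#' the native rate, then each cell resamples to its target rate, takes its
#' leading segment, converts to recurrence images and fits the model. One
#' metrics row per cell.
#'
#' @param cfg a [run_config()]; `cfg$synth` should generate records at
#'   least as long as the longest segment and at the highest rate.
#' @param freqs sampling rates in Hz (default 200, 300, 500).
#' @param lengths segment lengths in seconds (default 5, 10).
#' @param verbose print cell progress.
#' @return data frame with columns `freq_hz`, `length_s`, `f1`,
#'   `precision`, `recall`, `specificity`, `accuracy`.
#' @export
run_grid <- function(cfg = run_config(), freqs = c(200, 300, 500),
                     lengths = c(5, 10), verbose = FALSE) {
  parts <- resolve_run(cfg)
  records <- generate_dataset(parts$synth, cfg$n_per_class, parts$seed)
  split <- balance_and_split(records, parts$prep)
  rows <- list()
  for (fq in freqs) {
    for (ln in lengths) {
      if (verbose) message(sprintf("[grid] %g Hz x %g s", fq, ln))
      prep <- parts$prep
      prep$target_fs <- fq
      prep$segment_len <- ln
      rp_train <- prepare_rp_dataset(split$train_val, parts$rp, prep,
                                     cfg$leads)
      rp_test <- prepare_rp_dataset(split$test, parts$rp, prep, cfg$leads)
      mcfg <- parts$model
      mcfg$in_channels <- 3L * length(cfg$leads)
      model <- train_model(build_model(mcfg),
                           stack_subset(rp_train, cfg$leads),
                           rp_train$labels)
      pred <- predict_labels(model, stack_subset(rp_test, cfg$leads))
      m <- metrics(confusion(rp_test$labels, pred))
      rows[[length(rows) + 1]] <-
        data.frame(freq_hz = fq, length_s = ln, f1 = m$f1,
                   precision = m$precision, recall = m$recall,
                   specificity = m$specificity, accuracy = m$accuracy)
    }
  }
  do.call(rbind, rows)
}
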