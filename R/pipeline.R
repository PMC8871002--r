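# End-to-end pipeline: phantom -> (convert) -> weights -> train ->
# evaluate/predict, with a self-contained config and per-stage manifest.

#' Default pipeline configuration
#'
#' A self-contained description of a run: output directory, phantom
#' parameters, dataset size and split, network spec arguments, training
#' options and metric options.  A single global `seed` fans out to the
#' stages by fixed offsets (phantom: `seed`; network init: `seed + 1000`;
#' shuffling: `seed + 2000`), recorded in the manifest.
#'
#' @param out_dir run directory (artifacts are written beneath it).
#' @param seed global seed.
#' @param n_slices phantom dataset size.
#' @param height,width slice size (must be even).
#' @param num_classes classes for the network and metrics.
#' @param ... overrides for `phantom`, `train`, or `split` sub-lists.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("saxfcn_run_"), seed = 1L,
                           n_slices = 100L, height = 256L, width = 192L,
                           num_classes = 3L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), n_slices = as.integer(n_slices),
    num_classes = as.integer(num_classes),
    phantom = list(height = as.integer(height), width = as.integer(width)),
    split = c(train = 0.8, val = 0.1, test = 0.1),
    train = list(solver = "adam", learning_rate = 0.001, epochs = 150L,
                 mini_batch = 4L),
    metrics = list(bf_tolerance = NULL),
    image_format = "auto")
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as JSON (canonical) or YAML (read when the
#' \pkg{yaml} package is installed).
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @param config a `run_config` (for writing).
#' @return `read_config` returns a `run_config`; `write_config` the path.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the `yaml` package; use JSON", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  if (!is.null(names(base$split))) base$split <- unlist(base$split)
  class(base) <- "run_config"
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

manifest_append <- function(out_dir, stage, seed, outputs) {
  mf <- file.path(out_dir, "run_manifest.csv")
  existing <- vapply(outputs, function(f) file.exists(f), TRUE)
  hashes <- rep(NA_character_, length(outputs))
  hashes[existing] <- unname(tools::md5sum(outputs[existing]))
  row <- data.frame(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    seed = seed, output = outputs, md5 = hashes)
  write.table(row, mf, sep = ",", row.names = FALSE, col.names = !file.exists(mf),
              append = file.exists(mf))
  invisible(mf)
}

#' Run pipeline stages
#'
#' Executes the requested stages in order, each writing its artifacts under
#' `config$out_dir` and appending a line to `run_manifest.csv`:
#' \describe{
#'   \item{phantom}{generate the synthetic dataset; writes `data/images`,
#'     `data/masks`, `data/manifest.csv`.}
#'   \item{weights}{inverse-frequency class weights from the training split;
#'     writes `weights.json`.}
#'   \item{train}{train the FCN on the training split; writes
#'     `checkpoint.rds` plus a `checkpoint.json` sidecar (spec, seed, final
#'     loss/accuracy) and `history.csv`.}
#'   \item{evaluate}{metric report of the trained network on the test
#'     split; writes `metrics.json` and `confusion.csv`.}
#'   \item{predict}{predicted masks for the test split under `predictions/`.}
#' }
#' Stages consume the artifacts of earlier stages; a missing prerequisite
#' raises an error naming the stage that produces it.
#'
#' @param config a [default_config()] object (or path read via
#'   [read_config()]).
#' @param stages subset of `c("phantom", "weights", "train", "evaluate",
#'   "predict")`.
#' @return (invisibly) a list with the stage products created in this call.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("phantom", "weights", "train", "evaluate")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, c("phantom", "weights", "train", "evaluate",
                                "predict"), several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out, "config.json"))
  products <- list()
  C <- config$num_classes

  load_dataset <- function() {
    f <- file.path(out, "dataset.rds")
    if (!file.exists(f))
      stop("dataset not found; run the `phantom` stage first", call. = FALSE)
    readRDS(f)
  }

  if ("phantom" %in% stages) {
    params <- do.call(phantom_params, config$phantom)
    ds <- generate_dataset(config$n_slices, params, seed = config$seed,
                           split = config$split)
    write_dataset(ds, file.path(out, "data"), format = config$image_format)
    saveRDS(ds, file.path(out, "dataset.rds"))
    manifest_append(out, "phantom", config$seed,
                    c(file.path(out, "data", "manifest.csv"),
                      file.path(out, "dataset.rds")))
    products$dataset <- ds
  }

  if ("weights" %in% stages) {
    ds <- products$dataset %||% load_dataset()
    cw <- training_class_weights(ds, C)
    jsonlite::write_json(list(weights = cw$weights, frequencies = cw$frequencies,
                              total_pixels = cw$total_pixels),
                         file.path(out, "weights.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest_append(out, "weights", config$seed, file.path(out, "weights.json"))
    products$weights <- cw
  }

  if ("train" %in% stages) {
    ds <- products$dataset %||% load_dataset()
    wf <- file.path(out, "weights.json")
    if (is.null(products$weights) && !file.exists(wf))
      stop("class weights not found; run the `weights` stage first",
           call. = FALSE)
    cw <- products$weights %||% {
      j <- jsonlite::read_json(wf, simplifyVector = TRUE)
      j$weights
    }
    spec <- fcn_spec(input_shape = c(config$phantom$height,
                                     config$phantom$width, 1L),
                     num_classes = C)
    net <- build_network(spec, seed = config$seed + 1000L)
    cfg <- train_config(solver = config$train$solver,
                        learning_rate = config$train$learning_rate,
                        epochs = config$train$epochs,
                        mini_batch = config$train$mini_batch,
                        seed = config$seed + 2000L)
    fit <- train(net, ds$slices[ds$split$train], cfg, weights = cw)
    saveRDS(fit$network, file.path(out, "checkpoint.rds"))
    last <- fit$history[nrow(fit$history), ]
    jsonlite::write_json(list(spec = list(input_shape = spec$input_shape,
                                          num_classes = spec$num_classes,
                                          filters = spec$filters),
                              seed = net$seed, solver = cfg$solver,
                              learning_rate = cfg$learning_rate,
                              epochs = cfg$epochs, mini_batch = cfg$mini_batch,
                              final_loss = last$loss,
                              final_accuracy = last$accuracy),
                         file.path(out, "checkpoint.json"), auto_unbox = TRUE,
                         digits = NA)
    write.csv(fit$history, file.path(out, "history.csv"), row.names = FALSE)
    manifest_append(out, "train", cfg$seed,
                    c(file.path(out, "checkpoint.rds"),
                      file.path(out, "checkpoint.json"),
                      file.path(out, "history.csv")))
    products$fit <- fit
  }

  needs_net <- function() {
    f <- file.path(out, "checkpoint.rds")
    if (!is.null(products$fit)) return(products$fit$network)
    if (!file.exists(f))
      stop("checkpoint not found; run the `train` stage first", call. = FALSE)
    readRDS(f)
  }

  if ("evaluate" %in% stages) {
    ds <- products$dataset %||% load_dataset()
    net <- needs_net()
    test <- ds$slices[ds$split$test]
    rep <- metric_report(predict_masks(net, test),
                         lapply(test, `[[`, "mask"), C = C,
                         tolerance = config$metrics$bf_tolerance)
    jsonlite::write_json(list(per_class = rep$per_class,
                              aggregate = as.list(rep$aggregate),
                              dataset = as.list(rep$dataset),
                              mean_bf_score = rep$mean_bf_score),
                         file.path(out, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    write.csv(as.data.frame(unclass(rep$confusion)),
              file.path(out, "confusion.csv"))
    manifest_append(out, "evaluate", config$seed,
                    c(file.path(out, "metrics.json"),
                      file.path(out, "confusion.csv")))
    products$report <- rep
  }

  if ("predict" %in% stages) {
    ds <- products$dataset %||% load_dataset()
    net <- needs_net()
    test <- ds$slices[ds$split$test]
    pdir <- file.path(out, "predictions")
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    ext <- gray_ext(config$image_format)
    paths <- character(length(test))
    for (i in seq_along(test)) {
      stem <- sprintf("%s_s%02d", test[[i]]$patient_id, test[[i]]$slice_index)
      paths[i] <- file.path(pdir, paste0(stem, ext))
      write_gray(predict_mask(net, test[[i]]$image), paths[i])
    }
    manifest_append(out, "predict", config$seed, paths)
    products$predictions <- paths
  }

  invisible(products)
}
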