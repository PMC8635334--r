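# Dataset bundle I/O and the end-to-end pipeline runner.

#' Dataset bundle
#'
#' Container tying a window matrix to labels, record ids and provenance
#' (how the windows were produced: generator spec or source files, seeds,
#' preprocessing configuration).
#'
#' @param windows n x window_len numeric matrix.
#' @param labels optional length-n label vector.
#' @param record_ids optional length-n record id vector.
#' @param provenance named list describing the origin of the data.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(windows, labels = NULL, record_ids = NULL,
                           provenance = list()) {
  windows <- as.matrix(windows)
  if (!is.null(labels))
    ecg_check(length(labels) == nrow(windows),
              "labels length must match the number of windows")
  if (is.null(record_ids))
    record_ids <- sprintf("w%05d", seq_len(nrow(windows)))
  ecg_check(length(record_ids) == nrow(windows),
            "record_ids length must match the number of windows")
  structure(list(windows = unname(windows), labels = labels,
                 record_ids = record_ids, provenance = provenance),
            class = "dataset_bundle")
}

#' Write / read a dataset bundle
#'
#' `"csv"` writes `windows.csv` (one row per window, full precision) plus
#' a `meta.json` sidecar (labels, ids, provenance); `"rds"` writes a
#' single RDS file with the same sidecar. Reading validates the schema
#' and round-trips arrays, labels and ids.
#'
#' @param bundle a [dataset_bundle()].
#' @param path output directory (`csv`) or file (`rds`).
#' @param format `"csv"` or `"rds"`.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns the bundle.
#' @export
write_dataset <- function(bundle, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  ecg_check(inherits(bundle, "dataset_bundle"), "not a dataset_bundle")
  meta <- list(n = nrow(bundle$windows), window_len = ncol(bundle$windows),
               record_ids = bundle$record_ids,
               provenance = bundle$provenance)
  if (!is.null(bundle$labels)) meta$labels <- as.character(bundle$labels)
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format(bundle$windows, digits = 17, trim = TRUE),
                       file.path(path, "windows.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    saveRDS(bundle, path)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    b <- readRDS(path)
    ecg_check(inherits(b, "dataset_bundle"), "not a dataset_bundle file",
              class = "ecgvae_parse_error")
    return(b)
  }
  meta_path <- file.path(path, "meta.json")
  ecg_check(file.exists(meta_path), "meta.json missing from dataset dir",
            class = "ecgvae_parse_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (k in c("n", "window_len", "record_ids"))
    if (is.null(meta[[k]]))
      ecg_abort(sprintf("meta.json lacks required field '%s'", k),
                "ecgvae_parse_error")
  w <- as.matrix(utils::read.table(file.path(path, "windows.csv"),
                                   sep = ",", colClasses = "numeric"))
  if (nrow(w) != meta$n || ncol(w) != meta$window_len)
    ecg_abort(sprintf("windows.csv is %d x %d but meta.json says %d x %d",
                      nrow(w), ncol(w), meta$n, meta$window_len),
              "ecgvae_parse_error")
  dataset_bundle(w, labels = meta$labels, record_ids = meta$record_ids,
                 provenance = as.list(meta$provenance))
}

#' Run the full pipeline from a declarative configuration
#'
#' Executes, in order: synthetic data generation, preprocessing, CVAE
#' training, anomality scoring, threshold selection, feature extraction
#' and feature-reuse classification, writing every artifact (checkpoint,
#' scores.csv, threshold.json, features.csv, transfer.json, run log) into
#' `out_dir`. Every artifact records the seeds used.
#'
#' @param config nested list (e.g. parsed from YAML): sections `simulate`
#'   (`normal_counts`, `test_counts`, `duration`, `rate`), `cvae`
#'   (passed to [cvae_config()]), `train` (`max_epochs`, `patience`,
#'   `lr`, `batch_size`), `threshold` (`step`), `transfer`
#'   (`n_repeats`), `seed`. Unknown section names are rejected.
#' @param out_dir output directory.
#' @return Invisibly, a list with the run artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  known <- c("simulate", "cvae", "train", "threshold", "transfer", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    ecg_abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
              "ecgvae_config_error")
  seed <- config$seed %||% 1
  sim <- config$simulate %||% list()
  normal_counts <- unlist(sim$normal_counts %||%
                            list(SR = 120, SB = 40, ST_TACHY = 40))
  test_counts <- unlist(sim$test_counts %||%
                          list(SR = 40, AFIB_LIKE = 40))
  duration <- sim$duration %||% 10
  rate <- sim$rate %||% 250
  cvae_args <- config$cvae %||% list()
  cvae_args$seed <- cvae_args$seed %||% derive_seed(seed, 2)
  cfg <- do.call(cvae_config, cvae_args)  # fail fast on bad architecture
  tr_cfg <- config$train %||% list()

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  log_line <- function(stage, ...) {
    entry <- list(stage = stage, time = format(Sys.time()), ...)
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
    message(sprintf("[%s] %s", entry$time, stage))
  }

  log_line("simulate", seed = seed)
  train_recs <- generate_dataset(normal_counts, duration, rate,
                                 seed = derive_seed(seed, 10))
  test_recs <- generate_dataset(test_counts, duration, rate,
                                seed = derive_seed(seed, 11))
  log_line("preprocess")
  pp <- preprocess_records(train_recs)
  ppt <- preprocess_records(test_recs)
  n <- nrow(pp$windows)
  va_idx <- seq(5, n, by = 5)
  tr_idx <- setdiff(seq_len(n), va_idx)

  log_line("train", n_train = length(tr_idx), n_valid = length(va_idx))
  fit <- train_cvae(pp$windows[tr_idx, , drop = FALSE],
                    pp$windows[va_idx, , drop = FALSE], cfg,
                    max_epochs = tr_cfg$max_epochs %||% 30,
                    patience = tr_cfg$patience %||% 5,
                    lr = tr_cfg$lr %||% 1e-3,
                    batch_size = tr_cfg$batch_size %||% 8,
                    seed = derive_seed(seed, 3))
  save_cvae(fit$model, file.path(out_dir, "cvae.rds"), fit$history)

  log_line("score", n_test = nrow(ppt$windows))
  scores <- anomality_scores(ppt$windows, fit$model)
  write.csv(data.frame(record_id = ppt$record_ids, label = ppt$labels,
                       score = scores),
            file.path(out_dir, "scores.csv"), row.names = FALSE)

  log_line("threshold")
  abnormal <- as.integer(!ppt$labels %in% c("SR", "SB", "ST_TACHY"))
  thr <- NULL
  if (length(unique(abnormal)) == 2) {
    thr <- select_threshold(scores, abnormal,
                            step = config$threshold$step %||% 0.05)
    jsonlite::write_json(
      list(selected_threshold = thr$selected_threshold, grid = thr$grid,
           seed = seed),
      file.path(out_dir, "threshold.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
  }

  log_line("features")
  feats <- extract_features(ppt$windows, fit$model)
  fdf <- as.data.frame(feats)
  names(fdf) <- paste0("mu", seq_len(ncol(feats)))
  write.csv(cbind(record_id = ppt$record_ids, fdf),
            file.path(out_dir, "features.csv"), row.names = FALSE)

  transfer <- NULL
  if (length(unique(ppt$labels)) >= 2) {
    log_line("transfer")
    transfer <- feature_classify(
      feats, ppt$labels, anomality = scores,
      config = bootstrap_config(
        n_repeats = config$transfer$n_repeats %||% 5,
        seed = derive_seed(seed, 4)))
    jsonlite::write_json(
      list(mean = as.list(transfer$mean), sd = as.list(transfer$sd),
           per_class = transfer$per_class, params = transfer$params),
      file.path(out_dir, "transfer.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
  }
  log_line("done")
  invisible(list(model = fit$model, history = fit$history,
                 scores = scores, threshold = thr, features = feats,
                 transfer = transfer, out_dir = out_dir))
}
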