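# Two transfer-learning protocols: (a) feature reuse - gradient-boosted
# classification of rhythm labels from CVAE features; (b) weight reuse -
# a supervised classifier (CVAE encoder + dense head) initialized from
# pretrained encoder weights vs. random, with convergence comparison.

#' Repeated-split validation configuration
#'
#' @param n_repeats number of validation repeats (default 5).
#' @param train_fraction training share of each split (default 0.8).
#' @param seed master seed; repeat r uses a seed derived from `(seed, r)`.
#' @param bootstrap if `TRUE`, draw the training set with replacement
#'   (out-of-bag rows form the validation set) instead of an 80/20
#'   re-split.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_repeats = 5, train_fraction = 0.8, seed = 1,
                             bootstrap = FALSE) {
  ecg_check(n_repeats >= 1, "n_repeats must be >= 1")
  ecg_check(train_fraction > 0 && train_fraction < 1,
            "train_fraction must lie in (0, 1)")
  structure(list(n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction, seed = seed,
                 bootstrap = bootstrap),
            class = "bootstrap_config")
}

# Seeded train/validation index pair for repeat r; disjoint and exhaustive
# in re-split mode.
split_indices <- function(n, config, repeat_idx) {
  s <- derive_seed(config$seed, repeat_idx)
  if (config$bootstrap) {
    tr <- with_seed(s, sample.int(n, n, replace = TRUE))
    va <- setdiff(seq_len(n), unique(tr))
  } else {
    n_tr <- max(1L, floor(config$train_fraction * n))
    tr <- with_seed(s, sample.int(n, n_tr))
    va <- setdiff(seq_len(n), tr)
  }
  list(train = tr, valid = va)
}

#' Multi-class classification metrics
#'
#' One-vs-rest confusion per class: precision, recall and F1, plus overall
#' accuracy and the class-proportion-weighted F1. Classes absent from the
#' predictions get precision 0 by convention; weights are the class
#' proportions among the true labels.
#'
#' @param true,pred vectors of equal length (coerced to character).
#' @return List of class `classification_report` with `per_class`
#'   (data frame), `accuracy`, `weighted_f1`.
#' @export
classification_metrics <- function(true, pred) {
  ecg_check(length(true) == length(pred),
            "true and pred lengths differ")
  ecg_check(length(true) > 0, "empty label vectors")
  true <- as.character(true); pred <- as.character(pred)
  classes <- sort(unique(true))
  n <- length(true)
  rows <- lapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    m <- prf(tp, fp, fn)
    data.frame(class = cl, n = sum(true == cl),
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]])
  })
  per_class <- do.call(rbind, rows)
  w <- per_class$n / n
  structure(list(per_class = per_class,
                 accuracy = mean(true == pred),
                 weighted_f1 = sum(w * per_class$f1),
                 weighted_precision = sum(w * per_class$precision),
                 weighted_recall = sum(w * per_class$recall)),
            class = "classification_report")
}

#' Rhythm classification from CVAE features (feature reuse)
#'
#' Fits a gradient-boosted tree classifier (xgboost) on the latent feature
#' matrix over `n_repeats` seeded splits and reports each metric as mean
#' and SD across repeats. The anomality score can be appended as one extra
#' feature column.
#'
#' @param features n x d feature matrix.
#' @param labels length-n class labels (>= 2 classes).
#' @param anomality optional length-n anomality score column appended as
#'   feature d+1.
#' @param config a [bootstrap_config()].
#' @param nrounds boosting rounds (default 60); other xgboost parameters
#'   are library defaults, recorded in the report.
#' @return List of class `feature_classification_report`: per-repeat
#'   reports, `mean`/`sd` summaries (accuracy, weighted f1/precision/
#'   recall), per-class mean/sd data frame, and mean feature importances.
#' @export
feature_classify <- function(features, labels, anomality = NULL,
                             config = bootstrap_config(), nrounds = 60) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  ecg_check(length(classes) >= 2, "need at least 2 classes")
  ecg_check(nrow(features) == length(labels),
            "features and labels lengths differ")
  if (!is.null(anomality)) {
    ecg_check(length(anomality) == nrow(features),
              "anomality column length mismatch")
    features <- cbind(features, anomality = anomality)
  }
  cn <- colnames(features) %||% rep("", ncol(features))
  cn[!nzchar(cn)] <- paste0("f", which(!nzchar(cn)))
  colnames(features) <- cn
  y <- match(labels, classes) - 1L
  repeats <- vector("list", config$n_repeats)
  importances <- numeric(ncol(features))
  names(importances) <- colnames(features)
  for (r in seq_len(config$n_repeats)) {
    sp <- split_indices(nrow(features), config, r)
    dtrain <- xgboost::xgb.DMatrix(features[sp$train, , drop = FALSE],
                                   label = y[sp$train])
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes), nthread = 1),
      dtrain, nrounds = nrounds, verbose = 0)
    prob <- predict(fit,
                    xgboost::xgb.DMatrix(features[sp$valid, , drop = FALSE]))
    if (is.null(dim(prob)))
      prob <- matrix(prob, ncol = length(classes), byrow = TRUE)
    pred <- classes[max.col(prob)]
    repeats[[r]] <- classification_metrics(labels[sp$valid], pred)
    imp <- xgboost::xgb.importance(model = fit)
    importances[imp$Feature] <- importances[imp$Feature] +
      imp$Gain / config$n_repeats
  }
  overall <- sapply(c("accuracy", "weighted_f1", "weighted_precision",
                      "weighted_recall"),
                    function(m) sapply(repeats, `[[`, m))
  if (is.null(dim(overall))) overall <- matrix(overall, nrow = 1,
    dimnames = list(NULL, c("accuracy", "weighted_f1",
                            "weighted_precision", "weighted_recall")))
  pc <- lapply(repeats, `[[`, "per_class")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    f1s <- sapply(pc, function(d) {
      i <- match(cl, d$class); if (is.na(i)) NA else d$f1[i] })
    prs <- sapply(pc, function(d) {
      i <- match(cl, d$class); if (is.na(i)) NA else d$precision[i] })
    rcs <- sapply(pc, function(d) {
      i <- match(cl, d$class); if (is.na(i)) NA else d$recall[i] })
    data.frame(class = cl,
               f1_mean = mean(f1s, na.rm = TRUE),
               f1_sd = stats::sd(f1s, na.rm = TRUE),
               precision_mean = mean(prs, na.rm = TRUE),
               precision_sd = stats::sd(prs, na.rm = TRUE),
               recall_mean = mean(rcs, na.rm = TRUE),
               recall_sd = stats::sd(rcs, na.rm = TRUE))
  }))
  structure(list(repeats = repeats,
                 mean = colMeans(overall),
                 sd = apply(overall, 2, stats::sd),
                 per_class = per_class,
                 importances = sort(importances, decreasing = TRUE),
                 params = list(nrounds = nrounds,
                               n_repeats = config$n_repeats,
                               train_fraction = config$train_fraction,
                               bootstrap = config$bootstrap,
                               seed = config$seed)),
            class = "feature_classification_report")
}

# ---- weight-reuse classifier ---------------------------------------------

#' Build a supervised rhythm classifier from the CVAE encoder topology
#'
#' The classifier is the CVAE encoder followed by a dense head mapping the
#' latent mean branch to `n_classes` logits. With `init = "pretrained"`
#' the encoder (and mean-head) parameters are copied from a trained CVAE;
#' the classification head is always freshly initialized.
#'
#' @param config a [cvae_config()] (must match the checkpoint architecture
#'   when pretrained).
#' @param n_classes number of output classes.
#' @param init `"pretrained"` or `"random"`.
#' @param pretrained a trained `cvae_model` (required when pretrained).
#' @param seed seed for the head (and, when random, encoder) parameters.
#' @return An object of class `ecg_classifier`.
#' @export
build_classifier <- function(config, n_classes,
                             init = c("pretrained", "random"),
                             pretrained = NULL, seed = 1) {
  init <- match.arg(init)
  ecg_check(n_classes >= 2, "need at least 2 classes")
  base <- with_seed(seed, cvae_init_params(config))
  # lv_* is carried along unused so the shared encoder forward stays intact
  enc_names <- grep("^(enc|encp|mu_|lv_)", names(base), value = TRUE)
  params <- base[enc_names]
  if (init == "pretrained") {
    ecg_check(inherits(pretrained, "cvae_model"),
              "pretrained model required", class = "ecgvae_config_error")
    pc <- pretrained$config
    same <- pc$n_blocks == config$n_blocks &&
      pc$latent_dim == config$latent_dim &&
      pc$input_len == config$input_len &&
      all(pc$channel_schedule == config$channel_schedule) &&
      all(pc$stride_schedule == config$stride_schedule) &&
      all(pc$kernels == config$kernels)
    if (!same)
      ecg_abort("checkpoint architecture does not match config",
                "ecgvae_config_error")
    params <- pretrained$params[enc_names]
  }
  params$head_W <- with_seed(derive_seed(seed, 17),
    matrix(rnorm(config$latent_dim * n_classes,
                 sd = sqrt(1 / config$latent_dim)),
           config$latent_dim, n_classes))
  params$head_b <- numeric(n_classes)
  structure(list(config = config, params = params,
                 n_classes = as.integer(n_classes), init = init),
            class = "ecg_classifier")
}

# Forward pass to logits; optionally keeps caches for backprop.
classifier_fwd <- function(clf, xarr, keep_cache = FALSE) {
  shim <- list(config = clf$config, params = clf$params)
  enc <- cvae_encode_fwd(shim, xarr, keep_cache = keep_cache)
  logits <- nn_dense_fwd(enc$mu, clf$params$head_W, clf$params$head_b)
  list(logits = logits, enc = enc)
}

#' Predict class labels with a classifier
#'
#' @param object an `ecg_classifier`.
#' @param windows n x `input_len` matrix.
#' @param classes optional class name vector (else integer indices).
#' @param ... unused.
#' @return Predicted labels.
#' @export
predict.ecg_classifier <- function(object, windows, classes = NULL, ...) {
  xarr <- as_input_array(windows, object$config$input_len)
  fw <- classifier_fwd(object, xarr)
  idx <- max.col(fw$logits)
  if (is.null(classes)) idx else classes[idx]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# One cross-entropy training step over a batch; mirrors cvae_train_step's
# encoder backward with the logvar branch unused.
classifier_train_step <- function(clf, batch, y_idx, opt, lr) {
  cfg <- clf$config; p <- clf$params
  n <- nrow(batch)
  xarr <- as_input_array(batch, cfg$input_len)
  fw <- classifier_fwd(clf, xarr, keep_cache = TRUE)
  prob <- softmax_rows(fw$logits)
  eps <- 1e-12
  loss <- -mean(log(prob[cbind(seq_len(n), y_idx)] + eps))
  dlogits <- prob
  dlogits[cbind(seq_len(n), y_idx)] <-
    dlogits[cbind(seq_len(n), y_idx)] - 1
  dlogits <- dlogits / n
  g <- list()
  dh <- nn_dense_bwd(dlogits, fw$enc$mu, p$head_W)
  g$head_W <- dh$dW; g$head_b <- dh$db
  dmu <- dh$dx
  dmu_d <- nn_dense_bwd(dmu, fw$enc$flat, p$mu_W)
  g$mu_W <- dmu_d$dW; g$mu_b <- dmu_d$db
  dflat <- dmu_d$dx
  Cf <- cfg$channel_schedule[cfg$n_blocks]
  dhid <- t(dflat)
  dim(dhid) <- c(cfg$flat_len, Cf, n)
  for (b in rev(seq_len(cfg$n_blocks))) {
    cb <- fw$enc$caches[[b]]
    dhid <- nn_relu_bwd(dhid, cb$act)
    bw <- nn_conv_bwd(dhid, p[[sprintf("enc%d_W", b)]], cb$conv)
    g[[sprintf("enc%d_W", b)]] <- bw$dW
    g[[sprintf("enc%d_b", b)]] <- bw$db
    if (cb$has_proj) {
      pw <- nn_proj_bwd(dhid, p[[sprintf("encp%d_W", b)]], cb$proj)
      g[[sprintf("encp%d_W", b)]] <- pw$dW
      g[[sprintf("encp%d_b", b)]] <- pw$db
      dhid <- bw$dx + pw$dx
    } else {
      dhid <- bw$dx + dhid
    }
  }
  upd <- nn_adam_step(p, g, opt, lr = lr)
  clf$params <- upd$params
  list(clf = clf, opt = upd$state, loss = loss)
}

#' Train the weight-reuse classifier for a fixed epoch budget
#'
#' Cross-entropy minibatch training at a fixed learning rate for exactly
#' `epochs` epochs (defaults 1e-4 and 150, the reference protocol), with
#' per-epoch validation metrics recorded.
#'
#' @param windows n x `input_len` matrix.
#' @param labels length-n class labels.
#' @param init `"pretrained"` or `"random"`.
#' @param config a [cvae_config()].
#' @param pretrained trained `cvae_model` (when `init = "pretrained"`).
#' @param lr learning rate (default 1e-4).
#' @param epochs epoch budget (default 150).
#' @param batch_size minibatch size (default 32).
#' @param train_fraction training share of the split (default 0.8).
#' @param seed integer seed (split, initialization, shuffling).
#' @return List with `classifier`, `curve` (class `epoch_curve`: per-epoch
#'   validation accuracy/precision/recall/weighted f1, `init_mode`
#'   attribute), `best_epoch` (highest validation weighted F1) and
#'   `classes`.
#' @export
weight_transfer_train <- function(windows, labels, init, config,
                                  pretrained = NULL, lr = 1e-4,
                                  epochs = 150, batch_size = 32,
                                  train_fraction = 0.8, seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  ecg_check(length(classes) >= 2, "need at least 2 classes")
  y <- match(labels, classes)
  sp <- split_indices(nrow(windows),
                      bootstrap_config(1, train_fraction, seed), 1)
  clf <- build_classifier(config, length(classes), init,
                          pretrained = pretrained, seed = seed)
  opt <- nn_adam_init(clf$params)
  n_tr <- length(sp$train)
  curve <- data.frame(epoch = integer(), accuracy = numeric(),
                      precision = numeric(), recall = numeric(),
                      weighted_f1 = numeric())
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 3e6 + epoch),
                     sp$train[sample.int(n_tr)])
    for (start in seq(1L, n_tr, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_tr)]
      res <- classifier_train_step(clf, windows[idx, , drop = FALSE],
                                   y[idx], opt, lr)
      if (!is.finite(res$loss))
        ecg_abort(sprintf("non-finite classifier loss at epoch %d", epoch),
                  "ecgvae_training_error", epoch = epoch)
      clf <- res$clf; opt <- res$opt
    }
    pred <- predict(clf, windows[sp$valid, , drop = FALSE], classes)
    m <- classification_metrics(labels[sp$valid], pred)
    curve <- rbind(curve, data.frame(epoch = epoch,
                                     accuracy = m$accuracy,
                                     precision = m$weighted_precision,
                                     recall = m$weighted_recall,
                                     weighted_f1 = m$weighted_f1))
  }
  attr(curve, "init_mode") <- toupper(init)
  class(curve) <- c("epoch_curve", "data.frame")
  list(classifier = clf, curve = curve,
       best_epoch = which.max(curve$weighted_f1), classes = classes)
}

#' First epoch reaching a fraction of the final weighted F1
#'
#' Convergence-speed summary: the first epoch whose validation weighted F1
#' is at least `frac` times the final epoch's value.
#'
#' @param curve an `epoch_curve`.
#' @param frac target fraction (default 0.9).
#' @return Epoch index (integer).
#' @export
epochs_to_reach <- function(curve, frac = 0.9) {
  target <- frac * curve$weighted_f1[nrow(curve)]
  which(curve$weighted_f1 >= target)[1]
}

#' Compare two training curves
#'
#' Deterministic summary per metric: epoch of the (first) peak, peak
#' value, and the SD over the final five epochs (stability).
#'
#' @param curve_a,curve_b equal-length `epoch_curve` data frames.
#' @return Data frame with one row per (curve, metric).
#' @export
compare_initializations <- function(curve_a, curve_b) {
  ecg_check(nrow(curve_a) == nrow(curve_b), "curves have different lengths")
  metrics <- c("accuracy", "precision", "recall", "weighted_f1")
  summarize <- function(curve, name) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- curve[[m]]
      tailv <- tail(v, 5)
      data.frame(curve = name, metric = m,
                 epochs_to_peak = which.max(v),
                 peak = max(v),
                 final5_sd = if (length(tailv) > 1) stats::sd(tailv) else 0)
    }))
  }
  rbind(summarize(curve_a, attr(curve_a, "init_mode") %||% "A"),
        summarize(curve_b, attr(curve_b, "init_mode") %||% "B"))
}
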