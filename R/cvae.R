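# 1-D convolutional variational autoencoder: residual convolutional encoder
# to a diagonal Gaussian latent, reparameterized sampling, symmetric
# transposed-convolution decoder with output average pooling, ELBO loss,
# and training with patience-based early stopping.

#' CVAE architecture configuration
#'
#' The encoder is `n_blocks` residual blocks, each a single strided 1-D
#' convolution (kernel `kernel_early` in blocks 1-6, `kernel_late` after)
#' with an identity or strided 1x1 projection skip, followed by two dense
#' heads producing the latent mean and half-log-variance. The decoder
#' mirrors the encoder with transposed convolutions and ends with a
#' length-preserving 3-point average pooling.
#'
#' @param latent_dim latent dimensionality (default 60; the latent means
#'   are the feature vector).
#' @param n_blocks number of residual blocks (default 9).
#' @param kernel_early,kernel_late convolution kernel sizes (defaults 19
#'   for blocks 1-6 and 9 afterwards).
#' @param channel_schedule output channels per block; default doubles from
#'   16 and caps at 128.
#' @param stride_schedule stride per block; default all 2. The product of
#'   strides must divide `input_len`.
#' @param input_len window length (default 2048).
#' @param recon_loss `"sse"` (sum of squared errors, default) or `"sae"`
#'   (sum of absolute errors).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 60, n_blocks = 9, kernel_early = 19,
                        kernel_late = 9, channel_schedule = NULL,
                        stride_schedule = NULL, input_len = 2048,
                        recon_loss = c("sse", "sae"), seed = 1) {
  recon_loss <- match.arg(recon_loss)
  ecg_check(latent_dim > 0, "latent_dim must be > 0")
  ecg_check(n_blocks >= 1, "n_blocks must be >= 1")
  channel_schedule <- channel_schedule %||% pmin(16 * 2^(seq_len(n_blocks) - 1), 128)
  stride_schedule <- stride_schedule %||% rep(2L, n_blocks)
  ecg_check(length(channel_schedule) == n_blocks,
            "channel_schedule length must equal n_blocks",
            class = "ecgvae_config_error")
  ecg_check(length(stride_schedule) == n_blocks,
            "stride_schedule length must equal n_blocks",
            class = "ecgvae_config_error")
  kernels <- ifelse(seq_len(n_blocks) <= 6, kernel_early, kernel_late)
  L <- input_len
  for (b in seq_len(n_blocks)) {
    s <- stride_schedule[b]
    if (L %% s != 0)
      ecg_abort(sprintf(
        "block %d: stride %d does not divide the incoming length %d",
        b, s, L), "ecgvae_config_error")
    if (kernels[b] < s)
      ecg_abort(sprintf("block %d: kernel %d smaller than stride %d",
                        b, kernels[b], s), "ecgvae_config_error")
    L <- L %/% s
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 n_blocks = as.integer(n_blocks),
                 kernels = as.integer(kernels),
                 channel_schedule = as.integer(channel_schedule),
                 stride_schedule = as.integer(stride_schedule),
                 input_len = as.integer(input_len),
                 flat_len = as.integer(L),
                 recon_loss = recon_loss,
                 seed = as.integer(seed)),
            class = "cvae_config")
}

#' Latent code: diagonal Gaussian posterior parameters
#'
#' @param mu numeric vector of latent means (the CVAE feature vector).
#' @param sigma numeric vector of latent standard deviations, all > 0.
#' @return An object of class `latent_code`.
#' @export
latent_code <- function(mu, sigma) {
  ecg_check(length(mu) == length(sigma), "mu and sigma lengths differ",
            class = "ecgvae_shape_error")
  ecg_check(all(sigma > 0), "sigma must be strictly positive")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "latent_code")
}

# Parameter initialization: He-style for hidden layers, small-variance for
# the latent heads and the final reconstruction layer.
cvae_init_params <- function(config) {
  p <- list()
  Cin <- 1L
  for (b in seq_len(config$n_blocks)) {
    k <- config$kernels[b]; Cout <- config$channel_schedule[b]
    s <- config$stride_schedule[b]
    p[[sprintf("enc%d_W", b)]] <-
      matrix(rnorm(k * Cin * Cout, sd = sqrt(2 / (k * Cin))),
             k * Cin, Cout)
    p[[sprintf("enc%d_b", b)]] <- numeric(Cout)
    if (Cin != Cout || s != 1) {
      p[[sprintf("encp%d_W", b)]] <-
        matrix(rnorm(Cin * Cout, sd = sqrt(1 / Cin)), Cin, Cout)
      p[[sprintf("encp%d_b", b)]] <- numeric(Cout)
    }
    Cin <- Cout
  }
  flat <- config$flat_len * Cin
  p$mu_W <- matrix(rnorm(flat * config$latent_dim, sd = sqrt(1 / flat)),
                   flat, config$latent_dim)
  p$mu_b <- numeric(config$latent_dim)
  p$lv_W <- matrix(rnorm(flat * config$latent_dim, sd = 0.01),
                   flat, config$latent_dim)
  p$lv_b <- numeric(config$latent_dim)
  p$dec_fc_W <- matrix(rnorm(config$latent_dim * flat,
                             sd = sqrt(1 / config$latent_dim)),
                       config$latent_dim, flat)
  p$dec_fc_b <- numeric(flat)
  for (b in rev(seq_len(config$n_blocks))) {
    k <- config$kernels[b]
    Cin_b <- config$channel_schedule[b]
    Cout_b <- if (b == 1) 1L else config$channel_schedule[b - 1]
    p[[sprintf("dec%d_W", b)]] <-
      matrix(rnorm(k * Cout_b * Cin_b, sd = sqrt(2 / (k * Cin_b))),
             k * Cout_b, Cin_b)
    p[[sprintf("dec%d_b", b)]] <- numeric(Cout_b)
  }
  p
}

#' Build a CVAE model
#'
#' Initializes encoder and decoder parameters; identical seeds produce
#' identical parameters.
#'
#' @param config a [cvae_config()].
#' @return An object of class `cvae_model` with elements `config`, `params`
#'   and `trained` (logical).
#' @export
#' @examples
#' m <- build_cvae(cvae_config(latent_dim = 8, n_blocks = 3,
#'                             channel_schedule = c(4, 8, 8),
#'                             input_len = 256))
build_cvae <- function(config) {
  ecg_check(inherits(config, "cvae_config"), "config must be a cvae_config",
            class = "ecgvae_config_error")
  params <- with_seed(config$seed, cvae_init_params(config))
  structure(list(config = config, params = params, trained = FALSE),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<cvae_model: input %d -> latent %d, %d residual ",
                     "blocks, %strained>\n"),
              cfg$input_len, cfg$latent_dim, cfg$n_blocks,
              if (x$trained) "" else "un"))
  invisible(x)
}

# Window matrix (n x L) -> activation array (L, 1, n).
as_input_array <- function(x, input_len) {
  if (inherits(x, "window")) x <- matrix(x$values, nrow = 1)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  ecg_check(ncol(x) == input_len,
            sprintf("window length %d does not match model input length %d",
                    ncol(x), input_len), class = "ecgvae_shape_error")
  a <- t(x)
  dim(a) <- c(input_len, 1L, nrow(x))
  a
}

# Encoder forward pass. Returns mu, lv (n x latent) and caches.
cvae_encode_fwd <- function(model, xarr, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  n <- dim(xarr)[3]
  h <- xarr
  caches <- if (keep_cache) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    k <- cfg$kernels[b]; s <- cfg$stride_schedule[b]
    cf <- nn_conv_fwd(h, p[[sprintf("enc%d_W", b)]],
                      p[[sprintf("enc%d_b", b)]], k, s)
    has_proj <- !is.null(p[[sprintf("encp%d_W", b)]])
    if (has_proj) {
      pf <- nn_proj_fwd(h, p[[sprintf("encp%d_W", b)]],
                        p[[sprintf("encp%d_b", b)]], s)
      pre <- cf$y + pf$y
    } else {
      pf <- NULL
      pre <- cf$y + h
    }
    act <- nn_relu_fwd(pre)
    if (keep_cache)
      caches[[b]] <- list(conv = cf, proj = pf, act = act,
                          has_proj = has_proj)
    h <- act
  }
  flat <- h
  dim(flat) <- c(prod(dim(h)[1:2]), n)
  flat <- t(flat)
  mu <- nn_dense_fwd(flat, p$mu_W, p$mu_b)
  lv <- nn_dense_fwd(flat, p$lv_W, p$lv_b)
  list(mu = mu, lv = lv, flat = flat, caches = caches)
}

# Decoder forward pass. z: n x latent. Returns xhat (n x L) and caches.
cvae_decode_fwd <- function(model, z, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  n <- nrow(z)
  h0_pre <- nn_dense_fwd(z, p$dec_fc_W, p$dec_fc_b)
  h0 <- nn_relu_fwd(h0_pre)
  h <- t(h0)
  Cf <- cfg$channel_schedule[cfg$n_blocks]
  dim(h) <- c(cfg$flat_len, Cf, n)
  caches <- if (keep_cache) vector("list", cfg$n_blocks) else NULL
  for (b in rev(seq_len(cfg$n_blocks))) {
    k <- cfg$kernels[b]; s <- cfg$stride_schedule[b]
    tf <- nn_tconv_fwd(h, p[[sprintf("dec%d_W", b)]],
                       p[[sprintf("dec%d_b", b)]], k, s)
    if (b > 1) {
      act <- nn_relu_fwd(tf$y)
    } else {
      act <- tf$y  # final reconstruction layer is linear
    }
    if (keep_cache) caches[[b]] <- list(tconv = tf, act = act)
    h <- act
  }
  y <- nn_avgpool3_fwd(h)
  xhat <- y
  dim(xhat) <- c(cfg$input_len, n)
  list(xhat = t(xhat), h0 = h0, pre_pool = h, z = z, caches = caches)
}

#' Encode a window to its latent code
#'
#' Deterministic: returns the posterior mean and standard deviation. The
#' standard deviation is produced by exponentiating a predicted
#' half-log-variance, so positivity is structural.
#'
#' @param window a `window` object, a numeric vector of length
#'   `input_len`, or an n x `input_len` matrix (then a list of codes is
#'   returned).
#' @param model a [build_cvae()] model.
#' @return A [latent_code()] (or list of them for matrix input).
#' @export
encode <- function(window, model) {
  xarr <- as_input_array(window, model$config$input_len)
  enc <- cvae_encode_fwd(model, xarr)
  sigma <- exp(0.5 * enc$lv)
  if (dim(xarr)[3] == 1L) return(latent_code(enc$mu[1, ], sigma[1, ]))
  lapply(seq_len(nrow(enc$mu)),
         function(i) latent_code(enc$mu[i, ], sigma[i, ]))
}

#' Sample a latent vector by reparameterization
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)`; identical seeds give
#' identical draws.
#'
#' @param code a [latent_code()].
#' @param seed integer seed.
#' @return Numeric latent vector.
#' @export
sample_latent <- function(code, seed = 1) {
  eps <- with_seed(seed, rnorm(length(code$mu)))
  code$mu + code$sigma * eps
}

#' Decode a latent vector to a reconstruction
#'
#' @param z numeric vector of length `latent_dim`.
#' @param model a [build_cvae()] model.
#' @return Numeric vector of length `input_len`.
#' @export
decode <- function(z, model) {
  ecg_check(length(z) == model$config$latent_dim,
            sprintf("latent length %d does not match latent_dim %d",
                    length(z), model$config$latent_dim),
            class = "ecgvae_shape_error")
  dec <- cvae_decode_fwd(model, matrix(z, nrow = 1))
  as.numeric(dec$xhat[1, ])
}

#' Closed-form KL divergence to the standard normal prior
#'
#' For a diagonal Gaussian `N(mu, diag(sigma^2))`:
#' `sum_d 0.5 * (mu_d^2 + sigma_d^2 - 1 - 2*log(sigma_d))`.
#'
#' @param code a [latent_code()].
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(code) {
  ecg_check(all(code$sigma > 0), "sigma must be strictly positive")
  sum(0.5 * (code$mu^2 + code$sigma^2 - 1 - 2 * log(code$sigma)))
}

#' Reconstruction error between a window and its reconstruction
#'
#' Sum of squared errors over the window (or sum of absolute errors when
#' the model was configured with `recon_loss = "sae"`).
#'
#' @param x a `window` object or numeric vector.
#' @param xhat numeric vector of the same length.
#' @param loss `"sse"` or `"sae"`.
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(x, xhat, loss = c("sse", "sae")) {
  loss <- match.arg(loss)
  if (inherits(x, "window")) x <- x$values
  ecg_check(length(x) == length(xhat), "x and xhat lengths differ",
            class = "ecgvae_shape_error")
  if (loss == "sse") sum((x - xhat)^2) else sum(abs(x - xhat))
}

#' ELBO components for a batch of windows
#'
#' Reconstruction error (summed over the window, averaged over the batch)
#' plus the closed-form KL divergence (summed over latent dimensions,
#' averaged over the batch), using a seeded reparameterized sample. One
#' noise vector is drawn per call and shared across the batch rows, so the
#' components are invariant under duplicating rows (training steps use
#' independent per-row noise instead).
#'
#' @param batch n x `input_len` matrix of windows.
#' @param model a [build_cvae()] model.
#' @param seed integer seed for the latent sample.
#' @return List of class `elbo_components` with `recon_error`, `kl`,
#'   `total` (stored as their exact sum).
#' @export
elbo_loss <- function(batch, model, seed = 1) {
  if (is.numeric(batch) && is.null(dim(batch))) batch <- matrix(batch, 1)
  ecg_check(nrow(batch) > 0, "batch must be non-empty")
  cfg <- model$config
  xarr <- as_input_array(batch, cfg$input_len)
  enc <- cvae_encode_fwd(model, xarr)
  n <- nrow(batch)
  eps <- with_seed(seed, rnorm(cfg$latent_dim))
  sigma <- exp(0.5 * enc$lv)
  z <- enc$mu + sigma * matrix(eps, n, cfg$latent_dim, byrow = TRUE)
  dec <- cvae_decode_fwd(model, z)
  recon <- if (cfg$recon_loss == "sse") sum((dec$xhat - batch)^2) / n
           else sum(abs(dec$xhat - batch)) / n
  kl <- sum(0.5 * (enc$mu^2 + sigma^2 - 1 - enc$lv)) / n
  structure(list(recon_error = recon, kl = kl, total = recon + kl),
            class = "elbo_components")
}

# One training step: forward, backward, Adam update. Returns the updated
# model/optimizer state plus the batch loss. SSE loss only (training with
# "sae" uses the sign of the residual as its subgradient).
cvae_train_step <- function(model, batch, opt, lr, step_seed) {
  cfg <- model$config; p <- model$params
  n <- nrow(batch)
  xarr <- as_input_array(batch, cfg$input_len)
  enc <- cvae_encode_fwd(model, xarr, keep_cache = TRUE)
  eps <- with_seed(step_seed, matrix(rnorm(n * cfg$latent_dim), n))
  sigma <- exp(0.5 * enc$lv)
  z <- enc$mu + sigma * eps
  dec <- cvae_decode_fwd(model, z, keep_cache = TRUE)
  resid <- dec$xhat - batch
  if (cfg$recon_loss == "sse") {
    recon <- sum(resid^2) / n
    dxhat <- 2 * resid / n
  } else {
    recon <- sum(abs(resid)) / n
    dxhat <- sign(resid) / n
  }
  kl <- sum(0.5 * (enc$mu^2 + sigma^2 - 1 - enc$lv)) / n
  loss <- recon + kl
  if (!is.finite(loss)) return(list(model = model, opt = opt, loss = loss))

  g <- list()
  # ---- decoder backward ----
  dxa <- t(dxhat)
  dim(dxa) <- c(cfg$input_len, 1L, n)
  dh <- nn_avgpool3_bwd(dxa)
  for (b in seq_len(cfg$n_blocks)) {
    cb <- dec$caches[[b]]
    if (b > 1) dh <- nn_relu_bwd(dh, cb$act)
    bw <- nn_tconv_bwd(dh, p[[sprintf("dec%d_W", b)]], cb$tconv)
    g[[sprintf("dec%d_W", b)]] <- bw$dW
    g[[sprintf("dec%d_b", b)]] <- bw$db
    dh <- bw$dx
  }
  Cf <- cfg$channel_schedule[cfg$n_blocks]
  dh0 <- dh
  dim(dh0) <- c(cfg$flat_len * Cf, n)
  dh0 <- t(dh0)
  dh0 <- nn_relu_bwd(dh0, dec$h0)
  dfc <- nn_dense_bwd(dh0, z, p$dec_fc_W)
  g$dec_fc_W <- dfc$dW
  g$dec_fc_b <- dfc$db
  dz <- dfc$dx

  # ---- latent backward (reconstruction path + KL path) ----
  dmu <- dz + enc$mu / n
  dlv <- dz * eps * 0.5 * sigma + 0.5 * (sigma^2 - 1) / n
  dmu_d <- nn_dense_bwd(dmu, enc$flat, p$mu_W)
  dlv_d <- nn_dense_bwd(dlv, enc$flat, p$lv_W)
  g$mu_W <- dmu_d$dW; g$mu_b <- dmu_d$db
  g$lv_W <- dlv_d$dW; g$lv_b <- dlv_d$db
  dflat <- dmu_d$dx + dlv_d$dx

  # ---- encoder backward ----
  dh <- t(dflat)
  dim(dh) <- c(cfg$flat_len, Cf, n)
  for (b in rev(seq_len(cfg$n_blocks))) {
    cb <- enc$caches[[b]]
    dh <- nn_relu_bwd(dh, cb$act)
    bw <- nn_conv_bwd(dh, p[[sprintf("enc%d_W", b)]], cb$conv)
    g[[sprintf("enc%d_W", b)]] <- bw$dW
    g[[sprintf("enc%d_b", b)]] <- bw$db
    if (cb$has_proj) {
      pw <- nn_proj_bwd(dh, p[[sprintf("encp%d_W", b)]], cb$proj)
      g[[sprintf("encp%d_W", b)]] <- pw$dW
      g[[sprintf("encp%d_b", b)]] <- pw$db
      dh <- bw$dx + pw$dx
    } else {
      dh <- bw$dx + dh
    }
  }

  upd <- nn_adam_step(p, g, opt, lr = lr)
  model$params <- upd$params
  list(model = model, opt = upd$state, loss = loss,
       recon = recon, kl = kl)
}

# Incremental early-stopping scan: returns best epoch, stop epoch and
# whether the patience rule fired. "No improvement" means not strictly
# smaller than the running best.
early_stop_scan <- function(totals, patience) {
  best <- Inf; best_epoch <- 0L; bad <- 0L
  for (e in seq_along(totals)) {
    if (totals[e] < best) {
      best <- totals[e]; best_epoch <- e; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience)
        return(list(best_epoch = best_epoch, stop_epoch = e,
                    stopped_early = TRUE))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(totals),
       stopped_early = FALSE)
}

#' Train a CVAE with patience-based early stopping
#'
#' Minimizes the ELBO loss by minibatch Adam. After each epoch the
#' validation total (reconstruction error + KL, batch means) is evaluated;
#' training stops once the best validation total has not strictly improved
#' for `patience` consecutive epochs, and the parameters from the best
#' epoch are returned.
#'
#' @param train_windows,valid_windows n x `input_len` matrices.
#' @param config a [cvae_config()].
#' @param max_epochs maximum number of epochs.
#' @param patience consecutive non-improving epochs tolerated (default 5).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling shuffling and latent sampling;
#'   defaults to the config seed.
#' @param verbose print per-epoch validation losses.
#' @return List with `model` (trained, best-epoch parameters) and
#'   `history` (class `train_history`: per-epoch validation
#'   `recon_error`/`kl`/`total`, `best_epoch`, `stopped_early`).
#' @export
train_cvae <- function(train_windows, valid_windows, config,
                       max_epochs = 30, patience = 5, lr = 1e-3,
                       batch_size = 32, seed = NULL, verbose = FALSE) {
  ecg_check(nrow(train_windows) > 0 && nrow(valid_windows) > 0,
            "train and validation sets must be non-empty")
  seed <- seed %||% config$seed
  model <- build_cvae(config)
  opt <- nn_adam_init(model$params)
  n <- nrow(train_windows)
  hist <- data.frame(epoch = integer(), recon_error = numeric(),
                     kl = numeric(), total = numeric())
  best_total <- Inf; best_epoch <- 0L; best_params <- model$params
  bad <- 0L; stopped_early <- FALSE
  step <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- with_seed(derive_seed(seed, epoch), sample.int(n))
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      step <- step + 1L
      res <- cvae_train_step(model, train_windows[idx, , drop = FALSE],
                             opt, lr, step_seed = derive_seed(seed, 1e6 + step))
      if (!is.finite(res$loss))
        ecg_abort(sprintf("non-finite training loss at epoch %d", epoch),
                  "ecgvae_training_error", epoch = epoch)
      model <- res$model; opt <- res$opt
    }
    val <- elbo_loss(valid_windows, model, seed = derive_seed(seed, 2e6 + epoch))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   recon_error = val$recon_error,
                                   kl = val$kl, total = val$total))
    if (verbose)
      message(sprintf("epoch %d: recon %.2f kl %.2f total %.2f",
                      epoch, val$recon_error, val$kl, val$total))
    if (val$total < best_total) {
      best_total <- val$total; best_epoch <- epoch
      best_params <- model$params; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) { stopped_early <- TRUE; break }
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  history <- structure(list(epochs = hist, best_epoch = best_epoch,
                            stopped_early = stopped_early),
                       class = "train_history")
  list(model = model, history = history)
}

#' Save / load a CVAE checkpoint
#'
#' The parameters go to an RDS file; a JSON sidecar (`<path>.json`) records
#' the configuration, seed and training history for provenance.
#'
#' @param model a `cvae_model`.
#' @param path checkpoint file path.
#' @param history optional `train_history` to record in the sidecar.
#' @return `save_cvae` returns `path` invisibly; `load_cvae` returns the
#'   model.
#' @export
save_cvae <- function(model, path, history = NULL) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config), trained = model$trained)
  if (!is.null(history))
    side$history <- list(epochs = history$epochs,
                         best_epoch = history$best_epoch,
                         stopped_early = history$stopped_early)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_cvae
#' @export
load_cvae <- function(path) {
  model <- readRDS(path)
  ecg_check(inherits(model, "cvae_model"), "not a cvae checkpoint",
            class = "ecgvae_parse_error")
  model
}
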