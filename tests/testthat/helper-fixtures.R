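# Shared fixtures. The reduced trained CVAE is expensive (~2 min) and is
# built lazily once per session, then reused by every test that needs a
# trained model.

.fixtures <- new.env(parent = emptyenv())

# Reduced study configuration: latent 16, four residual blocks, stride
# schedule collapsing 2048 -> 16.
reduced_config <- function(seed = 11) {
  cvae_config(latent_dim = 16, n_blocks = 4, kernel_early = 19,
              channel_schedule = c(8, 16, 24, 32),
              stride_schedule = c(4, 4, 4, 2), input_len = 2048,
              seed = seed)
}

# Tiny configuration for fast structural / gradient tests.
tiny_config <- function(seed = 7, input_len = 64) {
  cvae_config(latent_dim = 4, n_blocks = 2, kernel_early = 5,
              kernel_late = 3, channel_schedule = c(3, 4),
              stride_schedule = c(4, 4), input_len = input_len, seed = seed)
}

# Trained reduced CVAE on ~500 synthetic normal-rhythm windows, plus the
# held-out test windows used by the anomaly and transfer checks.
trained_fixture <- function() {
  if (!is.null(.fixtures$trained)) return(.fixtures$trained)
  normals <- generate_dataset(c(SR = 360, SB = 120, ST_TACHY = 120),
                              duration = 10, rate = 250, seed = 42)
  pp <- preprocess_records(normals)
  n <- nrow(pp$windows)
  va <- seq(6, n, by = 6)
  tr <- setdiff(seq_len(n), va)
  fit <- train_cvae(pp$windows[tr, , drop = FALSE],
                    pp$windows[va, , drop = FALSE],
                    reduced_config(), max_epochs = 30, patience = 5,
                    batch_size = 8)
  .fixtures$trained <- list(model = fit$model, history = fit$history,
                            train_windows = pp$windows[tr, , drop = FALSE],
                            valid_windows = pp$windows[va, , drop = FALSE])
  .fixtures$trained
}

# Held-out test set: normals, AFIB-like, artifact-contaminated normals.
anomaly_testset <- function() {
  if (!is.null(.fixtures$anomaly)) return(.fixtures$anomaly)
  test_norm <- generate_dataset(c(SR = 60, SB = 20, ST_TACHY = 20),
                                duration = 10, rate = 250, seed = 777)
  test_afib <- generate_dataset(c(AFIB_LIKE = 100), duration = 10,
                                rate = 250, seed = 888)
  base <- generate_dataset(c(SR = 50), duration = 10, rate = 250,
                           seed = 999)
  kinds <- rep(c("BROADBAND_NOISE", "BASELINE_WANDER", "FLATLINE"),
               length.out = length(base))
  art <- lapply(seq_along(base), function(i) {
    a <- switch(kinds[i],
      BROADBAND_NOISE = artifact_spec("BROADBAND_NOISE", amplitude = 0.5),
      BASELINE_WANDER = artifact_spec("BASELINE_WANDER",
                                      frequency_hz = 0.3, amplitude = 3),
      FLATLINE = artifact_spec("FLATLINE", segment = c(2, 6)))
    add_artifact(base[[i]], a, seed = 1000 + i)
  })
  .fixtures$anomaly <- list(
    normal = preprocess_records(test_norm)$windows,
    afib = preprocess_records(test_afib)$windows,
    artifact = preprocess_records(art)$windows)
  .fixtures$anomaly
}

# Four-rhythm labelled window set for the transfer-learning checks.
fourclass_fixture <- function() {
  if (!is.null(.fixtures$fourclass)) return(.fixtures$fourclass)
  recs <- generate_dataset(c(SR = 200, SB = 200, ST_TACHY = 200,
                             AFIB_LIKE = 200),
                           duration = 10, rate = 250, seed = 1234)
  .fixtures$fourclass <- preprocess_records(recs)
  .fixtures$fourclass
}
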