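test_that("the default architecture has the reference shapes", {
  cfg <- cvae_config()  # latent 60, 9 blocks, input 2048
  model <- build_cvae(cfg)
  w <- sin(2 * pi * 1.2 * (0:2047) / 250)
  code <- encode(w, model)
  expect_length(code$mu, 60)
  expect_length(code$sigma, 60)
  expect_true(all(code$sigma > 0))
  expect_length(decode(code$mu, model), 2048)

  # round trip through a sampled latent preserves the window length
  z <- sample_latent(code, seed = 3)
  expect_length(decode(z, model), 2048)
})

test_that("model construction is seed-deterministic and validated", {
  cfg <- tiny_config(seed = 21)
  m1 <- build_cvae(cfg)
  m2 <- build_cvae(cfg)
  expect_identical(m1$params, m2$params)

  expect_error(cvae_config(n_blocks = 2, stride_schedule = c(3, 2),
                           channel_schedule = c(4, 4), input_len = 64),
               regexp = "block 1", class = "ecgvae_config_error")
  expect_error(cvae_config(n_blocks = 2, stride_schedule = c(2, 2),
                           channel_schedule = c(4, 4, 4), input_len = 64),
               class = "ecgvae_config_error")
})

test_that("encoding is deterministic; sampling is seeded", {
  model <- build_cvae(tiny_config())
  w <- rnorm(64)
  c1 <- encode(w, model)
  c2 <- encode(w, model)
  expect_identical(c1, c2)
  expect_error(encode(rnorm(63), model), class = "ecgvae_shape_error")

  z1 <- sample_latent(c1, seed = 11)
  z2 <- sample_latent(c1, seed = 11)
  expect_identical(z1, z2)

  tiny_sigma <- latent_code(c1$mu, rep(1e-12, 4))
  expect_equal(sample_latent(tiny_sigma, seed = 1), c1$mu,
               tolerance = 1e-10)
})

test_that("reparameterized draws have the prior moments at mu=0, sigma=1", {
  code <- latent_code(rep(0, 4), rep(1, 4))
  draws <- t(vapply(1:10000, function(s) sample_latent(code, seed = s),
                    numeric(4)))
  expect_true(all(abs(colMeans(draws)) < 0.05))
  v <- apply(draws, 2, var)
  expect_true(all(v > 0.9 & v < 1.1))
})

test_that("KL divergence matches the closed form and Monte Carlo", {
  expect_equal(kl_divergence(latent_code(rep(0, 60), rep(1, 60))), 0)
  expect_equal(kl_divergence(latent_code(1, 1)), 0.5)
  expect_equal(kl_divergence(latent_code(0, exp(1))),
               0.5 * (exp(2) - 1 - 2), tolerance = 1e-12)
  expect_error(kl_divergence(list(mu = 0, sigma = -1)),
               class = "ecgvae_invalid_argument")

  # MC estimate of E_q[log q - log p] within 3 SE at 1e6 draws,
  # randomized posteriors
  set.seed(40)
  for (rep in 1:3) {
    mu <- rnorm(2); sigma <- exp(rnorm(2, sd = 0.4))
    n <- 1e6
    z1 <- rnorm(n, mu[1], sigma[1]); z2 <- rnorm(n, mu[2], sigma[2])
    lq <- dnorm(z1, mu[1], sigma[1], log = TRUE) +
      dnorm(z2, mu[2], sigma[2], log = TRUE)
    lp <- dnorm(z1, log = TRUE) + dnorm(z2, log = TRUE)
    d <- lq - lp
    se <- sd(d) / sqrt(n)
    expect_lt(abs(kl_divergence(latent_code(mu, sigma)) - mean(d)), 3 * se)
  }
})

test_that("reconstruction error is the stated sum of squares", {
  x <- rnorm(2048)
  expect_equal(reconstruction_error(x, x), 0)
  expect_equal(reconstruction_error(x, x + 0.5), 512)

  set.seed(41)
  a <- rnorm(500); b <- rnorm(500)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2  # loop oracle
  expect_equal(reconstruction_error(a, b), acc, tolerance = 1e-9)
  expect_error(reconstruction_error(a, b[-1]), class = "ecgvae_shape_error")
})

test_that("ELBO components satisfy their bookkeeping identities", {
  model <- build_cvae(tiny_config())
  set.seed(42)
  batch <- matrix(rnorm(4 * 64), 4)
  e <- elbo_loss(batch, model, seed = 2)
  expect_identical(e$total, e$recon_error + e$kl)
  expect_gt(e$recon_error, 0)
  expect_true(is.finite(e$kl))

  one <- batch[1, , drop = FALSE]
  dup <- one[rep(1, 5), ]
  e1 <- elbo_loss(one, model, seed = 7)
  e5 <- elbo_loss(dup, model, seed = 7)
  expect_equal(e5$recon_error, e1$recon_error, tolerance = 1e-9)
  expect_equal(e5$kl, e1$kl, tolerance = 1e-9)

  expect_error(elbo_loss(matrix(numeric(0), 0, 64), model),
               class = "ecgvae_invalid_argument")
})

test_that("the early-stopping rule matches the brute-force oracle", {
  # hand trace: best at epoch 3, five non-improving epochs stop at 8
  tr <- ecgvae:::early_stop_scan(c(10, 9, 8, 8.5, 8.4, 8.3, 8.2, 8.1), 5)
  expect_identical(tr$best_epoch, 3L)
  expect_identical(tr$stop_epoch, 8L)
  expect_true(tr$stopped_early)

  oracle <- function(v, patience) {
    # exhaustive scan: for each epoch e check the trailing window
    best <- which.min(v[1])
    run_best <- v[1]; best_e <- 1L
    for (e in seq_along(v)) {
      if (v[e] < run_best) { run_best <- v[e]; best_e <- e }
      if (e - best_e >= patience)
        return(list(best_epoch = best_e, stop_epoch = e,
                    stopped_early = TRUE))
    }
    list(best_epoch = best_e, stop_epoch = length(v),
         stopped_early = FALSE)
  }
  set.seed(43)
  for (i in 1:100) {
    v <- round(runif(sample(3:20, 1), 0, 5), 1)  # ties are common
    patience <- sample(1:6, 1)
    expect_identical(ecgvae:::early_stop_scan(v, patience),
                     oracle(v, patience))
  }
})

test_that("training improves a tiny model and respects the epoch budget", {
  set.seed(44)
  base <- sin(2 * pi * 3 * (0:63) / 64)
  train <- t(replicate(48, base + rnorm(64, sd = 0.3)))
  valid <- t(replicate(12, base + rnorm(64, sd = 0.3)))

  fit1 <- train_cvae(train, valid, tiny_config(), max_epochs = 1)
  expect_identical(nrow(fit1$history$epochs), 1L)
  expect_false(fit1$history$stopped_early)

  fit <- train_cvae(train, valid, tiny_config(), max_epochs = 25,
                    patience = 25, batch_size = 8)
  h <- fit$history$epochs
  expect_lt(min(h$total), h$total[1])
  expect_identical(fit$history$best_epoch, which.min(h$total))
  expect_true(fit$model$trained)
})

test_that("checkpoints round-trip through disk", {
  model <- build_cvae(tiny_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_cvae(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_cvae(path)
  expect_identical(back$params, model$params)
  w <- rnorm(64)
  expect_identical(encode(w, back), encode(w, model))
})
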