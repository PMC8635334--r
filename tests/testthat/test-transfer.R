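test_that("classification metrics follow the one-vs-rest formulas", {
  true <- c("a", "b", "a", "c", "b", "a")
  m <- classification_metrics(true, true)
  expect_equal(m$accuracy, 1)
  expect_equal(m$weighted_f1, 1)

  # classes sized 3 and 1 with per-class f1 1.0 and 0.0
  m2 <- classification_metrics(c("a", "a", "a", "b"),
                               c("a", "a", "a", "c"))
  expect_equal(m2$per_class$f1, c(1, 0))
  expect_equal(m2$weighted_f1, 0.75)

  set.seed(70)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    n <- sample(20:80, 1)
    true <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:(k + 1)], n, replace = TRUE)
    got <- classification_metrics(true, pred)
    ref <- metrics_oracle(true, pred)
    expect_equal(got$accuracy, ref$accuracy, tolerance = 1e-9)
    expect_equal(got$weighted_f1, ref$weighted_f1, tolerance = 1e-9)
    expect_equal(got$per_class$f1, ref$f1, tolerance = 1e-9)
    # weighted f1 lies between the per-class extremes
    expect_gte(got$weighted_f1, min(ref$f1) - 1e-12)
    expect_lte(got$weighted_f1, max(ref$f1) + 1e-12)
  }

  expect_error(classification_metrics(c("a", "b"), c("a")),
               class = "ecgvae_invalid_argument")
})

test_that("validation splits are seeded, disjoint and exhaustive", {
  cfgA <- bootstrap_config(n_repeats = 5, seed = 3)
  for (r in 1:5) {
    s1 <- ecgvae:::split_indices(100, cfgA, r)
    s2 <- ecgvae:::split_indices(100, cfgA, r)
    expect_identical(s1, s2)
    expect_length(intersect(s1$train, s1$valid), 0)
    expect_setequal(c(s1$train, s1$valid), 1:100)
    expect_length(s1$train, 80)
  }
  # different repeats give different splits
  expect_false(identical(ecgvae:::split_indices(100, cfgA, 1)$train,
                         ecgvae:::split_indices(100, cfgA, 2)$train))
  # bootstrap mode resamples with replacement
  sb <- ecgvae:::split_indices(100, bootstrap_config(seed = 3,
                                                     bootstrap = TRUE), 1)
  expect_length(sb$train, 100)
  expect_gt(length(sb$train), length(unique(sb$train)))
})

test_that("boosted classification of separable features is perfect", {
  set.seed(71)
  f <- rbind(matrix(rnorm(60 * 4), 60),
             matrix(rnorm(60 * 4, mean = 8), 60))
  lab <- rep(c("x", "y"), each = 60)
  rep_ <- feature_classify(f, lab, config = bootstrap_config(5, seed = 2))
  expect_length(rep_$repeats, 5)
  expect_equal(unname(rep_$mean["weighted_f1"]), 1.0)
  expect_equal(unname(rep_$sd["weighted_f1"]), 0.0)

  expect_error(feature_classify(f, rep("x", 120)),
               class = "ecgvae_invalid_argument")
})

test_that("boosted classification of shuffled labels is at chance", {
  set.seed(72)
  f <- matrix(rnorm(200 * 8), 200)
  lab <- sample(rep(letters[1:4], each = 50))  # labels carry no signal
  rep_ <- feature_classify(f, lab, config = bootstrap_config(5, seed = 4))
  null_rate <- 0.25
  spread <- max(rep_$sd["weighted_f1"], 0.05)
  expect_lt(abs(rep_$mean[["weighted_f1"]] - null_rate), 3 * spread)
})

test_that("classifier builds copy or re-draw encoder weights as requested", {
  cfg <- tiny_config(seed = 13)
  fake_trained <- build_cvae(cfg)
  fake_trained$trained <- TRUE

  pre <- build_classifier(cfg, 3, "pretrained", pretrained = fake_trained,
                          seed = 99)
  enc_names <- grep("^(enc|mu_)", names(pre$params), value = TRUE)
  expect_identical(pre$params[enc_names], fake_trained$params[enc_names])

  r1 <- build_classifier(cfg, 3, "random", seed = 5)
  r2 <- build_classifier(cfg, 3, "random", seed = 5)
  expect_identical(r1$params, r2$params)
  expect_false(identical(r1$params$enc1_W, pre$params$enc1_W))

  W <- matrix(rnorm(4 * 64), 4)
  expect_length(predict(r1, W), 4)
  expect_true(all(predict(r1, W, classes = c("a", "b", "c")) %in%
                    c("a", "b", "c")))

  other <- cvae_config(latent_dim = 4, n_blocks = 2, kernel_early = 5,
                       kernel_late = 3, channel_schedule = c(4, 4),
                       stride_schedule = c(4, 4), input_len = 64, seed = 1)
  expect_error(build_classifier(other, 3, "pretrained",
                                pretrained = fake_trained),
               class = "ecgvae_config_error")
})

test_that("weight-reuse training runs the exact epoch budget", {
  set.seed(73)
  base <- sin(2 * pi * 2 * (0:63) / 64)
  W <- rbind(t(replicate(30, base + rnorm(64, sd = 0.2))),
             t(replicate(30, rev(base) + rnorm(64, sd = 0.2))))
  lab <- rep(c("p", "q"), each = 30)
  out <- weight_transfer_train(W, lab, "random", tiny_config(),
                               epochs = 1, seed = 3)
  expect_identical(nrow(out$curve), 1L)
  out3 <- weight_transfer_train(W, lab, "random", tiny_config(),
                                epochs = 3, lr = 1e-3, seed = 3)
  expect_identical(nrow(out3$curve), 3L)
  expect_identical(attr(out3$curve, "init_mode"), "RANDOM")
  expect_true(all(out3$curve$weighted_f1 >= 0 &
                    out3$curve$weighted_f1 <= 1))
})

test_that("curve comparison summaries are deterministic arithmetic", {
  mk <- function(v, mode) {
    d <- data.frame(epoch = seq_along(v), accuracy = v, precision = v,
                    recall = v, weighted_f1 = v)
    attr(d, "init_mode") <- mode
    class(d) <- c("epoch_curve", "data.frame")
    d
  }
  inc <- mk(seq(0.1, 0.9, length.out = 9), "PRETRAINED")
  cmp <- compare_initializations(inc, inc)
  expect_identical(cmp$epochs_to_peak, rep(9L, 8))
  expect_equal(cmp$peak, rep(0.9, 8))
  expect_equal(cmp[cmp$curve == "PRETRAINED", ],
               cmp[cmp$curve == "PRETRAINED", ])

  toy <- mk(c(0.2, 0.4, 0.6, 0.5, 0.7), "RANDOM")
  cmp2 <- compare_initializations(toy, toy)
  expect_equal(cmp2$final5_sd[1],
               sd(c(0.2, 0.4, 0.6, 0.5, 0.7)), tolerance = 1e-12)
  expect_identical(cmp2$epochs_to_peak[1], 5L)

  # epochs_to_reach: first epoch at >= 90% of the final value
  expect_identical(epochs_to_reach(toy, 0.9), 5L)  # target 0.63
  expect_identical(epochs_to_reach(toy, 0.5), 2L)  # target 0.35

  expect_error(compare_initializations(inc, toy),
               class = "ecgvae_invalid_argument")
})
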