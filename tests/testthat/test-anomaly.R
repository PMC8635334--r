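test_that("anomality scoring is the deterministic per-point mean error", {
  model <- build_cvae(tiny_config())
  w <- rnorm(64)
  s1 <- anomality_score(w, model)
  expect_identical(s1, anomality_score(w, model))
  code <- encode(w, model)
  expect_equal(s1, reconstruction_error(w, decode(code$mu, model)) / 64)

  # batch scoring agrees with the scalar path
  W <- rbind(w, rnorm(64))
  sb <- anomality_scores(W, model)
  expect_equal(sb[1], s1, tolerance = 1e-12)
  expect_equal(sb[2], anomality_score(W[2, ], model), tolerance = 1e-12)
})

test_that("threshold selection maximizes weighted F1 with precision ties", {
  # under the weighted-F1 rule the 0.50-0.65 plateau (abnormal precision 1)
  # beats the 0.10-0.25 plateau (precision 2/3); largest threshold wins
  res <- select_threshold(c(0.1, 0.5, 0.3, 0.7), c(0, 0, 1, 1))
  expect_equal(res$selected_threshold, 0.65, tolerance = 1e-9)
  expect_equal(res$selected_threshold,
               threshold_oracle(c(0.1, 0.5, 0.3, 0.7), c(0, 0, 1, 1)),
               tolerance = 1e-9)

  # perfectly separated scores
  set.seed(50)
  s <- c(runif(20, 0, 0.15), runif(20, 0.85, 1))
  l <- rep(c(0, 1), each = 20)
  res2 <- select_threshold(s, l)
  m <- detection_metrics(s, l, res2$selected_threshold)
  expect_equal(m$abnormal$precision, 1)
  expect_equal(m$abnormal$recall, 1)

  expect_error(select_threshold(c(0.1, 0.2), c(1, 1)),
               class = "ecgvae_invalid_argument")
})

test_that("threshold selection equals the exhaustive oracle on random data", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    s <- round(runif(n, 0, 1.5), 2)
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(select_threshold(s, l)$selected_threshold,
                 threshold_oracle(s, l), tolerance = 1e-9)
  }
})

test_that("detection metrics follow the confusion-count formulas", {
  # TP=3 FP=1 FN=0 TN=4 at threshold 0.5
  s <- c(rep(0.9, 4), rep(0.1, 4))
  l <- c(1, 1, 1, 0, 0, 0, 0, 0)
  m <- detection_metrics(s, l, 0.5)
  expect_identical(m$counts, list(tp = 3L, fp = 1L, fn = 0L, tn = 4L))
  expect_equal(m$abnormal$precision, 0.75)
  expect_equal(m$abnormal$recall, 1.0)
  expect_equal(m$abnormal$f1, 6 / 7, tolerance = 1e-12)
  expect_equal(m$accuracy, 7 / 8)

  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(c(0.1, 0.9, 0.2, 0.8), c(0, 0, 1, 1)), 0.5)
})

test_that("AUROC is rank-based: monotone-invariant and matches pROC", {
  set.seed(52)
  s <- runif(200); l <- rbinom(200, 1, 0.5)
  a <- auroc(s, l)
  expect_equal(auroc(exp(3 * s) + 7, l), a, tolerance = 1e-12)
  expect_equal(auroc(qlogis(s / 2 + 0.1), l), a, tolerance = 1e-12)
  ref <- suppressMessages(pROC::auc(pROC::roc(l, s, direction = "<",
                                              quiet = TRUE)))
  expect_equal(a, as.numeric(ref), tolerance = 1e-9)
})

test_that("Welch's t-test matches the reference implementation", {
  g <- c(1, 2, 3, 4)
  r0 <- welch_t_test(g, g)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  r1 <- welch_t_test(g, g + 10)
  expect_lt(r1$p, 0.001)

  set.seed(53)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b)
    r <- welch_t_test(a, b)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(r$p, ref$p.value, tolerance = 1e-6)
    expect_equal(r$df, unname(ref$parameter), tolerance = 1e-6)
  }

  expect_error(welch_t_test(1, c(1, 2)),
               class = "ecgvae_invalid_argument")
})

test_that("score histograms conserve counts on a uniform grid", {
  h <- score_histogram(c(0.1, 0.1, 0.9), 0.5)
  expect_equal(h$counts, c(2, 1))
  expect_equal(h$edges, c(0, 0.5, 1))

  set.seed(54)
  for (i in 1:10) {
    s <- abs(rnorm(sample(5:200, 1), sd = runif(1, 0.1, 2)))
    bw <- runif(1, 0.05, 0.5)
    h <- score_histogram(s, bw)
    expect_identical(sum(h$counts), length(s))
    expect_equal(diff(h$edges), rep(bw, length(h$counts)),
                 tolerance = 1e-9)
  }

  # left-skewed mixture (90% normals near 0.3): modal bin below 0.5
  set.seed(55)
  mix <- c(abs(rnorm(900, 0.3, 0.08)), rnorm(100, 1.0, 0.3))
  hm <- score_histogram(mix, 0.1)
  modal <- hm$edges[which.max(hm$counts)]
  expect_lt(modal, 0.5)

  expect_error(score_histogram(mix, 0), class = "ecgvae_invalid_argument")
})

test_that("RR irregularity implements the 50% change rule", {
  expect_equal(rr_irregularity(c(1, 1, 1)), 0)
  # +60% qualifies, the return step (-37.5%) does not
  expect_equal(rr_irregularity(c(1.0, 1.6, 1.0)), 0.5)

  two_beats <- rep(0, 500)
  two_beats[c(100, 300)] <- 10
  short <- ecg_record(two_beats, 100)
  expect_error(rr_irregularity_fraction(short),
               class = "ecgvae_insufficient_data")

  hits <- 0L
  for (s in 1:50) {
    sr <- generate_record(rhythm_spec("SR", heart_rate_bpm = 70, rr_cv = 0),
                          duration = 60, seed = 100 + s)
    af <- generate_record(rhythm_spec("AFIB_LIKE", rr_cv = 0.3),
                          duration = 60, seed = 200 + s)
    expect_equal(rr_irregularity_fraction(sr), 0)
    if (rr_irregularity_fraction(af) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 45)  # > 0 in at least 90% of draws
})
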