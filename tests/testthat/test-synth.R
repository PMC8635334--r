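test_that("beat template is the stated sum of Gaussians", {
  wp0 <- wave_params(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_equal(generate_beat_template(wp0, rr = 0.8, rate = 250),
               rep(0, 200))

  # single R wave: the closed-form Gaussian peaks at center * rr
  wp <- wave_params(amplitude = c(P = 0, Q = 0, R = 1, S = 0, T = 0),
                    center = c(P = 0.1, Q = 0.3, R = 0.4, S = 0.5, T = 0.7),
                    width = c(P = 0.02, Q = 0.02, R = 0.02, S = 0.02,
                              T = 0.02))
  beat <- generate_beat_template(wp, rr = 1, rate = 250)
  expect_length(beat, 250)
  expect_lte(abs(which.max(beat) - 101), 1)  # 0-based index 100

  expect_error(generate_beat_template(wp, rr = -1, rate = 250),
               class = "ecgvae_invalid_argument")
  expect_error(generate_beat_template(wp, rr = 1, rate = 0),
               class = "ecgvae_invalid_argument")
})

test_that("generated records honor the rhythm specification", {
  spec <- rhythm_spec("SR", heart_rate_bpm = 60, rr_cv = 0)
  rec <- generate_record(spec, duration = 10, rate = 250, seed = 1)
  expect_length(rec$samples, 2500)
  rr <- diff(detect_r_peaks(rec))
  expect_equal(mean(rr), 1.0, tolerance = 1e-8)

  rec2 <- generate_record(spec, duration = 10, rate = 250, seed = 1)
  expect_identical(rec$samples, rec2$samples)

  expect_error(generate_record(spec, duration = 0.5, rate = 250, seed = 1),
               class = "ecgvae_invalid_argument")
})

test_that("AFIB-like RR variability matches the requested CV", {
  spec <- rhythm_spec("AFIB_LIKE", heart_rate_bpm = 80, rr_cv = 0.25)
  # ~200 beats at 80 bpm needs 150 s
  rec <- generate_record(spec, duration = 152, rate = 250, seed = 3)
  rr <- diff(detect_r_peaks(rec))
  expect_gte(length(rr), 150)
  cv <- sd(rr) / mean(rr)
  expect_gte(cv, 0.15)
  expect_lte(cv, 0.35)
})

test_that("rhythm_spec enforces its class invariants", {
  expect_error(rhythm_spec("SB", heart_rate_bpm = 70))
  expect_error(rhythm_spec("ST_TACHY", heart_rate_bpm = 90))
  expect_error(rhythm_spec("AFIB_LIKE", rr_cv = 0.05))
  expect_error(rhythm_spec("AFIB_LIKE", p_wave_present = TRUE))
  expect_false(rhythm_spec("AFIB_LIKE")$p_wave_present)
})

test_that("artifacts follow their closed forms", {
  rec <- ecg_record(rep(0, 400), 200, record_id = "z")

  unchanged <- add_artifact(rec, artifact_spec("BROADBAND_NOISE",
                                               amplitude = 0), seed = 1)
  expect_identical(unchanged$samples, rec$samples)

  flat <- add_artifact(ecg_record(rnorm(100), 100),
                       artifact_spec("FLATLINE"), seed = 1)
  expect_identical(flat$samples, rep(0, 100))

  wander <- add_artifact(rec, artifact_spec("BASELINE_WANDER",
                                            frequency_hz = 0.2,
                                            amplitude = 2), seed = 1)
  # sample at t = 1.25 s: 2 * sin(2*pi*0.2*1.25) = 2
  i <- 1.25 * 200 + 1
  expect_equal(wander$samples[i], 2.0, tolerance = 1e-12)

  expect_error(artifact_spec("BASELINE_WANDER", frequency_hz = 0.6),
               class = "ecgvae_invalid_argument")
})

test_that("datasets are labelled, deterministic and class-ordered", {
  expect_identical(generate_dataset(c(SR = 0)), list())

  d <- generate_dataset(c(SR = 3), duration = 5, seed = 9)
  expect_length(d, 3)
  expect_true(all(vapply(d, `[[`, "", "label") == "SR"))

  d1 <- generate_dataset(c(SR = 2, AFIB_LIKE = 2), duration = 5, seed = 4)
  d2 <- generate_dataset(c(SR = 2, AFIB_LIKE = 2), duration = 5, seed = 4)
  expect_identical(d1, d2)

  mix <- generate_dataset(c(SR = 25, SB = 25), duration = 10, seed = 6)
  hr <- vapply(mix, function(r) 60 / mean(diff(detect_r_peaks(r))), 0)
  lab <- vapply(mix, `[[`, "", "label")
  expect_lt(mean(hr[lab == "SB"]), mean(hr[lab == "SR"]))
  # label fidelity up to one beat of edge truncation
  expect_true(all(hr[lab == "SB"] < 60))
  mix2 <- generate_dataset(c(ST_TACHY = 25), duration = 10, seed = 8)
  hr2 <- vapply(mix2, function(r) 60 / mean(diff(detect_r_peaks(r))), 0)
  expect_true(all(hr2 > 100))
})

test_that("AFIB-like records are more RR-irregular than rigid SR", {
  wins <- 0L
  for (s in 1:50) {
    sr <- generate_record(rhythm_spec("SR", heart_rate_bpm = 70, rr_cv = 0),
                          duration = 60, seed = s)
    af <- generate_record(rhythm_spec("AFIB_LIKE", rr_cv = 0.3),
                          duration = 60, seed = s)
    if (rr_irregularity_fraction(af) > rr_irregularity_fraction(sr))
      wins <- wins + 1L
  }
  expect_gte(wins, 45)
})

test_that("record directories round-trip through CSV + manifest", {
  d <- generate_dataset(c(SR = 2, SVT_LIKE = 1), duration = 3, seed = 2)
  dir <- withr::local_tempdir()
  write_record_dir(d, dir)
  back <- read_record_dir(dir)
  ids <- vapply(back, `[[`, "", "record_id")
  for (r in d) {
    i <- match(r$record_id, ids)
    expect_equal(back[[i]]$samples, r$samples, tolerance = 1e-12)
    expect_identical(back[[i]]$label, r$label)
  }

  writeLines(c("time_s,amplitude", "0,abc"), file.path(dir, "SR_001.csv"))
  expect_error(read_record_dir(dir), class = "ecgvae_parse_error")
})
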