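# Synthetic single-lead ECG generator: sum-of-Gaussians PQRST beats,
# rhythm classes with controllable rate / RR variability, and artifacts.

WAVE_NAMES <- c("P", "Q", "R", "S", "T")

#' PQRST wave morphology parameters
#'
#' Describes one beat as a sum of five Gaussian deflections (P, Q, R, S, T).
#' Each wave has an amplitude (millivolt-like arbitrary units), a center
#' expressed as a fraction of the RR interval in `[0, 1)`, and a width in
#' seconds. Defaults give a lead-II-like morphology with a dominant R peak,
#' scaled so that z-normalized records span roughly -2 to 6.
#'
#' @param amplitude named numeric vector of length 5 (P, Q, R, S, T).
#' @param center named numeric vector of centers as RR fractions,
#'   strictly increasing in P < Q < R < S < T order.
#' @param width named numeric vector of Gaussian widths in seconds, all > 0.
#' @return An object of class `wave_params`.
#' @export
#' @examples
#' wp <- wave_params()
#' beat <- generate_beat_template(wp, rr = 1, rate = 250)
wave_params <- function(amplitude = c(P = 0.15, Q = -0.10, R = 1.20,
                                      S = -0.25, T = 0.35),
                        center = c(P = 0.12, Q = 0.33, R = 0.37,
                                   S = 0.41, T = 0.62),
                        width = c(P = 0.025, Q = 0.012, R = 0.016,
                                  S = 0.014, T = 0.060)) {
  amplitude <- amplitude[WAVE_NAMES]
  center <- center[WAVE_NAMES]
  width <- width[WAVE_NAMES]
  ecg_check(!anyNA(amplitude) && !anyNA(center) && !anyNA(width),
            "wave_params needs named P,Q,R,S,T entries")
  ecg_check(all(width > 0), "wave widths must be > 0")
  ecg_check(all(center >= 0 & center < 1), "wave centers must lie in [0, 1)")
  ecg_check(all(diff(center) > 0),
            "wave centers must be strictly increasing P < Q < R < S < T")
  structure(list(amplitude = amplitude, center = center, width = width),
            class = "wave_params")
}

#' Rhythm specification for the synthetic generator
#'
#' @param rhythm_class one of `"SR"` (normal sinus), `"SB"` (sinus
#'   bradycardia, < 60 bpm), `"ST_TACHY"` (sinus tachycardia, > 100 bpm),
#'   `"AFIB_LIKE"` (irregular RR, absent P, fibrillatory baseline) or
#'   `"SVT_LIKE"` (very fast, regular, absent P).
#' @param heart_rate_bpm mean heart rate in beats per minute.
#' @param rr_cv coefficient of variation of the RR intervals (>= 0).
#' @param p_wave_present logical; `FALSE` suppresses the P wave.
#' @param fibrillatory_amplitude amplitude of the fibrillatory (f-wave)
#'   oscillation added between beats (>= 0).
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(rhythm_class = c("SR", "SB", "ST_TACHY",
                                         "AFIB_LIKE", "SVT_LIKE"),
                        heart_rate_bpm = NULL, rr_cv = NULL,
                        p_wave_present = NULL, fibrillatory_amplitude = NULL) {
  rhythm_class <- match.arg(rhythm_class)
  defaults <- switch(rhythm_class,
    SR        = list(hr = 75,  cv = 0.05, p = TRUE,  fib = 0),
    SB        = list(hr = 48,  cv = 0.05, p = TRUE,  fib = 0),
    ST_TACHY  = list(hr = 120, cv = 0.05, p = TRUE,  fib = 0),
    AFIB_LIKE = list(hr = 90,  cv = 0.25, p = FALSE, fib = 0.10),
    SVT_LIKE  = list(hr = 180, cv = 0.02, p = FALSE, fib = 0)
  )
  heart_rate_bpm <- heart_rate_bpm %||% defaults$hr
  rr_cv <- rr_cv %||% defaults$cv
  p_wave_present <- p_wave_present %||% defaults$p
  fibrillatory_amplitude <- fibrillatory_amplitude %||% defaults$fib
  ecg_check(heart_rate_bpm > 0, "heart_rate_bpm must be > 0")
  ecg_check(rr_cv >= 0, "rr_cv must be >= 0")
  ecg_check(fibrillatory_amplitude >= 0,
            "fibrillatory_amplitude must be >= 0")
  if (rhythm_class == "SB")
    ecg_check(heart_rate_bpm < 60, "SB requires heart_rate_bpm < 60")
  if (rhythm_class == "ST_TACHY")
    ecg_check(heart_rate_bpm > 100, "ST_TACHY requires heart_rate_bpm > 100")
  if (rhythm_class == "AFIB_LIKE") {
    ecg_check(rr_cv >= 0.15, "AFIB_LIKE requires rr_cv >= 0.15")
    ecg_check(!p_wave_present, "AFIB_LIKE requires p_wave_present = FALSE")
  }
  structure(list(rhythm_class = rhythm_class,
                 heart_rate_bpm = heart_rate_bpm, rr_cv = rr_cv,
                 p_wave_present = p_wave_present,
                 fibrillatory_amplitude = fibrillatory_amplitude),
            class = "rhythm_spec")
}

#' Artifact specification
#'
#' @param kind `"BASELINE_WANDER"` (additive sinusoid below 0.5 Hz, the band
#'   the preprocessing high-pass removes), `"BROADBAND_NOISE"` (additive
#'   zero-mean Gaussian noise) or `"FLATLINE"` (zeroes a segment).
#' @param frequency_hz wander frequency; must lie in (0, 0.5).
#' @param amplitude sinusoid amplitude / noise standard deviation (>= 0).
#' @param segment optional `c(start, end)` in seconds; default whole record.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("BASELINE_WANDER", "BROADBAND_NOISE",
                                   "FLATLINE"),
                          frequency_hz = 0.2, amplitude = 1, segment = NULL) {
  kind <- match.arg(kind)
  ecg_check(amplitude >= 0, "artifact amplitude must be >= 0")
  if (kind == "BASELINE_WANDER")
    ecg_check(frequency_hz > 0 && frequency_hz < 0.5,
              "baseline wander frequency must lie in (0, 0.5) Hz")
  if (!is.null(segment)) {
    ecg_check(length(segment) == 2 && segment[1] < segment[2] &&
                segment[1] >= 0, "segment must be c(start, end) seconds")
  }
  structure(list(kind = kind, frequency_hz = frequency_hz,
                 amplitude = amplitude, segment = segment),
            class = "artifact_spec")
}

#' Single-lead ECG record
#'
#' @param samples numeric vector of amplitudes (non-empty).
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param label optional rhythm/artifact tag.
#' @param record_id record identifier string.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate_hz, label = NULL,
                       record_id = "rec") {
  ecg_check(length(samples) > 0, "samples must be non-empty")
  ecg_check(is.numeric(sampling_rate_hz) && sampling_rate_hz > 0,
            "sampling_rate_hz must be > 0")
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 label = label, record_id = record_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.2f s)%s>\n",
              x$record_id, length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' One PQRST beat as a sum of Gaussians
#'
#' Evaluates, on a uniform grid of `round(rr * rate)` samples, the sum over
#' the five waves of `amplitude * exp(-(t - center*rr)^2 / (2 width^2))`.
#'
#' @param params a [wave_params()] object.
#' @param rr beat (RR interval) duration in seconds, > 0.
#' @param rate sampling rate in Hz, > 0.
#' @return Numeric vector of length `round(rr * rate)`.
#' @export
generate_beat_template <- function(params, rr, rate) {
  ecg_check(is.numeric(rr) && length(rr) == 1 && rr > 0, "rr must be > 0")
  ecg_check(is.numeric(rate) && length(rate) == 1 && rate > 0,
            "rate must be > 0")
  n <- round(rr * rate)
  t <- (seq_len(n) - 1) / rate
  y <- numeric(n)
  for (w in WAVE_NAMES) {
    a <- params$amplitude[[w]]
    if (a == 0) next
    mu <- params$center[[w]] * rr
    y <- y + a * exp(-(t - mu)^2 / (2 * params$width[[w]]^2))
  }
  y
}

# Truncated-normal RR sampling: normal(mean, cv*mean) floored at 0.25 s so
# beats never overlap the refractory period.
sample_rr <- function(n, mean_rr, cv) {
  rr <- rnorm(n, mean = mean_rr, sd = cv * mean_rr)
  pmax(rr, 0.25)
}

#' Generate one synthetic ECG record
#'
#' Concatenates PQRST beats whose RR intervals are drawn from a truncated
#' normal with mean `60 / heart_rate_bpm` and coefficient of variation
#' `rr_cv`. For rhythms without a P wave the P amplitude is zeroed; a
#' fibrillatory oscillation (sum of three seeded sinusoids in the 4-9 Hz
#' f-wave band) is added when `fibrillatory_amplitude > 0`.
#'
#' @param spec a [rhythm_spec()] object.
#' @param params a [wave_params()] object; default [wave_params()].
#' @param duration record length in seconds (must hold at least one beat).
#' @param rate sampling rate in Hz.
#' @param seed integer seed; identical `(spec, seed)` gives identical output.
#' @param record_id identifier for the produced record.
#' @return An [ecg_record()] labelled with the rhythm class.
#' @export
#' @examples
#' rec <- generate_record(rhythm_spec("SR", heart_rate_bpm = 60, rr_cv = 0),
#'                        duration = 10, rate = 250, seed = 1)
generate_record <- function(spec, params = wave_params(), duration,
                            rate = 250, seed = 1, record_id = NULL) {
  mean_rr <- 60 / spec$heart_rate_bpm
  ecg_check(duration >= mean_rr,
            "duration must hold at least one RR interval")
  if (!spec$p_wave_present) {
    params$amplitude[["P"]] <- 0
  }
  n <- round(duration * rate)
  with_seed(seed, {
    n_beats <- ceiling(duration / 0.25) + 2  # generous upper bound
    rr <- if (spec$rr_cv > 0) sample_rr(n_beats, mean_rr, spec$rr_cv)
          else rep(mean_rr, n_beats)
    onsets <- cumsum(c(0, rr))
    keep <- onsets < duration
    onsets <- onsets[keep]
    rr <- rr[seq_along(onsets)]
    y <- numeric(n)
    for (b in seq_along(onsets)) {
      beat <- generate_beat_template(params, rr[b], rate)
      i0 <- round(onsets[b] * rate) + 1
      i1 <- min(i0 + length(beat) - 1, n)
      if (i1 >= i0) y[i0:i1] <- y[i0:i1] + beat[seq_len(i1 - i0 + 1)]
    }
    if (spec$fibrillatory_amplitude > 0) {
      t <- (seq_len(n) - 1) / rate
      f <- runif(3, 4, 9)
      ph <- runif(3, 0, 2 * pi)
      fib <- rowSums(sapply(seq_len(3), function(k)
        sin(2 * pi * f[k] * t + ph[k])))
      y <- y + spec$fibrillatory_amplitude * fib / 3
    }
    ecg_record(y, rate, label = spec$rhythm_class,
               record_id = record_id %||%
                 sprintf("%s_seed%d", spec$rhythm_class, as.integer(seed)))
  })
}

#' Add an artifact to a record
#'
#' `BASELINE_WANDER` adds `amplitude * sin(2*pi*frequency_hz*t)`;
#' `BROADBAND_NOISE` adds seeded zero-mean Gaussian noise with standard
#' deviation `amplitude`; `FLATLINE` zeroes the given segment (default: the
#' whole record). The artifact kind is appended to the record label.
#'
#' @param record an [ecg_record()].
#' @param artifact an [artifact_spec()].
#' @param seed integer seed (used by `BROADBAND_NOISE` only).
#' @return The modified [ecg_record()].
#' @export
add_artifact <- function(record, artifact, seed = 1) {
  ecg_check(inherits(artifact, "artifact_spec"),
            "artifact must be an artifact_spec")
  n <- length(record$samples)
  rate <- record$sampling_rate_hz
  idx <- seq_len(n)
  if (!is.null(artifact$segment)) {
    i0 <- max(1L, floor(artifact$segment[1] * rate) + 1L)
    i1 <- min(n, ceiling(artifact$segment[2] * rate))
    idx <- if (i1 >= i0) i0:i1 else integer(0)
  }
  y <- record$samples
  if (artifact$kind == "BASELINE_WANDER") {
    t <- (idx - 1) / rate
    y[idx] <- y[idx] +
      artifact$amplitude * sin(2 * pi * artifact$frequency_hz * t)
  } else if (artifact$kind == "BROADBAND_NOISE") {
    if (artifact$amplitude > 0) {
      y[idx] <- y[idx] + with_seed(seed,
        rnorm(length(idx), sd = artifact$amplitude))
    }
  } else {  # FLATLINE
    y[idx] <- 0
  }
  record$samples <- y
  record$label <- paste(c(record$label, artifact$kind), collapse = "+")
  record
}

#' Generate a labelled synthetic dataset
#'
#' Per-record seeds are derived deterministically from the master seed via a
#' counter hash, so datasets are reproducible element-wise. Heart rates are
#' jittered per record within the class-typical range so that each class has
#' within-class variability.
#'
#' @param class_counts named integer vector, e.g. `c(SR = 100, SB = 100)`;
#'   names are rhythm classes accepted by [rhythm_spec()].
#' @param duration record duration in seconds.
#' @param rate sampling rate in Hz.
#' @param seed master integer seed.
#' @param params a [wave_params()] object.
#' @return List of labelled [ecg_record()] objects, in request order.
#' @export
generate_dataset <- function(class_counts, duration = 10, rate = 250,
                             seed = 1, params = wave_params()) {
  ecg_check(all(class_counts >= 0), "class counts must be >= 0")
  if (length(class_counts) == 0 || sum(class_counts) == 0) return(list())
  hr_range <- list(SR = c(60, 100), SB = c(40, 55), ST_TACHY = c(105, 150),
                   AFIB_LIKE = c(70, 110), SVT_LIKE = c(160, 200))
  out <- vector("list", sum(class_counts))
  k <- 0L
  counter <- 0L
  for (cls in names(class_counts)) {
    for (i in seq_len(class_counts[[cls]])) {
      counter <- counter + 1L
      s <- derive_seed(seed, counter)
      hr <- with_seed(s, runif(1, hr_range[[cls]][1], hr_range[[cls]][2]))
      spec <- rhythm_spec(cls, heart_rate_bpm = hr)
      k <- k + 1L
      out[[k]] <- generate_record(spec, params, duration, rate,
                                  seed = derive_seed(s, 1),
                                  record_id = sprintf("%s_%03d", cls, i))
    }
  }
  out
}

#' Write / read a record list as CSV files with a JSON sidecar
#'
#' Each record becomes `<record_id>.csv` with columns `time_s, amplitude`;
#' `manifest.json` stores record ids, labels and sampling rates.
#'
#' @param records list of [ecg_record()] objects.
#' @param dir output directory (created if missing).
#' @return `write_record_dir` returns `dir` invisibly; `read_record_dir`
#'   returns the list of records.
#' @export
write_record_dir <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (r in records) {
    t <- (seq_along(r$samples) - 1) / r$sampling_rate_hz
    write.csv(data.frame(time_s = t, amplitude = r$samples),
              file.path(dir, paste0(r$record_id, ".csv")), row.names = FALSE)
    manifest[[r$record_id]] <- list(label = r$label,
                                    sampling_rate_hz = r$sampling_rate_hz)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_record_dir
#' @export
read_record_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  ecg_check(file.exists(man_path), "manifest.json not found",
            class = "ecgvae_parse_error")
  manifest <- jsonlite::read_json(man_path)
  lapply(names(manifest), function(id) {
    df <- read.csv(file.path(dir, paste0(id, ".csv")))
    if (!is.numeric(df$amplitude))
      ecg_abort(sprintf("non-numeric amplitude in record %s", id),
                "ecgvae_parse_error")
    ecg_record(df$amplitude, manifest[[id]]$sampling_rate_hz,
               label = manifest[[id]]$label %||% NULL, record_id = id)
  })
}
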