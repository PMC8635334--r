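# Preprocessing chain: Butterworth baseline removal, resampling to 250 Hz,
# z-score normalization, segmentation into fixed 2,048-sample windows.

#' Preprocessing configuration
#'
#' @param highpass_cutoff_hz high-pass cutoff removing baseline wander
#'   (default 0.5 Hz).
#' @param target_rate_hz resampling target (default 250 Hz).
#' @param window_len window length in samples at the target rate
#'   (default 2048, i.e. ~8.2 s at 250 Hz).
#' @param filter_order Butterworth order (default 2; applied
#'   forward-backward, so the effective attenuation is doubled).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_cutoff_hz = 0.5, target_rate_hz = 250,
                              window_len = 2048, filter_order = 2) {
  ecg_check(highpass_cutoff_hz > 0, "cutoff must be > 0")
  ecg_check(target_rate_hz > 2 * highpass_cutoff_hz,
            "target rate must exceed twice the cutoff")
  ecg_check(window_len > 0, "window_len must be > 0")
  ecg_check(filter_order >= 1, "filter_order must be >= 1")
  structure(list(highpass_cutoff_hz = highpass_cutoff_hz,
                 target_rate_hz = target_rate_hz,
                 window_len = as.integer(window_len),
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Remove baseline wander with a zero-phase Butterworth high-pass
#'
#' Applies a Butterworth high-pass of the configured order and cutoff
#' forward and backward (`signal::filtfilt`), so the phase response is zero
#' and ECG morphology is not skewed.
#'
#' @param samples numeric vector.
#' @param rate sampling rate of `samples` in Hz.
#' @param config a [preprocess_config()].
#' @return Filtered vector, same length as the input.
#' @export
remove_baseline <- function(samples, rate, config = preprocess_config()) {
  ecg_check(length(samples) > 3 * config$filter_order,
            "input too short for the filter order")
  ecg_check(rate > 2 * config$highpass_cutoff_hz,
            "sampling rate must exceed twice the cutoff")
  bf <- signal::butter(config$filter_order,
                       W = config$highpass_cutoff_hz / (rate / 2),
                       type = "high")
  # odd (point-reflected) padding suppresses the filter's edge transients,
  # which at a 0.5 Hz cutoff would otherwise persist for seconds
  n <- length(samples)
  np <- min(n - 1, ceiling(3 * rate / config$highpass_cutoff_hz))
  padded <- c(2 * samples[1] - samples[(np + 1):2],
              samples,
              2 * samples[n] - samples[(n - 1):(n - np)])
  as.numeric(signal::filtfilt(bf, padded))[(np + 1):(np + n)]
}

#' Resample by linear interpolation onto a uniform target grid
#'
#' Sample `i` (0-based) is taken to sit at time `i / rate`; the output has
#' `round(n * dst_rate / src_rate)` samples at times `j / dst_rate`. Target
#' times beyond the last source sample carry the last value forward.
#'
#' @param samples numeric vector (non-empty).
#' @param src_rate,dst_rate source and target sampling rates in Hz.
#' @return Resampled numeric vector.
#' @export
resample_signal <- function(samples, src_rate, dst_rate) {
  ecg_check(length(samples) > 0, "cannot resample an empty signal")
  ecg_check(src_rate > 0 && dst_rate > 0, "rates must be > 0")
  if (src_rate == dst_rate) return(as.numeric(samples))
  n <- length(samples)
  m <- round(n * dst_rate / src_rate)
  if (n == 1) return(rep(as.numeric(samples), m))
  src_t <- (seq_len(n) - 1) / src_rate
  dst_t <- (seq_len(m) - 1) / dst_rate
  approx(src_t, samples, xout = dst_t, method = "linear", rule = 2)$y
}

#' Z-score normalization (population standard deviation)
#'
#' @param samples numeric vector with population SD above `1e-8`.
#' @param record_id identifier used in the degenerate-input error message.
#' @return Normalized vector with mean 0 and population SD 1.
#' @export
znormalize <- function(samples, record_id = "") {
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  if (!is.finite(sigma) || sigma <= 1e-8)
    ecg_abort(sprintf("(near-)constant signal cannot be z-normalized%s",
                      if (nzchar(record_id)) paste0(" [", record_id, "]")
                      else ""),
              "ecgvae_degenerate_input", record_id = record_id)
  (samples - mu) / sigma
}

#' Cut a signal into non-overlapping fixed-length windows
#'
#' Consecutive windows of exactly `window_len` samples; a trailing remainder
#' shorter than `window_len` is discarded.
#'
#' @param samples numeric vector.
#' @param window_len window length in samples.
#' @param source_record_id id recorded on each window.
#' @return List of `window` objects with fields `values`,
#'   `source_record_id` and 0-based `start_index`.
#' @export
make_windows <- function(samples, window_len = 2048, source_record_id = "") {
  ecg_check(window_len > 0, "window_len must be > 0")
  window_len <- as.integer(window_len)
  k <- length(samples) %/% window_len
  lapply(seq_len(k), function(i) {
    start <- (i - 1L) * window_len
    structure(list(values = samples[(start + 1L):(start + window_len)],
                   source_record_id = source_record_id,
                   start_index = start),
              class = "window")
  })
}

#' Full preprocessing of one record
#'
#' Applies, in order: [remove_baseline()] at the native rate,
#' [resample_signal()] to the target rate, [znormalize()], and
#' [make_windows()]; each emitted window is then re-standardized so every
#' window has mean 0 and population SD 1 exactly (a no-op when the record
#' yields a single full-length window up to the discarded remainder).
#' Stage errors are re-raised with the stage name.
#'
#' @param record an [ecg_record()].
#' @param config a [preprocess_config()].
#' @return List of `window` objects (possibly empty).
#' @export
#' @examples
#' rec <- generate_record(rhythm_spec("SR"), duration = 10, rate = 250,
#'                        seed = 1)
#' w <- preprocess_record(rec)
#' length(w[[1]]$values)  # 2048
preprocess_record <- function(record, config = preprocess_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, ecgvae_error = function(e) {
      e$message <- sprintf("[%s] %s", name, conditionMessage(e))
      stop(e)
    })
  }
  x <- stage("remove_baseline",
             remove_baseline(record$samples, record$sampling_rate_hz, config))
  x <- stage("resample_signal",
             resample_signal(x, record$sampling_rate_hz,
                             config$target_rate_hz))
  x <- stage("znormalize", znormalize(x, record$record_id))
  ws <- make_windows(x, config$window_len,
                     source_record_id = record$record_id)
  stage("znormalize", lapply(ws, function(w) {
    w$values <- znormalize(w$values, record$record_id)
    w
  }))
}

# Stack a list of windows into an n x window_len matrix.
windows_to_matrix <- function(windows) {
  ecg_check(length(windows) > 0, "no windows to stack")
  do.call(rbind, lapply(windows, function(w) w$values))
}

#' Preprocess a list of records into a window matrix
#'
#' Convenience wrapper: preprocesses every record and stacks the resulting
#' windows into a matrix, carrying per-window labels and record ids.
#' Records that fail the degenerate-input guard (e.g. full flatlines) are
#' dropped with a warning rather than aborting the batch.
#'
#' @param records list of [ecg_record()] objects.
#' @param config a [preprocess_config()].
#' @return List with `windows` (n x window_len matrix), `labels`
#'   (character), `record_ids` (character).
#' @export
preprocess_records <- function(records, config = preprocess_config()) {
  rows <- list(); labels <- character(); ids <- character()
  for (rec in records) {
    ws <- tryCatch(preprocess_record(rec, config),
                   ecgvae_degenerate_input = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     list()
                   })
    for (w in ws) {
      rows[[length(rows) + 1L]] <- w$values
      labels <- c(labels, rec$label %||% NA_character_)
      ids <- c(ids, rec$record_id)
    }
  }
  ecg_check(length(rows) > 0, "no windows produced from the record list")
  list(windows = do.call(rbind, rows), labels = labels, record_ids = ids)
}
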