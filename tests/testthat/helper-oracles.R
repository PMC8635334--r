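# Independent oracle implementations used to cross-check the package's
# metric and threshold computations. Deliberately naive (loops, exhaustive
# scans) and kept separate from the implementation under test.

# Exhaustive grid scan: weighted F1 primary, abnormal-precision tie-break,
# then the largest threshold.
threshold_oracle <- function(scores, labels, step = 0.05) {
  thr <- (floor(min(scores) / step):ceiling(max(scores) / step)) * step
  best <- NULL
  for (th in thr) {
    pred <- as.integer(scores > th)
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    pr_a <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc_a <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1_a <- if (pr_a + rc_a > 0) 2 * pr_a * rc_a / (pr_a + rc_a) else 0
    pr_n <- if (tn + fn > 0) tn / (tn + fn) else 0
    rc_n <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1_n <- if (pr_n + rc_n > 0) 2 * pr_n * rc_n / (pr_n + rc_n) else 0
    w <- mean(labels == 1)
    cand <- list(th = th, wf1 = w * f1_a + (1 - w) * f1_n, prec = pr_a)
    if (is.null(best) || cand$wf1 > best$wf1 + 1e-12 ||
        (abs(cand$wf1 - best$wf1) <= 1e-12 &&
         (cand$prec > best$prec + 1e-12 ||
          (abs(cand$prec - best$prec) <= 1e-12 && cand$th > best$th))))
      best <- cand
  }
  best$th
}

# Naive per-class one-vs-rest metrics via explicit loops.
metrics_oracle <- function(true, pred) {
  classes <- sort(unique(true))
  f1 <- pr <- rc <- w <- numeric(length(classes))
  for (j in seq_along(classes)) {
    cl <- classes[j]
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (true[i] == cl && pred[i] == cl) tp <- tp + 1
      if (true[i] != cl && pred[i] == cl) fp <- fp + 1
      if (true[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    pr[j] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc[j] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (pr[j] + rc[j] > 0) 2 * pr[j] * rc[j] / (pr[j] + rc[j])
             else 0
    w[j] <- sum(true == cl) / length(true)
  }
  list(accuracy = mean(true == pred), weighted_f1 = sum(w * f1),
       f1 = f1, precision = pr, recall = rc)
}
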