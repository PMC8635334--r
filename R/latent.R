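# Feature extraction from the latent means, latent-space exploration by
# coordinate perturbation, and 2-D embedding (t-SNE / LLE) of features.

#' Extract the CVAE feature matrix
#'
#' Row i is the latent mean vector of window i. Deterministic (no
#' sampling).
#'
#' @param windows n x `input_len` matrix (or list of `window` objects).
#' @param model a trained `cvae_model`.
#' @return n x `latent_dim` numeric matrix.
#' @export
extract_features <- function(windows, model) {
  ecg_check(inherits(model, "cvae_model"), "model must be a cvae_model",
            class = "ecgvae_model_error")
  if (is.list(windows)) windows <- windows_to_matrix(windows)
  xarr <- as_input_array(windows, model$config$input_len)
  enc <- cvae_encode_fwd(model, xarr)
  mu <- enc$mu
  ecg_check(all(is.finite(mu)), "non-finite feature values",
            class = "ecgvae_model_error")
  rownames(mu) <- rownames(windows)
  mu
}

#' Perturb one latent coordinate and decode
#'
#' Decodes the latent mean, and the mean with `delta` subtracted from and
#' added to coordinate `index` (1-based). No sampling is involved.
#'
#' @param code a [latent_code()].
#' @param index coordinate to perturb, in `1..latent_dim`.
#' @param model a trained `cvae_model`.
#' @param delta perturbation size (default 2, i.e. two prior standard
#'   deviations).
#' @return List of class `perturbation_result` with `base`, `minus`,
#'   `plus` reconstructions (each length `input_len`) and `index`.
#' @export
perturb_and_decode <- function(code, index, model, delta = 2.0) {
  d <- model$config$latent_dim
  ecg_check(index >= 1 && index <= d,
            sprintf("index must lie in 1..%d", d))
  zm <- code$mu; zm[index] <- zm[index] - delta
  zp <- code$mu; zp[index] <- zp[index] + delta
  structure(list(base = decode(code$mu, model),
                 minus = decode(zm, model),
                 plus = decode(zp, model),
                 index = index, delta = delta),
            class = "perturbation_result")
}

# ---- t-SNE (exact, O(n^2)) ----------------------------------------------

# Conditional Gaussian affinities calibrated to a target perplexity by
# bisection on the precision.
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_embed <- function(X, perplexity = 30, n_iter = 500, seed = 1) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  ecg_check(perplexity >= 2, "too few rows for t-SNE")
  D2 <- as.matrix(dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  Y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 200; momentum <- 0.5
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100) P * 4 else P  # early exaggeration
    sum_Y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_Y, sum_Y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  Y
}

# ---- LLE ------------------------------------------------------------------

lle_embed <- function(X, n_neighbors = 10, reg = 1e-3) {
  n <- nrow(X)
  ecg_check(n > n_neighbors + 1, "too few rows for LLE")
  D <- as.matrix(dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(n_neighbors + 1)]
    Z <- sweep(X[nb, , drop = FALSE], 2, X[i, ])
    C <- tcrossprod(Z)
    C <- C + diag(reg * sum(diag(C)) / n_neighbors + 1e-12, n_neighbors)
    w <- solve(C, rep(1, n_neighbors))
    W[i, nb] <- w / sum(w)
  }
  M <- diag(n) - W
  M <- crossprod(M)
  e <- eigen(M, symmetric = TRUE)
  idx <- order(e$values)[2:3]  # skip the constant bottom eigenvector
  e$vectors[, idx, drop = FALSE] * sqrt(n)
}

#' Embed a feature matrix into 2-D
#'
#' t-SNE (exact gradient descent with perplexity-calibrated affinities and
#' early exaggeration) or locally linear embedding (local Gram systems,
#' bottom eigenvectors). Both are seeded and deterministic for a fixed
#' seed; LLE is deterministic outright.
#'
#' @param features n x d numeric matrix.
#' @param method `"tsne"` or `"lle"`.
#' @param seed integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   for small n).
#' @param n_neighbors LLE neighborhood size (default 10).
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(features, method = c("tsne", "lle"), seed = 1,
                     perplexity = 30, n_neighbors = 10) {
  method <- match.arg(method)
  features <- as.matrix(features)
  ecg_check(nrow(features) >= 10, "too few rows to embed")
  if (method == "tsne") tsne_embed(features, perplexity, seed = seed)
  else lle_embed(features, n_neighbors)
}
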