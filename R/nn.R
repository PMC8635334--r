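# Minimal 1-D neural-network core used by the CVAE and the transfer
# classifier: im2col convolutions, transposed convolutions, strided 1x1
# projection skips, dense layers, ReLU, length-preserving average pooling,
# and Adam. Activations are arrays with dim (length, channels, batch) so
# that the length dimension is column-major-contiguous.
#
# Every backward pass is verified against central finite differences in the
# test suite on tiny configurations.

# --- im2col / col2im ------------------------------------------------------

# Unfold x (L, C, n) into a (k*C) x (Lout*n) matrix of sliding windows.
# pl/pr are left/right zero padding; geometry must satisfy
# (L + pl + pr - k) %% stride == 0.
nn_im2col <- function(x, k, stride, pl, pr) {
  d <- dim(x); L <- d[1]; C <- d[2]; n <- d[3]
  Lp <- L + pl + pr
  Lout <- (Lp - k) %/% stride + 1L
  if (pl > 0 || pr > 0) {
    xp <- array(0, c(Lp, C, n))
    xp[(pl + 1):(pl + L), , ] <- x
  } else xp <- x
  idx <- outer(seq_len(k), (seq_len(Lout) - 1L) * stride, "+")  # k x Lout
  cols <- xp[as.vector(idx), , , drop = FALSE]                  # (k*Lout,C,n)
  dim(cols) <- c(k, Lout, C, n)
  cols <- aperm(cols, c(1, 3, 2, 4))                            # (k,C,Lout,n)
  dim(cols) <- c(k * C, Lout * n)
  list(mat = cols, idx = idx, Lp = Lp, L = L, C = C, n = n,
       Lout = Lout, k = k, pl = pl)
}

# Scatter-add the inverse of nn_im2col: colsmat is (k*C) x (Lout*n);
# returns (L, C, n).
nn_col2im <- function(colsmat, k, C, Lout, n, idx, Lp, pl, L) {
  dim(colsmat) <- c(k, C, Lout, n)
  colsmat <- aperm(colsmat, c(1, 3, 2, 4))  # (k, Lout, C, n)
  dxp <- array(0, c(Lp, C, n))
  for (j in seq_len(k)) {
    cj <- colsmat[j, , , , drop = FALSE]    # (1, Lout, C, n)
    rows <- idx[j, ]
    dxp[rows, , ] <- dxp[rows, , ] + as.vector(cj)
  }
  dxp[(pl + 1):(pl + L), , , drop = FALSE]
}

# "Same"-style padding for stride-s convolution with kernel k: total k - s,
# split floor/ceil, so Lout = L / s exactly (requires k >= s, s | L).
nn_pad_split <- function(k, stride) {
  total <- k - stride
  c(pl = total %/% 2L, pr = total - total %/% 2L)
}

# --- convolution ----------------------------------------------------------

# W: (k*Cin) x Cout; b: Cout. x: (L, Cin, n) -> y: (L/stride, Cout, n).
nn_conv_fwd <- function(x, W, b, k, stride) {
  p <- nn_pad_split(k, stride)
  ic <- nn_im2col(x, k, stride, p[1], p[2])
  y <- crossprod(ic$mat, W)                  # (Lout*n) x Cout
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(ic$Lout, ic$n, length(b))
  list(y = aperm(y, c(1, 3, 2)), ic = ic)
}

nn_conv_bwd <- function(dy, W, cache) {
  ic <- cache$ic
  Cout <- dim(dy)[2]
  dym <- aperm(dy, c(1, 3, 2))
  dim(dym) <- c(ic$Lout * ic$n, Cout)
  dW <- ic$mat %*% dym
  db <- colSums(dym)
  dcols <- tcrossprod(W, dym)                # (k*Cin) x (Lout*n)
  dx <- nn_col2im(dcols, ic$k, ic$C, ic$Lout, ic$n, ic$idx, ic$Lp,
                  ic$pl, ic$L)
  list(dx = dx, dW = dW, db = db)
}

# --- transposed convolution ----------------------------------------------

# W: (k*Cout) x Cin; b: Cout. x: (Lin, Cin, n) -> y: (Lin*stride, Cout, n).
# Geometry is the mirror image of nn_conv_fwd (col2im on the output grid).
nn_tconv_fwd <- function(x, W, b, k, stride) {
  d <- dim(x); Lin <- d[1]; Cin <- d[2]; n <- d[3]
  Lout <- Lin * stride
  Cout <- length(b)
  p <- nn_pad_split(k, stride)
  Lp <- Lout + p[1] + p[2]
  idx <- outer(seq_len(k), (seq_len(Lin) - 1L) * stride, "+")
  xm <- aperm(x, c(1, 3, 2)); dim(xm) <- c(Lin * n, Cin)
  colsm <- tcrossprod(W, xm)                 # (k*Cout) x (Lin*n)
  y <- nn_col2im(colsm, k, Cout, Lin, n, idx, Lp, p[1], Lout)
  y <- y + rep(b, each = Lout)               # recycles over batch
  list(y = y, xm = xm, k = k, stride = stride, p = p, Lin = Lin,
       Cin = Cin, n = n, Cout = Cout)
}

nn_tconv_bwd <- function(dy, W, cache) {
  k <- cache$k; stride <- cache$stride; p <- cache$p
  ic <- nn_im2col(dy, k, stride, p[1], p[2]) # (k*Cout) x (Lin*n)
  dxm <- crossprod(ic$mat, W)                # (Lin*n) x Cin
  dW <- ic$mat %*% cache$xm
  db <- apply(dy, 2, sum)
  dim(dxm) <- c(cache$Lin, cache$n, cache$Cin)
  list(dx = aperm(dxm, c(1, 3, 2)), dW = dW, db = db)
}

# --- strided 1x1 projection (residual skip) -------------------------------

# W: Cin x Cout; subsamples positions 1, 1+s, ... then maps channels.
nn_proj_fwd <- function(x, W, b, stride) {
  d <- dim(x); L <- d[1]; Cin <- d[2]; n <- d[3]
  Lout <- L %/% stride
  pos <- seq(1L, by = stride, length.out = Lout)
  xs <- x[pos, , , drop = FALSE]
  xm <- aperm(xs, c(1, 3, 2)); dim(xm) <- c(Lout * n, Cin)
  y <- xm %*% W
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(Lout, n, length(b))
  list(y = aperm(y, c(1, 3, 2)), xm = xm, pos = pos, L = L,
       Cin = Cin, n = n, Lout = Lout)
}

nn_proj_bwd <- function(dy, W, cache) {
  Cout <- dim(dy)[2]
  dym <- aperm(dy, c(1, 3, 2)); dim(dym) <- c(cache$Lout * cache$n, Cout)
  dW <- crossprod(cache$xm, dym)
  db <- colSums(dym)
  dxm <- tcrossprod(dym, W)
  dim(dxm) <- c(cache$Lout, cache$n, cache$Cin)
  dxs <- aperm(dxm, c(1, 3, 2))
  dx <- array(0, c(cache$L, cache$Cin, cache$n))
  dx[cache$pos, , ] <- dxs
  list(dx = dx, dW = dW, db = db)
}

# --- dense / relu / average pooling ---------------------------------------

nn_dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(y))
}

nn_dense_bwd <- function(dy, x, W) {
  list(dx = tcrossprod(dy, W), dW = crossprod(x, dy), db = colSums(dy))
}

nn_relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

nn_relu_bwd <- function(dy, y) {
  dy * (y > 0)
}

# Length-preserving 3-point moving average with replicated edges,
# along the first dimension of (L, C, n).
nn_avgpool3_fwd <- function(x) {
  L <- dim(x)[1]
  xl <- x[c(1L, seq_len(L - 1L)), , , drop = FALSE]
  xr <- x[c(seq_len(L - 1L) + 1L, L), , , drop = FALSE]
  (xl + x + xr) / 3
}

nn_avgpool3_bwd <- function(dy) {
  L <- dim(dy)[1]
  dx <- dy / 3
  dx[seq_len(L - 1L), , ] <- dx[seq_len(L - 1L), , , drop = FALSE] +
    dy[seq_len(L - 1L) + 1L, , , drop = FALSE] / 3
  dx[seq_len(L - 1L) + 1L, , ] <- dx[seq_len(L - 1L) + 1L, , , drop = FALSE] +
    dy[seq_len(L - 1L), , , drop = FALSE] / 3
  dx[1L, , ] <- dx[1L, , , drop = FALSE] + dy[1L, , , drop = FALSE] / 3
  dx[L, , ] <- dx[L, , , drop = FALSE] + dy[L, , , drop = FALSE] / 3
  dx
}

# --- Adam -----------------------------------------------------------------

nn_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
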