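## Compact 1-D convolutional network baseline, implemented natively.
##
## Architecture: two convolutional blocks, each of two convolutional layers
## (five filters of width two, ReLU) followed by max pooling (size 2) and
## dropout; then one fully connected ReLU layer and a final fully connected
## sigmoid unit.  Trained with binary cross-entropy and the Adam optimizer
## at its default parameters.  The implementation is deliberately small and
## dependency-free; gradients are exact (verified against numerical
## differentiation in the test suite).

cnn_init <- function(input_len, hidden = 8L, filters = 5L, width = 2L) {
  L <- input_len
  dims <- c(L - 1L, L - 2L)
  p1 <- (L - 2L) %/% 2L
  dims <- c(dims, p1, p1 - 1L, p1 - 2L)
  p2 <- (p1 - 2L) %/% 2L
  if (p2 < 1L) stop_invalid("input shorter than the network's receptive field")
  flat <- p2 * filters
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  mk <- function(cin) array(he(width * cin, width * cin * filters),
                            dim = c(width, cin, filters))
  list(W1 = mk(1L), b1 = numeric(filters),
       W2 = mk(filters), b2 = numeric(filters),
       W3 = mk(filters), b3 = numeric(filters),
       W4 = mk(filters), b4 = numeric(filters),
       W5 = matrix(he(flat, flat * hidden), flat, hidden), b5 = numeric(hidden),
       W6 = matrix(he(hidden, hidden), hidden, 1L), b6 = 0,
       input_len = L, hidden = hidden, filters = filters, width = width)
}

conv1d_fwd <- function(x, W, b) {
  ## x: L x Cin, W: width x Cin x Cout -> (L - width + 1) x Cout
  w <- dim(W)[1]; Lo <- nrow(x) - w + 1L; Cout <- dim(W)[3]
  out <- matrix(rep(b, each = Lo), Lo, Cout)
  for (d in seq_len(w)) {
    Wd <- matrix(W[d, , ], nrow = dim(W)[2])  # Cin x Cout
    out <- out + x[d:(d + Lo - 1L), , drop = FALSE] %*% Wd
  }
  out
}

conv1d_bwd <- function(x, W, dout) {
  w <- dim(W)[1]; Lo <- nrow(dout)
  dW <- array(0, dim(W)); db <- colSums(dout)
  dx <- matrix(0, nrow(x), ncol(x))
  for (d in seq_len(w)) {
    xs <- x[d:(d + Lo - 1L), , drop = FALSE]
    dW[d, , ] <- crossprod(xs, dout)
    Wd <- matrix(W[d, , ], nrow = dim(W)[2])
    dx[d:(d + Lo - 1L), ] <- dx[d:(d + Lo - 1L), ] + dout %*% t(Wd)
  }
  list(dW = dW, db = db, dx = dx)
}

pool_fwd <- function(x) {
  Lo <- nrow(x) %/% 2L
  idx <- matrix(0L, Lo, ncol(x))
  out <- matrix(0, Lo, ncol(x))
  for (t in seq_len(Lo)) {
    a <- x[2L * t - 1L, ]; b <- x[2L * t, ]
    take_a <- a >= b
    out[t, ] <- ifelse(take_a, a, b)
    idx[t, ] <- ifelse(take_a, 2L * t - 1L, 2L * t)
  }
  list(out = out, idx = idx)
}

pool_bwd <- function(dout, idx, L) {
  dx <- matrix(0, L, ncol(dout))
  for (t in seq_len(nrow(dout)))
    for (c in seq_len(ncol(dout)))
      dx[idx[t, c], c] <- dx[idx[t, c], c] + dout[t, c]
  dx
}

cnn_forward <- function(par, x, dropout = 0, train = FALSE) {
  cache <- list(x0 = matrix(x, ncol = 1L))
  relu <- function(z) pmax(z, 0)
  drop_mask <- function(m) {
    if (train && dropout > 0)
      matrix(stats::rbinom(length(m), 1L, 1 - dropout) / (1 - dropout),
             nrow(m), ncol(m))
    else matrix(1, nrow(m), ncol(m))
  }
  cache$z1 <- conv1d_fwd(cache$x0, par$W1, par$b1); cache$a1 <- relu(cache$z1)
  cache$z2 <- conv1d_fwd(cache$a1, par$W2, par$b2); cache$a2 <- relu(cache$z2)
  p1 <- pool_fwd(cache$a2); cache$p1 <- p1
  cache$m1 <- drop_mask(p1$out); cache$d1 <- p1$out * cache$m1
  cache$z3 <- conv1d_fwd(cache$d1, par$W3, par$b3); cache$a3 <- relu(cache$z3)
  cache$z4 <- conv1d_fwd(cache$a3, par$W4, par$b4); cache$a4 <- relu(cache$z4)
  p2 <- pool_fwd(cache$a4); cache$p2 <- p2
  cache$m2 <- drop_mask(p2$out); cache$d2 <- p2$out * cache$m2
  cache$flat <- as.numeric(cache$d2)
  cache$z5 <- as.numeric(crossprod(par$W5, cache$flat)) + par$b5
  cache$a5 <- relu(cache$z5)
  cache$z6 <- sum(par$W6 * cache$a5) + par$b6
  cache$p <- 1 / (1 + exp(-cache$z6))
  cache
}

cnn_backward <- function(par, cache, y) {
  g <- list()
  dz6 <- cache$p - y  # d BCE / d z6
  g$W6 <- matrix(cache$a5 * dz6, ncol = 1L); g$b6 <- dz6
  da5 <- as.numeric(par$W6) * dz6
  dz5 <- da5 * (cache$z5 > 0)
  g$W5 <- outer(cache$flat, dz5); g$b5 <- dz5
  dflat <- as.numeric(par$W5 %*% dz5)
  dd2 <- matrix(dflat, nrow(cache$d2), ncol(cache$d2)) * cache$m2
  da4 <- pool_bwd(dd2, cache$p2$idx, nrow(cache$a4))
  dz4 <- da4 * (cache$z4 > 0)
  bw <- conv1d_bwd(cache$a3, par$W4, dz4); g$W4 <- bw$dW; g$b4 <- bw$db
  dz3 <- bw$dx * (cache$z3 > 0)
  bw <- conv1d_bwd(cache$d1, par$W3, dz3); g$W3 <- bw$dW; g$b3 <- bw$db
  dd1 <- bw$dx * cache$m1
  da2 <- pool_bwd(dd1, cache$p1$idx, nrow(cache$a2))
  dz2 <- da2 * (cache$z2 > 0)
  bw <- conv1d_bwd(cache$a1, par$W2, dz2); g$W2 <- bw$dW; g$b2 <- bw$db
  dz1 <- bw$dx * (cache$z1 > 0)
  bw <- conv1d_bwd(cache$x0, par$W1, dz1); g$W1 <- bw$dW; g$b1 <- bw$db
  g
}

.cnn_wnames <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4",
                 "W5", "b5", "W6", "b6")

#' Train the compact CNN baseline
#'
#' @param x numeric matrix of fixed-length RR windows (samples in rows;
#'   standardize beforehand).
#' @param y logical or 0/1 vector (positive class = 1).
#' @param dropout dropout rate of the two pooling blocks.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam step size (Adam's other parameters at their defaults).
#' @param hidden width of the fully connected ReLU layer.
#' @param seed optional RNG seed (initialization, shuffling, dropout).
#' @return an object of class \code{heat_cnn}.
#' @export
train_cnn <- function(x, y, dropout = 0.2, epochs = 100L, batch_size = 32L,
                      lr = 1e-3, hidden = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  par <- cnn_init(ncol(x), hidden = hidden)
  adam_m <- lapply(par[.cnn_wnames], function(w) w * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        cache <- cnn_forward(par, x[i, ], dropout = dropout, train = TRUE)
        g <- cnn_backward(par, cache, y[i])
        acc <- if (is.null(acc)) g
               else Map(`+`, acc, g[names(acc)])
      }
      t <- t + 1
      for (w in .cnn_wnames) {
        gw <- acc[[w]] / length(idx)
        adam_m[[w]] <- b1 * adam_m[[w]] + (1 - b1) * gw
        adam_v[[w]] <- b2 * adam_v[[w]] + (1 - b2) * gw^2
        mhat <- adam_m[[w]] / (1 - b1^t)
        vhat <- adam_v[[w]] / (1 - b2^t)
        par[[w]] <- par[[w]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(par = par, dropout = dropout), class = "heat_cnn")
}

#' @rdname train_cnn
#' @param model a trained \code{heat_cnn}.
#' @return \code{predict_cnn}: sigmoid probabilities in (0, 1), one per row.
#' @export
predict_cnn <- function(model, x) {
  x <- as.matrix(x)
  vapply(seq_len(nrow(x)), function(i)
    cnn_forward(model$par, x[i, ], train = FALSE)$p, numeric(1))
}
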