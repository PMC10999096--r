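#' @title Feed-forward neural network (multi-hidden-layer)
#' @description A compact, fully deterministic multilayer perceptron used
#'   for the DNN scoring-function variant (two or more hidden layers; the
#'   single-hidden-layer ANN variant is fitted with `nnet`). ReLU hidden
#'   units, sigmoid (classification) or linear (regression) output,
#'   inverted dropout, and Adam optimization on mini-batches.
#' @name mlp
#' @keywords internal
NULL

.mlp_init <- function(sizes) {
  # He-uniform initialization per layer
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    lim <- sqrt(6 / sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

#' Fit a multilayer perceptron
#'
#' @param x numeric matrix (rows = samples).
#' @param y numeric response: 0/1 for classification, real for regression.
#' @param hidden integer vector of hidden layer widths (length >= 2 for
#'   the DNN contract).
#' @param mode `"classification"` or `"regression"`.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param dropout dropout rate on hidden activations in `[0, 1)`.
#' @param seed RNG seed (weights, shuffling, dropout).
#' @return object of class `mlp_net`.
#' @keywords internal
mlp_fit <- function(x, y, hidden = c(64, 32),
                    mode = c("classification", "regression"),
                    lr = 1e-3, epochs = 60, batch_size = 32,
                    dropout = 0, seed = 1) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  n <- nrow(x)
  set.seed(seed)
  sizes <- c(ncol(x), hidden, 1L)
  par <- .mlp_init(sizes)
  nl <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1, n)]
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      # forward
      act <- list(xb); masks <- list()
      for (l in seq_len(nl)) {
        z <- sweep(act[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
        if (l < nl) {
          z <- pmax(z, 0)
          if (dropout > 0) {
            m <- matrix(stats::runif(length(z)) >= dropout, nrow(z), ncol(z))
            z <- z * m / (1 - dropout)
            masks[[l]] <- m
          }
        }
        act[[l + 1]] <- z
      }
      out <- act[[nl + 1]][, 1]
      # output-layer delta: both losses reduce to (prediction - target)
      pred <- if (mode == "classification") stats::plogis(out) else out
      delta <- matrix((pred - yb) / length(bi), ncol = 1)
      # backward
      t <- t + 1
      for (l in rev(seq_len(nl))) {
        gW <- t(act[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(par$W[[l]])
          delta <- delta * (act[[l]] > 0)
          if (dropout > 0 && !is.null(masks[[l - 1]]))
            delta <- delta * masks[[l - 1]] / (1 - dropout)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        par$W[[l]] <- par$W[[l]] -
          lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        par$b[[l]] <- par$b[[l]] -
          lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
  }
  structure(list(par = par, mode = mode, p = ncol(x), hidden = hidden),
            class = "mlp_net")
}

#' @export
predict.mlp_net <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$p) stop("feature count mismatch")
  a <- x
  nl <- length(object$par$W)
  for (l in seq_len(nl)) {
    a <- sweep(a %*% object$par$W[[l]], 2, object$par$b[[l]], "+")
    if (l < nl) a <- pmax(a, 0)
  }
  out <- a[, 1]
  if (object$mode == "classification") stats::plogis(out) else out
}
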