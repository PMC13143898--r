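# Single-hidden-layer ReLU multilayer perceptron for regression, trained
# with Adam on the mean-squared error.  Inputs and target are standardized
# internally; weights use He initialization.

mlpFit <- function(x, y, hidden = 100L, epochs = 400L, lr = 0.01,
                   seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xm <- colMeans(x)
  xs <- pmax(apply(x, 2L, stats::sd), 1e-8)
  ym <- mean(y); ys <- max(stats::sd(y), 1e-8)
  X <- sweep(sweep(x, 2L, xm), 2L, xs, "/")
  Y <- (y - ym) / ys
  withSeed(seed, {
    W1 <- matrix(rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden, 0, sqrt(2 / hidden)), hidden, 1L)
    b2 <- 0
    mW1 <- vW1 <- matrix(0, p, hidden); mb1 <- vb1 <- numeric(hidden)
    mW2 <- vW2 <- matrix(0, hidden, 1L); mb2 <- vb2 <- 0
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    for (t in seq_len(epochs)) {
      A <- X %*% W1 + matrix(b1, n, hidden, byrow = TRUE)
      H <- pmax(A, 0)                      # ReLU
      pred <- as.vector(H %*% W2 + b2)
      d <- 2 * (pred - Y) / n
      gW2 <- crossprod(H, d); gb2 <- sum(d)
      dH <- outer(d, as.vector(W2)) * (A > 0)
      gW1 <- crossprod(X, dH); gb1 <- colSums(dH)
      adam <- function(m, v, g) {
        m <- b1m * m + (1 - b1m) * g
        v <- b2m * v + (1 - b2m) * g^2
        mh <- m / (1 - b1m^t); vh <- v / (1 - b2m^t)
        list(m = m, v = v, step = lr * mh / (sqrt(vh) + eps))
      }
      u <- adam(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
      u <- adam(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
      u <- adam(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
      u <- adam(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, xm = xm, xs = xs,
                   ym = ym, ys = ys), class = "uavMlp")
  })
}

#' @export
predict.uavMlp <- function(object, newdata, ...) {
  X <- sweep(sweep(as.matrix(newdata), 2L, object$xm), 2L, object$xs, "/")
  H <- pmax(X %*% object$W1 +
              matrix(object$b1, nrow(X), length(object$b1), byrow = TRUE), 0)
  as.vector(H %*% object$W2 + object$b2) * object$ys + object$ym
}
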