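#' Outer-product (Hebbian) rule
#'
#' Sets the weights to the empirical correlation of the patterns mapped to
#' spins, `W = (1/m) sum_x s(x) s(x)'` with `s(x) = 2x - 1`, zero diagonal and
#' zero thresholds. The classical one-shot associative-memory rule; spins are
#' confined to this trainer, all dynamics stay in `{0,1}`.
#'
#' @param data a `pattern_set` or binary matrix. Pattern weights are used as
#'   mixture proportions.
#' @return a `hopfield_network`.
#' @export
train_opr <- function(data) {
  data <- as_pattern_set(data)
  S <- 2 * data$patterns - 1
  W <- crossprod(sqrt(data$weights) * S)
  diag(W) <- 0
  hopfield_network(W, rep(0, ncol(S)), validate = FALSE)
}

#' Perceptron rule
#'
#' Runs, for each node `i`, perceptron updates on the linear problem
#' `H(W_i' x - theta_i)` versus target `x_i` over all patterns; weight
#' updates are symmetrized and the diagonal zeroed after every epoch so the
#' result is a valid Hopfield network. Training stops early once every
#' pattern is a fixed point; otherwise the iterate with the highest storage
#' fraction seen (pocket) is returned with a warning.
#'
#' @inheritParams train_opr
#' @param epochs maximum number of epochs.
#' @param lr learning rate.
#' @param quiet suppress the non-convergence warning.
#' @return a `hopfield_network`.
#' @export
train_perceptron <- function(data, epochs = 200, lr = 0.1, quiet = FALSE) {
  data <- as_pattern_set(data)
  X <- data$patterns
  n <- ncol(X)
  W <- matrix(0, n, n)
  theta <- rep(0, n)
  best <- list(W = W, theta = theta, frac = -1)
  for (ep in seq_len(epochs)) {
    FF <- sweep(X %*% W, 2, theta)
    pred <- (FF > 0) + 0L
    err <- X - pred                      # +1: should fire, -1: should not
    frac <- mean(rowSums(err != 0) == 0)
    if (frac > best$frac) best <- list(W = W, theta = theta, frac = frac)
    if (frac == 1) return(hopfield_network(W, theta, validate = FALSE))
    dW <- crossprod(err, X)
    dW <- (dW + t(dW)) / 2
    diag(dW) <- 0
    W <- W + lr * dW
    theta <- theta - lr * colSums(err)
  }
  FF <- sweep(X %*% W, 2, theta)
  if (mean(rowSums((X - ((FF > 0) + 0L)) != 0) == 0) >= best$frac)
    best <- list(W = W, theta = theta)
  if (!quiet)
    warning("perceptron training did not store all patterns; returning pocket iterate")
  hopfield_network(best$W, best$theta, validate = FALSE)
}

#' Delta rule (logistic least mean squares)
#'
#' Gradient descent on `sum_x sum_i (x_i - sigma(F_i(x)))^2` with the
#' logistic map `sigma(r) = 1 / (1 + exp(-r))` (slope 1), symmetrizing the
#' weight step and zeroing the diagonal each epoch. The objective is
#' non-increasing for small learning rates (a backtracking halving is applied
#' when a step would increase it).
#'
#' @inheritParams train_perceptron
#' @return a `hopfield_network`; attribute `"trace"` holds the objective per
#'   epoch.
#' @export
train_delta <- function(data, epochs = 200, lr = 0.5) {
  data <- as_pattern_set(data)
  X <- data$patterns
  n <- ncol(X)
  W <- matrix(0, n, n)
  theta <- rep(0, n)
  objective <- function(W, theta) {
    P <- stats::plogis(sweep(X %*% W, 2, theta))
    sum((X - P)^2)
  }
  obj <- objective(W, theta)
  trace <- numeric(0)
  for (ep in seq_len(epochs)) {
    trace <- c(trace, obj)
    P <- stats::plogis(sweep(X %*% W, 2, theta))
    Gmat <- -2 * (X - P) * P * (1 - P)   # d obj / d F
    gW <- crossprod(Gmat, X)
    gW <- (gW + t(gW)) / 2
    diag(gW) <- 0
    gth <- -colSums(Gmat)
    repeat {
      Wc <- W - lr * gW
      thc <- theta - lr * gth
      newobj <- objective(Wc, thc)
      if (newobj <= obj || lr < 1e-12) break
      lr <- lr / 2
    }
    if (newobj > obj) break
    W <- Wc; theta <- thc; obj <- newobj
  }
  net <- hopfield_network(W, theta, validate = FALSE)
  attr(net, "trace") <- trace
  net
}
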