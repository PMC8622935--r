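#' Energy flow of a network on data
#'
#' The convex training objective
#' `EF(W, theta) = sum_x q_x sum_{x' in N1(x)} exp((E_x - E_{x'}) / 2)`,
#' where `N1(x)` is the set of states one bit flip from `x`. The energy
#' difference for flipping bit `i` is `E_x - E_{x'} = dx_i F_i` with
#' `dx_i = 1 - 2 x_i` and `F_i` the feedforward input, so the whole objective
#' is computed in `O(m n^2)` without enumerating states. Driving EF towards
#' zero forces every data pattern to be a fixed point of the dynamics
#' (every flip exponent, hence every `dx_i F_i`, is pushed negative).
#'
#' @param net a `hopfield_network`.
#' @param data a `pattern_set` (or binary matrix coerced to one).
#' @return scalar positive objective value.
#' @export
energy_flow <- function(net, data) {
  data <- as_pattern_set(data)
  if (n_nodes(data) != net$n) stop("data width does not match network size")
  ef_pieces(net, data)$ef
}

# Shared forward pass: flip exponents and their exponentials.
ef_pieces <- function(net, data) {
  X <- data$patterns
  FF <- X %*% net$W
  FF <- sweep(FF, 2, net$theta)        # F[x, i] = W_i' x - theta_i
  D <- 1 - 2 * X                       # dx_i = 1 - 2 x_i
  A <- exp((D * FF) / 2)               # one term per (pattern, flipped bit)
  list(X = X, D = D, A = A, ef = sum(data$weights * rowSums(A)))
}

#' Gradient of the energy flow
#'
#' Exact analytic gradient of [energy_flow()] with respect to the symmetric
#' zero-diagonal weight matrix and the thresholds. The weight gradient is
#' symmetrized (one parameter per unordered pair) and has zero diagonal; the
#' descent direction of the training rule is its negative.
#'
#' @inheritParams energy_flow
#' @return list with `gradW` (symmetric, zero diagonal) and `gradtheta`.
#' @export
ef_gradient <- function(net, data) {
  data <- as_pattern_set(data)
  if (n_nodes(data) != net$n) stop("data width does not match network size")
  pc <- ef_pieces(net, data)
  B <- (data$weights * (pc$A * pc$D)) / 2
  G <- crossprod(B, pc$X)
  gradW <- G + t(G)
  diag(gradW) <- 0
  list(gradW = gradW, gradtheta = -colSums(B))
}

#' Single-pattern update direction (local learning rule)
#'
#' The raw, unsymmetrized descent direction of the single-pattern energy
#' flow: `dW[i, j] = -x_j dx_i exp(dx_i F_i / 2)` and
#' `dtheta[i] = dx_i exp(dx_i F_i / 2)`. Each entry depends only on the
#' states and feedforward inputs of the two nodes it connects, which is what
#' makes the rule local: when pre- and postsynaptic nodes are both active and
#' the drive `F_i` is still negative the weight is strengthened
#' (potentiation), opposite activity weakens it (depression), and the factor
#' `exp(-F_i / 2)` attenuates potentiation as the drive grows (homeostasis).
#' Symmetrizing `dW` (done by [mef_online_step()]) leaves the energy function
#' unchanged.
#'
#' @param net a `hopfield_network`.
#' @param x a single binary pattern.
#' @return list with `dW` (unsymmetrized) and `dtheta`.
#' @export
mef_update_raw <- function(net, x) {
  x <- check_pattern(net, x)
  FF <- drop(net$W %*% x) - net$theta
  D <- 1 - 2 * x
  a <- exp(D * FF / 2)
  dW <- -outer(D * a, as.numeric(x))
  diag(dW) <- 0
  list(dW = dW, dtheta = D * a)
}

#' One online MEF step
#'
#' One exact gradient step of the single-pattern energy flow with step size
#' `lr`: the symmetrized weight direction coincides with the local rule of
#' [mef_update_raw()], and the threshold direction with half of its raw
#' form (the rule is stated up to a proportionality constant; the gradient
#' fixes it).
#'
#' @inheritParams mef_update_raw
#' @param lr positive learning rate.
#' @return the updated `hopfield_network`.
#' @export
mef_online_step <- function(net, x, lr) {
  if (lr <= 0) stop("lr must be positive")
  g <- ef_gradient(net, pattern_set(matrix(x, 1)))
  hopfield_network(net$W - lr * g$gradW, net$theta - lr * g$gradtheta,
                   validate = FALSE)
}

#' Training options for minimum energy flow
#'
#' @param max_iterations iteration cap for the optimizer.
#' @param tolerance stopping tolerance on the gradient (infinity norm for the
#'   first-order optimizer; projected-gradient tolerance for L-BFGS).
#' @param optimizer `"lbfgs"` (quasi-Newton, the default) or `"gd"`
#'   (first-order descent with backtracking line search). The objective is
#'   convex, so the choice affects speed only.
#' @param learning_rate initial step size for `"gd"` and for online training.
#' @param seed optional integer seed applied before training (training itself
#'   is deterministic from the zero start; the seed matters only for callers
#'   that randomize e.g. data order around it).
#' @return list of class `mef_options`.
#' @export
mef_options <- function(max_iterations = 200, tolerance = 1e-6,
                        optimizer = c("lbfgs", "gd"), learning_rate = 0.1,
                        seed = NULL) {
  optimizer <- match.arg(optimizer)
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, optimizer = optimizer,
                 learning_rate = learning_rate, seed = seed),
            class = "mef_options")
}

#' Train a Hopfield network by minimum energy flow
#'
#' Minimizes the convex objective [energy_flow()] over the strict upper
#' triangle of `W` and the thresholds, starting from the zero network (the
#' canonical, reproducible start for a convex problem). Returns the best
#' iterate; if the iteration cap is reached before the gradient tolerance a
#' warning is issued and the best iterate is returned (the objective has no
#' finite minimizer for some degenerate data sets, e.g. a single pattern
#' whose thresholds can be scaled indefinitely).
#'
#' @param data a `pattern_set` (or binary matrix). Duplicate patterns carry
#'   their empirical frequency as weight.
#' @param opts a [mef_options()] object.
#' @param quiet suppress the non-convergence warning.
#' @return a `hopfield_network`; attribute `"trace"` holds the objective per
#'   accepted iteration and attribute `"converged"` the stopping status.
#' @examples
#' ps <- pattern_set(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
#' net <- train_mef(ps, mef_options(max_iterations = 100))
#' is_fixed_point(net, c(1, 1, 0, 0))
#' @export
train_mef <- function(data, opts = mef_options(), quiet = FALSE) {
  data <- as_pattern_set(data)
  if (!is.null(opts$seed)) set.seed(opts$seed)
  n <- n_nodes(data)
  X <- data$patterns
  D <- 1 - 2 * X
  w <- data$weights
  nw <- n * (n - 1L) / 2L
  ut <- upper.tri(matrix(0, n, n))
  trace <- numeric(0)

  eval_ef <- function(par) {
    net <- network_from_par(par, n)
    FF <- sweep(X %*% net$W, 2, net$theta)
    A <- exp((D * FF) / 2)
    ef <- sum(w * rowSums(A))
    B <- (w * (A * D)) / 2
    G <- crossprod(B, X)
    gradW <- G + t(G)
    list(ef = ef, grad = c(gradW[ut], -colSums(B)))
  }

  par <- numeric(nw + n)
  if (opts$optimizer == "lbfgs") {
    last <- NULL
    fn <- function(p) {
      last <<- eval_ef(p)
      trace <<- c(trace, last$ef)
      last$ef
    }
    gr <- function(p) last$grad
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = opts$max_iterations,
                                       pgtol = opts$tolerance,
                                       factr = 10))
    par <- res$par
    converged <- res$convergence == 0
  } else {
    step <- opts$learning_rate
    cur <- eval_ef(par)
    converged <- FALSE
    for (it in seq_len(opts$max_iterations)) {
      trace <- c(trace, cur$ef)
      if (max(abs(cur$grad)) < opts$tolerance) { converged <- TRUE; break }
      repeat {
        cand <- par - step * cur$grad
        nxt <- eval_ef(cand)
        if (nxt$ef <= cur$ef) break
        step <- step / 2
        if (step < 1e-14) break
      }
      if (nxt$ef > cur$ef) break
      par <- cand
      cur <- nxt
      step <- step * 1.3
    }
  }
  if (!converged && !quiet)
    warning("MEF training stopped at the iteration cap; returning best iterate")
  net <- network_from_par(par, n)
  attr(net, "trace") <- trace
  attr(net, "converged") <- converged
  net
}
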