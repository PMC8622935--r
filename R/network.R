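#' Construct a Hopfield network
#'
#' A Hopfield network on `n` binary nodes is a pair `(W, theta)` of a real
#' symmetric weight matrix with zero diagonal and a threshold vector. The
#' energy of a state `x` in `{0,1}^n` is `E(x) = -x'Wx/2 + x'theta`, and the
#' asynchronous threshold dynamics never increase it.
#'
#' @param weights n x n numeric matrix; must be exactly symmetric with zero
#'   diagonal.
#' @param thresholds numeric vector of length n; finite.
#' @param validate set to `FALSE` to skip invariant checks (internal use on
#'   matrices already known to be valid).
#' @return an object of class `hopfield_network` with fields `n`, `W`, `theta`.
#' @examples
#' net <- hopfield_network(matrix(c(0, 2, 2, 0), 2), c(0, 0))
#' energy(net, c(1, 1))
#' @export
hopfield_network <- function(weights, thresholds, validate = TRUE) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  thresholds <- as.numeric(thresholds)
  n <- length(thresholds)
  if (validate) {
    if (nrow(weights) != n || ncol(weights) != n)
      stop("weights must be a ", n, " x ", n, " matrix to match thresholds")
    if (!all(is.finite(weights)) || !all(is.finite(thresholds)))
      stop("weights and thresholds must be finite")
    if (!identical(weights, t(weights)))
      stop("weights must be exactly symmetric")
    if (any(diag(weights) != 0))
      stop("weights must have zero diagonal")
  }
  structure(list(n = n, W = weights, theta = thresholds),
            class = "hopfield_network")
}

#' @export
print.hopfield_network <- function(x, ...) {
  cat("Hopfield network on", x$n, "nodes\n")
  cat("  |W| range: [", format(min(x$W)), ",", format(max(x$W)), "]\n")
  cat("  theta range: [", format(min(x$theta)), ",", format(max(x$theta)), "]\n")
  invisible(x)
}

#' Build a network from free parameters
#'
#' Packs/unpacks the strict upper triangle of `W` plus `theta`; the natural
#' parameterization of the convex training problem, in which symmetry and the
#' zero diagonal are structural rather than constraints.
#'
#' @param par numeric vector of length `n(n-1)/2 + n`.
#' @param n node count.
#' @return a `hopfield_network`.
#' @keywords internal
network_from_par <- function(par, n) {
  nw <- n * (n - 1L) / 2L
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- par[seq_len(nw)]
  W <- W + t(W)
  hopfield_network(W, par[nw + seq_len(n)], validate = FALSE)
}

#' @rdname network_from_par
#' @param net a `hopfield_network`.
#' @keywords internal
network_to_par <- function(net) {
  c(net$W[upper.tri(net$W)], net$theta)
}

check_pattern <- function(net, x) {
  x <- as.integer(x)
  if (length(x) != net$n)
    stop("pattern length ", length(x), " does not match network size ", net$n)
  if (any(x != 0L & x != 1L)) stop("pattern entries must be 0 or 1")
  x
}

check_order <- function(net, order) {
  if (is.null(order)) return(seq_len(net$n))
  order <- as.integer(order)
  if (!identical(sort(order), seq_len(net$n)))
    stop("order must be a permutation of 1..n")
  order
}

#' Energy of a state
#'
#' `E(x) = -x'Wx/2 + x'theta`; the Lyapunov function of the asynchronous
#' dynamics and the exponent of the associated Lenz-Ising distribution.
#'
#' @param net a `hopfield_network`.
#' @param x binary state vector.
#' @return scalar energy.
#' @export
energy <- function(net, x) {
  x <- check_pattern(net, x)
  -0.5 * drop(crossprod(x, net$W %*% x)) + sum(x * net$theta)
}

#' Feedforward input to a node
#'
#' `F_i = W_i' x - theta_i`, the signed drive that determines node `i`'s next
#' state. The zero diagonal means `x_i` itself never contributes.
#'
#' @inheritParams energy
#' @param i node index (1-based).
#' @return scalar feedforward input.
#' @export
feedforward <- function(net, x, i) {
  x <- check_pattern(net, x)
  i <- as.integer(i)
  if (i < 1L || i > net$n) stop("node index out of range")
  drop(crossprod(net$W[, i], x)) - net$theta[i]
}

#' One asynchronous pass of the dynamics
#'
#' Visits the nodes in `order`, setting `x_i <- 1` if the feedforward input at
#' the *running* state is strictly positive and `0` otherwise (ties go to 0).
#' The energy of the output never exceeds the energy of the input.
#'
#' @inheritParams energy
#' @param order permutation of `1..n`; defaults to ascending node index.
#' @return the updated binary state.
#' @export
async_pass <- function(net, x, order = NULL) {
  x <- check_pattern(net, x)
  order <- check_order(net, order)
  cpp_async_pass(net$W, net$theta, x, order - 1L)
}

#' Run the dynamics to a fixed point
#'
#' Repeats asynchronous passes until one pass changes nothing; the output
#' satisfies `x* = H(W x* - theta)` exactly. Energy monotonicity guarantees
#' termination in finitely many passes; `max_passes` is a safety cap that
#' should be unreachable for valid symmetric networks.
#'
#' @inheritParams async_pass
#' @param max_passes safety cap on the number of full passes.
#' @return the fixed-point state.
#' @export
converge <- function(net, x, order = NULL, max_passes = NULL) {
  x <- check_pattern(net, x)
  order <- check_order(net, order)
  if (is.null(max_passes)) max_passes <- default_max_passes(net$n)
  res <- cpp_converge(net$W, net$theta, x, order - 1L, as.integer(max_passes))
  if (!res$converged)
    stop("dynamics did not converge within ", max_passes,
         " passes; the network may violate symmetry")
  res$state
}

default_max_passes <- function(n) as.integer(min(10 * n * 65536, 2^31 - 1))

#' Converge a batch of patterns
#'
#' Applies [converge()] independently to every row of a pattern matrix (the
#' inner loop runs in compiled code).
#'
#' @inheritParams converge
#' @param X m x n binary matrix, one pattern per row.
#' @return m x n integer matrix of fixed points.
#' @export
converge_patterns <- function(net, X, order = NULL, max_passes = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (ncol(X) != net$n) stop("pattern width does not match network size")
  order <- check_order(net, order)
  if (is.null(max_passes)) max_passes <- default_max_passes(net$n)
  res <- cpp_converge_batch(net$W, net$theta, X, order - 1L,
                            as.integer(max_passes))
  if (!all(res$converged))
    stop("dynamics did not converge within ", max_passes, " passes")
  res$states
}

#' One synchronous (parallel) update
#'
#' All nodes are updated simultaneously from the input state:
#' `x'_i = H(F_i(x))`. Unlike the asynchronous dynamics this is not
#' energy-monotone in general, but a single parallel pass is the decoding
#' step of the hyperclique code construction.
#'
#' @inheritParams energy
#' @return the updated binary state.
#' @export
sync_update <- function(net, x) {
  x <- check_pattern(net, x)
  as.integer(drop(net$W %*% x) - net$theta > 0)
}

#' Test the fixed-point condition
#'
#' `TRUE` iff `x = H(W x - theta)` elementwise, i.e. `x` is a memory of the
#' network.
#'
#' @inheritParams energy
#' @return logical scalar.
#' @export
is_fixed_point <- function(net, x) {
  x <- check_pattern(net, x)
  all(x == as.integer(drop(net$W %*% x) - net$theta > 0))
}

#' Corrupt a pattern with independent bit flips
#'
#' Replaces each bit by its complement independently with probability `p`
#' (the p-corruption). The expected Hamming distance from the original is
#' `p * n`; at `p = 1/2` the output is independent of the input. Uses R's
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param x binary vector (or m x n binary matrix, corrupted rowwise).
#' @param p flip probability in `[0, 1]`.
#' @return object of the same shape as `x`.
#' @export
corrupt <- function(x, p) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]")
  if (is.matrix(x)) {
    flip <- matrix(stats::runif(length(x)) < p, nrow(x), ncol(x))
  } else {
    flip <- stats::runif(length(x)) < p
  }
  out <- ifelse(flip, 1L - x, as.integer(x))
  if (is.matrix(x)) {
    out <- matrix(as.integer(out), nrow(x), ncol(x))
  } else {
    out <- as.integer(out)
  }
  out
}
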