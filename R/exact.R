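#' Enumerate all binary states of n nodes
#'
#' States are ordered by their integer encoding with bit `i` of the state
#' index equal to `x_i` (little-endian): state index `s` (0-based) has
#' `x_i = bit i of s`. All exact 2^n-state objects in the package (Boltzmann
#' vectors, flow matrices, data distributions) share this ordering.
#'
#' @param n node count.
#' @return 2^n x n integer matrix, one state per row.
#' @export
all_states <- function(n) {
  s <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) bitwAnd(bitwShiftR(s, i - 1L), 1L),
         integer(length(s)))
}

check_exact_cap <- function(n, cap) {
  if (n > cap)
    stop("exact enumeration requested for n = ", n,
         " nodes, above the cap of ", cap,
         " (2^n state vectors); raise `cap` explicitly if you mean it")
}

state_energies <- function(net) {
  S <- all_states(net$n)
  -0.5 * rowSums((S %*% net$W) * S) + drop(S %*% net$theta)
}

#' Exact Boltzmann (Lenz-Ising) distribution
#'
#' Enumerates all 2^n energies and returns the distribution
#' `p_x = exp(-E_x) / Z`. Energies are shifted by their minimum before
#' exponentiation so the probabilities are overflow-safe; the partition
#' function is additionally reported on the log scale.
#'
#' @param net a `hopfield_network` with `net$n <= cap`.
#' @param cap largest node count for which enumeration is allowed.
#' @return an object of class `exact_distribution` with fields `n`,
#'   `probabilities`, `partition_function`, `log_partition`, `energies`.
#' @export
boltzmann <- function(net, cap = 12) {
  check_exact_cap(net$n, cap)
  E <- state_energies(net)
  w <- exp(-(E - min(E)))
  logZ <- log(sum(w)) - min(E)
  structure(list(n = net$n, probabilities = w / sum(w),
                 partition_function = exp(logZ), log_partition = logZ,
                 energies = E),
            class = "exact_distribution")
}

#' Exact flow matrix
#'
#' The 2^n x 2^n matrix `M` with `M[y, x] = exp((E_x - E_y)/2)` for states `y`
#' one bit flip from `x`, zero elsewhere off the diagonal, and diagonal chosen
#' so every column sums to zero. `M` satisfies detailed balance with the
#' Boltzmann vector `p` (so `M p = 0`), and its second smallest singular value
#' controls the projection bound relating energy flow to density estimation.
#'
#' @inheritParams boltzmann
#' @return an object of class `flow_matrix` with fields `n` and `M`.
#' @export
flow_matrix <- function(net, cap = 12) {
  check_exact_cap(net$n, cap)
  n <- net$n
  E <- state_energies(net)
  ns <- 2^n
  M <- matrix(0, ns, ns)
  s <- 0:(ns - 1)
  for (i in seq_len(n)) {
    y <- bitwXor(s, bitwShiftL(1L, i - 1L))
    M[cbind(y + 1L, s + 1L)] <- exp((E[s + 1L] - E[y + 1L]) / 2)
  }
  diag(M) <- 0
  diag(M) <- -colSums(M)
  structure(list(n = n, M = M), class = "flow_matrix")
}

#' Second smallest singular value of a flow matrix
#'
#' Strictly positive for any network, because the one-flip graph on `{0,1}^n`
#' (the hypercube) is connected, so the flow matrix has rank `2^n - 1`.
#'
#' @param fm a `flow_matrix` (or a plain square matrix).
#' @return scalar singular value.
#' @export
sigma2 <- function(fm) {
  M <- if (inherits(fm, "flow_matrix")) fm$M else as.matrix(fm)
  d <- sort(svd(M, nu = 0, nv = 0)$d)
  d[2]
}

#' Residual of a distribution after projection onto the model
#'
#' The l2 norm of `q - (<q,p>/<p,p>) p`: the distance from the data
#' distribution to its scalar projection onto the Boltzmann vector. This is
#' the quantity that the energy-flow bound controls.
#'
#' @param q numeric vector over all 2^n states (same ordering as
#'   [all_states()]); nonnegative, summing to 1.
#' @param p an `exact_distribution`, or a numeric vector of the same length.
#' @return scalar residual norm.
#' @export
projection_residual <- function(q, p) {
  pv <- if (inherits(p, "exact_distribution")) p$probabilities else as.numeric(p)
  if (length(q) != length(pv)) stop("q and p must have the same length")
  r <- q - (sum(q * pv) / sum(pv * pv)) * pv
  sqrt(sum(r^2))
}

#' Energy flow computed from the exact flow matrix
#'
#' `EF = sum_x q_x sum_{x' in N1(x)} M[x', x]`, i.e. the q-weighted
#' off-diagonal column mass of the flow matrix. Must agree with the direct
#' data-space computation in [energy_flow()]; the two independent code paths
#' cross-check each other.
#'
#' @inheritParams boltzmann
#' @param q numeric vector over all 2^n states.
#' @return scalar energy flow.
#' @export
energy_flow_exact <- function(net, q, cap = 12) {
  check_exact_cap(net$n, cap)
  fm <- flow_matrix(net, cap = cap)
  if (length(q) != nrow(fm$M)) stop("q must have length 2^n")
  sum(q * (-diag(fm$M)))
}

#' Numerically check the projection bound
#'
#' Evaluates both sides of the inequality
#' `||q - (<q,p>/<p,p>) p||_2 <= (2 / sigma2(M)) * EF(q)`
#' for a network and a data distribution `q`. The right-hand side follows
#' from the singular-value bound `||.||_2 <= ||Mq||_1 / sigma2` together with
#' the splitting of `M` into its diagonal and off-diagonal parts, each of
#' which contributes one energy flow to `||Mq||_1`.
#'
#' @inheritParams energy_flow_exact
#' @param slack additive tolerance used for the `holds` verdict.
#' @return list with `lhs`, `rhs`, `sigma2`, `ef`, `holds`.
#' @export
check_projection_bound <- function(net, q, cap = 12, slack = 1e-9) {
  check_exact_cap(net$n, cap)
  p <- boltzmann(net, cap = cap)
  fm <- flow_matrix(net, cap = cap)
  ef <- sum(q * (-diag(fm$M)))
  s2 <- sigma2(fm)
  lhs <- projection_residual(q, p)
  rhs <- 2 * ef / s2
  list(lhs = lhs, rhs = rhs, sigma2 = s2, ef = ef,
       holds = lhs <= rhs + slack)
}
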