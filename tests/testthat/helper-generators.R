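# Random objects used across the suite.

random_network <- function(n, scale = 1, theta_scale = 1) {
  W <- matrix(stats::rnorm(n * n, sd = scale), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  hopfield_network(W, stats::rnorm(n, sd = theta_scale))
}

random_pattern <- function(n) as.integer(stats::runif(n) < 0.5)

random_pattern_matrix <- function(m, n) {
  matrix(as.integer(stats::runif(m * n) < 0.5), m, n)
}

# A random probability vector over all 2^n states.
random_state_distribution <- function(n) {
  q <- stats::runif(2^n)
  q / sum(q)
}
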