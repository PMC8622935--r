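test_that("Boltzmann distribution matches closed forms", {
  net <- hopfield_network(matrix(0, 3, 3), c(0, 0, 0))
  p <- boltzmann(net)
  expect_equal(p$probabilities, rep(1 / 8, 8))
  expect_equal(p$partition_function, 8)
  t0 <- 0.7
  net1 <- hopfield_network(matrix(0, 1, 1), t0)
  p1 <- boltzmann(net1)
  # state order: index 0 = (0), index 1 = (1)
  expect_equal(p1$probabilities[2] / p1$probabilities[1], exp(-t0))
  set.seed(201)
  for (r in 1:30) {
    p <- boltzmann(random_network(sample(2:6, 1)))
    expect_equal(sum(p$probabilities), 1, tolerance = 1e-12)
  }
  expect_error(boltzmann(random_network(13)), "cap")
})

test_that("the flow matrix has the required structure", {
  net1 <- hopfield_network(matrix(0, 1, 1), 0)
  expect_equal(flow_matrix(net1)$M, matrix(c(-1, 1, 1, -1), 2))
  set.seed(202)
  for (r in 1:40) {
    n <- sample(2:6, 1)
    net <- random_network(n)
    M <- flow_matrix(net)$M
    p <- boltzmann(net)$probabilities
    # exactly zero column sums by construction
    expect_lt(max(abs(colSums(M))), 1e-12)
    # detailed balance M_xy p_y = M_yx p_x
    B <- M %*% diag(p)
    expect_lt(max(abs(B - t(B))) / max(abs(B)), 1e-10)
    # p is a null vector
    expect_lt(max(abs(M %*% p)), 1e-9)
    # off-diagonal support only on one-bit neighbors
    S <- all_states(n)
    H <- as.matrix(stats::dist(S, method = "manhattan"))
    expect_true(all((M != 0 & row(M) != col(M)) == (H == 1)))
  }
})

test_that("sigma2 is the second smallest singular value and is positive", {
  net1 <- hopfield_network(matrix(0, 1, 1), 0)
  fm <- flow_matrix(net1)
  expect_equal(sigma2(fm), 2)
  set.seed(203)
  for (r in 1:20) {
    fm <- flow_matrix(random_network(sample(2:6, 1)))
    d <- sort(svd(fm$M)$d)
    expect_gt(sigma2(fm), 0)
    # rank deficiency exactly one: smallest singular value ~ 0
    expect_lt(d[1], 1e-9 * d[length(d)])
    expect_equal(sigma2(fm), d[2])
  }
})

test_that("projection residual obeys Pythagoras", {
  set.seed(204)
  n <- 4
  p <- boltzmann(random_network(n))
  expect_equal(projection_residual(p$probabilities, p), 0, tolerance = 1e-12)
  for (r in 1:20) {
    q <- random_state_distribution(n)
    res <- projection_residual(q, p)
    proj <- sum(q * p$probabilities) / sqrt(sum(p$probabilities^2))
    expect_equal(res^2 + proj^2, sum(q^2), tolerance = 1e-10)
  }
  # q orthogonal to p -> residual equals ||q||
  pv <- c(1, 1, 0, 0) / 2
  q <- c(0, 0, 1, 1) / 2
  expect_equal(projection_residual(q, pv), sqrt(sum(q^2)))
  expect_error(projection_residual(c(1, 0), p), "length")
})

test_that("the exact and data-space energy flows agree", {
  net1 <- hopfield_network(matrix(0, 1, 1), 0)
  q <- c(0, 1)  # point mass on state (1)
  expect_equal(energy_flow_exact(net1, q), 1)
  set.seed(205)
  for (r in 1:25) {
    n <- sample(2:6, 1)
    net <- random_network(n)
    q <- random_state_distribution(n)
    ps <- pattern_set(all_states(n), weights = q, merge = FALSE)
    expect_equal(energy_flow(net, ps), energy_flow_exact(net, q),
                 tolerance = 1e-10)
    # the diagonal and off-diagonal parts of M carry equal l1 mass on q
    M <- flow_matrix(net)$M
    D <- diag(diag(M)); T_ <- M - D
    expect_equal(sum(abs(D %*% q)), sum(abs(T_ %*% q)), tolerance = 1e-10)
    expect_equal(sum(abs(T_ %*% q)), energy_flow_exact(net, q),
                 tolerance = 1e-10)
  }
})

test_that("eigenvector projection bound holds for singular PSD matrices", {
  # rank-(n-1) PSD A: ||x - <x,u1>u1||^2 <= x'Ax / lambda2
  set.seed(206)
  for (r in 1:20) {
    n <- sample(4:64, 1)
    B <- matrix(stats::rnorm(n * n), n, n)
    u <- stats::rnorm(n); u <- u / sqrt(sum(u^2))
    B <- B %*% (diag(n) - tcrossprod(u))  # kill one direction
    A <- crossprod(B)
    ev <- eigen(A, symmetric = TRUE)
    lambda2 <- rev(sort(ev$values))[n - 1]
    u1 <- ev$vectors[, n]
    x <- stats::rnorm(n)
    lhs <- sum((x - sum(x * u1) * u1)^2)
    expect_lte(lhs, drop(crossprod(x, A %*% x)) / lambda2 + 1e-8)
  }
})

test_that("the projection bound and its derivation chain hold numerically", {
  set.seed(207)
  worst <- 0
  for (r in 1:60) {
    n <- sample(2:6, 1)
    net <- random_network(n)
    q <- random_state_distribution(n)
    th <- check_projection_bound(net, q)
    expect_true(th$holds)
    # chain: lhs <= ||Mq||_2 / s2 <= ||Mq||_1 / s2 <= 2 EF / s2
    M <- flow_matrix(net)$M
    Mq <- drop(M %*% q)
    s2 <- th$sigma2
    expect_lte(th$lhs, sqrt(sum(Mq^2)) / s2 + 1e-9)
    expect_lte(sqrt(sum(Mq^2)), sum(abs(Mq)) + 1e-12)
    expect_lte(sum(abs(Mq)) / s2, 2 * th$ef / s2 + 1e-9)
    worst <- max(worst, th$lhs / th$rhs)
  }
  expect_lte(worst, 1)
  # adversarial data: point mass on the highest-energy state
  net <- random_network(5)
  E <- -0.5 * rowSums((all_states(5) %*% net$W) * all_states(5)) +
    drop(all_states(5) %*% net$theta)
  q <- numeric(32); q[which.max(E)] <- 1
  expect_true(check_projection_bound(net, q)$holds)
})
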