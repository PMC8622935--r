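test_that("energy flow matches closed forms on one node", {
  net <- hopfield_network(matrix(0, 1, 1), 0)
  expect_equal(energy_flow(net, matrix(1L, 1, 1)), 1)
  for (t0 in c(-1.3, 0.4, 2)) {
    nett <- hopfield_network(matrix(0, 1, 1), t0)
    expect_equal(energy_flow(nett, matrix(1L, 1, 1)), exp(t0 / 2))
  }
  expect_gt(energy_flow(random_network(3), random_pattern_matrix(4, 3)), 0)
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(301)
  for (r in 1:50) {
    n <- sample(2:6, 1)
    net <- random_network(n)
    ps <- pattern_set(random_pattern_matrix(sample(1:8, 1), n))
    g <- ef_gradient(net, ps)
    expect_equal(g$gradW, t(g$gradW))
    expect_true(all(diag(g$gradW) == 0))
    par <- hopnet:::network_to_par(net)
    f <- function(p) energy_flow(hopnet:::network_from_par(p, n), ps)
    h <- 1e-5
    num <- vapply(seq_along(par), function(i) {
      e1 <- par; e1[i] <- e1[i] + h
      e2 <- par; e2[i] <- e2[i] - h
      (f(e1) - f(e2)) / (2 * h)
    }, 0)
    ana <- c(g$gradW[upper.tri(g$gradW)], g$gradtheta)
    expect_lt(max(abs(num - ana)) / max(1e-12, max(abs(ana))), 1e-6)
  }
})

test_that("the single-pattern rule matches its termwise form", {
  set.seed(302)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    net <- random_network(n)
    x <- random_pattern(n)
    upd <- mef_update_raw(net, x)
    FF <- drop(net$W %*% x) - net$theta
    D <- 1 - 2 * x
    for (i in seq_len(n)) {
      expect_equal(upd$dtheta[i], D[i] * exp(D[i] * FF[i] / 2))
      for (j in seq_len(n)[-i]) {
        expect_equal(upd$dW[i, j], -x[j] * D[i] * exp(D[i] * FF[i] / 2))
      }
    }
    # symmetrized raw rule == negative batch gradient on the singleton
    g <- ef_gradient(net, pattern_set(matrix(x, 1)))
    expect_equal((upd$dW + t(upd$dW)) / 2, -g$gradW, tolerance = 1e-12)
    expect_equal(upd$dtheta, -2 * g$gradtheta, tolerance = 1e-12)
  }
})

test_that("the update rule expresses potentiation with homeostatic attenuation", {
  # both nodes active, negative drive: the pair weight is strengthened,
  # and the strengthening decays as the drive F_i grows
  net <- hopfield_network(matrix(c(0, 0.5, 0.5, 0), 2), c(2, 2))
  x <- c(1L, 1L)
  upd <- mef_update_raw(net, x)
  expect_gt(upd$dW[1, 2], 0)
  strengths <- vapply(c(0, 1, 2), function(th) {
    mef_update_raw(hopfield_network(matrix(c(0, 0.5, 0.5, 0), 2), c(-th, -th)),
                   x)$dW[1, 2]
  }, 0)
  expect_true(all(diff(strengths) < 0))
})

test_that("energy flow is convex in the parameters", {
  set.seed(303)
  for (r in 1:20) {
    n <- sample(2:6, 1)
    ps <- pattern_set(random_pattern_matrix(6, n))
    n1 <- random_network(n); n2 <- random_network(n)
    lam <- stats::runif(1)
    mix <- hopfield_network(lam * n1$W + (1 - lam) * n2$W,
                            lam * n1$theta + (1 - lam) * n2$theta)
    expect_lte(energy_flow(mix, ps),
               lam * energy_flow(n1, ps) + (1 - lam) * energy_flow(n2, ps) + 1e-10)
  }
})

test_that("training stores patterns and is optimizer-invariant", {
  set.seed(304)
  x <- random_pattern(6)
  net <- train_mef(matrix(x, 1), mef_options(max_iterations = 300), quiet = TRUE)
  expect_true(is_fixed_point(net, x))
  # complementary pair
  ps <- pattern_set(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  netc <- train_mef(ps, mef_options(max_iterations = 300), quiet = TRUE)
  expect_true(is_fixed_point(netc, c(1, 1, 0, 0)))
  expect_true(is_fixed_point(netc, c(0, 0, 1, 1)))
  # the objective is convex: both optimizers reach the same EF level
  X <- random_pattern_matrix(6, 5)
  nl <- train_mef(X, mef_options(max_iterations = 2000), quiet = TRUE)
  ng <- train_mef(X, mef_options(max_iterations = 20000, optimizer = "gd",
                                 learning_rate = 0.2), quiet = TRUE)
  expect_equal(energy_flow(nl, pattern_set(X)), energy_flow(ng, pattern_set(X)),
               tolerance = 5e-3)
  # training reduces the objective from the zero start
  zero <- hopfield_network(matrix(0, 5, 5), rep(0, 5))
  expect_lt(energy_flow(nl, pattern_set(X)), energy_flow(zero, pattern_set(X)))
})

test_that("all 6-cliques on 8 vertices are stored by batch training", {
  cp <- clique_patterns(8, 6)
  net <- train_mef(cp, mef_options(max_iterations = 300), quiet = TRUE)
  expect_equal(storage_fraction(net, cp), 1.0)
})

test_that("online steps match the batch direction and store a repeated pattern", {
  set.seed(305)
  n <- 5
  net <- random_network(n, scale = 0.3)
  x <- random_pattern(n)
  stepped <- mef_online_step(net, x, lr = 0.05)
  g <- ef_gradient(net, pattern_set(matrix(x, 1)))
  expect_equal(stepped$W, net$W - 0.05 * g$gradW, tolerance = 1e-12)
  expect_equal(stepped$theta, net$theta - 0.05 * g$gradtheta, tolerance = 1e-12)
  expect_error(mef_online_step(net, x, lr = 0), "positive")
  cur <- hopfield_network(matrix(0, n, n), rep(0, n))
  for (it in 1:400) cur <- mef_online_step(cur, x, lr = 0.1)
  expect_true(is_fixed_point(cur, x))
})

test_that("training is equivariant under node relabeling", {
  set.seed(306)
  n <- 6
  X <- random_pattern_matrix(8, n)
  perm <- sample(n)
  net1 <- train_mef(X, mef_options(max_iterations = 400), quiet = TRUE)
  net2 <- train_mef(X[, perm], mef_options(max_iterations = 400), quiet = TRUE)
  expect_equal(net2$W, net1$W[perm, perm], tolerance = 1e-4)
  expect_equal(net2$theta, net1$theta[perm], tolerance = 1e-4)
})

test_that("trained networks satisfy the projection bound via the exact route", {
  set.seed(307)
  n <- 5
  X <- random_pattern_matrix(10, n)
  ps <- pattern_set(X)
  net <- train_mef(ps, mef_options(max_iterations = 200), quiet = TRUE)
  q <- numeric(2^n)
  idx <- hopnet:::pattern_keys(all_states(n))
  q[match(hopnet:::pattern_keys(ps$patterns), idx)] <- ps$weights
  expect_true(check_projection_bound(net, q)$holds)
})

test_that("degenerate data trigger the iteration-cap warning", {
  expect_warning(train_mef(matrix(1L, 1, 3), mef_options(max_iterations = 5)),
                 "iteration cap")
  expect_error(pattern_set(matrix(integer(0), 0, 3)), "at least one")
})
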