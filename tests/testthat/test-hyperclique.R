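test_that("node subsets are counted and colex-ordered", {
  expect_equal(nrow(node_subsets(8, 1)), 28)
  expect_equal(nrow(node_subsets(4, 1)), 6)
  expect_equal(nrow(node_subsets(12, 2)), 220)
  expect_error(node_subsets(3, 2), "v > d")
  s <- subsets_colex(4, 2)
  expect_equal(s, rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4)))
  expect_identical(subset_rank(s), 1:6)
  # rank/order agree for a larger case
  s3 <- subsets_colex(7, 3)
  expect_identical(subset_rank(s3), seq_len(choose(7, 3)))
})

test_that("node adjacency means sharing all but one vertex", {
  expect_true(subsets_adjacent(c(1, 2), c(2, 3)))
  expect_false(subsets_adjacent(c(1, 2), c(3, 4)))
  expect_false(subsets_adjacent(c(1, 2), c(1, 2)))
  expect_true(subsets_adjacent(c(1, 2, 3), c(2, 3, 4)))
  expect_false(subsets_adjacent(c(1, 2, 3), c(3, 4, 5)))
  # the sparse adjacency agrees with the pairwise predicate (small case)
  code <- code_network(6, 2)
  A <- as.matrix(code$adjacency)
  for (i in seq_len(nrow(code$nodes))) {
    for (j in seq_len(nrow(code$nodes))) {
      expect_equal(A[i, j] == 1,
                   i != j && subsets_adjacent(code$nodes[i, ], code$nodes[j, ]))
    }
  }
  # degree identity w + w' = (d+1)(v - (d+1))
  expect_true(all(rowSums(A) == 3 * (6 - 3)))
})

test_that("codewords indicate hypercliques", {
  code <- code_network(4, 1)
  G <- hypergraph(4, 1, matrix(c(1, 2, 3), ncol = 1))
  x <- encode_hypergraph(code, G)
  on <- code$nodes[x == 1, ]
  expect_equal(sort(subset_rank(on)), sort(subset_rank(rbind(c(1, 2), c(1, 3), c(2, 3)))))
  # d = 2: a triangle lights exactly its 3-set
  code2 <- code_network(5, 2)
  G2 <- hypergraph(5, 2, rbind(c(1, 2), c(1, 3), c(2, 3)))
  x2 <- encode_hypergraph(code2, G2)
  expect_equal(sum(x2), 1)
  expect_equal(code2$nodes[x2 == 1, ], c(1, 2, 3))
  # empty hypergraph -> zero codeword
  expect_true(all(encode_hypergraph(code, hypergraph(4, 1)) == 0))
  expect_error(encode_hypergraph(code, hypergraph(5, 1)), "match")
})

test_that("complete-neighbor counts have the predicted scale", {
  v <- 64; d <- 1
  code <- code_network(v, d)
  G <- hypergraph(v, d, matrix(seq_len(v), ncol = 1))  # all hyperedges
  w <- w_counts(code, G)
  expect_true(all(w == (d + 1) * (v - d - 1)))
  expect_true(all(w_counts(code, hypergraph(v, d)) == 0))
  # random model, d = 1: every complete node {a,b} of a graph with r present
  # vertices has w = 2(r - 2), so the per-graph mean has exact expectation
  # v - 4 -- the finite-v form of the asymptotic scale (d+1) v / 2^d
  set.seed(501)
  vals <- vapply(1:30, function(t) {
    G <- random_hypergraph(v, d)
    x <- encode_hypergraph(code, G)
    mean(w_counts(code, G, x = x)[x == 1])
  }, 0)
  expect_lt(abs(mean(vals) - (v - 4)), 3 * stats::sd(vals) / sqrt(30))
  expect_lt(abs(mean(vals) / ((d + 1) * v / 2^d) - 1), 0.15)
})

test_that("typicality accepts random hypergraphs and rejects extremes", {
  v <- 64
  code <- code_network(v, 1)
  expect_false(in_typical_set(code, hypergraph(v, 1, matrix(seq_len(v), ncol = 1))))
  expect_false(in_typical_set(code, hypergraph(v, 1)))
  set.seed(502)
  acc <- mean(vapply(1:60, function(t) {
    in_typical_set(code, random_hypergraph(v, 1))
  }, TRUE))
  expect_gt(acc, 0.2)
  # sampled typical hypergraphs store their codeword exactly, by construction
  for (t in 1:5) {
    G <- sample_typical_hypergraph(code)
    y <- encode_hypergraph(code, G)
    expect_identical(decode_codeword(code, y), y)
  }
})

test_that("random hypergraphs have binomial edge counts and complete fraction", {
  set.seed(503)
  v <- 24; d <- 2
  ne <- vapply(1:60, function(t) sum(random_hypergraph(v, d)$edges), 0)
  expect_lt(abs(mean(ne) - choose(v, d) / 2),
            3 * sqrt(choose(v, d) / 4 / 60))
  code <- code_network(v, d)
  fr <- vapply(1:20, function(t) {
    mean(encode_hypergraph(code, random_hypergraph(v, d)))
  }, 0)
  expect_lt(abs(mean(fr) - 2^-(d + 1)), 3 * stats::sd(fr) / sqrt(20) + 0.01)
  # seeded reproducibility
  set.seed(99); g1 <- random_hypergraph(6, 2)
  set.seed(99); g2 <- random_hypergraph(6, 2)
  expect_identical(g1, g2)
})

test_that("analytic weights take their closed-form values", {
  expect_equal(analytic_weight(64, 1, 1), 1 / 48)
  expect_equal(code_network(64, 1)$weight, 4 / 192)
  # fixed-point margin ratio 2(d+1)/(2d+1) > 1 for all d
  for (d in 1:4) {
    v <- 100
    ratio <- (d + 1) / 2^d * analytic_weight(v, d, 1) * v / 1
    expect_equal(ratio, 2 * (d + 1) / (2 * d + 1))
    expect_gt(ratio, 1)
  }
  expect_error(analytic_weight(10, 1, z = 0), "positive")
})

test_that("robustness indices match their closed forms", {
  expect_equal(robustness_index(1, "constructed"), 0.5)
  expect_equal(robustness_index(2, "constructed"), 1 / 8)
  expect_equal(robustness_index(1, "mef_trained"), 1 / 4)
  for (d in 1:5) {
    expect_gte(robustness_index(d, "constructed"),
               robustness_index(d, "mef_trained"))
  }
  expect_error(robustness_index(0), "at least 1")
})

test_that("decoding is identity on codewords and degrades with corruption", {
  set.seed(504)
  v <- 32
  code <- code_network(v, 1)
  G <- sample_typical_hypergraph(code)
  y0 <- encode_hypergraph(code, G)
  expect_identical(decode_codeword(code, y0, "single_sync"), y0)
  expect_identical(decode_codeword(code, y0, "converge"), y0)
  expect_identical(decode_codeword(code, corrupt(y0, 0), "single_sync"), y0)
  rs <- robustness_sim(v, 1, p_grid = c(0.01, 0.25), trials = 15)
  expect_equal(attr(rs, "stored_fraction"), 1.0)
  expect_gte(rs$recovered[1], rs$recovered[2])
})

test_that("energy-flow fit of the two code parameters recovers the analytic ratio", {
  set.seed(505)
  v <- 32
  fit <- fit_code_parameters(v, 1, n_graphs = 20)
  target <- 2^2 / (3 * v)
  expect_lt(abs(fit$ratio - target) / target, 0.15)
})

test_that("distinct typical codewords accumulate (exponential memory, small v)", {
  set.seed(506)
  code <- code_network(20, 1)
  keys <- vapply(1:25, function(t) {
    paste(encode_hypergraph(code, sample_typical_hypergraph(code)),
          collapse = "")
  }, "")
  expect_gt(length(unique(keys)), 20)
})

test_that("recovery at fixed corruption improves with network size", {
  set.seed(507)
  frac <- vapply(c(24, 64), function(v) {
    rs <- robustness_sim(v, 1, p_grid = 0.05, trials = 40)
    rs$recovered
  }, 0)
  expect_gt(frac[2], frac[1])
})
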