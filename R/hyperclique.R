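#' All k-element subsets of 1..v in colexicographic order
#'
#' Colex order sorts subsets by their largest element, then the next largest,
#' and so on; the rank of a sorted subset `s` is
#' `1 + sum_i choose(s_i - 1, i)`. All subset-indexed structures in the
#' package (hypergraph edge vectors, code-network nodes) use this order.
#'
#' @param v ground-set size.
#' @param k subset size.
#' @return `choose(v, k)` x `k` integer matrix, one subset per row, each row
#'   sorted increasingly.
#' @export
subsets_colex <- function(v, k) {
  if (k > v) stop("subset size exceeds ground set")
  m <- t(utils::combn(v, k))
  m[order(subset_rank(m)), , drop = FALSE]
}

#' @rdname subsets_colex
#' @param s a sorted subset (vector), or a matrix of sorted subsets (rowwise).
#' @return integer colex rank(s), 1-based.
#' @export
subset_rank <- function(s) {
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  k <- ncol(s)
  r <- rep(1, nrow(s))
  for (i in seq_len(k)) r <- r + choose(s[, i] - 1, i)
  as.integer(r)
}

#' Nodes of the hyperclique code network
#'
#' Each node of the construction corresponds to a `(d+1)`-element subset of
#' the `v` vertices, so the network has `choose(v, d+1)` nodes.
#'
#' @param v vertex count; must exceed `d + 1`.
#' @param d hypergraph uniformity (`d >= 1`).
#' @return matrix of `(d+1)`-subsets in colex order, one node per row.
#' @export
node_subsets <- function(v, d) {
  if (v <= d + 1) stop("need v > d + 1")
  subsets_colex(v, d + 1)
}

#' Adjacency of two code-network nodes
#'
#' Two `(d+1)`-subsets are adjacent when they share all but one vertex, i.e.
#' their intersection has exactly `d` elements (for `d = 1`: edge pairs
#' sharing exactly one endpoint). Only adjacent node pairs carry nonzero
#' weight in the construction.
#'
#' @param si,sj `(d+1)`-element vertex subsets.
#' @return logical.
#' @export
subsets_adjacent <- function(si, sj) {
  if (length(si) != length(sj)) stop("subsets must have equal size")
  length(intersect(si, sj)) == length(si) - 1L
}

#' Construct a d-uniform hypergraph
#'
#' @param v vertex count.
#' @param d uniformity (hyperedges are d-element subsets of `1..v`).
#' @param hyperedges matrix with one d-subset per row (or vector for a single
#'   hyperedge / for `d = 1` a vector of vertices). Duplicates are merged
#'   with a warning.
#' @return object of class `hypergraph`: `v`, `d`, and logical `edges`
#'   indexed by colex rank over all `choose(v, d)` d-subsets.
#' @export
hypergraph <- function(v, d, hyperedges = NULL) {
  edges <- rep(FALSE, choose(v, d))
  if (!is.null(hyperedges) && length(hyperedges) > 0) {
    if (!is.matrix(hyperedges)) {
      hyperedges <- if (d == 1) matrix(hyperedges, ncol = 1)
                    else matrix(hyperedges, nrow = 1)
    }
    if (ncol(hyperedges) != d) stop("hyperedges must have ", d, " vertices each")
    if (any(hyperedges < 1 | hyperedges > v)) stop("vertex index out of range")
    hyperedges <- t(apply(hyperedges, 1, sort))
    if (ncol(hyperedges) != d) hyperedges <- t(hyperedges)  # single-row guard
    if (any(apply(hyperedges, 1, anyDuplicated) > 0))
      stop("hyperedges must contain distinct vertices")
    r <- subset_rank(hyperedges)
    if (anyDuplicated(r)) {
      warning("duplicate hyperedges merged")
      r <- unique(r)
    }
    edges[r] <- TRUE
  }
  structure(list(v = as.integer(v), d = as.integer(d), edges = edges),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(x$d, "-uniform hypergraph on ", x$v, " vertices, ", sum(x$edges),
      " hyperedges\n", sep = "")
  invisible(x)
}

#' Sample a random d-uniform hypergraph
#'
#' Every d-subset of the vertices is included independently with probability
#' 1/2 — the null model under which the typicality conditions of the code
#' construction concentrate. Uses R's global RNG.
#'
#' @inheritParams hypergraph
#' @return a `hypergraph`.
#' @export
random_hypergraph <- function(v, d) {
  if (v <= d) stop("need v > d")
  g <- hypergraph(v, d)
  g$edges <- stats::runif(choose(v, d)) < 0.5
  g
}

#' Analytic code weight
#'
#' The pairwise weight minimizing the structured energy flow of the
#' construction for threshold `z` (large-`z` limit):
#' `x = 2^(d+1) z / ((2d+1) v)`.
#'
#' @inheritParams node_subsets
#' @param z threshold value (`> 0`).
#' @return scalar weight.
#' @export
analytic_weight <- function(v, d, z = 1) {
  if (z <= 0) stop("z must be positive")
  2^(d + 1) * z / ((2 * d + 1) * v)
}

#' Build a hyperclique code network
#'
#' The two-parameter network of the construction: nodes are the
#' `(d+1)`-subsets of `v` vertices, weights equal `weight` on adjacent pairs
#' (subsets sharing `d` vertices) and zero elsewhere, and every threshold is
#' `z`. With the default analytic weight, every hypergraph in the typical set
#' (see [in_typical_set()]) has its hyperclique codeword as an exact fixed
#' point.
#'
#' @inheritParams node_subsets
#' @param z uniform threshold.
#' @param weight pairwise weight; defaults to [analytic_weight()].
#' @return object of class `code_network`: `v`, `d`, `z`, `weight`, `nodes`
#'   (subset matrix), `node_edges` (for each node, colex ranks of its
#'   `(d+1)` sub-hyperedges), and sparse 0/1 `adjacency`.
#' @export
code_network <- function(v, d, z = 1, weight = NULL) {
  if (is.null(weight)) weight <- analytic_weight(v, d, z)
  if (weight < 0) stop("weight must be nonnegative")
  nodes <- node_subsets(v, d)
  n <- nrow(nodes)
  # sub-hyperedges: drop one vertex at a time (rows stay sorted)
  node_edges <- vapply(seq_len(d + 1), function(drop_col) {
    subset_rank(nodes[, -drop_col, drop = FALSE])
  }, integer(n))
  if (!is.matrix(node_edges)) node_edges <- matrix(node_edges, nrow = n)
  # adjacency: nodes sharing exactly d vertices
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), d + 1),
                               j = as.vector(nodes), x = 1,
                               dims = c(n, v))
  inter <- as(as(Matrix::tcrossprod(memb), "generalMatrix"), "TsparseMatrix")
  keep <- inter@x == d & inter@i != inter@j
  adjacency <- Matrix::sparseMatrix(i = inter@i[keep] + 1L,
                                    j = inter@j[keep] + 1L, x = 1,
                                    dims = c(n, n))
  structure(list(v = v, d = d, z = z, weight = weight, nodes = nodes,
                 node_edges = node_edges, adjacency = adjacency),
            class = "code_network")
}

#' @export
print.code_network <- function(x, ...) {
  cat("Hyperclique code network: v =", x$v, ", d =", x$d, ",",
      nrow(x$nodes), "nodes; weight =", format(x$weight), ", z =", x$z, "\n")
  invisible(x)
}

#' Densify a code network into a Hopfield network
#'
#' @param code a `code_network` with at most `max_nodes` nodes.
#' @param max_nodes cap on dense materialization.
#' @return a `hopfield_network`.
#' @export
as_hopfield <- function(code, max_nodes = 20000) {
  n <- nrow(code$nodes)
  if (n > max_nodes)
    stop("refusing to densify ", n, " nodes (cap ", max_nodes, ")")
  W <- as.matrix(code$adjacency) * code$weight
  hopfield_network(W, rep(code$z, n), validate = FALSE)
}

#' Encode a hypergraph as a codeword
#'
#' The codeword `x(G)` has a 1 exactly at the *complete* nodes: those whose
#' `(d+1)`-subset is a hyperclique of `G`, i.e. all of its d-subsets are
#' hyperedges.
#'
#' @param code a `code_network`.
#' @param G a `hypergraph` with matching `(v, d)`.
#' @return binary codeword of length `choose(v, d+1)`.
#' @export
encode_hypergraph <- function(code, G) {
  if (G$v != code$v || G$d != code$d)
    stop("hypergraph (v, d) does not match the code network")
  hits <- matrix(G$edges[code$node_edges], nrow(code$node_edges))
  as.integer(rowSums(hits) == code$d + 1)
}

#' Complete-neighbor counts
#'
#' For every node `i`, the number `w(G, i)` of adjacent nodes that are
#' complete in `G`. Together with the incomplete-neighbor count it satisfies
#' `w + w' = (d+1)(v - d - 1)`, the degree of the adjacency structure.
#'
#' @inheritParams encode_hypergraph
#' @param x optional precomputed codeword.
#' @return integer vector of length `choose(v, d+1)`.
#' @export
w_counts <- function(code, G, x = NULL) {
  if (is.null(x)) x <- encode_hypergraph(code, G)
  as.integer(round(as.numeric(code$adjacency %*% x)))
}

#' Typicality slack
#'
#' Relative slack used to implement the `(1 +/- o(1))` factors of the
#' typical-set conditions. The Azuma-scale term `c log(v)/sqrt(v)` is capped
#' at `0.95 / (2 (d + 1))`: beyond `1 / (2 (d + 1))` the complete/incomplete
#' count windows cross the analytic decision threshold and membership in the
#' typical set would no longer guarantee fixed-point storage, so the cap is
#' the largest slack for which the construction's guarantee is meaningful
#' (the 0.95 keeps a strict margin).
#'
#' @inheritParams node_subsets
#' @param c slack scale.
#' @return slack in (0, 1).
#' @export
eps_slack <- function(v, d, c = 3) {
  min(c * log(v) / sqrt(v), 0.95 / (2 * (d + 1)))
}

#' Membership in the typical set
#'
#' A hypergraph is *typical* (robustly storable by construction) when
#' (1) every complete node has at least `(d+1) v / 2^d * (1 - eps)` complete
#' neighbors, (2) every incomplete node has at most `d v / 2^d * (1 + eps)`
#' complete neighbors, and (3) the number of complete nodes is within a
#' factor `1 +/- eps` of its null expectation `2^-(d+1) choose(v, d+1)`.
#' Conditions (1) and (2) are the one-sided bounds the storage proof
#' consumes; a two-sided reading of (2) would reject every hypergraph, since
#' nodes whose subset is entirely outside the hypergraph legitimately have
#' `w = 0`.
#'
#' @inheritParams encode_hypergraph
#' @param eps relative slack, see [eps_slack()].
#' @return logical.
#' @export
in_typical_set <- function(code, G, eps = eps_slack(code$v, code$d)) {
  v <- code$v; d <- code$d
  x <- encode_hypergraph(code, G)
  w <- w_counts(code, G, x = x)
  n_complete <- sum(x)
  expected_complete <- 2^-(d + 1) * choose(v, d + 1)
  if (abs(n_complete - expected_complete) > eps * expected_complete)
    return(FALSE)
  if (n_complete > 0 && any(w[x == 1] < (d + 1) * v / 2^d * (1 - eps)))
    return(FALSE)
  if (n_complete < length(x) && any(w[x == 0] > d * v / 2^d * (1 + eps)))
    return(FALSE)
  TRUE
}

#' Rejection-sample a typical hypergraph
#'
#' @inheritParams in_typical_set
#' @param max_tries attempts before giving up.
#' @return a `hypergraph` in the typical set.
#' @export
sample_typical_hypergraph <- function(code, eps = eps_slack(code$v, code$d),
                                      max_tries = 1000) {
  for (t in seq_len(max_tries)) {
    G <- random_hypergraph(code$v, code$d)
    if (in_typical_set(code, G, eps)) return(G)
  }
  stop("no typical hypergraph found in ", max_tries,
       " attempts; the slack `eps` may be too tight for this (v, d)")
}

#' Decode a noisy codeword
#'
#' `single_sync` applies one parallel threshold pass (the decoding step the
#' construction's robustness statement is about); `converge` iterates the
#' asynchronous dynamics to a fixed point.
#'
#' @param code a `code_network`.
#' @param y binary vector of length `choose(v, d+1)`.
#' @param mode `"single_sync"` or `"converge"`.
#' @return decoded binary vector.
#' @export
decode_codeword <- function(code, y, mode = c("single_sync", "converge")) {
  mode <- match.arg(mode)
  n <- nrow(code$nodes)
  if (length(y) != n) stop("codeword length must be ", n)
  if (mode == "single_sync") {
    as.integer(code$weight * as.numeric(code$adjacency %*% y) - code$z > 0)
  } else {
    converge(as_hopfield(code), y)
  }
}

#' Index of robustness
#'
#' Closed-form robustness indices of the hyperclique construction: the
#' largest corruption rate from which memories are recovered almost surely
#' as the network grows. `"constructed"` uses weights chosen for maximal
#' robustness, `alpha = 1 / (2^d (d+1) - 2d)`; `"mef_trained"` uses the
#' energy-flow-minimizing weights, `alpha = 1 / (2^(d+1) (d+1) - 4d)`. For
#' `d = 1` these give 1/2 and 1/4.
#'
#' @param d uniformity, `d >= 1`.
#' @param variant which weight setting.
#' @return scalar index in (0, 1/2].
#' @export
robustness_index <- function(d, variant = c("constructed", "mef_trained")) {
  variant <- match.arg(variant)
  if (d < 1) stop("d must be at least 1")
  switch(variant,
         constructed = 1 / (2^d * (d + 1) - 2 * d),
         mef_trained = 1 / (2^(d + 1) * (d + 1) - 4 * d))
}

#' Monte-Carlo robustness of the hyperclique code
#'
#' For each corruption rate `p`: sample a typical hypergraph, corrupt its
#' codeword bitwise at rate `p`, decode, and record whether the codeword was
#' recovered exactly. Also records the fraction of sampled codewords that
#' are exact fixed points.
#'
#' @inheritParams node_subsets
#' @param p_grid corruption rates.
#' @param trials Monte-Carlo trials per rate.
#' @param mode decoding mode, see [decode_codeword()].
#' @param z threshold.
#' @param eps typicality slack.
#' @param max_tries rejection-sampling cap per draw.
#' @return data.frame with columns `p`, `recovered` (fraction), `trials`;
#'   attribute `"stored_fraction"` gives the fixed-point rate of the sampled
#'   codewords.
#' @export
robustness_sim <- function(v, d, p_grid = seq(0.05, 0.45, by = 0.05),
                           trials = 100, mode = "single_sync", z = 1,
                           eps = eps_slack(v, d), max_tries = 1000) {
  if (trials < 1) stop("trials must be at least 1")
  code <- code_network(v, d, z = z)
  rec <- matrix(0, length(p_grid), trials)
  stored <- logical(trials)
  for (t in seq_len(trials)) {
    G <- sample_typical_hypergraph(code, eps = eps, max_tries = max_tries)
    y0 <- encode_hypergraph(code, G)
    stored[t] <- all(decode_codeword(code, y0, mode = "single_sync") == y0)
    for (k in seq_along(p_grid)) {
      y <- corrupt(y0, p_grid[k])
      rec[k, t] <- all(decode_codeword(code, y, mode = mode) == y0)
    }
  }
  out <- data.frame(p = p_grid, recovered = rowMeans(rec), trials = trials)
  attr(out, "stored_fraction") <- mean(stored)
  out
}

#' Fit the two code parameters by energy-flow minimization
#'
#' Minimizes the structured energy flow of the construction — the mean over
#' sampled typical hypergraphs of `sum_i exp((z - w_i x)/2)` for complete
#' nodes and `exp((w_i x - z)/2)` for incomplete ones — over the two free
#' parameters `(x, z)`. The objective has no finite minimizer (it decays
#' along the ray of growing `z` at the optimal ratio), so the optimizer runs
#' until its gradient tolerance and the recovered *ratio* `x / z` is the
#' meaningful quantity; it approaches the analytic `2^(d+1) / ((2d+1) v)`.
#'
#' @inheritParams node_subsets
#' @param n_graphs number of typical hypergraphs to sample.
#' @param eps typicality slack.
#' @param init starting values `c(x, z)`.
#' @param max_iterations optimizer cap.
#' @return list with `x`, `z`, `ratio`, `objective`, `n_graphs`.
#' @export
fit_code_parameters <- function(v, d, n_graphs = 50,
                                eps = eps_slack(v, d), init = c(0.05, 1),
                                max_iterations = 2000) {
  code <- code_network(v, d)
  wc <- list(); wi <- list()
  for (g in seq_len(n_graphs)) {
    G <- sample_typical_hypergraph(code, eps = eps)
    x <- encode_hypergraph(code, G)
    w <- w_counts(code, G, x = x)
    wc[[g]] <- w[x == 1]
    wi[[g]] <- w[x == 0]
  }
  wc <- unlist(wc); wi <- unlist(wi)
  fn <- function(par) {
    (sum(exp((par[2] - wc * par[1]) / 2)) +
       sum(exp((wi * par[1] - par[2]) / 2))) / n_graphs
  }
  gr <- function(par) {
    ec <- exp((par[2] - wc * par[1]) / 2)
    ei <- exp((wi * par[1] - par[2]) / 2)
    c(sum(-wc * ec / 2) + sum(wi * ei / 2),
      sum(ec / 2) - sum(ei / 2)) / n_graphs
  }
  res <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                      lower = c(0, 1e-8),
                      control = list(maxit = max_iterations, factr = 10,
                                     pgtol = 1e-12))
  list(x = res$par[1], z = res$par[2], ratio = res$par[1] / res$par[2],
       objective = res$value, n_graphs = n_graphs)
}
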