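#' Train a network with a named rule
#'
#' Dispatch helper used by the experiment harnesses; rules are pluggable so
#' learning curves can compare them on identical samples.
#'
#' @param rule one of `"mef"`, `"opr"`, `"perceptron"`, `"delta"`.
#' @param data a `pattern_set` or binary matrix.
#' @param opts [mef_options()] for `"mef"`; ignored otherwise.
#' @param epochs,lr epoch cap and learning rate for the iterative classical
#'   rules.
#' @return a `hopfield_network`.
#' @export
train_rule <- function(rule, data, opts = mef_options(), epochs = 200,
                       lr = 0.1) {
  switch(match.arg(rule, c("mef", "opr", "perceptron", "delta")),
         mef = train_mef(data, opts, quiet = TRUE),
         opr = train_opr(data),
         perceptron = train_perceptron(data, epochs = epochs, lr = lr,
                                       quiet = TRUE),
         delta = train_delta(data, epochs = epochs, lr = 0.5))
}

#' Random distinct cluster centers
#'
#' @param K number of centers (`K <= 2^n`).
#' @param n dimension.
#' @param max_retries retries allowed to resolve collisions.
#' @return K x n binary matrix of distinct uniform random centers.
#' @export
make_clusters <- function(K, n, max_retries = 100) {
  if (n < 30 && K > 2^n) stop("cannot draw ", K, " distinct centers in n = ", n)
  centers <- matrix(as.integer(stats::runif(K * n) < 0.5), K, n)
  for (r in seq_len(max_retries)) {
    dup <- duplicated(pattern_keys(centers))
    if (!any(dup)) return(centers)
    centers[dup, ] <- as.integer(stats::runif(sum(dup) * n) < 0.5)
  }
  stop("could not draw distinct centers after ", max_retries, " retries")
}

#' Sample a corrupted mixture of centers
#'
#' Each sample picks a center uniformly at random and flips each of its bits
#' independently with probability `p` — the generative model of the
#' cluster-entropy experiment.
#'
#' @param centers K x n binary matrix.
#' @param m sample count.
#' @param p bit-flip corruption rate.
#' @return a `pattern_set` (duplicates merged into weights).
#' @export
sample_mixture <- function(centers, m, p) {
  if (m < 1) stop("m must be at least 1")
  idx <- sample.int(nrow(centers), m, replace = TRUE)
  pattern_set(corrupt(centers[idx, , drop = FALSE], p))
}

#' Attractors reached from a set of patterns
#'
#' Converges every pattern under the asynchronous dynamics and tabulates the
#' distinct fixed points reached, weighted by the patterns' empirical
#' weights.
#'
#' @param net a `hopfield_network`.
#' @param data a `pattern_set` or binary matrix.
#' @param order node update order (default ascending).
#' @return list with `n_attractors`, `entropy` (Shannon, bits), `weights`
#'   (named by attractor in order of first appearance), and `labels`
#'   (attractor id per input pattern, dense from 1 in first-appearance
#'   order).
#' @export
attractor_summary <- function(net, data, order = NULL) {
  data <- as_pattern_set(data)
  fp <- converge_patterns(net, data$patterns, order = order)
  key <- pattern_keys(fp)
  labels <- match(key, unique(key))
  w <- as.numeric(rowsum(data$weights, labels))
  list(n_attractors = length(w),
       entropy = -sum(w * log2(w)),
       weights = w,
       labels = labels)
}

#' Shannon entropy of the attractor distribution
#'
#' The entropy estimate of the cluster experiment: converge every data point
#' and take the base-2 entropy of the resulting distribution over fixed
#' points. Never exceeds `log2` of the number of distinct inputs.
#'
#' @inheritParams attractor_summary
#' @return scalar entropy in bits.
#' @export
attractor_entropy <- function(net, data, order = NULL) {
  attractor_summary(net, data, order = order)$entropy
}

#' Cluster-entropy experiment
#'
#' Generates `K` hidden centers in dimension `n`, draws `m` samples corrupted
#' at rate `p`, trains a network with the given rule on the samples, and
#' reports the attractor count and entropy obtained by converging the
#' training samples. With enough samples and moderate corruption the network
#' stores exactly the hidden centers, so the entropy estimate matches
#' `log2(K)`; with few samples the noisy copies are stored individually and
#' the entropy overestimates the truth.
#'
#' @param K hidden cluster count.
#' @param n dimension.
#' @param m sample count.
#' @param p corruption rate.
#' @param rule training rule, see [train_rule()].
#' @param opts [mef_options()] passed to MEF training.
#' @return one-row data.frame `(K, n, m, p, entropy, n_attractors)`;
#'   attribute `"network"` carries the trained network.
#' @export
clustering_experiment <- function(K, n, m, p, rule = "mef",
                                  opts = mef_options(max_iterations = 100)) {
  centers <- make_clusters(K, n)
  data <- sample_mixture(centers, m, p)
  net <- train_rule(rule, data, opts = opts)
  summ <- attractor_summary(net, data)
  out <- data.frame(K = K, n = n, m = m, p = p, entropy = summ$entropy,
                    n_attractors = summ$n_attractors)
  attr(out, "network") <- net
  attr(out, "centers") <- centers
  out
}

#' Edge-indicator patterns of k-cliques
#'
#' All `choose(v, k)` k-cliques of the complete graph on `v` vertices,
#' encoded as indicator patterns over the `choose(v, 2)` edge nodes (colex
#' pair order). Each pattern has exactly `choose(k, 2)` ones.
#'
#' @param v vertex count.
#' @param k clique size (`k <= v`).
#' @return a `pattern_set` of `choose(v, k)` uniform-weight patterns.
#' @export
clique_patterns <- function(v, k) {
  if (k > v) stop("k must not exceed v")
  subsets <- subsets_colex(v, k)
  pattern_set(clique_indicators(v, subsets), merge = FALSE)
}

# Edge-indicator rows for a matrix of vertex subsets.
clique_indicators <- function(v, subsets) {
  pairs <- node_subsets(v, 1)
  memb <- matrix(0L, nrow(subsets), v)
  memb[cbind(rep(seq_len(nrow(subsets)), ncol(subsets)),
             as.vector(subsets))] <- 1L
  memb[, pairs[, 1], drop = FALSE] * memb[, pairs[, 2], drop = FALSE]
}

#' Fraction of patterns stored as fixed points
#'
#' @param net a `hopfield_network`.
#' @param data a `pattern_set` or binary matrix.
#' @return fraction in `[0, 1]` of patterns satisfying the fixed-point
#'   condition exactly.
#' @export
storage_fraction <- function(net, data) {
  data <- as_pattern_set(data)
  X <- data$patterns
  if (ncol(X) != net$n) stop("pattern width does not match network size")
  FF <- sweep(X %*% net$W, 2, net$theta)
  mean(rowSums(X != (FF > 0)) == 0)
}

#' Hidden-clique learning curve
#'
#' For each training ratio, samples that fraction of all k-cliques without
#' replacement, trains with the named rule, and evaluates the storage
#' fraction on *all* cliques; repeated over trials.
#'
#' @inheritParams clique_patterns
#' @param rule training rule, see [train_rule()].
#' @param ratios training ratios in (0, 1].
#' @param trials repetitions per ratio.
#' @param opts [mef_options()] for MEF.
#' @param epochs,lr settings for the iterative classical rules.
#' @return data.frame `(rule, ratio, mean, sd, trials)`.
#' @export
learning_curve <- function(rule, v, k, ratios = seq(0.1, 1, by = 0.1),
                           trials = 20, opts = mef_options(max_iterations = 150),
                           epochs = 200, lr = 0.1) {
  if (any(ratios <= 0 | ratios > 1)) stop("ratios must lie in (0, 1]")
  all_pat <- clique_patterns(v, k)
  N <- nrow(all_pat$patterns)
  res <- lapply(ratios, function(r) {
    fr <- vapply(seq_len(trials), function(t) {
      take <- sample.int(N, max(1L, round(r * N)))
      train <- pattern_set(all_pat$patterns[take, , drop = FALSE],
                           merge = FALSE)
      net <- train_rule(rule, train, opts = opts, epochs = epochs, lr = lr)
      storage_fraction(net, all_pat)
    }, numeric(1))
    data.frame(rule = rule, ratio = r, mean = mean(fr), sd = stats::sd(fr),
               trials = trials)
  })
  do.call(rbind, res)
}

# Sample `m` distinct k-subsets of 1..v (uniformly, by rejection on keys).
sample_k_subsets <- function(v, k, m, replace = FALSE) {
  draw <- function(mm) {
    t(vapply(seq_len(mm), function(i) sort(sample.int(v, k)), integer(k)))
  }
  out <- draw(m)
  if (!replace) {
    for (tries in 1:100) {
      dup <- duplicated(subset_rank(out))
      if (!any(dup)) break
      out[dup, ] <- draw(sum(dup))
    }
  }
  out
}

#' Critical training-sample count for clique generalization
#'
#' Finds, by bisection over the training-set size, the smallest number of
#' randomly drawn k-cliques such that a network trained on them stores at
#' least a `criterion` fraction of a fixed test set of random k-cliques.
#' Returns the count and its ratio to the total number `choose(v, k)` of
#' k-cliques. Each bisection probe draws a fresh training sample (without
#' replacement) and trains from scratch, so the returned count is a noisy
#' but unbiased estimate of the critical threshold.
#'
#' @inheritParams clique_patterns
#' @param criterion accuracy criterion (default 0.5).
#' @param test_size number of test cliques (sampled uniformly with
#'   replacement among all k-subsets).
#' @param max_count upper bound on the training count searched.
#' @param opts [mef_options()] for MEF training.
#' @return list with `c_v` (critical count), `ratio` (`c_v / choose(v, k)`),
#'   `accuracy` (test accuracy at `c_v`), `v`, `k`.
#' @export
critical_ratio <- function(v, k, criterion = 0.5, test_size = 1000,
                           max_count = 2048,
                           opts = mef_options(max_iterations = 60)) {
  if (criterion <= 0 || criterion >= 1) stop("criterion must be in (0, 1)")
  test <- pattern_set(clique_indicators(v, sample_k_subsets(v, k, test_size,
                                                            replace = TRUE)),
                      merge = FALSE)
  accuracy_at <- function(count) {
    train <- pattern_set(clique_indicators(v, sample_k_subsets(v, k, count)),
                         merge = FALSE)
    net <- train_mef(train, opts, quiet = TRUE)
    storage_fraction(net, test)
  }
  lo <- 0L
  hi <- as.integer(max_count)
  acc_hi <- accuracy_at(hi)
  if (acc_hi < criterion)
    stop("criterion ", criterion, " not reached with ", max_count,
         " training cliques; raise max_count")
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (accuracy_at(mid) >= criterion) {
      hi <- mid
      acc_hi <- NA_real_
    } else {
      lo <- mid
    }
  }
  list(c_v = hi, ratio = hi / choose(v, k), accuracy = accuracy_at(hi),
       v = v, k = k)
}
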