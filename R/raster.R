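#' Construct a binary spike raster
#'
#' @param mat neurons x bins binary matrix.
#' @param bin_ms bin width in milliseconds (`> 0`).
#' @return object of class `spike_raster` with fields `neurons`, `bins`,
#'   `bin_ms`, `mat`.
#' @export
spike_raster <- function(mat, bin_ms = 2) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (any(mat != 0L & mat != 1L)) stop("raster entries must be 0 or 1")
  if (bin_ms <= 0) stop("bin_ms must be positive")
  structure(list(neurons = nrow(mat), bins = ncol(mat), bin_ms = bin_ms,
                 mat = mat),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("Spike raster:", x$neurons, "neurons x", x$bins, "bins (",
      x$bin_ms, "ms );", sum(x$mat), "active bins\n")
  invisible(x)
}

#' Bin spike times into a binary raster
#'
#' An entry is 1 iff the neuron fired at least once in the bin (multiple
#' spikes are binarized away).
#'
#' @param spike_times list of per-neuron spike-time vectors (milliseconds).
#' @param bin_ms bin width in milliseconds.
#' @param duration_ms total duration; spike times must fall in
#'   `[0, duration_ms)`.
#' @return a `spike_raster`.
#' @export
binarize_spikes <- function(spike_times, bin_ms, duration_ms) {
  n_bins <- ceiling(duration_ms / bin_ms)
  mat <- matrix(0L, length(spike_times), n_bins)
  for (i in seq_along(spike_times)) {
    t <- spike_times[[i]]
    if (length(t) == 0) next
    if (any(t < 0)) stop("negative spike times")
    if (any(t >= duration_ms)) stop("spike times beyond duration")
    mat[i, unique(floor(t / bin_ms)) + 1L] <- 1L
  }
  spike_raster(mat, bin_ms)
}

#' Extract sliding spatiotemporal windows
#'
#' Flattens each `w_neurons x w_bins` window (column-major: neuron index
#' fastest) into a pattern of `w_neurons * w_bins` bits, one window per
#' stride step across the bins. The number of windows is
#' `floor((bins - w_bins) / stride) + 1`.
#'
#' @param raster a `spike_raster`.
#' @param w_neurons,w_bins window size; must fit within the raster.
#' @param stride start-bin step between consecutive windows.
#' @return list with `patterns` (windows x bits binary matrix), `start_bin`
#'   (1-based start bin per window), and the window geometry.
#' @export
raster_windows <- function(raster, w_neurons = raster$neurons, w_bins = 50,
                           stride = 1) {
  if (w_neurons > raster$neurons || w_bins > raster$bins)
    stop("window larger than raster")
  starts <- seq(1L, raster$bins - w_bins + 1L, by = stride)
  pat <- t(vapply(starts, function(s) {
    as.integer(raster$mat[seq_len(w_neurons), s:(s + w_bins - 1L)])
  }, integer(w_neurons * w_bins)))
  list(patterns = pat, start_bin = starts, w_neurons = w_neurons,
       w_bins = w_bins, stride = stride)
}

#' Reshape a flattened window back into a neurons x bins block
#'
#' @param pattern flattened window (as produced by [raster_windows()]).
#' @param w_neurons,w_bins window geometry.
#' @return `w_neurons x w_bins` integer matrix.
#' @export
unflatten_window <- function(pattern, w_neurons, w_bins) {
  matrix(as.integer(pattern), w_neurons, w_bins)
}

#' Label raster windows by their attractor
#'
#' Converges every window under the network dynamics; windows reaching the
#' same fixed point share an identifier. Identifiers are dense from 1 in
#' order of first appearance, so the timeline `(start_bin, attractor_id)` is
#' deterministic given the network and update order, and repeats of the same
#' spatiotemporal motif show up as repeats of an early identifier.
#'
#' @param net a `hopfield_network` on `w_neurons * w_bins` bits.
#' @param windows output of [raster_windows()].
#' @param order node update order (default ascending).
#' @return data.frame `(start_bin, attractor_id, first_appearance)`, where
#'   `first_appearance` is the window index at which the attractor was first
#'   reached.
#' @export
label_attractors <- function(net, windows, order = NULL) {
  summ <- attractor_summary(net, pattern_set(windows$patterns, merge = FALSE),
                            order = order)
  first <- match(seq_len(summ$n_attractors), summ$labels)
  data.frame(start_bin = windows$start_bin,
             attractor_id = summ$labels,
             first_appearance = first[summ$labels])
}

#' Synthesize a spike raster with planted motifs
#'
#' Builds a Bernoulli background raster, overwrites motif blocks at the given
#' start bins, then flips every bit independently at rate `flip_noise`. The
#' stand-in for a recorded spike train: repeating spatiotemporal structure
#' embedded in noise, with known ground truth.
#'
#' @param n_neurons,n_bins raster size.
#' @param motifs list of binary blocks (`n_neurons` x motif-bins each).
#' @param occurrences list (parallel to `motifs`) of 1-based start bins.
#'   Placements must not overlap.
#' @param background_rate Bernoulli rate of the background.
#' @param flip_noise bit-flip rate applied to the finished raster.
#' @param bin_ms bin width.
#' @return a `spike_raster`; attribute `"occurrences"` holds the ground-truth
#'   table `(motif, start_bin)`.
#' @export
synth_raster <- function(n_neurons, n_bins, motifs, occurrences,
                         background_rate = 0.1, flip_noise = 0,
                         bin_ms = 2) {
  mat <- matrix(as.integer(stats::runif(n_neurons * n_bins) < background_rate),
                n_neurons, n_bins)
  occupied <- rep(FALSE, n_bins)
  truth <- list()
  for (k in seq_along(motifs)) {
    blk <- as.matrix(motifs[[k]])
    if (nrow(blk) != n_neurons) stop("motif ", k, " does not span the neurons")
    wb <- ncol(blk)
    for (s in occurrences[[k]]) {
      if (s < 1 || s + wb - 1 > n_bins) stop("motif placement outside raster")
      span <- s:(s + wb - 1)
      if (any(occupied[span])) stop("overlapping motif placements")
      occupied[span] <- TRUE
      mat[, span] <- as.integer(blk)
      truth[[length(truth) + 1]] <- data.frame(motif = k, start_bin = s)
    }
  }
  if (flip_noise > 0) mat <- corrupt(mat, flip_noise)
  out <- spike_raster(mat, bin_ms)
  attr(out, "occurrences") <- if (length(truth)) do.call(rbind, truth)
                              else data.frame(motif = integer(), start_bin = integer())
  out
}

#' Random binary motif block
#'
#' @param n_neurons,n_bins block size.
#' @param rate firing rate of the motif block.
#' @return binary matrix.
#' @export
random_motif <- function(n_neurons, n_bins, rate = 0.5) {
  matrix(as.integer(stats::runif(n_neurons * n_bins) < rate), n_neurons, n_bins)
}

#' End-to-end motif recovery on a synthetic raster
#'
#' Extracts windows from a planted-motif raster, trains a network on all
#' windows with the given rule, labels every window by its attractor, and
#' scores, for each motif, the fraction of its planted occurrences that are
#' labeled with that motif's majority attractor. A labeling that collapses
#' distinct motifs onto one attractor is scored as failing for the smaller
#' motif (majority attractors must be distinct across motifs to count).
#'
#' @param raster a `spike_raster` produced by [synth_raster()] (its
#'   `"occurrences"` attribute is the ground truth).
#' @param w_bins window width in bins (windows span all neurons).
#' @param stride window stride; occurrence start bins must be reachable.
#' @param rule training rule.
#' @param opts [mef_options()] for MEF.
#' @return list with `recovery` (overall fraction of occurrences correctly
#'   labeled), `per_motif` (fraction per motif), `timeline` (the full
#'   labeling), `net`.
#' @export
motif_recovery <- function(raster, w_bins, stride = w_bins, rule = "mef",
                           opts = mef_options(max_iterations = 150)) {
  truth <- attr(raster, "occurrences")
  win <- raster_windows(raster, w_bins = w_bins, stride = stride)
  net <- train_rule(rule, pattern_set(win$patterns, merge = TRUE), opts = opts)
  timeline <- label_attractors(net, win)
  idx <- match(truth$start_bin, timeline$start_bin)
  if (anyNA(idx)) stop("occurrence start bins must lie on the window grid")
  ids <- timeline$attractor_id[idx]
  majority <- vapply(split(ids, truth$motif), function(g) {
    as.integer(names(which.max(table(g))))
  }, integer(1))
  # motifs may not share a majority attractor: keep the larger claimant
  claims <- split(seq_along(ids), truth$motif)
  correct <- logical(length(ids))
  for (mk in names(majority)) {
    hit <- ids[claims[[mk]]] == majority[[mk]]
    rivals <- majority[names(majority) != mk]
    if (majority[[mk]] %in% rivals) {
      sizes <- vapply(names(majority)[majority == majority[[mk]]],
                      function(o) sum(ids[claims[[o]]] == majority[[o]]),
                      numeric(1))
      if (names(which.max(sizes)) != mk) hit <- rep(FALSE, length(hit))
    }
    correct[claims[[mk]]] <- hit
  }
  per_motif <- vapply(split(correct, truth$motif), mean, numeric(1))
  list(recovery = mean(correct), per_motif = per_motif,
       timeline = timeline, net = net)
}

#' Canonical planted-motif raster
#'
#' The package's reference synthetic recording: two (or more) random motif
#' blocks spanning all neurons, planted on a regular slot grid covering a
#' `fill` fraction of the raster, over sparse Bernoulli background, with
#' bit-flip noise applied to the finished raster. Motif width doubles as the
#' window width of the downstream analysis; it is kept short so that the
#' number of windows comfortably exceeds the network's memorization
#' capacity (roughly twice the window bit count), which is the regime in
#' which training forms one prototype attractor per motif rather than one
#' per noisy occurrence.
#'
#' @param n_neurons,n_bins raster size.
#' @param w_bins motif (and window) width in bins.
#' @param n_motifs number of distinct motifs.
#' @param fill fraction of slots carrying a motif occurrence.
#' @param background_rate,flip_noise noise levels, see [synth_raster()].
#' @return a `spike_raster` with the ground-truth `"occurrences"` attribute;
#'   attribute `"motifs"` holds the planted blocks.
#' @export
demo_motif_raster <- function(n_neurons = 50, n_bins = 2000, w_bins = 2,
                              n_motifs = 2, fill = 0.9,
                              background_rate = 0.1, flip_noise = 0.1) {
  slots <- seq(1, n_bins - w_bins + 1, by = w_bins)
  per <- floor(fill * length(slots) / n_motifs)
  take <- sample(length(slots), n_motifs * per)
  motifs <- replicate(n_motifs, random_motif(n_neurons, w_bins),
                      simplify = FALSE)
  occurrences <- lapply(seq_len(n_motifs), function(k) {
    sort(slots[take[(k - 1) * per + seq_len(per)]])
  })
  out <- synth_raster(n_neurons, n_bins, motifs, occurrences,
                      background_rate = background_rate,
                      flip_noise = flip_noise)
  attr(out, "motifs") <- motifs
  out
}
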