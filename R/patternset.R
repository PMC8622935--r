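#' Construct a weighted set of binary patterns
#'
#' A pattern set is the empirical distribution `q` over binary states that a
#' network is trained on: an `m x n` binary matrix of unique patterns together
#' with nonnegative weights summing to one. Duplicate rows in the input are
#' merged and their weights accumulated (set `merge = FALSE` to keep duplicates
#' as given, e.g. when the caller guarantees uniqueness).
#'
#' @param patterns m x n binary matrix, one pattern per row, or a single
#'   binary vector.
#' @param weights optional nonnegative weights, one per input row; defaults to
#'   uniform. Normalised to sum to one.
#' @param merge merge duplicate patterns into their total weight.
#' @return an object of class `pattern_set` with fields `patterns` (integer
#'   matrix) and `weights`.
#' @examples
#' ps <- pattern_set(rbind(c(1, 0), c(1, 0), c(0, 1)))
#' ps$weights  # 2/3, 1/3
#' @export
pattern_set <- function(patterns, weights = NULL, merge = TRUE) {
  if (!is.matrix(patterns)) patterns <- matrix(patterns, nrow = 1)
  storage.mode(patterns) <- "integer"
  if (nrow(patterns) == 0) stop("pattern set must contain at least one pattern")
  if (any(patterns != 0L & patterns != 1L))
    stop("pattern entries must be 0 or 1")
  m <- nrow(patterns)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("need one weight per pattern")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  if (merge && m > 1) {
    key <- pattern_keys(patterns)
    if (anyDuplicated(key)) {
      w <- rowsum(weights, key)
      keep <- !duplicated(key)
      patterns <- patterns[keep, , drop = FALSE]
      weights <- as.numeric(w[match(key[keep], rownames(w)), ])
    }
  }
  weights <- weights / sum(weights)
  structure(list(patterns = patterns, weights = weights),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("Pattern set:", nrow(x$patterns), "unique patterns of length",
      ncol(x$patterns), "\n")
  invisible(x)
}

# String keys for rows of a binary matrix (used to merge/label duplicates).
pattern_keys <- function(X) {
  if (ncol(X) == 0) return(rep("", nrow(X)))
  do.call(paste, c(lapply(seq_len(ncol(X)), function(j) X[, j]), sep = ""))
}

n_nodes <- function(data) ncol(data$patterns)

as_pattern_set <- function(data) {
  if (inherits(data, "pattern_set")) return(data)
  pattern_set(data)
}
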