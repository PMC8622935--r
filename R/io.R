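#' Read and write pattern files
#'
#' Plain-text pattern files hold one binary pattern per line as a contiguous
#' string of `0`/`1` characters; lines starting with `#` are comments. All
#' patterns must have the same length. Reading merges duplicate lines into
#' empirical weights; [write_patterns()] writes one line per pattern,
#' repeating patterns in proportion to integer multiplicities when the
#' weights encode them, otherwise one line per unique pattern.
#'
#' @param path file path.
#' @param merge merge duplicate lines into weights (disable to preserve row
#'   order and multiplicity, e.g. when the file encodes a raster).
#' @return [read_patterns()]: a `pattern_set`.
#' @export
read_patterns <- function(path, merge = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  if (length(lines) == 0) stop("no patterns in ", path)
  bad <- grep("[^01]", lines)
  if (length(bad))
    stop("non-{0,1} character on pattern line ", which(keep)[bad[1]])
  n <- nchar(lines[1])
  if (any(nchar(lines) != n))
    stop("ragged pattern line ", which(keep)[which(nchar(lines) != n)[1]],
         ": expected ", n, " characters")
  X <- matrix(as.integer(unlist(strsplit(lines, "", fixed = TRUE))),
              nrow = length(lines), ncol = n, byrow = TRUE)
  pattern_set(X, merge = merge)
}

#' @rdname read_patterns
#' @param data a `pattern_set` or binary matrix.
#' @export
write_patterns <- function(data, path) {
  data <- as_pattern_set(data)
  lines <- pattern_keys(data$patterns)
  mult <- data$weights * max(1, nrow(data$patterns))
  reps <- round(mult)
  if (max(abs(mult - reps)) < 1e-9 && all(reps >= 1)) {
    lines <- rep(lines, reps)
  }
  writeLines(c("# hopnet patterns", lines), path)
  invisible(path)
}

#' Read and write network files
#'
#' Networks are stored as plain text: a versioned header with the node count,
#' then the threshold vector and the dense weight matrix written with 17
#' significant digits, which round-trips IEEE doubles exactly. Symmetry and
#' the zero diagonal are validated on read, so a tampered file is rejected.
#'
#' @param path file path.
#' @return [read_network()]: a `hopfield_network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "# hopnet network v"))
    stop("not a hopnet network file: ", path)
  version <- sub("^# hopnet network v", "", lines[1])
  if (version != "1") stop("unsupported network file version: ", version)
  n <- as.integer(sub("^n ", "", lines[2]))
  theta <- as.numeric(strsplit(sub("^theta ", "", lines[3]), " ")[[1]])
  if (length(theta) != n) stop("corrupt network file: theta length mismatch")
  W <- do.call(rbind, lapply(lines[3 + seq_len(n)], function(l) {
    as.numeric(strsplit(l, " ")[[1]])
  }))
  if (!identical(dim(W), c(n, n)))
    stop("corrupt network file: weight matrix shape mismatch")
  if (!isTRUE(all.equal(W, t(W), tolerance = 0)) || any(diag(W) != 0))
    stop("corrupt network file: weights not symmetric with zero diagonal")
  hopfield_network(W, theta)
}

#' @rdname read_network
#' @param net a `hopfield_network`.
#' @export
write_network <- function(net, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c("# hopnet network v1",
             paste("n", net$n),
             paste("theta", fmt(net$theta)),
             apply(net$W, 1, fmt))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write hypergraph files
#'
#' One hyperedge per line as space-separated 0-based vertex indices, with a
#' header comment `# v=<v> d=<d>`. Duplicate hyperedges are merged with a
#' warning; a line with the wrong number of vertices is an error.
#'
#' @param path file path.
#' @return [read_hypergraph()]: a `hypergraph`.
#' @export
read_hypergraph <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*v=", lines, value = TRUE)
  if (length(hdr) == 0) stop("missing '# v=... d=...' header in ", path)
  v <- as.integer(sub(".*v=([0-9]+).*", "\\1", hdr[1]))
  d <- as.integer(sub(".*d=([0-9]+).*", "\\1", hdr[1]))
  body <- trimws(lines[!grepl("^\\s*#", lines)])
  body <- body[nzchar(body)]
  edges <- lapply(body, function(l) as.integer(strsplit(l, "\\s+")[[1]]))
  arity <- lengths(edges)
  if (any(arity != d))
    stop("hyperedge with ", arity[arity != d][1], " vertices; expected ", d)
  mat <- if (length(edges)) do.call(rbind, edges) + 1L else NULL
  hypergraph(v, d, mat)
}

#' @rdname read_hypergraph
#' @param G a `hypergraph`.
#' @export
write_hypergraph <- function(G, path) {
  subs <- subsets_colex(G$v, G$d)[G$edges, , drop = FALSE]
  lines <- c(sprintf("# v=%d d=%d", G$v, G$d),
             apply(subs - 1L, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
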