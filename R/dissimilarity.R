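#' Bray-Curtis dissimilarity between two profiles
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' \[0, 1\]: 0 for identical profiles, 1 for disjoint compound supports.
#' Semi-metric — the triangle inequality can fail, which is why downstream
#' principal-coordinate embeddings must tolerate negative eigenvalues.
#'
#' @param x,y non-negative numeric vectors of equal length, not both zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  denom <- sum(x) + sum(y)
  if (denom <= 0) stop("both profiles are all-zero")
  sum(abs(x - y)) / denom
}

#' Bray-Curtis dissimilarity matrix of a compound table
#'
#' Dense symmetric matrix over all sample pairs, computed on the percent
#' relative abundances with no further transformation. Row closure to 100
#' means each entry also equals the Manhattan distance / 200; the two
#' routes are used as an internal cross-check in the test-suite.
#'
#' @param x a `compound_table` or numeric abundance matrix (rows = samples).
#' @return object of class `dissimilarity_matrix`: a symmetric n x n matrix
#'   with zero diagonal and sample-id dimnames.
#' @export
bray_curtis_matrix <- function(x) {
  m <- if (inherits(x, "compound_table")) x$abundances else x
  if (nrow(m) < 2) stop("need at least 2 samples")
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("all-zero profile for sample(s): ",
         paste(rownames(m)[rs <= 0], collapse = ", "))
  man <- as.matrix(stats::dist(m, method = "manhattan"))
  d <- man / outer(rs, rs, "+")
  diag(d) <- 0
  structure(d, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("Bray-Curtis dissimilarity: %d samples, range [%.3f, %.3f]\n",
              nrow(x), min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            max(abs(d - t(d))) < 1e-12, all(abs(diag(d)) < 1e-12))
  d
}

#' Write / read a dissimilarity matrix as square CSV
#'
#' Round-trippable: sample ids in the header and first column, values at
#' full precision.
#'
#' @param d dissimilarity matrix.
#' @param path CSV path.
#' @return `d` (writer, invisibly) or the matrix (reader).
#' @export
write_dissimilarity <- function(d, path) {
  cells <- apply(unclass(d), c(1, 2), function(v) sprintf("%.17g", v))
  df <- data.frame(sample_id = rownames(d), cells, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  structure(as_dist_matrix(m),
            class = c("dissimilarity_matrix", "matrix", "array"))
}
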