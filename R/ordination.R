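#' Principal coordinates analysis (classical scaling)
#'
#' Gower double-centering of the squared dissimilarities,
#' \eqn{G = -\tfrac12 J D^2 J} with \eqn{J = I - 11^T/n}, followed by an
#' eigendecomposition. Axes for positive eigenvalues are scaled by
#' \eqn{\sqrt{\lambda}}; negative eigenvalues — expected for semi-metric
#' input such as Bray-Curtis — are kept separately as "imaginary" axes so
#' dispersion analysis can correct squared distances with them.
#'
#' @param d symmetric dissimilarity matrix (n >= 3).
#' @param tol eigenvalues with `|lambda| <= tol * max(|lambda|)` are treated
#'   as null and dropped.
#' @return list of class `pcoa_result` with `coordinates` (n x m, positive
#'   axes), `imaginary_coordinates` (n x m'), `eigenvalues` (descending),
#'   `variance_explained` (per real axis, over the positive eigenvalue sum),
#'   and `trace` (sum of positive eigenvalues minus negative part check).
#' @export
pcoa <- function(d, tol = 1e-9) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  lambda <- e$values
  scale_ref <- max(abs(lambda))
  pos <- which(lambda > tol * scale_ref)
  neg <- which(lambda < -tol * scale_ref)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lambda[pos]), length(pos))
  imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-lambda[neg]), length(neg))
  rownames(coords) <- rownames(imag) <- rownames(d)
  colnames(coords) <- paste0("PCoA", seq_along(pos))
  if (length(neg)) colnames(imag) <- paste0("iPCoA", seq_along(neg))
  structure(list(coordinates = coords,
                 imaginary_coordinates = imag,
                 eigenvalues = lambda,
                 variance_explained = lambda[pos] / sum(lambda[pos]),
                 trace = sum(diag(G))),
            class = "pcoa_result")
}

gower_center <- function(d) {
  A <- -0.5 * d^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) +
    mean(A)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes stress-1
#' \eqn{\sqrt{\sum (\hat d_{ij} - \theta_{ij})^2 / \sum \hat d_{ij}^2}},
#' where \eqn{\hat d} are configuration distances and \eqn{\theta} is the
#' isotonic (pool-adjacent-violators) regression of \eqn{\hat d} on the rank
#' order of the input dissimilarities (primary/weak tie treatment: tied
#' input values are pre-sorted by current configuration distance). The
#' configuration is updated by iterative majorization (Guttman transform);
#' an iteration is accepted only if it lowers stress, so the reported stress
#' sequence is non-increasing. One start is seeded from PCoA, the remainder
#' from random Gaussian configurations; the best final stress wins.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (default 3 — profiles are plotted on
#'   X-Y-Z axes).
#' @param n_starts number of starts (1 PCoA-seeded + `n_starts - 1` random).
#' @param max_iter maximum accepted iterations per start.
#' @param tol convergence tolerance on the stress decrease.
#' @param seed integer seed for the random starts.
#' @return list of class `nmds_result`: `coordinates` (n x k, centered),
#'   `stress`, `stress_sequence` (accepted iterations of the winning start),
#'   `n_iterations`, `converged`, `best_of`.
#' @export
nmds <- function(d, k = 3, n_starts = 20, max_iter = 300, tol = 1e-7,
                 seed = 1L) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  stopifnot(k >= 1, n >= 3)
  low <- which(lower.tri(d))
  dv <- d[low]

  starts <- vector("list", n_starts)
  pc <- pcoa(d)
  X0 <- pc$coordinates
  if (ncol(X0) >= k) X0 <- X0[, seq_len(k), drop = FALSE]
  else X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
  starts[[1]] <- X0
  if (n_starts > 1) {
    rand <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
      matrix(stats::rnorm(n * k), n, k)))
    starts[seq_len(n_starts - 1) + 1] <- rand
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- nmds_one_start(starts[[s]], dv, low, n, k, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  dimnames(X) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(coordinates = X, stress = best$stress,
                 stress_sequence = best$stress_seq,
                 n_iterations = length(best$stress_seq),
                 converged = best$converged, best_of = n_starts),
            class = "nmds_result")
}

config_dist_vec <- function(X, low) {
  as.matrix(stats::dist(X))[low]
}

# disparities via PAVA on configuration distances in input-rank order
monotone_disparities <- function(cd, dv) {
  ord <- order(dv, cd)
  theta <- numeric(length(cd))
  theta[ord] <- stats::isoreg(seq_along(ord), cd[ord])$yf
  theta
}

stress1 <- function(cd, theta) {
  denom <- sum(cd^2)
  if (denom == 0) return(0)
  sqrt(sum((cd - theta)^2) / denom)
}

guttman_update <- function(X, theta, low, n) {
  cd <- config_dist_vec(X, low)
  ratio <- ifelse(cd > 0, theta / cd, 0)
  B <- matrix(0, n, n)
  B[low] <- -ratio
  B <- B + t(B)
  diag(B) <- -rowSums(B)
  (B %*% X) / n
}

nmds_one_start <- function(X, dv, low, n, k, max_iter, tol) {
  cd <- config_dist_vec(X, low)
  theta <- monotone_disparities(cd, dv)
  s <- stress1(cd, theta)
  stress_seq <- s
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    X_new <- guttman_update(X, theta, low, n)
    cd_new <- config_dist_vec(X_new, low)
    theta_new <- monotone_disparities(cd_new, dv)
    s_new <- stress1(cd_new, theta_new)
    if (s_new >= s - tol) {               # accept only improving iterations
      if (s_new < s) {
        X <- X_new; s <- s_new; stress_seq <- c(stress_seq, s_new)
      }
      converged <- TRUE
      break
    }
    X <- X_new; cd <- cd_new; theta <- theta_new; s <- s_new
    stress_seq <- c(stress_seq, s_new)
  }
  list(X = X, stress = s, stress_seq = stress_seq, converged = converged)
}
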