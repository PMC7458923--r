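#' Distance-based permutational multivariate ANOVA (sequential SS)
#'
#' Partitions the total sum of squared dissimilarities over an ordered term
#' list using the trace identity \eqn{ss_k = tr(H_k G) - tr(H_{k-1} G)},
#' where `G` is the Gower-centered matrix of `d` and `H_k` the hat matrix of
#' the design containing terms 1..k (Type I / sequential SS, so term order
#' matters and is reported). Pseudo-F for each term uses the residual mean
#' square of the full model. Significance is assessed by permuting whole
#' samples — restricted to stay within `strata` levels when given — and the
#' permutation p-value carries the +1 correction, so it can never be 0.
#'
#' @param d symmetric dissimilarity matrix.
#' @param metadata per-sample data.frame aligned with `d` rows.
#' @param terms ordered character vector of model terms over metadata
#'   columns, interactions written `a:b`. Default: the study's full
#'   crossed design.
#' @param n_perm number of permutations (the study used 9,999).
#' @param strata optional metadata column name (or factor) restricting
#'   permutations to within-level moves; default `"year"` following the
#'   sampling design ("three sampling years, each with four treatments").
#'   `NULL` permutes freely.
#' @param seed integer seed for the permutation stream.
#' @param year_numeric code `year` as a numeric covariate (df = 1) instead
#'   of a factor; both codings are supported because published analyses of
#'   this design differ on it.
#' @return data.frame of class `permanova_table`: one row per term plus
#'   `Residual` and `Total`, with columns `df, ss, r2, f, p`.
#' @export
permanova <- function(d, metadata,
                      terms = c("year", "species", "sex", "year:species",
                                "year:sex", "species:sex",
                                "year:species:sex"),
                      n_perm = 9999, strata = "year", seed = 1L,
                      year_numeric = FALSE) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (!is.null(rownames(d)) && "sample_id" %in% names(metadata) &&
      !identical(rownames(d), metadata$sample_id))
    stop("metadata rows do not align with the dissimilarity matrix")
  md <- metadata
  for (v in unique(unlist(strsplit(terms, ":", fixed = TRUE)))) {
    if (!v %in% names(md)) stop("term variable not in metadata: ", v)
    if (v == "year" && year_numeric) md[[v]] <- as.numeric(md[[v]])
    else if (!is.numeric(md[[v]]) || v == "year")
      md[[v]] <- factor(md[[v]])
  }

  fml <- stats::terms(stats::reformulate(terms), keep.order = TRUE)
  X <- stats::model.matrix(fml, data = md)
  assign <- attr(X, "assign")              # 0 = intercept, 1..K = terms
  K <- length(attr(fml, "term.labels"))
  # aliased columns (e.g. an empty design cell) are dropped in order, as in
  # lm(); a term losing all its columns is a hard error
  keep <- logical(ncol(X))
  rank_prev <- 0L
  for (j in seq_len(ncol(X))) {
    cols <- c(which(keep), j)
    r <- qr(X[, cols, drop = FALSE])$rank
    if (r > rank_prev) { keep[j] <- TRUE; rank_prev <- r }
  }
  if (any(!keep)) {
    dropped_terms <- unique(attr(fml, "term.labels")[assign[!keep]])
    dead <- setdiff(seq_len(K), unique(assign[keep]))
    if (length(dead))
      stop("fully aliased model term(s): ",
           paste(attr(fml, "term.labels")[dead], collapse = ", "))
    warning("aliased design column(s) dropped from term(s): ",
            paste(dropped_terms, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    assign <- assign[keep]
  }
  qr_x <- qr(X)
  if (!identical(qr_x$pivot[seq_len(ncol(X))], seq_len(ncol(X))))
    stop("design columns pivoted; term spans not nested")
  Q <- qr.Q(qr_x)
  df_terms <- tabulate(assign[assign > 0], nbins = K)

  G <- gower_center(d)
  ss_total <- sum(diag(G))
  # per-term projector increments flattened for fast permutation traces
  proj <- vapply(seq_len(K), function(k) {
    as.vector(tcrossprod(Q[, assign == k, drop = FALSE]))
  }, numeric(n * n))                       # (n^2) x K

  ss_of <- function(Gmat) as.vector(crossprod(proj, as.vector(Gmat)))
  f_of <- function(ss_terms) {
    ss_res <- ss_total - sum(ss_terms)
    f <- (ss_terms / df_terms) / (ss_res / df_res)
    f[is.nan(f)] <- 0          # 0/0: no signal anywhere
    f
  }
  df_res <- n - 1 - sum(df_terms)
  if (df_res < 1) stop("no residual degrees of freedom")

  ss_obs <- ss_of(G)
  f_obs <- f_of(ss_obs)

  strata_f <- NULL
  if (!is.null(strata)) {
    strata_f <- if (length(strata) == 1 && is.character(strata))
      factor(metadata[[strata]]) else factor(strata)
    if (any(table(strata_f) == 1))
      warning("strata level(s) of size 1: those samples never move")
  }
  exceed <- numeric(K)
  # ties between permuted and observed F count as exceedances; the small
  # slack absorbs summation-order noise in the permuted traces
  f_tol <- sqrt(.Machine$double.eps) * pmax(1, abs(f_obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      p <- permute_indices(n, strata_f)
      fp <- f_of(ss_of(G[p, p]))
      exceed <- exceed + (fp >= f_obs - f_tol)
    }
  })
  p_val <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(attr(fml, "term.labels"), "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    ss = c(ss_obs, ss_total - sum(ss_obs), ss_total),
    r2 = c(ss_obs, ss_total - sum(ss_obs), ss_total) / ss_total,
    f = c(f_obs, NA, NA),
    p = c(p_val, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "strata") <- if (is.null(strata_f)) "none" else
    if (is.character(strata) && length(strata) == 1) strata else "custom"
  class(out) <- c("permanova_table", "data.frame")
  out
}

#' Strata-restricted sample permutation
#'
#' Returns a permutation of `1:n`; when `strata` is given, indices are only
#' shuffled within each stratum level, never across.
#'
#' @param n number of samples.
#' @param strata optional factor of length n.
#' @return integer permutation vector.
#' @export
permute_indices <- function(n, strata = NULL) {
  idx <- seq_len(n)
  if (is.null(strata)) return(sample(idx))
  for (lv in levels(strata)) {
    members <- idx[strata == lv]
    if (length(members) > 1) idx[strata == lv] <- sample(members)
  }
  idx
}

#' @export
print.permanova_table <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations, strata: %s)\n",
              attr(x, "n_perm"), attr(x, "strata")))
  y <- as.data.frame(x)
  y$ss <- round(y$ss, 2); y$r2 <- round(y$r2, 2)
  y$f <- round(y$f, 2); y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
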