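#' Similarity percentage analysis (SIMPER) between two groups
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-compound contributions: for every between-group sample pair (j, k),
#' compound i contributes
#' \eqn{c_{ijk} = |x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})}, and the
#' average over all between-group pairs is reported. By construction the
#' per-compound averages sum exactly to the mean between-group dissimilarity
#' (the key conservation identity, asserted in the tests). Significance of
#' each contribution is a one-sided (greater) permutation test on the group
#' labels with the +1 correction; a Bonferroni flag is reported at
#' `alpha = 0.05 / p_total` with `p_total` the total number of identified
#' compounds in the table (113-style divisor), not the number tested.
#'
#' @param x a `compound_table` or abundance matrix.
#' @param groups two-level factor (or coercible), each level with >= 2
#'   samples.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param bonferroni_alpha numerator of the Bonferroni threshold.
#' @return data.frame of class `simper_result`, one row per compound,
#'   sorted by descending contribution: `compound_id, average, sd,
#'   contribution_pct, cumulative, p_perm, sig_bonferroni`; attributes
#'   `mean_dissimilarity`, `groups`, `alpha_bonferroni`.
#' @export
simper <- function(x, groups, n_perm = 999, seed = 1L,
                   bonferroni_alpha = 0.05) {
  m <- if (inherits(x, "compound_table")) x$abundances else x
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("SIMPER needs exactly two groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  stopifnot(length(groups) == nrow(m))

  obs <- simper_contributions(m, groups)
  ge <- numeric(ncol(m))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- simper_contributions(m, groups[sample.int(length(groups))])
      ge <- ge + (perm$average >= obs$average)
    }
  })
  p_perm <- (1 + ge) / (1 + n_perm)

  p_total <- ncol(m)
  alpha_b <- bonferroni_alpha / p_total
  ord <- order(obs$average, decreasing = TRUE)
  total <- sum(obs$average)
  out <- data.frame(compound_id = colnames(m)[ord],
                    average = obs$average[ord],
                    sd = obs$sd[ord],
                    contribution_pct = 100 * obs$average[ord] / total,
                    cumulative = cumsum(obs$average[ord]) / total,
                    p_perm = p_perm[ord],
                    sig_bonferroni = p_perm[ord] < alpha_b,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean_dissimilarity") <- total
  attr(out, "groups") <- levels(groups)
  attr(out, "alpha_bonferroni") <- alpha_b
  class(out) <- c("simper_result", "data.frame")
  out
}

# vectorized over all between-group pairs: npairs x p difference matrix
simper_contributions <- function(m, groups) {
  a <- which(groups == levels(groups)[1])
  b <- which(groups == levels(groups)[2])
  pairs <- expand.grid(j = a, k = b)
  diffs <- abs(m[pairs$j, , drop = FALSE] - m[pairs$k, , drop = FALSE])
  denom <- rowSums(m)[pairs$j] + rowSums(m)[pairs$k]
  contrib <- diffs / denom
  list(average = colMeans(contrib), sd = apply(contrib, 2, stats::sd))
}

#' Markers consistently significant across seasons
#'
#' Intersection of the compounds whose SIMPER permutation p-value falls
#' below `alpha` in every season analyzed (the study screened at p < 0.01
#' across the two reproductive seasons); per-season p-values and the
#' stricter Bonferroni flags (`alpha = 0.05 / p_total`) are reported
#' alongside, since the two thresholds select different subsets.
#'
#' @param per_season named list of `simper_result` objects (>= 2 seasons).
#' @param alpha per-season significance threshold.
#' @return list with `markers` (character, possibly empty — a warning, not
#'   an error) and `table` (data.frame: compound, per-season p, per-season
#'   Bonferroni flag).
#' @export
consistent_markers <- function(per_season, alpha = 0.01) {
  stopifnot(length(per_season) >= 2)
  sig_sets <- lapply(per_season, function(r)
    r$compound_id[r$p_perm < alpha])
  markers <- Reduce(intersect, sig_sets)
  if (!length(markers)) warning("no consistently significant compounds")
  tab <- data.frame(compound_id = markers, stringsAsFactors = FALSE)
  for (s in names(per_season)) {
    r <- per_season[[s]]
    idx <- match(markers, r$compound_id)
    tab[[paste0("p_", s)]] <- r$p_perm[idx]
    tab[[paste0("bonferroni_", s)]] <- r$sig_bonferroni[idx]
  }
  list(markers = markers, table = tab)
}

#' PCA reduction of a marker-compound set
#'
#' Principal component analysis of the abundance submatrix restricted to the
#' selected compounds. Components are retained while their cumulative
#' variance fraction stays within the threshold (always at least one), and
#' the compound with the largest absolute loading on the first component is
#' flagged as the top-variance marker. Correlation-mode (centered, unit
#' variance) by default; covariance-mode via `scale. = FALSE`.
#'
#' @param x a `compound_table` or matrix.
#' @param compounds compound ids to analyze (default: all columns).
#' @param cumulative_threshold retain components with cumulative variance
#'   fraction <= this (study value 0.75).
#' @param scale. standardize columns (correlation-mode PCA).
#' @return list of class `pca_selection`: `loadings`, `variance_explained`,
#'   `retained`, `top_variance_compound`, `scores`.
#' @export
pca_select <- function(x, compounds = NULL, cumulative_threshold = 0.75,
                       scale. = TRUE) {
  m <- if (inherits(x, "compound_table")) x$abundances else x
  if (!is.null(compounds)) {
    miss <- setdiff(compounds, colnames(m))
    if (length(miss)) stop("unknown compound(s): ", paste(miss, collapse = ", "))
    m <- m[, compounds, drop = FALSE]
  }
  if (ncol(m) < 2 || nrow(m) < 3)
    stop("PCA needs >= 2 compounds and >= 3 samples")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping constant compound(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 non-constant compounds")
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  retained <- max(1, sum(cumsum(ve) <= cumulative_threshold))
  structure(list(loadings = fit$rotation,
                 variance_explained = ve,
                 retained = retained,
                 top_variance_compound =
                   rownames(fit$rotation)[which.max(abs(fit$rotation[, 1]))],
                 scores = fit$x),
            class = "pca_selection")
}
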