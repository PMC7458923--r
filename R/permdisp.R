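#' Multivariate homogeneity of group dispersions (PERMDISP-style)
#'
#' Embeds the dissimilarity matrix by PCoA keeping both real and imaginary
#' axes, computes each sample's distance to its group centroid with the
#' semi-metric correction
#' \eqn{z^2 = \|x^{re} - c^{re}\|^2 - \|x^{im} - c^{im}\|^2}
#' (negative corrected squares are clamped to 0 with a warning), and tests
#' equality of mean dispersion across groups with a one-way ANOVA F on the
#' centroid distances.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups factor (or coercible) of group membership per sample.
#'   Groups of size 1 are excluded with a warning.
#' @return list of class `dispersion_result`: `distances` (per retained
#'   sample), `groups`, `group_means`, `anova_f`, `anova_p`, `df`, and
#'   `degenerate` (TRUE when all distances are 0 and F is undefined).
#' @export
permdisp <- function(d, groups) {
  d <- as_dist_matrix(d)
  groups <- factor(groups)
  stopifnot(length(groups) == nrow(d))
  sizes <- table(groups)
  if (any(sizes == 1)) {
    warning("excluding group(s) of size 1: ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes > 1]
    d <- d[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups of size >= 2")

  pc <- pcoa(d)
  re <- pc$coordinates
  im <- pc$imaginary_coordinates
  z2 <- numeric(nrow(d))
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    dr <- sweep(re[idx, , drop = FALSE], 2, colMeans(re[idx, , drop = FALSE]))
    z2[idx] <- rowSums(dr^2)
    if (ncol(im)) {
      di <- sweep(im[idx, , drop = FALSE], 2,
                  colMeans(im[idx, , drop = FALSE]))
      z2[idx] <- z2[idx] - rowSums(di^2)
    }
  }
  if (any(z2 < -1e-8))
    warning(sum(z2 < -1e-8),
            " negative corrected squared distance(s) clamped to 0")
  dist_c <- sqrt(pmax(z2, 0))

  degenerate <- stats::var(dist_c) < 1e-16
  if (degenerate) {
    warning("all centroid distances equal; dispersion F undefined")
    anova_f <- NA_real_; anova_p <- NA_real_; df <- c(NA, NA)
  } else {
    # a perfect between-group fit is legitimate here (tiny toy inputs);
    # the base "essentially perfect fit" warning is not actionable
    fit <- suppressWarnings(stats::anova(stats::lm(dist_c ~ groups)))
    anova_f <- fit$`F value`[1]
    anova_p <- fit$`Pr(>F)`[1]
    df <- fit$Df
  }
  structure(list(distances = dist_c, groups = groups,
                 group_means = tapply(dist_c, groups, mean),
                 anova_f = anova_f, anova_p = anova_p, df = df,
                 degenerate = degenerate),
            class = "dispersion_result")
}

#' Tukey HSD screening of group dispersions
#'
#' Studentized-range adjusted pairwise comparisons of mean
#' distance-to-centroid, plus the fraction of group pairs whose dispersions
#' are NOT significantly different — the "percent of pairwise comparisons
#' in which the homogeneity assumption is upheld" screen used before
#' PERMANOVA.
#'
#' @param disp a `dispersion_result` from [permdisp()].
#' @param alpha significance level for calling a pair heterogeneous.
#' @return list with `tukey_table` (data.frame `pair, diff, lwr, upr,
#'   p_adj`, one row per group pair) and `percent_homogeneous` in \[0, 1\].
#' @export
tukey_hsd_dispersion <- function(disp, alpha = 0.05) {
  stopifnot(inherits(disp, "dispersion_result"))
  if (disp$degenerate) stop("dispersions degenerate; Tukey HSD undefined")
  fit <- stats::aov(distances ~ groups,
                    data = data.frame(distances = disp$distances,
                                      groups = disp$groups))
  tk <- stats::TukeyHSD(fit, "groups")$groups
  tab <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(tukey_table = tab,
       percent_homogeneous = mean(tab$p_adj > alpha))
}
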