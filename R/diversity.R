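#' Chemical diversity of one secretion profile
#'
#' Shannon-type entropy of a sample's compound relative abundances,
#' \eqn{H_{chem} = -\sum_i p_i \ln p_i}, where \eqn{p_i} is the relative
#' abundance of compound i rescaled to proportions (`0 ln 0` taken as 0).
#' Invariant under row rescaling, so percent and proportion inputs agree.
#'
#' @param profile non-negative numeric vector with positive sum (one row of
#'   a compound table).
#' @return the diversity value, in \[0, ln(number of positive compounds)\].
#' @export
h_chem <- function(profile) {
  if (any(profile < 0)) stop("negative abundance in profile")
  s <- sum(profile)
  if (s <= 0) stop("all-zero profile")
  p <- profile[profile > 0] / s
  -sum(p * log(p))
}

#' Chemical richness of a sample set
#'
#' Number of compounds with strictly positive abundance in at least one
#' sample of the table.
#'
#' @param x a `compound_table` (or numeric matrix).
#' @return integer count.
#' @export
r_chem <- function(x) {
  m <- if (inherits(x, "compound_table")) x$abundances else x
  if (nrow(m) == 0) stop("empty sample set")
  sum(apply(m > 0, 2, any))
}

#' Group-wise diversity summary (study Table-1 layout)
#'
#' Per year x species x sex cell: sample count, chemical richness of the
#' cell, and mean and sample standard deviation (n - 1 denominator) of the
#' per-individual chemical diversity. Cells of one sample report `NA` for
#' the standard deviation; empty cells are omitted.
#'
#' @param x a `compound_table`.
#' @param metadata aligned metadata data.frame.
#' @param keys metadata columns defining the groups.
#' @return data.frame with one row per non-empty group: the key columns,
#'   `n`, `r_chem`, `h_mean`, `h_sd`.
#' @export
summarize_by_group <- function(x, metadata,
                               keys = c("year", "species", "sex")) {
  metadata <- check_metadata(metadata, x)
  h <- apply(x$abundances, 1, h_chem)
  key <- interaction(metadata[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    idx <- which(key == lv)
    cbind(metadata[idx[1], keys, drop = FALSE],
          data.frame(n = length(idx),
                     r_chem = r_chem(x$abundances[idx, , drop = FALSE]),
                     h_mean = mean(h[idx]),
                     h_sd = if (length(idx) > 1) stats::sd(h[idx]) else NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$year, out$species, out$sex), , drop = FALSE]
}
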