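# in-code fixtures and independent oracles shared across test files

make_table <- function(m, ids = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  compound_table(m)
}

# sparse positive random table; every row kept non-empty
random_sparse_table <- function(n, p, density = 0.6, seed = 1) {
  withr::local_seed(seed)
  m <- matrix(rexp(n * p) * rbinom(n * p, 1, density), n, p)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  normalize_rows(make_table(m))
}

# brute-force Bray-Curtis over all pairs, element by element
bc_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(m))) {
      num <- num + abs(m[i, k] - m[j, k])
      den <- den + m[i, k] + m[j, k]
    }
    d[i, j] <- num / den
  }
  d
}

# brute-force SIMPER: explicit loop over every between-group pair
simper_oracle <- function(m, groups) {
  groups <- factor(groups)
  a <- which(groups == levels(groups)[1])
  b <- which(groups == levels(groups)[2])
  contrib <- matrix(0, length(a) * length(b), ncol(m))
  r <- 0
  for (j in a) for (k in b) {
    r <- r + 1
    contrib[r, ] <- abs(m[j, ] - m[k, ]) / sum(m[j, ] + m[k, ])
  }
  colMeans(contrib)
}

# all permutations of 1..n (for exhaustive permutation-test oracles)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in seq_len(n)) out[[length(out) + 1]] <- append(sub, n, pos - 1)
  }
  out
}

# metadata frame for ad-hoc tables (single year/season unless given)
make_metadata <- function(ids, species, sex = "M", year = 2012L,
                          season = "rs") {
  data.frame(sample_id = ids, species = species,
             sex = rep_len(sex, length(ids)),
             year = rep_len(as.integer(year), length(ids)),
             season = rep_len(season, length(ids)),
             stringsAsFactors = FALSE)
}

# small two-group null spec for calibration studies
two_group_spec <- function(seed, n_per_group = 20, n_compounds = 30,
                           delta = 0) {
  cells <- data.frame(year = 2012L,
                      species = c("marthae", "subcristatus"),
                      sex = "M", n = n_per_group)
  synthetic_spec(cells, n_compounds = n_compounds,
                 species_markers = 1:3, sex_markers = 4:5,
                 year_markers = 6:7,
                 delta_species = delta, delta_sex = 0, delta_year = 0,
                 seed = seed)
}
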