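euclid_d <- function(X) {
  d <- as.matrix(dist(X))
  dimnames(d) <- list(sprintf("s%02d", seq_len(nrow(X))),
                      sprintf("s%02d", seq_len(nrow(X))))
  d
}

test_that("sequential SS on Euclidean distances match coordinate ANOVA", {
  withr::local_seed(6)
  n <- 24
  md <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   species = rep(c("marthae", "subcristatus"), each = n / 2),
                   sex = rep(c("F", "M"), n / 2),
                   year = rep(c(2012L, 2014L), times = n / 2),
                   season = "rs", stringsAsFactors = FALSE)
  X <- matrix(rnorm(n * 3), n, 3) +
    outer(as.numeric(factor(md$species)), c(1, 0, 0.5))
  pt <- permanova(euclid_d(X), md, terms = c("species", "sex",
                                             "species:sex"),
                  n_perm = 49, strata = NULL, seed = 1)
  # coordinate-wise sequential ANOVA summed over axes
  ss_aov <- rowSums(vapply(1:3, function(j) {
    fit <- stats::anova(stats::lm(X[, j] ~ species * sex, data = md))
    fit$`Sum Sq`
  }, numeric(4)))
  expect_equal(pt$ss[1:3], ss_aov[1:3], tolerance = 1e-8)
  expect_equal(pt$ss[pt$term == "Residual"], ss_aov[4], tolerance = 1e-8)
})

test_that("SS additivity and R2 hold for arbitrary dissimilarities", {
  gen <- generate_profiles(default_study_spec(9))
  d <- bray_curtis_matrix(gen$table)
  pt <- suppressWarnings(permanova(d, gen$metadata, n_perm = 19, seed = 2))
  ss_total <- pt$ss[pt$term == "Total"]
  expect_equal(sum(pt$ss[!pt$term %in% "Total"]), ss_total,
               tolerance = 1e-8)
  expect_equal(sum(unclass(d)^2) / nrow(unclass(d)) / 2, ss_total,
               tolerance = 1e-8)
  expect_equal(sum(pt$r2[!pt$term %in% "Total"]), 1, tolerance = 1e-10)
  expect_equal(sum(pt$df[!pt$term %in% "Total"]),
               pt$df[pt$term == "Total"])
})

test_that("observed statistics agree with the vegan adonis2 oracle", {
  gen <- generate_profiles(default_study_spec(12))
  d <- bray_curtis_matrix(gen$table)
  md <- transform(gen$metadata, year = factor(year))
  pt <- suppressWarnings(permanova(d, gen$metadata, n_perm = 19,
                                   strata = NULL, seed = 1))
  ad <- vegan::adonis2(as.dist(unclass(d)) ~ year * species * sex,
                       data = md, permutations = 19, by = "terms")
  expect_equal(pt$ss[1:7], ad$SumOfSqs[1:7], tolerance = 1e-10)
  expect_equal(pt$f[1:7], ad$F[1:7], tolerance = 1e-10)
  expect_equal(pt$r2[1:7], ad$R2[1:7], tolerance = 1e-10)
})

test_that("sampled p-values agree with exhaustive enumeration at n = 6", {
  withr::local_seed(8)
  n <- 6
  md <- make_metadata(sprintf("s%02d", 1:n),
                      rep(c("marthae", "subcristatus"), each = 3))
  X <- matrix(rnorm(n * 2), n, 2)
  X[md$species == "marthae", 1] <- X[md$species == "marthae", 1] + 1.5
  d <- euclid_d(X)

  # independent one-way pseudo-F from the group-sum identity:
  # SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2
  f_for <- function(perm) {
    dp <- d[perm, perm]
    ss_total <- sum(dp[lower.tri(dp)]^2) / n
    ss_within <- sum(vapply(unique(md$species), function(sp) {
      idx <- which(md$species == sp)
      sum(dp[idx, idx][lower.tri(dp[idx, idx])]^2) / length(idx)
    }, numeric(1)))
    (ss_total - ss_within) / (ss_within / (n - 2))
  }
  f_obs <- f_for(1:n)
  expect_equal(permanova(d, md, terms = "species", n_perm = 9,
                         strata = NULL, seed = 1)$f[1], f_obs,
               tolerance = 1e-10)
  f_all <- vapply(all_perms(n), f_for, numeric(1))
  p_exact <- mean(f_all >= f_obs)

  pt <- permanova(d, md, terms = "species", n_perm = 9999, strata = NULL,
                  seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(pt$p[1] - p_exact), 3 * se + 2 / 9999)
})

test_that("no-signal input gives F near 0 and p = 1", {
  m <- rbind(matrix(rep(c(60, 40), 6), 6, 2, byrow = TRUE))
  rownames(m) <- sprintf("s%d", 1:6); colnames(m) <- c("c1", "c2")
  md <- make_metadata(rownames(m),
                      rep(c("marthae", "subcristatus"), each = 3))
  d <- unclass(bray_curtis_matrix(make_table(m)))
  pt <- permanova(d, md, terms = "species", n_perm = 99, strata = NULL,
                  seed = 1)
  expect_lt(abs(pt$ss[1]), 1e-12)
  expect_equal(pt$p[1], 1)
})

test_that("p-values are invariant to factor relabeling", {
  gen <- generate_profiles(two_group_spec(14, n_per_group = 10, delta = 1))
  d <- bray_curtis_matrix(gen$table)
  md <- gen$metadata
  md2 <- md
  md2$species <- ifelse(md$species == "marthae", "subcristatus", "marthae")
  p1 <- permanova(d, md, terms = "species", n_perm = 199, seed = 5,
                  strata = NULL)$p[1]
  p2 <- permanova(d, md2, terms = "species", n_perm = 199, seed = 5,
                  strata = NULL)$p[1]
  expect_equal(p1, p2)
})

test_that("strata-restricted permutations never cross strata levels", {
  withr::local_seed(10)
  strata <- factor(rep(c("2012", "2014", "2015"), times = c(6, 5, 4)))
  for (i in 1:50) {
    p <- permute_indices(length(strata), strata)
    expect_identical(strata[p], strata)
    expect_identical(sort(p), seq_along(strata))
  }
})

test_that("aliasing: partial columns drop, full terms error", {
  gen <- generate_profiles(default_study_spec(2))
  d <- bray_curtis_matrix(gen$table)
  expect_warning(permanova(d, gen$metadata, n_perm = 9, seed = 1),
                 "aliased design column")
  md <- gen$metadata
  md$dup <- md$species   # perfectly confounded factor
  expect_error(suppressWarnings(
    permanova(d, md, terms = c("species", "dup"), n_perm = 9, seed = 1)),
    "fully aliased.*dup")
})

test_that("numeric year coding gives df = 1 for the year term", {
  gen <- generate_profiles(default_study_spec(2))
  d <- bray_curtis_matrix(gen$table)
  pt <- permanova(d, gen$metadata, n_perm = 9, seed = 1,
                  year_numeric = TRUE)
  expect_equal(pt$df[pt$term == "year"], 1)
  expect_equal(pt$df[1:7], rep(1, 7))
})
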