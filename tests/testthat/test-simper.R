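test_that("hand example: disjoint one-compound groups split the distance", {
  m <- rbind(A1 = c(100, 0, 0), A2 = c(100, 0, 0),
             B1 = c(0, 100, 0), B2 = c(0, 100, 0))
  colnames(m) <- c("c1", "c2", "c3")
  res <- simper(make_table(m), c("A", "A", "B", "B"), n_perm = 9, seed = 1)
  avg <- res$average[match(c("c1", "c2", "c3"), res$compound_id)]
  expect_equal(avg, c(0.5, 0.5, 0), tolerance = 1e-12)
  expect_equal(attr(res, "mean_dissimilarity"), 1)
  expect_equal(res$cumulative[nrow(res)], 1)
})

test_that("identical groups decompose a zero distance", {
  m <- rbind(a = c(60, 40), b = c(60, 40), c = c(60, 40), d = c(60, 40))
  colnames(m) <- c("c1", "c2")
  res <- simper(make_table(m), c("A", "A", "B", "B"), n_perm = 9, seed = 1)
  expect_equal(res$average, c(0, 0))
})

test_that("contributions equal the brute-force pairwise-loop oracle", {
  for (seed in 1:10) {
    tab <- random_sparse_table(6, 5, seed = seed)
    grp <- rep(c("A", "B"), each = 3)
    res <- simper(tab, grp, n_perm = 9, seed = seed)
    oracle <- simper_oracle(tab$abundances, grp)
    expect_lt(max(abs(res$average[match(compound_ids(tab),
                                        res$compound_id)] - oracle)),
              1e-12)
  }
})

test_that("conservation: contributions sum to mean between-group distance", {
  for (seed in 1:20) {
    tab <- random_sparse_table(10, 8, seed = 100 + seed)
    grp <- rep(c("A", "B"), each = 5)
    res <- simper(tab, grp, n_perm = 0, seed = 1)
    d <- unclass(bray_curtis_matrix(tab))
    expect_lt(abs(sum(res$average) - mean(d[1:5, 6:10])), 1e-10)
    expect_true(all(diff(res$cumulative) >= -1e-12))
  }
})

test_that("permutation p-values are invariant to group-label swap", {
  tab <- random_sparse_table(8, 6, seed = 33)
  grp <- rep(c("A", "B"), each = 4)
  r1 <- simper(tab, grp, n_perm = 199, seed = 7)
  r2 <- simper(tab, ifelse(grp == "A", "B", "A"), n_perm = 199, seed = 7)
  expect_equal(r1$p_perm[order(r1$compound_id)],
               r2$p_perm[order(r2$compound_id)])
})

test_that("planted markers are recovered as significant top contributors", {
  # contribution ranks are abundance-weighted, so a low-baseline marker can
  # sit below abundant noise compounds; recovery = small permutation p for
  # every marker, with a marker leading the significant set
  withr::local_seed(60)
  hits <- replicate(20, {
    seed <- sample.int(1e6, 1)
    gen <- generate_profiles(two_group_spec(seed, n_per_group = 25,
                                            delta = 3))
    res <- simper(gen$table, gen$metadata$species, n_perm = 99,
                  seed = seed)
    markers <- c("c001", "c002", "c003")
    sig <- res$compound_id[res$p_perm < 0.05]   # already contribution-sorted
    all(res$p_perm[res$compound_id %in% markers] < 0.05) &&
      sig[1] %in% markers
  })
  expect_gte(mean(hits), 0.9)
})

test_that("consistent markers intersect per-season significant sets", {
  gen12 <- generate_profiles(two_group_spec(71, n_per_group = 25, delta = 3))
  gen14 <- generate_profiles(two_group_spec(72, n_per_group = 20, delta = 3))
  r12 <- simper(gen12$table, gen12$metadata$species, n_perm = 199, seed = 1)
  r14 <- simper(gen14$table, gen14$metadata$species, n_perm = 199, seed = 2)
  cm <- consistent_markers(list(`2012` = r12, `2014` = r14), alpha = 0.01)
  expect_true(all(c("c001", "c002", "c003") %in% cm$markers))
  expect_true(all(cm$table$p_2012 < 0.01 & cm$table$p_2014 < 0.01))

  # identical results -> intersection is each season's significant set
  cm2 <- consistent_markers(list(a = r12, b = r12), alpha = 0.01)
  expect_setequal(cm2$markers, r12$compound_id[r12$p_perm < 0.01])
  # disjoint sets -> empty with warning
  fake <- r14
  fake$p_perm <- ifelse(fake$compound_id %in% cm$markers, 1, fake$p_perm)
  expect_warning(cm3 <- consistent_markers(list(a = r12, b = fake)),
                 "no consistently")
  expect_length(cm3$markers, 0)
})

test_that("Bonferroni flags use the total-compound divisor", {
  tab <- random_sparse_table(8, 20, seed = 55)
  res <- simper(tab, rep(c("A", "B"), each = 4), n_perm = 99, seed = 3)
  expect_equal(attr(res, "alpha_bonferroni"), 0.05 / 20)
  expect_identical(res$sig_bonferroni, res$p_perm < 0.05 / 20)
})

test_that("PCA selection finds the dominant-variance compound", {
  withr::local_seed(40)
  # two perfectly correlated compounds -> one component carries everything
  z <- rnorm(30)
  m <- cbind(c1 = z, c2 = 2 * z + 5)
  rownames(m) <- sprintf("s%02d", 1:30)
  sel <- pca_select(m + 100, cumulative_threshold = 0.75)
  expect_equal(sel$variance_explained[1], 1, tolerance = 1e-10)
  expect_equal(sel$retained, 1)

  # covariance-mode: variance-9 vs variance-1 uncorrelated pair
  m2 <- cbind(hi = rnorm(500, sd = 3), lo = rnorm(500, sd = 1))
  rownames(m2) <- sprintf("s%03d", 1:500)
  sel2 <- pca_select(m2, scale. = FALSE)
  expect_equal(sel2$variance_explained[1], 0.9, tolerance = 0.03)
  expect_equal(sel2$top_variance_compound, "hi")

  # constant columns are dropped with a warning
  m3 <- cbind(m2, flat = rep(1, 500))
  expect_warning(sel3 <- pca_select(m3, scale. = FALSE), "constant")
  expect_equal(nrow(sel3$loadings), 2)
})

test_that("a dominant planted marker tops the PCA of the marker set", {
  gen <- generate_profiles(two_group_spec(81, n_per_group = 40, delta = 4))
  sel <- pca_select(gen$table, compounds = sprintf("c%03d", 1:7),
                    scale. = FALSE)
  expect_true(sel$top_variance_compound %in% c("c001", "c002", "c003"))
})
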