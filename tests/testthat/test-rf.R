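test_that("stratified splits keep class proportions and are exhaustive", {
  labels <- factor(rep(c("marthae", "subcristatus"), c(116, 111)))
  sp <- stratified_split(labels, 0.5, seed = 1)
  expect_equal(sum(labels[sp$train] == "marthae"), 58)
  expect_equal(sum(labels[sp$train] == "subcristatus"), 56)  # 55.5 -> up
  expect_equal(sum(labels[sp$test] == "marthae"), 58)
  expect_equal(sum(labels[sp$test] == "subcristatus"), 55)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))

  expect_identical(stratified_split(labels, 0.5, seed = 9),
                   stratified_split(labels, 0.5, seed = 9))
  expect_error(stratified_split(factor(c("a", "b", "b")), 0.5), "size < 2")
  expect_error(stratified_split(labels, 0.999), "empty")
})

test_that("kappa matches its closed form and handles degenerate margins", {
  expect_equal(kappa_from_confusion(50, 0, 50, 0), 1)
  # Table-4-style worked example: sensitivity 0.966, specificity 0.958,
  # class sizes 116 / 111
  tp <- 0.966 * 116; fn <- 116 - tp; tn <- 0.958 * 111; fp <- 111 - tn
  expect_equal(round(kappa_from_confusion(tp, fp, tn, fn), 3), 0.924)
  # independent margins (exact product table) -> chance agreement, kappa 0
  n <- 200; p1 <- 0.3; p2 <- 0.6
  expect_lt(abs(kappa_from_confusion(n * p1 * p2, n * (1 - p1) * p2,
                                     n * (1 - p1) * (1 - p2),
                                     n * p1 * (1 - p2))), 1e-12)
  expect_warning(k <- kappa_from_confusion(10, 0, 0, 0), "degenerate")
  expect_equal(k, 1)
})

test_that("ROC/AUC equals the Mann-Whitney rank oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c("a", "a", "b", "b"), "a")
  expect_equal(r$auc, 1)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)

  withr::local_seed(3)
  for (i in 1:5) {
    s <- round(runif(60), 2)          # rounding forces score ties
    l <- sample(c("a", "b"), 60, replace = TRUE, prob = c(0.4, 0.6))
    u <- unname(stats::wilcox.test(s[l == "a"], s[l == "b"],
                                   exact = FALSE)$statistic)
    expect_equal(roc_auc(s, l, "a")$auc,
                 u / (sum(l == "a") * sum(l == "b")), tolerance = 1e-10)
  }
  # labels independent of scores -> AUC near 1/2
  s <- runif(2000); l <- sample(c("a", "b"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(s, l, "a")$auc - 0.5), 3 * sqrt(1 / (4 * 500)))
  expect_error(roc_auc(1:3, c("a", "a", "a"), "a"), "both classes")
})

test_that("chi-squared uniformity statistic hits its closed forms", {
  u <- chi2_uniformity(c(1000, rep(0, 10)))
  expect_equal(u$stat, 1000 * 10)      # all mass on one of 11 categories
  expect_equal(u$df, 10)
  expect_equal(chi2_uniformity(rep(25, 8))$stat, 0)
  expect_equal(chi2_uniformity(rep(25, 8))$p, 1)
})

test_that("tuning picks the OOB-best grid point deterministically", {
  gen <- generate_profiles(two_group_spec(91, n_per_group = 20, delta = 3))
  single <- rf_tune(gen$table, gen$metadata$species,
                    data.frame(n_trees = 100, mtry = 5), seed = 1)
  expect_equal(single$n_trees, 100)
  expect_equal(single$mtry, 5)

  grid <- data.frame(n_trees = c(100, 100, 200), mtry = c(3, 6, 3))
  t1 <- rf_tune(gen$table, gen$metadata$species, grid, seed = 2)
  t2 <- rf_tune(gen$table, gen$metadata$species, grid, seed = 2)
  expect_identical(t1, t2)
  expect_true(all(t1$grid$oob_error < 0.1))   # strongly separable data

  expect_error(rf_tune(gen$table, gen$metadata$species,
                       data.frame(n_trees = 10, mtry = 1000), seed = 1),
               "mtry exceeds")
})

test_that("protocol aggregates runs reproducibly", {
  gen <- generate_profiles(two_group_spec(17, n_per_group = 25, delta = 3))
  cfg <- rf_config(n_runs = 10, n_trees = 100, mtry = 5, master_seed = 4)
  r1 <- rf_protocol(gen$table, gen$metadata$species, cfg)
  r2 <- rf_protocol(gen$table, gen$metadata$species, cfg)
  expect_identical(r1$frequency, r2$frequency)
  expect_identical(r1$per_run, r2$per_run)
  expect_equal(r1$auc, r2$auc)

  expect_equal(sum(r1$frequency), 10)
  expect_equal(r1$chi2_df, length(r1$frequency) - 1)
  expect_equal(r1$metrics[["accuracy"]], mean(r1$per_run$accuracy))
  expect_true(all(r1$per_run$ci_low <= r1$per_run$accuracy &
                    r1$per_run$accuracy <= r1$per_run$ci_high))
  n_test <- 24   # 25 per class at 0.5: 13 train / 12 test each
  expect_true(all(r1$per_run$tp + r1$per_run$fp + r1$per_run$tn +
                    r1$per_run$fn == n_test))
  # per-run Clopper-Pearson CI is the exact binomial interval
  i <- 1
  ci <- stats::binom.test(r1$per_run$tp[i] + r1$per_run$tn[i],
                          n_test)$conf.int
  expect_equal(r1$per_run$ci_low[i], ci[1])
  expect_equal(r1$per_run$ci_high[i], ci[2])

  # averaged-AUC variant stays in [0, 1] and near the pooled one here
  r3 <- rf_protocol(gen$table, gen$metadata$species, cfg, pooled_roc = FALSE)
  expect_true(r3$auc >= 0 && r3$auc <= 1)
  expect_lt(abs(r3$auc - r1$auc), 0.1)
})
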