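#' Configuration for the repeated random-forest protocol
#'
#' The study protocol: 1,000 independent stratified ~50/50 train/test
#' splits; a forest tuned to 500 trees and 17 candidate variables per split
#' fitted on each training set; per-run confusion metrics on the test set;
#' the top compound by mean decrease in Gini impurity tallied per run.
#'
#' @param n_runs number of randomized splits.
#' @param train_fraction fraction of each class assigned to training
#'   (rounded half-up per class).
#' @param n_trees trees per forest.
#' @param mtry candidate variables per split.
#' @param positive_class label treated as positive for sensitivity /
#'   specificity (the study's positive class is the pink iguana,
#'   `marthae`).
#' @param master_seed integer; fans out one deterministic child seed per
#'   run.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_runs = 1000, train_fraction = 0.5, n_trees = 500,
                      mtry = 17, positive_class = "marthae",
                      master_seed = 1L) {
  stopifnot(n_runs >= 1, train_fraction > 0, train_fraction < 1,
            n_trees >= 1, mtry >= 1)
  structure(list(n_runs = as.integer(n_runs),
                 train_fraction = train_fraction,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 positive_class = positive_class,
                 master_seed = as.integer(master_seed)),
            class = "rf_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Class-stratified train/test split
#'
#' Per class, `round(class_n * train_fraction)` samples (half-up rounding)
#' go to training, the rest to test, so class proportions in both halves
#' track the full data. Disjoint and exhaustive.
#'
#' @param labels factor (or coercible) of class labels.
#' @param train_fraction training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.5, seed = 1L) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (any(sizes < 2)) stop("class(es) of size < 2: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  n_train <- round_half_up(sizes * train_fraction)
  if (any(n_train == sizes) || any(n_train == 0))
    stop("train_fraction leaves an empty train or test class")
  train <- with_seed(seed, {
    unlist(lapply(levels(labels), function(lv) {
      members <- which(labels == lv)
      sample(members, n_train[[lv]])
    }), use.names = FALSE)
  })
  list(train = sort(train),
       test = setdiff(seq_along(labels), train))
}

#' Tune forest size and mtry by out-of-bag error
#'
#' Evaluates each grid point on the full data by OOB error; ties broken
#' toward the smaller mtry, then the smaller number of trees.
#'
#' @param x a `compound_table` or matrix of predictors.
#' @param labels class labels.
#' @param grid data.frame with columns `n_trees` and `mtry`.
#' @param seed integer seed.
#' @return list with the chosen `n_trees`, `mtry` and the evaluated `grid`
#'   (with an `oob_error` column).
#' @export
rf_tune <- function(x, labels, grid, seed = 1L) {
  m <- if (inherits(x, "compound_table")) x$abundances else x
  stopifnot(nrow(grid) >= 1, all(c("n_trees", "mtry") %in% names(grid)))
  if (any(grid$mtry > ncol(m)))
    stop("mtry exceeds the number of compounds (", ncol(m), ")")
  labels <- factor(labels)
  seeds <- derive_seeds(seed, nrow(grid))
  grid$oob_error <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- with_seed(seeds[i],
      randomForest::randomForest(m, labels, ntree = grid$n_trees[i],
                                 mtry = grid$mtry[i]))
    mean(fit$predicted != labels)
  }, numeric(1))
  best <- grid[order(grid$oob_error, grid$mtry, grid$n_trees), ][1, ]
  list(n_trees = best$n_trees, mtry = best$mtry, grid = grid)
}

#' Cohen's kappa from a 2x2 confusion
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = (tp + tn)/N} and chance agreement
#' \eqn{p_e = [(tp+fp)(tp+fn) + (tn+fn)(tn+fp)] / N^2}. When the margins
#' are fully concentrated (`p_e = 1`), kappa is defined as 1 for perfect
#' agreement and 0 otherwise, with a warning.
#'
#' @param tp,fp,tn,fn confusion counts (positive class on rows of the
#'   usual layout).
#' @return kappa in \[-1, 1\].
#' @export
kappa_from_confusion <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  if (n <= 0) stop("empty confusion")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  if (abs(1 - pe) < 1e-15) {
    warning("degenerate margins; kappa set by agreement")
    return(if (abs(po - 1) < 1e-15) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve and AUC from scores
#'
#' Threshold sweep over the unique score values (ties share a threshold):
#' points are (FPR, TPR) for the rule "positive if score >= t", completed
#' by (0,0) and (1,1); AUC by the trapezoidal rule, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param scores numeric positive-class scores (e.g. forest vote
#'   fractions).
#' @param labels class labels; both classes must be present.
#' @param positive label of the positive class.
#' @return list with `roc` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive) {
  is_pos <- labels == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_pos) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_pos) / n0, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Chi-squared test of uniform category frequencies
#'
#' \eqn{\chi^2 = \sum_k (O_k - E)^2 / E} with \eqn{E = n / k} over the k
#' supplied categories, df = k - 1. With all n counts on one of k
#' categories the statistic reaches its maximum n(k - 1).
#'
#' @param counts non-negative category counts.
#' @return list with `stat`, `df`, `p`.
#' @export
chi2_uniformity <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 2, all(counts >= 0), sum(counts) > 0)
  expected <- sum(counts) / length(counts)
  stat <- sum((counts - expected)^2 / expected)
  list(stat = stat, df = length(counts) - 1,
       p = stats::pchisq(stat, df = length(counts) - 1, lower.tail = FALSE))
}

#' Repeated stratified random-forest importance-stability protocol
#'
#' For each run: a fresh stratified split, a forest on the training half
#' (bootstrap per tree, `mtry` candidate variables per node, Gini impurity
#' splitting, majority voting), test-set confusion with accuracy, Cohen's
#' kappa, sensitivity, specificity and an exact (Clopper-Pearson) 95%
#' accuracy CI, the top-1 compound by mean decrease in Gini, and per-sample
#' positive-class vote fractions. Aggregation: a frequency table of top
#' compounds over runs; a chi-squared uniformity test over the k compounds
#' observed as top at least once (`E = n_runs / k`, `df = k - 1`); means of
#' the per-run metrics; and a ROC/AUC from the pooled test-set vote
#' fractions across runs (per-run AUC averaging via `pooled_roc = FALSE`).
#' Bit-reproducible for a fixed `master_seed`.
#'
#' @param x a `compound_table` or predictor matrix.
#' @param labels binary class labels aligned with rows.
#' @param config an [rf_config()].
#' @param pooled_roc build one ROC from pooled votes (default) or average
#'   per-run AUCs.
#' @return list of class `rf_stability`: `frequency` (named counts summing
#'   to `n_runs`), `chi2_stat`, `chi2_df`, `chi2_p`, `metrics` (averaged),
#'   `per_run` (data.frame of run metrics), `roc`, `auc`, `config`.
#' @export
rf_protocol <- function(x, labels, config = rf_config(),
                        pooled_roc = TRUE) {
  m <- if (inherits(x, "compound_table")) x$abundances else x
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("protocol requires binary labels")
  if (!config$positive_class %in% levels(labels))
    stop("positive_class not a label level")
  if (config$mtry > ncol(m)) stop("mtry exceeds the number of compounds")
  pos <- config$positive_class

  seeds <- derive_seeds(config$master_seed, 2L * config$n_runs)
  per_run <- vector("list", config$n_runs)
  top <- character(config$n_runs)
  pooled_scores <- vector("list", config$n_runs)
  pooled_labels <- vector("list", config$n_runs)

  run_once <- function(seed) {
    split <- stratified_split(labels, config$train_fraction, seed)
    if (length(unique(labels[split$test])) < 2) return(NULL)
    fit <- with_seed(seed + 1L,
      randomForest::randomForest(m[split$train, , drop = FALSE],
                                 labels[split$train],
                                 ntree = config$n_trees,
                                 mtry = config$mtry))
    votes <- stats::predict(fit, m[split$test, , drop = FALSE],
                            type = "vote")[, pos]
    pred <- stats::predict(fit, m[split$test, , drop = FALSE],
                           type = "response")
    truth <- labels[split$test]
    tp <- sum(pred == pos & truth == pos)
    fp <- sum(pred == pos & truth != pos)
    tn <- sum(pred != pos & truth != pos)
    fn <- sum(pred != pos & truth == pos)
    n_test <- length(truth)
    ci <- stats::binom.test(tp + tn, n_test)$conf.int
    gini <- fit$importance[, "MeanDecreaseGini"]
    best <- which(gini == max(gini))
    if (length(best) > 1)
      warning("Gini importance tie; broken lexicographically")
    list(metrics = data.frame(
           accuracy = (tp + tn) / n_test,
           kappa = kappa_from_confusion(tp, fp, tn, fn),
           sensitivity = tp / (tp + fn),
           specificity = tn / (tn + fp),
           ci_low = ci[1], ci_high = ci[2],
           tp = tp, fp = fp, tn = tn, fn = fn),
         top = sort(names(best))[1],
         scores = votes, truth = as.character(truth))
  }

  spare <- length(seeds)
  for (r in seq_len(config$n_runs)) {
    res <- run_once(seeds[r])
    while (is.null(res)) {           # degenerate single-class test set
      message("degenerate run discarded; drawing replacement")
      res <- run_once(seeds[spare]); spare <- spare - 1L
    }
    per_run[[r]] <- res$metrics
    top[r] <- res$top
    pooled_scores[[r]] <- res$scores
    pooled_labels[[r]] <- res$truth
  }

  per_run <- do.call(rbind, per_run)
  freq <- table(top)
  k <- length(freq)
  if (k > 1) {
    u <- chi2_uniformity(as.numeric(freq))
    chi2 <- u$stat; chi2_p <- u$p
  } else {
    chi2 <- NA_real_; chi2_p <- NA_real_
  }
  if (pooled_roc) {
    rr <- roc_auc(unlist(pooled_scores), unlist(pooled_labels), pos)
    roc <- rr$roc; auc <- rr$auc
  } else {
    aucs <- mapply(function(s, l) roc_auc(s, l, pos)$auc,
                   pooled_scores, pooled_labels)
    roc <- NULL; auc <- mean(aucs)
  }
  structure(list(frequency = freq, chi2_stat = chi2, chi2_df = k - 1,
                 chi2_p = chi2_p,
                 metrics = colMeans(per_run[, c("accuracy", "kappa",
                                                "sensitivity", "specificity",
                                                "ci_low", "ci_high")]),
                 per_run = per_run, roc = roc, auc = auc, config = config),
            class = "rf_stability")
}

#' @export
print.rf_stability <- function(x, ...) {
  cat(sprintf("RF stability: %d runs, %d distinct top compounds\n",
              x$config$n_runs, length(x$frequency)))
  cat(sprintf("  chi2 = %.1f (df = %d, p = %.3g); AUC = %.3f\n",
              x$chi2_stat, x$chi2_df, x$chi2_p, x$auc))
  print(round(x$metrics, 3))
  invisible(x)
}
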