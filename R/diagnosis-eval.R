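# Random-forest diagnosis under leave-one-out with nested hyperparameter
# selection, plus the evaluation statistics.

#' Rank-based area under the ROC curve
#'
#' AUC with half credit for ties; identical to the normalized Mann-Whitney
#' statistic `U / (n1 * n2)` of the positive-class probabilities.
#'
#' @param probs Numeric scores (higher = more ASD-like).
#' @param labels Vector with both classes present; `positive` marks the
#'   positive class.
#' @param positive Positive-class label (default `"ASD"`).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(probs, labels, positive = "ASD") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold classification metrics
#'
#' Predicts the positive class when the probability is at or above the
#' threshold; reports accuracy, sensitivity (recall on the positive class)
#' and specificity.
#'
#' @inheritParams roc_auc
#' @param threshold Probability threshold (default 0.5).
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(probs, labels, threshold = 0.5,
                              positive = "ASD") {
  pos <- labels == positive
  assert_that(sum(pos) > 0 && sum(!pos) > 0, "both classes must be present")
  pred <- probs >= threshold
  list(
    accuracy = mean(pred == pos),
    sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos)
  )
}

#' Default hyperparameter grid
#'
#' The crossed grid of tree depth and minimum samples per leaf
#' {1, 2, 4, 8, 16, 32, 64} x {1, 2, 4, 8, 16, 32, 64}.
#'
#' @param depths,leaves Candidate values.
#' @return Data frame with columns `depth`, `leaf`.
#' @export
default_grid <- function(depths = c(1, 2, 4, 8, 16, 32, 64),
                         leaves = c(1, 2, 4, 8, 16, 32, 64)) {
  expand.grid(depth = depths, leaf = leaves)
}

impute_median <- function(train, test) {
  med <- apply(train, 2, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  fill <- function(M) {
    for (j in seq_len(ncol(M))) {
      bad <- is.na(M[, j])
      if (any(bad)) M[bad, j] <- med[j]
    }
    M
  }
  list(train = fill(train), test = fill(test))
}

# Probability forest with balanced per-tree class sampling: each tree draws
# the same number of subjects from both classes, so leave-one-out folds
# (which always leave the held-out subject's class one short) do not push
# class base rates against the held-out subject.
fit_predict_rf <- function(Xtr, ytr, Xte, n_trees, depth, leaf, seed) {
  n <- length(ytr)
  m <- min(table(ytr))
  fit <- ranger::ranger(
    x = Xtr, y = ytr, num.trees = n_trees,
    max.depth = depth, min.node.size = leaf,
    probability = TRUE, num.threads = 1, seed = seed,
    sample.fraction = rep(m / n, 2), replace = TRUE,
    respect.unordered.factors = FALSE
  )
  pr <- stats::predict(fit, data = Xte, num.threads = 1)$predictions
  pr[, "ASD"]
}

# stratified fold assignment (deterministic under the caller's RNG)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Leave-one-out diagnosis with nested hyperparameter selection
#'
#' For each held-out subject, an inner stratified k-fold cross-validation on
#' the remaining subjects selects the tree depth and minimum leaf size
#' maximizing mean inner AUC (ties broken toward smaller depth, then larger
#' leaf — the simpler model); a probability random forest is then refit on
#' the full remainder and produces the held-out subject's out-of-sample
#' ASD probability (mean of per-tree class fractions). Missing feature
#' values are imputed by the training-fold median, inside each fold. The
#' held-out subject's data — including its label — never enters training.
#'
#' @param fm A `feature_matrix` (labels `"ASD"`/`"NT"`, at least 6 subjects
#'   per class).
#' @param grid Hyperparameter grid from [default_grid()].
#' @param n_trees Trees per forest (default 1000).
#' @param seed Integer seed; fixed seed gives a bit-identical result.
#' @param inner_folds Inner folds (default 3).
#' @param threshold Probability threshold for derived metrics.
#' @return Object of class `cv_result`: `subjects` data frame (one row per
#'   subject: `subject_id`, `label`, `prob`, `pred`, chosen `depth`/`leaf`),
#'   plus `auc`, `accuracy`, `sensitivity`, `specificity`, `seed`.
#' @export
loo_nested_cv <- function(fm, grid = default_grid(), n_trees = 1000,
                          seed = 1, inner_folds = 3, threshold = 0.5) {
  y <- factor(fm$meta$label, levels = c("NT", "ASD"))
  assert_that(nlevels(droplevels(y)) == 2, "need both classes in the data")
  assert_that(min(table(y)) >= inner_folds * 2,
              "too few subjects per class for stratified inner folds")
  X <- fm$X
  n <- nrow(X)
  probs <- numeric(n)
  chosen <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("depth", "leaf")))
  for (i in seq_len(n)) {
    # per-subject RNG substream: outer loop order never affects inner draws
    set.seed(child_seed(seed, paste0("outer", i)))
    Xtr_all <- X[-i, , drop = FALSE]
    ytr_all <- y[-i]
    fold <- stratified_folds(ytr_all, inner_folds)
    auc_fold <- matrix(NA_real_, nrow(grid), inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(ytr_all[!tr])) < 2) next
      imp <- impute_median(Xtr_all[tr, , drop = FALSE],
                           Xtr_all[!tr, , drop = FALSE])
      for (g in seq_len(nrow(grid))) {
        p <- fit_predict_rf(imp$train, ytr_all[tr], imp$test, n_trees,
                            grid$depth[g], grid$leaf[g],
                            seed = child_seed(seed, paste(i, f, g)))
        auc_fold[g, f] <- roc_auc(p, as.character(ytr_all[!tr]))
      }
    }
    mean_auc <- rowMeans(auc_fold, na.rm = TRUE)
    # ties -> smaller depth, then larger leaf
    ord <- order(-mean_auc, grid$depth, -grid$leaf)
    best <- ord[1]
    chosen[i, ] <- c(grid$depth[best], grid$leaf[best])
    imp <- impute_median(Xtr_all, X[i, , drop = FALSE])
    probs[i] <- fit_predict_rf(imp$train, ytr_all, imp$test, n_trees,
                               grid$depth[best], grid$leaf[best],
                               seed = child_seed(seed, paste0("refit", i)))
  }
  subjects <- data.frame(
    subject_id = fm$meta$subject_id,
    label = as.character(y),
    prob = probs,
    pred = ifelse(probs >= threshold, "ASD", "NT"),
    depth = chosen[, "depth"],
    leaf = chosen[, "leaf"],
    stringsAsFactors = FALSE
  )
  cm <- confusion_metrics(probs, as.character(y), threshold)
  structure(list(subjects = subjects,
                 auc = roc_auc(probs, as.character(y)),
                 accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                 specificity = cm$specificity, seed = seed,
                 threshold = threshold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("<cv_result> n = %d, AUC = %.3f, accuracy = %.2f, ",
                     "sensitivity = %.2f, specificity = %.2f (seed %s)\n"),
              nrow(x$subjects), x$auc, x$accuracy, x$sensitivity,
              x$specificity, format(x$seed)))
  invisible(x)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold`, `fpr`, `tpr` over all score cut points.
#' @export
roc_points <- function(probs, labels, positive = "ASD") {
  pos <- labels == positive
  th <- c(Inf, sort(unique(probs), decreasing = TRUE))
  data.frame(
    threshold = th,
    fpr = vapply(th, function(t) sum(probs >= t & !pos) / sum(!pos),
                 numeric(1)),
    tpr = vapply(th, function(t) sum(probs >= t & pos) / sum(pos),
                 numeric(1))
  )
}

#' Majority-vote baseline predictions
#'
#' @param labels Class labels.
#' @return Vector predicting the most frequent class for every subject
#'   (first level on an exact tie).
#' @export
majority_vote <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  rep(names(tab)[1], length(labels))
}

#' McNemar comparison of two classifiers
#'
#' Compares the per-subject correctness of two prediction vectors via the
#' discordant pairs: exact two-sided binomial p on the discordant count and
#' the continuity-corrected chi-square variant.
#'
#' @param preds_a,preds_b Predicted labels for the same subjects.
#' @param labels True labels.
#' @return List: `n_discordant`, `b` (A correct, B wrong), `c` (A wrong,
#'   B correct), `statistic` (chi-square), `p_exact`, `p_chisq`.
#' @export
mcnemar_vs_baseline <- function(preds_a, preds_b, labels) {
  assert_that(length(preds_a) == length(labels) &&
                length(preds_b) == length(labels),
              "prediction vectors must match the label vector")
  ca <- preds_a == labels
  cb <- preds_b == labels
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  nd <- b + cc
  if (nd == 0) {
    return(list(n_discordant = 0L, b = b, c = cc, statistic = 0,
                p_exact = 1, p_chisq = 1))
  }
  p_exact <- min(1, 2 * stats::pbinom(min(b, cc), nd, 0.5))
  stat <- (abs(b - cc) - 1)^2 / nd
  list(n_discordant = nd, b = b, c = cc, statistic = stat,
       p_exact = p_exact,
       p_chisq = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Spearman correlation of class probability with a covariate
#'
#' Rank correlation (average ranks on ties) of out-of-sample probabilities
#' with a severity score or age; exact p by permutation distribution for
#' small n (no ties), t-approximation otherwise.
#'
#' @param probs Numeric vector.
#' @param covariate Numeric vector, same length, at least 5 pairs after
#'   removing missing values.
#' @return List `rho`, `p`, `n`; `rho = NA` for a constant covariate.
#' @export
severity_correlation <- function(probs, covariate) {
  keep <- !is.na(probs) & !is.na(covariate)
  x <- probs[keep]; yv <- covariate[keep]
  assert_that(length(x) >= 5, "need at least 5 paired values")
  if (stats::sd(yv) == 0 || stats::sd(x) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ties <- any(duplicated(x)) || any(duplicated(yv))
  ct <- suppressWarnings(stats::cor.test(
    x, yv, method = "spearman",
    exact = !ties && length(x) <= 8
  ))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Expert-rating comparison
#'
#' Converts per-video visual-analog ratings (0-10) into predictions
#' (ASD iff rating >= 5, the boundary counting as ASD), computes per-rater
#' accuracy, and correlates accuracy with rater experience via
#' [severity_correlation()].
#'
#' @param ratings Data frame with columns `rater`, `subject_id`, `rating`.
#' @param labels Named vector of true labels (names = subject ids).
#' @param experience Named numeric vector (months) per rater, or `NULL`.
#' @return List: `per_rater` data frame (`rater`, `n`, `accuracy`),
#'   `mean_accuracy`, and `experience_cor` (or `NULL`).
#' @export
expert_comparison <- function(ratings, labels, experience = NULL) {
  pred <- ifelse(ratings$rating >= 5, "ASD", "NT")
  correct <- pred == labels[as.character(ratings$subject_id)]
  per <- stats::aggregate(correct,
                          by = list(rater = ratings$rater),
                          FUN = mean)
  names(per)[2] <- "accuracy"
  per$n <- as.integer(table(ratings$rater)[as.character(per$rater)])
  res <- list(per_rater = per[c("rater", "n", "accuracy")],
              mean_accuracy = mean(per$accuracy),
              experience_cor = NULL)
  if (!is.null(experience) && length(per$rater) >= 5) {
    res$experience_cor <- severity_correlation(
      per$accuracy, experience[as.character(per$rater)]
    )
  }
  res
}
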