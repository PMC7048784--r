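test_that("rank AUC equals brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("ASD", "ASD", "NT", "NT")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("ASD", "NT"), 3)), 0.5)

  set.seed(17)
  for (rep in 1:10) {
    probs <- round(runif(8), 2)  # rounding forces occasional ties
    labels <- sample(rep(c("ASD", "NT"), 4))
    pos <- which(labels == "ASD"); neg <- which(labels == "NT")
    pairs <- expand.grid(i = pos, j = neg)
    brute <- mean(ifelse(probs[pairs$i] > probs[pairs$j], 1,
                         ifelse(probs[pairs$i] == probs[pairs$j], 0.5, 0)))
    expect_equal(roc_auc(probs, labels), brute)
  }
  expect_error(roc_auc(c(0.1, 0.2), c("ASD", "ASD")), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  probs <- runif(30)
  labels <- sample(rep(c("ASD", "NT"), 15))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, probs, levels = c("NT", "ASD"),
                        direction = "<"))
  ))
  expect_equal(roc_auc(probs, labels), ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone probability transforms", {
  set.seed(31)
  probs <- runif(20)
  labels <- sample(rep(c("ASD", "NT"), 10))
  a1 <- roc_auc(probs, labels)
  expect_equal(roc_auc(plogis(5 * probs - 2), labels), a1)
  expect_equal(roc_auc(probs^3, labels), a1)
})

test_that("confusion metrics match a hand-counted table", {
  probs <- c(0.9, 0.6, 0.4, 0.2, 0.55, 0.1)
  labels <- c("ASD", "ASD", "ASD", "NT", "NT", "NT")
  m <- confusion_metrics(probs, labels)
  # predictions: ASD ASD NT | NT ASD NT -> TP 2, FN 1, TN 2, FP 1
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 2 / 3)

  perfect <- confusion_metrics(c(1, 1, 0, 0), c("ASD", "ASD", "NT", "NT"))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  all_nt <- confusion_metrics(rep(0, 4), c("ASD", "ASD", "NT", "NT"))
  expect_equal(all_nt$sensitivity, 0)
  expect_equal(all_nt$specificity, 1)
})

test_that("a separating feature yields AUC 1 and noise stays near chance", {
  fm <- make_fm(6, p = 5, separator = TRUE, seed = 3)
  cv <- loo_nested_cv(fm, grid = default_grid(c(2, 8), c(1, 4)),
                      n_trees = 100, seed = 1)
  expect_equal(cv$auc, 1)
  expect_equal(nrow(cv$subjects), 12)
  expect_equal(anyDuplicated(cv$subjects$subject_id), 0)
  expect_true(all(cv$subjects$prob >= 0 & cv$subjects$prob <= 1))
})

test_that("the held-out subject's label never influences its probability", {
  fm <- make_fm(8, p = 8, seed = 5)
  cv1 <- loo_nested_cv(fm, grid = default_grid(4, 2), n_trees = 100,
                       seed = 11)
  fm_flip <- fm
  fm_flip$meta$label[3] <- ifelse(fm$meta$label[3] == "ASD", "NT", "ASD")
  cv2 <- loo_nested_cv(fm_flip, grid = default_grid(4, 2), n_trees = 100,
                       seed = 11)
  expect_identical(cv1$subjects$prob[3], cv2$subjects$prob[3])
})

test_that("a fixed seed reproduces the CV result bit-identically", {
  fm <- make_fm(6, p = 8, seed = 6)
  cv1 <- loo_nested_cv(fm, grid = default_grid(c(2, 16), 2), n_trees = 80,
                       seed = 42)
  cv2 <- loo_nested_cv(fm, grid = default_grid(c(2, 16), 2), n_trees = 80,
                       seed = 42)
  expect_identical(cv1$subjects, cv2$subjects)
  expect_identical(cv1$auc, cv2$auc)
})

test_that("single-class data is rejected", {
  fm <- make_fm(6, p = 4, seed = 2)
  fm$meta$label <- "ASD"
  expect_error(loo_nested_cv(fm), "both classes")
})

test_that("McNemar discordant-pair arithmetic matches hand calculation", {
  labels <- rep("ASD", 10)
  a <- rep("ASD", 10)                      # all correct
  b <- c(rep("NT", 8), "ASD", "ASD")       # 8 discordant, all favoring a
  m <- mcnemar_vs_baseline(a, b, labels)
  expect_equal(m$n_discordant, 8)
  expect_equal(m$p_exact, 2 * 0.5^8, tolerance = 1e-12)

  same <- mcnemar_vs_baseline(a, a, labels)
  expect_equal(same$p_exact, 1)

  # statistic is invariant to relabeling both classes
  labels2 <- c(rep("ASD", 5), rep("NT", 5))
  pa <- sample(c("ASD", "NT"), 10, replace = TRUE)
  pb <- sample(c("ASD", "NT"), 10, replace = TRUE)
  swap <- function(v) ifelse(v == "ASD", "NT", "ASD")
  m1 <- mcnemar_vs_baseline(pa, pb, labels2)
  m2 <- mcnemar_vs_baseline(swap(pa), swap(pb), swap(labels2))
  expect_equal(m1$statistic, m2$statistic)
})

test_that("majority vote predicts the modal class", {
  expect_equal(unique(majority_vote(c("NT", "NT", "ASD"))), "NT")
})

test_that("severity correlation matches exhaustive permutation at n = 6", {
  probs <- c(0.1, 0.3, 0.2, 0.8, 0.7, 0.9)
  sev <- c(1, 3, 2, 9, 6, 10)  # same rank order as probs
  r <- severity_correlation(probs, sev)
  expect_equal(r$rho, 1)  # perfectly monotone

  probs2 <- c(0.15, 0.3, 0.5, 0.62, 0.71, 0.9)
  sev2 <- c(4, 1, 6, 3, 5, 2)
  r2 <- severity_correlation(probs2, sev2)
  perms <- combinat_perms(6)
  rhos <- apply(perms, 1, function(p) cor(seq_len(6), p, method = "spearman"))
  p_oracle <- mean(abs(rhos) >= abs(r2$rho) - 1e-9)
  expect_equal(r2$p, p_oracle, tolerance = 1e-9)

  rev <- severity_correlation(probs, -probs)
  expect_equal(rev$rho, -1)
  expect_true(is.na(severity_correlation(probs, rep(1, 6))$rho))
})

test_that("expert ratings convert to accuracies with the >= 5 boundary", {
  labels <- c(s1 = "ASD", s2 = "NT", s3 = "ASD", s4 = "NT")
  ratings <- data.frame(
    rater = rep(c("r1", "r2", "r3"), each = 4),
    subject_id = rep(names(labels), 3),
    rating = c(10, 0, 9, 1,    # r1 perfect
               5, 5, 5, 5,     # r2 rates everyone exactly 5 -> all ASD
               0, 10, 1, 9)    # r3 inverted
  )
  res <- expert_comparison(ratings, labels)
  acc <- setNames(res$per_rater$accuracy, res$per_rater$rater)
  expect_equal(unname(acc["r1"]), 1)
  expect_equal(unname(acc["r2"]), 0.5)  # boundary 5 counts as ASD
  expect_equal(unname(acc["r3"]), 0)
  expect_equal(res$mean_accuracy, mean(c(1, 0.5, 0)))
})
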