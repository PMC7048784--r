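# Non-parametric group statistics with effect sizes and multiplicity control.

group_test_result <- function(test, statistic, p, effect_size = NA_real_,
                              z = NA_real_, df1 = NA_real_, df2 = NA_real_,
                              note = "") {
  data.frame(test = test, statistic = statistic, df1 = df1, df2 = df2,
             z = z, p = p, effect_size = effect_size, note = note,
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test with effect size
#'
#' Two-sided rank-sum comparison of two independent samples. `U` is the
#' rank-sum of `x` minus `n1(n1+1)/2`. The p-value is exact (full
#' enumeration of rank assignments) when `n1 + n2 <= exact_max` and there
#' are no ties, otherwise a normal approximation with tie correction. The
#' effect size is `r = |Z| / sqrt(n1 + n2)` from the (tie-corrected) normal
#' approximation.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param exact_max Maximum total sample size for the exact p (default 12).
#' @return One-row data frame (`test`, `statistic` = U, `z`, `p`,
#'   `effect_size`).
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  assert_that(length(x) >= 2 && length(y) >= 2,
              "both samples need at least 2 observations")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  if (!ties && n <= exact_max) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else if (sigma2 > 0) {
    # continuity-corrected normal approximation
    zc <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(zc, 0))
  } else {
    p <- 1
  }
  group_test_result("mann_whitney", U, min(p, 1),
                    effect_size = abs(z) / sqrt(n), z = z)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired comparison (e.g., emotional part vs neutral baseline).
#' Zero differences are dropped; `W` is the sum of positive-difference
#' ranks. Exact p by full sign enumeration (2^n assignments, valid also
#' under tied magnitudes) for `n <= exact_max`, otherwise a
#' continuity-corrected normal approximation with tie correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Maximum n (non-zero differences) for the exact p
#'   (default 12).
#' @return One-row data frame; `note = "degenerate"` and `p = NA` when all
#'   differences are zero.
#' @export
wilcoxon_signed <- function(x, y, exact_max = 12) {
  assert_that(length(x) == length(y), "samples must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(group_test_result("wilcoxon_signed", NA_real_, NA_real_,
                             note = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.numeric(signs %*% r)
    p <- mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
  } else if (sigma2 > 0) {
    zc <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(zc, 0))
  } else {
    p <- 1
  }
  group_test_result("wilcoxon_signed", W, min(p, 1),
                    effect_size = abs(z) / sqrt(n), z = z)
}

#' Two-way group x gender ANOVA with generalized eta squared
#'
#' Between-subjects two-way ANOVA with type-II sums of squares (robust to
#' unbalanced cells), reporting F, p and generalized eta squared
#' (`SS_effect / (SS_effect + SS_error)`, both factors treated as
#' manipulated) for each main effect and the interaction.
#'
#' @param values Numeric response.
#' @param group,gender Factors (or coercible) of the same length.
#' @return Data frame with rows `group`, `gender`, `group:gender`.
#' @export
anova_group_gender <- function(values, group, gender) {
  group <- factor(group); gender <- factor(gender)
  assert_that(all(table(group, gender) >= 2),
              "each group x gender cell needs at least 2 observations")
  d <- data.frame(y = values, g = group, s = gender)
  fit <- stats::lm(y ~ g * s, data = d)
  a2 <- car::Anova(fit, type = 2)
  ss <- a2[["Sum Sq"]]
  rows_wanted <- c("g", "s", "g:s")
  idx <- match(rows_wanted, rownames(a2))
  err <- which(rownames(a2) == "Residuals")
  out <- do.call(rbind, lapply(seq_along(rows_wanted), function(k) {
    i <- idx[k]
    group_test_result(
      test = c("group", "gender", "group:gender")[k],
      statistic = a2[["F value"]][i],
      p = a2[["Pr(>F)"]][i],
      effect_size = ss[i] / (ss[i] + ss[err]),
      df1 = a2[["Df"]][i], df2 = a2[["Df"]][err]
    )
  }))
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative counts with nonzero margins.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row data frame (`statistic` = X^2, `df1` = 1).
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2, 2)), "table must be 2x2")
  assert_that(all(table >= 0), "counts must be nonnegative")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "all margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  group_test_result("chi_square", unname(ct$statistic), ct$p.value,
                    df1 = unname(ct$parameter))
}

#' Holm step-down multiplicity correction
#'
#' @param pvals Numeric p-values in [0, 1].
#' @return Adjusted p-values (same order), monotone and capped at 1.
#' @export
holm_correct <- function(pvals) {
  assert_that(all(pvals >= 0 & pvals <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}
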