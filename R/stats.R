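#' Correlation pruning of a feature table
#'
#' Greedy elimination of highly correlated feature pairs: features are
#' visited in table (manifest) order; for each pair with absolute Pearson
#' correlation above the threshold, the later feature is dropped.
#' Correlations are computed on pairwise-complete observations.
#' Zero-variance features are dropped first (logged with rule
#' `"zero_variance"`).
#'
#' @param table Data frame or matrix of numeric features (patients x
#'   features), >= 3 patients.
#' @param threshold Absolute Pearson correlation above which the later
#'   feature of a pair is discarded (default 0.9).
#' @return List with `retained` (feature names, original order) and
#'   `dropped` (data frame: `feature`, `rule`, `partner`, `r`).
#' @export
prune_correlated <- function(table, threshold = 0.9) {
  x <- as.matrix(table)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  nm <- colnames(x)
  dropped <- list()
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  zv <- !is.finite(sds) | sds == 0
  for (f in nm[zv])
    dropped[[length(dropped) + 1]] <-
      data.frame(feature = f, rule = "zero_variance", partner = NA, r = NA)
  keep <- nm[!zv]
  x <- x[, keep, drop = FALSE]
  alive <- rep(TRUE, length(keep))
  if (length(keep) >= 2) {
    cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    for (i in seq_along(keep)) {
      if (!alive[i]) next
      for (j in seq_along(keep)) {
        if (j <= i || !alive[j]) next
        r <- cm[i, j]
        if (is.finite(r) && abs(r) > threshold) {
          alive[j] <- FALSE
          dropped[[length(dropped) + 1]] <-
            data.frame(feature = keep[j], rule = "correlation",
                       partner = keep[i], r = r)
        }
      }
    }
  }
  list(retained = keep[alive],
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(feature = character(), rule = character(),
                                 partner = character(), r = numeric()))
}

#' Two-group comparison with normality-driven test selection
#'
#' The univariate comparison applied to each feature: Shapiro--Wilk
#' normality per group at `alpha_gate`; if both groups are compatible with
#' normality, Levene's test decides between the pooled-variance Student
#' t-test and Welch's t-test; otherwise the two-sided Wilcoxon rank-sum test
#' is used (exact when the combined sample is small and untied, normal
#' approximation with tie correction otherwise). All tests are two-sided.
#'
#' @param values Numeric vector.
#' @param labels Two-level factor/vector aligned with `values`.
#' @param alpha_gate Significance level of the normality and
#'   homoscedasticity gatekeeper tests.
#' @param test `"auto"` (default), or force `"t"` / `"wilcoxon"`.
#' @param welch_fallback If `FALSE`, always use the pooled t-test in the
#'   normal branch regardless of Levene's result.
#' @return A `test_result`: list with `test_used` (`"t_pooled"`,
#'   `"t_welch"`, `"wilcoxon_ranksum"`), `statistic`, `p_value`,
#'   `direction` (sign of group-2 minus group-1 median), `n1`, `n2`,
#'   `normal` and `homoscedastic` flags.
#' @export
compare_groups <- function(values, labels, alpha_gate = 0.05,
                           test = c("auto", "t", "wilcoxon"),
                           welch_fallback = TRUE) {
  test <- match.arg(test)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]
  labels <- droplevels(factor(labels[ok]))
  if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  if (length(g1) < 3 || length(g2) < 3)
    stop("both groups need at least 3 complete observations")
  direction <- sign(stats::median(g2) - stats::median(g1))

  normal <- NA
  homosced <- NA
  if (test == "auto") {
    sw <- function(x) {
      if (stats::sd(x) == 0) return(0)  # degenerate: clearly non-normal
      stats::shapiro.test(x)$p.value
    }
    normal <- sw(g1) >= alpha_gate && sw(g2) >= alpha_gate
    branch <- if (normal) "t" else "wilcoxon"
  } else branch <- test

  if (branch == "t") {
    lev <- car::leveneTest(values ~ labels, center = mean)
    homosced <- lev[1, "Pr(>F)"] >= alpha_gate
    pooled <- homosced || !welch_fallback
    ht <- stats::t.test(g2, g1, var.equal = pooled)
    res <- list(test_used = if (pooled) "t_pooled" else "t_welch",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    n <- length(g1) + length(g2)
    ties <- anyDuplicated(values) > 0
    exact <- n <= 20 && !ties
    ht <- suppressWarnings(
      stats::wilcox.test(g2, g1, exact = exact, correct = !exact))
    res <- list(test_used = "wilcoxon_ranksum",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  structure(c(res, list(direction = direction,
                        n1 = length(g1), n2 = length(g2),
                        normal = normal, homoscedastic = homosced)),
            class = "test_result")
}

#' Univariate feature screen
#'
#' Runs [compare_groups()] on every feature of a (pruned) table and returns
#' the per-feature results, flagging those with `p < alpha`. No multiplicity
#' correction is applied by default; Benjamini--Hochberg adjustment is
#' available via `adjust = "BH"`.
#'
#' @param table Data frame of features (patients x features).
#' @param labels Two-level outcome aligned with rows.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param min_group Minimum complete observations per group; features below
#'   it are skipped with a log entry.
#' @param ... Passed to [compare_groups()].
#' @return List with `results` (data frame: feature, test_used, statistic,
#'   p_value, direction, n1, n2, significant), `significant` (feature
#'   names), and `skipped`.
#' @export
screen_features <- function(table, labels, alpha = 0.05, adjust = "none",
                            min_group = 3L, ...) {
  feats <- colnames(table)
  rows <- list()
  skipped <- character()
  for (f in feats) {
    v <- table[[f]]
    ok <- is.finite(v) & !is.na(labels)
    tab <- table(factor(labels[ok]))
    if (length(tab) < 2 || any(tab < min_group)) {
      skipped <- c(skipped, f)
      next
    }
    tr <- compare_groups(v, labels, ...)
    rows[[f]] <- data.frame(feature = f, test_used = tr$test_used,
                            statistic = tr$statistic, p_value = tr$p_value,
                            direction = tr$direction, n1 = tr$n1, n2 = tr$n2)
  }
  res <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(feature = character(), test_used = character(),
                         statistic = numeric(), p_value = numeric(),
                         direction = numeric(), n1 = integer(), n2 = integer())
  if (nrow(res) && adjust == "BH")
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  list(results = res,
       significant = res$feature[res$significant],
       skipped = skipped)
}
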