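test_that("correlation pruning drops the later member of correlated pairs", {
  set.seed(1)
  x <- rnorm(30)
  tab <- data.frame(a = x, b = rnorm(30), dup = x, c = rnorm(30))
  pr <- prune_correlated(tab, 0.9)
  expect_true("a" %in% pr$retained)
  expect_false("dup" %in% pr$retained)
  expect_equal(pr$dropped$partner[pr$dropped$feature == "dup"], "a")

  # three mutually correlated features -> one survivor under the greedy pass
  z <- rnorm(50)
  tri <- data.frame(f1 = z, f2 = z + rnorm(50, 0, 0.01),
                    f3 = z + rnorm(50, 0, 0.01))
  pr2 <- prune_correlated(tri, 0.9)
  expect_equal(pr2$retained, "f1")

  # near-orthogonal features all retained
  set.seed(2)
  ortho <- as.data.frame(qr.Q(qr(matrix(rnorm(100), 20, 5))))
  expect_equal(length(prune_correlated(ortho, 0.9)$retained), 5)

  # zero variance dropped first with its own rule
  zv <- data.frame(k = rep(1, 20), ok = rnorm(20), ok2 = rnorm(20))
  pr3 <- prune_correlated(zv, 0.9)
  expect_false("k" %in% pr3$retained)
  expect_equal(pr3$dropped$rule[pr3$dropped$feature == "k"], "zero_variance")
})

test_that("Wilcoxon branch matches exact enumeration on small samples", {
  # {1,2,3} vs {4,5,6}: 2/20 of the C(6,3) assignments are as extreme
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                      test = "wilcoxon")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$test_used, "wilcoxon_ranksum")
  expect_equal(r$direction, 1)

  # agreement with exhaustive permutation for combined n <= 10, over random draws
  perm_p <- function(x, g) {
    n <- length(x)
    idx1 <- which(g == unique(g)[1])
    combs <- combn(n, length(idx1))
    w_obs <- sum(rank(x)[idx1])
    ws <- apply(combs, 2, function(ii) sum(rank(x)[ii]))
    ew <- mean(ws)
    mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
  }
  set.seed(42)
  for (i in 1:12) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- sample(1:50, n1 + n2)           # untied
    g <- rep(c("a", "b"), c(n1, n2))
    r <- compare_groups(x, g, test = "wilcoxon")
    expect_equal(r$p_value, perm_p(x, g), tolerance = 1e-12,
                 label = paste("draw", i))
  }
})

test_that("label permutation of one pooled sample gives p = 1 under the exact test", {
  x <- c(3, 1, 4, 1.5, 5, 9)        # same values in both groups
  r <- compare_groups(c(x[1:3], x[1:3]), rep(c("a", "b"), each = 3),
                      test = "wilcoxon")
  expect_equal(r$p_value, 1)
})

test_that("test selection branches on Shapiro and Levene gates", {
  set.seed(7)
  g1 <- rnorm(30); g2 <- rnorm(30, 0.5)
  r <- compare_groups(c(g1, g2), rep(c("a", "b"), each = 30))
  expect_true(r$test_used %in% c("t_pooled", "t_welch"))
  expect_true(r$normal)
  # heavy-tailed data routes to Wilcoxon
  h1 <- rcauchy(30); h2 <- rcauchy(30)
  r2 <- compare_groups(c(h1, h2), rep(c("a", "b"), each = 30))
  expect_equal(r2$test_used, "wilcoxon_ranksum")
  # unequal variances with normal data route to Welch
  set.seed(8)
  v1 <- rnorm(40, 0, 1); v2 <- rnorm(40, 0, 5)
  r3 <- compare_groups(c(v1, v2), rep(c("a", "b"), each = 40))
  if (r3$test_used != "wilcoxon_ranksum") {
    expect_equal(r3$test_used, "t_welch")
    expect_false(r3$homoscedastic)
  }
  expect_error(compare_groups(1:5, c("a", "a", "b", "b", "b")), "at least 3")
})

test_that("screen respects alpha boundaries and patient order", {
  set.seed(3)
  tab <- as.data.frame(matrix(rnorm(40 * 6), 40))
  names(tab) <- paste0("f", 1:6)
  y <- rep(c("a", "b"), each = 20)
  s0 <- screen_features(tab, y, alpha = 0)
  expect_length(s0$significant, 0)
  s1 <- screen_features(tab, y, alpha = 1)
  expect_equal(s1$results$feature, names(tab))  # everything passes at alpha 1
  # invariance to patient order
  perm <- sample(40)
  s2 <- screen_features(tab[perm, ], y[perm], alpha = 0.05)
  s3 <- screen_features(tab, y, alpha = 0.05)
  expect_equal(s2$results$p_value, s3$results$p_value)
  # scaling invariance of the Wilcoxon branch
  r1 <- compare_groups(tab$f1, y, test = "wilcoxon")
  r2 <- compare_groups(tab$f1 * 1e6, y, test = "wilcoxon")
  expect_equal(r1$p_value, r2$p_value)
})

test_that("type-I error of the screen is close to alpha on null cohorts", {
  set.seed(12345)
  n_cohorts <- 400
  n_feat <- 8
  rej <- 0; tot <- 0
  for (i in seq_len(n_cohorts)) {
    tab <- as.data.frame(matrix(rnorm(40 * n_feat), 40))
    y <- rep(c("a", "b"), each = 20)
    s <- screen_features(tab, y, alpha = 0.05)
    rej <- rej + sum(s$results$significant)
    tot <- tot + nrow(s$results)
  }
  rate <- rej / tot
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
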