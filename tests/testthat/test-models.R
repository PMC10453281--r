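test_that("VIF matches the 1/(1-R^2) definition and filters iteratively", {
  set.seed(21)
  n <- 120
  x1 <- rnorm(n); x2 <- rnorm(n)
  x3 <- 0.8 * x1 + 0.6 * x2 + rnorm(n, 0, 0.3)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  # definition-based oracle via separate regressions
  vif_oracle <- function(d, nm) {
    r2 <- summary(lm(reformulate(setdiff(names(d), nm), nm), data = d))$r.squared
    1 / (1 - r2)
  }
  vf <- vif_filter(d, cap = 1e9)           # cap high: nothing dropped
  expect_equal(vf$retained, names(d))
  # cross-check against car::vif on a joint model
  y <- rnorm(n)
  cv <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
  for (nm in names(d))
    expect_equal(unname(cv[nm]), vif_oracle(d, nm), tolerance = 1e-8)

  # orthogonal predictors: all VIF 1, none dropped at cap 5
  q <- as.data.frame(qr.Q(qr(matrix(rnorm(n * 3), n, 3))))
  expect_equal(vif_filter(q, 5)$retained, names(q))

  # near-duplicate pair: one eliminated first
  d2 <- data.frame(a = x1, b = x1 + rnorm(n, 0, 1e-4), c = x2)
  vf2 <- vif_filter(d2, 5)
  expect_equal(length(vf2$retained), 2)
  expect_true("c" %in% vf2$retained)
  expect_true(nrow(vf2$trace) == 1 && vf2$trace$vif > 5)

  # perfect collinearity flagged as infinite
  d3 <- data.frame(a = x1, b = 2 * x1, c = x2)
  vf3 <- vif_filter(d3, 5)
  expect_true(is.infinite(vf3$trace$vif[1]))
})

test_that("AIC backward selection is monotone and retains true predictors", {
  set.seed(31)
  n <- 200
  keep_rate <- 0
  for (rep in 1:20) {
    x <- as.data.frame(matrix(rnorm(n * 6), n))
    names(x) <- c("signal", paste0("noise", 1:5))
    p <- plogis(1.5 * x$signal)
    x$y <- factor(rbinom(n, 1, p))
    bs <- backward_select_aic(x, "y", setdiff(names(x), "y"))
    expect_lte(bs$aic, bs$aic_full + 1e-9)   # final AIC <= full AIC
    keep_rate <- keep_rate + ("signal" %in% bs$selected)
  }
  expect_gte(keep_rate / 20, 0.9)
})

test_that("empty candidate set returns the intercept-only model", {
  set.seed(5)
  d <- data.frame(y = factor(rbinom(40, 1, 0.5)))
  bs <- backward_select_aic(d, "y", character(0))
  expect_length(bs$selected, 0)
  expect_equal(length(coef(bs$fit)), 1)
})

test_that("pooled CV AUC equals the brute-force concordance oracle", {
  set.seed(41)
  n <- 80
  d <- data.frame(x = rnorm(n))
  d$y <- factor(rbinom(n, 1, plogis(d$x)))
  rep1 <- crossvalidate(d, "y", "x", seed = 2)
  yn <- as.integer(d$y) - 1
  expect_equal(rep1$auc, bf_auc(rep1$predictions, yn), tolerance = 1e-10)
})

test_that("a perfectly separating predictor reaches AUC and accuracy 1", {
  d <- data.frame(x = c(rnorm(30, -4), rnorm(30, 4)),
                  y = factor(rep(c(0, 1), each = 30)))
  rep1 <- crossvalidate(d, "y", "x", seed = 3)
  expect_true(rep1$separation)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$accuracy, 1)
})

test_that("null predictors give CV AUC near 0.5 over 50 seeds", {
  set.seed(51)
  aucs <- vapply(1:50, function(s) {
    n <- 200
    d <- as.data.frame(matrix(rnorm(n * 3), n))
    names(d) <- c("a", "b", "c")
    d$y <- factor(rbinom(n, 1, 0.5))
    crossvalidate(d, "y", c("a", "b", "c"), seed = s)$auc
  }, 1)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("CV folds are stratified, seeded and recorded", {
  set.seed(61)
  d <- data.frame(x = rnorm(60), y = factor(rep(c(0, 1), c(45, 15))))
  r1 <- crossvalidate(d, "y", "x", seed = 9)
  r2 <- crossvalidate(d, "y", "x", seed = 9)
  expect_identical(r1$fold_assignments, r2$fold_assignments)
  expect_identical(r1$auc, r2$auc)
  # each fold has members of the minority class spread over >= 2 folds
  yn <- as.integer(d$y) - 1
  expect_gte(length(unique(r1$fold_assignments[yn == 1])), 2)
})

test_that("model_p is the likelihood-ratio test against the intercept-only model", {
  set.seed(71)
  n <- 100
  d <- data.frame(x = rnorm(n))
  d$y <- factor(rbinom(n, 1, plogis(2 * d$x)))
  rep1 <- crossvalidate(d, "y", "x", seed = 1)
  fit <- glm(y ~ x, data = d, family = binomial())
  null <- glm(y ~ 1, data = d, family = binomial())
  p_oracle <- pchisq(2 * (logLik(fit) - logLik(null)), 1, lower.tail = FALSE)
  expect_equal(rep1$model_p, as.numeric(p_oracle), tolerance = 1e-10)
})

test_that("the model grid yields 24 reports, deterministic, with VIF <= 5", {
  cc <- tiny_cohort_config(n = 16, seed = 13,
                           bcr_fraction = 0.25)
  coh <- generate_cohort(cc)
  ft <- build_feature_table(coh)
  g1 <- run_all_models(ft, coh$clinical, seed = 4)
  expect_length(g1$reports, 24)
  expect_equal(nrow(g1$summary), 24)
  g2 <- run_all_models(ft, coh$clinical, seed = 4)
  expect_equal(g1$summary, g2$summary)
  # metrics in range, AIC finite, retained VIFs within cap
  expect_true(all(g1$summary$auc >= 0 & g1$summary$auc <= 1, na.rm = TRUE))
  for (r in g1$reports) {
    expect_true(is.finite(r$aic))
    vars <- r$selected_variables
    if (length(vars) >= 2) {
      dat <- cbind(ft, coh$clinical)
      dat$perineural_num <- ifelse(coh$clinical$perineural_invasion == "yes", 1,
                                   ifelse(coh$clinical$perineural_invasion == "no", 0, NA))
      dat$n_stage_num <- as.integer(coh$clinical$n_stage == "cN1")
      sub <- dat[complete.cases(dat[, vars, drop = FALSE]), vars, drop = FALSE]
      v <- vapply(vars, function(nm) {
        r2 <- summary(lm(reformulate(sprintf("`%s`", setdiff(vars, nm)),
                                     sprintf("`%s`", nm)), data = sub))$r.squared
        1 / (1 - r2)
      }, 1)
      expect_true(all(v <= 5 + 1e-6))
    }
  }
})
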