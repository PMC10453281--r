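#' Iterative variance-inflation-factor filtering
#'
#' Computes each variable's VIF as `1 / (1 - R^2)` from regressing it on the
#' remaining variables, drops the largest VIF above the cap, and repeats
#' until all retained VIFs are at or below the cap. Perfectly collinear
#' variables appear with infinite VIF and are dropped first.
#'
#' @param design Data frame or matrix (patients x variables), complete
#'   cases used; requires `n > variables + 1`.
#' @param cap VIF threshold (default 5).
#' @return List with `retained` (names) and `trace` (data frame of
#'   eliminated variables with their VIF at elimination).
#' @export
vif_filter <- function(design, cap = 5) {
  x <- as.matrix(design)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  stopifnot(ncol(x) >= 1)
  vars <- colnames(x)
  trace <- list()
  # zero-variance columns are aliased with the intercept: flagged, dropped
  for (nm in vars[apply(x, 2, stats::sd) == 0]) {
    trace[[length(trace) + 1]] <- data.frame(variable = nm, vif = Inf)
    vars <- setdiff(vars, nm)
  }
  repeat {
    if (length(vars) < 2) break
    if (nrow(x) <= length(vars) + 1)
      stop("need more observations than variables + 1 for VIF filtering")
    v <- vapply(vars, function(nm) {
      fit <- stats::lm.fit(cbind(1, x[, setdiff(vars, nm), drop = FALSE]),
                           x[, nm])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((x[, nm] - mean(x[, nm]))^2)
      if (!is.finite(r2) || r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 1)
    if (max(v) <= cap) break
    worst <- vars[which.max(v)]
    trace[[length(trace) + 1]] <- data.frame(variable = worst,
                                             vif = unname(max(v)))
    vars <- setdiff(vars, worst)
  }
  list(retained = vars,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(variable = character(), vif = numeric()))
}

#' Backward variable selection by AIC for a logistic model
#'
#' Starts from the full logit GLM on the candidate set and iteratively
#' removes the single variable whose removal most reduces the AIC
#' (`-2 loglik + 2 (k+1)`), stopping when no removal reduces it. Ties are
#' broken by removing the later-ordered variable. An empty candidate set
#' yields the intercept-only model. Quasi-complete separation is detected
#' from the GLM warning and flagged; prediction then falls back to a
#' ridge-penalised fit downstream.
#'
#' @param data Data frame holding candidates and outcome.
#' @param outcome Name of the binary outcome column (factor or 0/1).
#' @param candidates Character vector of candidate variable names.
#' @return List with `selected` (names), `fit` (the final `glm`), `aic`,
#'   `aic_full`, `separation` flag, and `trace` of removals.
#' @export
backward_select_aic <- function(data, outcome, candidates) {
  fit_glm <- function(vars) {
    fml <- if (length(vars))
      stats::reformulate(sprintf("`%s`", vars), response = sprintf("`%s`", outcome))
    else stats::as.formula(sprintf("`%s` ~ 1", outcome))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = data, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    attr(fit, "separation") <- sep
    fit
  }
  current <- candidates
  fit <- fit_glm(current)
  aic_full <- stats::AIC(fit)
  trace <- list()
  while (length(current) > 0) {
    aics <- vapply(seq_along(current), function(i)
      stats::AIC(fit_glm(current[-i])), 1)
    best <- max(which(aics == min(aics)))   # tie: drop the later variable
    if (min(aics) >= stats::AIC(fit) - 1e-9) break
    trace[[length(trace) + 1]] <-
      data.frame(removed = current[best], aic_after = aics[best])
    current <- current[-best]
    fit <- fit_glm(current)
  }
  list(selected = current, fit = fit, aic = stats::AIC(fit),
       aic_full = aic_full,
       separation = isTRUE(attr(fit, "separation")),
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(removed = character(), aic_after = numeric()))
}

# Stratified k-fold assignment; every fold gets members of both classes
# whenever class counts allow it.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated performance of a selected logistic model
#'
#' Seeded stratified 5-fold cross-validation: the selected model is refit on
#' each training split and out-of-fold probabilities are pooled. Reported
#' metrics: AUC over the pooled predictions, and accuracy / sensitivity /
#' specificity at probability threshold 0.5 (sensitivity is the true
#' positive rate of the event class, the second factor level). `model_p` is
#' the likelihood-ratio test of the final model against the intercept-only
#' model on the full data. If separation is flagged, per-fold fits use a
#' lightly ridge-penalised logistic regression instead.
#'
#' @param data Data frame with outcome and variables.
#' @param outcome Binary outcome column name; event = second factor level.
#' @param variables Selected variable names (possibly empty).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param ridge_lambda Penalty used by the separation fallback.
#' @return A `model_report`: list with `selected_variables`,
#'   `coefficients`, `aic`, `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `model_p`, `fold_assignments`, `separation`,
#'   `predictions`.
#' @export
crossvalidate <- function(data, outcome, variables, folds = 5L, seed = 1L,
                          ridge_lambda = 1e-2) {
  y <- data[[outcome]]
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  yn <- as.integer(y) - 1L   # event = second level
  n <- length(yn)
  # every training split (all folds but one) must contain both classes,
  # i.e. each class must be spread over at least two folds
  covers <- function(fold) all(vapply(unique(yn), function(cl)
    length(unique(fold[yn == cl])) >= 2, TRUE))
  fold <- stratified_folds(yn, folds, seed)
  if (!covers(fold)) {
    fold <- stratified_folds(yn, folds, seed + 1L)
    if (!covers(fold))
      stop("cannot build folds: a class has fewer than 2 members")
  }

  sel <- backward_refit(data, outcome, variables)
  prob <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    prob[!tr] <- fit_predict_logit(data[tr, , drop = FALSE],
                                   data[!tr, , drop = FALSE],
                                   outcome, variables,
                                   separation = sel$separation,
                                   ridge_lambda = ridge_lambda)
  }
  auc <- pooled_auc(prob, yn)
  pred <- as.integer(prob >= 0.5)
  acc <- mean(pred == yn)
  sens <- if (sum(yn == 1)) mean(pred[yn == 1] == 1) else NA_real_
  spec <- if (sum(yn == 0)) mean(pred[yn == 0] == 0) else NA_real_

  # full-data likelihood-ratio test vs intercept-only
  null_fit <- stats::glm(yn ~ 1, family = stats::binomial())
  lr <- 2 * (stats::logLik(sel$fit) - stats::logLik(null_fit))
  df <- length(stats::coef(sel$fit)) - 1
  model_p <- if (df > 0) stats::pchisq(as.numeric(lr), df, lower.tail = FALSE)
             else 1

  structure(list(selected_variables = variables,
                 coefficients = stats::coef(sel$fit),
                 aic = stats::AIC(sel$fit),
                 auc = auc, accuracy = acc,
                 sensitivity = sens, specificity = spec,
                 model_p = model_p,
                 fold_assignments = fold,
                 separation = sel$separation,
                 predictions = prob),
            class = "model_report")
}

# Full-data fit of a fixed variable set (no selection).
backward_refit <- function(data, outcome, variables) {
  y <- as.integer(factor(data[[outcome]])) - 1L
  df <- data.frame(.y = y, data[, variables, drop = FALSE], check.names = FALSE)
  sep <- FALSE
  fml <- if (length(variables))
    stats::reformulate(sprintf("`%s`", variables), response = ".y")
  else stats::as.formula(".y ~ 1")
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, separation = sep)
}

fit_predict_logit <- function(train, test, outcome, variables, separation,
                              ridge_lambda) {
  ytr <- as.integer(factor(train[[outcome]],
                           levels = levels(factor(c(train[[outcome]],
                                                    test[[outcome]]))))) - 1L
  if (length(variables) == 0)
    return(rep(mean(ytr), nrow(test)))
  if (separation) {
    xtr <- as.matrix(train[, variables, drop = FALSE])
    xte <- as.matrix(test[, variables, drop = FALSE])
    if (ncol(xtr) == 1) { xtr <- cbind(xtr, 0); xte <- cbind(xte, 0) }
    p <- tryCatch({
      fit <- suppressWarnings(
        glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                       lambda = ridge_lambda))
      as.numeric(stats::predict(fit, xte, type = "response"))
    }, error = function(e) NULL)
    if (!is.null(p)) return(p)
    fit_predict_logit(train, test, outcome, variables, separation = FALSE,
                      ridge_lambda = ridge_lambda)
  } else {
    df <- data.frame(.y = ytr, train[, variables, drop = FALSE],
                     check.names = FALSE)
    fml <- stats::reformulate(sprintf("`%s`", variables), response = ".y")
    fit <- suppressWarnings(stats::glm(fml, data = df,
                                       family = stats::binomial()))
    suppressWarnings(as.numeric(
      stats::predict(fit, newdata = test, type = "response")))
  }
}

# Pooled AUC (probability that a random event outranks a random non-event,
# ties counted half).
pooled_auc <- function(prob, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, prob, quiet = TRUE, direction = "<",
                        levels = c(0, 1)))))
}

#' Run the full model grid
#'
#' Builds the 24 predictive models of the analysis: 3 endpoints (risk
#' group; BCR; BCR within the high/unfavorable-intermediate subgroup) x
#' 4 regions (cztz, pz, sv, whole) x 2 variants (imaging only; imaging +
#' clinical). For each cell: univariate screening of the region's features
#' (after correlation pruning), VIF filtering, AIC backward selection, and
#' stratified 5-fold cross-validated performance. The clinical candidate
#' set is ECOG PS, age and perineural invasion for the risk endpoint, plus
#' PSA, ISUP grade and N stage for the BCR endpoints. Endpoints with no
#' significant screen survivors yield an intercept-only report, flagged.
#'
#' @param feature_table Output of [build_feature_table()].
#' @param clinical Clinical data frame (as from [generate_cohort()]).
#' @param alpha Univariate significance level.
#' @param cor_threshold Correlation-pruning threshold.
#' @param vif_cap VIF elimination cap.
#' @param folds CV folds.
#' @param seed Seed for fold assignment.
#' @param endpoints Subset of `c("risk_group", "bcr", "bcr_high_unfIR")`.
#' @param regions Subset of `c("cztz", "pz", "sv", "whole")`.
#' @return A `model_grid`: list of `model_report`s keyed
#'   `endpoint.region.variant`, plus a `summary` data frame shaped like a
#'   performance table (Sen/Spe/Acc/AUC/p per model).
#' @export
run_all_models <- function(feature_table, clinical, alpha = 0.05,
                           cor_threshold = 0.9, vif_cap = 5, folds = 5L,
                           seed = 1L,
                           endpoints = c("risk_group", "bcr", "bcr_high_unfIR"),
                           regions = c("cztz", "pz", "sv", "whole")) {
  stopifnot(identical(feature_table$patient_id, clinical$patient_id))
  clin_risk <- c("ecog", "age", "perineural_num")
  clin_bcr <- c(clin_risk, "psa", "isup", "n_stage_num")
  clinical$perineural_num <- ifelse(clinical$perineural_invasion == "yes", 1,
                                    ifelse(clinical$perineural_invasion == "no",
                                           0, NA))
  clinical$n_stage_num <- as.integer(clinical$n_stage == "cN1")

  reports <- list()
  rows <- list()
  for (ep in endpoints) {
    if (ep == "risk_group") {
      keep <- rep(TRUE, nrow(clinical))
      y <- factor(clinical$risk_group, levels = c(1, 2))
      clin_vars <- clin_risk
    } else if (ep == "bcr") {
      keep <- rep(TRUE, nrow(clinical))
      y <- factor(clinical$bcr_10y, levels = c("no", "yes"))
      clin_vars <- clin_bcr
    } else {
      keep <- clinical$risk_group == 2
      y <- factor(clinical$bcr_10y, levels = c("no", "yes"))
      clin_vars <- clin_bcr
    }
    yk <- droplevels(y[keep])
    for (rg in regions) {
      fcols <- grep(paste0("^", rg, "__"), colnames(feature_table),
                    value = TRUE)
      ft <- feature_table[keep, fcols, drop = FALSE]
      pruned <- prune_correlated(ft, cor_threshold)
      scr <- screen_features(ft[, pruned$retained, drop = FALSE], yk,
                             alpha = alpha)
      imaging_sig <- scr$significant
      # small-sample guard: keep the strongest survivors (smallest p) so the
      # candidate count stays below n/3 and the VIF step is well posed
      cap <- max(1L, floor(sum(keep) / 3))
      if (length(imaging_sig) > cap) {
        pv <- scr$results$p_value[match(imaging_sig, scr$results$feature)]
        imaging_sig <- imaging_sig[order(pv)][seq_len(cap)]
      }
      for (variant in c("imaging", "imaging+clinical")) {
        cand <- imaging_sig
        dat <- cbind(ft, clinical[keep, , drop = FALSE])
        dat$.outcome <- yk
        if (variant == "imaging+clinical") cand <- c(cand, clin_vars)
        cand <- cand[vapply(cand, function(v)
          sum(stats::complete.cases(dat[, v, drop = FALSE])) > 0, TRUE)]
        if (length(cand))
          dat <- dat[stats::complete.cases(dat[, cand, drop = FALSE]), ,
                     drop = FALSE]
        flagged_empty <- length(cand) == 0
        # keep the design well posed: n must exceed candidates + 1
        while (length(cand) >= nrow(dat) - 1 &&
               length(intersect(cand, imaging_sig)) > 0) {
          weakest <- utils::tail(intersect(cand, imaging_sig), 1)
          cand <- setdiff(cand, weakest)
        }
        vt <- data.frame(variable = character(), vif = numeric())
        if (length(cand) >= 2) {
          vf <- vif_filter(dat[, cand, drop = FALSE], cap = vif_cap)
          cand <- vf$retained
          vt <- vf$trace
        }
        bs <- backward_select_aic(dat, ".outcome", cand)
        rep_k <- tryCatch(
          crossvalidate(dat, ".outcome", bs$selected, folds = folds,
                        seed = seed),
          error = function(e) structure(
            list(selected_variables = bs$selected,
                 coefficients = stats::coef(bs$fit), aic = bs$aic,
                 auc = NA_real_, accuracy = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 model_p = NA_real_, fold_assignments = NULL,
                 separation = bs$separation, predictions = NULL,
                 cv_error = conditionMessage(e)),
            class = "model_report"))
        rep_k$vif_trace <- vt
        rep_k$aic_full <- bs$aic_full
        rep_k$endpoint <- ep; rep_k$region <- rg; rep_k$variant <- variant
        rep_k$no_candidates <- flagged_empty
        key <- paste(ep, rg, variant, sep = ".")
        reports[[key]] <- rep_k
        rows[[key]] <- data.frame(endpoint = ep, region = rg,
                                  variant = variant,
                                  n = nrow(dat),
                                  n_selected = length(bs$selected),
                                  sensitivity = rep_k$sensitivity,
                                  specificity = rep_k$specificity,
                                  accuracy = rep_k$accuracy,
                                  auc = rep_k$auc,
                                  p_value = rep_k$model_p)
      }
    }
  }
  structure(list(reports = reports,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "model_grid")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s | %s | %s\n",
              x$endpoint %||% "?", x$region %||% "?", x$variant %||% "?"))
  cat("  variables:", if (length(x$selected_variables))
    paste(x$selected_variables, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  AUC %.3f acc %.3f sens %.3f spec %.3f p %.3g (AIC %.1f)\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$model_p,
              x$aic))
  invisible(x)
}

#' @export
print.model_grid <- function(x, ...) {
  print(x$summary, digits = 3)
  invisible(x)
}
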