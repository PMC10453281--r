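#' Pipeline configuration
#'
#' All analysis thresholds and switches in one place; defaults are the
#' published settings of the procedure (correlation threshold 0.9, VIF cap
#' 5, alpha 0.05, 5-fold CV).
#'
#' @param alpha Univariate significance level.
#' @param cor_threshold Correlation-pruning threshold.
#' @param vif_cap VIF elimination cap.
#' @param folds Cross-validation folds.
#' @param n_levels Gray levels for texture discretisation.
#' @param tofts_method `"linear"` or `"nls"` voxel-wise Tofts fitting.
#' @param shape_mode Whole-gland shape aggregation (`"union"` or `"sum"`).
#' @param seed Seed for fold assignment.
#' @param endpoints,regions Model grid selections.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, cor_threshold = 0.9, vif_cap = 5,
                            folds = 5L, n_levels = 32L,
                            tofts_method = "linear", shape_mode = "union",
                            seed = 1L,
                            endpoints = c("risk_group", "bcr", "bcr_high_unfIR"),
                            regions = c("cztz", "pz", "sv", "whole")) {
  structure(list(alpha = alpha, cor_threshold = cor_threshold,
                 vif_cap = vif_cap, folds = as.integer(folds),
                 n_levels = as.integer(n_levels),
                 tofts_method = tofts_method, shape_mode = shape_mode,
                 seed = as.integer(seed),
                 endpoints = endpoints, regions = regions),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' End to end: feature extraction for every case, per-endpoint univariate
#' screening tables, and the full model grid. Deterministic given the
#' cohort and config.
#'
#' @param cohort A `phantom_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `screen_<endpoint>.tsv` and `models.tsv`.
#' @return List with `features` (data frame), `screens` (per endpoint),
#'   and `models` (a `model_grid`).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  features <- build_feature_table(cohort,
                                  n_levels = config$n_levels,
                                  tofts_method = config$tofts_method,
                                  shape_mode = config$shape_mode)
  clinical <- cohort$clinical

  screens <- list()
  for (ep in intersect(config$endpoints, c("risk_group", "bcr"))) {
    y <- if (ep == "risk_group") factor(clinical$risk_group)
         else factor(clinical$bcr_10y, levels = c("no", "yes"))
    tabs <- list()
    for (rg in config$regions) {
      fcols <- grep(paste0("^", rg, "__"), colnames(features), value = TRUE)
      ft <- features[, fcols, drop = FALSE]
      pr <- prune_correlated(ft, config$cor_threshold)
      sc <- screen_features(ft[, pr$retained, drop = FALSE], y,
                            alpha = config$alpha)
      if (nrow(sc$results)) {
        sc$results$region <- rg
        tabs[[rg]] <- sc$results
      }
    }
    screens[[ep]] <- do.call(rbind, c(tabs, make.row.names = FALSE))
  }

  models <- run_all_models(features, clinical,
                           alpha = config$alpha,
                           cor_threshold = config$cor_threshold,
                           vif_cap = config$vif_cap,
                           folds = config$folds, seed = config$seed,
                           endpoints = config$endpoints,
                           regions = config$regions)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    for (ep in names(screens))
      utils::write.table(screens[[ep]],
                         file.path(out_dir, paste0("screen_", ep, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(models$summary, file.path(out_dir, "models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(features = features, screens = screens, models = models)
}
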