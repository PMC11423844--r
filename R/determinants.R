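# Random-forest determinants analysis: regress bias-corrected efficiency
# on the contextual covariates plus year, evaluate fit on repeated
# cross-validation held-out predictions, rank variables by perturbation
# (permutation) importance over subsamples, and trace partial-dependence
# curves. Forests are fitted with ranger, single-threaded and seeded, so
# every result is reproducible.

#' Random-forest configuration
#'
#' @param n_trees trees per forest (default 500).
#' @param vars_per_split candidate variables at each split (mtry,
#'   default 5).
#' @param cv_folds,cv_repeats repeated k-fold cross-validation layout
#'   (default 10 x 3).
#' @param n_importance_subsamples bootstrap subsamples per variable for
#'   perturbation importance (default 50).
#' @param n_pd_observations observations sampled for partial dependence
#'   (default 500).
#' @param seed integer RNG seed.
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 500L, vars_per_split = 5L, cv_folds = 10L,
                      cv_repeats = 3L, n_importance_subsamples = 50L,
                      n_pd_observations = 500L, seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees),
              vars_per_split = as.integer(vars_per_split),
              cv_folds = as.integer(cv_folds),
              cv_repeats = as.integer(cv_repeats),
              n_importance_subsamples = as.integer(n_importance_subsamples),
              n_pd_observations = as.integer(n_pd_observations),
              seed = as.integer(seed))
  if (any(unlist(cfg[1:6]) < 1L)) stop("all rf_config counts must be >= 1")
  structure(cfg, class = "rf_config")
}

rmse_of <- function(obs, pred) sqrt(mean((obs - pred)^2))

fit_metrics <- function(obs, pred) {
  mse <- mean((obs - pred)^2)
  list(mse = mse, rmse = sqrt(mse),
       r_squared = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
       mad = median(abs(obs - pred)))
}

ranger_fit <- function(df, config, seed) {
  ranger::ranger(target ~ ., data = df, num.trees = config$n_trees,
                 mtry = min(config$vars_per_split, ncol(df) - 1L),
                 num.threads = 1L, seed = seed, keep.inbag = TRUE,
                 respect.unordered.factors = TRUE)
}

ranger_predict <- function(model, newdata) {
  predict(model, data = newdata, num.threads = 1L)$predictions
}

# Out-of-bag prediction for rows of the training data (possibly permuted
# or resampled): each row is predicted only by the trees in which it was
# not an in-bag observation. `rows` maps each row of `newdata` back to
# its original training-row index so the right out-of-bag tree set is
# used. Evaluating perturbations out-of-bag avoids the memorization bias
# that inflates the apparent importance of irrelevant features when a
# forest is scored on its own training data.
ranger_oob_predict <- function(model, newdata, rows) {
  pall <- predict(model, data = newdata, num.threads = 1L,
                  predict.all = TRUE)$predictions
  inbag <- matrix(unlist(model$inbag.counts), ncol = model$num.trees)
  oob <- (inbag == 0)[rows, , drop = FALSE]
  rowSums(pall * oob) / pmax(rowSums(oob), 1L)
}

#' Fit the efficiency random forest with repeated cross-validation
#'
#' Trains a random-forest regressor of the target (bias-corrected
#' efficiency) on the given feature table and reports fit metrics (MSE,
#' RMSE, R-squared, median absolute error) computed on held-out
#' predictions pooled across all folds and repeats of a repeated k-fold
#' cross-validation — never on the training fit. A final forest trained
#' on all rows is returned for importance and partial-dependence work.
#'
#' @param features data frame of numeric predictors (contextual variables
#'   plus year; year enters as a numeric).
#' @param target numeric response in (0, 1], same length as
#'   `nrow(features)`; must not be constant.
#' @param config an [rf_config()].
#' @return list of class `rf_fit`: `model` (ranger object), `metrics`
#'   (list mse/rmse/r_squared/mad), `cv_predictions` (data frame of
#'   pooled held-out rows), `feature_names`, `config`.
#' @export
fit_rf <- function(features, target, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  features <- as.data.frame(features)
  n <- nrow(features)
  if (length(target) != n) stop("target length must match feature rows")
  if (anyNA(features) || anyNA(target)) stop("missing values not allowed")
  if (n < config$cv_folds) stop("fewer rows than cv_folds")
  if (sd(target) < 1e-12) stop("constant target: nothing to learn")
  if (config$vars_per_split > ncol(features))
    stop("vars_per_split exceeds the number of predictors")

  df <- cbind(features, target = target)
  obs <- pred <- numeric(0)
  row_id <- rep_id <- integer(0)
  with_local_seed(config$seed, {
    for (r in seq_len(config$cv_repeats)) {
      fold <- sample(rep_len(seq_len(config$cv_folds), n))
      for (k in seq_len(config$cv_folds)) {
        hold <- fold == k
        fit <- ranger_fit(df[!hold, , drop = FALSE], config,
                          seed = derive_seed(config$seed, r * 25L + k))
        p <- ranger_predict(fit, df[hold, , drop = FALSE])
        obs <- c(obs, target[hold]); pred <- c(pred, p)
        row_id <- c(row_id, which(hold)); rep_id <- c(rep_id, rep(r, sum(hold)))
      }
    }
  })
  model <- ranger_fit(df, config, seed = derive_seed(config$seed, 999L))
  structure(list(model = model, metrics = fit_metrics(obs, pred),
                 cv_predictions = data.frame(row = row_id, repeat_id = rep_id,
                                             observed = obs, predicted = pred),
                 feature_names = names(features), config = config),
            class = "rf_fit")
}

#' Perturbation (permutation) variable importance over subsamples
#'
#' For each feature, draws `n_importance_subsamples` bootstrap subsamples
#' (with replacement, size n), permutes the feature's values within each
#' subsample, and records the change in prediction RMSE against the
#' subsample's own unperturbed baseline. Predictions are evaluated
#' out-of-bag (each row predicted only by trees that did not see it in
#' training), so an irrelevant feature's mean change is near zero rather
#' than inflated by memorized noise splits. A variable whose scrambling
#' raises RMSE carries predictive information.
#'
#' @param fit an `rf_fit` from [fit_rf()].
#' @param features,target the data the model was fitted on, in training
#'   row order (required for the out-of-bag bookkeeping).
#' @param config an [rf_config()]; `seed` and `n_importance_subsamples`
#'   are used.
#' @return data frame `variable`, `mean_delta_rmse`, `sd_delta_rmse`,
#'   `rank` (1 = most important), ordered by rank.
#' @export
perturbation_importance <- function(fit, features, target,
                                    config = fit$config) {
  stopifnot(inherits(fit, "rf_fit"))
  features <- as.data.frame(features)
  if (!setequal(names(features), fit$feature_names))
    stop("features do not match the fitted model: ",
         paste(setdiff(fit$feature_names, names(features)), collapse = ", "))
  n <- nrow(features)
  S <- config$n_importance_subsamples
  res <- with_local_seed(derive_seed(config$seed, 101L), {
    sapply(fit$feature_names, function(v) {
      delta <- vapply(seq_len(S), function(s) {
        idx <- sample.int(n, n, replace = TRUE)
        sub <- features[idx, , drop = FALSE]
        base <- rmse_of(target[idx], ranger_oob_predict(fit$model, sub, idx))
        sub[[v]] <- sub[[v]][sample.int(n)]
        rmse_of(target[idx], ranger_oob_predict(fit$model, sub, idx)) - base
      }, numeric(1))
      c(mean(delta), sd(delta))
    })
  })
  out <- data.frame(variable = fit$feature_names,
                    mean_delta_rmse = res[1, ], sd_delta_rmse = res[2, ],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_delta_rmse), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Partial-dependence curve of one feature
#'
#' Samples `min(n_pd_observations, n)` rows without replacement; for each
#' of `grid_size` values spanning the feature's observed 1st-99th
#' percentile range, sets the feature to that value in all sampled rows
#' and averages the model predictions.
#'
#' @param fit an `rf_fit`.
#' @param features the feature table.
#' @param variable feature name (numeric).
#' @param config an [rf_config()].
#' @param grid_size number of grid points (default 20).
#' @return data frame `variable`, `grid`, `mean_prediction` with grid
#'   ascending.
#' @export
partial_dependence <- function(fit, features, variable, config = fit$config,
                               grid_size = 20L) {
  stopifnot(inherits(fit, "rf_fit"))
  features <- as.data.frame(features)
  if (!variable %in% fit$feature_names)
    stop("variable '", variable, "' is not a model feature")
  if (!is.numeric(features[[variable]]))
    stop("variable '", variable, "' is not numeric")
  n <- nrow(features)
  idx <- with_local_seed(derive_seed(config$seed, 202L),
                         sample.int(n, min(config$n_pd_observations, n)))
  qs <- quantile(features[[variable]], c(0.01, 0.99), names = FALSE)
  grid <- if (diff(qs) < 1e-12) qs[1] else
    seq(qs[1], qs[2], length.out = grid_size)
  sub <- features[idx, , drop = FALSE]
  mp <- vapply(grid, function(g) {
    sub[[variable]] <- g
    mean(ranger_predict(fit$model, sub))
  }, numeric(1))
  data.frame(variable = variable, grid = grid, mean_prediction = mp,
             stringsAsFactors = FALSE)
}

#' Per-region random-forest refits
#'
#' Fits an independent forest (same configuration) within each region and
#' returns its cross-validated metrics and perturbation importance.
#' Regions with fewer rows than `cv_folds` are skipped with a warning and
#' listed in the result.
#'
#' @param features feature table including no region column.
#' @param target response vector.
#' @param region integer region id per row.
#' @param config an [rf_config()].
#' @return list of class `rf_regional`: `regions` (named list, each with
#'   `fit`, `metrics`, `importance`), `skipped` (integer vector).
#' @export
fit_regional <- function(features, target, region, config = rf_config()) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(target),
            length(region) == length(target))
  out <- list(); skipped <- integer(0)
  for (r in sort(unique(region))) {
    sel <- region == r
    if (sum(sel) < config$cv_folds) {
      warning("region ", r, " has ", sum(sel),
              " rows (< cv_folds); skipped", call. = FALSE)
      skipped <- c(skipped, r)
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 300L + r)
    fit <- fit_rf(features[sel, , drop = FALSE], target[sel], cfg)
    imp <- perturbation_importance(fit, features[sel, , drop = FALSE],
                                   target[sel], cfg)
    out[[as.character(r)]] <- list(fit = fit, metrics = fit$metrics,
                                   importance = imp)
  }
  structure(list(regions = out, skipped = skipped), class = "rf_regional")
}
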