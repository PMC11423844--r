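# a small regression fixture: one dominant predictor, three noise columns
make_linear_fixture <- function(n = 400L, seed = 17L) {
  withr::with_seed(seed, {
    df <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n),
                     noise = runif(n))
    list(features = df, target = 5 * df$x1 + rnorm(n, 0, 0.5))
  })
}

small_cfg <- function(seed, ...) {
  rf_config(n_trees = 300L, vars_per_split = 2L, cv_folds = 5L,
            cv_repeats = 1L, n_importance_subsamples = 30L, seed = seed, ...)
}

test_that("degenerate fits are rejected", {
  fx <- make_linear_fixture(60L)
  expect_error(fit_rf(fx$features, rep(0.5, 60), small_cfg(1L)),
               "constant target")
  expect_error(fit_rf(fx$features[1:3, ], fx$target[1:3], small_cfg(1L)),
               "fewer rows than cv_folds")
  expect_error(fit_rf(fx$features, fx$target[-1], small_cfg(1L)), "length")
  expect_error(fit_rf(fx$features, fx$target,
                      rf_config(vars_per_split = 9L, seed = 1L)),
               "vars_per_split")
})

test_that("cross-validated metrics are internally consistent and honest", {
  fx <- make_linear_fixture()
  fit <- fit_rf(fx$features, fx$target, small_cfg(17L))
  expect_equal(fit$metrics$rmse^2, fit$metrics$mse, tolerance = 1e-12)
  expect_lte(fit$metrics$mad, fit$metrics$rmse)
  expect_gt(fit$metrics$r_squared, 0.8)   # strong linear signal
  # pooled CV predictions cover every row once per repeat
  expect_identical(sort(unique(fit$cv_predictions$row)), 1:400)
  # a pure-noise target is not learnable
  noise_target <- withr::with_seed(13, rnorm(400))
  fit0 <- fit_rf(fx$features, noise_target, small_cfg(13L))
  expect_lt(fit0$metrics$r_squared, 0.1)
})

test_that("perturbation importance ranks the dominant predictor first and is seeded", {
  fx <- make_linear_fixture()
  fit <- fit_rf(fx$features, fx$target, small_cfg(17L))
  imp <- perturbation_importance(fit, fx$features, fx$target)
  expect_identical(imp$variable[1], "x1")
  expect_identical(imp$rank, 1:4)
  expect_true(all(is.finite(imp$mean_delta_rmse)))
  # an independent noise column carries no signal (out-of-bag evaluation)
  nz <- imp[imp$variable == "noise", ]
  expect_lte(abs(nz$mean_delta_rmse), 2 * nz$sd_delta_rmse)
  expect_identical(imp, perturbation_importance(fit, fx$features, fx$target))
  expect_error(perturbation_importance(fit, fx$features[, 1:3], fx$target),
               "do not match")
})

test_that("partial dependence recovers monotone effects and flat irrelevance", {
  fx <- make_linear_fixture()
  fit <- fit_rf(fx$features, fx$target, small_cfg(17L))
  pd <- partial_dependence(fit, fx$features, "x1")
  expect_false(is.unsorted(pd$grid))
  expect_gt(cor(pd$grid, pd$mean_prediction, method = "kendall"), 0.9)
  # a feature the data-generating process never uses stays flat
  pd0 <- partial_dependence(fit, fx$features, "noise")
  expect_lt(diff(range(pd0$mean_prediction)), 0.1 * diff(range(fx$target)))
  expect_identical(pd, partial_dependence(fit, fx$features, "x1"))
  expect_error(partial_dependence(fit, fx$features, "absent"), "not a model feature")
})

test_that("regional refits recover region-specific determinants and skip thin regions", {
  ce <- synthetic_config()$context_effects
  ce2 <- ce; ce2["indigenous_pct"] <- 2.5; ce2["marginalization"] <- 0.2
  g <- generate_panel(synthetic_config(n_jurisdictions = 72L, seed = 19L,
                                       context_effects_by_region = list("2" = ce2)))
  pc <- panel_columns()
  feats <- g$panel[, c(pc$context, "year")]
  cfg <- rf_config(n_trees = 150L, cv_folds = 5L, cv_repeats = 1L,
                   n_importance_subsamples = 30L, seed = 19L)
  reg <- fit_regional(feats, g$truth$true_efficiency, g$panel$region, cfg)
  expect_length(reg$skipped, 0)
  # the region whose generator weights indigenous share most heavily
  # ranks it in its top-3 determinants
  expect_true("indigenous_pct" %in%
                head(reg$regions[["2"]]$importance$variable, 3))
  for (r in reg$regions) expect_lte(r$metrics$mad, r$metrics$rmse)

  # a region with too few rows is skipped with a warning
  region2 <- g$panel$region
  thin <- which(g$panel$region == 4)
  region2[thin[-(1:3)]] <- 3L
  expect_warning(reg2 <- fit_regional(feats, g$truth$true_efficiency,
                                      region2, cfg),
                 "skipped")
  expect_identical(reg2$skipped, 4L)
  expect_false("4" %in% names(reg2$regions))
})

test_that("exchangeable regions agree on the dominant determinant", {
  g <- generate_panel(synthetic_config(n_jurisdictions = 72L, seed = 19L,
                                       region_gradient = 0))
  pc <- panel_columns()
  feats <- g$panel[, c(pc$context, "year")]
  cfg <- rf_config(n_trees = 150L, cv_folds = 5L, cv_repeats = 1L,
                   n_importance_subsamples = 30L, seed = 19L)
  reg <- fit_regional(feats, g$truth$true_efficiency, g$panel$region, cfg)
  top1 <- vapply(reg$regions, function(r) r$importance$variable[1],
                 character(1))
  expect_gte(max(table(top1)), 4)
})

test_that("cross-validated forest tracks bias-corrected efficiency end-to-end", {
  # full default study conditions: 242 jurisdictions, 12 years, B = 100
  g <- generate_panel(synthetic_config(seed = 11L))
  pan <- add_input_aggregates(g$panel)
  est <- bootstrap_panel(pan, c("infra_total", "hr_total"),
                         c("treated", "controlled"),
                         bootstrap_config(B = 100L, seed = 11L,
                                          warn_small_B = FALSE))
  dat <- merge(pan, est, by = c("jurisdiction_id", "year"))
  pc <- panel_columns()
  fit <- fit_rf(dat[, c(pc$context, "year")], dat$bias_corrected_efficiency,
                rf_config(seed = 11L))
  expect_gte(fit$metrics$r_squared, 0.7)
  expect_lte(fit$metrics$mad, fit$metrics$rmse)
})
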