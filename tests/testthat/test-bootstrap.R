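test_that("reflected bandwidth follows Silverman's rule on the reflected sample", {
  expect_identical(reflected_bandwidth(rep(1, 5)), 0)
  theta <- c(1, 1.5, 2, 2.5)
  # hand formula on the 8-point reflected sample {theta} U {2 - theta}
  expect_equal(reflected_bandwidth(theta),
               silverman_reflected_reference(theta), tolerance = 1e-12)
  # location shifts act only through sd/IQR of the reflected sample
  theta2 <- theta + 0.3
  expect_equal(reflected_bandwidth(theta2),
               silverman_reflected_reference(theta2), tolerance = 1e-12)
  expect_error(reflected_bandwidth(1.2), "length")
})

test_that("smoothed resampling is boundary-respecting, seeded and degenerate-safe", {
  expect_identical(smoothed_resample(rep(1, 10), 0), rep(1, 10))
  theta <- c(1.1, 1.3, 1.8, 2.4)
  h <- reflected_bandwidth(theta)
  s1 <- withr::with_seed(5, smoothed_resample(theta, h))
  s2 <- withr::with_seed(5, smoothed_resample(theta, h))
  expect_identical(s1, s2)
  big <- withr::with_seed(6, smoothed_resample(rep(theta, 250), h))
  expect_true(all(big >= 1))
})

test_that("smoothed resample mean matches the analytic reflected-mixture mean", {
  theta <- rep(c(1.2, 1.4), 50000)
  h <- reflected_bandwidth(theta)
  draws <- withr::with_seed(42, smoothed_resample(theta, h))
  # target: T = 1 + (D - 1)/c + (h/c) eps over the reflected atoms D,
  # folded at the boundary, so E = 1 + mean_a E|N((a-1)/c, h/c)|
  cc <- sqrt(1 + h^2 / var(theta))
  mu <- (c(0.6, 0.8, 1.2, 1.4) - 1) / cc
  s <- h / cc
  efold <- function(mu, s)
    s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) + mu * (1 - 2 * pnorm(-mu / s))
  target <- 1 + mean(efold(mu, s))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - target), 3 * mc_se)
})

test_that("a degenerate year of identical DMUs has zero bias and unit scores", {
  pr <- dea_problem(matrix(rep(c(2, 3), each = 6), 6),
                    matrix(rep(c(5, 4), each = 6), 6), year = 2010L)
  est <- bootstrap_year(pr, bootstrap_config(B = 20L, seed = 2L,
                                             warn_small_B = FALSE))
  expect_equal(est$raw_efficiency, rep(1, 6))
  expect_equal(est$bias, rep(0, 6))
  expect_equal(est$bias_corrected_efficiency, rep(1, 6))
  expect_equal(est$ci_low, rep(1, 6))
  expect_equal(est$ci_high, rep(1, 6))
})

test_that("bias correction moves scores away from the frontier, reproducibly", {
  g <- generate_panel(synthetic_config(n_jurisdictions = 50L, years = 2009L,
                                       noise_scale = 0, seed = 5L))
  pan <- add_input_aggregates(g$panel)
  pr <- dea_problem(as.matrix(pan[, c("infra_total", "hr_total")]),
                    as.matrix(pan[, c("treated", "controlled")]),
                    year = 2009L, dmu_ids = pan$jurisdiction_id)
  cfg <- bootstrap_config(B = 100L, seed = 5L, warn_small_B = FALSE)
  est <- bootstrap_year(pr, cfg)
  expect_true(all(est$bias_corrected_efficiency <=
                    est$raw_efficiency + 1e-9))
  expect_true(all(est$ci_low <= est$bias_corrected_efficiency &
                    est$bias_corrected_efficiency <= est$ci_high))
  expect_true(all(est$ci_high <= 1 + 1e-12 & est$ci_low > 0))
  expect_identical(est, bootstrap_year(pr, cfg))
})

test_that("small B triggers the stability warning", {
  pr <- dea_problem(matrix(c(1, 2, 3), 3), matrix(c(1, 3, 3.5), 3),
                    year = 2009L)
  expect_warning(bootstrap_year(pr, bootstrap_config(B = 50L, seed = 1L)),
                 "small for stable")
})

test_that("panel bootstrap derives per-year seeds and keeps ids", {
  g <- generate_panel(synthetic_config(n_jurisdictions = 20L,
                                       years = 2009:2011, seed = 9L))
  pan <- add_input_aggregates(g$panel)
  cfg <- bootstrap_config(B = 15L, seed = 9L, warn_small_B = FALSE)
  est <- bootstrap_panel(pan, c("infra_total", "hr_total"),
                         c("treated", "controlled"), cfg)
  expect_identical(nrow(est), 60L)
  expect_setequal(unique(est$year), 2009:2011)
  expect_identical(est, bootstrap_panel(pan, c("infra_total", "hr_total"),
                                        c("treated", "controlled"), cfg))
  # a single year re-run in isolation reproduces its slice exactly
  one <- bootstrap_panel(pan[pan$year != 2010, ],
                         c("infra_total", "hr_total"),
                         c("treated", "controlled"), cfg)
  expect_equal(est[est$year == 2009, ], one[one$year == 2009, ])
})
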