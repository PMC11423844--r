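# Simar-Wilson smoothed homogeneous bootstrap for output-oriented DEA.
#
# DEA distances are estimated against an estimated frontier and are biased
# toward it (efficiency over-stated). The smoothed bootstrap resamples the
# distances from a reflected kernel density estimate on [1, Inf), rescales
# observed outputs into pseudo-outputs, re-solves the DEA against each
# pseudo reference set, and uses the bootstrap distribution to estimate
# and remove the bias and to form confidence intervals.

#' Bootstrap configuration
#'
#' @param B number of resamples (default 100). Note 100 is small for
#'   stable per-DMU confidence intervals; a warning is emitted below 500.
#' @param ci_level two-sided confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @param warn_small_B warn when B < 500 (default TRUE).
#' @return a `bootstrap_config` list.
#' @export
bootstrap_config <- function(B = 100L, ci_level = 0.95, seed = 1L,
                             warn_small_B = TRUE) {
  B <- as.integer(B)
  stopifnot(B >= 1L, ci_level > 0, ci_level < 1)
  structure(list(B = B, bandwidth_rule = "silverman_reflected",
                 ci_level = ci_level, seed = as.integer(seed),
                 warn_small_B = isTRUE(warn_small_B)),
            class = "bootstrap_config")
}

#' Silverman bandwidth on the reflected distance sample
#'
#' Farrell distances live on \[1, Inf); a kernel density estimate on the
#' raw sample would put mass below 1. The sample is therefore reflected
#' about the boundary, \{theta_i\} union \{2 - theta_i\}, and Silverman's
#' rule of thumb is applied to the 2n reflected points:
#' \eqn{h = 0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\,(2n)^{-1/5}}.
#'
#' @param theta numeric vector of Farrell distances, all >= 1, length >= 2.
#' @return bandwidth h >= 0 (0 for a zero-variance sample).
#' @export
reflected_bandwidth <- function(theta) {
  stopifnot(length(theta) >= 2, all(theta >= 1 - 1e-12))
  refl <- c(theta, 2 - theta)
  s <- sd(refl)
  iqr <- unname(diff(quantile(refl, c(0.25, 0.75))))
  if (s < 1e-14 || iqr < 1e-14) return(0)
  0.9 * min(s, iqr / 1.34) * (2 * length(theta))^(-1 / 5)
}

#' Smoothed resample of Farrell distances
#'
#' One bootstrap draw of pseudo-distances: sample with replacement from
#' the reflected set \{theta\} union \{2 - theta\}, add kernel noise
#' \eqn{h\,\varepsilon} with standard-normal \eqn{\varepsilon}, shrink the
#' centered draws by \eqn{1/\sqrt{1 + h^2/\hat\sigma^2_\theta}} so the
#' smoothed sample keeps the empirical variance, then fold any value below
#' the boundary back via \eqn{\theta^* \leftarrow 2 - \theta^*}. All
#' outputs are >= 1. Uses the current RNG stream; seed outside.
#'
#' @param theta Farrell distances >= 1.
#' @param h bandwidth from [reflected_bandwidth()].
#' @return pseudo-distances, same length as `theta`.
#' @export
smoothed_resample <- function(theta, h) {
  n <- length(theta)
  refl <- c(theta, 2 - theta)
  draws <- refl[sample.int(2L * n, n, replace = TRUE)]
  if (h > 0) {
    sigma2 <- var(theta)
    corr <- if (sigma2 > 0) sqrt(1 + h^2 / sigma2) else 1
    m <- mean(draws)
    draws <- m + (draws + h * rnorm(n) - m) / corr
  }
  ifelse(draws < 1, 2 - draws, draws)
}

#' Bias-corrected efficiency for one year via the smoothed bootstrap
#'
#' For each resample b: draw pseudo-distances \eqn{\theta^*_i}, rescale
#' observed outputs to pseudo-outputs
#' \eqn{y_i^{(b)} = (\theta_i/\theta_i^*)\,y_i}, and re-solve the
#' output-oriented DEA of every observed DMU against the pseudo reference
#' set. On the efficiency scale the bias estimate is
#' \eqn{\widehat{bias}_i = \mathrm{mean}_b(1/\theta_i^{(b)}) - 1/\theta_i}
#' and the corrected score \eqn{2/\theta_i - \mathrm{mean}_b(1/\theta_i^{(b)})};
#' percentile confidence intervals come from the bootstrap distribution of
#' corrected scores, clipped to (0, 1].
#'
#' @param problem a [dea_problem()] (VRS, output-oriented).
#' @param config a [bootstrap_config()].
#' @return data frame, one row per DMU: `dmu_id`, `year`, `theta`,
#'   `raw_efficiency`, `bias`, `bias_corrected_efficiency`, `ci_low`,
#'   `ci_high`, `n_boot_used`.
#' @export
bootstrap_year <- function(problem, config = bootstrap_config()) {
  stopifnot(inherits(problem, "dea_problem"),
            inherits(config, "bootstrap_config"))
  if (config$warn_small_B && config$B < 500L)
    warning("B = ", config$B,
            " resamples is small for stable confidence intervals",
            call. = FALSE)
  n <- nrow(problem$X)
  theta <- vapply(seq_len(n),
                  function(i) farrell_output_distance(problem, i)$theta,
                  numeric(1))
  h <- if (n >= 2) reflected_bandwidth(theta) else 0

  boot_eff <- matrix(NA_real_, n, config$B)
  n_fail <- 0L
  with_local_seed(config$seed, {
    for (b in seq_len(config$B)) {
      theta_star <- smoothed_resample(theta, h)
      Yb <- problem$Y * (theta / theta_star)
      tb <- tryCatch(
        farrell_against_reference(problem$X, Yb, problem$X, problem$Y,
                                  problem$rts),
        error = function(e) rep(NA_real_, n))
      if (anyNA(tb)) n_fail <- n_fail + 1L
      boot_eff[, b] <- 1 / tb
    }
  })
  if (n_fail > max(1L, ceiling(0.01 * config$B)))
    stop("bootstrap LP failure rate above 1% (", n_fail, "/", config$B,
         " resamples failed)")

  raw <- 1 / theta
  # pseudo outputs are radial contractions toward the raw frontier, so the
  # pseudo technology is nested in the raw one and every bootstrap distance
  # satisfies theta_b <= theta exactly; clamping enforces the identity
  # against LP tolerance jitter
  boot_eff <- pmax(boot_eff, raw)
  ok <- rowSums(!is.na(boot_eff))
  mean_boot <- rowMeans(boot_eff, na.rm = TRUE)
  bias <- mean_boot - raw
  corrected <- raw - bias
  # bootstrap distribution of corrected scores: 2/theta - 1/theta*_b
  corr_dist <- 2 * raw - boot_eff
  alpha <- (1 - config$ci_level) / 2
  qs <- t(apply(corr_dist, 1, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE))
  clip01 <- function(x) pmin(pmax(x, 1e-12), 1)
  corrected <- clip01(corrected)
  ci_low <- pmin(clip01(qs[, 1]), corrected)
  ci_high <- pmax(clip01(qs[, 2]), corrected)

  data.frame(dmu_id = problem$dmu_ids, year = problem$year, theta = theta,
             raw_efficiency = raw, bias = bias,
             bias_corrected_efficiency = corrected,
             ci_low = ci_low, ci_high = ci_high, n_boot_used = ok,
             stringsAsFactors = FALSE)
}

#' Raw and bias-corrected efficiency for a whole panel
#'
#' Estimates one frontier per calendar year (cross-sections, not a pooled
#' intertemporal frontier) and runs the smoothed bootstrap within each
#' year. Per-year RNG streams are derived from the master seed by fixed
#' offsets so individual years are independently reproducible.
#'
#' @param panel panel data frame (see [panel_schema()]).
#' @param input_cols,output_cols column names used as DEA inputs/outputs.
#' @param config a [bootstrap_config()]; its seed is the master seed.
#' @param id_col,year_col id and year column names.
#' @return data frame of per-DMU estimates for all years, with a
#'   `jurisdiction_id` column.
#' @export
bootstrap_panel <- function(panel, input_cols, output_cols,
                            config = bootstrap_config(),
                            id_col = "jurisdiction_id", year_col = "year") {
  years <- sort(unique(panel[[year_col]]))
  out <- lapply(years, function(yr) {
    slice <- panel[panel[[year_col]] == yr, , drop = FALSE]
    X <- as.matrix(slice[, input_cols, drop = FALSE])
    zero <- colSums(X > 0) == 0L
    if (any(zero)) {
      message("bootstrap_panel: dropping all-zero input column(s) for year ",
              yr, ": ", paste(input_cols[zero], collapse = ", "))
      X <- X[, !zero, drop = FALSE]
    }
    pr <- dea_problem(X, as.matrix(slice[, output_cols, drop = FALSE]),
                      rts = "vrs", year = yr,
                      dmu_ids = as.character(slice[[id_col]]))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, yr - min(years) + 1L)
    cfg$warn_small_B <- FALSE
    est <- bootstrap_year(pr, cfg)
    names(est)[names(est) == "dmu_id"] <- "jurisdiction_id"
    est
  })
  if (config$warn_small_B && config$B < 500L)
    warning("B = ", config$B,
            " resamples is small for stable confidence intervals",
            call. = FALSE)
  do.call(rbind, out)
}
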