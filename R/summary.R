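# Yearly and regional summarization of efficiency estimates: means with
# standard errors and normal-approximation confidence intervals, growth
# rates, OLS trend tests and between-region one-way ANOVA.

#' Yearly means of raw and bias-corrected efficiency
#'
#' Per-year mean of the raw and corrected scores across jurisdictions,
#' with SE = sd/sqrt(n) and a normal-approximation 95% interval
#' mean +/- 1.96 SE on the corrected mean (the interval is on the yearly
#' average, not per DMU). A year with a single estimate has no SE; its
#' interval collapses to the point and is flagged.
#'
#' @param estimates data frame from [bootstrap_panel()] (needs `year`,
#'   `raw_efficiency`, `bias_corrected_efficiency`).
#' @return data frame `year`, `mean_raw`, `mean_corrected`, `se_corrected`,
#'   `ci_low`, `ci_high`, `n`, `degenerate`.
#' @export
summarize_years <- function(estimates) {
  stopifnot(all(c("year", "raw_efficiency", "bias_corrected_efficiency")
                %in% names(estimates)))
  if (nrow(estimates) == 0L) stop("no estimates to summarize")
  out <- do.call(rbind, lapply(split(estimates, estimates$year), function(d) {
    n <- nrow(d)
    m <- mean(d$bias_corrected_efficiency)
    se <- if (n > 1) sd(d$bias_corrected_efficiency) / sqrt(n) else NA_real_
    data.frame(year = d$year[1], mean_raw = mean(d$raw_efficiency),
               mean_corrected = m, se_corrected = se,
               ci_low = if (n > 1) m - 1.96 * se else m,
               ci_high = if (n > 1) m + 1.96 * se else m,
               n = n, degenerate = n == 1L)
  }))
  rownames(out) <- NULL
  out[order(out$year), ]
}

#' Growth rate between two period means, truncated to two decimals
#'
#' \eqn{100 (end - start)/start}, truncated toward zero (not rounded) at
#' the second decimal. Truncation is the convention that reproduces
#' published two-decimal growth rates computed from two-decimal period
#' means (66.666... prints as 66.66, -1.9607... as -1.96).
#'
#' @param start_mean,end_mean period means; `start_mean` must be > 0.
#' @return growth rate in percent, truncated at two decimals.
#' @export
growth_rate <- function(start_mean, end_mean) {
  if (any(start_mean <= 0)) stop("start_mean must be > 0")
  pct <- 100 * (end_mean - start_mean) / start_mean
  trunc(round(pct * 100, 6)) / 100
}

#' Two-sided trend test on year
#'
#' p-value for the slope of an ordinary least-squares regression of the
#' score on calendar year, pooling all jurisdiction-year scores of one
#' group.
#'
#' @param scores numeric scores.
#' @param years corresponding years; at least 3 distinct values.
#' @return two-sided p-value.
#' @export
trend_test <- function(scores, years) {
  if (length(unique(years)) < 3L) stop("need >= 3 distinct years")
  if (sd(scores) < 1e-12) return(1)   # flat series: no evidence of trend
  fit <- lm(scores ~ years)
  unname(summary(fit)$coefficients["years", "Pr(>|t|)"])
}

#' Between-region difference test within one year
#'
#' One-way ANOVA F-test of equal mean scores across regions.
#'
#' @param scores numeric scores for one year.
#' @param regions region id per score; >= 2 regions with >= 2 scores each.
#' @return p-value of the F test.
#' @export
region_difference_test <- function(scores, regions) {
  tab <- table(regions)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 regions with >= 2 scores each")
  anova(lm(scores ~ factor(regions)))[["Pr(>F)"]][1]
}

#' Regional summary table (period means, growth rate, trend)
#'
#' One row per region plus a pooled row (region 0 = all jurisdictions):
#' mean and SD of the corrected score in each reported year, the growth
#' rate between the first and last reported year computed from the
#' region's own (two-decimal-rounded) means under the truncation
#' convention of [growth_rate()], and the OLS trend p-value over all
#' years. Per-year between-region difference tests are attached as an
#' attribute `region_tests`.
#'
#' @param estimates estimates with `jurisdiction_id`, `year`,
#'   `bias_corrected_efficiency`.
#' @param regions data frame `jurisdiction_id`, `region` (1..K).
#' @param report_years years to report means for (default
#'   c(2009, 2015, 2020) intersected with the data).
#' @return data frame with columns `region`, `mean_<yr>`/`sd_<yr>` per
#'   reported year, `growth_rate_pct`, `trend_p`.
#' @export
summarize_regions <- function(estimates, regions,
                              report_years = c(2009L, 2015L, 2020L)) {
  est <- merge(estimates, regions, by = "jurisdiction_id")
  yrs <- sort(unique(est$year))
  report_years <- intersect(report_years, yrs)
  if (length(report_years) < 2L)
    report_years <- range(yrs)
  groups <- c(0L, sort(unique(est$region)))
  rows <- lapply(groups, function(r) {
    d <- if (r == 0L) est else est[est$region == r, , drop = FALSE]
    row <- list(region = r)
    for (yr in report_years) {
      s <- d$bias_corrected_efficiency[d$year == yr]
      row[[paste0("mean_", yr)]] <- mean(s)
      row[[paste0("sd_", yr)]] <- sd(s)
    }
    m1 <- round(row[[paste0("mean_", min(report_years))]], 2)
    m2 <- round(row[[paste0("mean_", max(report_years))]], 2)
    row$growth_rate_pct <- growth_rate(m1, m2)
    row$trend_p <- trend_test(d$bias_corrected_efficiency, d$year)
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  tests <- vapply(report_years, function(yr) {
    d <- est[est$year == yr, , drop = FALSE]
    region_difference_test(d$bias_corrected_efficiency, d$region)
  }, numeric(1))
  attr(out, "region_tests") <- setNames(tests, report_years)
  out
}

#' Plain-text report of the regional summary
#'
#' @param region_summary result of [summarize_regions()].
#' @return character vector of report lines (also printed invisibly).
#' @export
format_region_report <- function(region_summary) {
  yrs <- sub("^mean_", "", grep("^mean_", names(region_summary), value = TRUE))
  hdr <- sprintf("%-18s %s %10s %8s", "Group",
                 paste(sprintf("%12s", yrs), collapse = " "),
                 "Growth", "P-trend")
  lines <- c("Average bias-corrected efficiency by region", hdr)
  for (i in seq_len(nrow(region_summary))) {
    r <- region_summary[i, ]
    lab <- if (r$region == 0) "All jurisdictions" else
      paste("Region", r$region)
    cells <- vapply(yrs, function(y)
      sprintf("%5.2f (%4.2f)", r[[paste0("mean_", y)]],
              r[[paste0("sd_", y)]]), character(1))
    lines <- c(lines, sprintf("%-18s %s %10.2f %8.3g", lab,
                              paste(cells, collapse = " "),
                              r$growth_rate_pct, r$trend_p))
  }
  tst <- attr(region_summary, "region_tests")
  if (!is.null(tst))
    lines <- c(lines, sprintf("Between-region difference test p: %s",
                              paste(sprintf("%s=%.3g", names(tst), tst),
                                    collapse = ", ")))
  lines
}
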