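# Synthetic jurisdiction-year panel generator.
#
# Emulates an administrative diabetes primary-care panel: 16 input rates
# per 10,000 inhabitants (4 infrastructure + 12 human-resource variables),
# two outputs (patients under treatment, patients controlled), and 7
# contextual covariates, for n jurisdictions over a year range, in 6
# socioeconomic regions. The true technology is a Cobb-Douglas frontier on
# two input aggregates with sum of elasticities < 1 (strictly variable
# returns to scale); inefficiency enters multiplicatively as exp(-u) with
# u >= 0 driven by the contextual variables, so the exact Farrell output
# distance exp(u) is known for every record.

# 2009-anchored input rate means (per 10,000 inhabitants) and the marginal
# dispersion used for the gamma draws.
.input_means_2009 <- c(
  general_medical_offices = 2.41, emergency_medical_offices = 0.02,
  nonhospital_emergency_beds = 0.72, nonhospital_recovery_beds = 0.28,
  general_practitioner = 2.14, medical_intern = 1.23,
  physician_admin = 0.14, general_nurse = 1.75, nurse_specialist = 0.01,
  nurse_intern = 0.61, nurse_admin = 0.09, chemist = 0.04,
  social_worker = 0.03, nutritionist = 0.02, lab_technician = 0.07,
  dietician_technician = 0.01)

.infrastructure_cols <- names(.input_means_2009)[1:4]
.human_resource_cols <- names(.input_means_2009)[5:16]

.context_cols <- c("marginalization", "phc_coverage", "indigenous_pct",
                   "demand", "gini", "gov_support", "employment")

#' Configuration for the synthetic panel generator
#'
#' Defaults encode the study conditions the generator emulates: 242
#' jurisdictions in 6 regions observed 2009-2020, input rates at the 2009
#' magnitudes of the administrative panel, a Cobb-Douglas frontier on the
#' infrastructure and human-resource aggregates with elasticities summing
#' to 0.75 (variable returns to scale), and context-driven inefficiency
#' whose signs match the determinants the study reports (marginalization,
#' indigenous share and care demand raise inefficiency; coverage,
#' employment and government support reduce it). A mild hump-shaped year
#' multiplier on inefficiency makes mean efficiency rise to 2016 and
#' decline after.
#'
#' @param n_jurisdictions number of DMUs (default 242).
#' @param years inclusive integer year range (default 2009:2020).
#' @param n_regions number of regions (default 6).
#' @param frontier_scale positive scale A of the frontier
#'   \eqn{g(x) = A\,\mathrm{infra}^{\alpha_1}\,\mathrm{hr}^{\alpha_2}}.
#' @param frontier_elasticities positive vector `c(infrastructure, human_resources)`
#'   with sum < 1.
#' @param context_effects named signed vector: effect of each standardized
#'   contextual variable on the inefficiency term u (positive = less
#'   efficient).
#' @param context_effects_by_region optional list (names `"1"`..`"6"`) of
#'   per-region replacements for `context_effects`.
#' @param inefficiency_scale sigma of the half-normal inefficiency noise
#'   (> 0).
#' @param noise_scale sigma of the two-sided log-normal measurement noise
#'   (>= 0); set 0 for exact frontier dominance.
#' @param controlled_share mean share of treated patients that are
#'   controlled, in (0,1); jittered per record.
#' @param region_gradient scale of the systematic region-level shifts in
#'   context means (1 = full south-to-north gradient, 0 = exchangeable
#'   regions).
#' @param seed integer RNG seed; identical (config, seed) gives an
#'   identical panel.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_jurisdictions = 242L,
                             years = 2009:2020,
                             n_regions = 6L,
                             frontier_scale = 565,
                             frontier_elasticities = c(infrastructure = 0.30,
                                                       human_resources = 0.45),
                             context_effects = c(marginalization = 1.0,
                                                 phc_coverage = -0.6,
                                                 indigenous_pct = 0.8,
                                                 demand = 0.6,
                                                 gini = 0.4,
                                                 gov_support = -0.3,
                                                 employment = -0.4),
                             context_effects_by_region = NULL,
                             inefficiency_scale = 0.05,
                             noise_scale = 0.05,
                             controlled_share = 0.40,
                             region_gradient = 1,
                             seed = 1L) {
  cfg <- list(n_jurisdictions = as.integer(n_jurisdictions),
              years = as.integer(years), n_regions = as.integer(n_regions),
              frontier_scale = frontier_scale,
              frontier_elasticities = frontier_elasticities,
              context_effects = context_effects,
              context_effects_by_region = context_effects_by_region,
              inefficiency_scale = inefficiency_scale,
              noise_scale = noise_scale,
              controlled_share = controlled_share,
              region_gradient = region_gradient,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_jurisdictions >= 1L, length(cfg$years) >= 1L,
            cfg$n_regions >= 1L, cfg$frontier_scale > 0)
  a <- cfg$frontier_elasticities
  if (any(a <= 0) || sum(a) >= 1)
    stop("frontier elasticities must be positive and sum to < 1 (VRS)")
  if (cfg$inefficiency_scale <= 0) stop("inefficiency_scale must be > 0")
  if (cfg$noise_scale < 0) stop("noise_scale must be >= 0")
  if (cfg$controlled_share <= 0 || cfg$controlled_share >= 1)
    stop("controlled_share must lie in (0,1)")
  if (!all(names(cfg$context_effects) == .context_cols))
    stop("context_effects must be named: ",
         paste(.context_cols, collapse = ", "))
  invisible(cfg)
}

softplus <- function(t) log1p(exp(-abs(t))) + pmax(t, 0)

# Hump-shaped year multiplier on inefficiency: highest at the range start,
# lowest at 2016, partial rebound after — mean efficiency rises to a peak
# then declines. Calibrated so the default config's yearly mean efficiency
# runs roughly 0.45 (2009) -> 0.70 (2016) -> 0.53 (2020).
year_ineff_multiplier <- function(year) {
  7.09 - 5.94 * exp(-((year - 2016) / 5)^2)
}

# Contextual inefficiency: softplus of the standardized context score,
# centered so a zero context effect means zero inefficiency (exactly on
# the frontier), clipped at 0. Only above-median contextual disadvantage
# generates inefficiency; the half-normal term adds idiosyncratic slack.
context_inefficiency <- function(score) {
  pmax(softplus(score) - log(2), 0)
}

# Frontier output for a record: Cobb-Douglas on the two input aggregates.
frontier_output <- function(infra_total, hr_total, config) {
  a <- config$frontier_elasticities
  config$frontier_scale * infra_total^a[[1]] * hr_total^a[[2]]
}

#' True efficiency implied by an inefficiency draw
#'
#' Ground-truth accessor for synthetic records: the true efficiency is
#' \eqn{e^{-u}} and equals observed treated output divided by the frontier
#' output when the measurement noise is zero.
#'
#' @param u non-negative inefficiency value.
#' @return efficiency in (0, 1].
#' @export
true_efficiency <- function(u) {
  if (any(u < 0)) stop("u must be non-negative")
  exp(-u)
}

#' Generate a synthetic jurisdiction-year panel with known ground truth
#'
#' Draws contextual covariates (with region-level shifts so regions differ
#' systematically), input rates calibrated to the 2009 magnitudes,
#' frontier outputs, and inefficiency
#' \eqn{u = m(\mathrm{year})\,[\max(\mathrm{softplus}(\beta^\top z) -
#' \log 2,\, 0) + |N(0,\sigma_u)|]} where z are the standardized
#' contextual variables; the softplus is centered so that zero context
#' effects put every unit exactly on the frontier.
#' Outputs are `treated = g(x) exp(-u) exp(v)` and `controlled` a jittered
#' share of treated.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (one row per jurisdiction-year, the schema of
#'   [panel_schema()]) and `truth` (`jurisdiction_id`, `year`,
#'   `true_farrell`, `true_efficiency`, `u`).
#' @export
generate_panel <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  with_local_seed(config$seed, generate_panel_impl(config))
}

generate_panel_impl <- function(config) {
  n <- config$n_jurisdictions
  years <- config$years
  ids <- sprintf("J%03d", seq_len(n))
  region <- rep_len(seq_len(config$n_regions), n)

  # Region-level socioeconomic gradients: low-index regions are the more
  # marginalized ones (higher marginalization/indigenous share, lower
  # coverage and employment), mirroring a south-to-north gradient.
  g <- if (config$n_regions > 1)
    config$region_gradient *
      ((config$n_regions - region) / (config$n_regions - 1) - 0.5) else 0

  rows <- vector("list", length(years))
  truths <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    ctx <- data.frame(
      marginalization = pmin(pmax(rnorm(n, 28.7 + 14 * g, 9), 0), 100),
      phc_coverage = pmin(pmax(rnorm(n, 50 - 12 * g, 12), 0), 100),
      indigenous_pct = pmin(100 * rbeta(n, 0.25, 2.6) * (1 + 0.8 * g), 100),
      demand = rgamma(n, shape = 9, scale = 0.1),
      gini = pmin(pmax(rnorm(n, 0.40, 0.04), 0), 1),
      gov_support = pmin(rgamma(n, shape = 0.9, scale = 8), 100),
      employment = pmin(pmax(rnorm(n, 90.6 - 4 * g, 5), 0), 100))

    # Input rates: gamma marginals at the 2009 anchor means (CV 0.5), with
    # a mild secular decline in infrastructure; the emergency-office rate
    # vanishes entirely after 2012, exercising the zero-column drop.
    decline <- 1 - 0.012 * (yr - min(years))
    mu <- .input_means_2009
    mu[.infrastructure_cols] <- mu[.infrastructure_cols] * decline
    Xin <- vapply(names(mu), function(v)
      rgamma(n, shape = 4, scale = mu[[v]] / 4), numeric(n))
    colnames(Xin) <- names(mu)
    if (yr > 2012) Xin[, "emergency_medical_offices"] <- 0

    infra_total <- rowSums(Xin[, .infrastructure_cols, drop = FALSE])
    hr_total <- rowSums(Xin[, .human_resource_cols, drop = FALSE])
    gx <- frontier_output(infra_total, hr_total, config)

    z <- scale(as.matrix(ctx))
    z[is.nan(z)] <- 0   # zero-variance column (degenerate configs)
    beta <- matrix(0, n, 1)
    for (r in unique(region)) {
      ce <- config$context_effects
      if (!is.null(config$context_effects_by_region) &&
          !is.null(config$context_effects_by_region[[as.character(r)]]))
        ce <- config$context_effects_by_region[[as.character(r)]]
      sel <- region == r
      beta[sel] <- z[sel, , drop = FALSE] %*% ce[.context_cols]
    }
    u <- year_ineff_multiplier(yr) *
      (context_inefficiency(drop(beta)) +
         abs(rnorm(n, 0, config$inefficiency_scale)))
    # cap inefficiency so outputs stay at administrative patient-count
    # magnitudes (minimum efficiency ~0.4%); a handful of worst units tie
    # at the cap rather than generating meaningless sub-unit counts
    u <- pmin(u, 5.5)
    v <- if (config$noise_scale > 0) rnorm(n, 0, config$noise_scale) else 0
    treated <- gx * exp(-u) * exp(v)
    share <- pmin(pmax(rnorm(n, config$controlled_share, 0.05), 0.02), 0.98)
    controlled <- share * treated

    if (!all(is.finite(c(treated, controlled, u))))
      stop("non-finite draw in synthetic generation (seed ", config$seed,
           ", year ", yr, ")")

    rows[[k]] <- data.frame(jurisdiction_id = ids, year = yr,
                            region = region, Xin,
                            treated = treated, controlled = controlled,
                            ctx, stringsAsFactors = FALSE)
    truths[[k]] <- data.frame(jurisdiction_id = ids, year = yr,
                              true_farrell = exp(u),
                              true_efficiency = exp(-u), u = u,
                              stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  rownames(panel) <- rownames(truth) <- NULL
  list(panel = panel, truth = truth)
}

#' Input, output and context column names of the panel schema
#'
#' @return named list of character vectors: `id`, `inputs`,
#'   `infrastructure`, `human_resources`, `outputs`, `context`.
#' @export
panel_columns <- function() {
  list(id = c("jurisdiction_id", "year", "region"),
       inputs = names(.input_means_2009),
       infrastructure = .infrastructure_cols,
       human_resources = .human_resource_cols,
       outputs = c("treated", "controlled"),
       context = .context_cols)
}

#' Append aggregate input columns used by the known technology
#'
#' The synthetic frontier is defined on two input aggregates; scoring on
#' them gives a well-specified DEA model for recovery checks.
#'
#' @param panel a panel data frame with the 16 input columns.
#' @return the panel with `infra_total` and `hr_total` columns appended.
#' @export
add_input_aggregates <- function(panel) {
  panel$infra_total <- rowSums(panel[, .infrastructure_cols, drop = FALSE])
  panel$hr_total <- rowSums(panel[, .human_resource_cols, drop = FALSE])
  panel
}
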