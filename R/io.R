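# Schema-validated CSV I/O, YAML configuration and pipeline orchestration.
# All CSVs use UTF-8, a header row and '.' as the decimal separator.

#' Panel schema
#'
#' The required columns of a jurisdiction-year panel, in order: ids
#' (jurisdiction_id, year, region), 16 input rates, 2 outputs and 7
#' contextual variables.
#'
#' @return data frame `column`, `type` (`character`/`integer`/`numeric`),
#'   `group`.
#' @export
panel_schema <- function() {
  pc <- panel_columns()
  data.frame(
    column = c(pc$id, pc$inputs, pc$outputs, pc$context),
    type = c("character", "integer", "integer",
             rep("numeric", length(pc$inputs) + 2L + length(pc$context))),
    group = c(rep("id", 3L),
              rep("infrastructure", length(pc$infrastructure)),
              rep("human_resources", length(pc$human_resources)),
              rep("output", 2L), rep("context", length(pc$context))),
    stringsAsFactors = FALSE)
}

#' Validate a panel against the schema
#'
#' Checks column presence, type coercibility, duplicate
#' (jurisdiction_id, year) pairs, non-negative rates and outputs,
#' controlled <= treated, gini in \[0,1\] and percentage columns in
#' \[0,100\].
#'
#' @param panel data frame to validate.
#' @return data frame of violations (`row`, `column`, `problem`);
#'   zero rows when the panel is valid.
#' @export
validate_panel <- function(panel) {
  sch <- panel_schema()
  v <- list()
  add <- function(row, column, problem)
    v[[length(v) + 1L]] <<- data.frame(row = row, column = column,
                                       problem = problem,
                                       stringsAsFactors = FALSE)
  missing_cols <- setdiff(sch$column, names(panel))
  for (mc in missing_cols) add(NA_integer_, mc, "missing column")
  if (length(missing_cols) == 0L) {
    dup <- duplicated(panel[, c("jurisdiction_id", "year")])
    for (i in which(dup)) add(i, "jurisdiction_id", "duplicate (id, year) pair")
    num_cols <- sch$column[sch$type == "numeric"]
    for (cl in c(num_cols, "year", "region")) {
      x <- suppressWarnings(as.numeric(panel[[cl]]))
      for (i in which(is.na(x))) add(i, cl, "not numeric")
    }
    pc <- panel_columns()
    for (cl in c(pc$inputs, pc$outputs)) {
      x <- suppressWarnings(as.numeric(panel[[cl]]))
      for (i in which(!is.na(x) & x < 0)) add(i, cl, "negative rate")
    }
    bad <- which(panel$controlled > panel$treated + 1e-9)
    for (i in bad) add(i, "controlled", "controlled > treated")
    for (i in which(panel$gini < 0 | panel$gini > 1))
      add(i, "gini", "gini outside [0,1]")
    for (cl in c("phc_coverage", "indigenous_pct", "employment",
                 "gov_support")) {
      x <- panel[[cl]]
      for (i in which(x < 0 | x > 100))
        add(i, cl, "percentage outside [0,100]")
    }
  }
  if (length(v) == 0L)
    data.frame(row = integer(0), column = character(0),
               problem = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, v)
}

#' Read and validate a panel CSV
#'
#' @param path CSV file written by [write_panel()] or matching
#'   [panel_schema()].
#' @return validated panel data frame.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  panel <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(panel) == 0L) stop("empty panel file: ", path)
  viol <- validate_panel(panel)
  if (nrow(viol) > 0L) {
    msg <- paste(sprintf("row %s, %s: %s", viol$row, viol$column,
                         viol$problem), collapse = "; ")
    stop("panel failed schema validation: ", msg)
  }
  panel$jurisdiction_id <- as.character(panel$jurisdiction_id)
  panel
}

#' Write a panel (or any stage artifact) as CSV
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Nested blocks `synthetic`, `dea`, `bootstrap`, `determinants`,
#' `summary` plus top-level `seed`, `outdir` and `stages`. Missing fields
#' fall back to package defaults.
#'
#' @param path YAML file; see
#'   `system.file("extdata", "example-config.yml", package = "jurisdea")`
#'   for a template.
#' @return `run_config` list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config_from_list(cfg)
}

#' Build a run configuration from a list
#'
#' @param cfg named list (possibly empty) with any of the blocks of
#'   [load_run_config()].
#' @return `run_config` list with all defaults filled in.
#' @export
run_config_from_list <- function(cfg = list()) {
  seed <- as.integer(cfg$seed %||% 1L)
  syn <- do.call(synthetic_config,
                 modifyList(list(seed = derive_seed(seed, 1L)),
                            cfg$synthetic %||% list()))
  boot <- do.call(bootstrap_config,
                  modifyList(list(seed = derive_seed(seed, 2L),
                                  warn_small_B = FALSE),
                             cfg$bootstrap %||% list()))
  det <- do.call(rf_config,
                 modifyList(list(seed = derive_seed(seed, 3L)),
                            cfg$determinants %||% list()))
  dea <- modifyList(list(input_cols = panel_columns()$inputs,
                         output_cols = panel_columns()$outputs,
                         rts = "vrs"),
                    cfg$dea %||% list())
  stages <- cfg$stages %||% c("describe", "dea", "rf", "regional")
  structure(list(seed = seed, outdir = cfg$outdir %||% "jurisdea-output",
                 stages = stages, synthetic = syn, dea = dea,
                 bootstrap = boot, determinants = det),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the analysis in order: (1) descriptive summary of the panel,
#' (2) per-year DEA with the smoothed bootstrap, (3) random-forest
#' determinants analysis (metrics, importance, partial dependence),
#' (4) regional subgroup refits and the regional summary table. Stage
#' artifacts are written under `config$outdir`; a JSON manifest records
#' files, checksums and seeds. Re-running with the same configuration
#' reproduces identical files.
#'
#' @param config a `run_config` ([run_config_from_list()] /
#'   [load_run_config()]).
#' @param panel optional panel data frame; when NULL a synthetic panel is
#'   generated from `config$synthetic` (truth is then also written).
#' @return the manifest list, invisibly; see `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config = run_config_from_list(), panel = NULL) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_panel(df, p)
    files <<- c(files, p)
    p
  }
  stage <- function(s) s %in% config$stages

  if (is.null(panel)) {
    gen <- generate_panel(config$synthetic)
    panel <- gen$panel
    put(gen$panel, "panel.csv")
    put(gen$truth, "truth.csv")
  }
  viol <- validate_panel(panel)
  if (nrow(viol) > 0L) stop("stage input: panel failed validation")
  pc <- panel_columns()

  if (stage("describe")) {
    message("stage: describe")
    num_cols <- c(pc$inputs, pc$outputs, pc$context)
    desc <- do.call(rbind, lapply(split(panel, panel$year), function(d)
      data.frame(year = d$year[1], variable = num_cols,
                 mean = vapply(num_cols, function(cl) mean(d[[cl]]), 0),
                 se = vapply(num_cols, function(cl)
                   sd(d[[cl]]) / sqrt(nrow(d)), 0))))
    rownames(desc) <- NULL
    put(desc, "descriptives.csv")
  }

  estimates <- NULL
  if (stage("dea")) {
    message("stage: dea + bootstrap (B = ", config$bootstrap$B, ")")
    estimates <- bootstrap_panel(panel, config$dea$input_cols,
                                 config$dea$output_cols, config$bootstrap)
    put(estimates, "estimates.csv")
    put(summarize_years(estimates), "year_summary.csv")
    regions <- unique(panel[, c("jurisdiction_id", "region")])
    rs <- summarize_regions(estimates, regions)
    put(cbind(rs), "region_summary.csv")
    writeLines(format_region_report(rs), file.path(outdir, "region_report.txt"))
    files <- c(files, file.path(outdir, "region_report.txt"))
  }

  rf <- NULL
  if (stage("rf")) {
    if (is.null(estimates)) stop("stage rf requires stage dea")
    message("stage: rf determinants")
    dat <- merge(panel, estimates, by = c("jurisdiction_id", "year"))
    feats <- dat[, c(pc$context, "year")]
    rf <- fit_rf(feats, dat$bias_corrected_efficiency, config$determinants)
    put(data.frame(metric = names(rf$metrics),
                   value = unlist(rf$metrics)), "rf_metrics.csv")
    imp <- perturbation_importance(rf, feats, dat$bias_corrected_efficiency,
                                   config$determinants)
    put(imp, "importance.csv")
    pd <- do.call(rbind, lapply(c(pc$context, "year"), function(v)
      partial_dependence(rf, feats, v, config$determinants)))
    put(pd, "partial_dependence.csv")
    pred_year <- aggregate(list(mean_predicted = ranger_predict(rf$model, feats)),
                           by = list(year = dat$year), FUN = mean)
    put(pred_year, "predicted_year_means.csv")
  }

  if (stage("regional")) {
    if (is.null(estimates)) stop("stage regional requires stage dea")
    message("stage: regional refits")
    dat <- merge(panel, estimates, by = c("jurisdiction_id", "year"))
    feats <- dat[, c(pc$context, "year")]
    reg <- fit_regional(feats, dat$bias_corrected_efficiency, dat$region,
                        config$determinants)
    for (r in names(reg$regions)) {
      sub <- file.path(outdir, paste0("region_", r))
      dir.create(sub, showWarnings = FALSE)
      put(reg$regions[[r]]$importance,
          file.path(paste0("region_", r), "importance.csv"))
      put(data.frame(metric = names(reg$regions[[r]]$metrics),
                     value = unlist(reg$regions[[r]]$metrics)),
          file.path(paste0("region_", r), "rf_metrics.csv"))
    }
    if (length(reg$skipped))
      files <- files  # skipped regions recorded in manifest below
    skipped_regions <- reg$skipped
  } else skipped_regions <- integer(0)

  manifest <- list(package = "jurisdea",
                   version = as.character(utils::packageVersion("jurisdea")),
                   seed = config$seed, stages = config$stages,
                   skipped_regions = skipped_regions,
                   files = lapply(files, function(f)
                     list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
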