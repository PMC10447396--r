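#' Pipeline run configuration
#'
#' Declares a full analysis run: the simulation (or pre-simulated
#' records), the exposure lag window, which model specifications to fit
#' (unadjusted, fully adjusted, RW2, a lag sweep), the subgroup
#' partitions, the trend analysis, the output directory and the root
#' seed. All randomness flows from the root seed, split per stage, and
#' the seeds are recorded in the output manifest.
#'
#' @param sim a [sim_config()].
#' @param lag_set exposure lag window for the main analysis.
#' @param models character subset of `c("unadjusted", "adjusted")`.
#' @param rw2 also fit the RW2 exposure-response sensitivity model.
#' @param lag_sweep also fit the adjusted model for each window
#'   `{0}, {0,1}, ..., {0..5}`.
#' @param partitions list of character vectors of subgroup columns.
#' @param trend run the posterior-draw yearly-trend procedure (requires
#'   >= 3 years).
#' @param trend_by optional grouping column for the trend.
#' @param noise_counts defect counts handed to [inject_cascade_noise()]
#'   before cleaning (0s disable).
#' @param fuzz_radius residence jitter radius in km.
#' @param min_events minimum events per subgroup / year.
#' @param outdir output directory (created if missing).
#' @param seed root seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       lag_set = 0:3,
                       models = c("unadjusted", "adjusted"),
                       rw2 = FALSE,
                       lag_sweep = FALSE,
                       partitions = list(c("sex", "age_group")),
                       trend = FALSE,
                       trend_by = NULL,
                       noise_counts = c(duplicates = 0, out_of_extent = 0,
                                        non_summer = 0, under_5 = 0,
                                        missing = 0),
                       fuzz_radius = 0.1,
                       min_events = 50L,
                       outdir = tempfile("heatasthma_run_"),
                       seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(sim = sim, lag_set = lag_set, models = models, rw2 = rw2,
                 lag_sweep = lag_sweep, partitions = partitions,
                 trend = trend, trend_by = trend_by,
                 noise_counts = noise_counts, fuzz_radius = fuzz_radius,
                 min_events = min_events, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full case-crossover pipeline
#'
#' Orchestrates simulate -> inject noise -> clean -> link -> strata ->
#' fit(s) -> subgroups -> trend, writing every artifact (exclusion
#' report, coefficient tables, subgroup and trend tables, ground truth)
#' plus a manifest (config hash, per-stage seeds, package version, file
#' list) into `config$outdir`. Stage failures propagate with the stage
#' name attached.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(sim = config$seed, noise = config$seed + 1000L,
                link = config$seed + 2000L, trend = config$seed + 3000L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- config$sim
  sim$seed <- seeds$sim
  artifacts <- character(0)
  keep <- function(f) { artifacts <<- c(artifacts, basename(f)); f }

  temp <- stage("temperature", make_temperature_surface(sim))
  cov <- stage("covariates", make_covariate_surfaces(sim, temp))
  holidays <- stage("holidays", make_holiday_calendar(sim))
  patients <- stage("patients", make_patients(sim, temp))
  records <- stage("admissions",
                   simulate_admissions(sim, temp, cov, holidays, patients))
  write_truth_json(records, keep(file.path(config$outdir, "ground_truth.json")))
  if (sum(config$noise_counts) > 0)
    records <- stage("noise", inject_cascade_noise(records,
                                                   config$noise_counts,
                                                   seed = seeds$noise))
  write_admissions_csv(records, keep(file.path(config$outdir, "admissions.csv")))

  cleaned <- stage("exclusions", apply_exclusions(records))
  message(paste(utils::capture.output(print(cleaned$report)), collapse = "\n"))
  exclusion_report_json(cleaned$report,
                        keep(file.path(config$outdir, "exclusion_report.json")))

  linked <- stage("linkage",
                  link_records(cleaned$records, temp, cov, holidays,
                               lag_set = config$lag_set,
                               fuzz_radius = config$fuzz_radius,
                               period_breaks = sim$period_breaks,
                               seed = seeds$link))
  strata <- stage("strata", build_strata(linked, temp, cov, holidays))
  message("built ", max(strata$stratum), " strata (",
          nrow(strata), " stratum-days)")

  fits <- list()
  specs <- list()
  if ("unadjusted" %in% config$models) specs$unadjusted <- unadjusted_spec()
  if ("adjusted" %in% config$models) specs$adjusted <- adjusted_spec()
  for (nm in names(specs)) {
    fits[[nm]] <- stage(paste0("fit_", nm),
                        fit_model(build_design_matrix(strata, specs[[nm]])))
  }
  if (config$rw2)
    fits$rw2 <- stage("fit_rw2",
                      fit_model(build_design_matrix(strata,
                        model_spec(temp_term = "rw2"))))
  if (config$lag_sweep) {
    for (L in 0:5) {
      nm <- paste0("lag0_", L)
      st <- stage(nm, build_strata(linked, temp, cov, holidays, lag_set = 0:L))
      fits[[nm]] <- stage(nm, fit_model(build_design_matrix(st, adjusted_spec())))
    }
  }

  subgroups <- list()
  for (part in config$partitions) {
    nm <- paste(part, collapse = "_")
    subgroups[[nm]] <- stage(paste0("subgroup_", nm),
                             subgroup_fit(linked, part, adjusted_spec(),
                                          temp, cov, holidays,
                                          min_events = config$min_events))
  }
  trend <- NULL
  if (config$trend)
    trend <- stage("trend",
                   yearly_trend(linked, adjusted_spec(), temp, cov, holidays,
                                seed = seeds$trend, by = config$trend_by,
                                min_events = config$min_events))

  files <- write_tables(list(fits = fits, subgroups = subgroups,
                             trend = trend), config$outdir)
  artifacts <- c(artifacts, basename(files))

  cfg_json <- file.path(config$outdir, "run_config.json")
  jsonlite::write_json(serialise_run_config(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, basename(cfg_json))
  manifest <- list(package_version = as.character(utils::packageVersion("heatasthma")),
                   config_hash = unname(tools::md5sum(cfg_json)),
                   seeds = seeds, artifacts = sort(unique(artifacts)),
                   n_retained = cleaned$report$retained,
                   created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(fits = fits, subgroups = subgroups,
                             trend = trend, report = cleaned$report,
                             outdir = config$outdir)))
}

# JSON-safe view of a run_config (functions and surfaces excluded)
serialise_run_config <- function(config) {
  sim <- config$sim
  sim$response <- if (is.null(sim$response)) NULL else "<custom function>"
  class(sim) <- NULL
  out <- unclass(config)
  out$sim <- sim
  out
}

#' Write tidy result tables
#'
#' Schema-stable CSVs: `effects_<model>.csv` (one row per coefficient:
#' term, estimate, lower, upper, se, plus the percent change per 1 degree
#' C), `subgroups_<partition>.csv` (one row per subgroup), `trend.csv`
#' (one row per group: slope median and CrI) and `trend_yearly.csv`, and
#' `rw2_curve.csv` when present. Empty subgroup lists produce a
#' header-only file.
#'
#' @param results list with elements `fits` (named list of `cco_fit`),
#'   `subgroups` (named list of `subgroup_results`) and optionally
#'   `trend` (a `trend_result`).
#' @param outdir output directory.
#' @return character vector of files written.
#' @export
write_tables <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results$fits)) {
    fit <- results$fits[[nm]]
    tab <- fit$coefficients
    if (!is.null(fit$percent_change)) {
      tab$pct_change <- NA_real_
      i <- match("temp", tab$term)
      tab$pct_change[i] <- fit$percent_change$median
    }
    f <- file.path(outdir, paste0("effects_", nm, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(fit$curve)) {
      f <- file.path(outdir, paste0("rw2_curve_", nm, ".csv"))
      utils::write.csv(fit$curve, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  for (nm in names(results$subgroups)) {
    sg <- results$subgroups[[nm]]
    tab <- if (length(sg$results)) as.data.frame(sg)
    else data.frame(subgroup = character(0), n_events = integer(0),
                    pct_change = numeric(0), lower = numeric(0),
                    upper = numeric(0))
    f <- file.path(outdir, paste0("subgroups_", nm, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(results$trend)) {
    tr <- results$trend
    slope_tab <- do.call(rbind, lapply(names(tr$groups), function(g)
      data.frame(group = g, slope_median = tr$groups[[g]]$slope_median,
                 slope_lower = tr$groups[[g]]$slope_lower,
                 slope_upper = tr$groups[[g]]$slope_upper)))
    f <- file.path(outdir, "trend.csv")
    utils::write.csv(slope_tab, f, row.names = FALSE)
    files <- c(files, f)
    yearly_tab <- do.call(rbind, lapply(names(tr$groups), function(g)
      cbind(group = g, tr$groups[[g]]$yearly)))
    f <- file.path(outdir, "trend_yearly.csv")
    utils::write.csv(yearly_tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  files
}
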