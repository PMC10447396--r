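#' Referent days for a time-stratified case-crossover stratum
#'
#' The referents of an event day are every other date in the same
#' calendar month and year that falls on the same weekday. Depending on
#' the month's length and weekday structure this gives 3 or 4 referents.
#'
#' @param date Date vector of event days.
#' @return list of Date vectors (one per event), event day excluded.
#' @export
referent_days <- function(date) {
  date <- as.Date(date)
  lapply(seq_along(date), function(i) {
    same <- same_weekday_days(date[i])
    same[same != date[i]]
  })
}

# every day of the event's calendar month/year on the event's weekday
# (the stratum's day set, event included)
same_weekday_days <- function(d) {
  d <- as.Date(d)
  first <- as.Date(format(d, "%Y-%m-01"))
  days <- seq(first, by = "day", length.out = days_in_month(d))
  days[weekday_of(days) == weekday_of(d)]
}

days_in_month <- function(d) {
  first <- as.Date(format(as.Date(d), "%Y-%m-01"))
  as.integer(format(seq(first, by = "month", length.out = 2)[2] - 1, "%d"))
}

#' Build one case-crossover stratum
#'
#' @param record one linked record (list or single-row data.frame with
#'   `record_id`, `patient_id`, `date`, `cell`).
#' @param temp a `temp_surface`.
#' @param cov a `covariate_surface`.
#' @param holidays holiday Date vector.
#' @param lag_set exposure lag window, re-anchored at every stratum day.
#' @return data.frame with one row per stratum day: `date`, `case`,
#'   `x_lag`, `rainfall`, `humidity`, `wind`, `holiday`.
#' @export
build_stratum <- function(record, temp, cov, holidays, lag_set = 0:3) {
  days <- sort(c(as.Date(record$date), referent_days(record$date)[[1]]))
  x <- vapply(days, function(d)
    lagged_mean_exposure(list(date = d, cell = record$cell), temp, lag_set),
    numeric(1))
  ccell <- fine_to_coarse_index(temp$cells$row[record$cell],
                                temp$cells$col[record$cell],
                                cov$coarse_factor, cov$grid$cols)
  di <- match(days, cov$dates)
  if (anyNA(di))
    stop("design error: covariates missing for stratum day(s) ",
         paste(format(days[is.na(di)]), collapse = ", "))
  data.frame(record_id = record$record_id, patient_id = record$patient_id,
             date = days, case = as.integer(days == as.Date(record$date)),
             x_lag = x,
             rainfall = cov$rainfall[ccell, di],
             humidity = cov$humidity[ccell, di],
             wind = cov$wind[ccell, di],
             holiday = as.integer(days %in% holidays))
}

#' Build all case-crossover strata
#'
#' One stratum per retained admission record: the event day plus its
#' same-weekday/month/year referents, each day carrying its own
#' lag-averaged temperature (window re-anchored at that day) and same-day
#' covariates at the record's assigned cell.
#'
#' @param linked `linked_records` from [link_records()].
#' @param temp,cov,holidays the surfaces and holiday calendar.
#' @param lag_set exposure lag window; defaults to the window used at
#'   linkage.
#' @return data.frame of class `cco_strata`, long format: `stratum`
#'   (integer), `record_id`, `patient_id`, `date`, `case`, `x_lag`,
#'   `rainfall`, `humidity`, `wind`, `holiday`.
#' @export
build_strata <- function(linked, temp, cov, holidays,
                         lag_set = attr(linked, "lag_set")) {
  stopifnot(nrow(linked) > 0)
  if (is.null(lag_set)) lag_set <- 0:3
  dates <- as.Date(linked$date)
  # the stratum day set is shared by every event in the same
  # (year, month, weekday) cell -- enumerate it once per cell
  key <- paste(year_of(dates), month_of(dates), weekday_of(dates))
  ukey <- !duplicated(key)
  cell_days <- lapply(dates[ukey], same_weekday_days)
  names(cell_days) <- key[ukey]
  sets <- cell_days[key]
  ord <- rep(seq_len(nrow(linked)), lengths(sets))
  day <- as.Date(unlist(sets), origin = "1970-01-01")
  cellv <- linked$cell[ord]
  xlf <- lagged_mean_field(temp, lag_set)
  di <- match(day, attr(xlf, "dates"))
  if (anyNA(di))
    stop("design error: exposure missing for stratum day(s) ",
         paste(format(utils::head(unique(day[is.na(di)]), 3)), collapse = ", "))
  ccell <- fine_to_coarse_index(temp$cells$row[cellv], temp$cells$col[cellv],
                                cov$coarse_factor, cov$grid$cols)
  fdi <- match(day, cov$dates)
  out <- data.frame(stratum = ord,
                    record_id = linked$record_id[ord],
                    patient_id = linked$patient_id[ord],
                    date = day,
                    case = as.integer(day == dates[ord]),
                    x_lag = xlf[cbind(cellv, di)],
                    rainfall = cov$rainfall[cbind(ccell, fdi)],
                    humidity = cov$humidity[cbind(ccell, fdi)],
                    wind = cov$wind[cbind(ccell, fdi)],
                    holiday = as.integer(day %in% holidays))
  class(out) <- c("cco_strata", "data.frame")
  attr(out, "lag_set") <- lag_set
  out
}

#' Model specification for the conditional Poisson fit
#'
#' @param temp_term `"linear"` (single temperature column) or `"rw2"`
#'   (binned temperature with a random-walk-2 smoothness prior).
#' @param confounders subset of `c("rainfall", "humidity", "wind",
#'   "holiday")`; the fully adjusted model uses all four, the unadjusted
#'   model none.
#' @param n_bins number of equal-width temperature bins for `"rw2"`
#'   (>= 4; default 20).
#' @param patient_effect include a per-patient normal random effect. Each
#'   stratum belongs to one admission (hence one patient), so the term is
#'   constant within every stratum and cancels from the conditional
#'   likelihood; it is carried for fidelity and reported in the
#'   diagnostics, and cannot move the exposure estimate.
#' @param patient_effect_scope `"recurrent"` (patients with >= 2
#'   admissions, the default) or `"all"`.
#' @param prior_sd_beta normal prior SD for fixed effects (default 10;
#'   `Inf` gives a flat prior).
#' @param prior_sd_patient half-normal prior scale for the patient-effect
#'   SD.
#' @param prior_sd_rw2 half-normal prior scale for the RW2 smoothness SD
#'   (on the scaled structure matrix).
#' @param holiday_coding `"holiday1"` (internal convention, 1 = holiday)
#'   or `"inverse"` (0 = holiday, 1 otherwise, as sometimes coded in
#'   administrative analyses); only the holiday coefficient's sign
#'   differs, the temperature estimate is unaffected.
#' @param backend `"laplace"` (deterministic, default) or `"mcmc"`.
#' @param mcmc list of options for the MCMC backend: `chains`, `draws`,
#'   `warmup`, `seed`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(temp_term = c("linear", "rw2"),
                       confounders = c("rainfall", "humidity", "wind", "holiday"),
                       n_bins = 20L,
                       patient_effect = FALSE,
                       patient_effect_scope = c("recurrent", "all"),
                       prior_sd_beta = 10,
                       prior_sd_patient = 1,
                       prior_sd_rw2 = 1,
                       holiday_coding = c("holiday1", "inverse"),
                       backend = c("laplace", "mcmc"),
                       mcmc = list(chains = 4L, draws = 1000L,
                                   warmup = 500L, seed = 1L)) {
  temp_term <- match.arg(temp_term)
  backend <- match.arg(backend)
  if (length(confounders) > 0) {
    bad <- setdiff(confounders, c("rainfall", "humidity", "wind", "holiday"))
    if (length(bad))
      stop("configuration error: unknown confounder term(s): ",
           paste(bad, collapse = ", "))
  }
  if (temp_term == "rw2" && n_bins < 4L)
    stop("configuration error: rw2 requires n_bins >= 4")
  if (prior_sd_beta <= 0 || prior_sd_patient <= 0 || prior_sd_rw2 <= 0)
    stop("configuration error: prior SDs must be positive")
  structure(list(temp_term = temp_term, confounders = confounders,
                 n_bins = as.integer(n_bins),
                 patient_effect = isTRUE(patient_effect),
                 patient_effect_scope = match.arg(patient_effect_scope),
                 prior_sd_beta = prior_sd_beta,
                 prior_sd_patient = prior_sd_patient,
                 prior_sd_rw2 = prior_sd_rw2,
                 holiday_coding = match.arg(holiday_coding),
                 backend = backend, mcmc = mcmc),
            class = "model_spec")
}

#' Fully adjusted model specification
#' @param ... passed to [model_spec()].
#' @return a `model_spec` with all four confounders.
#' @export
adjusted_spec <- function(...) model_spec(confounders = c("rainfall",
  "humidity", "wind", "holiday"), ...)

#' Unadjusted model specification
#' @param ... passed to [model_spec()].
#' @return a `model_spec` with the temperature term only.
#' @export
unadjusted_spec <- function(...) model_spec(confounders = character(0), ...)

#' Build the stratified design matrix
#'
#' Emits the response (case indicator), the stratum index, and the
#' covariate columns in documented order: the temperature term first
#' (single `temp` column, or `n_bins` bin-indicator columns under an RW2
#' specification, exposures assigned to the nearest bin midpoint), then
#' any confounders in the order rainfall, humidity, wind, holiday.
#'
#' @param strata a `cco_strata` data.frame.
#' @param spec a [model_spec()].
#' @return object of class `cco_design`: list with matrix `X`, response
#'   `y`, integer `stratum`, `patient_id`, `terms`, and (for rw2) the
#'   `rw2_prior` and per-row `bin` index.
#' @export
build_design_matrix <- function(strata, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"), nrow(strata) > 0)
  s <- as.integer(factor(strata$stratum))
  y <- as.integer(strata$case)
  cases_per <- rowsum(y, s)
  if (any(cases_per != 1L))
    stop("data error: every stratum must contain exactly one case day")
  rw2 <- NULL; bin <- NULL
  if (spec$temp_term == "linear") {
    X <- cbind(temp = strata$x_lag)
  } else {
    rw2 <- make_rw2_prior(strata$x_lag, spec$n_bins)
    bin <- bin_of(strata$x_lag, rw2)
    X <- matrix(0, nrow(strata), spec$n_bins,
                dimnames = list(NULL, sprintf("temp_bin_%02d", seq_len(spec$n_bins))))
    X[cbind(seq_len(nrow(strata)), bin)] <- 1
  }
  ord <- c("rainfall", "humidity", "wind", "holiday")
  for (v in ord[ord %in% spec$confounders]) {
    col <- strata[[v]]
    if (v == "holiday" && spec$holiday_coding == "inverse") col <- 1L - col
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- v
  }
  structure(list(X = X, y = y, stratum = s, patient_id = strata$patient_id,
                 terms = colnames(X), spec = spec, rw2_prior = rw2, bin = bin,
                 x_lag = strata$x_lag),
            class = "cco_design")
}

#' Serialise strata to long-format CSV
#' @param strata a `cco_strata`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_strata_csv <- function(strata, path) {
  utils::write.csv(as.data.frame(strata), path, row.names = FALSE)
  invisible(path)
}

#' Read strata back from CSV
#' @param path file written by [write_strata_csv()].
#' @return a `cco_strata` data.frame.
#' @export
read_strata_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  class(out) <- c("cco_strata", "data.frame")
  out
}
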