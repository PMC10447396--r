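#' Daily mean temperature from Tmin and Tmax
#'
#' The daily mean is the average of the daily minimum and maximum,
#' elementwise: `(tmin + tmax) / 2`. Missing cell-days propagate as NA,
#' never silently imputed.
#'
#' @param surface a `temp_surface`.
#' @return matrix (cells x dates) of daily mean temperature.
#' @export
compute_daily_mean <- function(surface) {
  stopifnot(inherits(surface, "temp_surface"))
  if (any(surface$tmin > surface$tmax, na.rm = TRUE))
    stop("invalid surface: Tmin > Tmax for some cell-day")
  (surface$tmin + surface$tmax) / 2
}

#' Fuzz a location uniformly on a disc
#'
#' Privacy-style jitter: each point is displaced to a uniform draw on the
#' disc of the given radius about it (so the mean squared displacement is
#' radius^2 / 2). Deterministic given the RNG state.
#'
#' @param x,y coordinates in km.
#' @param radius disc radius in km (default 0.1, i.e. 100 m).
#' @return data.frame with fuzzed `x`, `y`.
#' @export
fuzz_location <- function(x, y, radius = 0.1) {
  stopifnot(radius >= 0)
  n <- length(x)
  r <- radius * sqrt(runif(n))
  th <- 2 * pi * runif(n)
  data.frame(x = x + r * cos(th), y = y + r * sin(th))
}

#' Assign a point to its containing fine grid cell
#'
#' Cells are unit (1 km) squares with half-open boundaries: a point on a
#' shared edge belongs to the lower/left cell whose interval is
#' left/bottom-inclusive. Points outside the extent raise a linkage error.
#'
#' @param x,y coordinates in km.
#' @param surface a `temp_surface` (for the grid extent).
#' @return integer cell ids (row-major, matching `surface$cells$cell`).
#' @export
assign_cell <- function(x, y, surface) {
  rows <- surface$grid$rows; cols <- surface$grid$cols
  bad <- !is.finite(x) | !is.finite(y) | x < 0 | x >= cols | y < 0 | y >= rows
  if (any(bad))
    stop("linkage error: ", sum(bad), " point(s) outside the grid extent")
  col <- floor(x) + 1L
  row <- floor(y) + 1L
  (row - 1L) * cols + col
}

# clamp points to just inside the extent (fuzzing must never create
# exclusions)
clamp_to_extent <- function(x, y, surface, eps = 1e-9) {
  cols <- surface$grid$cols; rows <- surface$grid$rows
  list(x = pmin(pmax(x, 0), cols - eps), y = pmin(pmax(y, 0), rows - eps))
}

# Lag-averaged daily-mean temperature field: matrix (cells x target dates)
# where entry [c, d] is the mean of Tmean at cell c over
# {target_date[d] - L : L in lag_set}. Errors if a required day is absent.
lagged_mean_field <- function(surface, lag_set = 0:3,
                              target_dates = summer_dates(surface$dates)) {
  tmean <- compute_daily_mean(surface)
  acc <- 0
  for (L in lag_set) {
    idx <- match(target_dates - L, surface$dates)
    if (anyNA(idx)) {
      miss <- target_dates[is.na(idx)] - L
      stop("exposure error: temperature missing for required day(s) ",
           paste(format(utils::head(unique(miss), 3)), collapse = ", "))
    }
    acc <- acc + tmean[, idx, drop = FALSE]
  }
  out <- acc / length(lag_set)
  colnames(out) <- format(target_dates)
  attr(out, "dates") <- target_dates
  attr(out, "lag_set") <- lag_set
  out
}

#' Lag-averaged temperature exposure for one record
#'
#' Arithmetic mean of the daily mean temperature at the record's cell over
#' the days `date - L` for each lag `L` in `lag_set` (lag 0 = the event
#' day itself; the default window `0:3` spans the event day and the three
#' preceding days). Errors, naming the date, if any required day is
#' missing -- never a partial average.
#'
#' @param record a list/row with `date` (Date) and `cell` (fine cell id).
#' @param surface a `temp_surface`.
#' @param lag_set integer lags, default `0:3`.
#' @return scalar exposure in degrees C.
#' @export
lagged_mean_exposure <- function(record, surface, lag_set = 0:3) {
  days <- as.Date(record$date) - lag_set
  idx <- match(days, surface$dates)
  if (anyNA(idx))
    stop("exposure error: temperature missing for ",
         paste(format(days[is.na(idx)]), collapse = ", "))
  tmean <- compute_daily_mean(surface)
  mean(tmean[record$cell, idx])
}

#' Apply the record exclusion cascade
#'
#' Removes, in this fixed order, (1) duplicate records (full-field
#' equality, including the record id), (2) records with residence outside
#' the grid extent, (3) records not dated June--August, (4) records aged
#' under 5 years, and (5) records with missing sex or age. Each record is
#' counted under the first rule that removes it, so the tallies
#' reconcile: input = retained + sum(removed).
#'
#' @param records admission records (as from [simulate_admissions()] or
#'   [inject_cascade_noise()]).
#' @param extent `c(x, y)` grid extent in km; defaults to the records'
#'   `extent` attribute.
#' @return list with `records` (retained, defect tag column dropped) and
#'   `report` (class `exclusion_report`).
#' @export
apply_exclusions <- function(records, extent = attr(records, "extent")) {
  if (is.null(extent))
    stop("apply_exclusions needs the grid extent (records attribute or argument)")
  n_in <- nrow(records)
  content <- c("record_id", "patient_id", "date", "age", "sex", "x", "y", "icd10")
  content <- intersect(content, names(records))
  removed <- c(duplicates = 0L, out_of_extent = 0L, non_summer = 0L,
               under_age = 0L, missing_field = 0L)

  dup <- duplicated(records[content])
  removed["duplicates"] <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  out <- !is.finite(records$x) | !is.finite(records$y) |
    records$x < 0 | records$x > extent[1] |
    records$y < 0 | records$y > extent[2]
  removed["out_of_extent"] <- sum(out)
  records <- records[!out, , drop = FALSE]

  ns <- !(month_of(records$date) %in% 6:8)
  removed["non_summer"] <- sum(ns)
  records <- records[!ns, , drop = FALSE]

  young <- !is.na(records$age) & records$age < 5
  removed["under_age"] <- sum(young)
  records <- records[!young, , drop = FALSE]

  mis <- is.na(records$age) | is.na(records$sex) | records$sex == ""
  removed["missing_field"] <- sum(mis)
  records <- records[!mis, , drop = FALSE]

  if (nrow(records) == 0L)
    stop("empty cohort: no records retained after exclusions")
  records$defect <- NULL
  rownames(records) <- NULL
  attr(records, "extent") <- extent
  report <- structure(list(input = n_in, removed = removed,
                           retained = nrow(records)),
                      class = "exclusion_report")
  list(records = records, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade\n")
  cat(sprintf("  input records            %8d\n", x$input))
  lab <- c(duplicates = "duplicate records", out_of_extent = "outside extent",
           non_summer = "non-summer months", under_age = "aged under 5",
           missing_field = "missing sex or age")
  for (k in names(x$removed))
    cat(sprintf("  - removed %-16s %8d\n", lab[[k]], x$removed[[k]]))
  cat(sprintf("  retained for analysis    %8d\n", x$retained))
  invisible(x)
}

#' Serialise an exclusion report to JSON
#'
#' @param report an `exclusion_report`.
#' @param path optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
exclusion_report_json <- function(report, path = NULL) {
  obj <- list(input = report$input, removed = as.list(report$removed),
              retained = report$retained)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Link cleaned records to exposures and covariates
#'
#' For every retained record: fuzz the residence location on a 100 m disc
#' (clamping any point pushed outside the grid back to the boundary),
#' assign the containing fine cell and its region, compute the
#' lag-averaged mean-temperature exposure anchored at the admission date,
#' attach same-day (lag 0) rainfall, humidity and wind from the containing
#' coarse cell, flag national holidays, and derive the age group and study
#' period.
#'
#' @param records retained records from [apply_exclusions()].
#' @param temp a `temp_surface`.
#' @param cov a `covariate_surface`.
#' @param holidays Date vector of national holidays.
#' @param lag_set integer lags for the exposure window (default `0:3`).
#' @param fuzz_radius jitter radius in km (default 0.1 = 100 m; 0 disables).
#' @param period_breaks period definition (list of year vectors); default
#'   splits the years present into three near-equal spans.
#' @param seed RNG seed for the jitter (linkage is pure given the seed).
#' @return data.frame of class `linked_records`: record fields plus
#'   `x_fuzz`, `y_fuzz`, `cell`, `region`, `x_lag`, `rainfall`,
#'   `humidity`, `wind`, `holiday`, `age_group`, `period`.
#' @export
link_records <- function(records, temp, cov, holidays, lag_set = 0:3,
                         fuzz_radius = 0.1, period_breaks = NULL, seed = 1L) {
  stopifnot(inherits(temp, "temp_surface"), inherits(cov, "covariate_surface"))
  set.seed(seed)
  fz <- fuzz_location(records$x, records$y, fuzz_radius)
  cl <- clamp_to_extent(fz$x, fz$y, temp)
  cell <- assign_cell(cl$x, cl$y, temp)
  xlf <- lagged_mean_field(temp, lag_set)
  sdates <- attr(xlf, "dates")
  di <- match(as.Date(records$date), sdates)
  if (anyNA(di))
    stop("linkage error: record date(s) outside the summer exposure range: ",
         paste(format(utils::head(unique(records$date[is.na(di)]), 3)),
               collapse = ", "))
  ccell <- fine_to_coarse_index(temp$cells$row[cell], temp$cells$col[cell],
                                cov$coarse_factor, cov$grid$cols)
  fdi <- match(as.Date(records$date), cov$dates)
  if (anyNA(fdi)) stop("linkage error: covariates missing for some record dates")
  out <- records
  out$x_fuzz <- cl$x; out$y_fuzz <- cl$y
  out$cell <- cell
  out$region <- temp$cells$region[cell]
  out$x_lag <- xlf[cbind(cell, di)]
  out$rainfall <- cov$rainfall[cbind(ccell, fdi)]
  out$humidity <- cov$humidity[cbind(ccell, fdi)]
  out$wind <- cov$wind[cbind(ccell, fdi)]
  if (anyNA(out$rainfall) || anyNA(out$humidity) || anyNA(out$wind))
    stop("linkage error: missing coarse covariate value")
  out$holiday <- as.integer(as.Date(records$date) %in% holidays)
  out$age_group <- age_group_of(records$age)
  if (is.null(period_breaks))
    period_breaks <- default_periods(sort(unique(year_of(records$date))))
  out$period <- period_of(year_of(records$date), period_breaks)
  out$year <- year_of(records$date)
  class(out) <- c("linked_records", "data.frame")
  attr(out, "lag_set") <- lag_set
  attr(out, "extent") <- attr(records, "extent")
  out
}
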