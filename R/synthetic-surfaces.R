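#' Generate the fine-grid daily temperature surface
#'
#' Builds daily Tmin/Tmax on the fine grid for 26 May -- 31 August of each
#' simulated year. The daily mean is the sum of a smooth spatial gradient,
#' a per-year offset, a sinusoidal within-summer seasonal cycle, a shared
#' AR(1) day-to-day anomaly and small independent cell-day noise; Tmin and
#' Tmax sit symmetrically around it at a random half-range, so
#' (Tmin + Tmax) / 2 recovers the mean exactly and Tmin <= Tmax always.
#' The late-May spill-over guarantees lag 0--5 exposures exist for 1 June
#' events.
#'
#' @param config a [sim_config()].
#' @return object of class `temp_surface`: list with `dates` (Date),
#'   `cells` (data.frame: cell, row, col, x0, y0, region), matrices
#'   `tmin` and `tmax` (cells x dates), and `grid` metadata.
#' @export
make_temperature_surface <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  dates <- surface_dates(config$years)
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  nc <- rows * cols; nd <- length(dates)
  cells <- data.frame(cell = seq_len(nc),
                      row = rep(seq_len(rows), each = cols),
                      col = rep(seq_len(cols), times = rows))
  cells$x0 <- cells$col - 1; cells$y0 <- cells$row - 1
  cells$region <- region_of_cell(cells$row, cells$col, config)

  if (!is.null(config$constant_field)) {
    v <- config$constant_field
    tmin <- tmax <- matrix(v, nc, nd)
  } else {
    # smooth gradient: warmer towards low row (south) and high col (east)
    g <- config$spatial_amp * (0.5 - (cells$row - 0.5) / rows) +
      0.4 * config$spatial_amp * ((cells$col - 0.5) / cols - 0.5)
    lt <- as.POSIXlt(dates)
    yr <- lt$year + 1900L
    doy <- lt$yday + 1L
    uy <- sort(unique(yr))
    year_eff <- setNames(rnorm(length(uy), 0, config$year_effect_sd), uy)
    season <- config$season_amp * cos(2 * pi * (doy - 196) / 365)
    # shared AR(1) anomaly, restarted at stationarity each year
    anom <- numeric(nd)
    phi <- config$ar_phi; s <- config$temp_sd
    for (y in uy) {
      id <- which(yr == y)
      e <- rnorm(length(id))
      a <- numeric(length(id))
      a[1] <- s * e[1]
      if (length(id) > 1)
        for (d in 2:length(id)) a[d] <- phi * a[d - 1] + s * sqrt(1 - phi^2) * e[d]
      anom[id] <- a
    }
    day_part <- unname(config$temp_mean + year_eff[as.character(yr)] +
                         season + anom)
    tmean <- outer(g, day_part, `+`) +
      matrix(rnorm(nc * nd, 0, config$cell_noise_sd), nc, nd)
    hr <- matrix(pmax(0.5, rnorm(nc * nd, config$diurnal_half_range, 1)), nc, nd)
    tmin <- tmean - hr
    tmax <- tmean + hr
  }
  structure(list(dates = dates, cells = cells, tmin = tmin, tmax = tmax,
                 grid = list(rows = rows, cols = cols,
                             extent = c(x = cols, y = rows))),
            class = "temp_surface")
}

#' @export
print.temp_surface <- function(x, ...) {
  cat("<temp_surface>", nrow(x$cells), "cells x", length(x$dates), "days;",
      "extent", x$grid$cols, "x", x$grid$rows, "km;",
      format(min(x$dates)), "to", format(max(x$dates)), "\n")
  invisible(x)
}

# Dates 26 May - 31 Aug for each year (real Gregorian calendar).
surface_dates <- function(years) {
  as.Date(unlist(lapply(years, function(y)
    seq(as.Date(sprintf("%d-05-26", y)), as.Date(sprintf("%d-08-31", y)),
        by = "day"))), origin = "1970-01-01")
}

# Event-eligible days: June-August.
summer_dates <- function(dates) dates[month_of(dates) %in% 6:8]

month_of <- function(dates) as.POSIXlt(dates)$mon + 1L
year_of <- function(dates) as.POSIXlt(dates)$year + 1900L
# ISO-ish weekday, Monday = 1 ... Sunday = 7
weekday_of <- function(dates) {
  wd <- as.POSIXlt(dates)$wday
  ifelse(wd == 0L, 7L, wd)
}

region_of_cell <- function(row, col, config) {
  rb <- config$region_tiling["row_blocks"]
  cb <- config$region_tiling["col_blocks"]
  rh <- config$grid_shape[1] %/% rb
  cw <- config$grid_shape[2] %/% cb
  ((row - 1L) %/% rh) * cb + ((col - 1L) %/% cw) + 1L
}

#' Generate coarse-grid daily meteorological covariates
#'
#' Rainfall (mm), relative humidity (%) and wind speed (m/s) on the coarse
#' grid (one coarse cell covers `coarse_factor^2` fine cells). Each
#' variable is a linear transform of a latent standard-normal field built
#' to have the configured correlation (`cov_temp_cor`) with the coarse-cell
#' daily mean temperature, then mapped to its physical range (humidity
#' clamped to \[0, 100\], rainfall and wind floored at >= 0).
#'
#' @param config a [sim_config()].
#' @param temp the matching [make_temperature_surface()] output.
#' @return object of class `covariate_surface`: list with `dates`, coarse
#'   `cells` (cell, row, col), matrices `rainfall`, `humidity`, `wind`
#'   (coarse cells x dates) and `coarse_factor`.
#' @export
make_covariate_surfaces <- function(config, temp) {
  stopifnot(inherits(config, "sim_config"), inherits(temp, "temp_surface"))
  set.seed(config$seed + 23L)
  cf <- config$coarse_factor
  crows <- config$grid_shape[1] %/% cf
  ccols <- config$grid_shape[2] %/% cf
  ncc <- crows * ccols; nd <- length(temp$dates)
  ccells <- data.frame(cell = seq_len(ncc),
                       row = rep(seq_len(crows), each = ccols),
                       col = rep(seq_len(ccols), times = crows))
  # coarse-cell daily mean temperature (average of covered fine cells)
  fmap <- fine_to_coarse_index(temp$cells$row, temp$cells$col, cf, ccols)
  tmean <- compute_daily_mean(temp)
  tc <- rowsum(tmean, fmap) / as.vector(table(fmap))
  tsd <- sd(as.vector(tc))
  # a degenerate (constant) field carries no signal to correlate with
  zt <- if (tsd > 0) (tc - mean(tc)) / tsd else matrix(0, ncc, nd)
  latent <- function(rho) {
    rho * zt + sqrt(1 - rho^2) * matrix(rnorm(ncc * nd), ncc, nd)
  }
  rho <- config$cov_temp_cor
  rainfall <- matrix(pmax(0, 2.5 + 2.5 * latent(rho[["rainfall"]])), ncc, nd)
  humidity <- matrix(pmin(100, pmax(0, 70 + 10 * latent(rho[["humidity"]]))),
                     ncc, nd)
  wind <- matrix(pmax(0.1, 4 + 1.5 * latent(rho[["wind"]])), ncc, nd)
  structure(list(dates = temp$dates, cells = ccells, rainfall = rainfall,
                 humidity = humidity, wind = wind, coarse_factor = cf,
                 grid = list(rows = crows, cols = ccols)),
            class = "covariate_surface")
}

#' @export
print.covariate_surface <- function(x, ...) {
  cat("<covariate_surface>", nrow(x$cells), "coarse cells x",
      length(x$dates), "days; coarse factor", x$coarse_factor, "\n")
  invisible(x)
}

# coarse cell index for fine cells given fine (row, col)
fine_to_coarse_index <- function(row, col, coarse_factor, ccols) {
  ((row - 1L) %/% coarse_factor) * ccols + ((col - 1L) %/% coarse_factor) + 1L
}

#' Generate the synthetic national-holiday calendar
#'
#' Two holidays per summer: the second Monday of July and the last Monday
#' of August (a synthetic stand-in for a real holiday calendar; the August
#' one mirrors the English summer bank holiday).
#'
#' @param config a [sim_config()].
#' @return Date vector, all within the simulated range.
#' @export
make_holiday_calendar <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(config$years, function(y) {
    jul <- seq(as.Date(sprintf("%d-07-01", y)), by = "day", length.out = 31)
    aug <- seq(as.Date(sprintf("%d-08-01", y)), by = "day", length.out = 31)
    c(jul[weekday_of(jul) == 1L][2], rev(aug[weekday_of(aug) == 1L])[1])
  })
  as.Date(unlist(out), origin = "1970-01-01")
}

#' Generate the synthetic patient population
#'
#' Patients receive a uniform home location on the grid (km coordinates),
#' an age drawn to echo the age mix of asthma admissions (roughly 30%
#' children 5--15, 52% adults 16--64, 18% aged 65+), a sex, and the region
#' of their home cell. Ages are fixed over the study (no ageing).
#'
#' @param config a [sim_config()].
#' @param temp the temperature surface (for the grid extent and regions).
#' @return data.frame: patient_id, age, sex, x, y, region.
#' @export
make_patients <- function(config, temp) {
  stopifnot(inherits(config, "sim_config"), inherits(temp, "temp_surface"))
  set.seed(config$seed + 37L)
  np <- config$n_patients
  x <- runif(np, 0, config$grid_shape[2])
  y <- runif(np, 0, config$grid_shape[1])
  grp <- sample(c("5-15", "16-64", "65+"), np, replace = TRUE,
                prob = c(0.30, 0.52, 0.18))
  age <- integer(np)
  age[grp == "5-15"] <- sample(5:15, sum(grp == "5-15"), replace = TRUE)
  age[grp == "16-64"] <- sample(16:64, sum(grp == "16-64"), replace = TRUE)
  age[grp == "65+"] <- sample(65:90, sum(grp == "65+"), replace = TRUE)
  sex <- sample(c("male", "female"), np, replace = TRUE)
  cell <- assign_cell(x, y, temp)
  data.frame(patient_id = sprintf("P%05d", seq_len(np)), age = age,
             sex = sex, x = x, y = y,
             region = temp$cells$region[cell])
}
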