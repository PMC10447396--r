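#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the study calendar,
#' the exposure field, the patient population, the admission-generating
#' model (with a known log rate change per degree Celsius), and optional
#' subgroup effect modifiers. Defaults emulate an English summer study at
#' 1 km resolution with 11 km meteorological covariates and nine regions.
#'
#' @param seed integer root seed; every generator stage derives its own
#'   stream from it, so a fixed config is byte-reproducible.
#' @param years calendar years simulated (events occur June--August; the
#'   temperature surface starts on 26 May so lags up to 5 days exist for
#'   1 June events).
#' @param n_patients number of patients.
#' @param grid_shape `c(rows, cols)` of the fine (1 km) grid; both must be
#'   divisible by `coarse_factor`, and the grid must tile into `n_regions`
#'   rectangular blocks.
#' @param coarse_factor ratio of coarse (meteorology) to fine cell size
#'   (11 mirrors 11 km over 1 km).
#' @param n_regions number of rectangular regions (default 9).
#' @param beta_temp ground-truth log rate change per 1 degree C of the
#'   lag-averaged mean temperature. `log(1.02)` is a 2% risk increase.
#' @param gamma named coefficients for `rainfall` (per mm), `humidity`
#'   (per %), `wind` (per m/s) and `holiday` (indicator, 1 = holiday).
#' @param sigma_patient SD of the per-patient normal random effect
#'   (drawn once per patient, shared across their admissions).
#' @param baseline_log_rate intercept of the daily log admission rate;
#'   ignored when `target_events` is given.
#' @param target_events if non-NULL, the intercept is solved so the
#'   expected total number of admissions equals this count.
#' @param modifiers optional list of named multiplier vectors applied to
#'   `beta_temp` by subgroup: elements `age` (names `"5-15"`, `"16-64"`,
#'   `"65+"`), `sex` (`"male"`, `"female"`), `period`, `region`
#'   (region id as character) and `year` (calendar year as character).
#'   Multipliers compose multiplicatively.
#' @param response optional function of the lag-averaged temperature that
#'   replaces the linear term `beta_temp * x` in the log rate (used for
#'   non-linear, e.g. threshold, truths).
#' @param constant_field if non-NULL, every cell-day has
#'   Tmin = Tmax = this value (degenerate field for tests).
#' @param temp_mean,temp_sd mean and marginal day-to-day SD (degrees C) of
#'   the regional daily temperature anomaly process.
#' @param ar_phi AR(1) coefficient of the daily anomaly.
#' @param season_amp amplitude (degrees C) of the within-summer seasonal
#'   cycle (peaks mid-July).
#' @param spatial_amp amplitude (degrees C) of the smooth north-south /
#'   east-west spatial gradient across the grid.
#' @param cell_noise_sd SD of independent cell-day temperature noise.
#' @param diurnal_half_range mean half-range (Tmax - Tmean) in degrees C.
#' @param year_effect_sd SD of the per-year temperature offset.
#' @param cov_temp_cor named target correlations of daily `rainfall`,
#'   `humidity` and `wind` with the coarse-cell mean temperature.
#' @param weekday_effects length-7 additive log-rate effects, Monday first.
#' @param month_effects named additive log-rate effects for months 6, 7, 8.
#' @param admission_year_sd SD of per-year additive log-rate effects.
#' @param season_admission_amp amplitude of a within-summer sinusoidal
#'   admission baseline (the field evidence on its size is thin, so it is
#'   a parameter, default 0).
#' @param lag_set integer lags (days before admission, 0 = same day) whose
#'   mean temperature drives the simulated rate; default `0:3`.
#' @param period_breaks optional list of contiguous year vectors defining
#'   periods; default splits `years` into three near-equal spans.
#' @param rate_cap_log generation guard: an error is raised if any daily
#'   log rate exceeds this cap.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, years = 2003, grid_shape = c(11, 11),
#'                   coarse_factor = 11, n_regions = 1, n_patients = 50,
#'                   target_events = 100)
sim_config <- function(seed = 1L,
                       years = 2002:2007,
                       n_patients = 2000L,
                       grid_shape = c(33L, 33L),
                       coarse_factor = 11L,
                       n_regions = 9L,
                       beta_temp = log(1.02),
                       gamma = c(rainfall = -0.004, humidity = 0.002,
                                 wind = -0.01, holiday = -0.15),
                       sigma_patient = 0.3,
                       baseline_log_rate = -7,
                       target_events = 5000,
                       modifiers = list(),
                       response = NULL,
                       constant_field = NULL,
                       temp_mean = 15.5,
                       temp_sd = 3.5,
                       ar_phi = 0.55,
                       season_amp = 2,
                       spatial_amp = 2,
                       cell_noise_sd = 0.6,
                       diurnal_half_range = 4,
                       year_effect_sd = 0.6,
                       cov_temp_cor = c(rainfall = -0.3, humidity = -0.5,
                                        wind = -0.15),
                       weekday_effects = c(0.05, 0.02, 0, 0, 0.02, -0.08, -0.10),
                       month_effects = c("6" = 0, "7" = -0.05, "8" = -0.02),
                       admission_year_sd = 0.15,
                       season_admission_amp = 0,
                       lag_set = 0:3,
                       period_breaks = NULL,
                       rate_cap_log = 0) {
  grid_shape <- as.integer(grid_shape)
  years <- sort(as.integer(years))
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("configuration error: grid_shape must be two positive integers")
  if (n_regions < 1L)
    stop("configuration error: n_regions must be >= 1")
  if (any(grid_shape %% coarse_factor != 0L))
    stop("configuration error: grid_shape must be divisible by coarse_factor")
  tiling <- region_tiling(grid_shape, n_regions)  # errors if impossible
  if (sigma_patient < 0) stop("configuration error: sigma_patient must be >= 0")
  need <- c("rainfall", "humidity", "wind", "holiday")
  if (!all(need %in% names(gamma)))
    stop("configuration error: gamma must name ", paste(need, collapse = ", "))
  if (!all(lag_set == as.integer(lag_set)) || any(lag_set < 0))
    stop("configuration error: lag_set must be non-negative integers")
  if (is.null(period_breaks)) period_breaks <- default_periods(years)
  cfg <- list(seed = as.integer(seed), years = years,
              n_patients = as.integer(n_patients), grid_shape = grid_shape,
              coarse_factor = as.integer(coarse_factor),
              n_regions = as.integer(n_regions), region_tiling = tiling,
              beta_temp = beta_temp, gamma = gamma[need],
              sigma_patient = sigma_patient,
              baseline_log_rate = baseline_log_rate,
              target_events = target_events, modifiers = modifiers,
              response = response, constant_field = constant_field,
              temp_mean = temp_mean, temp_sd = temp_sd, ar_phi = ar_phi,
              season_amp = season_amp, spatial_amp = spatial_amp,
              cell_noise_sd = cell_noise_sd,
              diurnal_half_range = diurnal_half_range,
              year_effect_sd = year_effect_sd, cov_temp_cor = cov_temp_cor,
              weekday_effects = weekday_effects, month_effects = month_effects,
              admission_year_sd = admission_year_sd,
              season_admission_amp = season_admission_amp,
              lag_set = as.integer(sort(unique(lag_set))),
              period_breaks = period_breaks, rate_cap_log = rate_cap_log)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  years:", paste(range(x$years), collapse = "-"),
      sprintf("(%d)", length(x$years)), "\n")
  cat("  grid:", x$grid_shape[1], "x", x$grid_shape[2],
      "fine cells; coarse factor", x$coarse_factor,
      ";", x$n_regions, "regions\n")
  cat("  patients:", x$n_patients,
      if (!is.null(x$target_events)) paste("; target events", x$target_events)
      else paste("; baseline log rate", signif(x$baseline_log_rate, 3)), "\n")
  cat(sprintf("  beta_temp: %.5f (%.2f%% per degree C)\n", x$beta_temp,
              100 * (exp(x$beta_temp) - 1)))
  invisible(x)
}

# Find a rows x cols block tiling of the grid into n_regions rectangles,
# preferring the most nearly square factorisation of n_regions.
region_tiling <- function(grid_shape, n_regions) {
  cand <- NULL
  for (a in seq_len(n_regions)) {
    if (n_regions %% a != 0L) next
    b <- n_regions %/% a
    if (grid_shape[1] %% a == 0L && grid_shape[2] %% b == 0L) {
      if (is.null(cand) || abs(a - b) < abs(cand[1] - cand[2])) cand <- c(a, b)
    }
  }
  if (is.null(cand))
    stop("configuration error: grid_shape ", grid_shape[1], "x", grid_shape[2],
         " cannot be tiled into ", n_regions, " rectangular regions")
  c(row_blocks = cand[1], col_blocks = cand[2])
}

# Split the study years into three near-equal contiguous periods (fewer if
# fewer than three years), labelled "first-last".
default_periods <- function(years) {
  k <- min(3L, length(years))
  idx <- sort(rep_len(seq_len(k), length(years)))
  sp <- split(years, idx)
  names(sp) <- vapply(sp, function(y)
    if (length(y) > 1) paste0(min(y), "-", max(y)) else as.character(y), "")
  sp
}

#' Assign study period labels to calendar years
#'
#' @param year integer vector of calendar years.
#' @param period_breaks list of year vectors as stored in a
#'   [sim_config()] (`$period_breaks`).
#' @return character vector of period labels (NA for years outside all
#'   periods).
#' @export
period_of <- function(year, period_breaks) {
  lab <- rep(NA_character_, length(year))
  for (p in names(period_breaks)) lab[year %in% period_breaks[[p]]] <- p
  lab
}

#' Assign age groups used throughout the analysis
#'
#' Children 5--15, working-age adults 16--64, older adults 65+ (integer
#' years, inclusive bounds).
#'
#' @param age integer ages in years.
#' @return factor with levels `"5-15"`, `"16-64"`, `"65+"` (NA below 5 or
#'   missing).
#' @export
age_group_of <- function(age) {
  g <- rep(NA_character_, length(age))
  g[!is.na(age) & age >= 5 & age <= 15] <- "5-15"
  g[!is.na(age) & age >= 16 & age <= 64] <- "16-64"
  g[!is.na(age) & age >= 65] <- "65+"
  factor(g, levels = c("5-15", "16-64", "65+"))
}
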