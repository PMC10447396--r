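# Small study configurations shared across tests. Sizes are chosen so a
# single dataset simulates and fits in well under a second.

if (requireNamespace("survival", quietly = TRUE))
  suppressPackageStartupMessages(library(survival))

tiny_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, years = 2003, grid_shape = c(11, 11),
         coarse_factor = 11, n_regions = 1, n_patients = 300,
         target_events = 200),
    list(...))
  do.call(sim_config, args)
}

small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, years = 2002:2004, grid_shape = c(22, 22),
         coarse_factor = 11, n_regions = 4, n_patients = 2000,
         target_events = 5000),
    list(...))
  do.call(sim_config, args)
}

# full generator chain up to admission records
sim_world <- function(cfg) {
  temp <- make_temperature_surface(cfg)
  cov <- make_covariate_surfaces(cfg, temp)
  holidays <- make_holiday_calendar(cfg)
  patients <- make_patients(cfg, temp)
  records <- simulate_admissions(cfg, temp, cov, holidays, patients)
  list(cfg = cfg, temp = temp, cov = cov, holidays = holidays,
       patients = patients, records = records)
}

# chain through cleaning and linkage
sim_linked <- function(cfg, fuzz_radius = 0.1) {
  w <- sim_world(cfg)
  w$clean <- apply_exclusions(w$records)
  w$linked <- link_records(w$clean$records, w$temp, w$cov, w$holidays,
                           fuzz_radius = fuzz_radius, seed = cfg$seed)
  w
}

# chain through strata to a fitted model
sim_fit <- function(cfg, spec = adjusted_spec(), fuzz_radius = 0.1) {
  w <- sim_linked(cfg, fuzz_radius = fuzz_radius)
  w$strata <- build_strata(w$linked, w$temp, w$cov, w$holidays)
  w$fit <- fit_model(build_design_matrix(w$strata, spec))
  w
}

# brute-force referent oracle: scan every day of the event's month
brute_referents <- function(d) {
  d <- as.Date(d)
  first <- as.Date(format(d, "%Y-%m-01"))
  days <- first + 0:30
  days <- days[format(days, "%m") == format(d, "%m")]
  wd <- function(x) format(x, "%u")
  days[wd(days) == wd(d) & days != d]
}
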