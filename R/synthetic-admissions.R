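#' Simulate asthma admission records
#'
#' For every patient-day in June--August an admission count is drawn from
#' a Poisson law whose log rate is
#' `intercept + weekday + month + year + f(x_lag) + gamma' (rainfall,
#' humidity, wind, holiday) + b_patient`, where `x_lag` is the
#' lag-averaged daily-mean temperature at the patient's home cell,
#' `f(x) = beta_temp * x` by default (optionally modified per subgroup or
#' replaced by a custom response function), and `b_patient` is a normal
#' random effect drawn once per patient. Each unit of the count becomes
#' one admission record, so recurrent (even same-day) admissions occur
#' naturally. The ground-truth parameters are attached as the `truth`
#' attribute of the returned records.
#'
#' @param config a [sim_config()].
#' @param temp,cov,holidays,patients the other generator outputs.
#' @return data.frame of admission records (record_id, patient_id, date,
#'   age, sex, x, y, icd10, defect = NA) with attributes `truth` (list of
#'   generative parameters) and `extent`.
#' @export
simulate_admissions <- function(config, temp, cov, holidays, patients) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 53L)
  sdates <- summer_dates(temp$dates)
  nd <- length(sdates); np <- nrow(patients)
  xlf <- lagged_mean_field(temp, config$lag_set, sdates)

  wde <- config$weekday_effects[weekday_of(sdates)]
  moe <- config$month_effects[as.character(month_of(sdates))]
  yrs <- year_of(sdates)
  uy <- sort(unique(yrs))
  ye <- setNames(rnorm(length(uy), 0, config$admission_year_sd), uy)
  doy <- as.POSIXlt(sdates)$yday + 1L
  seas <- config$season_admission_amp * sin(2 * pi * (doy - 152) / 92)
  hol <- as.integer(sdates %in% holidays)
  day_part <- wde + moe + ye[as.character(yrs)] + seas +
    config$gamma[["holiday"]] * hol

  pcell <- assign_cell(patients$x, patients$y, temp)
  ccell <- fine_to_coarse_index(temp$cells$row[pcell], temp$cells$col[pcell],
                                cov$coarse_factor, cov$grid$cols)
  b <- rnorm(np, 0, config$sigma_patient)
  cdi <- match(sdates, cov$dates)
  covpart <- config$gamma[["rainfall"]] * cov$rainfall[ccell, cdi, drop = FALSE] +
    config$gamma[["humidity"]] * cov$humidity[ccell, cdi, drop = FALSE] +
    config$gamma[["wind"]] * cov$wind[ccell, cdi, drop = FALSE]

  X <- xlf[pcell, , drop = FALSE]
  if (!is.null(config$response)) {
    temppart <- config$response(X)
  } else {
    bm <- beta_matrix(config, patients, uy)        # patients x years
    temppart <- bm[, match(yrs, uy), drop = FALSE] * X
  }
  eta0 <- temppart + covpart +
    matrix(day_part, np, nd, byrow = TRUE) + b

  if (!is.null(config$target_events)) {
    m <- max(eta0)
    intercept <- log(config$target_events) - (m + log(sum(exp(eta0 - m))))
  } else intercept <- config$baseline_log_rate
  eta <- eta0 + intercept
  if (max(eta) > config$rate_cap_log)
    stop("generation error: daily log rate ", signif(max(eta), 4),
         " exceeds the cap ", config$rate_cap_log,
         "; check baseline_log_rate/target_events and beta_temp")

  counts <- matrix(rpois(length(eta), exp(eta)), np, nd)
  hit <- which(counts > 0, arr.ind = TRUE)
  pi <- rep(hit[, 1], counts[hit])
  di <- rep(hit[, 2], counts[hit])
  o <- order(di, pi)
  pi <- pi[o]; di <- di[o]
  rec <- data.frame(record_id = sprintf("R%07d", seq_along(pi)),
                    patient_id = patients$patient_id[pi],
                    date = sdates[di],
                    age = patients$age[pi],
                    sex = patients$sex[pi],
                    x = patients$x[pi],
                    y = patients$y[pi],
                    icd10 = sample(c("J45", "J46"), length(pi),
                                   replace = TRUE, prob = c(0.9, 0.1)),
                    defect = NA_character_)
  attr(rec, "extent") <- temp$grid$extent
  attr(rec, "truth") <- list(beta_temp = config$beta_temp,
                             pct_change = 100 * (exp(config$beta_temp) - 1),
                             gamma = config$gamma,
                             sigma_patient = config$sigma_patient,
                             intercept = intercept,
                             weekday_effects = config$weekday_effects,
                             month_effects = config$month_effects,
                             year_effects = ye,
                             patient_effects = setNames(b, patients$patient_id),
                             modifiers = config$modifiers,
                             lag_set = config$lag_set)
  rec
}

# per-(patient, year) multiplier-adjusted temperature coefficient
beta_matrix <- function(config, patients, years) {
  np <- nrow(patients)
  m <- matrix(config$beta_temp, np, length(years),
              dimnames = list(NULL, years))
  mods <- config$modifiers
  pick <- function(tab, key) {
    out <- rep(1, length(key))
    hit <- !is.na(key) & key %in% names(tab)
    out[hit] <- tab[key[hit]]
    out
  }
  if (!is.null(mods$age))
    m <- m * pick(mods$age, as.character(age_group_of(patients$age)))
  if (!is.null(mods$sex)) m <- m * pick(mods$sex, patients$sex)
  if (!is.null(mods$region)) m <- m * pick(mods$region, as.character(patients$region))
  per <- period_of(years, config$period_breaks)
  ymult <- rep(1, length(years))
  if (!is.null(mods$period)) ymult <- ymult * pick(mods$period, per)
  if (!is.null(mods$year)) ymult <- ymult * pick(mods$year, as.character(years))
  sweep(m, 2, ymult, `*`)
}

#' Inject known defects to exercise the exclusion cascade
#'
#' Appends exactly the requested numbers of defective records to a clean
#' record set: byte-identical duplicates (same record id as their source,
#' as duplicated hospital records share content), out-of-extent
#' residences, non-summer admission dates, under-5 ages, and missing
#' sex/age. Each injected record carries its defect type in the `defect`
#' column so tests can reconcile the cascade's tallies.
#'
#' @param records clean admission records.
#' @param counts named integer vector with any of `duplicates`,
#'   `out_of_extent`, `non_summer`, `under_5`, `missing`.
#' @param seed RNG seed for sampling which records to clone.
#' @return records with the injected rows appended (attributes preserved).
#' @export
inject_cascade_noise <- function(records,
                                 counts = c(duplicates = 5, out_of_extent = 2,
                                            non_summer = 10, under_5 = 3,
                                            missing = 1),
                                 seed = 1L) {
  set.seed(seed)
  full <- c(duplicates = 0L, out_of_extent = 0L, non_summer = 0L,
            under_5 = 0L, missing = 0L)
  full[names(counts)] <- as.integer(counts)
  counts <- full
  if (sum(counts) == 0L) return(records)
  extent <- attr(records, "extent")
  truth <- attr(records, "truth")
  clone <- function(n) records[sample.int(nrow(records), n, replace = TRUE), ,
                               drop = FALSE]
  extra <- list()
  nid <- 0L
  new_id <- function(n) {
    ids <- sprintf("RX%05d", nid + seq_len(n)); nid <<- nid + n; ids
  }
  if (counts["duplicates"] > 0) {
    d <- records[sample.int(nrow(records), counts["duplicates"]), , drop = FALSE]
    d$defect <- "duplicate"                      # id and content kept verbatim
    extra <- c(extra, list(d))
  }
  if (counts["out_of_extent"] > 0) {
    d <- clone(counts["out_of_extent"])
    d$record_id <- new_id(nrow(d))
    d$x <- extent[1] + runif(nrow(d), 1, 10)
    d$defect <- "out_of_extent"
    extra <- c(extra, list(d))
  }
  if (counts["non_summer"] > 0) {
    d <- clone(counts["non_summer"])
    d$record_id <- new_id(nrow(d))
    yr <- year_of(d$date)
    d$date <- as.Date(ifelse(runif(nrow(d)) < 0.5,
                             sprintf("%d-05-10", yr), sprintf("%d-09-15", yr)))
    d$defect <- "non_summer"
    extra <- c(extra, list(d))
  }
  if (counts["under_5"] > 0) {
    d <- clone(counts["under_5"])
    d$record_id <- new_id(nrow(d))
    d$age <- sample(0:4, nrow(d), replace = TRUE)
    d$defect <- "under_age"
    extra <- c(extra, list(d))
  }
  if (counts["missing"] > 0) {
    d <- clone(counts["missing"])
    d$record_id <- new_id(nrow(d))
    miss_sex <- runif(nrow(d)) < 0.5
    d$sex[miss_sex] <- NA_character_
    d$age[!miss_sex] <- NA_integer_
    d$defect <- "missing_field"
    extra <- c(extra, list(d))
  }
  out <- do.call(rbind, c(list(records), extra))
  rownames(out) <- NULL
  attr(out, "extent") <- extent
  attr(out, "truth") <- truth
  out
}
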