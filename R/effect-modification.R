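#' Subgroup (effect-modification) analyses
#'
#' Re-runs the full pipeline -- strata, design matrix, fit -- independently
#' within each level of a partition of the cohort (age group, sex, study
#' period, region, or any combination), sharing no information across
#' subgroups. Subgroups with fewer events than `min_events` are skipped
#' with a warning rather than crashing the analysis.
#'
#' @param linked `linked_records`.
#' @param partition character vector of linked-record columns defining
#'   the subgrouping (e.g. `c("sex", "age_group")`); their interaction
#'   must be a total function on retained records.
#' @param spec a [model_spec()].
#' @param temp,cov,holidays the surfaces and holiday calendar.
#' @param min_events minimum events per subgroup (default 50).
#' @return object of class `subgroup_results`: list of per-subgroup
#'   entries (label, n_events, fit) plus the partition definition.
#' @export
subgroup_fit <- function(linked, partition, spec, temp, cov, holidays,
                         min_events = 50L) {
  stopifnot(all(partition %in% names(linked)))
  lab <- interaction(lapply(partition, function(v) linked[[v]]),
                     sep = " / ", drop = TRUE)
  if (anyNA(lab))
    stop("partition is not a total function on the retained records")
  res <- list()
  for (lv in levels(lab)) {
    sub <- linked[lab == lv, , drop = FALSE]
    if (nrow(sub) < min_events) {
      warning("subgroup '", lv, "' skipped: only ", nrow(sub), " events")
      next
    }
    strata <- build_strata(sub, temp, cov, holidays,
                           lag_set = attr(linked, "lag_set"))
    fit <- fit_model(build_design_matrix(strata, spec))
    res[[lv]] <- list(label = lv, n_events = nrow(sub), fit = fit)
  }
  structure(list(results = res, partition = partition,
                 n_total = nrow(linked)), class = "subgroup_results")
}

#' @export
as.data.frame.subgroup_results <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    pc <- r$fit$percent_change
    data.frame(subgroup = r$label, n_events = r$n_events,
               pct_change = pc$median, lower = pc$lower, upper = pc$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.subgroup_results <- function(x, ...) {
  cat("<subgroup_results> partition:", paste(x$partition, collapse = " x "),
      "\n")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Posterior-draw yearly trend of the temperature effect
#'
#' Fits the model separately for each calendar year (optionally within a
#' grouping variable such as age group), draws `n_draws` values from each
#' year's posterior of the percent change per 1 degree C, and for each
#' draw index fits an ordinary least-squares line of effect on calendar
#' year. The `n_draws` slopes form the posterior of the linear temporal
#' trend (percent-change units per year), summarised by the median and
#' 95% credible interval. Years with fewer events than `min_events` are
#' omitted from the regression (with a warning).
#'
#' @param linked `linked_records` spanning at least three distinct years.
#' @param spec a [model_spec()].
#' @param temp,cov,holidays the surfaces and holiday calendar.
#' @param n_draws posterior draws per year (default 1000).
#' @param seed RNG seed for the draws.
#' @param by optional column name (e.g. `"age_group"`) to run the
#'   procedure within each level; NULL pools all events.
#' @param min_events minimum events per year (default 100).
#' @param weighted if TRUE, weight the per-draw regression by the inverse
#'   posterior variance of each year's effect (off by default; the plain
#'   procedure fits unweighted lines).
#' @return object of class `trend_result`: per group a list with
#'   `yearly` (year, n_events, median, lower, upper), `slopes` (n_draws
#'   values), `slope_median`, `slope_lower`, `slope_upper`.
#' @export
yearly_trend <- function(linked, spec, temp, cov, holidays,
                         n_draws = 1000L, seed = 1L, by = NULL,
                         min_events = 100L, weighted = FALSE) {
  years <- sort(unique(linked$year))
  if (length(years) < 3L)
    stop("yearly trend requires at least 3 distinct years")
  groups <- if (is.null(by)) list(all = rep(TRUE, nrow(linked)))
  else {
    lv <- unique(as.character(linked[[by]]))
    setNames(lapply(lv, function(l) as.character(linked[[by]]) == l), lv)
  }
  set.seed(seed)
  out <- list()
  for (gname in names(groups)) {
    gl <- linked[groups[[gname]], , drop = FALSE]
    est <- se <- nev <- rep(NA_real_, length(years))
    for (i in seq_along(years)) {
      sub <- gl[gl$year == years[i], , drop = FALSE]
      nev[i] <- nrow(sub)
      if (nrow(sub) < min_events) {
        warning("year ", years[i], " omitted for group '", gname,
                "': only ", nrow(sub), " events")
        next
      }
      strata <- build_strata(sub, temp, cov, holidays,
                             lag_set = attr(linked, "lag_set"))
      fit <- fit_model(build_design_matrix(strata, spec))
      j <- match("temp", fit$coefficients$term)
      est[i] <- fit$coefficients$estimate[j]
      se[i] <- fit$coefficients$se[j]
    }
    ok <- !is.na(est)
    if (sum(ok) < 3L)
      stop("fewer than 3 usable years for group '", gname, "'")
    # n_draws x n_years matrix of percent-change draws
    pct <- sapply(which(ok), function(i)
      percent_change(rnorm(n_draws, est[i], se[i])))
    if (n_draws == 1L) pct <- matrix(pct, nrow = 1L)
    yr <- years[ok]
    w <- if (weighted) 1 / (se[ok]^2 * (100 * exp(est[ok]))^2) else rep(1, sum(ok))
    xb <- sum(w * yr) / sum(w)
    xc <- yr - xb
    slopes <- drop(pct %*% (w * xc)) / sum(w * xc^2)
    yearly <- data.frame(year = years, n_events = nev,
                         median = percent_change(est),
                         lower = percent_change(est - qnorm(0.975) * se),
                         upper = percent_change(est + qnorm(0.975) * se))
    out[[gname]] <- list(yearly = yearly, slopes = slopes,
                         slope_median = median(slopes),
                         slope_lower = unname(quantile(slopes, 0.025)),
                         slope_upper = unname(quantile(slopes, 0.975)))
  }
  structure(list(groups = out, n_draws = n_draws, by = by, seed = seed),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("<trend_result>", x$n_draws, "posterior draws per year\n")
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    cat(sprintf("  %s: slope %.3f (95%% CrI %.3f to %.3f) %%/year over %d years\n",
                g, r$slope_median, r$slope_lower, r$slope_upper,
                sum(!is.na(r$yearly$median))))
  }
  invisible(x)
}
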