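# hand-built design for closed-form checks: strata of size k with printed
# exposures
toy_design <- function(x_by_stratum, case_index) {
  n <- lengths(x_by_stratum)
  strata <- data.frame(
    stratum = rep(seq_along(x_by_stratum), n),
    record_id = rep(sprintf("R%d", seq_along(x_by_stratum)), n),
    patient_id = rep(sprintf("P%d", seq_along(x_by_stratum)), n),
    date = as.Date("2003-07-01") + sequence(n),
    case = unlist(lapply(seq_along(n), function(i)
      as.integer(seq_len(n[i]) == case_index[i]))),
    x_lag = unlist(x_by_stratum),
    rainfall = 0, humidity = 0, wind = 0, holiday = 0)
  class(strata) <- c("cco_strata", "data.frame")
  build_design_matrix(strata, unadjusted_spec())
}

test_that("conditional log-likelihood has its closed forms", {
  d <- toy_design(list(c(10, 12, 14, 16), c(9, 11, 13)), c(2, 1))
  # beta = 0: each stratum contributes -log(k)
  expect_equal(conditional_loglik(0, d), -log(4) - log(3))
  # brute-force multinomial denominator at beta = 0.3
  beta <- 0.3
  manual <- (12 * beta - log(sum(exp(c(10, 12, 14, 16) * beta)))) +
    (9 * beta - log(sum(exp(c(9, 11, 13) * beta))))
  expect_equal(conditional_loglik(beta, d), manual)
  # derivatives agree with numerical differentiation
  ll <- conditional_loglik(beta, d, derivatives = TRUE)
  eps <- 1e-6
  num_g <- (conditional_loglik(beta + eps, d) -
              conditional_loglik(beta - eps, d)) / (2 * eps)
  expect_equal(unname(attr(ll, "gradient")), num_g, tolerance = 1e-5)
})

test_that("within-stratum constants leave the likelihood unchanged", {
  d <- toy_design(list(c(10, 12, 14, 16), c(9, 11, 13)), c(2, 1))
  d_shift <- d
  shift <- c(100, -40)[d$stratum]
  d_shift$X <- d$X + shift
  for (b in c(-0.5, 0, 0.2, 1))
    expect_equal(conditional_loglik(b, d_shift), conditional_loglik(b, d))
})

test_that("zero or duplicated case rows raise a data error", {
  d <- toy_design(list(c(10, 12, 14, 16)), 2)
  d$y[1] <- 1L
  expect_error(conditional_loglik(0, d), "data error")
})

test_that("flat-prior Laplace mode equals the conditional-logistic MLE", {
  skip_if_not_installed("survival")
  for (seed in c(31, 32)) {
    w <- sim_linked(tiny_cfg(seed = seed))
    st <- build_strata(w$linked, w$temp, w$cov, w$holidays)
    f <- fit_model(build_design_matrix(st, adjusted_spec(prior_sd_beta = Inf)))
    cl <- survival::clogit(
      case ~ x_lag + rainfall + humidity + wind + holiday + survival::strata(stratum),
      data = st)
    expect_lt(max(abs(unname(f$mode) - unname(coef(cl)))), 1e-6)
  }
})

test_that("percent change is the exact monotone transform", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(percent_change(c(-0.01, 0, 0.01)),
               c(100 * (exp(-0.01) - 1), 0, 100 * (exp(0.01) - 1)))
  # CrI of % change equals transformed CrI of beta
  w <- sim_fit(tiny_cfg(seed = 33))
  i <- match("temp", w$fit$coefficients$term)
  expect_equal(w$fit$percent_change$lower,
               percent_change(w$fit$coefficients$lower[i]))
  expect_equal(w$fit$percent_change$upper,
               percent_change(w$fit$coefficients$upper[i]))
  expect_true(w$fit$percent_change$lower <= w$fit$percent_change$median)
  expect_true(w$fit$percent_change$median <= w$fit$percent_change$upper)
})

test_that("a stratum-constant covariate cannot move the exposure estimate", {
  w <- sim_fit(tiny_cfg(seed = 34))
  st <- w$strata
  d <- build_design_matrix(st, adjusted_spec())
  # splice in an arbitrary patient-level 'deprivation' column
  dep <- setNames(rnorm(length(unique(st$patient_id)), 0, 3),
                  unique(st$patient_id))
  d2 <- d
  d2$X <- cbind(d$X, deprivation = dep[st$patient_id])
  d2$terms <- colnames(d2$X)
  f1 <- fit_model(d, adjusted_spec())
  f2 <- fit_model(d2, adjusted_spec())
  expect_lt(abs(f1$percent_change$median - f2$percent_change$median), 1e-6)
})

test_that("patient random effects cancel from the conditional likelihood", {
  w <- sim_linked(tiny_cfg(seed = 35))
  st <- build_strata(w$linked, w$temp, w$cov, w$holidays)
  f_off <- fit_model(build_design_matrix(st, adjusted_spec()))
  f_on <- fit_model(build_design_matrix(st,
    adjusted_spec(patient_effect = TRUE)))
  expect_equal(f_on$percent_change$median, f_off$percent_change$median)
  expect_false(is.null(f_on$diagnostics$patient_effect))
  expect_gte(f_on$diagnostics$patient_effect$n_terms, 0)
})

test_that("the MCMC backend agrees with the Laplace approximation", {
  w <- sim_linked(tiny_cfg(seed = 36))
  st <- build_strata(w$linked, w$temp, w$cov, w$holidays)
  f_lap <- fit_model(build_design_matrix(st, unadjusted_spec()))
  f_mc <- fit_model(build_design_matrix(st, unadjusted_spec(
    backend = "mcmc",
    mcmc = list(chains = 4, draws = 1500, warmup = 500, seed = 2))))
  expect_true(all(f_mc$diagnostics$rhat < 1.1))
  expect_gt(min(f_mc$diagnostics$ess), 50)
  expect_lt(abs(f_mc$percent_change$median - f_lap$percent_change$median), 0.4)
  # CrI endpoints on the same scale and ordered
  expect_lt(f_mc$percent_change$lower, f_mc$percent_change$median)
  expect_gt(f_mc$percent_change$upper, f_mc$percent_change$median)
})
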