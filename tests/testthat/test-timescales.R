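test_that("spike-count autocorrelation matches its estimator contract", {
  # white noise counts: all lags near zero
  set.seed(1)
  counts <- matrix(rpois(200 * 20, 5), 200, 20)
  acf <- acf_from_counts(counts)
  expect_true(all(abs(acf$r) < 3 / sqrt(200)))
  expect_equal(acf$n_pairs, 20 - acf$lag_ms / 50)

  # counts identical across bins within trial, varying across trials
  v <- rpois(100, 10)
  acf2 <- acf_from_counts(matrix(v, 100, 20))
  expect_true(all(abs(acf2$r - 1) < 1e-12))

  # OU-modulated Poisson: ratio r(50)/r(250) ~ exp(200/200) within 25%
  sp <- simulate_fixation_trials(1000, tau_ms = 200, seed = 42)
  counts3 <- t(vapply(sp, function(s) tabulate(floor(s / 50) + 1, 20),
                      integer(20)))
  acf3 <- acf_from_counts(counts3)
  expect_lt(abs(acf3$r[1] / acf3$r[5] - exp(1)), 0.25 * exp(1))
})

test_that("noise-free curves invert exactly and match the brute force", {
  lags <- seq(50, 950, by = 50)

  r1 <- 0.5 * exp(-lags / 200)
  acf1 <- tibble::tibble(lag_ms = lags, r = r1)
  class(acf1) <- c("wm_acf", class(acf1))
  f1 <- fit_tau(acf1)
  expect_equal(f1$tau_ms, 200, tolerance = 1e-3)
  expect_equal(f1$A, 0.5, tolerance = 1e-3)
  expect_equal(f1$B, 0, tolerance = 1e-3)

  r2 <- 0.4 * (exp(-lags / 120) + 0.2)
  acf2 <- tibble::tibble(lag_ms = lags, r = r2)
  class(acf2) <- c("wm_acf", class(acf2))
  f2 <- fit_tau(acf2)
  expect_equal(f2$tau_ms, 120, tolerance = 1e-3)
  expect_equal(f2$A, 0.4, tolerance = 1e-3)
  expect_equal(f2$B, 0.2, tolerance = 1e-3)

  # noisy curve: agreement with the independent brute-force fit
  set.seed(7)
  r3 <- 0.3 * (exp(-lags / 150) + 0.1) + rnorm(19, 0, 0.01)
  acf3 <- tibble::tibble(lag_ms = lags, r = r3)
  class(acf3) <- c("wm_acf", class(acf3))
  f3 <- fit_tau(acf3)
  start <- f3$fit_start_lag_ms
  bf <- brute_force_tau(lags[lags >= start], r3[lags >= start])
  expect_equal(f3$tau_ms, bf$tau, tolerance = 1e-3)
  expect_equal(f3$A, bf$A, tolerance = 1e-3)

  # scaling r and A jointly leaves tau untouched
  acf4 <- acf1
  acf4$r <- acf1$r * 0.5
  f4 <- fit_tau(acf4)
  expect_equal(f4$tau_ms, f1$tau_ms, tolerance = 1e-6)
  expect_equal(f4$A, f1$A * 0.5, tolerance = 1e-6)
})

test_that("fit start skips a depressed first lag", {
  lags <- seq(50, 950, by = 50)
  r <- 0.5 * exp(-lags / 150)
  r[1] <- r[2] * 0.5                 # refractory dip at the first lag
  acf <- tibble::tibble(lag_ms = lags, r = r)
  class(acf) <- c("wm_acf", class(acf))
  f <- fit_tau(acf)
  expect_equal(f$fit_start_lag_ms, 100)  # starts at the peak, skips the dip
  expect_equal(f$tau_ms, 150, tolerance = 1e-3)
})

test_that("exclusion rules fire in the stated order", {
  lags <- seq(50, 950, by = 50)
  mk_acf <- function(r, rate = 5) {
    a <- tibble::tibble(lag_ms = lags, r = r)
    class(a) <- c("wm_acf", class(a))
    attr(a, "rate_hz") <- rate
    a
  }
  decaying <- mk_acf(0.5 * exp(-lags / 200))
  fit <- fit_tau(decaying)

  # rule 1 wins over anything downstream
  out1 <- apply_exclusions(fit, mk_acf(0.5 * exp(-lags / 200), rate = 0.5))
  expect_equal(out1$status, "excluded_low_rate")

  # rule 2: monotonically increasing over the first 250 ms
  rising <- mk_acf(c(seq(0.1, 0.3, length.out = 5), rep(0.3, 14)))
  out2 <- apply_exclusions(fit_tau(rising), rising)
  expect_equal(out2$status, "excluded_no_decline")

  # rule 3: extreme parameters
  f3 <- fit
  f3$tau_ms <- 1500
  expect_equal(apply_exclusions(f3, decaying)$status,
               "excluded_extreme_params")
  f4 <- fit
  f4$A <- 1.3
  expect_equal(apply_exclusions(f4, decaying)$status,
               "excluded_extreme_params")

  # a 0.5 Hz neuron with extreme parameters reports the low-rate exclusion
  out5 <- apply_exclusions(f3, mk_acf(0.5 * exp(-lags / 200), rate = 0.5))
  expect_equal(out5$status, "excluded_low_rate")

  # optional automated poor-fit flag replaces visual inspection
  noisy <- mk_acf(c(0.3, 0.1, rep(0, 17)) + sin(seq_len(19)) * 0.2)
  ffit <- fit_tau(noisy)
  if (ffit$status == "fitted" && is.finite(ffit$r_squared) &&
      ffit$r_squared < 0.2 && ffit$A >= 0 && ffit$A <= 1.2 &&
      ffit$tau_ms >= 10 && ffit$tau_ms <= 1000) {
    expect_equal(apply_exclusions(ffit, noisy, r2_threshold = 0.2)$status,
                 "flagged_poor_fit")
  }
  expect_equal(apply_exclusions(fit, decaying)$status, "fitted")
})

test_that("population fit pools per-neuron points coherently", {
  lags <- seq(50, 950, by = 50)
  mk <- function(r) {
    a <- tibble::tibble(lag_ms = lags, r = r)
    class(a) <- c("wm_acf", class(a))
    a
  }
  curve <- mk(0.5 * exp(-lags / 200))

  # identical neurons -> population tau equals the single-neuron tau
  pop <- fit_population_tau(list(curve, curve, curve))
  expect_equal(pop$tau_ms, 200, tolerance = 1e-3)

  # single-neuron input degenerates to fit_tau
  one <- fit_population_tau(list(curve))
  ft <- fit_tau(curve)
  expect_equal(one$tau_ms, ft$tau_ms, tolerance = 1e-9)

  # pooled mix of tau 50 and tau 500 sits strictly between
  mix <- fit_population_tau(c(replicate(5, mk(0.5 * exp(-lags / 50)),
                                        simplify = FALSE),
                              replicate(5, mk(0.5 * exp(-lags / 500)),
                                        simplify = FALSE)))
  expect_gt(mix$tau_ms, 50)
  expect_lt(mix$tau_ms, 500)
})

test_that("median split by tau follows the stated tie rules", {
  mk_fits <- function(taus, status = "fitted") {
    tibble::tibble(neuron_id = seq_along(taus), tau_ms = taus,
                   status = status)
  }
  sp <- median_split_by_tau(mk_fits(c(50, 100, 200, 400)))
  expect_setequal(sp$low_tau, 1:2)
  expect_setequal(sp$high_tau, 3:4)

  sp2 <- median_split_by_tau(mk_fits(c(50, 100, 200)))
  expect_setequal(sp2$low_tau, 1:2)     # median element goes low
  expect_setequal(sp2$high_tau, 3)

  f <- mk_fits(c(50, 100, 200, 400))
  f$status[2] <- "excluded_low_rate"
  sp3 <- median_split_by_tau(f)
  expect_false(2 %in% c(sp3$low_tau, sp3$high_tau))

  expect_error(median_split_by_tau(mk_fits(50)), "fewer than 2")
})

test_that("fit_timescales produces one coherent row per neuron", {
  g <- tiny_session()
  fits <- fit_timescales(g$session)
  expect_equal(nrow(fits), 12)
  expect_true(all(fits$status %in%
                    c("fitted", "excluded_low_rate", "excluded_no_decline",
                      "excluded_extreme_params", "flagged_poor_fit")))
  ok <- fits$status == "fitted"
  expect_true(all(fits$tau_ms[ok] >= 10 & fits$tau_ms[ok] <= 1000))
  expect_true(all(fits$A[ok] >= 0 & fits$A[ok] <= 1.2))
})
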