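sc0 <- sc_params(k_d = 0.02, k_a1 = 0.001, k_a2 = 0.02, k_e = 0.1,
                 V_I = 0.12, F = 0.8, I_b = 30)
bw <- 80

test_that("no boluses means basal insulin throughout", {
  out <- simulate_sc_fast(sc0, list(), seq(-60, 180, 10), bw)
  expect_true(all(out$values == 30))
})

test_that("the depot system is linear: boluses superpose", {
  tt <- seq(-45, 180, 5)
  one <- simulate_sc_fast(sc0, list(list(time = -45, dose = 8)), tt, bw)
  two <- simulate_sc_fast(sc0, list(list(time = -45, dose = 4),
                                    list(time = -45, dose = 4)), tt, bw)
  expect_equal(one$values, two$values, tolerance = 1e-8)
  half <- simulate_sc_fast(sc0, list(list(time = -45, dose = 4)), tt, bw)
  expect_equal(one$values - 30, 2 * (half$values - 30), tolerance = 1e-6)
})

test_that("absorbed insulin obeys the closed-form mass balance", {
  # area above basal over [bolus, horizon] = F*dose_pmol/(k_e*V_I*BW)
  tt <- seq(-45, 1000, 0.5)
  out <- simulate_sc_fast(sc0, list(list(time = -45, dose = 6)), tt, bw)
  auc <- hepaflux:::trapz(tt, out$values - sc0$I_b)
  expect_equal(auc, sc0$F * 6 * 6000 / (sc0$k_e * sc0$V_I * bw),
               tolerance = 0.01)
  expect_true(all(out$values >= 0))
})

test_that("fitting noise-free simulated data recovers the rate constants", {
  tt <- blood_grid()
  meas <- simulate_sc_fast(sc0, list(list(time = -45, dose = 8)), tt, bw)
  init <- sc0
  for (nm in c("k_d", "k_a1", "k_a2", "k_e")) init[[nm]] <- sc0[[nm]] * 1.2
  init <- do.call(sc_params, unclass(init))
  fit <- fit_sc_model(meas, list(list(time = -45, dose = 8)), init, bw)
  for (nm in c("k_d", "k_a1", "k_a2", "k_e"))
    expect_equal(fit$params[[nm]], sc0[[nm]], tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)
})

test_that("equal lower and upper bounds hold a parameter fixed", {
  tt <- blood_grid()
  meas <- simulate_sc_fast(sc0, list(list(time = -45, dose = 8)), tt, bw)
  fit <- fit_sc_model(meas, list(list(time = -45, dose = 8)), sc0, bw,
                      options = list(lower = c(k_a1 = 0.005),
                                     upper = c(k_a1 = 0.005)))
  expect_equal(fit$params$k_a1, 0.005)
  expect_true(is.na(fit$cv[["k_a1"]]))
})

test_that("elimination half-life survives assay noise", {
  tt <- blood_grid()
  clean <- simulate_sc_fast(sc0, list(list(time = -45, dose = 8)), tt, bw)
  set.seed(314)
  noisy <- hf_ts(tt, pmax(clean$values * (1 + 0.06 * rnorm(length(tt))), 0),
                 "pmol/l")
  fit <- quiet(fit_sc_model(noisy, list(list(time = -45, dose = 8)), sc0, bw))
  half_true <- log(2) / sc0$k_e
  half_est <- log(2) / fit$params$k_e
  expect_lt(abs(half_est / half_true - 1), 0.25)
})

test_that("identifiability contracts are enforced", {
  tt <- blood_grid()
  meas <- simulate_sc_fast(sc0, list(list(time = -45, dose = 8)), tt, bw)
  expect_error(fit_sc_model(meas, list(list(time = -45, dose = 0)), sc0, bw),
               "identifiable")
  short <- ts_window(meas, -60, 30)
  expect_error(fit_sc_model(short, list(list(time = -45, dose = 8)), sc0, bw),
               "post-bolus")
  expect_warning(simulate_sc_fast(sc0, list(list(time = 500, dose = 4)),
                                  seq(0, 180, 10), bw), "after the last")
})

test_that("composite active insulin applies the published fractions", {
  tt <- seq(0, 60, 10)
  zero <- hf_ts(tt, rep(0, length(tt)), "pmol/l")
  long100 <- hf_ts(tt, rep(100, length(tt)), "pmol/l")
  long40 <- hf_ts(tt, rep(40, length(tt)), "pmol/l")
  expect_equal(composite_active_insulin(zero, long100, "degludec")$values,
               rep(2.85, length(tt)))
  expect_equal(composite_active_insulin(zero, long40, "detemir")$values,
               rep(10, length(tt)))
  expect_equal(composite_active_insulin(zero, long100, "glargine")$values,
               rep(100, length(tt)))
  fast <- hf_ts(tt, 50 + tt, "pmol/l")
  expect_equal(composite_active_insulin(fast, long100, "none")$values,
               fast$values)
  expect_error(composite_active_insulin(fast, long100, "nph"),
               "unknown analogue.*glargine")
})
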