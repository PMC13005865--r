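test_that("worked partition arithmetic matches the saturating transform", {
  tt <- c(0, 30, 60)
  total <- hf_ts(tt, rep(6, 3), "mmol/l")
  ratio <- hf_ts(tt, rep(0.5, 3), "ratio")
  res <- partition_glucose(total, ratio, baseline_ratio = 0, purity = 1)
  expect_equal(res$exogenous$values, rep(2, 3))   # 6 * 0.5/1.5
  expect_equal(res$endogenous$values, rep(4, 3))
})

test_that("a tracer-free signal partitions to pure endogenous glucose", {
  tt <- blood_grid()
  total <- hf_ts(tt, 5 + 0.01 * pmax(tt, 0), "mmol/l")
  ratio <- hf_ts(tt, rep(0.004, length(tt)), "ratio")
  res <- partition_glucose(total, ratio, baseline_ratio = 0.004,
                           purity = 0.99)
  expect_true(all(res$exogenous$values == 0))
  expect_equal(res$endogenous$values, total$values)
})

test_that("sources always sum to the measured total", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    tt <- sort(sample(seq(-60, 180, 5), n))
    total <- hf_ts(tt, runif(n, 3, 15), "mmol/l")
    ratio <- hf_ts(tt, runif(n, 0, 2), "ratio")
    res <- suppressWarnings(
      partition_glucose(total, ratio, baseline_ratio = runif(1, 0, 0.1),
                        purity = runif(1, 0.9, 1)))
    expect_equal(res$exogenous$values + res$endogenous$values, total$values,
                 tolerance = 1e-12)
    expect_true(all(res$exogenous$values >= 0))
    expect_true(all(res$endogenous$values >= 0))
  }
})

test_that("exogenous share is monotone in the measured ratio", {
  total <- hf_ts(0, 8, "mmol/l")
  exo_at <- function(r)
    partition_glucose(total, hf_ts(0, r, "ratio"), 0, 0.99)$exogenous$values
  rr <- seq(0, 3, by = 0.1)
  expect_true(all(diff(vapply(rr, exo_at, numeric(1))) >= 0))
})

test_that("purity correction rescales the corrected ratio linearly", {
  total <- hf_ts(0, 6, "mmol/l")
  ratio <- hf_ts(0, 0.01, "ratio")
  r_full <- partition_glucose(total, ratio, 0, purity = 1)$corrected_ratio
  r_half <- partition_glucose(total, ratio, 0, purity = 0.5)$corrected_ratio
  expect_equal(r_half$values, 2 * r_full$values)
})

test_that("noise-free generated ratios invert to the ground-truth sources", {
  res <- noise_free("healthy")
  ds <- res$dataset
  pre <- ds$plasma_ratio$times <= 0
  out <- partition_glucose(ds$plasma_total_glucose, ds$plasma_ratio,
                           baseline_ratio = mean(ds$plasma_ratio$values[pre]),
                           purity = 0.99)
  expect_equal(out$exogenous$values, res$truth$channels$exogenous$values,
               tolerance = 1e-6)
  expect_equal(out$endogenous$values, res$truth$channels$endogenous$values,
               tolerance = 1e-6)
})

test_that("contract violations are rejected, negative corrections clipped", {
  total <- hf_ts(c(0, 10), c(6, 6), "mmol/l")
  ratio10 <- hf_ts(c(0, 12), c(0.1, 0.1), "ratio")
  expect_error(partition_glucose(total, ratio10, 0, 0.99), "share a time grid")
  expect_error(partition_glucose(total, hf_ts(c(0, 10), c(0.1, 0.1), "ratio"),
                                 0, purity = 0), "purity")
  expect_warning(
    res <- partition_glucose(total, hf_ts(c(0, 10), c(0.01, 0.3), "ratio"),
                             baseline_ratio = 0.05, purity = 0.99),
    "clipped")
  expect_equal(res$exogenous$values[1], 0)

  # mole-percent-excess convention: exo = total * r'
  mpe <- partition_glucose(total, hf_ts(c(0, 10), c(0.2, 0.2), "ratio"),
                           0, purity = 1, convention = "mpe")
  expect_equal(mpe$exogenous$values, c(1.2, 1.2))
})
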