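bw <- 80
mk_params <- function(D = 0, SI_D = 1e-4, SI_P = 3e-3, p2 = 0.02,
                      p2P = 0.015, GE_P = 0, GEZI = 0.02, G_b = 5.2,
                      I_b = 40, V = 0.125) {
  omm_params(V = V, GEZI_D = GEZI, SI_D = SI_D, p2 = p2, SI_P = SI_P,
             p2P = p2P, GE_P = GE_P, G_b = G_b, I_b = I_b,
             gi = gi_params(k_max = 0.02, k_min = 0.005, k_abs = 0.03,
                            f_bio = 0.85, D = D))
}
flat_insulin <- function(level, t_end = 300)
  hf_ts(c(-60, t_end), c(level, level), "pmol/l")

test_that("basal insulin and no dose is a steady state", {
  p <- mk_params()
  out <- simulate_omm(p, flat_insulin(p$I_b), bw, seq(-60, 180, 10))
  expect_equal(out$G_endo$values, rep(p$G_b, length(out$G_endo$values)),
               tolerance = 1e-7)
  expect_true(all(out$G_exo$values == 0))
  expect_equal(out$EGP_over_basal$values,
               rep(1, length(out$EGP_over_basal$values)), tolerance = 1e-7)
  expect_equal(out$Rd_over_basal$values,
               rep(1, length(out$Rd_over_basal$values)), tolerance = 1e-7)
})

test_that("tracer can only enter through the meal", {
  p <- mk_params(D = 0, SI_P = 0)
  out <- simulate_omm(p, flat_insulin(p$I_b + 200), bw, seq(0, 180, 10))
  expect_true(all(out$G_exo$values == 0))
})

test_that("with constant remote insulin the glucose pool decays to the
          closed-form steady state at rate GEZI + X", {
  ci <- 150                      # step above basal
  p <- mk_params(SI_D = 1e-4, SI_P = 0, p2 = 50)  # fast remote equilibration
  out <- simulate_omm(p, flat_insulin(p$I_b + ci), bw, seq(0, 240, 1))
  x0 <- p$SI_D * ci
  S <- p$GEZI_D * p$G_b / (p$GEZI_D + x0)     # steady level
  g <- out$G_endo
  anchor <- ts_interp(g, 5)                    # after the X transient
  pred <- S + (anchor - S) * exp(-(p$GEZI_D + x0) * (g$times - 5))
  late <- g$times >= 5
  expect_equal(g$values[late], pred[late], tolerance = 1e-5)
})

test_that("production is floored at zero, never negative", {
  p <- mk_params(SI_P = 0.05)    # absurdly strong suppression
  out <- simulate_omm(p, flat_insulin(p$I_b + 400), bw, seq(-60, 180, 5))
  expect_true(all(out$EGP$values >= 0))
  expect_true(any(out$EGP$values == 0))
})

test_that("suppression and disposal summaries compute their definitions", {
  tt <- seq(0, 180, 1)
  expect_equal(egp_suppression(hf_ts(tt, rep(1, length(tt)), "dimensionless"),
                               c(0, 180)), 0)
  expect_equal(egp_suppression(hf_ts(tt, rep(0, length(tt)), "dimensionless"),
                               c(0, 180)), 1)
  expect_equal(rd_fractional_increase(hf_ts(tt, rep(2, length(tt)),
                                            "dimensionless"), c(0, 180)), 1)
  ramp <- hf_ts(tt, 1 + 2 * tt / 180, "dimensionless")  # 1 -> 3 linearly
  expect_equal(rd_fractional_increase(ramp, c(0, 180)), 1)
  expect_error(egp_suppression(ramp, c(0, 300)), "outside series support")
})

test_that("basal-insulin glucose effectiveness is the documented sum", {
  p <- mk_params(SI_D = 5e-5, GEZI = 0.01, I_b = 60)
  expect_equal(report_ge_disposal(p), 0.01 + 5e-5 * 60)
  expect_equal(report_ge_disposal(mk_params(SI_D = 0, GEZI = 0.01)), 0.01)
})

test_that("noise-free fits recover the generating parameters", {
  # three perturbed healthy subjects through the full pipeline
  co <- quiet(generate_cohort(list(list(profile = default_profile("healthy"),
                                        n = 3L)), seed = 13, noise = FALSE))
  for (s in co) {
    a <- quiet(analyze_subject(s$dataset))
    tr <- s$truth$omm; est <- a$fit$params
    for (nm in c("SI_D", "p2", "SI_P", "p2P", "GE_P"))
      expect_equal(est[[nm]], tr[[nm]], tolerance = 1e-2)
    for (nm in c("k_max", "k_min", "k_abs"))
      expect_equal(est$gi[[nm]], tr$gi[[nm]], tolerance = 1e-2)
  }
})

test_that("fit contracts: identifiability, missing input, T1D fixing rule", {
  res <- noise_free("t1d_sub1")
  ds <- res$dataset
  pre <- ds$plasma_ratio$times <= 0
  part <- partition_glucose(ds$plasma_total_glucose, ds$plasma_ratio,
                            mean(ds$plasma_ratio$values[pre]), 0.99)
  ins <- res$truth$insulin_input
  p0 <- res$truth$omm
  expect_error(fit_omm(part$exogenous, part$endogenous, NULL, p0,
                       ds$body_weight), "insulin series missing")
  short <- ts_window(part$exogenous, -60, 90)
  short_e <- ts_window(part$endogenous, -60, 90)
  expect_error(fit_omm(short, short_e, ins, p0, ds$body_weight),
               "post-dose samples")
  w <- capture_warnings(
    fit_omm(part$exogenous, part$endogenous, ins, p0, ds$body_weight,
            options = list(group = "t1d", maxiter = 1,
                           free = c("SI_D", "SI_P", "GE_P"))))
  expect_true(any(grepl("GE_P left free", w)))
})

test_that("insulin input must cover the simulation window", {
  p <- mk_params()
  expect_error(simulate_omm(p, hf_ts(c(-60, 60), c(40, 40), "pmol/l"), bw,
                            seq(-60, 180, 10)), "before the simulation window")
})
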