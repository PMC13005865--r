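#' Generate one virtual subject
#'
#' Forward-simulates the full mechanistic model for a [profile_spec] and
#' samples it on the study grids (venous samples at T-60, 0, 10, 20, 30,
#' 60, 90, 120, 150, 180 min; glucagon on its sparser subset; MR channels
#' every 10 min from 0 to 180), optionally adding multiplicative Gaussian
#' measurement noise truncated at zero. With `noise = FALSE` the dataset
#' carries the ground-truth trajectories sampled without error, and the
#' generator is fully deterministic.
#'
#' The glucose system is integrated by [simulate_omm()] itself (generator
#' and estimator share one forward core). For healthy profiles the known
#' insulin input is the piecewise-linear interpolation of the endogenous
#' insulin curve through the venous grid — exactly the representation the
#' downstream fit uses. For diabetes profiles the input is the composite
#' active insulin (subcutaneous bolus model plus the active fraction of the
#' constant basal analogue) on a dense grid.
#'
#' @param profile a [profile_spec].
#' @param seed integer RNG seed for the measurement noise.
#' @param noise add measurement noise (default `TRUE`).
#' @param config an `hf_config`.
#' @return `list(dataset = subject_dataset, truth = list(...))`; `truth`
#'   holds the sampled parameters (including the solved hepatic inflow rate
#'   and glycogen ramp amplitude), the noise-free channels and the dense
#'   model fluxes.
#' @export
generate_subject <- function(profile, seed = 1L, noise = TRUE,
                             config = default_config()) {
  stopifnot(inherits(profile, "profile_spec"))
  bg <- blood_grid(); gg <- glucagon_grid(); mg <- mr_grid()
  bw <- profile$body_weight
  dense <- seq(-60, 180, by = config$dense_dt)

  # --- known insulin input and measured insulin channels ------------------
  if (profile$group == "healthy") {
    fast_bg <- endogenous_insulin(profile$insulin_curve, bg)
    long_bg <- hf_ts(bg, rep(0, length(bg)), "pmol/l",
                     "plasma long-acting insulin")
    insulin_input <- hf_ts(bg, fast_bg$values, "pmol/l",
                           "active insulin input")
    sc_truth <- NULL
  } else {
    fast_bg <- simulate_sc_fast(profile$sc, profile$bolus_events, bg, bw,
                                config)
    fast_dense <- simulate_sc_fast(profile$sc, profile$bolus_events, dense,
                                   bw, config)
    long_bg <- hf_ts(bg, rep(profile$long_conc, length(bg)), "pmol/l",
                     "plasma long-acting insulin")
    insulin_input <- composite_active_insulin(fast_dense, long_bg,
                                              profile$basal_analogue,
                                              config$active_fractions)
    sc_truth <- profile$sc
  }

  # --- glucose system -----------------------------------------------------
  fluxes <- simulate_omm(profile$omm, insulin_input, bw, bg,
                         dense = TRUE, config = config)
  exo_bg <- fluxes$sampled$G_exo$values
  endo_bg <- fluxes$sampled$G_endo$values
  total_bg <- exo_bg + endo_bg
  r0 <- profile$natural_abundance_ratio
  ratio_bg <- r0 + config$tracer_purity * exo_bg / endo_bg

  # --- hepatic tracer compartment -----------------------------------------
  hep <- hepatic_exchange(fluxes$G_exo, profile$hepatic, mg, config)
  n_ratio <- config$deuterons_per_glucose / config$deuterons_per_water
  amp_vox <- hep$conc / config$water_reference_conc * n_ratio *
    profile$water_ref_amplitude

  # --- glycogen trajectory -------------------------------------------------
  gly <- glycogen_trajectory(profile$glycogen, mg)
  cal <- profile$glycogen_cal
  cal_scale <- cal$phantom_concentration / cal$phantom_amplitude *
    cal$f_distance * cal$f_loading * cal$f_T1 * cal$f_NOE
  gly_amp <- gly$conc / cal_scale

  # --- glucagon (descriptive only) ----------------------------------------
  gcg <- glucagon_curve(profile$glucagon, gg)

  truth_channels <- list(
    total = hf_ts(bg, total_bg, "mmol/l", "plasma total glucose"),
    ratio = hf_ts(bg, ratio_bg, "ratio", "plasma D-Glc/tracee molar ratio"),
    exogenous = fluxes$sampled$G_exo,
    endogenous = fluxes$sampled$G_endo,
    insulin_fast = fast_bg, insulin_long = long_bg,
    glucagon = hf_ts(gg, gcg, "pmol/l", "plasma glucagon"),
    hepatic_dglc = hf_ts(mg, hep$conc, "mmol/l",
                         "hepatic D-Glc concentration"),
    glycogen = hf_ts(mg, gly$conc, "mmol/l", "liver glycogen concentration"))

  noisy <- function(v, cv) {
    if (!noise || cv <= 0) return(v)
    pmax(0, v * (1 + cv * stats::rnorm(length(v))))
  }
  if (noise) set.seed(as.integer(seed) %% .Machine$integer.max)
  cvs <- profile$noise_cv
  total_m <- noisy(total_bg, cvs[["glucose_total"]])
  ratio_m <- noisy(ratio_bg, cvs[["ratio"]])
  fast_m <- noisy(fast_bg$values, cvs[["insulin_fast"]])
  long_m <- noisy(long_bg$values, cvs[["insulin_long"]])
  gcg_m <- noisy(gcg, cvs[["glucagon"]])
  vox_m <- lapply(1:6, function(v) noisy(amp_vox, cvs[["dmi_glc"]]))
  gly_m <- noisy(gly_amp, cvs[["c13_glycogen"]])

  ds <- subject_dataset(
    subject_id = sprintf("%s_seed%d", profile$name, as.integer(seed)),
    group = profile$group, subgroup_hint = profile$subgroup,
    body_weight = bw, height = profile$height,
    dose_grams = profile$dose_grams,
    bolus_events = profile$bolus_events,
    basal_analogue = profile$basal_analogue,
    plasma_total_glucose = hf_ts(bg, total_m, "mmol/l",
                                 "plasma total glucose"),
    plasma_ratio = hf_ts(bg, ratio_m, "ratio",
                         "plasma D-Glc/tracee molar ratio"),
    plasma_insulin_fast = hf_ts(bg, fast_m, "pmol/l",
                                "plasma fast-acting insulin"),
    plasma_insulin_long = hf_ts(bg, long_m, "pmol/l",
                                "plasma long-acting insulin"),
    plasma_glucagon = hf_ts(gg, gcg_m, "pmol/l", "plasma glucagon"),
    hepatic_dglc_amplitudes = lapply(seq_along(vox_m), function(v)
      hf_ts(mg, vox_m[[v]], "a.u.", sprintf("hepatic D-Glc voxel %d", v))),
    water_reference_amplitude = profile$water_ref_amplitude,
    glycogen_amplitudes = hf_ts(mg, gly_m, "a.u.",
                                "liver glycogen amplitude"),
    glycogen_cal = profile$glycogen_cal,
    config = config)

  truth <- list(profile = profile, omm = profile$omm, sc = sc_truth,
                hepatic_k_in = hep$k_in, hepatic_k_out = profile$hepatic$k_out,
                glycogen_amplitude = gly$A,
                insulin_input = insulin_input,
                fluxes = fluxes, channels = truth_channels)
  list(dataset = ds, truth = truth)
}

# baseline + log-Gaussian postprandial excursion, peaking at t_peak
endogenous_insulin <- function(curve, times) {
  v <- rep(curve$I_b, length(times))
  pos <- times > 0
  v[pos] <- curve$I_b + (curve$I_peak - curve$I_b) *
    exp(-(log(times[pos] / curve$t_peak))^2 / (2 * curve$sigma^2))
  hf_ts(times, v, "pmol/l", "plasma fast-acting insulin")
}

# first-order plasma-liver exchange L' = k_in * G_exo - k_out * L;
# linear in k_in, so the inflow rate is solved exactly from the peak target
hepatic_exchange <- function(g_exo_dense, hepatic, times, config) {
  fG <- stats::approxfun(g_exo_dense$times, g_exo_dense$values, rule = 2)
  rhs <- function(t, y, p) list(fG(t) - p * y)
  t0 <- min(g_exo_dense$times)
  grid <- sort(unique(c(seq(t0, max(times), by = config$dense_dt), times)))
  sol <- deSolve::lsoda(c(h = 0), grid, rhs, hepatic$k_out,
                        rtol = config$ode_rtol, atol = config$ode_atol, maxsteps = 20000)
  h <- stats::approx(sol[, "time"], sol[, "h"], xout = times, rule = 2)$y
  hmax <- max(h[times >= 0])
  k_in <- if (hmax > 1e-12) hepatic$peak_target / hmax else 0
  list(conc = k_in * h, k_in = k_in)
}

# glycogen(t) = baseline + A * pnorm((t - t_on)/w); A solved so the
# trapezoidal incremental AUC over 0-180 (baseline at T0) on the reporting
# grid equals the profile's target
glycogen_trajectory <- function(gly, times) {
  u <- stats::pnorm((times - gly$t_on) / gly$w)
  u0 <- stats::pnorm((0 - gly$t_on) / gly$w)
  denom <- trapz(times, u - u0)
  if (abs(denom) < 1e-9)
    stop("glycogen_trajectory: ramp carries no incremental area on the grid",
         call. = FALSE)
  A <- gly$iauc_target / denom
  conc <- gly$baseline + A * (u - u0)
  if (any(conc <= 0))
    stop("glycogen_trajectory: trajectory crosses zero; implausible ",
         "baseline/amplitude combination", call. = FALSE)
  list(conc = conc, A = A)
}

# descriptive decline-then-rise curve through (0, g0), (t_nadir, nadir),
# (180, g_end); quadratic in each branch, flat at the nadir
glucagon_curve <- function(g, times) {
  v <- numeric(length(times))
  pre <- times <= 0
  v[pre] <- g$g0
  fall <- !pre & times <= g$t_nadir
  v[fall] <- g$nadir + (g$g0 - g$nadir) *
    ((g$t_nadir - times[fall]) / g$t_nadir)^2
  rise <- times > g$t_nadir
  v[rise] <- g$nadir + (g$g_end - g$nadir) *
    ((times[rise] - g$t_nadir) / (max(times) - g$t_nadir))^2
  v
}

#' Generate a cohort of virtual subjects
#'
#' Draws independent subjects from a mixture of profiles. Between-subject
#' variation is applied as lognormal multipliers (unit mean) on the
#' parameters named in each profile's `between_cv` map before the subject
#' is forward-simulated; measurement noise is then added per
#' [generate_subject()]. A given `seed` reproduces the cohort exactly.
#'
#' @param mixture list of `list(profile = profile_spec, n = count)`;
#'   see [study_mixture()] for the default study emulation.
#' @param seed integer master seed.
#' @param noise add measurement noise (default `TRUE`).
#' @param config an `hf_config`.
#' @return list with one `list(dataset, truth)` element per subject.
#' @export
generate_cohort <- function(mixture, seed = 1L, noise = TRUE,
                            config = default_config()) {
  if (!length(mixture)) stop("generate_cohort: empty mixture", call. = FALSE)
  for (m in mixture)
    if (is.null(m$n) || m$n < 1L)
      stop("generate_cohort: each mixture entry needs n >= 1", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- list()
  idx <- 0L
  for (m in mixture) {
    for (i in seq_len(m$n)) {
      idx <- idx + 1L
      cvs <- m$profile$between_cv
      z <- stats::rnorm(length(cvs)); names(z) <- names(cvs)
      sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      pp <- perturb_profile(m$profile, z)
      res <- generate_subject(pp, seed = sub_seed, noise = noise,
                              config = config)
      res$dataset$subject_id <- sprintf("%s_%02d", m$profile$name, i)
      out[[idx]] <- res
    }
  }
  out
}

# unit-mean lognormal multiplier for CV c: exp(sigma*z - sigma^2/2)
ln_mult <- function(z, cv) {
  if (cv <= 0) return(1)
  s <- sqrt(log(1 + cv^2))
  exp(s * z - s^2 / 2)
}

perturb_profile <- function(profile, z) {
  cvs <- profile$between_cv
  m <- vapply(names(cvs), function(nm) ln_mult(z[[nm]], cvs[[nm]]),
              numeric(1))
  p <- profile
  o <- unclass(p$omm); g <- unclass(o$gi)
  o$SI_D <- o$SI_D * m[["SI_D"]]; o$SI_P <- o$SI_P * m[["SI_P"]]
  o$p2 <- o$p2 * m[["p2"]]; o$p2P <- o$p2P * m[["p2P"]]
  o$GE_P <- o$GE_P * m[["GE_P"]]
  o$G_b <- o$G_b * m[["G_b"]]
  g$k_max <- g$k_max * m[["empty_scale"]]
  g$k_min <- g$k_min * m[["empty_scale"]]
  g$k_abs <- g$k_abs * m[["k_abs"]]
  o$gi <- do.call(gi_params, g)
  o$EGP_b <- NULL   # re-derive the basal balance for the perturbed G_b
  p$body_weight <- p$body_weight * m[["body_weight"]]
  if (!is.null(p$insulin_curve)) {
    ic <- p$insulin_curve
    ic$I_b <- ic$I_b * m[["I_b"]]
    ic$I_peak <- max(ic$I_b, ic$I_peak * m[["I_peak"]])
    ic$t_peak <- ic$t_peak * m[["t_peak"]]
    p$insulin_curve <- ic
    o$I_b <- ic$I_b
  }
  if (!is.null(p$sc)) {
    s <- unclass(p$sc)
    s$k_d <- s$k_d * m[["sc_k_d"]]; s$k_a1 <- s$k_a1 * m[["sc_k_a1"]]
    s$k_a2 <- s$k_a2 * m[["sc_k_a2"]]; s$k_e <- s$k_e * m[["sc_k_e"]]
    p$sc <- do.call(sc_params, s)
    p$long_conc <- p$long_conc * m[["long_conc"]]
    frac <- default_config()$active_fractions
    phi <- if (p$basal_analogue == "none") 0 else frac[[p$basal_analogue]]
    o$I_b <- p$sc$I_b + phi * p$long_conc
  }
  p$omm <- do.call(omm_params, o)
  p$hepatic$peak_target <- p$hepatic$peak_target * m[["hepatic_peak"]]
  p$hepatic$k_out <- p$hepatic$k_out * m[["hepatic_k_out"]]
  p$glycogen$baseline <- p$glycogen$baseline * m[["glycogen_baseline"]]
  p$glycogen$iauc_target <- p$glycogen$iauc_target * m[["glycogen_iauc"]]
  p$glucagon$g0 <- max(p$glucagon$g0 * m[["glucagon_g0"]], p$glucagon$nadir)
  p
}
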