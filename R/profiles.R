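#' Virtual-subject profile
#'
#' A profile bundles every parameter needed to forward-simulate one study
#' participant: anthropometrics and dose, the glucose–insulin model with its
#' gastrointestinal sub-model, the insulin exposure description (an
#' endogenous secretion-shaped curve for healthy subjects; a subcutaneous
#' bolus model plus constant basal-analogue exposure for diabetes
#' profiles), the lumped hepatic tracer exchange, the parametric glycogen
#' and glucagon trajectories, and the measurement / between-subject noise
#' maps.
#'
#' Rather than storing opaque rate constants for the observational
#' channels, profiles store the printed cohort summaries they are meant to
#' reproduce (hepatic peak concentration, glycogen incremental AUC): the
#' generator solves the corresponding linear scale factors exactly, so the
#' emitted trajectories hit those calibration anchors by construction.
#'
#' @param name profile name (`healthy`, `t1d_sub1`, `t1d_sub2`, or custom).
#' @param group `"healthy"` or `"t1d"`.
#' @param subgroup `"none"`, `"1"` or `"2"`.
#' @param body_weight,height,dose_grams anthropometrics and tracer dose.
#' @param omm an [omm_params] (with its [gi_params]).
#' @param insulin_curve healthy endogenous insulin description:
#'   `list(I_b, I_peak, t_peak, sigma)` — a baseline plus log-Gaussian
#'   postprandial excursion peaking at `t_peak` minutes; `NULL` for t1d.
#' @param sc an [sc_params] for the fast-acting bolus model; `NULL` for
#'   healthy.
#' @param bolus_events list of `list(time, dose, analogue)`.
#' @param basal_analogue long-acting analogue name or `"none"`.
#' @param long_conc constant circulating long-acting analogue concentration,
#'   pmol/l (pump replacement emulation).
#' @param hepatic `list(k_out, peak_target)`: first-order plasma–liver
#'   tracer exchange; the inflow rate is solved so the noise-free hepatic
#'   peak equals `peak_target` mmol/l.
#' @param glycogen `list(baseline, t_on, w, iauc_target)`: concentration
#'   trajectory `baseline + A * pnorm((t - t_on)/w)` with `A` solved so the
#'   incremental AUC over 0–180 min equals `iauc_target` mmol/l x min
#'   (sign included).
#' @param glucagon `list(g0, nadir, t_nadir, g_end)` descriptive
#'   decline-then-rise curve, pmol/l.
#' @param natural_abundance_ratio pre-dose background of the measured molar
#'   ratio (default 0: the instrument-level background is treated as
#'   removed upstream).
#' @param water_ref_amplitude baseline water amplitude, a.u.
#' @param glycogen_cal a [glycogen_calibration].
#' @param noise_cv named per-channel measurement CVs.
#' @param between_cv named per-parameter lognormal between-subject CVs
#'   (see [generate_cohort()]).
#' @return an object of class `profile_spec`.
#' @export
profile_spec <- function(name, group, subgroup = "none",
                         body_weight, height, dose_grams,
                         omm, insulin_curve = NULL, sc = NULL,
                         bolus_events = list(), basal_analogue = "none",
                         long_conc = 0,
                         hepatic, glycogen, glucagon,
                         natural_abundance_ratio = 0,
                         water_ref_amplitude = 100,
                         glycogen_cal = default_glycogen_cal(),
                         noise_cv = default_config()$noise_cv,
                         between_cv = default_between_cv()) {
  stopifnot(inherits(omm, "omm_params"))
  if (hepatic$k_out <= 0)
    stop("profile_spec: hepatic k_out must be > 0", call. = FALSE)
  if (hepatic$peak_target < 0)
    stop("profile_spec: hepatic peak target must be >= 0", call. = FALSE)
  if (glycogen$baseline <= 0)
    stop("profile_spec: glycogen baseline must be > 0", call. = FALSE)
  if (glycogen$w <= 0)
    stop("profile_spec: glycogen ramp width must be > 0", call. = FALSE)
  if (any(noise_cv < 0) || any(unlist(between_cv) < 0))
    stop("profile_spec: CVs must be >= 0", call. = FALSE)
  if (!is.null(insulin_curve)) {
    if (insulin_curve$I_b < 0 || insulin_curve$I_peak < insulin_curve$I_b ||
        insulin_curve$t_peak <= 0 || insulin_curve$sigma <= 0)
      stop("profile_spec: invalid insulin curve", call. = FALSE)
  }
  structure(list(name = name, group = group, subgroup = subgroup,
                 body_weight = body_weight, height = height,
                 dose_grams = dose_grams, omm = omm,
                 insulin_curve = insulin_curve, sc = sc,
                 bolus_events = bolus_events,
                 basal_analogue = basal_analogue, long_conc = long_conc,
                 hepatic = hepatic, glycogen = glycogen,
                 glucagon = glucagon,
                 natural_abundance_ratio = natural_abundance_ratio,
                 water_ref_amplitude = water_ref_amplitude,
                 glycogen_cal = glycogen_cal,
                 noise_cv = noise_cv, between_cv = between_cv),
            class = "profile_spec")
}

#' Default phantom calibration used by the synthetic generator
#' @return a [glycogen_calibration] with plausible bench values.
#' @export
default_glycogen_cal <- function() {
  glycogen_calibration(phantom_concentration = 300, phantom_amplitude = 1000,
                       f_distance = 1.15, f_loading = 0.92,
                       f_T1 = 1.25, f_NOE = 0.85)
}

#' Default between-subject variability map
#'
#' Lognormal coefficients of variation applied per subject by
#' [generate_cohort()]. Kinetic parameters get a moderate 15% CV; the
#' observational calibration anchors inherit the relative SDs of the
#' printed cohort summaries (e.g. hepatic peak 3.0 +/- 0.8 mmol/l implies
#' roughly 27%). `empty_scale` multiplies `k_max` and `k_min` jointly so
#' the emptying nonlinearity keeps its shape.
#'
#' @return named numeric vector of CVs.
#' @export
default_between_cv <- function() {
  c(SI_D = 0.15, SI_P = 0.15, p2 = 0.15, p2P = 0.15, GE_P = 0.15,
    G_b = 0.07, empty_scale = 0.15, k_abs = 0.15,
    I_peak = 0.30, t_peak = 0.20, I_b = 0.20,
    sc_k_d = 0.15, sc_k_a1 = 0.15, sc_k_a2 = 0.15, sc_k_e = 0.15,
    long_conc = 0.20,
    glycogen_baseline = 0.20, glycogen_iauc = 0.40,
    hepatic_peak = 0.27, hepatic_k_out = 0.15,
    glucagon_g0 = 0.30, body_weight = 0.12)
}

#' Built-in calibrated study profiles
#'
#' Returns one of the three documented default profiles. Their parameter
#' values are calibrated once so that the noise-free forward simulation,
#' followed by the full analysis pipeline, reproduces the headline cohort
#' summaries of the emulated study: for the healthy profile a basal/peak
#' total glucose of 5.2/7.5 mmol/l, an endogenous-glucose nadir of
#' 1.2 mmol/l, a hepatic D-Glc peak of 3.0 mmol/l, a glycogen iAUC of
#' 2.4 mol/l x min and 63% EGP suppression over three hours; for the two
#' diabetes subgroup profiles half-emptying times of 65.3 and 110.7 min,
#' first-hour EGP suppression of 0.26 and 0.11, hepatic peaks of 6.1 and
#' 2.7 mmol/l and glycogen iAUCs of +2.5 and -3.0 mol/l x min.
#'
#' @param name `"healthy"`, `"t1d_sub1"` or `"t1d_sub2"`.
#' @param config an `hf_config` (supplies the fixed population `GEZI_D` and
#'   its diabetes scaling).
#' @return a [profile_spec].
#' @export
default_profile <- function(name = c("healthy", "t1d_sub1", "t1d_sub2"),
                            config = default_config()) {
  name <- match.arg(name)
  dose_grams <- 60
  D <- dose_grams / config$glucose_molar_mass
  gezi_h <- config$gezi_disposal_healthy
  gezi_t1d <- gezi_h * config$gezi_t1d_scale

  if (name == "healthy") {
    gi <- gi_params(k_max = 0.01968098728, k_min = 0.004373552728,
                    k_abs = 0.022, b = 0.7, c = 0.2, f_bio = 0.85, D = D)
    omm <- omm_params(V = 0.125, GEZI_D = gezi_h,
                      SI_D = 4.0e-5, p2 = 0.02,
                      SI_P = 5.03083081e-3, p2P = 0.012,
                      GE_P = 0.2420986376,
                      G_b = 5.2, I_b = 43.4, gi = gi)
    return(profile_spec(
      name = name, group = "healthy", subgroup = "none",
      body_weight = 81.8, height = 1.76, dose_grams = dose_grams,
      omm = omm,
      insulin_curve = list(I_b = 43.4, I_peak = 366, t_peak = 81.2,
                           sigma = 0.5),
      hepatic = list(k_out = 0.025, peak_target = 3.0),
      glycogen = list(baseline = 230, t_on = 90, w = 30,
                      iauc_target = 2400),
      glucagon = list(g0 = 4.41, nadir = 1.05, t_nadir = 63, g_end = 3.2)))
  }

  if (name == "t1d_sub1") {
    gi <- gi_params(k_max = 0.02144001279, k_min = 0.004764447287,
                    k_abs = 0.035, b = 0.7, c = 0.2, f_bio = 0.85, D = D)
    omm <- omm_params(V = 0.125, GEZI_D = gezi_t1d,
                      SI_D = 4.0e-5, p2 = 0.02,
                      SI_P = 1.90821702e-3, p2P = 0.012, GE_P = 0,
                      G_b = 10.8, I_b = 70, gi = gi)
    sc <- sc_params(k_d = 0.020194555, k_a1 = 0.001, k_a2 = 0.020194555,
                    k_e = 0.10, V_I = 0.12, F = 0.76465795, I_b = 0)
    return(profile_spec(
      name = name, group = "t1d", subgroup = "1",
      body_weight = 77.5, height = 1.70, dose_grams = dose_grams,
      omm = omm, sc = sc,
      bolus_events = list(list(time = -45, dose = 8.2, analogue = "aspart")),
      basal_analogue = "detemir", long_conc = 280,
      hepatic = list(k_out = 0.025, peak_target = 6.1),
      glycogen = list(baseline = 274, t_on = 80, w = 40,
                      iauc_target = 2500),
      glucagon = list(g0 = 2.01, nadir = 1.15, t_nadir = 52, g_end = 1.9)))
  }

  gi <- gi_params(k_max = 0.01264705233, k_min = 0.002810456073,
                  k_abs = 0.012, b = 0.7, c = 0.2, f_bio = 0.85, D = D)
  omm <- omm_params(V = 0.125, GEZI_D = gezi_t1d,
                    SI_D = 4.0e-5, p2 = 0.02,
                    SI_P = 1.197476828e-3, p2P = 0.012, GE_P = 0,
                    G_b = 10.6, I_b = 55, gi = gi)
  sc <- sc_params(k_d = 0.01524686, k_a1 = 0.001, k_a2 = 0.01524686,
                  k_e = 0.10, V_I = 0.12, F = 0.82787339, I_b = 0)
  profile_spec(
    name = name, group = "t1d", subgroup = "2",
    body_weight = 87.5, height = 1.76, dose_grams = dose_grams,
    omm = omm, sc = sc,
    bolus_events = list(list(time = -48, dose = 7.4, analogue = "aspart")),
    basal_analogue = "detemir", long_conc = 220,
    hepatic = list(k_out = 0.025, peak_target = 2.7),
    glycogen = list(baseline = 312, t_on = 30, w = 50,
                    iauc_target = -3000),
    glucagon = list(g0 = 3.98, nadir = 2.51, t_nadir = 60, g_end = 3.6))
}

#' The emulated study's default cohort mixture
#'
#' Ten healthy participants plus a diabetes arm of six subgroup-1 and four
#' subgroup-2 subjects.
#'
#' @param config an `hf_config`.
#' @return list of `list(profile, n)` entries for [generate_cohort()].
#' @export
study_mixture <- function(config = default_config()) {
  list(list(profile = default_profile("healthy", config), n = 10L),
       list(profile = default_profile("t1d_sub1", config), n = 6L),
       list(profile = default_profile("t1d_sub2", config), n = 4L))
}
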