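#' Oral minimal model parameters
#'
#' Parameters of the single-tracer oral minimal model of glucose–insulin
#' interaction. Insulin acts through two remote compartments: `X` stimulates
#' glucose disposal (rate `p2`, sensitivity `SI_D`) and `X_P` suppresses
#' endogenous glucose production (rate `p2P`, sensitivity `SI_P`). Glucose
#' exerts its own effects through `GEZI_D` (disposal glucose effectiveness
#' at zero insulin, fixed to a population value for identifiability) and
#' `GE_P` (production glucose effectiveness, fixed to zero in the diabetes
#' group where it cannot be reliably quantified).
#'
#' At basal steady state fluxes balance: `EGP_b = GEZI_D * G_b * V`; when
#' `EGP_b` is not supplied it is derived from that balance.
#'
#' @param V glucose distribution volume, l/kg.
#' @param GEZI_D disposal glucose effectiveness at zero insulin, min^-1.
#' @param SI_D disposal insulin sensitivity, min^-1 per pmol/l.
#' @param p2 disposal remote-insulin rate constant, min^-1.
#' @param SI_P production insulin sensitivity (fractional suppression per
#'   pmol/l).
#' @param p2P production remote-insulin rate constant, min^-1.
#' @param GE_P production glucose effectiveness (fractional suppression per
#'   mmol/l).
#' @param G_b basal plasma glucose, mmol/l.
#' @param I_b basal active insulin, pmol/l.
#' @param EGP_b basal endogenous glucose production, mmol/kg/min; default
#'   from the basal flux balance.
#' @param gi a [gi_params] absorption sub-model.
#' @return an object of class `omm_params`.
#' @export
omm_params <- function(V, GEZI_D, SI_D, p2, SI_P, p2P, GE_P = 0,
                       G_b, I_b, EGP_b = NULL, gi) {
  stopifnot(inherits(gi, "gi_params"))
  if (V <= 0 || p2 <= 0 || p2P <= 0)
    stop("omm_params: V, p2, p2P must be > 0", call. = FALSE)
  if (SI_D < 0 || SI_P < 0 || GE_P < 0)
    stop("omm_params: SI_D, SI_P, GE_P must be >= 0", call. = FALSE)
  if (GEZI_D <= 0 || G_b <= 0)
    stop("omm_params: GEZI_D and G_b must be > 0", call. = FALSE)
  if (is.null(EGP_b)) EGP_b <- GEZI_D * G_b * V
  if (EGP_b <= 0) stop("omm_params: EGP_b must be > 0", call. = FALSE)
  structure(list(V = V, GEZI_D = GEZI_D, SI_D = SI_D, p2 = p2,
                 SI_P = SI_P, p2P = p2P, GE_P = GE_P,
                 G_b = G_b, I_b = I_b, EGP_b = EGP_b, gi = gi),
            class = "omm_params")
}

#' @export
print.omm_params <- function(x, ...) {
  cat(sprintf(paste0("<omm_params> V=%.3f l/kg GEZI_D=%.4g SI_D=%.3g ",
                     "p2=%.3g SI_P=%.3g p2P=%.3g GE_P=%.3g\n",
                     "  G_b=%.2f mmol/l I_b=%.1f pmol/l EGP_b=%.4g ",
                     "mmol/kg/min, dose %.1f mmol\n"),
              x$V, x$GEZI_D, x$SI_D, x$p2, x$SI_P, x$p2P, x$GE_P,
              x$G_b, x$I_b, x$EGP_b, x$gi$D))
  invisible(x)
}

#' Forward-simulate the oral minimal model
#'
#' Integrates the coupled gastrointestinal/glucose/remote-insulin system
#' with insulin as a known input (linear interpolation between samples,
#' constant extrapolation before the first sample):
#' \deqn{X' = -p_2 (X - SI_D (I - I_b))}
#' \deqn{X_P' = -p_{2P} (X_P - SI_P (I - I_b))}
#' \deqn{G_{exo}' = -(GEZI_D + X) G_{exo} + Ra(t)/V}
#' \deqn{EGP = EGP_b \max(0,\, 1 - GE_P (G - G_b) - X_P)}
#' \deqn{G_{endo}' = -(GEZI_D + X) G_{endo} + EGP/V}
#' with \eqn{G = G_{exo} + G_{endo}} and disposal
#' \eqn{R_d = (GEZI_D + X) G V}. The dose enters the stomach at t = 0.
#' Production is floored at zero; it can never be negative.
#'
#' @param params an [omm_params].
#' @param insulin [hf_ts] of (composite active) insulin, pmol/l; its grid
#'   must extend to the end of the simulation window.
#' @param body_weight kg.
#' @param times requested sampling grid (minutes; may include pre-dose
#'   times). Integration starts at `min(times)` from the basal state.
#' @param dense if `TRUE` (default) trajectories are solved and returned on
#'   an internal 0.5-min grid and summary scalars are computed; if `FALSE`
#'   only the sampled predictions are returned (used inside fitting loops).
#' @param config an `hf_config`.
#' @return a list of class `flux_trajectories`: `G_exo`, `G_endo`, `EGP`,
#'   `EGP_over_basal`, `Rd`, `Rd_over_basal` (dense [hf_ts]), `absorption`
#'   (an `absorption_trajectories`), `sampled` (list with `G_exo`, `G_endo`
#'   at `times`) and `scalars` (named vector: iAUC(Ra)/dose at 60/180,
#'   relative-iAUC summaries of Rd and EGP, fractional EGP suppression at
#'   60/180, Rd fractional increase, `t50`).
#' @export
simulate_omm <- function(params, insulin, body_weight, times,
                         dense = TRUE, config = default_config()) {
  stopifnot(inherits(params, "omm_params"), inherits(insulin, "hf_ts"))
  t0 <- min(times); t_end <- max(times)
  if (max(insulin$times) < t_end - 1e-9)
    stop("simulate_omm: insulin grid ends at ", max(insulin$times),
         " min, before the simulation window end (", t_end, " min)",
         call. = FALSE)
  fI <- stats::approxfun(insulin$times, insulin$values, rule = 2)
  gi <- params$gi
  has_dose <- gi$D > 0 && t_end > 0

  t_start <- if (has_dose) min(t0, 0) else t0
  grid <- if (dense) {
    sort(unique(c(seq(t_start, t_end, by = config$dense_dt), t_end, 0, times)))
  } else sort(unique(c(t_start, 0, times)))
  grid <- grid[grid >= t_start]

  rhs <- function(t, y, p) {
    I <- fI(t)
    di <- I - p$I_b
    ke <- k_empt(y[1], p$gi)
    ra <- p$gi$f_bio * p$gi$k_abs * y[2] / body_weight
    G <- y[5] + y[6]
    egp <- p$EGP_b * max(0, 1 - p$GE_P * (G - p$G_b) - y[4])
    list(c(
      qsto = -ke * y[1],
      qgut = ke * y[1] - p$gi$k_abs * y[2],
      X = -p$p2 * (y[3] - p$SI_D * di),
      XP = -p$p2P * (y[4] - p$SI_P * di),
      Gexo = -(p$GEZI_D + y[3]) * y[5] + ra / p$V,
      Gendo = -(p$GEZI_D + y[3]) * y[6] + egp / p$V))
  }
  y0 <- c(qsto = 0, qgut = 0, X = 0, XP = 0, Gexo = 0, Gendo = params$G_b)
  ev <- if (has_dose)
    list(data = data.frame(var = "qsto", time = 0, value = gi$D,
                           method = "add")) else NULL
  sol <- deSolve::lsoda(y0, grid, rhs, params,
                        rtol = config$ode_rtol, atol = config$ode_atol, maxsteps = 20000,
                        events = ev)
  if (attr(sol, "istate")[1] < 0)
    stop("simulate_omm: solver failure (istate = ", attr(sol, "istate")[1],
         ")", call. = FALSE)
  if (min(sol[, "Gexo"]) < -1e-6 || min(sol[, "Gendo"]) < -1e-6)
    stop("simulate_omm: negative glucose state encountered (min G_exo = ",
         signif(min(sol[, "Gexo"]), 3), ", min G_endo = ",
         signif(min(sol[, "Gendo"]), 3), "); check parameters",
         call. = FALSE)

  tg <- sol[, "time"]
  gexo <- pmax(sol[, "Gexo"], 0); gendo <- pmax(sol[, "Gendo"], 0)
  sample_at <- function(v, tt) stats::approx(tg, v, xout = tt, rule = 2)$y
  sampled <- list(
    G_exo = hf_ts(times, sample_at(gexo, times), "mmol/l",
                  "exogenous glucose (model)"),
    G_endo = hf_ts(times, sample_at(gendo, times), "mmol/l",
                   "endogenous glucose (model)"))
  if (!dense)
    return(structure(list(sampled = sampled), class = "flux_trajectories"))

  G <- gexo + gendo
  X <- sol[, "X"]; XP <- sol[, "XP"]
  egp <- params$EGP_b * pmax(0, 1 - params$GE_P * (G - params$G_b) - XP)
  rd <- (params$GEZI_D + X) * G * params$V
  rd_b <- params$GEZI_D * params$G_b * params$V
  ra <- gi$f_bio * gi$k_abs * pmax(sol[, "qgut"], 0) / body_weight
  gr <- if (gi$D > 0) pmax(sol[, "qsto"], 0) / gi$D else rep(1, length(tg))
  # the solver reports the pre-event state at the ingestion instant;
  # by definition the whole dose is in the stomach at t = 0
  if (has_dose) gr[tg == 0] <- 1

  post <- tg >= 0
  gr_ts <- hf_ts(tg[post], gr[post], "dimensionless", "gastric retention")
  ra_ts <- hf_ts(tg[post], ra[post], "mmol/kg/min", "meal rate of appearance")
  t50 <- if (gi$D > 0) compute_t50(gr_ts) else NA_real_
  appeared <- function(tt) {
    if (gi$D <= 0 || tt > t_end) return(NA_real_)
    idx <- tg >= 0 & tg <= tt
    trapz(tg[idx], ra[idx]) * body_weight / gi$D
  }
  absorption <- structure(list(
    GR = gr_ts, Ra = ra_ts, GR_dense = gr_ts, Ra_dense = ra_ts, t50 = t50,
    fraction_appeared_60 = appeared(60),
    fraction_appeared_180 = appeared(180)), class = "absorption_trajectories")

  egp_rel <- hf_ts(tg, egp / params$EGP_b, "dimensionless", "EGP/EGP_b")
  rd_rel <- hf_ts(tg, rd / rd_b, "dimensionless", "Rd/Rd_b")
  win180 <- c(0, min(180, t_end)); win60 <- c(0, min(60, t_end))
  scalars <- c(
    ra_iauc_dose_60 = appeared(60),
    ra_iauc_dose_180 = appeared(180),
    iauc_egp_rel_180 = iauc_value(egp_rel, win180, baseline_value = 1),
    iauc_rd_rel_180 = iauc_value(rd_rel, win180, baseline_value = 1),
    egp_suppression_60 = egp_suppression(egp_rel, win60),
    egp_suppression_180 = egp_suppression(egp_rel, win180),
    rd_increase_180 = rd_fractional_increase(rd_rel, win180),
    t50 = t50)

  structure(list(
    G_exo = hf_ts(tg, gexo, "mmol/l", "exogenous glucose (model)"),
    G_endo = hf_ts(tg, gendo, "mmol/l", "endogenous glucose (model)"),
    EGP = hf_ts(tg, egp, "mmol/kg/min", "endogenous glucose production"),
    EGP_over_basal = egp_rel,
    Rd = hf_ts(tg, rd, "mmol/kg/min", "glucose disposal"),
    Rd_over_basal = rd_rel,
    absorption = absorption, sampled = sampled, scalars = scalars
  ), class = "flux_trajectories")
}

#' Fractional suppression of endogenous glucose production
#'
#' One minus the time-average of EGP relative to basal over a window;
#' equivalently the negative incremental AUC of EGP/EGP_b (baseline 1)
#' divided by the window width.
#'
#' @param egp_over_basal [hf_ts] of EGP/EGP_b (dimensionless).
#' @param window `c(t_start, t_end)` in minutes, within the series support.
#' @return suppression fraction (0 = no suppression, 1 = complete).
#' @export
egp_suppression <- function(egp_over_basal, window) {
  check_window(egp_over_basal, window)
  1 - window_mean(egp_over_basal, window)
}

#' Fractional increase of glucose disposal
#'
#' Time-average of Rd relative to basal over a window, minus one: the
#' mirror-image summary of [egp_suppression()].
#'
#' @param rd_over_basal [hf_ts] of Rd/Rd_b.
#' @param window `c(t_start, t_end)` in minutes.
#' @return fractional increase above basal disposal.
#' @export
rd_fractional_increase <- function(rd_over_basal, window) {
  check_window(rd_over_basal, window)
  window_mean(rd_over_basal, window) - 1
}

check_window <- function(x, window) {
  stopifnot(inherits(x, "hf_ts"))
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be c(t_start, t_end) with t_end > t_start",
         call. = FALSE)
  if (window[1] < min(x$times) - 1e-9 || window[2] > max(x$times) + 1e-9)
    stop(sprintf("window [%g, %g] outside series support [%g, %g]",
                 window[1], window[2], min(x$times), max(x$times)),
         call. = FALSE)
  invisible(TRUE)
}

# trapezoidal time-average over a window, interpolating at the endpoints
window_mean <- function(x, window) {
  tt <- sort(unique(c(window, x$times[x$times > window[1] &
                                        x$times < window[2]])))
  vv <- ts_interp(x, tt)
  trapz(tt, vv) / (window[2] - window[1])
}

#' Basal-insulin glucose effectiveness for disposal
#'
#' Derived summary `GE_D = GEZI_D + SI_D * I_b`: glucose effectiveness at
#' the subject's basal (not zero) insulin. Reported alongside the fixed
#' `GEZI_D` so the zero-insulin and basal-insulin conventions are not
#' conflated.
#'
#' @param params an [omm_params].
#' @return GE_D in min^-1.
#' @export
report_ge_disposal <- function(params) {
  stopifnot(inherits(params, "omm_params"))
  params$GEZI_D + params$SI_D * params$I_b
}
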