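#' Subcutaneous insulin kinetic parameters
#'
#' Two-compartment subcutaneous depot with dual absorption routes: a bolus
#' enters the first depot compartment, from which insulin is either absorbed
#' directly into plasma (`k_a1`) or transferred (`k_d`) to a second
#' compartment absorbed at `k_a2`; plasma insulin is eliminated at `k_e`
#' towards its basal level.
#'
#' @param k_d depot transfer rate, min^-1.
#' @param k_a1,k_a2 absorption rates of the two routes, min^-1.
#' @param k_e plasma elimination rate, min^-1.
#' @param V_I insulin distribution volume, l/kg.
#' @param F bioavailability fraction, `0 < F <= 1`.
#' @param I_b basal plasma insulin, pmol/l (>= 0).
#' @return an object of class `sc_params`.
#' @export
sc_params <- function(k_d, k_a1, k_a2, k_e, V_I = 0.12, F = 0.8, I_b = 0) {
  p <- list(k_d = k_d, k_a1 = k_a1, k_a2 = k_a2, k_e = k_e,
            V_I = V_I, F = F, I_b = I_b)
  if (any(!vapply(p, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("sc_params: all parameters must be finite numbers", call. = FALSE)
  if (k_d < 0 || k_a1 <= 0 || k_a2 <= 0 || k_e <= 0 || V_I <= 0)
    stop("sc_params: rates and volume must be positive (k_d may be 0)",
         call. = FALSE)
  if (F <= 0 || F > 1) stop("sc_params: need 0 < F <= 1", call. = FALSE)
  if (I_b < 0) stop("sc_params: I_b must be >= 0", call. = FALSE)
  structure(p, class = "sc_params")
}

#' Simulate plasma insulin after subcutaneous boluses
#'
#' Forward-solves the depot model for a list of bolus injections and returns
#' the plasma fast-acting insulin concentration on the requested grid.
#' Doses are in insulin units (1 U = 6000 pmol); concentrations in pmol/l.
#'
#' The system is linear, so responses to multiple boluses superpose and the
#' area above basal of one bolus equals
#' \eqn{F \cdot dose / (k_e V_I BW)} (mass balance).
#'
#' @param params an [sc_params].
#' @param boluses list of `list(time = min, dose = U)` (dose >= 0).
#' @param times requested output grid, minutes.
#' @param body_weight kg.
#' @param config an `hf_config`.
#' @return an [hf_ts] in pmol/l on `times`.
#' @export
simulate_sc_fast <- function(params, boluses, times, body_weight,
                             config = default_config()) {
  stopifnot(inherits(params, "sc_params"))
  doses <- vapply(boluses, function(b) as.numeric(b$dose), numeric(1))
  btimes <- vapply(boluses, function(b) as.numeric(b$time), numeric(1))
  if (any(doses < 0)) stop("simulate_sc_fast: doses must be >= 0",
                           call. = FALSE)
  if (length(btimes) && any(btimes > max(times)))
    warning("simulate_sc_fast: bolus after the last requested time ",
            "contributes nothing to the output window")
  if (!length(boluses) || all(doses == 0))
    return(hf_ts(times, rep(params$I_b, length(times)), "pmol/l",
                 "plasma fast-acting insulin"))

  t0 <- min(times[1], btimes)
  grid <- sort(unique(c(seq(t0, max(times), by = config$dense_dt),
                        max(times), times, btimes)))
  rhs <- function(t, y, p) {
    list(c(-(p$k_a1 + p$k_d) * y[1],
           p$k_d * y[1] - p$k_a2 * y[2],
           -p$k_e * (y[3] - p$I_b) +
             p$F * (p$k_a1 * y[1] + p$k_a2 * y[2]) / (p$V_I * body_weight)))
  }
  ev <- data.frame(var = "q1", time = btimes, value = doses * 6000,
                   method = "add")
  ev <- ev[ev$value > 0, , drop = FALSE]
  sol <- deSolve::lsoda(c(q1 = 0, q2 = 0, I = params$I_b), grid, rhs, params,
                        rtol = config$ode_rtol, atol = config$ode_atol, maxsteps = 20000,
                        events = list(data = ev))
  vals <- stats::approx(sol[, "time"], sol[, "I"], xout = times, rule = 2)$y
  hf_ts(times, pmax(vals, 0), "pmol/l", "plasma fast-acting insulin")
}

#' Fit the subcutaneous insulin model to measured concentrations
#'
#' Weighted least squares against measured fast-acting insulin, with known
#' bolus timing and dosing. By default the four rate constants are free and
#' `V_I`, `F`, `I_b` are fixed (only the ratio F/V_I is identifiable from
#' concentration data, so volume and bioavailability come from the
#' configuration). Weighting is proportional (constant CV) by default.
#'
#' Setting `lower == upper` for a parameter holds it fixed at that value.
#'
#' @param measured [hf_ts] of plasma fast-acting insulin, pmol/l.
#' @param boluses list of `list(time, dose)`, dose in U; at least one
#'   positive dose.
#' @param init an [sc_params] initial guess.
#' @param body_weight kg.
#' @param options list: `free` (names among k_d, k_a1, k_a2, k_e), `lower`,
#'   `upper` named bound vectors, `weighting` ("proportional" or "constant"),
#'   `maxiter`.
#' @param config an `hf_config`.
#' @return list of class `sc_fit` with `params` ([sc_params]), `fitted`
#'   ([hf_ts] at the measured times), `rss` (weighted), `cv` (asymptotic
#'   fractional SE per free parameter), `converged`, `message`.
#' @export
fit_sc_model <- function(measured, boluses, init, body_weight,
                         options = list(), config = default_config()) {
  stopifnot(inherits(measured, "hf_ts"), inherits(init, "sc_params"))
  doses <- vapply(boluses, function(b) as.numeric(b$dose), numeric(1))
  if (!length(boluses) || all(doses == 0))
    stop("fit_sc_model: all-zero doses; kinetic parameters are not ",
         "identifiable without an input", call. = FALSE)
  first_bolus <- min(vapply(boluses, function(b) b$time, numeric(1)))
  n_post <- sum(measured$times > first_bolus)
  free <- options$free %||% c("k_d", "k_a1", "k_a2", "k_e")
  lower <- rep(1e-6, length(free)); names(lower) <- free
  upper <- rep(5, length(free)); names(upper) <- free
  lower["k_d"] <- 0
  if (!is.null(options$lower)) lower[names(options$lower)] <- options$lower
  if (!is.null(options$upper)) upper[names(options$upper)] <- options$upper
  if (n_post < 5L)
    stop("fit_sc_model: need at least 5 post-bolus samples", call. = FALSE)
  if (sum(lower < upper) > n_post)
    stop("fit_sc_model: more free parameters than post-bolus samples",
         call. = FALSE)
  weighting <- options$weighting %||% config$fit_weighting
  w <- if (weighting == "proportional") {
    floor_ <- 0.05 * max(abs(measured$values))
    1 / pmax(abs(measured$values), floor_)
  } else rep(1, length(measured$values))

  p0 <- unlist(unclass(init)[free])
  resid_fn <- function(p) {
    par <- init
    par[free] <- as.list(pmin(pmax(p, lower), upper))
    sim <- try(simulate_sc_fast(par, boluses, measured$times, body_weight,
                                config), silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(measured$values)))
    w * (sim$values - measured$values)
  }
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = options$maxiter %||% config$fit_maxiter,
    ftol = config$fit_ftol, ptol = 1e-12,
    epsfcn = 1e-6)  # forward-difference step ~1e-3 relative, well above
                    # the ODE solver tolerance so Jacobians are not noise
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl)
  est <- pmin(pmax(fit$par, lower), upper)
  out <- init; out[free] <- as.list(est)
  out <- do.call(sc_params, unclass(out))
  fitted <- simulate_sc_fast(out, boluses, measured$times, body_weight,
                             config)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit_sc_model: optimiser did not converge (", fit$message, ")")
  cv <- asymptotic_cv(fit, est, lower, upper)
  structure(list(params = out, fitted = fitted,
                 rss = sum(fit$fvec^2), cv = cv,
                 converged = converged, message = fit$message,
                 free = free), class = "sc_fit")
}

# asymptotic fractional standard errors from the LM Jacobian; NA where the
# estimate sits on a bound or the information matrix is singular
asymptotic_cv <- function(fit, est, lower, upper) {
  free_idx <- which(lower < upper)
  cv <- rep(NA_real_, length(est)); names(cv) <- names(est)
  dof <- length(fit$fvec) - length(free_idx)
  if (dof <= 0) return(cv)
  s2 <- sum(fit$fvec^2) / dof
  h <- try(solve(fit$hessian), silent = TRUE)
  if (inherits(h, "try-error")) return(cv)
  se <- sqrt(pmax(diag(h) * s2, 0))
  cv[] <- ifelse(abs(est) > 0, se / abs(est), NA_real_)
  cv[lower >= upper] <- NA_real_
  cv
}

#' Composite active insulin
#'
#' Superimposes the free-active fraction of a circulating long-acting
#' analogue onto the fast-acting insulin concentration, producing the total
#' active insulin profile used as the known input of the glucose model.
#' Established free-active fractions: glargine 100%, detemir 25%, degludec
#' 2.85%; `analogue = "none"` contributes nothing.
#'
#' @param fast [hf_ts] fast-acting insulin, pmol/l.
#' @param long_conc [hf_ts] long-acting analogue concentration, pmol/l
#'   (interpolated onto the fast grid if sampled differently).
#' @param analogue analogue name, or `"none"`.
#' @param fractions named active-fraction map (defaults from the config).
#' @return [hf_ts] composite active insulin on the fast grid.
#' @export
composite_active_insulin <- function(fast, long_conc, analogue,
                                     fractions =
                                       default_config()$active_fractions) {
  stopifnot(inherits(fast, "hf_ts"))
  if (analogue == "none")
    return(hf_ts(fast$times, fast$values, "pmol/l", "composite active insulin"))
  if (!analogue %in% names(fractions))
    stop("composite_active_insulin: unknown analogue '", analogue,
         "'; known: ", paste(names(fractions), collapse = ", "),
         call. = FALSE)
  phi <- fractions[[analogue]]
  lv <- ts_interp(long_conc, fast$times)
  hf_ts(fast$times, fast$values + phi * lv, "pmol/l",
        "composite active insulin")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
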