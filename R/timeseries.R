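#' Longitudinal measurement series
#'
#' `hf_ts()` builds the elementary container used throughout the package: a
#' sampled time course on a grid of minutes relative to T0 (the start of dose
#' ingestion; negative times are pre-dose). Every physiological channel —
#' plasma glucose, tracer/tracee ratio, insulin, glucagon, spectral
#' amplitudes, model-derived fluxes — is carried in this form.
#'
#' @param times numeric, minutes relative to T0, strictly increasing.
#' @param values numeric, same length as `times`, finite.
#' @param unit declared unit; one of `"mmol/l"`, `"pmol/l"`, `"ratio"`,
#'   `"a.u."`, `"mmol/l/min"`, `"mmol/kg/min"`, `"dimensionless"`.
#' @param label free-text channel description.
#' @return an object of class `hf_ts`.
#' @export
hf_ts <- function(times, values, unit, label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 1L) stop("hf_ts: need at least one sample", call. = FALSE)
  if (length(times) != length(values))
    stop("hf_ts: times and values must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("hf_ts: times and values must be finite", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("hf_ts: times must be strictly increasing", call. = FALSE)
  if (!unit %in% hf_units())
    stop(sprintf("hf_ts: unknown unit '%s' (known: %s)", unit,
                 paste(hf_units(), collapse = ", ")), call. = FALSE)
  structure(list(times = times, values = values, unit = unit,
                 label = as.character(label)[1]),
            class = "hf_ts")
}

hf_units <- function() {
  c("mmol/l", "pmol/l", "ratio", "a.u.", "mmol/l/min", "mmol/kg/min",
    "dimensionless")
}

#' @export
print.hf_ts <- function(x, ...) {
  cat(sprintf("<hf_ts> %s [%s], %d samples, t = %g..%g min\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$unit, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.hf_ts <- function(x, ...) {
  data.frame(time_min = x$times, value = x$values, unit = x$unit,
             stringsAsFactors = FALSE)
}

#' @export
length.hf_ts <- function(x) length(x$times)

#' Evaluate a series at arbitrary times
#'
#' Linear interpolation between samples; constant extrapolation beyond the
#' first/last sample. This is the convention used to feed sparsely sampled
#' insulin into the glucose model as a continuous known input.
#'
#' @param x an [hf_ts].
#' @param t numeric vector of times (minutes).
#' @param rule passed through; default constant extrapolation at both ends.
#' @return numeric vector of interpolated values.
#' @export
ts_interp <- function(x, t, rule = 2) {
  stopifnot(inherits(x, "hf_ts"))
  if (length(x$times) == 1L) return(rep(x$values, length(t)))
  stats::approx(x$times, x$values, xout = t, rule = rule)$y
}

#' Restrict a series to a time window
#' @param x an [hf_ts].
#' @param from,to window bounds in minutes (inclusive).
#' @return an [hf_ts] on the retained samples.
#' @export
ts_window <- function(x, from = -Inf, to = Inf) {
  keep <- x$times >= from & x$times <= to
  if (!any(keep)) stop("ts_window: no samples in window", call. = FALSE)
  hf_ts(x$times[keep], x$values[keep], x$unit, x$label)
}

#' Study sampling grids
#'
#' The measurement schedules of the emulated protocol, in minutes relative
#' to dose ingestion: venous blood sampling at T-60, 0, 10, 20, 30, 60, 90,
#' 120, 150 and 180; glucagon on its sparser designed subset; interleaved
#' MR acquisitions every 10 min (extended to 180 so the reported 0-180
#' incremental AUCs of the imaging channels are computable).
#'
#' @return numeric vector of sampling times (minutes).
#' @export
blood_grid <- function() c(-60, 0, 10, 20, 30, 60, 90, 120, 150, 180)

#' @rdname blood_grid
#' @export
glucagon_grid <- function() c(0, 10, 30, 60, 120, 180)

#' @rdname blood_grid
#' @export
mr_grid <- function() seq(0, 180, by = 10)
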