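#' Analysis configuration
#'
#' Central bag of constants and options shared by the quantification and
#' modelling stages. Every entry can be overridden via [load_config()] or by
#' passing a modified list.
#'
#' @details Key entries:
#' * `tracer_purity` — isotopic purity of the ingested tracer (fraction,
#'   default 0.99).
#' * `water_reference_conc` — assumed hepatic natural-abundance
#'   mono-deuterated water concentration used as the internal reference for
#'   deuterium imaging, mmol/l (default 8.94).
#' * `deuterons_per_glucose`, `deuterons_per_water` — deuteron multiplicities
#'   used for per-deuteron amplitude normalisation (defaults 2 and 1; the
#'   tracer carries two deuterons at C6, semi-heavy water one).
#' * `gezi_disposal_healthy` — population value of disposal glucose
#'   effectiveness at zero insulin, min^-1; fixed (not fitted) for
#'   identifiability. Default 0.0145 min^-1 lies in the range reported for
#'   healthy adults by minimal-model studies.
#' * `gezi_t1d_scale` — proportional adjustment of the population GEZI for
#'   the diabetes group (default 0.5).
#' * `active_fractions` — free-active fractions of long-acting insulin
#'   analogues superimposed onto fast-acting insulin: glargine 1.00,
#'   detemir 0.25, degludec 0.0285.
#' * `glucose_molar_mass` — 180.156 g/mol, used for the gram-to-mmol dose
#'   conversion (isotope mass difference ignored, <1.2%).
#' * `ratio_convention` — `"ttr"` (tracer-to-tracee molar ratio, default) or
#'   `"mpe"` (mole percent excess) for the partition arithmetic.
#' * `noise_cv` — per-channel measurement coefficients of variation used by
#'   the synthetic generator.
#' * solver/fit tolerances and the default RNG seed.
#'
#' @return a named list of class `hf_config`.
#' @export
default_config <- function() {
  structure(list(
    tracer_purity = 0.99,
    natural_abundance_ratio = 0,
    ratio_convention = "ttr",
    water_reference_conc = 8.94,
    deuterons_per_glucose = 2L,
    deuterons_per_water = 1L,
    gezi_disposal_healthy = 0.02,
    gezi_t1d_scale = 0.5,
    active_fractions = c(glargine = 1.00, detemir = 0.25, degludec = 0.0285),
    glucose_molar_mass = 0.180156,   # g/mmol
    units_per_pmol = 1 / 6000,       # 1 U = 6000 pmol insulin
    noise_cv = c(glucose_total = 0.02, ratio = 0.02, insulin_fast = 0.06,
                 insulin_long = 0.06, glucagon = 0.10, dmi_glc = 0.08,
                 c13_glycogen = 0.10),
    ode_rtol = 1e-8,
    ode_atol = 1e-8,
    dense_dt = 0.5,                  # min, internal reporting grid
    fit_maxiter = 300L,
    fit_ftol = 1e-12,
    fit_weighting = "proportional",  # or "constant"
    t_test_var_equal = TRUE,
    seed = 1L,
    log_level = "info"
  ), class = "hf_config")
}

#' Load a configuration file
#'
#' Reads a JSON (or YAML, if the \pkg{yaml} package is installed) file whose
#' entries override [default_config()]. Unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @return an `hf_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ov <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(ov)) {
    v <- ov[[k]]
    if (k == "active_fractions") v <- unlist(v)
    cfg[[k]] <- v
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$tracer_purity > 0, cfg$tracer_purity <= 1,
            all(cfg$active_fractions >= 0), all(cfg$active_fractions <= 1),
            cfg$ode_rtol > 0, cfg$ode_atol > 0, cfg$dense_dt > 0,
            cfg$water_reference_conc > 0,
            cfg$deuterons_per_glucose >= 1, cfg$deuterons_per_water >= 1,
            cfg$ratio_convention %in% c("ttr", "mpe"))
  invisible(cfg)
}

#' Minimal timestamped logger
#'
#' Writes level-tagged messages to `stderr` (and optionally a file). Levels:
#' debug < info < warn < error; messages below the configured level are
#' dropped.
#'
#' @param level message level.
#' @param ... message parts, pasted.
#' @param config an `hf_config` (for the threshold).
#' @param file optional path appended to.
#' @return invisibly, the formatted line (or `NULL` if suppressed).
#' @export
hf_log <- function(level = c("info", "debug", "warn", "error"), ...,
                   config = default_config(), file = NULL) {
  level <- match.arg(level)
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[[level]] < ranks[[config$log_level]]) return(invisible(NULL))
  line <- sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(..., collapse = ""))
  cat(line, "\n", file = stderr(), sep = "")
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
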