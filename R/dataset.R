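#' Glycogen calibration record
#'
#' Phantom-replacement calibration for natural-abundance carbon-13 liver
#' glycogen quantification: an external phantom of known concentration plus
#' multiplicative corrections for coil-to-liver distance, coil loading, T1
#' relaxation and nuclear Overhauser enhancement.
#'
#' @param phantom_concentration phantom glycogen (glucosyl-unit) conc, mmol/l.
#' @param phantom_amplitude fitted phantom peak amplitude, a.u.
#' @param f_distance,f_loading,f_T1,f_NOE dimensionless correction factors
#'   (all > 0).
#' @return an object of class `glycogen_calibration`.
#' @export
glycogen_calibration <- function(phantom_concentration, phantom_amplitude,
                                 f_distance = 1, f_loading = 1,
                                 f_T1 = 1, f_NOE = 1) {
  x <- list(phantom_concentration = phantom_concentration,
            phantom_amplitude = phantom_amplitude,
            f_distance = f_distance, f_loading = f_loading,
            f_T1 = f_T1, f_NOE = f_NOE)
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num) || any(unlist(x) <= 0))
    stop("glycogen_calibration: all entries must be positive numbers",
         call. = FALSE)
  structure(x, class = "glycogen_calibration")
}

#' One participant's complete dataset
#'
#' Bundles subject metadata with every measured time series of the
#' postprandial tracer study: plasma channels on the venous sampling grid,
#' per-voxel hepatic deuterated-glucose amplitudes and glycogen amplitudes
#' on the MR grid, and the calibration needed to quantify them.
#'
#' @param subject_id character id.
#' @param group `"healthy"` or `"t1d"`.
#' @param subgroup_hint generating subgroup if known: `"none"`, `"1"`, `"2"`.
#' @param body_weight kg (> 0).
#' @param height m.
#' @param dose_grams grams of the dideuterated glucose dose (0 allowed for
#'   null experiments).
#' @param bolus_events list of `list(time = min, dose = U, analogue = name)`
#'   fast-acting insulin boluses.
#' @param basal_analogue `"none"`, `"glargine"`, `"detemir"` or `"degludec"`.
#' @param plasma_total_glucose,plasma_ratio,plasma_insulin_fast,plasma_insulin_long,plasma_glucagon
#'   [hf_ts] channels (glucagon may sit on its sparser grid).
#' @param hepatic_dglc_amplitudes list of per-voxel [hf_ts] amplitude series.
#' @param water_reference_amplitude pre-ingestion semi-heavy-water amplitude,
#'   a.u. (scalar, voxel-averaged).
#' @param glycogen_amplitudes [hf_ts] of glycogen peak amplitudes.
#' @param glycogen_cal a [glycogen_calibration].
#' @param config an `hf_config`, used for the gram-to-mmol dose conversion.
#' @return an object of class `subject_dataset`; `dose_mmol` is derived as
#'   `dose_grams / glucose_molar_mass`.
#' @export
subject_dataset <- function(subject_id, group, subgroup_hint = "none",
                            body_weight, height = NA_real_, dose_grams,
                            bolus_events = list(), basal_analogue = "none",
                            plasma_total_glucose, plasma_ratio,
                            plasma_insulin_fast, plasma_insulin_long,
                            plasma_glucagon,
                            hepatic_dglc_amplitudes,
                            water_reference_amplitude,
                            glycogen_amplitudes, glycogen_cal,
                            config = default_config()) {
  if (!group %in% c("healthy", "t1d"))
    stop("subject_dataset: group must be 'healthy' or 't1d'", call. = FALSE)
  if (!basal_analogue %in% c("none", names(config$active_fractions)))
    stop("subject_dataset: unknown basal analogue '", basal_analogue, "'",
         call. = FALSE)
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("subject_dataset: body_weight must be > 0", call. = FALSE)
  if (dose_grams < 0) stop("subject_dataset: dose_grams must be >= 0",
                           call. = FALSE)
  ds <- structure(list(
    subject_id = as.character(subject_id),
    group = group,
    subgroup_hint = as.character(subgroup_hint),
    body_weight = body_weight,
    height = height,
    dose_grams = dose_grams,
    dose_mmol = dose_grams / config$glucose_molar_mass,
    bolus_events = bolus_events,
    basal_analogue = basal_analogue,
    plasma_total_glucose = plasma_total_glucose,
    plasma_ratio = plasma_ratio,
    plasma_insulin_fast = plasma_insulin_fast,
    plasma_insulin_long = plasma_insulin_long,
    plasma_glucagon = plasma_glucagon,
    hepatic_dglc_amplitudes = hepatic_dglc_amplitudes,
    water_reference_amplitude = water_reference_amplitude,
    glycogen_amplitudes = glycogen_amplitudes,
    glycogen_cal = glycogen_cal
  ), class = "subject_dataset")
  ds
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s (%s%s), %.1f kg, dose %.1f g (%.2f mmol)\n",
              x$subject_id, x$group,
              if (x$subgroup_hint != "none") paste0("/sub", x$subgroup_hint) else "",
              x$body_weight, x$dose_grams, x$dose_mmol))
  cat(sprintf("  boluses: %d; basal analogue: %s; voxels: %d\n",
              length(x$bolus_events), x$basal_analogue,
              length(x$hepatic_dglc_amplitudes)))
  invisible(x)
}

#' Validate a subject dataset
#'
#' Pure check of the dataset invariants; returns findings rather than
#' throwing, so a pipeline can log and decide. Glucagon being present only on
#' its sparser designed grid is not a finding.
#'
#' @param ds a [subject_dataset].
#' @return a data.frame with columns `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows when everything holds.
#' @export
validate_dataset <- function(ds) {
  sev <- character(0); msg <- character(0)
  add <- function(s, m) { sev <<- c(sev, s); msg <<- c(msg, m) }

  if (!is.numeric(ds$body_weight) || ds$body_weight <= 0)
    add("error", "body_weight must be > 0")
  if (ds$dose_grams < 0) add("error", "dose_grams must be >= 0")

  chans <- c("plasma_total_glucose", "plasma_ratio", "plasma_insulin_fast",
             "plasma_insulin_long", "plasma_glucagon", "glycogen_amplitudes")
  for (ch in chans) {
    x <- ds[[ch]]
    if (!inherits(x, "hf_ts")) { add("error", paste0(ch, " is not an hf_ts")); next }
    if (length(x$times) > 1L && any(diff(x$times) <= 0))
      add("error", paste0(ch, ": times not strictly increasing"))
    if (any(!is.finite(x$values)))
      add("error", paste0(ch, ": non-finite values"))
  }

  nv <- length(ds$hepatic_dglc_amplitudes)
  if (nv < 1L) add("error", "no hepatic voxel amplitude series")
  if (nv >= 1L && nv != 6L)
    add("warning", sprintf(paste0("%d hepatic voxels supplied; the protocol ",
        "averages six central voxels"), nv))
  if (!is.numeric(ds$water_reference_amplitude) ||
      ds$water_reference_amplitude <= 0)
    add("error", "water_reference_amplitude must be > 0")

  if (ds$group == "t1d") {
    pre <- vapply(ds$bolus_events, function(b) isTRUE(b$time < 0), logical(1))
    if (!any(pre))
      add("warning", "no prandial bolus before T0 for a t1d subject")
  }
  data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
}

channel_units <- function() {
  c(glucose_total = "mmol/l", ratio = "ratio", insulin_fast = "pmol/l",
    insulin_long = "pmol/l", glucagon = "pmol/l", dmi_glc = "a.u.",
    c13_glycogen = "a.u.")
}

#' Write a subject dataset to disk
#'
#' Documented on-disk layout: a directory holding `meta.json` (metadata and
#' calibration) and `measurements.csv`, a tidy long table with columns
#' `time_min, channel, voxel, value, unit`. `voxel` is empty except for the
#' per-voxel `dmi_glc` channel.
#'
#' @param ds a [subject_dataset].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
save_subject <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    subject_id = ds$subject_id, group = ds$group,
    subgroup_hint = ds$subgroup_hint,
    body_weight = ds$body_weight, height = ds$height,
    dose_grams = ds$dose_grams,
    bolus_events = ds$bolus_events,
    basal_analogue = ds$basal_analogue,
    water_reference_amplitude = ds$water_reference_amplitude,
    glycogen_calibration = unclass(ds$glycogen_cal)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cu <- channel_units()
  row <- function(ts, channel, voxel = NA_integer_)
    data.frame(time_min = ts$times, channel = channel, voxel = voxel,
               value = ts$values, unit = ts$unit, stringsAsFactors = FALSE)
  tab <- rbind(
    row(ds$plasma_total_glucose, "glucose_total"),
    row(ds$plasma_ratio, "ratio"),
    row(ds$plasma_insulin_fast, "insulin_fast"),
    row(ds$plasma_insulin_long, "insulin_long"),
    row(ds$plasma_glucagon, "glucagon"),
    do.call(rbind, lapply(seq_along(ds$hepatic_dglc_amplitudes), function(v)
      row(ds$hepatic_dglc_amplitudes[[v]], "dmi_glc", v))),
    row(ds$glycogen_amplitudes, "c13_glycogen"))
  utils::write.csv(tab, file.path(dir, "measurements.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a subject dataset from disk
#'
#' Counterpart of [save_subject()]; round-trips all fields to declared float
#' precision. Unknown units and non-increasing grids are rejected.
#'
#' @param path dataset directory.
#' @param config an `hf_config`.
#' @return a validated [subject_dataset].
#' @export
load_dataset <- function(path, config = default_config()) {
  mpath <- file.path(path, "meta.json")
  cpath <- file.path(path, "measurements.csv")
  if (!file.exists(mpath)) stop("missing metadata file: ", mpath, call. = FALSE)
  if (!file.exists(cpath)) stop("missing measurements file: ", cpath, call. = FALSE)
  meta <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  req <- c("subject_id", "group", "body_weight", "dose_grams",
           "basal_analogue", "water_reference_amplitude",
           "glycogen_calibration")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("schema error: meta.json missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  reqc <- c("time_min", "channel", "voxel", "value", "unit")
  missc <- setdiff(reqc, names(tab))
  if (length(missc))
    stop("schema error: measurements.csv missing column(s): ",
         paste(missc, collapse = ", "), call. = FALSE)
  cu <- channel_units()
  bad <- setdiff(unique(tab$unit), hf_units())
  if (length(bad))
    stop("unit error: unknown unit(s) in measurements.csv: ",
         paste(bad, collapse = ", "), call. = FALSE)
  expected <- cu[tab$channel]
  wrong <- which(!is.na(expected) & expected != tab$unit)
  if (length(wrong))
    stop(sprintf(paste0("unit error: channel '%s' declared in '%s' but ",
                        "expected '%s' (no conversion is applied)"),
                 tab$channel[wrong[1]], tab$unit[wrong[1]],
                 expected[wrong[1]]), call. = FALSE)

  pull <- function(channel, label) {
    sub <- tab[tab$channel == channel, ]
    if (nrow(sub) == 0L)
      stop("schema error: measurements.csv has no rows for channel '",
           channel, "'", call. = FALSE)
    sub <- sub[order(sub$time_min), ]
    if (any(diff(sub$time_min) <= 0))
      stop("validation error: non-increasing times for channel '", channel,
           "'", call. = FALSE)
    hf_ts(sub$time_min, sub$value, cu[[channel]], label)
  }
  dmi <- tab[tab$channel == "dmi_glc", ]
  voxels <- sort(unique(dmi$voxel))
  vox_list <- lapply(voxels, function(v) {
    sub <- dmi[dmi$voxel == v, ]
    sub <- sub[order(sub$time_min), ]
    hf_ts(sub$time_min, sub$value, "a.u.", sprintf("hepatic D-Glc voxel %d", v))
  })
  gcal <- do.call(glycogen_calibration, meta$glycogen_calibration)
  subject_dataset(
    subject_id = meta$subject_id, group = meta$group,
    subgroup_hint = if (is.null(meta$subgroup_hint)) "none" else meta$subgroup_hint,
    body_weight = meta$body_weight,
    height = if (is.null(meta$height)) NA_real_ else as.numeric(meta$height),
    dose_grams = meta$dose_grams,
    bolus_events = lapply(meta$bolus_events, function(b)
      list(time = b$time, dose = b$dose, analogue = b$analogue)),
    basal_analogue = meta$basal_analogue,
    plasma_total_glucose = pull("glucose_total", "plasma total glucose"),
    plasma_ratio = pull("ratio", "plasma D-Glc/tracee molar ratio"),
    plasma_insulin_fast = pull("insulin_fast", "plasma fast-acting insulin"),
    plasma_insulin_long = pull("insulin_long", "plasma long-acting insulin"),
    plasma_glucagon = pull("glucagon", "plasma glucagon"),
    hepatic_dglc_amplitudes = vox_list,
    water_reference_amplitude = meta$water_reference_amplitude,
    glycogen_amplitudes = pull("c13_glycogen", "liver glycogen amplitude"),
    glycogen_cal = gcal,
    config = config
  )
}
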