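#' Hepatic deuterated-glucose concentration from imaging amplitudes
#'
#' Water-referenced quantification for deuterium metabolic imaging: each
#' voxel's glucose-peak amplitude is normalised per deuteron (the tracer
#' carries two deuterons, semi-heavy water one), ratioed against that
#' voxel's pre-ingestion natural-abundance water amplitude, and scaled by
#' the assumed hepatic semi-heavy-water concentration (8.94 mmol/l by
#' default). Voxels are averaged after per-voxel quantification, so voxel
#' order is irrelevant.
#'
#' @param voxel_amplitudes list of per-voxel [hf_ts] glucose-peak
#'   amplitudes, a.u., all on one grid, all values >= 0.
#' @param water_baseline_amplitude pre-ingestion water amplitude, a.u. (> 0).
#' @param config an `hf_config` supplying `water_reference_conc`,
#'   `deuterons_per_glucose`, `deuterons_per_water`.
#' @return [hf_ts] hepatic D-Glc concentration, mmol/l (mmol per selected
#'   volume; no vascular/hepatocellular partition is attempted).
#' @export
dglc_concentration <- function(voxel_amplitudes, water_baseline_amplitude,
                               config = default_config()) {
  if (!length(voxel_amplitudes))
    stop("dglc_concentration: need at least one voxel", call. = FALSE)
  if (!all(vapply(voxel_amplitudes, inherits, logical(1), "hf_ts")))
    stop("dglc_concentration: voxel amplitudes must be hf_ts", call. = FALSE)
  if (!is.numeric(water_baseline_amplitude) || water_baseline_amplitude <= 0)
    stop("dglc_concentration: water amplitude must be > 0", call. = FALSE)
  tref <- voxel_amplitudes[[1]]$times
  for (v in voxel_amplitudes) {
    if (!isTRUE(all.equal(v$times, tref, tolerance = 1e-9)))
      stop("dglc_concentration: voxel grids are misaligned", call. = FALSE)
    if (any(v$values < 0))
      stop("dglc_concentration: negative amplitude sample", call. = FALSE)
  }
  per_deuteron_water <- water_baseline_amplitude / config$deuterons_per_water
  conc <- vapply(voxel_amplitudes, function(v)
    (v$values / config$deuterons_per_glucose) / per_deuteron_water *
      config$water_reference_conc, numeric(length(tref)))
  conc <- if (is.matrix(conc)) rowMeans(conc) else mean(conc)
  hf_ts(tref, conc, "mmol/l", "hepatic D-Glc concentration")
}

#' Liver glycogen concentration from natural-abundance carbon-13 amplitudes
#'
#' Phantom-replacement quantification with the multiplicative correction
#' chain for coil-to-liver distance, coil loading, T1 relaxation and nuclear
#' Overhauser enhancement:
#' \deqn{C(t) = \frac{A(t)}{A_{phantom}} C_{phantom} f_{dist} f_{load} f_{T1} f_{NOE}}
#'
#' @param amplitudes [hf_ts] glycogen peak amplitudes, a.u., values >= 0.
#' @param cal a [glycogen_calibration].
#' @return [hf_ts] liver glycogen concentration, mmol/l (glucosyl units).
#' @export
glycogen_concentration <- function(amplitudes, cal) {
  stopifnot(inherits(amplitudes, "hf_ts"))
  if (!inherits(cal, "glycogen_calibration"))
    stop("glycogen_concentration: non-positive or invalid calibration",
         call. = FALSE)
  if (any(amplitudes$values < 0))
    stop("glycogen_concentration: negative amplitude sample", call. = FALSE)
  scale <- cal$phantom_concentration / cal$phantom_amplitude *
    cal$f_distance * cal$f_loading * cal$f_T1 * cal$f_NOE
  hf_ts(amplitudes$times, amplitudes$values * scale, "mmol/l",
        "liver glycogen concentration")
}
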