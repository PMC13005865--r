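#' Run the full per-subject analysis pipeline
#'
#' Executes, for one [subject_dataset], the complete analysis chain of the
#' study design: quantify hepatic D-Glc (water-referenced) and glycogen
#' (phantom-referenced); partition plasma glucose into exogenous and
#' endogenous series using the measured pre-dose baseline ratio and the
#' configured tracer purity; build the known active-insulin input (measured
#' insulin interpolated linearly for healthy subjects; a fitted
#' subcutaneous bolus model plus the active fraction of the long-acting
#' analogue for diabetes subjects); fit the oral minimal model with the
#' group's fixing rules; and compute the summary metrics.
#'
#' @param ds a [subject_dataset].
#' @param config an `hf_config`.
#' @param init optional [profile_spec] supplying initial parameter values
#'   for the fits; by default the built-in profile matching the subject's
#'   group (and `subgroup_hint`, when present) provides population starting
#'   values.
#' @return list of class `subject_analysis`: `quant` (hepatic D-Glc and
#'   glycogen [hf_ts]), `partition` ([partition_glucose] result),
#'   `insulin_exposure` (`fast_fit` (`NULL` for healthy), `composite`,
#'   `analogue`), `fit` (an `omm_fit`), `metrics` (named numeric vector,
#'   see [metric_manifest()]).
#' @export
analyze_subject <- function(ds, config = default_config(), init = NULL) {
  stopifnot(inherits(ds, "subject_dataset"))
  v <- validate_dataset(ds)
  if (any(v$severity == "error"))
    stop("analyze_subject: invalid dataset: ",
         paste(v$message[v$severity == "error"], collapse = "; "),
         call. = FALSE)

  if (is.null(init)) {
    init_name <- if (ds$group == "healthy") "healthy"
    else if (ds$subgroup_hint == "2") "t1d_sub2" else "t1d_sub1"
    init <- default_profile(init_name, config)
  }

  # --- quantification -----------------------------------------------------
  hep <- dglc_concentration(ds$hepatic_dglc_amplitudes,
                            ds$water_reference_amplitude, config)
  gly <- glycogen_concentration(ds$glycogen_amplitudes, ds$glycogen_cal)

  # --- tracer partition ----------------------------------------------------
  pre <- ds$plasma_ratio$times <= 0
  baseline_ratio <- mean(ds$plasma_ratio$values[pre])
  part <- partition_glucose(ds$plasma_total_glucose, ds$plasma_ratio,
                            baseline_ratio = baseline_ratio,
                            purity = config$tracer_purity,
                            convention = config$ratio_convention)

  # --- active insulin input ------------------------------------------------
  if (ds$group == "healthy") {
    insulin_input <- hf_ts(ds$plasma_insulin_fast$times,
                           ds$plasma_insulin_fast$values +
                             ds$plasma_insulin_long$values,
                           "pmol/l", "active insulin input")
    exposure <- list(fast_fit = NULL, composite = insulin_input,
                     analogue = "none")
  } else {
    sc_fit <- fit_sc_model(ds$plasma_insulin_fast, ds$bolus_events,
                           init = init$sc, body_weight = ds$body_weight,
                           config = config)
    dense <- seq(min(ds$plasma_insulin_fast$times), 180,
                 by = config$dense_dt)
    fast_dense <- simulate_sc_fast(sc_fit$params, ds$bolus_events, dense,
                                   ds$body_weight, config)
    insulin_input <- composite_active_insulin(fast_dense,
                                              ds$plasma_insulin_long,
                                              ds$basal_analogue,
                                              config$active_fractions)
    exposure <- list(fast_fit = sc_fit, composite = insulin_input,
                     analogue = ds$basal_analogue)
  }

  # --- oral minimal model fit ----------------------------------------------
  gezi <- config$gezi_disposal_healthy *
    if (ds$group == "t1d") config$gezi_t1d_scale else 1
  G_b <- part$endogenous$values[1]          # fasting, pre-bolus sample
  I_b <- ts_interp(insulin_input, min(insulin_input$times))
  gi0 <- init$omm$gi
  params0 <- omm_params(V = init$omm$V, GEZI_D = gezi,
                        SI_D = init$omm$SI_D, p2 = init$omm$p2,
                        SI_P = init$omm$SI_P, p2P = init$omm$p2P,
                        GE_P = if (ds$group == "t1d") 0 else init$omm$GE_P,
                        G_b = G_b, I_b = I_b,
                        gi = gi_params(gi0$k_max, gi0$k_min, gi0$k_abs,
                                       gi0$b, gi0$c, gi0$f_bio,
                                       D = ds$dose_mmol))
  fit <- fit_omm(part$exogenous, part$endogenous, insulin_input, params0,
                 ds$body_weight, options = list(group = ds$group),
                 config = config)

  metrics <- subject_metrics(ds, hep, gly, part, insulin_input, fit)
  structure(list(quant = list(hepatic_dglc = hep, glycogen = gly),
                 partition = part, insulin_exposure = exposure,
                 fit = fit, metrics = metrics),
            class = "subject_analysis")
}

#' Names of the per-subject summary metrics
#'
#' The fixed manifest of scalar outcomes every cohort report carries: the
#' basal/peak/nadir summaries of each measured channel, insulin exposure
#' windows (including the full T-60 to T180 interval), glucagon summaries,
#' the fitted sensitivity/effectiveness indices and the model-derived flux
#' summaries.
#'
#' @return character vector of metric names.
#' @export
metric_manifest <- function() {
  c("basal_glucose", "peak_glucose", "peak_glucose_time",
    "exo_peak", "exo_peak_time", "endo_nadir", "endo_nadir_time",
    "insulin_basal", "insulin_peak", "insulin_peak_time",
    "insulin_auc_0_60", "insulin_auc_0_180", "insulin_auc_all",
    "insulin_mean",
    "glucagon_t0", "glucagon_nadir", "glucagon_nadir_time",
    "glucagon_iauc_0_60", "glucagon_iauc_0_180", "glucagon_mean",
    "hepatic_dglc_peak", "hepatic_dglc_peak_time",
    "glycogen_basal", "glycogen_iauc_0_180",
    "si_disposal", "si_production", "ge_disposal", "ge_production",
    "gezi_disposal",
    "egp_suppression_0_60", "egp_suppression_0_180", "rd_increase_0_180",
    "t50_gr", "ra_iauc_dose_60", "ra_iauc_dose_180")
}

subject_metrics <- function(ds, hep, gly, part, insulin_input, fit) {
  total <- ds$plasma_total_glucose
  ins <- hf_ts(ds$plasma_insulin_fast$times,
               ds$plasma_insulin_fast$values + ds$plasma_insulin_long$values,
               "pmol/l", "plasma insulin")
  gcg <- ds$plasma_glucagon
  pn_tot <- peak_nadir(total); pn_exo <- peak_nadir(part$exogenous)
  pn_endo <- peak_nadir(part$endogenous); pn_ins <- peak_nadir(ins)
  pn_gcg <- peak_nadir(gcg); pn_hep <- peak_nadir(hep)
  auc <- function(x, w) {
    tt <- sort(unique(c(w, x$times[x$times > w[1] & x$times < w[2]])))
    trapz(tt, ts_interp(x, tt))
  }
  sc <- fit$fluxes$scalars
  c(basal_glucose = total$values[1],
    peak_glucose = pn_tot$peak_value, peak_glucose_time = pn_tot$peak_time,
    exo_peak = pn_exo$peak_value, exo_peak_time = pn_exo$peak_time,
    endo_nadir = pn_endo$nadir_value, endo_nadir_time = pn_endo$nadir_time,
    insulin_basal = ins$values[1],
    insulin_peak = pn_ins$peak_value, insulin_peak_time = pn_ins$peak_time,
    insulin_auc_0_60 = auc(ins, c(0, 60)) / 1000,     # nmol/l x min
    insulin_auc_0_180 = auc(ins, c(0, 180)) / 1000,
    insulin_auc_all = auc(ins, c(-60, 180)) / 1000,
    insulin_mean = auc(ins, c(-60, 180)) / 240,
    glucagon_t0 = ts_interp(gcg, 0),
    glucagon_nadir = pn_gcg$nadir_value,
    glucagon_nadir_time = pn_gcg$nadir_time,
    glucagon_iauc_0_60 = iauc(gcg, c(0, 60), baseline_time = 0)$value,
    glucagon_iauc_0_180 = iauc(gcg, c(0, 180), baseline_time = 0)$value,
    glucagon_mean = auc(gcg, c(0, 180)) / 180,
    hepatic_dglc_peak = pn_hep$peak_value,
    hepatic_dglc_peak_time = pn_hep$peak_time,
    glycogen_basal = ts_interp(gly, 0),
    glycogen_iauc_0_180 = iauc(gly, c(0, 180), baseline_time = 0)$value,
    si_disposal = fit$params$SI_D, si_production = fit$params$SI_P,
    ge_disposal = report_ge_disposal(fit$params),
    ge_production = fit$params$GE_P,
    gezi_disposal = fit$params$GEZI_D,
    egp_suppression_0_60 = sc[["egp_suppression_60"]],
    egp_suppression_0_180 = sc[["egp_suppression_180"]],
    rd_increase_0_180 = sc[["rd_increase_180"]],
    t50_gr = sc[["t50"]],
    ra_iauc_dose_60 = sc[["ra_iauc_dose_60"]],
    ra_iauc_dose_180 = sc[["ra_iauc_dose_180"]])
}

#' Assemble the cohort report
#'
#' Aggregates per-subject analyses into group summaries (mean, SD, SEM and
#' t-based 95% CI per metric), pairwise group comparisons (healthy vs
#' diabetes and, within the diabetes arm, the two discovered subgroups)
#' using pooled-variance two-sample t tests without multiplicity
#' correction, and the hierarchical subgroup clustering on the incremental
#' AUCs (0–180 min, baseline T0) of measured plasma D-Glc and hepatic
#' D-Glc.
#'
#' @param analyses list of `subject_analysis` objects.
#' @param datasets matching list of [subject_dataset]s (group labels).
#' @param config an `hf_config`.
#' @return list of class `cohort_report`: `subjects` (long data.frame of
#'   metrics), `summary` (per group x metric), `comparisons`, `cluster` (a
#'   `cluster_result` over the diabetes arm, or `NULL` if that arm has
#'   fewer than two subjects).
#' @export
build_cohort_report <- function(analyses, datasets,
                                config = default_config()) {
  stopifnot(length(analyses) == length(datasets), length(analyses) >= 1L)
  groups <- vapply(datasets, function(d) d$group, character(1))
  ids <- vapply(datasets, function(d) d$subject_id, character(1))
  if (!any(groups == "healthy") || !any(groups == "t1d"))
    if (length(unique(groups)) == 0L) stop("empty cohort", call. = FALSE)
  mets <- t(vapply(analyses, function(a) a$metrics,
                   numeric(length(metric_manifest()))))
  rownames(mets) <- ids

  # subgroup discovery within the diabetes arm
  cluster <- NULL
  subgroup <- rep(NA_character_, length(ids))
  t1d_idx <- which(groups == "t1d")
  if (length(t1d_idx) >= 2L) {
    feats <- cbind(
      iauc_plasma_dglc = vapply(analyses[t1d_idx], function(a)
        iauc(a$partition$exogenous, c(0, 180), baseline_time = 0)$value,
        numeric(1)),
      iauc_hepatic_dglc = vapply(analyses[t1d_idx], function(a)
        iauc(a$quant$hepatic_dglc, c(0, 180), baseline_time = 0)$value,
        numeric(1)))
    rownames(feats) <- ids[t1d_idx]
    cluster <- cluster_subgroups(feats, k = 2)
    subgroup[t1d_idx] <- as.character(cluster$labels)
  }

  tier <- function(sel, label) {
    if (!any(sel)) return(NULL)
    do.call(rbind, lapply(metric_manifest(), function(mn) {
      x <- mets[sel, mn]; x <- x[is.finite(x)]
      n <- length(x)
      if (n == 0L)
        return(data.frame(group = label, metric = mn, n = 0L,
                          mean = NA_real_, sd = NA_real_, sem = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_))
      m <- mean(x); s <- if (n > 1) stats::sd(x) else NA_real_
      sem <- if (n > 1) s / sqrt(n) else NA_real_
      half <- if (n > 1) stats::qt(0.975, n - 1) * sem else NA_real_
      data.frame(group = label, metric = mn, n = n, mean = m, sd = s,
                 sem = sem, ci_lo = m - half, ci_hi = m + half)
    }))
  }
  summary_df <- rbind(tier(groups == "healthy", "healthy"),
                      tier(groups == "t1d", "t1d"),
                      tier(!is.na(subgroup) & subgroup == "1", "t1d_sub1"),
                      tier(!is.na(subgroup) & subgroup == "2", "t1d_sub2"))

  compare <- function(sel_a, sel_b, label) {
    do.call(rbind, lapply(metric_manifest(), function(mn) {
      a <- mets[sel_a, mn]; a <- a[is.finite(a)]
      b <- mets[sel_b, mn]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L)
        return(data.frame(comparison = label, metric = mn, t = NA_real_,
                          p = NA_real_, diff = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_))
      ct <- two_sample_t(a, b, metric = mn,
                         var_equal = config$t_test_var_equal)
      data.frame(comparison = label, metric = mn, t = ct$t, p = ct$p,
                 diff = ct$difference, ci_lo = ct$ci95[1],
                 ci_hi = ct$ci95[2])
    }))
  }
  comparisons <- NULL
  if (sum(groups == "healthy") >= 2L && sum(groups == "t1d") >= 2L)
    comparisons <- compare(groups == "healthy", groups == "t1d",
                           "healthy_vs_t1d")
  s1 <- !is.na(subgroup) & subgroup == "1"
  s2 <- !is.na(subgroup) & subgroup == "2"
  if (sum(s1) >= 2L && sum(s2) >= 2L)
    comparisons <- rbind(comparisons, compare(s1, s2, "sub1_vs_sub2"))

  subjects <- data.frame(subject_id = ids, group = groups,
                         subgroup = subgroup,
                         as.data.frame(mets), row.names = NULL)
  structure(list(subjects = subjects, summary = summary_df,
                 comparisons = comparisons, cluster = cluster),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", nrow(x$subjects), "subjects:",
      sum(x$subjects$group == "healthy"), "healthy,",
      sum(x$subjects$group == "t1d"), "t1d")
  if (!is.null(x$cluster))
    cat(" (subgroups ", paste(table(x$cluster$labels), collapse = "+"),
        ", silhouette ", signif(x$cluster$silhouette, 3), ")", sep = "")
  cat("\n")
  key <- c("basal_glucose", "peak_glucose", "exo_peak", "endo_nadir",
           "hepatic_dglc_peak", "glycogen_iauc_0_180",
           "egp_suppression_0_180", "t50_gr")
  print(x$summary[x$summary$metric %in% key,
                  c("group", "metric", "n", "mean", "sd")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (machine readable: subjects, summaries, comparisons,
#' cluster labels and silhouette) and `report.md` (human-readable summary
#' tables).
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
save_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(subjects = report$subjects, summary = report$summary,
                  comparisons = report$comparisons,
                  cluster = if (!is.null(report$cluster))
                    list(labels = report$cluster$labels,
                         silhouette = report$cluster$silhouette))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  md <- c("# Cohort report", "",
          sprintf("%d subjects (%d healthy, %d t1d)",
                  nrow(report$subjects),
                  sum(report$subjects$group == "healthy"),
                  sum(report$subjects$group == "t1d")), "",
          "## Group summaries (mean +/- SD)", "")
  for (g in unique(report$summary$group)) {
    md <- c(md, sprintf("### %s", g), "",
            "| metric | n | mean | sd | sem |", "|---|---|---|---|---|")
    sg <- report$summary[report$summary$group == g, ]
    md <- c(md, sprintf("| %s | %d | %.4g | %.4g | %.4g |", sg$metric,
                        sg$n, sg$mean, sg$sd, sg$sem), "")
  }
  if (!is.null(report$comparisons)) {
    md <- c(md, "## Comparisons (two-sample t)", "",
            "| comparison | metric | t | p |", "|---|---|---|---|",
            sprintf("| %s | %s | %.3g | %.3g |",
                    report$comparisons$comparison,
                    report$comparisons$metric, report$comparisons$t,
                    report$comparisons$p))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
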