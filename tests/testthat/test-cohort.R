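test_that("incremental AUC matches closed forms and is additive", {
  tt <- seq(0, 180, 10)
  const <- hf_ts(tt, rep(7, length(tt)), "mmol/l")
  expect_equal(iauc(const, c(0, 180), 0)$value, 0)
  ramp <- hf_ts(tt, 5 + 0.01 * tt, "mmol/l")
  expect_equal(iauc(ramp, c(0, 180), 0)$value, 0.01 * 180^2 / 2)  # 162
  # additivity with a shared baseline, exact for the trapezoid rule
  set.seed(8)
  wig <- hf_ts(tt, 5 + cumsum(rnorm(length(tt))), "mmol/l")
  expect_equal(iauc(wig, c(0, 60), 0)$value + iauc(wig, c(60, 180), 0)$value,
               iauc(wig, c(0, 180), 0)$value, tolerance = 1e-12)
  expect_error(iauc(ramp, c(0, 300), 0), "outside")
})

test_that("peaks and nadirs exclude pre-dose samples and break ties early", {
  tt <- blood_grid()
  v <- c(9, 5, 5.5, 6, 6.5, 7, 7.5, 7, 6, 5.8)  # max at T-60 excluded
  pn <- peak_nadir(hf_ts(tt, v, "mmol/l"))
  expect_equal(pn$peak_value, 7.5)
  expect_equal(pn$peak_time, 90)
  expect_equal(pn$nadir_value, 5)
  expect_equal(pn$nadir_time, 0)
  tie <- hf_ts(tt, c(1, 1, 2, 3, 4, 5, 5, 4, 3, 2), "mmol/l")
  expect_equal(peak_nadir(tie)$peak_time, 60)     # earliest of the tie
  mono <- hf_ts(tt, seq_along(tt), "mmol/l")
  expect_equal(peak_nadir(mono)$peak_time, 180)
  expect_error(peak_nadir(mono, exclude_before = 500), "excluded")
})

test_that("pooled t test agrees with the textbook formula", {
  ct <- two_sample_t(1:5, 2:6)
  expect_equal(ct$t, -1)
  expect_equal(ct$df, 8)
  expect_equal(ct$p, 0.3466, tolerance = 1e-3)
  # brute-force oracle on random small samples
  set.seed(42)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), mean = runif(1))
    ct <- two_sample_t(a, b)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    p_ref <- 2 * pt(-abs(t_ref), na + nb - 2)
    expect_equal(ct$t, t_ref, tolerance = 1e-10)
    expect_equal(ct$p, p_ref, tolerance = 1e-10)
    expect_true(ct$ci95[1] <= ct$difference && ct$difference <= ct$ci95[2])
  }
  ident <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(two_sample_t(1, 2:4), "n >= 2")
})

test_that("well-separated blobs cluster perfectly and ordering is irrelevant", {
  set.seed(5)
  f1 <- cbind(rnorm(6, 0), rnorm(6, 0))
  f2 <- cbind(rnorm(4, 10), rnorm(4, 10))
  feats <- rbind(f1, f2)
  cl <- cluster_subgroups(feats, k = 2)
  # cluster 1 must be the high-plasma-iAUC group
  expect_equal(cl$labels, c(rep(2, 6), rep(1, 4)))
  expect_gt(cl$silhouette, 0.8)
  perm <- sample(nrow(feats))
  cl_p <- cluster_subgroups(feats[perm, ], k = 2)
  expect_equal(cl_p$labels, cl$labels[perm])
  # scaling a feature is absorbed by the z-scoring
  cl_s <- cluster_subgroups(cbind(feats[, 1] * 1e4, feats[, 2]), k = 2)
  expect_equal(cl_s$labels, cl$labels)
  expect_true(is.na(cluster_subgroups(feats, k = 1)$silhouette))
  expect_error(cluster_subgroups(feats[c(1, 1, 1), ], k = 2), "distinct")
})

test_that("cohort report covers the metric manifest with correct summaries", {
  mix <- list(list(profile = default_profile("healthy"), n = 2L),
              list(profile = default_profile("t1d_sub1"), n = 2L),
              list(profile = default_profile("t1d_sub2"), n = 2L))
  co <- quiet(generate_cohort(mix, seed = 4, noise = FALSE))
  analyses <- lapply(co, function(s) quiet(analyze_subject(s$dataset)))
  rep <- build_cohort_report(analyses, lapply(co, `[[`, "dataset"))
  healthy <- rep$summary[rep$summary$group == "healthy", ]
  expect_setequal(healthy$metric, metric_manifest())
  # SEM = SD/sqrt(n) everywhere it is defined
  ok <- !is.na(healthy$sem)
  expect_equal(healthy$sem[ok], healthy$sd[ok] / sqrt(healthy$n[ok]))
  expect_true(all(c("healthy_vs_t1d", "sub1_vs_sub2") %in%
                    rep$comparisons$comparison))
  expect_equal(as.integer(sort(table(rep$cluster$labels))), c(2L, 2L))

  dir <- withr::local_tempdir()
  save_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "report.md")))
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(nrow(back$subjects), 6)
})

test_that("degenerate cohorts keep their identities", {
  p <- default_profile("healthy")
  p$between_cv[] <- 0
  co <- quiet(generate_cohort(list(list(profile = p, n = 2L)), seed = 9,
                              noise = FALSE))
  analyses <- lapply(co, function(s) quiet(analyze_subject(s$dataset)))
  supp <- vapply(analyses, function(a)
    a$metrics[["egp_suppression_0_180"]], numeric(1))
  expect_equal(supp[1], supp[2], tolerance = 1e-9)
})
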