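test_that("time series container enforces its invariants", {
  expect_error(hf_ts(c(0, 0, 10), c(1, 2, 3), "mmol/l"),
               "strictly increasing")
  expect_error(hf_ts(c(0, 10), c(1, NA), "mmol/l"), "finite")
  expect_error(hf_ts(0, 1, "mg/dl"), "unknown unit")
  x <- hf_ts(c(-60, 0, 30), c(5, 5.1, 6), "mmol/l", "glucose")
  expect_equal(ts_interp(x, 15), (5.1 + 6) / 2)
  expect_equal(ts_interp(x, c(-100, 100)), c(5, 6))  # constant extrapolation
})

test_that("gram dose converts to millimoles with the fixed molar mass", {
  ds <- noise_free("healthy")$dataset
  expect_equal(ds$dose_grams, 60)
  expect_equal(ds$dose_mmol, 60 / 0.180156)
  expect_equal(round(ds$dose_mmol, 2), 333.04)
})

test_that("save/load round-trips a generated subject field for field", {
  dir <- withr::local_tempdir()
  g <- quiet(generate_subject(default_profile("t1d_sub1"), seed = 3,
                              noise = TRUE))
  save_subject(g$dataset, dir)
  back <- load_dataset(dir)
  for (f in c("subject_id", "group", "subgroup_hint", "basal_analogue"))
    expect_identical(back[[f]], g$dataset[[f]])
  for (f in c("body_weight", "height", "dose_grams", "dose_mmol",
              "water_reference_amplitude"))
    expect_equal(back[[f]], g$dataset[[f]], tolerance = 1e-9)
  for (ch in c("plasma_total_glucose", "plasma_ratio", "plasma_insulin_fast",
               "plasma_insulin_long", "plasma_glucagon",
               "glycogen_amplitudes")) {
    expect_equal(back[[ch]]$times, g$dataset[[ch]]$times, tolerance = 1e-9)
    expect_equal(back[[ch]]$values, g$dataset[[ch]]$values, tolerance = 1e-9)
  }
  expect_length(back$hepatic_dglc_amplitudes, 6)
  expect_equal(back$hepatic_dglc_amplitudes[[4]]$values,
               g$dataset$hepatic_dglc_amplitudes[[4]]$values,
               tolerance = 1e-9)
  expect_equal(unclass(back$glycogen_cal), unclass(g$dataset$glycogen_cal),
               tolerance = 1e-9)
  expect_equal(back$bolus_events, g$dataset$bolus_events)
})

test_that("loader rejects undeclared units and missing schema pieces", {
  dir <- withr::local_tempdir()
  g <- noise_free("healthy")
  save_subject(g$dataset, dir)
  tab <- read.csv(file.path(dir, "measurements.csv"))
  tab$unit[tab$channel == "glucose_total"] <- "mg/dl"
  write.csv(tab, file.path(dir, "measurements.csv"), row.names = FALSE)
  expect_error(load_dataset(dir), "unit error")

  save_subject(g$dataset, dir)
  tab <- read.csv(file.path(dir, "measurements.csv"))
  write.csv(tab[, setdiff(names(tab), "voxel")],
            file.path(dir, "measurements.csv"), row.names = FALSE)
  expect_error(load_dataset(dir), "schema error.*voxel")

  save_subject(g$dataset, dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  meta$body_weight <- NULL
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(load_dataset(dir), "schema error.*body_weight")
})

test_that("validation reports findings without mutating the dataset", {
  ds <- noise_free("healthy")$dataset
  snapshot <- ds
  expect_identical(nrow(validate_dataset(ds)), 0L)
  expect_identical(ds, snapshot)

  ds5 <- ds
  ds5$hepatic_dglc_amplitudes <- ds$hepatic_dglc_amplitudes[1:5]
  v <- validate_dataset(ds5)
  expect_true(any(v$severity == "warning" & grepl("six", v$message)))

  dst <- noise_free("t1d_sub1")$dataset
  dst$bolus_events <- list()
  v <- validate_dataset(dst)
  expect_true(any(v$severity == "warning" &
                    grepl("prandial bolus", v$message)))
})

test_that("config loading merges overrides and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(tracer_purity = 0.95,
                            active_fractions = list(glargine = 1,
                                                    detemir = 0.25,
                                                    degludec = 0.0285)),
                       path, auto_unbox = TRUE)
  cfg <- load_config(path)
  expect_equal(cfg$tracer_purity, 0.95)
  expect_equal(cfg$water_reference_conc, 8.94)  # untouched default
  jsonlite::write_json(list(tracer_puritty = 0.95), path, auto_unbox = TRUE)
  expect_error(load_config(path), "unknown config keys")
})
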