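test_that("condition enforces the vehicle rule and key fields", {
  expect_s3_class(condition("CL1", "DMSO", 0, 30000), "ws_condition")
  expect_s3_class(condition("CL1", "DrugX", 2.5, 30000), "ws_condition")
  expect_error(condition("CL1", "DMSO", 1, 30000), "vehicle rule")
  expect_error(condition("CL1", "DrugX", 0, 30000), "vehicle rule")
  expect_error(condition("CL1", "DrugX", -1, 30000), ">= 0")
})

test_that("well_timeseries validates trace shape and ranges", {
  cond <- condition("CL1", "DMSO", 0, 30000)
  expect_error(well_timeseries(cond, c(0, 2), c(0, 1), c(1, 1)),
               "length >= 3")
  expect_error(well_timeseries(cond, c(1, 2, 3), rep(0, 3), rep(1, 3)),
               "start at 0")
  expect_error(well_timeseries(cond, c(0, 2, 2), rep(0, 3), rep(1, 3)),
               "strictly increasing")
  expect_error(well_timeseries(cond, c(0, 2, 4), c(0, 0.5, 1.2), rep(1, 3)),
               "\\[0, 1\\]")
})

test_that("plate_dataset rejects incomplete strata and mixed grids", {
  times <- c(0, 2, 4)
  trt <- mk_well(times, c(0, 0.2, 0.4), drug = "DrugX", conc = 5)
  expect_error(plate_dataset(list(trt)), "stratum-completeness")
  ctrl_offgrid <- mk_well(c(0, 3, 6), c(0, 0.5, 1))
  expect_error(plate_dataset(list(trt, ctrl_offgrid)), "common time grid")
  ok <- plate_dataset(list(trt, mk_well(times, c(0, 0.5, 1))))
  expect_length(ok$wells, 2L)
})

test_that("read_timeseries parses a small export and validates it", {
  dir <- withr::local_tempdir()
  times <- seq(0, 72, by = 2)
  rwd_ctrl <- pmin(times / 24, 1) * 100
  rwd_trt <- pmin(times / 48, 1) * 100
  paths <- write_csv_pair(
    dir,
    mk_ts_df(c("A1", "A2"), times, list(rwd_ctrl, rwd_trt),
             list(rep(10, 37), rep(12, 37))),
    mk_pm_df(c("A1", "A2"), c("DMSO", "DrugX"), c(0, 5)))
  ds <- read_timeseries(paths["ts"], paths["pm"])
  expect_length(ds$wells, 2L)
  expect_length(ds$wells[[1]]$times, 37L)
  # percent-to-fraction conversion
  expect_equal(ds$wells[[1]]$rwd, pmin(times / 24, 1))
})

test_that("read_timeseries errors name the offending column or well", {
  dir <- withr::local_tempdir()
  times <- c(0, 2, 4)
  # RWD of 150% in well A2
  paths <- write_csv_pair(
    dir,
    mk_ts_df(c("A1", "A2"), times, list(c(0, 50, 100), c(0, 150, 80)),
             list(rep(1, 3), rep(1, 3))),
    mk_pm_df(c("A1", "A2"), c("DMSO", "DrugX"), c(0, 5)))
  expect_error(read_timeseries(paths["ts"], paths["pm"]),
               "range error.*A2")
  # missing column
  ts2 <- mk_ts_df("A1", times, list(c(0, 50, 100)), list(rep(1, 3)))
  names(ts2)[3] <- "rwd"
  p2 <- write_csv_pair(dir, ts2, mk_pm_df("A1", "DMSO", 0))
  expect_error(read_timeseries(p2["ts"], p2["pm"]), "rwd_pct")
  # treated stratum with no vehicle well
  p3 <- write_csv_pair(
    dir,
    mk_ts_df("A1", times, list(c(0, 50, 100)), list(rep(1, 3))),
    mk_pm_df("A1", "DrugX", 5))
  expect_error(read_timeseries(p3["ts"], p3["pm"]), "stratum-completeness")
})

test_that("RWD overshoot in (100, 105] is clamped, larger values error", {
  dir <- withr::local_tempdir()
  times <- c(0, 2, 4)
  paths <- write_csv_pair(
    dir,
    mk_ts_df("A1", times, list(c(0, 103, 104.9)), list(rep(1, 3))),
    mk_pm_df("A1", "DMSO", 0))
  ds <- read_timeseries(paths["ts"], paths["pm"])
  expect_equal(ds$wells[[1]]$rwd, c(0, 1, 1))
  paths2 <- write_csv_pair(
    dir,
    mk_ts_df("A1", times, list(c(0, 105.1, 90)), list(rep(1, 3))),
    mk_pm_df("A1", "DMSO", 0))
  expect_error(read_timeseries(paths2["ts"], paths2["pm"]), "range error")
})

test_that("write/read round trip reproduces every numeric field exactly", {
  ds <- simulate_screen(sim_params(seed = 42), "mixed", replicates = 1L)
  dir <- withr::local_tempdir()
  write_plate_dataset(ds, file.path(dir, "ts.csv"), file.path(dir, "pm.csv"))
  back <- read_timeseries(file.path(dir, "ts.csv"), file.path(dir, "pm.csv"))
  expect_length(back$wells, length(ds$wells))
  key <- function(w) paste(w$condition$drug, w$condition$concentration)
  ord <- order(vapply(ds$wells, key, ""))
  ord_b <- order(vapply(back$wells, key, ""))
  for (i in seq_along(ord)) {
    a <- ds$wells[[ord[i]]]
    b <- back$wells[[ord_b[i]]]
    expect_identical(b$times, a$times)
    expect_identical(b$caspase, a$caspase)
    # RWD passes through the percent conversion (two correctly-rounded
    # float operations), so agreement is to the last ulp rather than
    # bit-identical
    expect_equal(b$rwd, a$rwd, tolerance = 1e-15)
  }
})

test_that("aggregate_replicates averages pointwise and is idempotent", {
  times <- c(0, 2, 4)
  r1 <- mk_well(times, c(0, 0.5, 1))
  r2 <- mk_well(times, c(0, 0.3, 0.9), replicate = 2L)
  ds <- plate_dataset(list(r1, r2))
  agg <- aggregate_replicates(ds)
  expect_length(agg$wells, 1L)
  expect_equal(agg$wells[[1]]$rwd, c(0, 0.4, 0.95))
  expect_equal(agg$metadata$replicates_averaged, 2L)
  # idempotent; single replicate passes through unchanged
  agg2 <- aggregate_replicates(agg)
  expect_identical(agg2$wells[[1]]$rwd, agg$wells[[1]]$rwd)
  r2_off <- mk_well(c(0, 3, 6), c(0, 0.3, 0.9), replicate = 2L)
  expect_error(aggregate_replicates(plate_dataset(list(r1, r2_off))),
               "sequencing error")
})

test_that("analysis config reads YAML and JSON with defaults", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("endpoint_method: B", "slope_threshold: 0.03"), yml)
  cfg <- read_analysis_config(yml)
  expect_equal(cfg$endpoint_method, "B")
  expect_equal(cfg$slope_threshold, 0.03)
  expect_equal(cfg$rwd_target, 0.5)  # untouched default
  jsn <- file.path(dir, "cfg.json")
  writeLines('{"endpoint_method": "C", "ks_alpha": 0.01}', jsn)
  cfg2 <- read_analysis_config(jsn)
  expect_equal(cfg2$endpoint_method, "C")
  expect_equal(cfg2$ks_alpha, 0.01)
  writeLines("slope_thresh: 1", yml)
  expect_error(read_analysis_config(yml), "unknown config field")
})
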