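# In-code fixtures shared across test files.

# A well with explicit traces; fills in a vehicle-control condition by
# default.
mk_well <- function(times, rwd, caspase = rep(1, length(times)),
                    cell_line = "CL1", drug = "DMSO", conc = 0,
                    density = 30000L, replicate = 1L) {
  well_timeseries(condition(cell_line, drug, conc, density,
                            replicate = replicate),
                  times, rwd, caspase)
}

# A tiny two-well stratum (one control, one treated) on a 2 h grid.
mk_two_well_plate <- function(t_max = 72, interval = 2) {
  times <- seq(0, t_max, by = interval)
  ctrl <- mk_well(times, pmin(times / 24, 1))
  trt <- mk_well(times, pmin(times / 48, 1), drug = "DrugX", conc = 5)
  plate_dataset(list(ctrl, trt))
}

# Write a minimal CSV pair readable by read_timeseries(); returns paths.
write_csv_pair <- function(dir, ts_df, pm_df) {
  ts <- file.path(dir, "ts.csv")
  pm <- file.path(dir, "pm.csv")
  utils::write.csv(ts_df, ts, row.names = FALSE, quote = FALSE)
  utils::write.csv(pm_df, pm, row.names = FALSE, quote = FALSE)
  c(ts = ts, pm = pm)
}

mk_ts_df <- function(wells, times, rwd_pct, caspase) {
  do.call(rbind, lapply(seq_along(wells), function(i) {
    data.frame(well = wells[i], time_h = times,
               rwd_pct = rwd_pct[[i]], caspase_au = caspase[[i]])
  }))
}

mk_pm_df <- function(wells, drugs, concs, cell_line = "CL1",
                     density = 30000L, mmc = 1L, replicate = 1L) {
  data.frame(well = wells, cell_line = cell_line, drug = drugs,
             conc_uM = concs, density = density, mmc = mmc,
             replicate = replicate)
}

# Manufactured landscape fits for unit-testing the tangent rule.
mk_linear_fit <- function(slope) {
  structure(list(model = "linear",
                 params = list(slope_dc_per_wc = slope),
                 r2 = NA_real_,
                 points = data.frame(concentration = numeric(0),
                                     wc = numeric(0), dc = numeric(0))),
            class = "ws_landscape_fit")
}

mk_first_order_fit <- function(wc_max, k) {
  structure(list(model = "first_order",
                 params = list(wc_max = wc_max, k = k),
                 r2 = 1,
                 points = data.frame(concentration = numeric(0),
                                     wc = numeric(0), dc = numeric(0))),
            class = "ws_landscape_fit")
}

# Metrics data frame for a single series, from explicit (wc, dc) vectors.
mk_series_metrics <- function(wc, dc, conc = NULL) {
  n <- length(wc)
  if (is.null(conc)) conc <- 10 / 2^((n - 1):0)
  data.frame(concentration = c(0, conc), wc = c(0, wc), dc = c(0, dc))
}
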