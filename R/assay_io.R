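#' Read a plate time-series export and plate map into a dataset
#'
#' Reads the two CSV files produced by a live-imaging export (or by
#' [write_plate_dataset()] / [simulate_screen()]):
#'
#' * time series: columns `well, time_h, rwd_pct, caspase_au`, one row per
#'   well and time point, RWD in percent;
#' * plate map: columns `well, cell_line, drug, conc_uM, density, mmc,
#'   replicate` (`mmc` coded 0/1), one row per well.
#'
#' RWD is converted to a fraction on read. Values in (100, 105]% are clamped
#' to 100% (instrument overshoot); values above 105% are a range error.
#' Wells present in only one of the two files are an error, as are
#' non-monotone time stamps, incomplete strata (treated wells with no DMSO
#' control) and mismatched time grids within a stratum.
#'
#' @param path path to the time-series CSV.
#' @param plate_map_path path to the plate-map CSV.
#' @return A [plate_dataset()].
#' @export
read_timeseries <- function(path, plate_map_path) {
  for (p in c(path, plate_map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_ts <- c("well", "time_h", "rwd_pct", "caspase_au")
  miss <- setdiff(need_ts, names(ts))
  if (length(miss))
    stop("format error: time-series file is missing column(s) ",
         paste(miss, collapse = ", "))
  pm <- utils::read.csv(plate_map_path, stringsAsFactors = FALSE)
  need_pm <- c("well", "cell_line", "drug", "conc_uM", "density", "mmc",
               "replicate")
  miss <- setdiff(need_pm, names(pm))
  if (length(miss))
    stop("format error: plate map is missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(pm$well))
    stop("plate map lists well '", pm$well[duplicated(pm$well)][1L],
         "' more than once")

  ts_wells <- unique(ts$well)
  only_ts <- setdiff(ts_wells, pm$well)
  only_pm <- setdiff(pm$well, ts_wells)
  if (length(only_ts) || length(only_pm))
    stop("wells present in only one file: ",
         paste(c(only_ts, only_pm), collapse = ", "))

  rows_by_well <- split(seq_len(nrow(ts)), factor(ts$well, levels = ts_wells))
  wells <- vector("list", length(ts_wells))
  for (i in seq_along(ts_wells)) {
    wid <- ts_wells[i]
    idx <- rows_by_well[[wid]]
    times <- ts$time_h[idx]
    rwd_pct <- ts$rwd_pct[idx]
    casp <- ts$caspase_au[idx]
    if (any(diff(times) <= 0))
      stop("sequencing error: non-monotone time stamps in well '", wid, "'")
    if (any(rwd_pct < 0) || any(rwd_pct > 105))
      stop("range error: RWD outside [0, 105]% in well '", wid, "'")
    rwd_pct <- pmin(rwd_pct, 100)  # clamp instrument overshoot
    m <- pm[pm$well == wid, , drop = FALSE]
    cond <- condition(cell_line = as.character(m$cell_line),
                      drug = as.character(m$drug),
                      concentration = as.numeric(m$conc_uM),
                      density = as.integer(m$density),
                      mmc = as.logical(as.integer(m$mmc)),
                      replicate = as.integer(m$replicate))
    wells[[i]] <- well_timeseries(cond, times, rwd_pct / 100, casp)
  }
  plate_dataset(wells, metadata = list(source = path,
                                       plate_map = plate_map_path))
}

#' Write a plate dataset as a time-series CSV and plate-map CSV
#'
#' Writes the exact file pair that [read_timeseries()] reads, at full
#' numeric precision: times and caspase values round-trip bit-for-bit, and
#' RWD — stored on disk in percent — round-trips to within one ulp (the
#' fraction-to-percent conversion is two correctly rounded float
#' operations). Well ids are assigned `W0001`, `W0002`, ... in dataset
#' order.
#'
#' @param dataset a [plate_dataset()].
#' @param path output path for the time-series CSV.
#' @param plate_map_path output path for the plate-map CSV.
#' @return Invisibly, the character vector of assigned well ids.
#' @export
write_plate_dataset <- function(dataset, path, plate_map_path) {
  stopifnot(inherits(dataset, "ws_plate"))
  n <- length(dataset$wells)
  ids <- sprintf("W%04d", seq_len(n))
  num <- function(x) sprintf("%.17g", x)
  ts_lines <- c("well,time_h,rwd_pct,caspase_au")
  pm_lines <- c("well,cell_line,drug,conc_uM,density,mmc,replicate")
  for (i in seq_len(n)) {
    w <- dataset$wells[[i]]
    ts_lines <- c(ts_lines,
                  paste(ids[i], num(w$times), num(w$rwd * 100),
                        num(w$caspase), sep = ","))
    cond <- w$condition
    pm_lines <- c(pm_lines,
                  paste(ids[i], cond$cell_line, cond$drug,
                        num(cond$concentration), cond$density,
                        as.integer(cond$mmc), cond$replicate, sep = ","))
  }
  writeLines(ts_lines, path)
  writeLines(pm_lines, plate_map_path)
  invisible(ids)
}

#' Average replicate wells
#'
#' Collapses wells that share the same condition up to replicate id into a
#' single well whose RWD and caspase traces are pointwise means. Replicates
#' must share an identical time grid; mismatches are a sequencing error.
#' Scoring operates on these per-condition mean curves. The number of
#' replicates collapsed per condition is recorded in
#' `metadata$replicates_averaged`.
#'
#' @param dataset a [plate_dataset()].
#' @return A [plate_dataset()] with one well per distinct condition
#'   (replicate id set to 1).
#' @export
aggregate_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "ws_plate"))
  if (length(dataset$wells) == 0L)
    stop("empty-input error: dataset has no wells")
  keys <- vapply(dataset$wells,
                 function(w) condition_key(w$condition, replicate = FALSE), "")
  groups <- split(dataset$wells, factor(keys, levels = unique(keys)))
  out <- vector("list", length(groups))
  counts <- integer(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    grid <- g[[1L]]$times
    if (!all(vapply(g, function(w) identical(w$times, grid), TRUE)))
      stop("sequencing error: replicates of '", format(g[[1L]]$condition),
           "' are on different time grids")
    rwd <- rowMeans(vapply(g, `[[`, grid, "rwd"))
    casp <- rowMeans(vapply(g, `[[`, grid, "caspase"))
    cond <- g[[1L]]$condition
    cond$replicate <- 1L
    out[[i]] <- well_timeseries(cond, grid, rwd, casp)
    counts[i] <- length(g)
  }
  md <- dataset$metadata
  md$replicates_averaged <- counts
  plate_dataset(out, metadata = md)
}
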