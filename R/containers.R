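#' Experimental condition annotation for one well
#'
#' A condition identifies what was done to a well: which cell line, which
#' compound at which concentration, how many cells were seeded, whether the
#' culture was pre-treated with mitomycin C (MMC, blocking proliferation so
#' that wound closure reflects migration and death only), and the biological
#' replicate id. The drug label `"DMSO"` is reserved for the vehicle control
#' and must carry concentration 0; conversely a concentration of 0 is only
#' valid for the vehicle.
#'
#' @param cell_line character scalar, cell-line label.
#' @param drug character scalar; `"DMSO"` denotes the vehicle control.
#' @param concentration numeric scalar, micromolar, >= 0 (0 for vehicle).
#' @param density integer scalar, seeded cells per well.
#' @param mmc logical scalar, mitomycin-C pre-treatment flag.
#' @param replicate integer scalar >= 1, biological replicate id.
#' @return A list of class `ws_condition`.
#' @export
condition <- function(cell_line, drug, concentration, density, mmc = TRUE,
                      replicate = 1L) {
  stopifnot(is.character(cell_line), length(cell_line) == 1L,
            is.character(drug), length(drug) == 1L,
            is.numeric(concentration), length(concentration) == 1L,
            is.numeric(density), length(density) == 1L,
            is.logical(mmc), length(mmc) == 1L,
            is.numeric(replicate), length(replicate) == 1L)
  if (concentration < 0)
    stop("concentration must be >= 0, got ", concentration)
  if (replicate < 1 || replicate != as.integer(replicate))
    stop("replicate must be a positive integer, got ", replicate)
  if ((drug == "DMSO") != (concentration == 0))
    stop("vehicle rule violated: drug == \"DMSO\" if and only if ",
         "concentration == 0 (got drug = ", drug,
         ", concentration = ", concentration, ")")
  structure(
    list(cell_line = cell_line, drug = drug,
         concentration = as.numeric(concentration),
         density = as.integer(density), mmc = as.logical(mmc),
         replicate = as.integer(replicate)),
    class = "ws_condition")
}

#' @export
format.ws_condition <- function(x, ...) {
  sprintf("%s | %s @ %g uM | %d cells/well | MMC=%s | rep %d",
          x$cell_line, x$drug, x$concentration, x$density, x$mmc, x$replicate)
}

#' @export
print.ws_condition <- function(x, ...) {
  cat("<condition> ", format(x), "\n", sep = "")
  invisible(x)
}

# Full well key (uniqueness within a dataset) and the stratum key under
# which control-normalization happens: wells sharing (cell_line, density,
# mmc) are scored against the same vehicle control.
condition_key <- function(cond, replicate = TRUE) {
  base <- paste(cond$cell_line, cond$drug,
                format(cond$concentration, digits = 15),
                cond$density, cond$mmc, sep = "\r")
  if (replicate) paste(base, cond$replicate, sep = "\r") else base
}

stratum_key <- function(cond) {
  paste(cond$cell_line, cond$density, cond$mmc, sep = "\r")
}

is_control <- function(cond) cond$drug == "DMSO"

#' One well's sampled time series
#'
#' Holds the instrument trace for a single well: sampling times in hours
#' (starting at 0, strictly increasing), relative wound density (RWD) as a
#' fraction in \[0, 1\] (the fraction of the original wound area repopulated
#' by cells), and the integrated caspase-3/7 signal in arbitrary units
#' (a cumulative apoptosis readout).
#'
#' @param cond a [condition()] object.
#' @param times numeric vector of sampling times in hours.
#' @param rwd numeric vector of relative wound density fractions in \[0, 1\].
#' @param caspase numeric vector of integrated caspase-3/7 signal, >= 0.
#' @return A list of class `ws_well`.
#' @export
well_timeseries <- function(cond, times, rwd, caspase) {
  stopifnot(inherits(cond, "ws_condition"))
  n <- length(times)
  if (n < 3L || length(rwd) != n || length(caspase) != n)
    stop("times, rwd and caspase must have equal length >= 3 (got ",
         n, ", ", length(rwd), ", ", length(caspase), ")")
  if (!all(is.finite(times)) || !all(is.finite(rwd)) ||
      !all(is.finite(caspase)))
    stop("well trace contains non-finite values")
  if (times[1L] != 0)
    stop("times must start at 0, got ", times[1L])
  if (any(diff(times) <= 0))
    stop("sequencing error: times must be strictly increasing")
  if (any(rwd < 0) || any(rwd > 1))
    stop("rwd must lie in [0, 1] as a fraction; got range [",
         min(rwd), ", ", max(rwd), "]")
  if (any(caspase < 0))
    stop("caspase signal must be >= 0")
  structure(
    list(condition = cond, times = as.numeric(times), rwd = as.numeric(rwd),
         caspase = as.numeric(caspase)),
    class = "ws_well")
}

#' @export
print.ws_well <- function(x, ...) {
  cat("<well> ", format(x$condition), "\n  ",
      length(x$times), " samples over [0, ", max(x$times), "] h; final RWD ",
      signif(x$rwd[length(x$rwd)], 3), "\n", sep = "")
  invisible(x)
}

#' A validated plate dataset
#'
#' Collects wells into a dataset and enforces the structural invariants the
#' scoring pipeline relies on: unique condition keys, at least one vehicle
#' (DMSO) well in every (cell line, density, MMC) stratum that contains a
#' treated well, and a common sampling grid within each stratum (no silent
#' resampling).
#'
#' @param wells list of [well_timeseries()] objects.
#' @param metadata free-form named list (plate id, acquisition interval, ...).
#' @return A list of class `ws_plate` with elements `wells` and `metadata`.
#' @export
plate_dataset <- function(wells, metadata = list()) {
  stopifnot(is.list(wells), all(vapply(wells, inherits, TRUE, "ws_well")))
  if (length(wells) == 0L) stop("empty-input error: dataset has no wells")
  keys <- vapply(wells, function(w) condition_key(w$condition), "")
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1L]
    stop("duplicate well condition: ",
         format(wells[[match(dup, keys)]]$condition))
  }
  strata <- vapply(wells, function(w) stratum_key(w$condition), "")
  for (s in unique(strata)) {
    in_s <- wells[strata == s]
    ctrl <- vapply(in_s, function(w) is_control(w$condition), TRUE)
    if (any(!ctrl) && !any(ctrl))
      stop("stratum-completeness error: stratum '",
           gsub("\r", " / ", s),
           "' has treated wells but no DMSO vehicle control")
    grid <- in_s[[1L]]$times
    same <- vapply(in_s, function(w) identical(w$times, grid), TRUE)
    if (!all(same))
      stop("sequencing error: wells of stratum '", gsub("\r", " / ", s),
           "' are not on a common time grid")
  }
  structure(list(wells = wells, metadata = metadata), class = "ws_plate")
}

#' @export
print.ws_plate <- function(x, ...) {
  conds <- lapply(x$wells, `[[`, "condition")
  cat("<plate dataset> ", length(x$wells), " wells; ",
      length(unique(vapply(conds, `[[`, "", "cell_line"))), " cell line(s); ",
      length(unique(vapply(conds, `[[`, "", "drug"))), " drug label(s); ",
      length(unique(vapply(conds, stratum_key, ""))), " stratum(a)\n",
      sep = "")
  invisible(x)
}

# Split a plate into its strata, preserving well order.
split_strata <- function(dataset) {
  strata <- vapply(dataset$wells, function(w) stratum_key(w$condition), "")
  lapply(split(dataset$wells, factor(strata, levels = unique(strata))),
         identity)
}
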