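#' Trapezoidal area under a sampled trace
#'
#' Integrates a sampled trace over `[times[1], t_end]` with the trapezoid
#' rule on the native grid. When `t_end` falls between samples the trace is
#' linearly interpolated at `t_end`, so the result is exact for any
#' piecewise-linear trace.
#'
#' @param times numeric vector, strictly increasing sampling times (hours).
#' @param values numeric vector of the same length, finite.
#' @param t_end end of the integration window, in
#'   `(times[1], max(times)]`.
#' @return The integral, in value-hours.
#' @export
trapezoid_auc <- function(times, values, t_end) {
  stopifnot(length(times) == length(values), length(times) >= 2L,
            all(is.finite(times)), all(is.finite(values)))
  if (any(diff(times) <= 0))
    stop("sequencing error: times must be strictly increasing")
  if (t_end <= times[1L] || t_end > times[length(times)])
    stop("window error: t_end = ", t_end, " outside (",
         times[1L], ", ", times[length(times)], "]")
  keep <- times < t_end
  tt <- c(times[keep], t_end)
  vv <- c(values[keep],
          stats::approx(times, values, xout = t_end)$y)
  sum(diff(tt) * (vv[-length(vv)] + vv[-1L]) / 2)
}

#' Time at which RWD first reaches a target fraction
#'
#' Returns the earliest time at which the linearly interpolated RWD trace
#' first reaches `target`; `NA` if the target is never reached within the
#' trace. Used both as endpoint criterion C (half-closure time, `target`
#' 0.5) and as a summary of intrinsic closure speed.
#'
#' @param series a [well_timeseries()].
#' @param target fraction in (0, 1).
#' @return Hours, or `NA_real_` if never reached.
#' @export
time_to_rwd <- function(series, target) {
  stopifnot(inherits(series, "ws_well"), target > 0, target < 1)
  rwd <- series$rwd
  times <- series$times
  i <- which(rwd >= target)[1L]
  if (is.na(i)) return(NA_real_)
  if (rwd[i] == target || i == 1L) return(times[i])
  # first crossing lies between samples i-1 and i
  t0 <- times[i - 1L]; r0 <- rwd[i - 1L]
  t0 + (target - r0) / (rwd[i] - r0) * (times[i] - t0)
}

# Central-difference slope of a trace (one-sided at the ends), smoothed by
# a centered moving average of odd width w (partial windows at the edges).
smoothed_slope <- function(times, values, w) {
  n <- length(times)
  s <- numeric(n)
  s[1L] <- (values[2L] - values[1L]) / (times[2L] - times[1L])
  s[n] <- (values[n] - values[n - 1L]) / (times[n] - times[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    s[i] <- (values[i + 1L] - values[i - 1L]) / (times[i + 1L] - times[i - 1L])
  }
  half <- (w - 1L) %/% 2L
  if (half == 0L) return(s)
  vapply(seq_len(n), function(i) {
    mean(s[max(1L, i - half):min(n, i + half)])
  }, 0)
}

#' Analysis-window endpoint for a condition within its stratum
#'
#' Implements the three endpoint criteria (see [analysis_config()]):
#'
#' * method A: the fixed experiment endpoint, identical for all strata;
#' * method B: the earliest time at which the smoothed central-difference
#'   slope of the *control* RWD trace falls to `slope_threshold` or below,
#'   searched only after the control RWD has exceeded `slope_guard` (so the
#'   initial lag plateau cannot trigger it). The same window applies to
#'   every condition of the stratum. Falls back to the last observed time if
#'   the control never slows down.
#' * method C: the per-condition time to reach `rwd_target` closure,
#'   falling back to the last observed time when never reached.
#'
#' @param stratum list of [well_timeseries()] sharing one
#'   (cell line, density, MMC) stratum.
#' @param config an [analysis_config()].
#' @param cond the queried [condition()] (needed for method C).
#' @return Window end, in hours.
#' @export
endpoint_time <- function(stratum, config, cond) {
  stopifnot(inherits(config, "ws_config"))
  method <- config$endpoint_method
  if (method == "A") return(config$fixed_endpoint)
  if (method == "B") {
    ctrl <- Filter(function(w) is_control(w$condition), stratum)
    if (length(ctrl) == 0L)
      stop("stratum error: endpoint method B needs a DMSO control well")
    times <- ctrl[[1L]]$times
    rwd <- rowMeans(vapply(ctrl, `[[`, times, "rwd"))
    sl <- smoothed_slope(times, rwd, config$slope_smooth_window)
    ok <- rwd > config$slope_guard & sl <= config$slope_threshold
    i <- which(ok)[1L]
    return(if (is.na(i)) times[length(times)] else times[i])
  }
  # method C
  key <- condition_key(cond, replicate = FALSE)
  hit <- Filter(function(w)
    condition_key(w$condition, replicate = FALSE) == key, stratum)
  if (length(hit) == 0L)
    stop("condition not found in stratum: ", format(cond))
  w <- hit[[1L]]
  t50 <- time_to_rwd(w, config$rwd_target)
  if (is.na(t50)) w$times[length(w$times)] else t50
}

#' Closure and death change metrics for one stratum
#'
#' For every condition of a (cell line, density, MMC) stratum, integrates
#' RWD and caspase signal over the analysis window chosen by the configured
#' endpoint method, and computes the control-normalized quantities
#'
#' * wound-closure change `wc  = (AUC(RWD)_ctrl - AUC(RWD)_xi) / AUC(RWD)_ctrl`,
#' * drug-independent closure `wc_ind = AUC(RWD)_xi / AUC(RWD)_ctrl`
#'   (so `wc + wc_ind = 1`),
#' * death change `dc = (AUC(D)_xi - AUC(D)_ctrl) / AUC(D)_max`, with
#'   `AUC(D)_max` the stratum-wide maximum (control included).
#'
#' `dc` is clamped at 0 (a drug cannot contribute negative death to closure
#' delay); the raw value is kept in `dc_raw`. Under endpoint method C the
#' windows differ between conditions, so AUCs are divided by the window
#' length (time-averaged) before the formulas, making them comparable.
#' Negative `wc` (drug accelerates closure) is retained here and flagged
#' downstream.
#'
#' @param stratum list of [well_timeseries()] from a single stratum
#'   (replicates already averaged; multiple DMSO wells are pooled by
#'   pointwise mean).
#' @param config an [analysis_config()].
#' @return A data frame with one row per condition: the condition columns,
#'   `window_end`, `auc_rwd`, `wc`, `wc_ind`, `auc_death`, `dc`, `dc_raw`,
#'   `endpoint_method`.
#' @export
closure_death_metrics <- function(stratum, config) {
  stopifnot(is.list(stratum), length(stratum) >= 1L,
            all(vapply(stratum, inherits, TRUE, "ws_well")),
            inherits(config, "ws_config"))
  skeys <- unique(vapply(stratum, function(w) stratum_key(w$condition), ""))
  if (length(skeys) != 1L)
    stop("closure_death_metrics expects wells from a single stratum, got ",
         length(skeys))
  ctrl <- Filter(function(w) is_control(w$condition), stratum)
  if (length(ctrl) == 0L)
    stop("stratum error: no DMSO control well")
  # pool control wells (pointwise mean) so 'the control' is unique
  ctrl_times <- ctrl[[1L]]$times
  ctrl_well <- well_timeseries(
    ctrl[[1L]]$condition, ctrl_times,
    rowMeans(vapply(ctrl, `[[`, ctrl_times, "rwd")),
    rowMeans(vapply(ctrl, `[[`, ctrl_times, "caspase")))
  conds <- c(list(ctrl_well), Filter(function(w) !is_control(w$condition),
                                     stratum))

  windowed <- function(w, t_end) {
    a_rwd <- trapezoid_auc(w$times, w$rwd, t_end)
    a_d <- trapezoid_auc(w$times, w$caspase, t_end)
    if (config$endpoint_method == "C") {
      span <- t_end - w$times[1L]
      a_rwd <- a_rwd / span
      a_d <- a_d / span
    }
    c(a_rwd, a_d)
  }

  t_ctrl <- endpoint_time(stratum, config, ctrl_well$condition)
  a_ctrl <- windowed(ctrl_well, t_ctrl)
  if (a_ctrl[1L] == 0)
    stop("degenerate-control error: control AUC(RWD) is zero")

  n <- length(conds)
  window_end <- auc_rwd <- auc_death <- numeric(n)
  for (i in seq_len(n)) {
    w <- conds[[i]]
    window_end[i] <- endpoint_time(stratum, config, w$condition)
    a <- windowed(w, window_end[i])
    auc_rwd[i] <- a[1L]
    auc_death[i] <- a[2L]
  }
  wc <- (a_ctrl[1L] - auc_rwd) / a_ctrl[1L]
  wc_ind <- auc_rwd / a_ctrl[1L]
  auc_d_max <- max(auc_death)
  if (auc_d_max == 0) {
    warning("stratum-wide AUC(D) maximum is zero; all dc set to 0")
    dc_raw <- rep(0, n)
  } else {
    dc_raw <- (auc_death - a_ctrl[2L]) / auc_d_max
  }
  dc <- pmax(dc_raw, 0)

  cdf <- do.call(rbind, lapply(conds, function(w) {
    cond <- w$condition
    data.frame(cell_line = cond$cell_line, drug = cond$drug,
               concentration = cond$concentration, density = cond$density,
               mmc = cond$mmc, stringsAsFactors = FALSE)
  }))
  cdf$window_end <- window_end
  cdf$auc_rwd <- auc_rwd
  cdf$wc <- wc
  cdf$wc_ind <- wc_ind
  cdf$auc_death <- auc_death
  cdf$dc <- dc
  cdf$dc_raw <- dc_raw
  cdf$endpoint_method <- config$endpoint_method
  rownames(cdf) <- NULL
  cdf
}

#' Closure/death metrics for every stratum of a plate
#'
#' Convenience wrapper applying [closure_death_metrics()] to each
#' (cell line, density, MMC) stratum of a dataset. Replicates must already
#' be averaged (see [aggregate_replicates()]).
#'
#' @param dataset a [plate_dataset()].
#' @param config an [analysis_config()].
#' @return A data frame, rows for all strata stacked.
#' @export
plate_metrics <- function(dataset, config) {
  stopifnot(inherits(dataset, "ws_plate"))
  do.call(rbind, lapply(split_strata(dataset), closure_death_metrics,
                        config = config))
}
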