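#' Fit the death-closure dose landscape
#'
#' Across a concentration series, each dose contributes one point
#' `(dc, wc)`: death change on the horizontal axis, wound-closure change on
#' the vertical axis, with the vehicle control pinning the origin. The
#' relationship is captured by a first-order saturation model
#' `wc = wc_max * (1 - exp(-k * dc))` fitted by least squares. When the fit
#' is inadequate (r-squared on the wc residuals below `r2_threshold`), when
#' the points form a vertical line (no death at any dose, e.g. a purely
#' migrastatic compound), or when the optimizer fails, a straight line
#' through the origin, `dc = slope * wc`, is used instead.
#'
#' @param metrics data frame from [closure_death_metrics()] restricted to a
#'   single (cell line, drug, density) series; the control row may be
#'   included or omitted (the origin is always part of the fit). At least 3
#'   dose points are required.
#' @param r2_threshold first-order acceptance threshold (default 0.6).
#' @return A list of class `ws_landscape_fit`: `model` (`"first_order"` or
#'   `"linear"`), `params` (`wc_max`, `k`, or `slope_dc_per_wc`), `r2` (of
#'   the first-order fit; `NA` when it could not be attempted), and
#'   `points` (data frame `concentration`, `wc`, `dc`, origin included).
#' @export
fit_landscape <- function(metrics, r2_threshold = 0.6) {
  stopifnot(is.data.frame(metrics),
            all(c("concentration", "wc", "dc") %in% names(metrics)))
  dosed <- metrics[metrics$concentration > 0, , drop = FALSE]
  if (nrow(dosed) < 3L)
    stop("insufficient-data error: need >= 3 dose points, got ", nrow(dosed))
  if (all(c("cell_line", "drug", "density") %in% names(metrics)) &&
      length(unique(paste(dosed$cell_line, dosed$drug, dosed$density))) > 1L)
    stop("fit_landscape expects a single (cell line, drug, density) series")
  dosed <- dosed[order(dosed$concentration), , drop = FALSE]
  pts <- data.frame(concentration = c(0, dosed$concentration),
                    wc = c(0, dosed$wc), dc = c(0, dosed$dc))

  linear_fit <- function(r2 = NA_real_) {
    sw2 <- sum(pts$wc^2)
    slope <- if (sw2 > 0) sum(pts$wc * pts$dc) / sw2 else 0
    structure(list(model = "linear",
                   params = list(slope_dc_per_wc = slope),
                   r2 = r2, points = pts),
              class = "ws_landscape_fit")
  }

  # vertical-line case: no usable spread in dc
  if (stats::var(pts$dc) < 1e-12) return(linear_fit())

  wc_max0 <- max(max(pts$wc), 1e-3)
  nz <- which(pts$dc > 0)[1L]
  k0 <- max((pts$wc[nz] / pts$dc[nz]) / wc_max0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(wc ~ wc_max * (1 - exp(-k * dc)), data = pts,
                      start = list(wc_max = wc_max0, k = k0),
                      lower = c(wc_max = 1e-9, k = 1e-9),
                      upper = c(wc_max = 1.5, k = 1e4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(linear_fit())
  pred <- stats::predict(fit, pts)
  ss_res <- sum((pts$wc - pred)^2)
  ss_tot <- sum((pts$wc - mean(pts$wc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (!is.finite(r2) || r2 < r2_threshold) return(linear_fit(r2))
  cf <- stats::coef(fit)
  structure(list(model = "first_order",
                 params = list(wc_max = unname(cf["wc_max"]),
                               k = unname(cf["k"])),
                 r2 = r2, points = pts),
            class = "ws_landscape_fit")
}

#' @export
print.ws_landscape_fit <- function(x, ...) {
  if (x$model == "first_order")
    cat("<landscape fit> first-order: wc_max = ",
        signif(x$params$wc_max, 4), ", k = ", signif(x$params$k, 4),
        ", r2 = ", signif(x$r2, 4), "\n", sep = "")
  else
    cat("<landscape fit> linear: dc = ",
        signif(x$params$slope_dc_per_wc, 4), " * wc",
        if (is.finite(x$r2)) paste0(" (first-order r2 = ", signif(x$r2, 4),
                                    " rejected)") else "",
        "\n", sep = "")
  invisible(x)
}

# Predicted wc at a death change dc, under either model. For the linear
# model dc = slope * wc this is the inverse ray (undefined slope 0 maps all
# wc to dc 0; prediction only used for diagnostics/tests there).
predict_wc <- function(fit, dc) {
  if (fit$model == "first_order")
    fit$params$wc_max * (1 - exp(-fit$params$k * dc))
  else if (fit$params$slope_dc_per_wc != 0)
    dc / fit$params$slope_dc_per_wc
  else rep(NA_real_, length(dc))
}

#' Tangent angle of the landscape at an observed dose point
#'
#' The tangent angle theta is measured from the vertical (wound-closure)
#' axis: `theta = arctan(dDC/dWC)` along the fitted curve. A vertical
#' landscape (closure delayed with no death) gives theta = 0; a horizontal
#' one gives theta = pi/2, so `theta / (pi/2)` is the death share of the
#' closure delay.
#'
#' For the first-order model the point is projected onto the curve through
#' its closure change: the abscissa `dc_fit = -log(1 - wc/wc_max) / k`
#' replaces the noisy observed `dc`, and
#' `theta = arctan(1 / (k * (wc_max - wc)))`. A point at or beyond `wc_max`
#' has no tangent and is clamped to pi/2 with a warning. For the linear
#' model `theta = arctan(max(slope, 0))` (a negative fitted slope cannot
#' mean negative death share).
#'
#' @param fit a [fit_landscape()] result.
#' @param wc observed wound-closure change of the dose point.
#' @param dc observed death change of the dose point.
#' @return Angle in radians, clamped to `[0, pi/2]`.
#' @export
theta_at <- function(fit, wc, dc) {
  stopifnot(inherits(fit, "ws_landscape_fit"))
  if (fit$model == "linear")
    return(min(max(atan(max(fit$params$slope_dc_per_wc, 0)), 0), pi / 2))
  wc_max <- fit$params$wc_max
  k <- fit$params$k
  wcc <- max(wc, 0)
  if (wcc >= wc_max) {
    warning("wc = ", signif(wc, 4), " at or beyond fitted wc_max = ",
            signif(wc_max, 4), "; tangent undefined, theta clamped to pi/2")
    return(pi / 2)
  }
  # tangent at the projected abscissa: dWC/dDC = wc_max*k*exp(-k*dc_fit)
  #                                           = k*(wc_max - wc)
  min(max(atan(1 / (k * (wc_max - wcc))), 0), pi / 2)
}

#' Per-dose migration and death scores
#'
#' Splits each dose's closure delay into the two phenotypes by the tangent
#' rule: `death = wc * theta/(pi/2)` and `migration = wc - death`, using
#' `max(wc, 0)` so that doses where the drug *accelerates* closure score
#' (0, 0) and are flagged `closure_enhancement`.
#'
#' @param fit a [fit_landscape()] result for the same series.
#' @param metrics the metrics data frame the fit was produced from.
#' @return A data frame ordered by ascending concentration: `concentration`,
#'   `wc`, `dc`, `theta`, `migration`, `death`, `closure_enhancement`.
#' @export
phenotype_scores <- function(fit, metrics) {
  stopifnot(inherits(fit, "ws_landscape_fit"))
  dosed <- metrics[metrics$concentration > 0, , drop = FALSE]
  dosed <- dosed[order(dosed$concentration), , drop = FALSE]
  n <- nrow(dosed)
  theta <- migration <- death <- numeric(n)
  for (i in seq_len(n)) {
    theta[i] <- theta_at(fit, dosed$wc[i], dosed$dc[i])
    wcc <- max(dosed$wc[i], 0)
    death[i] <- wcc * theta[i] / (pi / 2)
    migration[i] <- wcc - death[i]
  }
  data.frame(concentration = dosed$concentration, wc = dosed$wc,
             dc = dosed$dc, theta = theta, migration = migration,
             death = death, closure_enhancement = dosed$wc < 0,
             row.names = NULL)
}

#' Lumped (dose-cumulative) phenotype scores
#'
#' Summarizes a concentration series into one migration and one death score
#' by the normalized AUC over the log2-dose axis (the dose design is a
#' two-fold serial dilution, so log2 spacing is uniform): the trapezoidal
#' integral of each score against log2(concentration) divided by the
#' log2-range. A constant score c lumps to c for any dose grid.
#'
#' @param scores data frame from [phenotype_scores()], >= 2 concentrations.
#' @return A list of class `ws_lumped`: `migration_lumped`, `death_lumped`,
#'   and their difference `bias_lumped = death_lumped - migration_lumped`.
#' @export
lumped_scores <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("concentration", "migration", "death") %in% names(scores)))
  conc <- scores$concentration
  if (length(conc) < 2L)
    stop("insufficient-data error: lumped scores need >= 2 concentrations")
  if (any(diff(conc) <= 0))
    stop("concentrations must be strictly increasing")
  lx <- log2(conc)
  span <- lx[length(lx)] - lx[1L]
  trapz <- function(y) sum(diff(lx) * (y[-length(y)] + y[-1L]) / 2)
  mig <- trapz(scores$migration) / span
  dth <- trapz(scores$death) / span
  structure(list(migration_lumped = mig, death_lumped = dth,
                 bias_lumped = dth - mig),
            class = "ws_lumped")
}

#' @export
print.ws_lumped <- function(x, ...) {
  cat("<lumped scores> migration ", signif(x$migration_lumped, 4),
      ", death ", signif(x$death_lumped, 4),
      " (bias ", signif(x$bias_lumped, 4), ")\n", sep = "")
  invisible(x)
}
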