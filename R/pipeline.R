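#' Score a plate dataset end to end
#'
#' The full pipeline: averages replicates, computes closure/death metrics
#' per stratum, then for every treated (cell line, drug, density, MMC)
#' series fits the death-closure landscape, decomposes each dose's closure
#' delay into migration and death, lumps the dose series, derives the bias
#' profile, and classifies the drug.
#'
#' @param dataset a [plate_dataset()].
#' @param config an [analysis_config()].
#' @return A list of class `ws_result`:
#'   * `metrics` — per-condition closure/death metrics;
#'   * `scores` — per-dose scores with bias columns, one row per
#'     (cell line, drug, density, concentration);
#'   * `series` — one row per series: lumped scores, classification,
#'     fitted model and its r-squared;
#'   * `fits` — named list of `ws_landscape_fit` objects;
#'   * `config` — the configuration used.
#' @export
score_plate <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "ws_plate"), inherits(config, "ws_config"))
  dataset <- aggregate_replicates(dataset)
  metrics <- plate_metrics(dataset, config)

  treated <- metrics[metrics$concentration > 0, , drop = FALSE]
  skey <- paste(treated$cell_line, treated$drug, treated$density,
                treated$mmc, sep = "\r")
  fits <- list()
  scores_rows <- list()
  series_rows <- list()
  for (key in unique(skey)) {
    rows <- treated[skey == key, , drop = FALSE]
    ctrl <- metrics[metrics$concentration == 0 &
                      metrics$cell_line == rows$cell_line[1L] &
                      metrics$density == rows$density[1L] &
                      metrics$mmc == rows$mmc[1L], , drop = FALSE]
    ser <- rbind(ctrl, rows)
    fit <- fit_landscape(ser, r2_threshold = config$r2_threshold)
    sc <- phenotype_scores(fit, ser)
    bp <- bias_profile(sc)
    lump <- lumped_scores(sc)
    label <- classify_drug(lump, config$activity_floor, config$bias_floor)
    id <- data.frame(cell_line = rows$cell_line[1L], drug = rows$drug[1L],
                     density = rows$density[1L], mmc = rows$mmc[1L],
                     stringsAsFactors = FALSE)
    sc_out <- cbind(id[rep(1L, nrow(sc)), , drop = FALSE], sc,
                    bias = bp$bias, distance = bp$distance,
                    angle = bp$angle)
    rownames(sc_out) <- NULL
    fits[[gsub("\r", "/", key)]] <- fit
    scores_rows[[key]] <- sc_out
    series_rows[[key]] <- cbind(
      id,
      data.frame(model = fit$model, r2 = fit$r2,
                 migration_lumped = lump$migration_lumped,
                 death_lumped = lump$death_lumped,
                 bias_lumped = lump$bias_lumped,
                 classification = label, stringsAsFactors = FALSE))
  }
  structure(list(metrics = metrics,
                 scores = do.call(rbind, unname(scores_rows)),
                 series = do.call(rbind, unname(series_rows)),
                 fits = fits, config = config),
            class = "ws_result")
}

#' @export
print.ws_result <- function(x, ...) {
  cat("<scored plate> endpoint method ", x$config$endpoint_method, "; ",
      nrow(x$metrics), " conditions, ",
      if (is.null(x$series)) 0L else nrow(x$series), " series\n", sep = "")
  if (!is.null(x$series))
    print(x$series[, c("cell_line", "drug", "density", "model",
                       "migration_lumped", "death_lumped",
                       "classification")], digits = 3)
  invisible(x)
}

#' Robustness of bias profiles across seeding densities
#'
#' For every (cell line, drug, MMC) series scored at two or more seeding
#' densities, compares the per-dose bias values of each density pair with
#' the two-sample KS test ([ks_compare()]). A significant distance means
#' the phenotypic readout depends on how many cells were plated — an
#' artifact the endpoint choice should minimize.
#'
#' @param result a [score_plate()] result (or its `scores` data frame).
#' @param alpha significance level; defaults to the result's `ks_alpha`.
#' @return A data frame, one row per density pair per series: `cell_line`,
#'   `drug`, `mmc`, `density_a`, `density_b`, `ks_distance`, `p_value`,
#'   `significant`, `endpoint_method`.
#' @export
density_robustness <- function(result, alpha = NULL) {
  if (inherits(result, "ws_result")) {
    scores <- result$scores
    if (is.null(alpha)) alpha <- result$config$ks_alpha
    method <- result$config$endpoint_method
  } else {
    scores <- result
    if (is.null(alpha)) alpha <- 0.05
    method <- NA_character_
  }
  stopifnot(is.data.frame(scores),
            all(c("cell_line", "drug", "density", "bias") %in% names(scores)))
  gkey <- paste(scores$cell_line, scores$drug, scores$mmc, sep = "\r")
  out <- list()
  for (key in unique(gkey)) {
    g <- scores[gkey == key, , drop = FALSE]
    dens <- sort(unique(g$density))
    if (length(dens) < 2L) next
    for (i in seq_len(length(dens) - 1L)) for (j in (i + 1L):length(dens)) {
      ks <- ks_compare(g$bias[g$density == dens[i]],
                       g$bias[g$density == dens[j]],
                       alpha = alpha,
                       pair = as.character(dens[c(i, j)]))
      out[[length(out) + 1L]] <- data.frame(
        cell_line = g$cell_line[1L], drug = g$drug[1L], mmc = g$mmc[1L],
        density_a = dens[i], density_b = dens[j],
        ks_distance = ks$ks_distance, p_value = ks$p_value,
        significant = ks$significant, endpoint_method = method,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    stop("density_robustness needs >= 2 densities for at least one series")
  do.call(rbind, out)
}
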