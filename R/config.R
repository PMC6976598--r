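#' Analysis configuration
#'
#' Bundles the tunable parameters of the scoring pipeline.
#'
#' The analysis window for AUC-based scoring is chosen by `endpoint_method`:
#' * `"A"` — fixed experiment endpoint (`fixed_endpoint`, default 72 h);
#' * `"B"` — the time at which the vehicle-control closure rate declines
#'   below `slope_threshold` (RWD fraction per hour), applied to every
#'   condition of the stratum;
#' * `"C"` — the per-condition time at which RWD first reaches `rwd_target`
#'   (falling back to the last observed time when never reached).
#'
#' @param endpoint_method one of `"A"`, `"B"`, `"C"`.
#' @param fixed_endpoint hours; analysis window for method A.
#' @param slope_threshold RWD fraction per hour; method B decline threshold.
#' @param rwd_target fraction in (0, 1); closure target for method C (and
#'   the basis of the method-B plateau guard).
#' @param r2_threshold r-squared below which the first-order landscape fit is
#'   replaced by the linear fallback.
#' @param ks_alpha significance level for density-robustness KS tests.
#' @param slope_smooth_window odd integer; moving-average width applied to
#'   the control slope series in method B.
#' @param slope_guard RWD fraction the control must exceed before the
#'   method-B decline search starts (guards against the initial lag
#'   plateau); defaults to `rwd_target / 2`.
#' @param activity_floor minimum lumped migration + death below which a drug
#'   is classified inactive.
#' @param bias_floor minimum |lumped death - lumped migration| needed to call
#'   a drug migrastatic or cytotoxic rather than balanced.
#' @return A list of class `ws_config`.
#' @export
analysis_config <- function(endpoint_method = "A",
                            fixed_endpoint = 72,
                            slope_threshold = 0.02,
                            rwd_target = 0.5,
                            r2_threshold = 0.6,
                            ks_alpha = 0.05,
                            slope_smooth_window = 3L,
                            slope_guard = NULL,
                            activity_floor = 0.05,
                            bias_floor = 0.05) {
  endpoint_method <- match.arg(endpoint_method, c("A", "B", "C"))
  if (is.null(slope_guard)) slope_guard <- rwd_target / 2
  stopifnot(fixed_endpoint > 0, slope_threshold > 0,
            rwd_target > 0, rwd_target < 1,
            r2_threshold > 0, r2_threshold < 1,
            ks_alpha > 0, ks_alpha < 1,
            slope_smooth_window >= 1, slope_smooth_window %% 2 == 1,
            slope_guard >= 0, slope_guard < 1,
            activity_floor >= 0, bias_floor >= 0)
  structure(
    list(endpoint_method = endpoint_method,
         fixed_endpoint = as.numeric(fixed_endpoint),
         slope_threshold = as.numeric(slope_threshold),
         rwd_target = as.numeric(rwd_target),
         r2_threshold = as.numeric(r2_threshold),
         ks_alpha = as.numeric(ks_alpha),
         slope_smooth_window = as.integer(slope_smooth_window),
         slope_guard = as.numeric(slope_guard),
         activity_floor = as.numeric(activity_floor),
         bias_floor = as.numeric(bias_floor)),
    class = "ws_config")
}

#' @export
print.ws_config <- function(x, ...) {
  cat("<analysis config> endpoint method ", x$endpoint_method, "\n", sep = "")
  for (f in setdiff(names(x), "endpoint_method"))
    cat("  ", f, ": ", x[[f]], "\n", sep = "")
  invisible(x)
}

#' Read an analysis configuration from YAML or JSON
#'
#' The file may set any subset of the [analysis_config()] fields; unset
#' fields keep their defaults. Unknown field names are an error so that
#' typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `ws_config` object.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
                 yaml = , yml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("unsupported config format '.", ext,
                      "': use YAML or JSON"))
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}
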