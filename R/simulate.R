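#' Simulator parameters
#'
#' Parameters of the mechanistic scratch-assay generator. The wound closes
#' by cell migration at front speed `v` (fraction of the wound per hour)
#' while cells die at rate `delta` (per hour); both respond to dose through
#' Hill functions:
#'
#' * `v = v0 * (density/density_ref)^density_exponent * (1 - emax_mig * H_mig(d))`
#' * `delta = delta0 + dmax * H_death(d)`, `H(d) = d^h / (ec50^h + d^h)`.
#'
#' Only surviving cells advance the front, so
#' `RWD(t) = 1 - exp(-v * (1 - exp(-delta * t)) / delta)` (limit `v * t` as
#' `delta -> 0`): death both slows closure and caps its plateau, which is
#' exactly the confound — cytotoxicity mimicking migration inhibition in
#' the raw closure trace — that the scoring pipeline must disentangle. The
#' caspase-3/7 reporter integrates death:
#' `caspase(t) = caspase_baseline + caspase_gain * (1 - exp(-delta * t))`.
#' Observation noise is multiplicative lognormal (signals stay positive),
#' seeded per well from `(seed, condition)` so any subset of wells is
#' reproducible independently of generation order.
#'
#' Defaults emulate an intermediate-motility bile-duct cancer line under
#' MMC: half-closure in ~7 h at the reference density of 30,000 cells/well,
#' faster closure at higher seeding density, sub-micromolar motility
#' inhibition and a death response shifted to higher doses (so the default
#' mixed compound is low-dose migrastatic, high-dose cytotoxic).
#'
#' @param v0 closure front speed at the reference density, per hour.
#' @param density_ref reference seeding density, cells per well.
#' @param density_exponent power-law exponent of speed vs density.
#' @param delta0 baseline (vehicle) death rate, per hour.
#' @param emax_mig,ec50_mig,hill_mig Hill parameters of motility inhibition
#'   (`emax_mig` in \[0, 1\]; `ec50_mig` in micromolar).
#' @param dmax,ec50_death,hill_death Hill parameters of death induction
#'   (`dmax` per hour; `ec50_death` in micromolar).
#' @param caspase_gain AU per unit cumulative death fraction.
#' @param caspase_baseline AU, reporter background.
#' @param noise_sd lognormal sigma of per-sample multiplicative noise.
#' @param seed integer master seed; fixes all randomness.
#' @param sample_interval hours between samples (default 2).
#' @param duration total monitored time in hours (default 72).
#' @return A list of class `ws_sim_params`.
#' @export
sim_params <- function(v0 = 0.1, density_ref = 30000,
                       density_exponent = 0.5, delta0 = 0.002,
                       emax_mig = 0.9, ec50_mig = 0.5, hill_mig = 1.5,
                       dmax = 0.15, ec50_death = 2.5, hill_death = 2,
                       caspase_gain = 1000, caspase_baseline = 50,
                       noise_sd = 0.02, seed = 1L,
                       sample_interval = 2, duration = 72) {
  stopifnot(v0 >= 0, density_ref > 0, delta0 >= 0,
            emax_mig >= 0, emax_mig <= 1, ec50_mig > 0, hill_mig > 0,
            dmax >= 0, ec50_death > 0, hill_death > 0,
            caspase_gain >= 0, caspase_baseline >= 0, noise_sd >= 0,
            sample_interval > 0, duration >= 3 * sample_interval)
  structure(as.list(environment()), class = "ws_sim_params")
}

hill <- function(d, ec50, h) {
  ifelse(d <= 0, 0, d^h / (ec50^h + d^h))
}

# Deterministic 31-bit seed from the master seed and the well's condition,
# so each well's noise stream is independent of generation order.
well_seed <- function(seed, cond) {
  s <- paste(seed, cond$cell_line, cond$drug,
             format(cond$concentration, digits = 15), cond$density,
             as.integer(cond$mmc), cond$replicate, sep = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# True per-condition rates implied by the parameters.
true_rates <- function(params, cond) {
  d <- cond$concentration
  v <- params$v0 * (cond$density / params$density_ref)^params$density_exponent *
    (1 - params$emax_mig * hill(d, params$ec50_mig, params$hill_mig))
  delta <- params$delta0 + params$dmax * hill(d, params$ec50_death,
                                              params$hill_death)
  list(v = v, delta = delta)
}

#' Simulate one well
#'
#' Evaluates the closed-form closure and caspase kinetics for a condition
#' (see [sim_params()]) on the sampling grid and applies per-sample
#' multiplicative lognormal noise. RWD is clamped to \[0, 1\] after noise.
#'
#' @param params a [sim_params()] object.
#' @param cond a [condition()].
#' @return A [well_timeseries()].
#' @export
simulate_well <- function(params, cond) {
  stopifnot(inherits(params, "ws_sim_params"), inherits(cond, "ws_condition"))
  times <- seq(0, params$duration, by = params$sample_interval)
  r <- true_rates(params, cond)
  # cumulative death fraction 1 - S(t); (1 - e^(-delta t))/delta -> t as
  # delta -> 0
  if (r$delta == 0) {
    eff_t <- times
    dead <- numeric(length(times))
  } else {
    dead <- -expm1(-r$delta * times)
    eff_t <- dead / r$delta
  }
  rwd <- -expm1(-r$v * eff_t)
  caspase <- params$caspase_baseline + params$caspase_gain * dead
  if (params$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(well_seed(params$seed, cond))
    n <- length(times)
    rwd <- rwd * exp(stats::rnorm(n, 0, params$noise_sd))
    caspase <- caspase * exp(stats::rnorm(n, 0, params$noise_sd))
  }
  well_timeseries(cond, times, pmin(pmax(rwd, 0), 1), pmax(caspase, 0))
}

#' Default eight-point two-fold dilution series
#'
#' @param top top concentration in micromolar (default 10).
#' @param n number of doses (default 8).
#' @return Concentrations in ascending order, micromolar.
#' @export
twofold_doses <- function(top = 10, n = 8L) {
  sort(top / 2^(seq_len(n) - 1L))
}

#' Simulate a full screen with known ground truth
#'
#' Generates a plate dataset for one drug under a named effect scenario:
#'
#' * `pure_migrastatic` — motility inhibition only (`dmax = 0`);
#' * `pure_cytotoxic` — death induction only (`emax_mig = 0`);
#' * `mixed` — both, with `ec50_death > ec50_mig` (low-dose migrastatic,
#'   high-dose cytotoxic);
#' * `null` — no drug effect at all.
#'
#' Every (density) stratum gets its vehicle (DMSO) wells. The true per-well
#' rates are recorded in `metadata$ground_truth`. The dataset is fully
#' reproducible from `params$seed`.
#'
#' @param params a [sim_params()] object; its Hill parameters are
#'   overridden as the scenario dictates.
#' @param scenario one of `"pure_migrastatic"`, `"pure_cytotoxic"`,
#'   `"mixed"`, `"null"`.
#' @param densities seeding densities, cells per well.
#' @param doses treated concentrations in micromolar (default the 8-point
#'   two-fold series from 10).
#' @param replicates biological replicates per condition.
#' @param cell_line,drug labels for the simulated line and compound.
#' @return A [plate_dataset()].
#' @export
simulate_screen <- function(params = sim_params(),
                            scenario = c("pure_migrastatic",
                                         "pure_cytotoxic", "mixed", "null"),
                            densities = 30000,
                            doses = twofold_doses(),
                            replicates = 2L,
                            cell_line = "SIM-1",
                            drug = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(all(doses > 0), replicates >= 1L, length(densities) >= 1L)
  params <- switch(scenario,
    pure_migrastatic = { params$dmax <- 0; params },
    pure_cytotoxic = { params$emax_mig <- 0; params },
    mixed = {
      if (params$ec50_death <= params$ec50_mig)
        stop("mixed scenario requires ec50_death > ec50_mig")
      params
    },
    null = { params$dmax <- 0; params$emax_mig <- 0; params })
  if (is.null(drug))
    drug <- paste0("SIM-", toupper(substr(scenario, 1, 3)))
  wells <- list()
  truth <- list()
  for (dens in densities) {
    for (rep in seq_len(replicates)) {
      conds <- c(list(condition(cell_line, "DMSO", 0, dens,
                                replicate = rep)),
                 lapply(sort(doses), function(d)
                   condition(cell_line, drug, d, dens, replicate = rep)))
      for (cond in conds) {
        wells[[length(wells) + 1L]] <- simulate_well(params, cond)
        r <- true_rates(params, cond)
        truth[[length(truth) + 1L]] <- data.frame(
          cell_line = cond$cell_line, drug = cond$drug,
          concentration = cond$concentration, density = cond$density,
          replicate = cond$replicate, v = r$v, delta = r$delta,
          scenario = scenario, stringsAsFactors = FALSE)
      }
    }
  }
  plate_dataset(wells,
                metadata = list(scenario = scenario, seed = params$seed,
                                ground_truth = do.call(rbind, truth)))
}

#' Write a simulated screen to disk
#'
#' Emits the CSV pair read by [read_timeseries()] plus a ground-truth JSON
#' (true front speed and death rate per well, and the scenario) for test
#' harnesses.
#'
#' @param dataset a dataset from [simulate_screen()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_screen <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ws_plate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts_path <- file.path(dir, "timeseries.csv")
  pm_path <- file.path(dir, "plate_map.csv")
  gt_path <- file.path(dir, "ground_truth.json")
  write_plate_dataset(dataset, ts_path, pm_path)
  gt <- dataset$metadata$ground_truth
  jsonlite::write_json(
    list(scenario = dataset$metadata$scenario,
         seed = dataset$metadata$seed,
         wells = gt),
    gt_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(ts_path, pm_path, gt_path))
}
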