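test_that("trapezoid_auc matches closed-form integrals of linear traces", {
  expect_equal(trapezoid_auc(c(0, 1, 2), c(0, 1, 2), 2), 2)
  expect_equal(trapezoid_auc(seq(0, 72, 2), rep(1, 37), 72), 72)
  # t_end between samples: 1 (triangle to t=2) + 0.75 (strip over [2,3])
  expect_equal(trapezoid_auc(c(0, 2, 4), c(0, 1, 0), 3), 1.75)
  expect_error(trapezoid_auc(c(0, 2, 4), c(0, 1, 0), 5), "window error")
  expect_error(trapezoid_auc(c(0, 2, 4), c(0, 1, 0), 0), "window error")
})

test_that("trapezoid_auc is exact on random piecewise-linear traces", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    times <- cumsum(c(0, runif(n - 1, 0.5, 3)))
    vals <- runif(n, 0, 2)
    t_end <- runif(1, times[2], times[n])
    # oracle: sum of exact segment integrals of the interpolant
    grid <- sort(unique(c(times[times <= t_end], t_end)))
    v <- stats::approx(times, vals, xout = grid)$y
    oracle <- sum(diff(grid) * (v[-length(v)] + v[-1]) / 2)
    expect_equal(trapezoid_auc(times, vals, t_end), oracle, tolerance = 1e-12)
  }
})

test_that("time_to_rwd interpolates the first crossing", {
  w <- mk_well(c(0, 2, 4, 6), c(0, 0.25, 0.5, 0.75))
  expect_equal(time_to_rwd(w, 0.5), 4)
  w2 <- mk_well(c(0, 2, 4), c(0, 0.4, 0.8))
  expect_equal(time_to_rwd(w2, 0.5), 2.5)
  w3 <- mk_well(c(0, 2, 4), c(0, 0.2, 0.3))
  expect_true(is.na(time_to_rwd(w3, 0.5)))
})

test_that("endpoint criteria A, B and C give their characteristic windows", {
  cfg_a <- analysis_config("A")
  times <- seq(0, 72, by = 2)
  ctrl <- mk_well(times, pmin(times / 24, 1))
  trt <- mk_well(times, 1 - exp(-0.1 * times), drug = "DrugX", conc = 5)
  stratum <- list(ctrl, trt)
  expect_equal(endpoint_time(stratum, cfg_a, trt$condition), 72)

  # control closes linearly in 24 h: smoothed central-difference slope first
  # drops below 0.02/h at 26 h (enumerated on the 2 h grid)
  cfg_b <- analysis_config("B")
  expect_equal(endpoint_time(stratum, cfg_b, trt$condition), 26)
  expect_equal(endpoint_time(stratum, cfg_b, ctrl$condition), 26)
  expect_error(endpoint_time(list(trt), cfg_b, trt$condition),
               "stratum error")

  # per-condition half-closure time, ln(2)/0.1 up to grid interpolation
  cfg_c <- analysis_config("C")
  expect_equal(endpoint_time(stratum, cfg_c, trt$condition),
               log(2) / 0.1, tolerance = 0.01)
  # unreachable target falls back to the last observed time
  slow <- mk_well(times, pmin(times / 400, 1), drug = "DrugY", conc = 5)
  stratum2 <- list(ctrl, slow)
  expect_equal(endpoint_time(stratum2, cfg_c, slow$condition), 72)
})

test_that("method B guard ignores the initial lag plateau", {
  times <- seq(0, 72, by = 2)
  # flat (slope 0) for 10 h, then linear closure: without the guard the
  # initial plateau would trigger at t = 0
  rwd <- pmin(pmax(times - 10, 0) / 24, 1)
  ctrl <- mk_well(times, rwd)
  t_b <- endpoint_time(list(ctrl), analysis_config("B"), ctrl$condition)
  expect_gt(t_b, 10)
})

test_that("closure and death changes follow the control-normalized formulas", {
  times <- c(0, 1, 2)
  cfg <- analysis_config("A", fixed_endpoint = 2)
  ctrl <- mk_well(times, c(0, 0.5, 1), caspase = rep(5, 3))
  t1 <- mk_well(times, c(0, 0.5, 1), caspase = rep(15, 3),
                drug = "DrugX", conc = 5)
  t2 <- mk_well(times, c(0, 0, 0), caspase = rep(20, 3),
                drug = "DrugX", conc = 10)
  m <- closure_death_metrics(list(ctrl, t1, t2), cfg)
  m <- m[order(m$concentration), ]
  # control: wc = 0, dc = 0 by construction
  expect_equal(m$wc[1], 0)
  expect_equal(m$dc[1], 0)
  # treated AUC(RWD) equal to control: no closure effect
  expect_equal(m$wc[2], 0)
  expect_equal(m$wc_ind[2], 1)
  # AUC(D): ctrl 10, t1 30, max 40 -> dc = (30 - 10)/40
  expect_equal(m$dc[2], 0.5)
  # full block: wc = 1, wc_ind = 0
  expect_equal(m$wc[3], 1)
  expect_equal(m$wc_ind[3], 0)
  expect_true(all(abs(m$wc + m$wc_ind - 1) <= 1e-12))
})

test_that("dc is clamped at zero with the raw value retained", {
  times <- c(0, 1, 2)
  cfg <- analysis_config("A", fixed_endpoint = 2)
  ctrl <- mk_well(times, c(0, 0.5, 1), caspase = rep(10, 3))
  protect <- mk_well(times, c(0, 0.4, 0.8), caspase = rep(4, 3),
                     drug = "DrugX", conc = 5)
  m <- closure_death_metrics(list(ctrl, protect), cfg)
  row <- m[m$concentration > 0, ]
  expect_equal(row$dc, 0)
  expect_lt(row$dc_raw, 0)
})

test_that("wc is antitone in treated closure AUC and dc monotone in death AUC", {
  times <- seq(0, 72, by = 2)
  cfg <- analysis_config("A")
  ctrl <- mk_well(times, pmin(times / 24, 1), caspase = rep(5, 37))
  rates <- c(30, 40, 60)
  wells <- c(list(ctrl), lapply(seq_along(rates), function(i)
    mk_well(times, pmin(times / rates[i], 1),
            caspase = rep(5 + 3 * i, 37), drug = "DrugX",
            conc = 2.5 * 2^(i - 1))))
  m <- closure_death_metrics(wells, cfg)
  m <- m[order(m$concentration), ]
  # slower closure (larger fill time) at higher dose -> smaller AUC -> larger wc
  expect_true(all(diff(m$wc[m$concentration > 0]) > 0))
  expect_true(all(diff(m$dc[m$concentration > 0]) > 0))
})

test_that("method C compares time-averaged AUCs across unequal windows", {
  # treated closes at half speed but with identical shape: time-averaged
  # RWD up to the half-closure time is identical, so wc = 0
  times <- seq(0, 72, by = 2)
  cfg <- analysis_config("C")
  ctrl <- mk_well(times, pmin(times / 24, 1), caspase = rep(5, 37))
  trt <- mk_well(times, pmin(times / 48, 1), caspase = rep(5, 37),
                 drug = "DrugX", conc = 5)
  m <- closure_death_metrics(list(ctrl, trt), cfg)
  expect_equal(m$window_end[m$concentration == 0], 12)
  expect_equal(m$window_end[m$concentration > 0], 24)
  expect_equal(m$wc[m$concentration > 0], 0, tolerance = 1e-12)
})

test_that("degenerate strata are reported", {
  times <- c(0, 1, 2)
  cfg <- analysis_config("A", fixed_endpoint = 2)
  ctrl0 <- mk_well(times, c(0, 0, 0), caspase = rep(5, 3))
  expect_error(closure_death_metrics(list(ctrl0), cfg),
               "degenerate-control")
  ctrl <- mk_well(times, c(0, 0.5, 1), caspase = rep(0, 3))
  trt <- mk_well(times, c(0, 0.4, 0.8), caspase = rep(0, 3),
                 drug = "DrugX", conc = 5)
  expect_warning(m <- closure_death_metrics(list(ctrl, trt), cfg),
                 "AUC\\(D\\) maximum is zero")
  expect_true(all(m$dc == 0))
})
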