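test_that("running median smooths as specified, including edges", {
  ## constant series unchanged
  expect_equal(running_median(rep(4, 50), 30, 1), rep(4, 50))
  ## single-frame spike removed with window >= 3
  x <- rep(10, 30); x[15] <- 100
  expect_equal(running_median(x, 3, 1), rep(10, 30))
  ## median filtering is idempotent on a two-level step series
  step <- c(rep(2, 20), rep(8, 20))
  once <- running_median(step, 5, 1)
  expect_equal(running_median(once, 5, 1), once)
  ## and output values are always drawn from the input range
  expect_true(all(once >= 2 & once <= 8))
  ## truncated-edge behaviour matches a naive centered-window oracle
  set.seed(71)
  y <- rnorm(40)
  k <- 7; h <- 3
  oracle <- vapply(seq_along(y), function(i)
    median(y[max(1, i - h):min(40, i + h)]), 1)
  expect_equal(running_median(y, k, 1), oracle)
  ## window below one frame interval is rejected
  expect_error(running_median(y, 0.5, 1), "frame interval")
})

test_that("binding and unbinding detection follow the hysteresis rule", {
  mk <- function(d, dt = 10) data.table::data.table(
    frame = seq_along(d), time_ns = (seq_along(d) - 1) * dt,
    distance = d, smoothed = d)
  ## distance stepping to 5 A at 2 us
  d1 <- mk(c(rep(30, 200), rep(5, 100)))
  b <- detect_binding(d1)
  expect_equal(b$t_on, 2)
  expect_false(b$censored)
  ## never approaches: censored
  b2 <- detect_binding(mk(rep(35, 100)))
  expect_true(b2$censored)
  expect_equal(b2$censor_time, 0.99)
  ## bound at 4 A, jumps to 25 A after 0.5 us (from block start)
  d3 <- mk(c(rep(4, 50), rep(25, 50)))
  u <- detect_unbinding(d3, block_start = 0)
  expect_equal(u$t_off, 0.5)
  ## excursion between d_on and d_off: no unbinding (hysteresis)
  d4 <- mk(c(rep(4, 30), rep(15, 40), rep(4, 30)))
  expect_true(detect_unbinding(d4, block_start = 0)$censored)
  expect_error(detect_unbinding(d4, block_start = 5), "beyond")
  ## config validation
  expect_error(blocker_config(d_on = 20, d_off = 10), "d_off > d_on")
})

test_that("detection is invariant to flipping isolated frames (window >= 3)", {
  set.seed(72)
  base <- c(rep(30, 300), rep(4, 300), rep(30, 300))
  flip <- base
  idx <- seq(10, 890, by = 40)          # isolated single frames
  flip[idx] <- ifelse(base[idx] > 10, 4, 30)
  mk <- function(d) data.table::data.table(
    frame = seq_along(d), time_ns = (seq_along(d) - 1) * 10,
    distance = d, smoothed = running_median(d, 30, 10))
  expect_equal(detect_binding(mk(flip))$t_on,
               detect_binding(mk(base))$t_on)
  expect_equal(detect_unbinding(mk(flip), block_start = 3)$t_off,
               detect_unbinding(mk(base), block_start = 3)$t_off)
})

test_that("censored exponential MLE and its chi-squared interval", {
  e1 <- estimate_tau(c(2, 4, 6))
  expect_equal(e1$tau, 4)
  e2 <- estimate_tau(c(3, 5), censored = 10)
  expect_equal(e2$tau, 9)               # (3+5+10)/2
  expect_lt(e2$ci_lo, 9); expect_gt(e2$ci_hi, 9)
  ## zero uncensored events: lower bound only
  e3 <- estimate_tau(numeric(0), censored = c(10, 10, 10))
  expect_true(is.na(e3$tau))
  expect_gt(e3$lower_bound, 0)
  ## unbiased on uncensored samples: 1000 batches at n = 50
  set.seed(73)
  tau_hats <- replicate(1000, estimate_tau(rexp(50, 1 / 7))$tau)
  expect_equal(mean(tau_hats), 7, tolerance = 0.02)
  ## CI coverage is approximately nominal
  covered <- replicate(500, {
    e <- estimate_tau(rexp(30, 1 / 7))
    e$ci_lo <= 7 && 7 <= e$ci_hi
  })
  expect_gt(mean(covered), 0.90)
})

test_that("station classification matches an interval-scan oracle", {
  g <- default_geometry()
  expect_equal(classify_station(-42, g), "CTD")
  expect_equal(classify_station(-8, g), "above_D173")   # D173 plane to SF
  expect_equal(classify_station(-70, g), "bulk")
  expect_equal(classify_station(2, g), "SF")
  expect_equal(classify_station(20, g), "translocated")
  set.seed(74)
  z <- runif(2000, -80, 40)
  breaks <- c(-55, -30, -20, -10, -6.6, 16.5)
  bands <- c("bulk", "CTD", "G_loop", "cavity", "above_D173", "SF",
             "translocated")
  oracle <- vapply(z, function(zz) bands[sum(zz >= breaks) + 1L], "")
  expect_identical(classify_station(z, g), oracle)
})

test_that("blocker distance detection matches the ground-truth log", {
  sc <- scenario_preset("WT", voltage = 215)
  for (seed in c(81, 82, 83)) {
    sim <- simulate_pore(sc$model, sc$gate, sc$blocker, duration = 30,
                         seed = seed)
    bt <- log_spm_times(sim)$bind
    if (!length(bt)) next
    tr <- render_frames(sim, dt_ns = 10, include = c("spm", "landmarks"),
                        seed = seed + 10)
    b <- detect_binding(blocker_distance_series(tr))
    expect_false(b$censored)
    ## the 10-A criterion is first met on the approach just before the
    ## deep-site entry; agreement within the smoothing window
    expect_lt(abs(b$t_on - bt[1]), 0.05)
  }
})

test_that("displaced-ion counting uses before/after region occupancy", {
  ## constructed tracks: 6 ions vanish from the TM pore at t = 1 us
  zin <- site_z(c("S1", "S2", "S3", "S5", "S6", "S6"))
  zin[6] <- -12                          # one cavity ion
  zl <- lapply(seq_along(zin), function(i)
    c(rep(zin[i], 100), rep(30, 100)))
  names(zl) <- paste0("i", seq_along(zin))
  tr <- tracks_from_z(zl)
  d <- displaced_ions(tr, bind_time = 1, window = 0.5, pre_margin = 0.05)
  expect_equal(d$displaced, 6)
  expect_equal(d$n_before, 6)
  expect_equal(d$n_after, 0)
  ## no binding -> undefined, flagged
  expect_error(displaced_ions(tr, NA), "undefined")
  ## window past the end truncates with a warning
  expect_warning(displaced_ions(tr, bind_time = 1.8, window = 5), "truncat")
})

test_that("currents partition into blocked and unblocked segments", {
  ev <- data.table::data.table(
    particle_id = paste0("p", 1:10), direction = "outward",
    t_enter = (1:10) - 0.2, t_exit = 1:10)
  bm <- block_modulated_current(ev, rbind(c(4, 8)), duration = 10,
                                voltage = 310)
  expect_equal(bm$blocked$n_out, 4)      # events at t = 4..7 in [4, 8)
  expect_equal(bm$unblocked$n_out, 6)
  expect_equal(bm$blocked$n_out + bm$unblocked$n_out, nrow(ev))
  expect_equal(bm$t_blocked, 4)
  ## no blocker: everything unblocked
  bm2 <- block_modulated_current(ev, matrix(numeric(0), ncol = 2),
                                 duration = 10, voltage = 310)
  expect_null(bm2$blocked)
  expect_equal(bm2$unblocked$n_out, 10)
  ## a fully blocked mechanism-constrained run conducts nothing while bound
  sc <- scenario_preset("WT", voltage = 215)
  sim <- simulate_pore(sc$model, sc$gate, sc$blocker, duration = 30,
                       seed = 84)
  st <- log_spm_times(sim)
  if (length(st$bind)) {
    t_end <- if (length(st$unbind)) st$unbind[1] else sim$duration
    tr <- render_frames(sim, dt_ns = 5, include = "ions", seed = 85)
    evs <- detect_permeation_events(tr)
    bm3 <- block_modulated_current(evs, rbind(c(st$bind[1] + 0.01, t_end)),
                                   duration = sim$duration, voltage = 215)
    if (!is.null(bm3$blocked)) expect_equal(bm3$blocked$n_out, 0)
  }
})

test_that("unbinding times decrease with hyperpolarizing voltage", {
  mean_unbind <- function(V, n = 25) {
    sc <- spm_unbinding_scenario(V)
    mean(vapply(seq_len(n), function(i) {
      s <- simulate_pore(sc$model, sc$gate, sc$blocker,
                         duration = 120, seed = 9000 + 37 * i)
      u <- log_spm_times(s)$unbind
      if (length(u)) u[1] else s$duration
    }, 1))
  }
  m155 <- mean_unbind(-155)
  m215 <- mean_unbind(-215)
  m310 <- mean_unbind(-310)
  expect_gt(m155, m215)
  expect_gt(m215, m310)
})
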