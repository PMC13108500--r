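test_that("phase-shift wrapping reproduces the worked equivalence", {
  expect_equal(wrap_phase_shift(-0.7 * pi), 0.3 * pi)
  expect_equal(wrap_phase_shift(0.2 * pi), 0.2 * pi)
  expect_equal(wrap_phase_shift(1.6 * pi), -0.4 * pi)
  x <- seq(-10, 10, length.out = 401)
  expect_equal(wrap_phase_shift(wrap_phase_shift(x)), wrap_phase_shift(x))
  expect_equal(wrap_phase_shift(x + pi), wrap_phase_shift(x),
               tolerance = 1e-12)
  w <- wrap_phase_shift(x)
  expect_true(all(w >= -pi / 2 & w < pi / 2))
})

test_that("doubled-angle circular mean matches a brute-force oracle", {
  expect_equal(circ_mean(c(0.1 * pi, 0.3 * pi)), 0.2 * pi)
  expect_equal(circ_mean(rep(0.37, 10)), 0.37)
  # boundary case {+0.4 pi, -0.4 pi}: antipodal-ish pair averages to the
  # +/- pi/2 boundary, mapped to -pi/2 by convention, never to 0
  b <- circ_mean(c(0.4 * pi, -0.4 * pi))
  expect_equal(abs(b), pi / 2, tolerance = 1e-9)
  expect_lt(abs(b - (-pi / 2)), 1e-9)

  # oracle: brute-force maximizer of the doubled-angle resultant
  oracle <- function(x) {
    grid <- seq(-pi / 2, pi / 2, length.out = 20001)
    cost <- vapply(grid, function(m) sum(cos(2 * (x - m))), numeric(1))
    grid[which.max(cost)]
  }
  set.seed(31)
  for (i in 1:10) {
    x <- wrap_phase_shift(rnorm(7, sd = 0.4))
    expect_equal(circ_mean(x), oracle(x), tolerance = 5e-3)
  }
  expect_true(is.na(circ_mean(NA_real_)))
  expect_equal(circ_sd(rep(0.2, 5)), 0)
})

test_that("stimulation times hit the requested phases of the resting run", {
  # planted sinusoid run: trough at t0, period P; target pi lands at t0+P/2
  spec <- planted_sync_spec(2, group = c(1, 1), period = 0.4, drift_sd = 0,
                            n_samples = 1200, seed = 5)
  run <- generate_planted_oscillations(spec)
  pts <- locate_phase_times(run, 1, window_start = 100,
                            targets = pi, n_cycles = 1, poststim = 100)
  tr <- suppressWarnings(extract_phase(run))$troughs[[1]]
  t0 <- tr[tr >= 100][1]
  expect_equal(pts$sample, t0 + 20, tolerance = 0.51)  # P/2 = 20 samples

  pts50 <- locate_phase_times(run, 1, window_start = 100,
                              n_cycles = 5, poststim = 100)
  expect_equal(nrow(pts50), 50)      # 10 targets x 5 cycles
  expect_equal(unname(pts50$sample[1]), unname(t0), tolerance = 1e-9)
})

test_that("experiment design accounting matches the full-scale protocol", {
  d <- stimulation_design(regions = c(1, 3, 8, 14, 21, 27))
  expect_equal(nrow(d), 4500)
  expect_equal(nrow(d[d$region == 1, ]), 750)
  cell <- d[d$region == 1 & d$state == "Psi2" & d$phase_bin == 4, ]
  expect_equal(nrow(cell), 25)
})

test_that("a null pulse leaves the whole downstream stack at zero", {
  runs <- fx_wp_runs()
  cat_ <- fx_wp_catalog()
  con <- fx_con29()
  w <- cat_$windows
  pw <- which(w$state == "Psi1" & w$is_prototype)[1]
  run <- runs[[w$run[pw]]]
  pts <- suppressWarnings(locate_phase_times(run, 3, w$start[pw],
                                             targets = c(0, pi),
                                             n_cycles = 1))
  pair <- run_paired_experiment(run, con, 3, pts$time[1], amplitude = 0)
  expect_identical(pair$stim$re, pair$unstim$re)
  port <- phase_shift_portrait(pair)
  expect_true(all(port[is.finite(port)] == 0))
  expect_equal(group_average_portrait(list(port, port))[is.finite(port)],
               port[is.finite(port)])
})

test_that("paired runs share their pre-pulse history and replay bitwise", {
  runs <- fx_wp_runs()
  cat_ <- fx_wp_catalog()
  con <- fx_con29()
  w <- cat_$windows
  pw <- which(w$state == "Psi1" & w$is_prototype)[1]
  run <- runs[[w$run[pw]]]
  pts <- suppressWarnings(locate_phase_times(run, 3, w$start[pw],
                                             targets = pi, n_cycles = 1))
  pair <- run_paired_experiment(run, con, 3, pts$time[1], amplitude = 300)
  pair2 <- run_paired_experiment(run, con, 3, pts$time[1], amplitude = 300)
  expect_identical(pair$stim$re, pair2$stim$re)       # replay
  expect_identical(pair$unstim$re, pair2$unstim$re)
  expect_false(identical(pair$stim$re, pair$unstim$re))
  # portraits are wrapped into [-pi/2, pi/2)
  port <- phase_shift_portrait(pair)
  v <- port[is.finite(port)]
  expect_true(all(v >= -pi / 2 & v < pi / 2))
})

test_that("group averaging acts on the complex plane, elementwise", {
  a <- matrix(0.1 * pi, 2, 3)
  b <- matrix(0.3 * pi, 2, 3)
  expect_equal(group_average_portrait(list(a, b)),
               matrix(0.2 * pi, 2, 3))
  # NA entries are ignored where possible, NA where never defined
  a[1, 1] <- NA
  g <- group_average_portrait(list(a, b))
  expect_equal(g[1, 1], 0.3 * pi)
  a[, ] <- NA; b[, ] <- NA
  expect_true(all(is.na(group_average_portrait(list(a, b)))))
})

test_that("the PRC reducer averages retained trials and excludes switchers", {
  # all retained, constant shift delta: PRC = delta, SEM 0
  ex <- make_toy_experiments(dphi_value = 0.25, n_regions = 3)
  prc <- effective_prc(ex)
  expect_true(all(prc$mean_shift == 0.25))
  expect_true(all(prc$sem == 0))
  expect_true(all(prc$n_retained == 3))
  expect_true(all(prc$n_switched == 0))

  # every trial switches: bins undefined with n = 0, never zero-filled
  ex2 <- make_toy_experiments(dphi_value = 0.25, n_regions = 3,
                              end_stim = "Psi2")
  prc2 <- effective_prc(ex2)
  expect_true(all(is.na(prc2$mean_shift)))
  expect_true(all(prc2$n_retained == 0))
  expect_true(all(prc2$n_switched == 3))
  # accounting: retained + switched + failed covers every trial of a cell
  expect_true(all(prc2$n_retained + prc2$n_switched + prc2$n_failed == 3))
})

test_that("switching statistics subtract the matched spontaneous rate", {
  same <- make_toy_experiments(end_stim = "Psi1", end_unstim = "Psi1")
  sw <- switching_statistics(same)
  expect_true(all(sw$delta_p == 0))

  always <- make_toy_experiments(end_stim = "Psi2", end_unstim = "Psi1")
  sw2 <- switching_statistics(always)
  expect_true(all(sw2$p_stim == 1 & sw2$p_unstim == 0 & sw2$delta_p == 1))

  suppress <- make_toy_experiments(end_stim = "Psi1", end_unstim = "None")
  sw3 <- switching_statistics(suppress)
  expect_true(all(sw3$delta_p == -1))   # suppression bound
  trans <- attr(sw3, "transitions")
  expect_equal(sum(trans), 2 * nrow(suppress$trials))
})
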