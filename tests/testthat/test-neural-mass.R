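test_that("derivatives match a hand evaluation for an isolated region", {
  p <- nm_params(G_ee = 0, I_ext = 6)
  sc <- matrix(0, 1, 1)
  d <- nm_derivatives(rep(0, 8), p, sc)
  # r' = (1/tau_e) * Delta_e / (pi tau_e) = 1/(100 pi); V' = (eta + I_ext)/tau_e
  expect_equal(d[1], 1 / (100 * pi))
  expect_equal(d[2], 0.1)
  expect_equal(d[5], 1 / (100 * pi))   # I population mirrors it
  expect_equal(d[6], 0.1)
})

test_that("G_ee = 0 decouples the network into independent regions", {
  set.seed(11)
  N <- 4
  sc <- matrix(runif(N * N), N, N); diag(sc) <- 0
  p <- nm_params(G_ee = 0)
  x <- runif(8 * N, -1, 1)
  d_net <- nm_derivatives(x, p, sc)
  for (j in seq_len(N)) {
    idx <- j + (0:7) * N
    d_one <- nm_derivatives(x[idx], p, matrix(0, 1, 1))
    expect_equal(d_net[idx], d_one, tolerance = 1e-15)
  }
})

test_that("coupling is bilinear: doubling SC and halving G_ee cancels", {
  set.seed(12)
  N <- 3
  sc <- matrix(runif(N * N), N, N); diag(sc) <- 0
  x <- runif(8 * N, -1, 1)
  d1 <- nm_derivatives(x, nm_params(G_ee = 80), sc)
  d2 <- nm_derivatives(x, nm_params(G_ee = 40), 2 * sc)
  expect_equal(d1, d2, tolerance = 1e-13)
})

test_that("heun_step reproduces the predictor-corrector hand example", {
  # x' = -x, x0 = 1, dt = 0.1: predictor 0.9, corrector 1 - 0.095 = 0.905
  out <- heun_step(1, 0.1, function(x) -x)
  expect_equal(out, 0.905)
  expect_identical(heun_step(c(1, 2), 0, function(x) -x), c(1, 2))
})

test_that("Heun is second order on the linear test equation", {
  run <- function(dt) {
    x <- 1
    for (i in seq_len(round(1 / dt))) x <- heun_step(x, dt, function(v) -v)
    abs(x - exp(-1))
  }
  e1 <- run(0.1); e2 <- run(0.05)
  expect_gt(e1 / e2, 3.5)
  expect_lt(e1 / e2, 4.5)
})

test_that("compiled simulator agrees with the pure-R reference to machine precision", {
  con <- generate_connectome(n_regions = 5, seed = 4)
  p <- nm_params()
  cfg <- sim_config(dt = 0.001, downsample = 10, n_transient = 0,
                    n_samples = 20, seed = 9)
  sim <- simulate_network(cfg, p, con)
  x <- sample_initial_conditions(9, 5)
  f <- function(v) nm_derivatives(v, p, con$weights)
  ref <- matrix(NA_real_, 5, 20)
  for (s in 1:20) {
    for (k in 1:10) x <- heun_step(x, 0.001, f)
    ref[, s] <- x[1:5]
  }
  expect_equal(unname(sim$re), ref, tolerance = 1e-13)
})

test_that("simulation is deterministic and the null stimulus is exact", {
  con <- generate_connectome(n_regions = 6, seed = 5)
  cfg <- sim_config(n_transient = 10, n_samples = 40, seed = 3)
  a <- simulate_network(cfg, nm_params(), con)
  b <- simulate_network(cfg, nm_params(), con)
  expect_identical(a$re, b$re)
  z <- simulate_network(cfg, nm_params(), con,
                        stimuli = list(stimulus_event(2, onset = 0.05,
                                                      amplitude = 0)))
  expect_identical(a$re, z$re)
})

test_that("configured lengths and spans are honoured", {
  con <- generate_connectome(n_regions = 3, seed = 6)
  cfg <- sim_config(n_transient = 5, n_samples = 50, seed = 1)
  sim <- simulate_network(cfg, nm_params(), con)
  expect_equal(ncol(sim$re), 50)
  expect_equal(sim$sampling, 0.01)
  expect_equal(diff(range(sim$time)), 49 * 0.01, tolerance = 1e-12)
  expect_error(simulate_network(cfg, nm_params(), con,
                                stimuli = list(stimulus_event(9, 0.1))),
               "unknown region")
  expect_error(simulate_network(cfg, nm_params(), con,
                                stimuli = list(stimulus_event(1, 99))),
               "outside run span")
})

test_that("initial conditions are seeded, distinct across seeds, rates non-negative", {
  a <- sample_initial_conditions(1, 29)
  b <- sample_initial_conditions(1, 29)
  c_ <- sample_initial_conditions(2, 29)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  expect_true(all(a[1:29] >= 0), all(a[4 * 29 + 1:29] >= 0))
})

test_that("an isolated region's fixed point is stationary under the integrator", {
  p <- nm_params(G_ee = 0)
  sc1 <- matrix(0, 1, 1)
  f <- function(x) nm_derivatives(x, p, sc1)
  x0 <- simulate_network(sim_config(n_transient = 0, n_samples = 1500,
                                    seed = 1), p, sc1)$final_state
  fp <- pracma::fsolve(f, x0)$x           # independent root-finder
  expect_lt(max(abs(f(fp))), 1e-7)
  sim <- simulate_network(sim_config(n_transient = 0, n_samples = 100,
                                     seed = 1), p, sc1, init = fp)
  drift <- max(abs(sim$final_state - fp))
  expect_lt(drift, 1e-8)                  # per one time unit of simulation
})

test_that("rerunning stored provenance replays the trajectory bitwise", {
  con <- generate_connectome(n_regions = 4, seed = 8)
  cfg <- sim_config(n_transient = 5, n_samples = 60, seed = 4,
                    save_full = TRUE)
  run <- simulate_network(cfg, nm_params(), con)
  rerun <- simulate_network(do.call(sim_config, run$provenance$config),
                            do.call(nm_params, run$provenance$params), con)
  expect_identical(run$re, rerun$re)
  # restart from a stored mid-run state reproduces the remaining samples
  m0 <- 20
  tail_run <- simulate_network(sim_config(n_transient = 0, n_samples = 40,
                                          seed = 4),
                               nm_params(), con,
                               init = run$full_state[, m0])
  expect_identical(unname(tail_run$re), unname(run$re[, (m0 + 1):60]))
})

test_that("the working point sustains network oscillations", {
  runs <- fx_wp_runs()
  re <- runs[[1]]$re
  half1 <- re[, 1:1500]; half2 <- re[, 1501:3000]
  # non-decaying amplitude: late oscillation range comparable to early
  r1 <- apply(half1, 1, function(x) diff(range(x)))
  r2 <- apply(half2, 1, function(x) diff(range(x)))
  expect_true(all(r2 > 0.5 * r1))
  expect_true(all(r2 > 0.05 * apply(re, 1, mean)))  # visible oscillation
})
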