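sinusoid_mts <- function(period_samples, n, phase0 = 0, amp = 1) {
  t <- seq_len(n) - 1
  matrix(amp * (1 - cos(2 * pi * t / period_samples + phase0)), nrow = 1)
}

test_that("trough-interpolated phase advances linearly and recovers the period", {
  x <- sinusoid_mts(20, 400)
  ph <- extract_phase(x)
  tr <- ph$troughs[[1]]
  expect_equal(unique(diff(tr)), 20)
  valid <- which(!is.na(ph$phi[1, ]))
  slopes <- diff(ph$phi[1, valid])
  expect_equal(slopes, rep(2 * pi / 20, length(slopes)), tolerance = 1e-9)
})

test_that("phase extraction ignores amplitude modulation preserving troughs", {
  t <- seq_len(400) - 1
  base <- 1 - cos(2 * pi * t / 20)
  env <- 1 + 0.5 * sin(2 * pi * t / 400)     # slow positive envelope
  ph1 <- extract_phase(matrix(base, 1))
  ph2 <- extract_phase(matrix(base * env, 1))
  expect_identical(ph1$troughs, ph2$troughs)
  expect_equal(ph1$phi, ph2$phi)
})

test_that("constant signals are fully masked with a warning", {
  x <- rbind(sinusoid_mts(20, 200)[1, ], rep(3, 200))
  expect_warning(ph <- extract_phase(x), "masked")
  expect_true(all(is.na(ph$phi[2, ])))
  expect_false(all(is.na(ph$phi[1, ])))
})

test_that("rate metrics reproduce the hand-computed examples", {
  const <- matrix(2, 3, 100)
  m <- rate_metrics(const)
  expect_equal(m$R_tot, 2)
  expect_equal(m$R_het, 0)
  expect_equal(m$R_var, 0)

  two <- rbind(rep(1, 50), rep(3, 50))
  m2 <- rate_metrics(two)
  # population sd across regions: sqrt(((1-2)^2+(3-2)^2)/2)/2 = 0.5
  expect_equal(m2$R_het, 0.5)

  alt <- matrix(rep(c(0, 2), 50), 1)
  m3 <- suppressWarnings(rate_metrics(alt))
  expect_equal(m3$R_tot, 1)
  expect_equal(m3$R_var, 1)

  # an all-zero input warns about both the grand mean and the regional cvs
  expect_warning(expect_warning(rate_metrics(matrix(0, 2, 10)), "zero"),
                 "cv undefined")
})

test_that("PLV matches its defining cases", {
  T <- 500
  phi <- rbind(seq(0, 50, length.out = T),
               seq(0, 50, length.out = T) + 1.3)  # constant difference
  ps <- structure(list(phi = phi), class = "phase_series")
  plv <- plv_matrix(ps)
  expect_equal(plv[1, 2], 1, tolerance = 1e-12)
  expect_true(isSymmetric(plv))
  expect_equal(diag(plv), rep(1, 2))

  # antipodal differences cancel exactly
  phi2 <- rbind(rep(0, 100), rep(c(0, pi), 50))
  plv2 <- plv_matrix(structure(list(phi = phi2), class = "phase_series"))
  expect_equal(plv2[1, 2], 0, tolerance = 1e-12)
})

test_that("independent uniform phases give PLV at the sqrt(T) noise scale", {
  set.seed(99)
  T <- 1e4
  phi <- rbind(cumsum(runif(T, 0, 2 * pi)), cumsum(runif(T, 0, 2 * pi)))
  plv <- plv_matrix(structure(list(phi = phi), class = "phase_series"))
  expect_lt(plv[1, 2], 0.05)
})

test_that("PLV summaries follow the top-quartile convention", {
  m <- matrix(0.4, 5, 5); diag(m) <- 1
  s <- plv_summaries(m)
  expect_equal(s$PLV_all, 0.4)
  expect_equal(s$PLV_top, 0.4)
  expect_equal(plv_summaries(matrix(1, 29, 29))$n_pairs, 406)

  # 4 regions, pairs {0.1..0.6}: top quartile = ceil(0.25*6) = 2 links
  m4 <- matrix(0, 4, 4)
  m4[upper.tri(m4)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m4 <- m4 + t(m4); diag(m4) <- 1
  s4 <- plv_summaries(m4)
  expect_equal(s4$PLV_all, 0.35)
  expect_equal(s4$PLV_top, 0.55)
})

test_that("PLV_top never falls below PLV_all on random matrices", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m); diag(m) <- 1
    s <- plv_summaries(m)
    expect_gte(s$PLV_top, s$PLV_all)
    expect_true(s$PLV_all >= 0 && s$PLV_top <= 1)
  }
})

test_that("a single-point sweep equals the direct computation and failures are rows", {
  con <- generate_connectome(n_regions = 8, seed = 10)
  cfg <- sim_config(n_transient = 50, n_samples = 400, seed = 2)
  tab <- sweep_regimes(80, 6, cfg, con)
  expect_equal(nrow(tab), 1)
  sim <- simulate_network(cfg, nm_params(G_ee = 80, I_ext = 6), con)
  direct <- rate_metrics(sim)
  expect_equal(tab$R_tot, direct$R_tot)
  expect_equal(tab$R_var, direct$R_var)
  ps <- plv_summaries(plv_matrix(suppressWarnings(extract_phase(sim))))
  expect_equal(tab$PLV_all, ps$PLV_all)

  # a blow-up is recorded as a failed row, not an error
  tab2 <- sweep_regimes(c(80, 80000), 6, cfg, con)
  expect_equal(tab2$status, c("ok", "failed"))
  expect_true(is.na(tab2$R_tot[2]))
})

test_that("R_tot trends upward with the background drive", {
  con <- generate_connectome(n_regions = 8, seed = 10)
  cfg <- sim_config(n_transient = 50, n_samples = 300, seed = 2)
  tab <- sweep_regimes(80, c(4, 6, 8), cfg, con)
  expect_true(cor(tab$iext, tab$R_tot, method = "kendall") > 0)
})
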