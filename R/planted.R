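#' Specification of a planted-synchrony fixture
#'
#' Describes a multivariate oscillatory signal with known ground truth:
#' regions in the same locked group share one phase trajectory up to fixed
#' per-region lag offsets (plus optional white phase jitter); regions in
#' different groups, and unlocked regions, drift apart (group-specific
#' frequency detuning plus a slow phase random walk) so their long-run PLV
#' is low. Used to test every dynamic-FC stage against a known answer.
#'
#' @param n_regions Number of regions.
#' @param group Integer group id per region; `NA` = unlocked (independent
#'   drift).
#' @param lag Per-region phase offset within its group, as a fraction of a
#'   cycle in \[0, 0.5\] (pairwise planted lag = difference of offsets).
#' @param period Oscillation period in time units; must exceed twice the
#'   sampling interval.
#' @param jitter_sd White per-sample phase noise of locked regions,
#'   radians (0 = noiseless).
#' @param drifter_jitter_sd White per-sample phase noise of unlocked
#'   regions (default 1), keeping their phase relations incoherent so
#'   windowed PLV toward any region stays near zero.
#' @param detune_range Magnitude range of the log frequency detuning of
#'   every trajectory other than group 1 (default c(0.3, 0.6), random
#'   sign). Bounded away from zero so no drifter can shadow the reference
#'   group's frequency even within a single analysis window; drives
#'   cross-group decoherence.
#' @param drift_sd Per-sample sd of the slow phase random walk added to
#'   every group trajectory (default 0.02 rad).
#' @param n_samples Number of samples.
#' @param sampling Sampling interval in time units.
#' @param seed Integer seed.
#' @export
planted_sync_spec <- function(n_regions, group = rep(1, n_regions),
                              lag = rep(0, n_regions),
                              period = 0.37, jitter_sd = 0,
                              drifter_jitter_sd = 1,
                              detune_range = c(0.3, 0.6), drift_sd = 0.02,
                              n_samples = 3000, sampling = 0.01, seed = 1) {
  stopifnot(length(group) == n_regions, length(lag) == n_regions,
            all(lag >= 0 & lag <= 0.5), period > 2 * sampling,
            jitter_sd >= 0, n_samples >= 2)
  structure(list(n_regions = n_regions, group = group, lag = lag,
                 period = period, jitter_sd = jitter_sd,
                 drifter_jitter_sd = drifter_jitter_sd,
                 detune_range = detune_range, drift_sd = drift_sd,
                 n_samples = as.integer(n_samples), sampling = sampling,
                 seed = as.integer(seed)),
            class = "planted_sync_spec")
}

#' Generate planted-synchrony oscillations
#'
#' Realizes a [planted_sync_spec()] as an `mts` object. Signals are raised
#' cosines `1 - cos(phi)` so troughs fall exactly at phase 0 (mod
#' 2\eqn{\pi}) and the trough-interpolation phase extractor recovers the
#' planted phases. Within a locked group, pairwise phase differences equal
#' 2\eqn{\pi} times the planted lag difference plus jitter; the first group
#' keeps an exact frequency multiplier of 1 so planted lags are exact in
#' units of the nominal period.
#'
#' @param spec A [planted_sync_spec()].
#' @return An `mts` object (with `$planted` carrying the ground truth).
#' @export
generate_planted_oscillations <- function(spec) {
  stopifnot(inherits(spec, "planted_sync_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  N <- spec$n_regions; T <- spec$n_samples
  tt <- (seq_len(T) - 1) * spec$sampling
  groups <- unique(spec$group[!is.na(spec$group)])
  # trajectory per locked group; unlocked regions get private trajectories
  traj_id <- integer(N)
  for (j in seq_len(N))
    traj_id[j] <- if (is.na(spec$group[j])) -j else match(spec$group[j], groups)
  uid <- unique(traj_id)
  base <- matrix(0, length(uid), T)
  for (i in seq_along(uid)) {
    mult <- if (uid[i] == 1) 1 else
      exp(sample(c(-1, 1), 1) * runif(1, spec$detune_range[1],
                                      spec$detune_range[2]))
    drift <- if (spec$drift_sd > 0) cumsum(rnorm(T, 0, spec$drift_sd)) else 0
    base[i, ] <- 2 * pi * tt / (spec$period * mult) + drift
  }
  re <- matrix(0, N, T,
               dimnames = list(sprintf("R%02d", seq_len(N) - 1), NULL))
  phi_true <- matrix(0, N, T)
  for (j in seq_len(N)) {
    phi <- base[match(traj_id[j], uid), ] + 2 * pi * spec$lag[j]
    sdj <- if (is.na(spec$group[j])) spec$drifter_jitter_sd else spec$jitter_sd
    if (sdj > 0) phi <- phi + rnorm(T, 0, sdj)
    phi_true[j, ] <- phi
    re[j, ] <- 1 - cos(phi)
  }
  structure(list(re = re, sampling = spec$sampling,
                 time = tt, labels = rownames(re),
                 n_negative_rate = 0L,
                 planted = list(spec = spec, phi = phi_true),
                 provenance = list(generator = "planted_sync",
                                   spec = unclass(spec))),
            class = "mts")
}

#' Planted three-state fixture runs
#'
#' Builds one run per planted FC state. Every state's coalition is the
#' 12-region core plus two of three 3-region peripheral groups (each
#' peripheral group is shared by exactly two states), so hub vectors
#' differ between states, the core is a hub in every state, and just under
#' 46 percent of all links have a high median PLV — matching the bimodal
#' link-strength distribution the 54th-percentile link threshold presumes.
#' Lag patterns over the core differ per state; the remaining 8 regions
#' are unlocked drifters. Ground truth: all windows of run i belong to
#' state i. Analyze with `hub_threshold = 17` (the within-coalition
#' degree) and 3 hub / 3 lag clusters.
#'
#' @param n_samples Samples per run (default 1540, i.e. 41 windows of 140
#'   at 75% overlap).
#' @param period Oscillation period in time units (default 0.37, matching
#'   the simulated working point's realized period).
#' @param jitter_sd Phase jitter (default 0).
#' @param seed Base seed; run i uses `seed + i`.
#' @return List of three `mts` runs, with `attr(, "truth")` describing
#'   coalitions, lags and the recommended analysis settings.
#' @export
generate_planted_states <- function(n_samples = 1540, period = 0.37,
                                    jitter_sd = 0, seed = 100) {
  N <- 29
  core <- 1:12
  periph <- list(g12 = 13:15, g13 = 16:18, g23 = 19:21)
  extras <- list(c(periph$g12, periph$g13),   # state 1
                 c(periph$g12, periph$g23),   # state 2
                 c(periph$g13, periph$g23))   # state 3
  lags <- list(rep(0, 18),
               c(rep(0, 6), rep(0.25, 6), rep(0, 6)),
               c(rep(0, 6), rep(0.45, 6), rep(0.2, 6)))
  runs <- vector("list", 3)
  for (s in 1:3) {
    members <- c(core, extras[[s]])
    group <- rep(NA_integer_, N); group[members] <- 1L
    lag <- rep(0, N); lag[members] <- lags[[s]]
    spec <- planted_sync_spec(N, group = group, lag = lag, period = period,
                              jitter_sd = jitter_sd,
                              n_samples = n_samples, seed = seed + s)
    runs[[s]] <- generate_planted_oscillations(spec)
  }
  attr(runs, "truth") <- list(core = core, extras = extras, lags = lags,
                              hub_threshold = 17, n_hub_clusters = 3,
                              n_lag_clusters = 3)
  runs
}
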