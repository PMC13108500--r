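#' Neural-mass model parameters
#'
#' Parameters of the exact mean-field reduction of coupled quadratic
#' integrate-and-fire E and I populations (one pair per region, PING-like
#' E-I loop). Defaults are the printed working values of the whole-brain
#' model; the two free global parameters explored when choosing a dynamical
#' working point are `G_ee` (global excitatory-to-excitatory coupling) and
#' `I_ext` (homogeneous background drive to both populations).
#'
#' @param delta_e,delta_i Half-width of the Lorentzian heterogeneity of the
#'   E / I population (default 1, 1).
#' @param eta_e,eta_i Mean heterogeneous current of the E / I population
#'   (default -5, -5).
#' @param tau_e,tau_i Characteristic time constants of the E / I population
#'   (default 10, 10, model time units).
#' @param tau_s Synaptic time constant (default 1).
#' @param J_ei Local I-to-E synaptic weight (default 19).
#' @param J_ie Local E-to-I synaptic weight (default 19).
#' @param J_ee,J_ii Local recurrent E-to-E / I-to-I weights. Default 0: the
#'   local loop is a pure E<->I (PING) motif; both are configurable.
#' @param gamma_ratio Ratio of long-range E-to-I to E-to-E coupling,
#'   `G_ei = gamma_ratio * G_ee` (default 5).
#' @param G_ee Global excitatory coupling scaling the connectome (default 80,
#'   the working point).
#' @param I_ext Background drive (default 6, the working point).
#' @return A named list of class `nm_params`.
#' @export
nm_params <- function(delta_e = 1, delta_i = 1, eta_e = -5, eta_i = -5,
                      tau_e = 10, tau_i = 10, tau_s = 1,
                      J_ei = 19, J_ie = 19, J_ee = 0, J_ii = 0,
                      gamma_ratio = 5, G_ee = 80, I_ext = 6) {
  stopifnot(tau_e > 0, tau_i > 0, tau_s > 0, delta_e > 0, delta_i > 0,
            gamma_ratio >= 0)
  structure(list(delta_e = delta_e, delta_i = delta_i,
                 eta_e = eta_e, eta_i = eta_i,
                 tau_e = tau_e, tau_i = tau_i, tau_s = tau_s,
                 J_ei = J_ei, J_ie = J_ie, J_ee = J_ee, J_ii = J_ii,
                 gamma_ratio = gamma_ratio, G_ee = G_ee, I_ext = I_ext),
            class = "nm_params")
}

#' Simulation configuration
#'
#' @param dt Integration step (default 0.00005 time units; kept very small so
#'   that millisecond-scale rectangular pulses are resolved).
#' @param downsample Number of integration steps per saved sample (default
#'   200, i.e. sampling interval 0.01 time units).
#' @param n_transient Saved samples discarded as initial transient
#'   (default 400).
#' @param n_samples Saved samples kept after the transient (default 3000).
#' @param seed Integer seed for the random initial condition.
#' @param save_v Also save membrane potentials V_e, V_i.
#' @param save_full Also save the full 8N-dimensional state at every saved
#'   sample (needed to restart paired stimulation runs mid-trajectory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.00005, downsample = 200, n_transient = 400,
                       n_samples = 3000, seed = 1,
                       save_v = FALSE, save_full = FALSE) {
  stopifnot(dt > 0, downsample >= 1, n_samples >= 1, n_transient >= 0)
  structure(list(dt = dt, downsample = as.integer(downsample),
                 n_transient = as.integer(n_transient),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 save_v = save_v, save_full = save_full),
            class = "sim_config")
}

#' Random initial network state
#'
#' Seeded draw of the 8N state vector: rates uniform on \[0, 0.5\] (rates are
#' non-negative by construction), membrane potentials uniform on \[-2, 0\],
#' synaptic variables 0. Bounded and regime-agnostic; the model's attractor
#' is reached after the transient cut regardless.
#'
#' @param seed Integer seed.
#' @param n_regions Number of regions N.
#' @return Numeric vector of length 8N, blocks
#'   (r_e, V_e, s_ee, s_ei, r_i, V_i, s_ie, s_ii).
#' @export
sample_initial_conditions <- function(seed, n_regions) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  N <- n_regions
  x <- numeric(8 * N)
  x[seq_len(N)]           <- runif(N, 0, 0.5)   # r_e
  x[N + seq_len(N)]       <- runif(N, -2, 0)    # V_e
  x[4 * N + seq_len(N)]   <- runif(N, 0, 0.5)   # r_i
  x[5 * N + seq_len(N)]   <- runif(N, -2, 0)    # V_i
  x
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Time derivatives of the network state (reference implementation)
#'
#' Pure-R evaluation of the mean-field equations for all 8N state variables.
#' The compiled integrator used by [simulate_network()] implements the same
#' equations; this function is the transparent reference (and the hook for
#' root-finding, e.g. locating single-region fixed points).
#'
#' Per region j (E population; the I population mirrors it):
#' \deqn{\dot r_e = (\Delta_e/(\pi\tau_e) + 2 V_e r_e)/\tau_e}
#' \deqn{\dot V_e = (V_e^2 + \eta_e + I_{ext} + I_{stim} + \tau_e s_{ee}
#'   - \tau_e s_{ei} - \tau_e^2 \pi^2 r_e^2)/\tau_e}
#' \deqn{\dot s_{ee} = (-s_{ee} + J_{ee} r_e + G_{ee}\sum_k SC_{jk} r_{e,k})/\tau_s}
#' \deqn{\dot s_{ei} = (-s_{ei} + J_{ei} r_i)/\tau_s}
#' The long-range term for the I population is scaled by
#' `gamma_ratio * G_ee`. Coupling is instantaneous.
#'
#' @param state Numeric vector of length 8N (see
#'   [sample_initial_conditions()] for the block layout).
#' @param params An [nm_params()] object.
#' @param sc N x N connectivity matrix (row j = inputs to region j).
#' @param stim Per-region additive membrane current (length N, applied to
#'   both V_e and V_i), default zero.
#' @return Numeric vector of length 8N of time derivatives.
#' @export
nm_derivatives <- function(state, params, sc, stim = NULL) {
  N <- nrow(sc)
  stopifnot(length(state) == 8 * N)
  if (is.null(stim)) stim <- numeric(N)
  stopifnot(length(stim) == N)
  p <- params
  ix <- function(b) (b - 1) * N + seq_len(N)
  re <- state[ix(1)]; Ve <- state[ix(2)]; see <- state[ix(3)]; sei <- state[ix(4)]
  ri <- state[ix(5)]; Vi <- state[ix(6)]; sie <- state[ix(7)]; sii <- state[ix(8)]
  coup <- as.vector(sc %*% re)
  dre <- (p$delta_e / (pi * p$tau_e) + 2 * Ve * re) / p$tau_e
  dVe <- (Ve^2 + p$eta_e + p$I_ext + stim + p$tau_e * see - p$tau_e * sei -
            p$tau_e^2 * pi^2 * re^2) / p$tau_e
  dsee <- (-see + p$J_ee * re + p$G_ee * coup) / p$tau_s
  dsei <- (-sei + p$J_ei * ri) / p$tau_s
  dri <- (p$delta_i / (pi * p$tau_i) + 2 * Vi * ri) / p$tau_i
  dVi <- (Vi^2 + p$eta_i + p$I_ext + stim + p$tau_i * sie - p$tau_i * sii -
            p$tau_i^2 * pi^2 * ri^2) / p$tau_i
  dsie <- (-sie + p$J_ie * re + p$gamma_ratio * p$G_ee * coup) / p$tau_s
  dsii <- (-sii + p$J_ii * ri) / p$tau_s
  c(dre, dVe, dsee, dsei, dri, dVi, dsie, dsii)
}

#' One Heun (modified Euler) predictor-corrector step
#'
#' `x_pred = x + dt f(x)`; `x_next = x + dt/2 (f(x) + f(x_pred))`.
#' Second-order accurate for smooth systems; the deterministic integrator
#' used throughout.
#'
#' @param state Numeric state vector.
#' @param dt Step size (> 0; `dt = 0` returns the state unchanged).
#' @param f Derivative function `f(state) -> dstate`.
#' @return Updated state vector.
#' @export
heun_step <- function(state, dt, f) {
  stopifnot(dt >= 0)
  k1 <- f(state)
  pred <- state + dt * k1
  out <- state + (dt / 2) * (k1 + f(pred))
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))[1]
    stop("non-finite value after Heun step (component ", bad, ")")
  }
  out
}

#' A single-pulse stimulus event
#'
#' Rectangular current pulse emulating a Dirac delta: amplitude `amplitude`
#' added to the membrane-potential equations of both the E and I population
#' of one region, for `duration` time units (default one sampling interval,
#' 0.01, i.e. 200 integration steps at the default `dt`).
#'
#' @param region 1-based region index.
#' @param onset Onset time in simulation time units, measured from the start
#'   of the integration call (including any transient).
#' @param amplitude Pulse amplitude (default 300).
#' @param duration Pulse length in time units (default 0.01).
#' @export
stimulus_event <- function(region, onset, amplitude = 300, duration = 0.01) {
  stopifnot(amplitude >= 0, duration > 0, region >= 1)
  structure(list(region = as.integer(region), onset = onset,
                 amplitude = amplitude, duration = duration),
            class = "stimulus_event")
}

#' Simulate the coupled network
#'
#' Heun integration of the full network at step `config$dt`, downsampled by
#' `config$downsample`, discarding `config$n_transient` saved samples and
#' keeping `config$n_samples`. Fully deterministic: identical inputs give
#' bit-identical trajectories.
#'
#' @param config A [sim_config()].
#' @param params An [nm_params()].
#' @param sc A [connectome][generate_connectome] or plain square matrix.
#' @param stimuli List of [stimulus_event()]s (onsets measured from the start
#'   of integration, transient included).
#' @param init Optional 8N initial state; default drawn by
#'   [sample_initial_conditions()] with `config$seed`.
#' @param burn_steps Extra integration steps (not multiples of the sampling
#'   interval) run before saving starts, used to restart mid-trajectory;
#'   default 0.
#' @return A `mts` object: list with `re` (N x T matrix of excitatory
#'   rates), optional `ve`/`vi`, optional `full_state`, `final_state`,
#'   `sampling` (interval), `time` (sample times) and `provenance`.
#' @export
simulate_network <- function(config, params, sc, stimuli = list(),
                             init = NULL, burn_steps = 0) {
  scm <- as_sc_matrix(sc)
  N <- nrow(scm)
  if (is.null(init)) init <- sample_initial_conditions(config$seed, N)
  stopifnot(length(init) == 8 * N)
  ns <- length(stimuli)
  reg <- integer(ns); ons <- integer(ns); dur <- integer(ns); amp <- numeric(ns)
  total_time <- (burn_steps + (config$n_transient + config$n_samples) *
                   config$downsample) * config$dt
  for (i in seq_along(stimuli)) {
    s <- stimuli[[i]]
    if (s$region < 1 || s$region > N)
      stop("stimulus on unknown region ", s$region, " (N = ", N, ")")
    if (s$onset < 0 || s$onset > total_time)
      stop("stimulus onset ", s$onset, " outside run span [0, ",
           total_time, "]")
    reg[i] <- s$region - 1L
    ons[i] <- as.integer(round(s$onset / config$dt))
    dur[i] <- max(1L, as.integer(round(s$duration / config$dt)))
    amp[i] <- s$amplitude
  }
  raw <- simulate_network_cpp(scm, unclass(params), init, config$dt,
                              config$downsample,
                              as.integer(burn_steps +
                                config$n_transient * config$downsample),
                              config$n_samples,
                              reg, ons, dur, amp,
                              config$save_v, config$save_full)
  labels <- sc_labels(sc, N)
  rownames(raw$re) <- labels
  sampling <- config$dt * config$downsample
  structure(list(
    re = raw$re,
    ve = raw$ve, vi = raw$vi,
    full_state = raw$full_state,
    final_state = raw$final_state,
    n_negative_rate = raw$n_negative_rate,
    sampling = sampling,
    time = (config$n_transient + seq_len(config$n_samples)) * sampling +
      burn_steps * config$dt,
    labels = labels,
    provenance = list(config = unclass(config), params = unclass(params),
                      sc_hash = sc_hash(scm), stimuli = stimuli,
                      burn_steps = burn_steps,
                      init = init)
  ), class = "mts")
}

as_sc_matrix <- function(sc) {
  if (inherits(sc, "connectome")) return(sc$weights)
  stopifnot(is.matrix(sc), nrow(sc) == ncol(sc))
  sc
}

sc_labels <- function(sc, N) {
  if (inherits(sc, "connectome")) sc$labels
  else if (!is.null(rownames(sc))) rownames(sc)
  else sprintf("R%02d", seq_len(N) - 1)
}

# cheap content hash for provenance (sum-based; not cryptographic)
sc_hash <- function(m) {
  v <- as.vector(m)
  sprintf("%.10e/%.10e/%d", sum(v), sum(v * seq_along(v)), length(v))
}

#' @export
print.mts <- function(x, ...) {
  cat("Multivariate neural-mass time series\n")
  cat(sprintf("  regions: %d, samples: %d, sampling interval: %g\n",
              nrow(x$re), ncol(x$re), x$sampling))
  cat(sprintf("  r_e range: [%.3g, %.3g]\n", min(x$re), max(x$re)))
  if (x$n_negative_rate > 0)
    cat(sprintf("  WARNING: %d negative-rate samples\n", x$n_negative_rate))
  invisible(x)
}
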