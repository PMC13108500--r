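# Shared fixtures, built lazily and memoised for the whole test run so the
# expensive simulations happen at most once.

.fx_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- builder()
  .fx_env[[name]]
}

# default 29-region surrogate connectome
fx_con29 <- function() fixture("con29", function() generate_connectome(seed = 1))

# the 13 resting runs of the full design at the working point
# (full state kept so stimulation experiments can restart mid-trajectory)
fx_wp_runs <- function() fixture("wp_runs", function() {
  con <- fx_con29()
  lapply(1:13, function(i)
    simulate_network(sim_config(seed = 1 + i, save_full = TRUE),
                     nm_params(), con))
})

# hub threshold 14: the surrogate's analog of the printed degree cut,
# chosen by the same criterion the study used (nearly every window keeps
# at least one hub while none saturates, and hub assignment varies
# maximally across windows)
fx_wp_catalog <- function() fixture("wp_catalog", function() {
  suppressWarnings(extract_fc_states(fx_wp_runs(), hub_threshold = 14,
                                     n_prototypes = 30))
})

fx_wp_classifier <- function() fixture("wp_classifier", function() {
  suppressWarnings(fit_state_classifier(fx_wp_catalog(), k = 15))
})

# reduced stimulation experiment set: one stimulated region, full phase
# grid, 2 prototype windows x 2 cycles per state
fx_stim_experiments <- function() fixture("stim_experiments", function() {
  suppressWarnings(run_stimulation_experiments(
    fx_wp_runs(), fx_wp_catalog(), fx_con29(), fx_wp_classifier(),
    regions = 5, n_windows = 2, n_cycles = 2))
})

# planted three-state fixture and its catalog (analysis settings from truth)
fx_planted_runs <- function() fixture("planted_runs",
                                      function() generate_planted_states())

fx_planted_catalog <- function() fixture("planted_catalog", function() {
  tr <- attr(fx_planted_runs(), "truth")
  suppressWarnings(extract_fc_states(
    fx_planted_runs(), hub_threshold = tr$hub_threshold,
    n_hub_clusters = tr$n_hub_clusters, n_lag_clusters = tr$n_lag_clusters,
    n_prototypes = 20))
})

# synthetic dataset where the phase shift depends jointly on state and
# stimulation phase, so state-blind features cannot predict it
make_planted_dependence <- function(n = 240, seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  state <- sample(paste0("Psi", 1:3), n, replace = TRUE)
  s_num <- as.integer(factor(state))
  phase <- runif(n, 0, 2 * pi)
  shift <- wrap_phase_shift(0.35 * sin(phase + 2 * s_num) +
                              rnorm(n, 0, 0.05))
  list(x_phase = cbind(cos = cos(phase), sin = sin(phase)),
       x_state = matrix(s_num, ncol = 1, dimnames = list(NULL, "state")),
       y = cbind(cos(shift), sin(shift)), state = state, shift = shift)
}

# minimal hand-built experiment set (no simulation) for unit tests of the
# PRC / switching reducers and feature assembly
make_toy_experiments <- function(dphi_value = 0.1, n_regions = 29,
                                 end_stim = NULL, end_unstim = NULL,
                                 states = "Psi1", n_bins = 2, n_rep = 3,
                                 catalog_row = 1L) {
  trials <- expand.grid(rep = seq_len(n_rep), phase_bin = seq_len(n_bins),
                        state = states, stringsAsFactors = FALSE)
  n <- nrow(trials)
  targets <- seq(0, 2 * pi, length.out = n_bins + 1)[seq_len(n_bins)]
  tr <- data.frame(stim_region = 1L, state = trials$state,
                   phase_bin = trials$phase_bin,
                   phase = targets[trials$phase_bin],
                   run = 1L, window_start = 1L, cycle = trials$rep,
                   onset_time = as.numeric(seq_len(n)),
                   end_state_stim = if (is.null(end_stim))
                     trials$state else rep_len(end_stim, n),
                   end_state_unstim = if (is.null(end_unstim))
                     trials$state else rep_len(end_unstim, n),
                   status = "ok", stringsAsFactors = FALSE)
  dphi <- matrix(dphi_value, n, n_regions)
  structure(list(trials = tr, dphi_late = dphi,
                 catalog_row = rep_len(catalog_row, n),
                 design = list(regions = 1L, states = states,
                               n_phases = n_bins, n_windows = 1,
                               n_cycles = n_rep, amplitude = 300,
                               poststim = 500, late_window = 361:500,
                               targets = targets)),
            class = "stim_experiments")
}
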