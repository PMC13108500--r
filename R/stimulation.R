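#' Wrap a phase shift into \[-pi/2, pi/2)
#'
#' Phase-shift differences between stimulated and unstimulated runs are
#' reduced modulo \eqn{\pi} into \eqn{[-\pi/2, \pi/2)}: shifts of
#' \eqn{-0.7\pi} and \eqn{+0.3\pi} are functionally equivalent and both map
#' to \eqn{+0.3\pi}. Idempotent.
#'
#' @param x Numeric (radians).
#' @return Wrapped values in \[-pi/2, pi/2).
#' @export
wrap_phase_shift <- function(x) {
  ((x + pi / 2) %% pi) - pi / 2
}

#' Circular mean and spread of pi-periodic phase shifts
#'
#' Wrapped phase shifts live on a circle of circumference \eqn{\pi}, so
#' averages are taken on the complex plane after doubling:
#' mean = \eqn{\frac{1}{2}\mathrm{Arg}\,\sum e^{2ix}}, mapped into
#' \[-pi/2, pi/2) (the boundary \eqn{+\pi/2} maps to \eqn{-\pi/2}).
#' `circ_sd_pi` is the corresponding circular standard deviation
#' \eqn{\frac{1}{2}\sqrt{-2\log R}} with \eqn{R = |\mathrm{mean}\ e^{2ix}|}.
#' Ordinary period-2\eqn{\pi} versions are available via `period = "2pi"`.
#'
#' @param x Numeric vector (radians); `NA`s dropped.
#' @param period `"pi"` (default) or `"2pi"`.
#' @return Scalar mean (or sd); `NA` if no finite values.
#' @export
circ_mean <- function(x, period = c("pi", "2pi")) {
  period <- match.arg(period)
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  if (period == "pi") {
    m <- 0.5 * Arg(mean(exp(2i * x)))
    if (m >= pi / 2) m <- m - pi
    m
  } else {
    Arg(mean(exp(1i * x)))
  }
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x, period = c("pi", "2pi")) {
  period <- match.arg(period)
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  if (period == "pi") {
    R <- Mod(mean(exp(2i * x)))
    0.5 * sqrt(max(0, -2 * log(max(R, .Machine$double.xmin))))
  } else {
    R <- Mod(mean(exp(1i * x)))
    sqrt(max(0, -2 * log(max(R, .Machine$double.xmin))))
  }
}

#' Locate stimulation times at prescribed phases
#'
#' Because the model is deterministic, the phase at which a pulse lands can
#' be anticipated exactly from the unstimulated run: within a chosen window,
#' the first `n_cycles` oscillation cycles of the target region (consecutive
#' trough pairs starting in the window) are scanned, and within each cycle
#' the time at which the trough-interpolated phase crosses each target is
#' computed by linear interpolation. Times closer than `poststim` samples to
#' the end of the run are dropped (with a warning about reduced counts).
#'
#' @param run Unstimulated `mts` resting run.
#' @param region Stimulated region index.
#' @param window_start Window start sample (1-based).
#' @param targets Phase targets in radians (default 10 steps spanning
#'   \[0, 2 pi)).
#' @param n_cycles Cycles per window (default 5).
#' @param poststim Required post-stimulation samples (default 500).
#' @param phases Optional precomputed `phase_series` of the run.
#' @return Data frame `cycle`, `phase`, `time` (absolute simulation time),
#'   `sample` (fractional sample index).
#' @export
locate_phase_times <- function(run, region, window_start,
                               targets = seq(0, 2 * pi,
                                             length.out = 11)[1:10],
                               n_cycles = 5, poststim = 500,
                               phases = NULL) {
  if (is.null(phases)) phases <- suppressWarnings(extract_phase(run))
  tr <- phases$troughs[[region]]
  if (length(tr) < 2) stop("region ", region, " has no phase series")
  tr <- tr[tr >= window_start]
  T <- ncol(run$re)
  out <- list()
  n_avail <- max(0, length(tr) - 1)
  for (cyc in seq_len(min(n_cycles, n_avail))) {
    t0 <- tr[cyc]; t1 <- tr[cyc + 1]
    for (ph in targets) {
      s <- t0 + (ph / (2 * pi)) * (t1 - t0)     # fractional sample index
      if (s + poststim <= T)
        out[[length(out) + 1]] <- data.frame(
          cycle = cyc, phase = ph,
          time = run$time[1] + (s - 1) * run$sampling, sample = s)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(cycle = integer(0), phase = numeric(0), time = numeric(0),
               sample = numeric(0))
  want <- min(n_cycles, n_avail) * length(targets)
  if (nrow(res) < n_cycles * length(targets))
    warning("only ", nrow(res), " of ", n_cycles * length(targets),
            " stimulation points available (cycles found: ", n_avail,
            "; end-of-run margin applied)")
  res
}

#' Run one paired (stimulated / unstimulated) experiment
#'
#' Restarts the integration from the resting run's stored full network
#' state just before the requested onset, then runs two simulations that
#' are identical except for the pulse amplitude (the matched control uses
#' amplitude 0). Both members therefore share a bitwise-identical history
#' up to pulse onset, and any divergence afterwards is caused by the pulse
#' alone.
#'
#' @param run Resting `mts` simulated with `save_full = TRUE`.
#' @param sc The connectome used for `run`.
#' @param region Stimulated region.
#' @param onset_time Absolute simulation time of pulse onset (from
#'   [locate_phase_times()]).
#' @param amplitude Pulse amplitude (default 300).
#' @param duration Pulse duration in time units (default one sampling
#'   interval).
#' @param poststim Saved post-stimulation samples (default 500).
#' @return A `paired_run`: list with `stim`, `unstim` (`mts` objects whose
#'   first sample is one sampling interval after pulse onset), `region`,
#'   `onset_time`, `amplitude`.
#' @export
run_paired_experiment <- function(run, sc, region, onset_time,
                                  amplitude = 300, duration = NULL,
                                  poststim = 500) {
  if (is.null(run$full_state))
    stop("run must be simulated with save_full = TRUE to restart from it")
  cfgl <- run$provenance$config
  dt <- cfgl$dt; ds <- cfgl$downsample
  if (is.null(duration)) duration <- dt * ds
  m0 <- max(1, floor((onset_time - run$time[1]) / run$sampling) + 1)
  while (run$time[m0] > onset_time && m0 > 1) m0 <- m0 - 1
  init <- run$full_state[, m0]
  burn <- as.integer(round((onset_time - run$time[m0]) / dt))
  cfg <- sim_config(dt = dt, downsample = ds, n_transient = 0,
                    n_samples = poststim, seed = cfgl$seed)
  mk <- function(amp) {
    sim <- simulate_network(cfg, do.call(nm_params, run$provenance$params),
                            sc,
                            stimuli = list(stimulus_event(region,
                                                          onset = burn * dt,
                                                          amplitude = amp,
                                                          duration = duration)),
                            init = init, burn_steps = burn)
    sim$time <- run$time[m0] + (burn * dt) + seq_len(poststim) * sim$sampling
    sim
  }
  structure(list(stim = mk(amplitude), unstim = mk(0), region = region,
                 onset_time = onset_time, amplitude = amplitude,
                 poststim = poststim),
            class = "paired_run")
}

#' Phase-shifting portrait of a paired run
#'
#' Wrapped phase difference (stimulated minus unstimulated, reduced to
#' \[-pi/2, pi/2)) for every affected region at each post-stimulation
#' sample. Samples where either member's phase is undefined are `NA`.
#'
#' @param pair A `paired_run`.
#' @return N x poststim matrix of wrapped phase shifts.
#' @export
phase_shift_portrait <- function(pair) {
  ps <- suppressWarnings(extract_phase(pair$stim))$phi
  pu <- suppressWarnings(extract_phase(pair$unstim))$phi
  wrap_phase_shift(ps - pu)
}

#' Average phase-shifting portraits on the complex plane
#'
#' Element-wise doubled-angle circular mean over a list of portraits
#' (pi-periodic data), NA-aware.
#'
#' @param portraits List of equal-dimension portrait matrices.
#' @return One portrait matrix.
#' @export
group_average_portrait <- function(portraits) {
  stopifnot(length(portraits) > 0)
  dims <- dim(portraits[[1]])
  z <- matrix(0 + 0i, dims[1], dims[2])
  n <- matrix(0L, dims[1], dims[2])
  for (p in portraits) {
    ok <- is.finite(p)
    z[ok] <- z[ok] + exp(2i * p[ok])
    n <- n + ok
  }
  out <- 0.5 * Arg(z / pmax(n, 1))
  out[out >= pi / 2] <- out[out >= pi / 2] - pi
  out[n == 0] <- NA_real_
  out
}

#' Plan and run a grid of phased stimulation experiments
#'
#' For each requested (stimulated region, FC state), stimulation is applied
#' in the state's top-typicality prototype windows, in `n_cycles`
#' consecutive oscillation cycles per window, at `n_phases` phases spanning
#' \[0, 2 pi) — the full design gives
#' `n_phases * n_windows * n_cycles` trials per (region, state). Every
#' trial is a paired stimulated/unstimulated experiment; per trial the
#' late-window phase shift of every affected region and the classified
#' post-stimulation state of both members are recorded.
#'
#' @param runs List of resting `mts` runs simulated with
#'   `save_full = TRUE` (the same list the catalog was built from).
#' @param catalog The `state_catalog` of those runs.
#' @param sc The connectome.
#' @param classifier A `state_knn`; default fitted from the catalog with
#'   its default k.
#' @param regions Stimulated region indices.
#' @param states States to stimulate in (default the three Psi states).
#' @param n_phases Phase bins (default 10).
#' @param n_windows Prototype windows per state (default 5).
#' @param n_cycles Cycles per window (default 5).
#' @param amplitude Pulse amplitude (default 300).
#' @param poststim Post-stimulation samples (default 500).
#' @param late_window Sample range of the late post-stimulation window used
#'   for the phase-shift average and state classification (default: the
#'   final 140 samples, i.e. 361:500 at the default `poststim`).
#' @return A `stim_experiments` object: `trials` data frame (one row per
#'   trial: stim_region, state, phase_bin, phase, run, window_start, cycle,
#'   onset_time, end_state_stim, end_state_unstim, status), `dphi_late`
#'   (trials x regions matrix), `catalog_row` (index of the stimulated
#'   window in the catalog), and the design parameters.
#' @export
run_stimulation_experiments <- function(runs, catalog, sc,
                                        classifier = NULL,
                                        regions,
                                        states = c("Psi1", "Psi2", "Psi3"),
                                        n_phases = 10, n_windows = 5,
                                        n_cycles = 5, amplitude = 300,
                                        poststim = 500,
                                        late_window = NULL) {
  if (is.null(late_window)) {
    stopifnot(poststim >= 140)
    late_window <- (poststim - 139):poststim
  }
  if (is.null(classifier)) classifier <- fit_state_classifier(catalog)
  targets <- seq(0, 2 * pi, length.out = n_phases + 1)[seq_len(n_phases)]
  N <- catalog$params$n_regions
  phases_cache <- lapply(runs, function(r) suppressWarnings(extract_phase(r)))
  trials <- list(); dphi <- list(); cat_rows <- integer(0)
  for (st in states) {
    wins <- which(catalog$windows$state == st)
    if (length(wins) == 0) { warning("no windows in state ", st); next }
    wins <- wins[order(-catalog$windows$typicality[wins])]
    # drop prototype windows too close to the run end to fit the
    # post-stimulation horizon (pulses must precede it by `poststim`
    # samples); the next-most-typical windows take their place
    ok_end <- vapply(wins, function(wi) {
      Tlen <- ncol(runs[[catalog$windows$run[wi]]]$re)
      catalog$windows$start[wi] + poststim + 200 <= Tlen
    }, logical(1))
    if (!all(ok_end))
      warning(sum(!ok_end), " prototype window(s) of ", st,
              " skipped: too close to the run end")
    wins <- wins[ok_end]
    wins <- wins[seq_len(min(n_windows, length(wins)))]
    for (w in wins) {
      ri <- catalog$windows$run[w]
      wstart <- catalog$windows$start[w]
      for (reg in regions) {
        pts <- suppressWarnings(
          locate_phase_times(runs[[ri]], reg, wstart, targets,
                             n_cycles, poststim,
                             phases = phases_cache[[ri]]))
        for (i in seq_len(nrow(pts))) {
          pair <- tryCatch(
            run_paired_experiment(runs[[ri]], sc, reg, pts$time[i],
                                  amplitude = amplitude,
                                  poststim = poststim),
            error = function(e) e)
          row <- data.frame(stim_region = reg, state = st,
                            phase_bin = match(pts$phase[i], targets),
                            phase = pts$phase[i], run = ri,
                            window_start = wstart, cycle = pts$cycle[i],
                            onset_time = pts$time[i],
                            end_state_stim = NA_character_,
                            end_state_unstim = NA_character_,
                            status = "ok", stringsAsFactors = FALSE)
          if (inherits(pair, "error")) {
            row$status <- "failed"
            trials[[length(trials) + 1]] <- row
            dphi[[length(dphi) + 1]] <- rep(NA_real_, N)
            cat_rows <- c(cat_rows, w)
            next
          }
          port <- phase_shift_portrait(pair)
          dphi[[length(dphi) + 1]] <-
            apply(port[, late_window, drop = FALSE], 1, circ_mean)
          for (member in c("stim", "unstim")) {
            seg <- pair[[member]]$re[, late_window, drop = FALSE]
            phi_full <- suppressWarnings(extract_phase(pair[[member]]))$phi
            lab <- tryCatch(
              classify_state(classifier,
                             window_features(seg, catalog,
                                             phi = phi_full[, late_window,
                                                            drop = FALSE])),
              error = function(e) NA_character_)
            row[[paste0("end_state_", member)]] <- as.character(lab)[1]
          }
          trials[[length(trials) + 1]] <- row
          cat_rows <- c(cat_rows, w)
        }
      }
    }
  }
  if (length(trials) == 0)
    stop("no stimulation trials could be planned: no prototype window of ",
         "the requested states leaves room for ", poststim,
         " post-stimulation samples")
  trials <- do.call(rbind, trials)
  dphi <- do.call(rbind, dphi)
  colnames(dphi) <- rownames(runs[[1]]$re) %||% sprintf("R%02d", seq_len(N) - 1)
  structure(list(trials = trials, dphi_late = dphi, catalog_row = cat_rows,
                 design = list(regions = regions, states = states,
                               n_phases = n_phases, n_windows = n_windows,
                               n_cycles = n_cycles, amplitude = amplitude,
                               poststim = poststim,
                               late_window = late_window,
                               targets = targets)),
            class = "stim_experiments")
}

#' @export
print.stim_experiments <- function(x, ...) {
  cat("Stimulation experiment set:", nrow(x$trials), "paired trials\n")
  print(table(region = x$trials$stim_region, state = x$trials$state))
  invisible(x)
}

#' State-specific effective phase-response curves
#'
#' Per (stimulated region, FC state, affected region, phase bin): the
#' doubled-angle circular mean of the late-window phase shifts over the
#' trials that did **not** switch state (stimulated member's classified
#' post-stimulation state equals the state at stimulation time), with SEM
#' = circular sd / sqrt(n retained). Bins with no retained trial are
#' undefined (`NA`), never zero-filled.
#'
#' @param experiments A `stim_experiments`.
#' @return An `effective_prc`: data frame with columns `stim_region`,
#'   `state`, `affected_region`, `phase_bin`, `mean_shift`, `sem`,
#'   `n_retained`, `n_switched`, `n_failed`.
#' @export
effective_prc <- function(experiments) {
  tr <- experiments$trials
  N <- ncol(experiments$dphi_late)
  out <- list()
  for (reg in unique(tr$stim_region)) for (st in unique(tr$state)) {
    for (b in sort(unique(tr$phase_bin))) {
      sel <- which(tr$stim_region == reg & tr$state == st &
                     tr$phase_bin == b)
      if (length(sel) == 0) next
      ok <- sel[tr$status[sel] == "ok"]
      retained <- ok[!is.na(tr$end_state_stim[ok]) &
                       tr$end_state_stim[ok] == st]
      n_sw <- sum(tr$status[sel] == "ok") - length(retained)
      for (a in seq_len(N)) {
        vals <- experiments$dphi_late[retained, a]
        out[[length(out) + 1]] <- data.frame(
          stim_region = reg, state = st, affected_region = a,
          phase_bin = b,
          mean_shift = circ_mean(vals),
          sem = if (length(retained) > 0)
            circ_sd(vals) / sqrt(length(retained)) else NA_real_,
          n_retained = length(retained), n_switched = n_sw,
          n_failed = sum(tr$status[sel] != "ok"),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, out), class = c("effective_prc", "data.frame"))
}

#' Stimulation-induced state-switching statistics
#'
#' Per (stimulated region, start state, phase bin): the probability that
#' the stimulated member's classified post-stimulation state differs from
#' the start state, the same probability for the matched unstimulated
#' member (spontaneous switching), and their difference
#' \eqn{\Delta P}. Any end label different from the start state — including
#' "None" — counts as a switch (landings in "None" are also reported
#' separately). A full start-to-end transition count table is attached.
#'
#' @param experiments A `stim_experiments`.
#' @return A `switch_curve`: data frame `stim_region`, `state`,
#'   `phase_bin`, `n`, `p_stim`, `p_unstim`, `delta_p`, `p_stim_none`,
#'   `n_unclassifiable`; attribute `transitions` = count table
#'   (member x start x end).
#' @export
switching_statistics <- function(experiments) {
  tr <- experiments$trials
  out <- list()
  for (reg in unique(tr$stim_region)) for (st in unique(tr$state)) {
    for (b in sort(unique(tr$phase_bin))) {
      sel <- tr[tr$stim_region == reg & tr$state == st &
                  tr$phase_bin == b & tr$status == "ok", ]
      if (nrow(sel) == 0) next
      cls <- !is.na(sel$end_state_stim) & !is.na(sel$end_state_unstim)
      s <- sel[cls, ]
      out[[length(out) + 1]] <- data.frame(
        stim_region = reg, state = st, phase_bin = b, n = nrow(s),
        p_stim = mean(s$end_state_stim != st),
        p_unstim = mean(s$end_state_unstim != st),
        delta_p = mean(s$end_state_stim != st) -
          mean(s$end_state_unstim != st),
        p_stim_none = mean(s$end_state_stim == "None"),
        n_unclassifiable = sum(!cls), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  ok <- tr[tr$status == "ok" & !is.na(tr$end_state_stim), ]
  trans <- table(member = rep(c("stim", "unstim"), each = nrow(ok)),
                 start = rep(ok$state, 2),
                 end = c(ok$end_state_stim, ok$end_state_unstim))
  structure(res, class = c("switch_curve", "data.frame"),
            transitions = trans)
}

#' Enumerate the stimulation experiment design
#'
#' Pure accounting of the experimental plan: one row per intended trial,
#' the full crossing of stimulated regions, FC states, phase bins, and
#' (window, cycle) repeats. The printed full-scale design (10 phases, 3
#' states, 5 windows x 5 cycles, 6 regions) yields 750 trials per region,
#' 25 per (region, state, phase) cell and 4,500 in total.
#'
#' @param regions Stimulated region indices.
#' @param states FC states stimulated.
#' @param n_phases,n_windows,n_cycles Design counts (defaults 10, 5, 5).
#' @return Data frame `region`, `state`, `phase_bin`, `window`, `cycle`.
#' @export
stimulation_design <- function(regions, states = c("Psi1", "Psi2", "Psi3"),
                               n_phases = 10, n_windows = 5, n_cycles = 5) {
  expand.grid(region = regions, state = states,
              phase_bin = seq_len(n_phases), window = seq_len(n_windows),
              cycle = seq_len(n_cycles), stringsAsFactors = FALSE)
}
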