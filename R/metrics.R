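#' Trough-anchored instantaneous phase
#'
#' The instantaneous phase of each region's excitatory-rate oscillation is
#' obtained by linear interpolation between successive troughs: phase 0 (mod
#' 2\eqn{\pi}) at each trough, growing linearly to 2\eqn{\pi} at the next.
#' Anchoring to troughs removes any effect of amplitude modulation. Phase is
#' undefined (masked) before the first and after the last trough; a region
#' with fewer than two detected troughs is fully masked with a warning.
#'
#' Troughs are local minima of the signal (peaks of the inverted signal)
#' at least `min_separation` samples apart, optionally filtered by a
#' minimum prominence relative to the signal range. The default prominence
#' is 0: the model is deterministic and noiseless, so every local minimum
#' is a genuine trough, and rare large-amplitude population spikes make
#' any range-relative prominence cutoff discard genuine shallow cycles.
#' Raise `min_prominence` for noisy imported signals.
#'
#' @param ts An `mts` object from [simulate_network()] /
#'   [generate_planted_oscillations()], or a plain region x sample matrix.
#' @param min_prominence Minimum trough prominence as a fraction of the
#'   region's signal range (default 0).
#' @param min_separation Minimum trough separation in samples (default 3).
#' @return A `phase_series` object: list with `phi` (region x sample matrix
#'   of unwrapped phase, `NA` where undefined), `troughs` (list of trough
#'   sample indices per region), `sampling`.
#' @export
extract_phase <- function(ts, min_prominence = 0, min_separation = 3) {
  re <- if (inherits(ts, "mts")) ts$re else as.matrix(ts)
  sampling <- if (inherits(ts, "mts")) ts$sampling else 1
  N <- nrow(re); T <- ncol(re)
  phi <- matrix(NA_real_, N, T, dimnames = list(rownames(re), NULL))
  troughs <- vector("list", N)
  masked <- character(0)
  for (j in seq_len(N)) {
    tr <- find_troughs(re[j, ], min_prominence, min_separation)
    troughs[[j]] <- tr
    if (length(tr) < 2) {
      masked <- c(masked, rownames(re)[j] %||% as.character(j))
      next
    }
    for (i in seq_len(length(tr) - 1)) {
      idx <- tr[i]:tr[i + 1]
      phi[j, idx] <- 2 * pi * (i - 1) +
        2 * pi * (idx - tr[i]) / (tr[i + 1] - tr[i])
    }
  }
  if (length(masked) > 0)
    warning("region(s) with < 2 troughs fully masked: ",
            paste(masked, collapse = ", "))
  structure(list(phi = phi, troughs = troughs, sampling = sampling),
            class = "phase_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate oscillation troughs
#'
#' Strict local minima (plateaus collapse to their first sample) filtered by
#' prominence relative to the adjacent local maxima and by a minimum
#' separation; when two candidates are too close, the deeper one wins.
#'
#' @param x Numeric signal.
#' @inheritParams extract_phase
#' @return Integer vector of trough sample indices (possibly empty).
#' @export
find_troughs <- function(x, min_prominence = 0, min_separation = 3) {
  T <- length(x)
  if (T < 3) return(integer(0))
  rng <- max(x) - min(x)
  if (rng == 0) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the sign over plateaus so flat-bottomed troughs are found once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  cand <- which(diff(s) > 0) + 1L
  cand <- cand[x[cand] < x[pmax(cand - 1L, 1L)] | x[cand] < x[pmin(cand + 1L, T)]]
  if (length(cand) == 0) return(integer(0))
  # prominence: smaller of the rises toward the neighbouring maxima
  keep <- logical(length(cand))
  bounds <- c(1L, cand, T)
  for (i in seq_along(cand)) {
    left <- max(x[bounds[i]:cand[i]])
    right <- max(x[cand[i]:bounds[i + 2]])
    keep[i] <- min(left, right) - x[cand[i]] >= min_prominence * rng
  }
  cand <- cand[keep]
  if (length(cand) < 2) return(cand)
  # enforce separation, deeper trough wins
  out <- cand[1]
  for (i in 2:length(cand)) {
    if (cand[i] - out[length(out)] < min_separation) {
      if (x[cand[i]] < x[out[length(out)]]) out[length(out)] <- cand[i]
    } else out <- c(out, cand[i])
  }
  out
}

#' Rate-based regime descriptors
#'
#' Three summaries of the excitatory-rate trajectories used to map dynamical
#' regimes:
#' * `R_tot`: median over regions of the time-averaged rate
#'   \eqn{\mu_j = \sum_t r_{jt}/T} — overall activity level.
#' * `R_het`: coefficient of variation across regions of the \eqn{\mu_j}
#'   (population standard deviation over the grand mean
#'   \eqn{\mu_{tot}}) — rate heterogeneity.
#' * `R_var`: median over regions of the per-region temporal CV
#'   \eqn{cv_j} — oscillation amplitude relative to the mean.
#'
#' All standard deviations are population (divide by J or T, not J-1/T-1),
#' matching the defining sums. A zero grand mean or zero regional mean makes
#' the corresponding CV undefined (`NaN`, with a warning).
#'
#' @param ts An `mts` or region x sample matrix.
#' @return Named list `R_tot`, `R_het`, `R_var` (plus `mu`, the per-region
#'   time averages).
#' @export
rate_metrics <- function(ts) {
  re <- if (inherits(ts, "mts")) ts$re else as.matrix(ts)
  stopifnot(ncol(re) > 0)
  mu <- rowMeans(re)
  mu_tot <- mean(mu)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  R_het <- if (mu_tot == 0) {
    warning("grand-mean rate is zero; R_het undefined"); NaN
  } else sd_pop(mu) / mu_tot
  cv <- vapply(seq_len(nrow(re)), function(j) {
    if (mu[j] == 0) NaN
    else sqrt(mean((re[j, ] - mu[j])^2)) / mu[j]
  }, numeric(1))
  if (anyNA(cv)) warning("region(s) with zero mean rate; their cv undefined")
  list(R_tot = median(mu), R_het = R_het, R_var = median(cv, na.rm = TRUE),
       mu = mu)
}

#' Pairwise phase-locking value matrix
#'
#' \eqn{PLV_{jk} = |T^{-1}\sum_t e^{i(\phi_j(t) - \phi_k(t))}|} over the
#' samples where both phases are defined. 1 = perfectly consistent phase
#' relation, 0 = none. Symmetric, diagonal 1; pairs with fewer than
#' `min_overlap` common valid samples are `NA`.
#'
#' @param phases A `phase_series` from [extract_phase()].
#' @param min_overlap Minimum number of common valid samples (default 10).
#' @return N x N symmetric matrix.
#' @export
plv_matrix <- function(phases, min_overlap = 10) {
  phi <- if (inherits(phases, "phase_series")) phases$phi else as.matrix(phases)
  N <- nrow(phi)
  z <- exp(1i * phi)
  plv <- matrix(NA_real_, N, N, dimnames = list(rownames(phi), rownames(phi)))
  diag(plv) <- 1
  valid <- !is.na(phi)
  for (j in seq_len(N - 1)) {
    for (k in (j + 1):N) {
      ok <- valid[j, ] & valid[k, ]
      n <- sum(ok)
      if (n >= min_overlap) {
        plv[j, k] <- plv[k, j] <- Mod(mean(z[j, ok] * Conj(z[k, ok])))
      }
    }
  }
  plv
}

#' Network-level PLV summaries
#'
#' `PLV_all` is the mean over the N(N-1)/2 unique region pairs; `PLV_top`
#' the mean over the `ceiling(0.25 * n_pairs)` largest pairwise values (the
#' top quartile of links). Undefined pairs are dropped from both (their
#' count is reported).
#'
#' @param plv Symmetric PLV matrix from [plv_matrix()].
#' @param top_fraction Fraction of strongest links averaged for `PLV_top`
#'   (default 0.25).
#' @return Named list `PLV_all`, `PLV_top`, `n_pairs`, `n_undefined`.
#' @export
plv_summaries <- function(plv, top_fraction = 0.25) {
  v <- plv[upper.tri(plv)]
  n_pairs <- length(v)
  und <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0) return(list(PLV_all = NA_real_, PLV_top = NA_real_,
                                  n_pairs = n_pairs, n_undefined = und))
  n_top <- min(ceiling(top_fraction * n_pairs), length(v))
  # ties at the quartile boundary: value then pair index (sort is stable)
  ord <- order(v, decreasing = TRUE)
  list(PLV_all = mean(v),
       PLV_top = mean(v[ord[seq_len(n_top)]]),
       n_pairs = n_pairs, n_undefined = und)
}

#' Sweep the (G_ee, I_ext) plane
#'
#' One resting simulation per grid point (one seed per point by default),
#' summarized by the rate metrics and PLV summaries. Blown-up runs are
#' recorded as failed rows; the sweep continues.
#'
#' @param gee_values,iext_values Numeric vectors defining the grid.
#' @param config A [sim_config()]; its seed is used for every point unless
#'   `seeds` is given.
#' @param sc Connectome.
#' @param params Base [nm_params()]; `G_ee`/`I_ext` are overridden per point.
#' @param seeds Optional vector of seeds, one simulation per seed per point
#'   (metrics pooled by averaging).
#' @return Data frame with columns `gee`, `iext`, `seed`, `R_tot`, `R_het`,
#'   `R_var`, `PLV_all`, `PLV_top`, `status`.
#' @export
sweep_regimes <- function(gee_values, iext_values, config, sc,
                          params = nm_params(), seeds = NULL) {
  if (is.null(seeds)) seeds <- config$seed
  grid <- expand.grid(gee = gee_values, iext = iext_values, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gee[i]; ie <- grid$iext[i]; s <- grid$seed[i]
    p <- params; p$G_ee <- g; p$I_ext <- ie
    cfg <- config; cfg$seed <- as.integer(s)
    out <- data.frame(gee = g, iext = ie, seed = s, R_tot = NA_real_,
                      R_het = NA_real_, R_var = NA_real_,
                      PLV_all = NA_real_, PLV_top = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    sim <- tryCatch(simulate_network(cfg, p, sc), error = function(e) e)
    if (inherits(sim, "error")) { out$status <- "failed"; return(out) }
    rm_ <- rate_metrics(sim)
    out$R_tot <- rm_$R_tot; out$R_het <- rm_$R_het; out$R_var <- rm_$R_var
    ph <- suppressWarnings(extract_phase(sim))
    ps <- plv_summaries(plv_matrix(ph))
    out$PLV_all <- ps$PLV_all; out$PLV_top <- ps$PLV_top
    out
  })
  do.call(rbind, rows)
}
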