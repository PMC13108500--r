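#' Sliding-window specification
#'
#' @param length Window length in samples (default 140).
#' @param overlap Overlap fraction in \[0, 1) (default 0.75, i.e. stride 35).
#' @return List of class `windowing_spec` with `length`, `overlap`, `stride`.
#' @export
windowing_spec <- function(length = 140, overlap = 0.75) {
  stopifnot(overlap >= 0, overlap < 1, length >= 2)
  stride <- max(1L, as.integer(round(length * (1 - overlap))))
  structure(list(length = as.integer(length), overlap = overlap,
                 stride = stride), class = "windowing_spec")
}

#' Sliding-window start/end indices
#'
#' Windows start at sample 1, advance by the stride, and the last window
#' lies fully inside the series: the count is
#' `floor((T - L) / stride) + 1`.
#'
#' @param ts An `mts`, or an integer series length.
#' @param spec A [windowing_spec()].
#' @return Data frame with `start`, `end` (1-based, inclusive); zero rows
#'   (with a warning) if the series is shorter than one window.
#' @export
sliding_windows <- function(ts, spec = windowing_spec()) {
  T <- if (inherits(ts, "mts")) ncol(ts$re) else as.integer(ts)
  L <- spec$length
  if (T < L) {
    warning("series length ", T, " shorter than one window (", L, ")")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  n <- (T - L) %/% spec$stride + 1L
  start <- 1L + (seq_len(n) - 1L) * spec$stride
  data.frame(start = start, end = start + L - 1L)
}

upper_pairs <- function(N) {
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

# PLV of all pairs within a phase slice, via masked complex inner products
window_plv_matrix <- function(phi, min_overlap = 10) {
  valid <- !is.na(phi)
  z <- exp(1i * phi)
  z[!valid] <- 0
  counts <- valid %*% t(valid)
  num <- Mod(z %*% Conj(t(z)))
  plv <- ifelse(counts >= min_overlap, num / pmax(counts, 1), NA_real_)
  diag(plv) <- 1
  plv
}

#' Global link threshold from per-link median PLV
#'
#' The windowed PLV of every link, taken over all windows, is summarized by
#' its median; the returned scalar is the `percentile`-th percentile
#' (default 54) of the distribution of these per-link medians, computed with
#' linear interpolation between order statistics (`stats::quantile` type 7).
#' One global scalar, reused to binarize every window.
#'
#' @param link_plv Windows x links matrix of PLV values (NA allowed).
#' @param percentile Percentile in \[0, 100\] (default 54).
#' @return Scalar threshold.
#' @export
link_threshold <- function(link_plv, percentile = 54) {
  med <- apply(link_plv, 2, median, na.rm = TRUE)
  unname(quantile(med, percentile / 100, na.rm = TRUE, type = 7))
}

#' Hub vector of one window
#'
#' Hubness of a region is its degree in the binarized windowed PLV graph
#' (links with PLV at or above the global threshold, so that a threshold
#' falling exactly on the strong mode of a bimodal link distribution still
#' retains that mode); hubs are regions with hubness greater than or equal
#' to `hub_threshold`.
#'
#' @param plv N x N windowed PLV matrix.
#' @param threshold Global link threshold from [link_threshold()].
#' @param hub_threshold Minimum degree for hub status (default 21).
#' @return List with `degree` (integer vector) and `hub` (0/1 vector).
#' @export
hub_vector <- function(plv, threshold, hub_threshold = 21) {
  adj <- !is.na(plv) & plv >= threshold
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  list(degree = as.integer(deg), hub = as.integer(deg >= hub_threshold))
}

# low-pass a real sequence in Fourier space: keep harmonics up to
# `mult` times the dominant (largest-amplitude) non-DC frequency
fourier_lowpass <- function(v, mult = 3) {
  n <- length(v)
  co <- fft(v)
  amp <- Mod(co[2:(n %/% 2 + 1)])
  kd <- which.max(amp)
  kmax <- min(mult * kd, n %/% 2)
  keep <- c(1, 2:(kmax + 1), if (kmax > 0) (n - kmax + 1):n)
  mask <- rep(FALSE, n); mask[unique(pmin(keep, n))] <- TRUE
  Re(fft(co * mask, inverse = TRUE)) / n
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# parabolic refinement of a local-max position (indices of v, 1-based)
refine_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(as.numeric(i))
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom == 0) return(as.numeric(i))
  i + 0.5 * (v[i - 1] - v[i + 1]) / denom
}

#' Normalized phase lag of one signal pair
#'
#' Cross-correlogram of the two (demeaned) rate segments over positive
#' latencies. The lag is the latency of the first off-zero correlogram
#' peak divided by the interval between the first and second peaks (the
#' mean oscillation period), reduced modulo 1, with parabolic sub-sample
#' peak refinement. Peaks are located on the raw (taper-corrected)
#' correlogram; if that yields no usable peak pair — as happens for noisy,
#' weakly periodic correlograms — detection is retried on a low-pass
#' smoothed version (Fourier-space cutoff at `lowpass_mult` times the
#' dominant frequency). Smoothing is a fallback only, because for clean
#' deterministic segments spanning few cycles it measurably shifts peak
#' locations. Convention: `lag(x, y)` is the fraction of a period by which
#' `y` trails `x`; 0 = in-phase, 0.5 = anti-phase.
#'
#' @param x,y Numeric signal segments of equal length.
#' @param max_lag Largest latency scanned (default 70% of the segment).
#' @param lowpass_mult Harmonic cutoff of the fallback smoothing as a
#'   multiple of the correlogram's dominant frequency (default 3).
#' @return Scalar lag in \[0, 1), or `NA` if no off-zero peak pair exists.
#' @export
pairwise_lag <- function(x, y, max_lag = floor(0.7 * length(x)),
                         lowpass_mult = 3) {
  L <- length(x)
  stopifnot(length(y) == L, max_lag < L)
  x <- x - mean(x); y <- y - mean(y)
  n2 <- stats::nextn(2 * L)
  X <- fft(c(x, numeric(n2 - L)))
  Y <- fft(c(y, numeric(n2 - L)))
  cc <- Re(fft(Conj(X) * Y, inverse = TRUE)) / n2
  # cc[1 + m] = sum_t x[t] y[t + m]: peak at m where y trails x by m
  m <- 0:max_lag
  raw <- cc[1 + m] / (L - m)          # unbiased taper correction
  lag_from <- function(v) {
    pk <- local_maxima(v)
    pk <- pk[pk > 1]                  # off-zero
    if (length(pk) < 2) return(NA_real_)
    t1 <- refine_peak(v, pk[1]) - 1
    t2 <- refine_peak(v, pk[2]) - 1
    period <- t2 - t1
    if (period < 3) return(NA_real_)  # implausibly fast: not a real cycle
    (t1 / period) %% 1
  }
  out <- lag_from(raw)
  if (is.na(out)) out <- lag_from(fourier_lowpass(raw, lowpass_mult))
  out
}

#' Agglomerative clustering of window vectors
#'
#' Hierarchical agglomerative clustering (Euclidean distance, Ward
#' linkage), cut at `n_clusters`. Also reports the mean silhouette width
#' for each candidate cluster count in `silhouette_range`, supporting an
#' average-silhouette choice of the cut.
#'
#' @param x Windows x features matrix.
#' @param n_clusters Number of clusters to cut at.
#' @param silhouette_range Candidate counts for the silhouette report
#'   (default 2:8).
#' @return List with `cluster` (integer ids), `silhouette` (per-window
#'   silhouette width at `n_clusters`), `report` (data frame k /
#'   mean_silhouette), `hclust`.
#' @export
cluster_windows <- function(x, n_clusters, silhouette_range = 2:8) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < n_clusters)
    stop("fewer distinct vectors (", nrow(unique(x)),
         ") than clusters (", n_clusters, ")")
  d <- dist(x)
  hc <- hclust(d, method = "ward.D2")
  ids <- cutree(hc, k = n_clusters)
  sil <- cluster::silhouette(ids, d)
  silw <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, length(ids))
  rep_k <- silhouette_range[silhouette_range <= nrow(unique(x)) &
                              silhouette_range < nrow(x)]
  report <- data.frame(k = rep_k, mean_silhouette = vapply(rep_k, function(k) {
    s <- cluster::silhouette(cutree(hc, k = k), d)
    if (is.matrix(s)) mean(s[, "sil_width"]) else NA_real_
  }, numeric(1)))
  list(cluster = as.integer(ids), silhouette = as.numeric(silw),
       report = report, hclust = hc)
}

#' Stable hub regions
#'
#' Regions labeled as a hub in at least one window of every hub cluster.
#' Phase-lag vectors are computed only over pairs of these regions.
#'
#' @param hub Windows x regions 0/1 hub matrix.
#' @param hub_cluster Integer hub-cluster id per window.
#' @return Integer vector of stable region indices (error if empty).
#' @export
stable_hub_regions <- function(hub, hub_cluster) {
  cl <- sort(unique(hub_cluster))
  per_cluster <- vapply(cl, function(k)
    colSums(hub[hub_cluster == k, , drop = FALSE]) > 0, logical(ncol(hub)))
  stable <- which(rowSums(per_cluster) == length(cl))
  if (length(stable) < 2)
    stop("fewer than two stable hub regions; phase-lag clustering impossible")
  stable
}

#' Assign FC-state labels from the two clusterings
#'
#' Builds the hub-cluster x lag-cluster contingency table; the three most
#' populated cells (ties broken by hub id then lag id) define the states
#' Psi1, Psi2, Psi3 in decreasing size order; all other windows are "None".
#'
#' @param hub_cluster,lag_cluster Integer cluster ids per window.
#' @param n_states Number of intersection cells promoted to states
#'   (default 3).
#' @return List with `state` (character per window), `cells` (the promoted
#'   cells), `contingency`.
#' @export
derive_states <- function(hub_cluster, lag_cluster, n_states = 3) {
  stopifnot(length(hub_cluster) == length(lag_cluster))
  tab <- table(hub = hub_cluster, lag = lag_cluster)
  cells <- as.data.frame(tab, stringsAsFactors = FALSE)
  cells <- cells[cells$Freq > 0, ]
  if (nrow(cells) < n_states)
    stop("only ", nrow(cells), " nonempty hub x lag cells; cannot form ",
         n_states, " states")
  cells$hub <- as.integer(cells$hub); cells$lag <- as.integer(cells$lag)
  cells <- cells[order(-cells$Freq, cells$hub, cells$lag), ]
  top <- cells[seq_len(n_states), ]
  state <- rep("None", length(hub_cluster))
  for (i in seq_len(n_states)) {
    sel <- hub_cluster == top$hub[i] & lag_cluster == top$lag[i]
    state[sel] <- paste0("Psi", i)
  }
  list(state = state, cells = top, contingency = tab)
}

lag_embedding <- function(lagmat) {
  emb <- cbind(cos(2 * pi * lagmat), sin(2 * pi * lagmat))
  colnames(emb) <- c(paste0("cos_", colnames(lagmat) %||%
                              seq_len(ncol(lagmat))),
                     paste0("sin_", colnames(lagmat) %||%
                              seq_len(ncol(lagmat))))
  emb
}

impute_columns <- function(x) {
  nas <- is.na(x)
  if (any(nas)) {
    cm <- colMeans(x, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    for (j in which(colSums(nas) > 0)) x[nas[, j], j] <- cm[j]
  }
  list(x = x, n_imputed = sum(nas))
}

#' Extract discrete FC states from resting runs
#'
#' The full unsupervised stage: sliding-window PLV matrices; a global link
#' threshold (percentile of per-link median PLV); binarization, hubness and
#' hub vectors; agglomerative clustering of hub vectors; the stable-hub
#' region set and windowed phase lags over its pairs; clustering of lag
#' vectors (embedded on the unit circle to respect the 0/1 wrap);
#' state assignment from the largest hub x lag intersections; typicality
#' (sum of the two silhouette widths) and prototype selection.
#'
#' @param runs List of `mts` resting runs (same region set).
#' @param spec A [windowing_spec()].
#' @param hub_threshold Minimum degree for hub status (default 21).
#' @param n_hub_clusters,n_lag_clusters Cluster counts (defaults 5, 4).
#' @param n_states Number of states (default 3).
#' @param link_percentile Link-threshold percentile (default 54).
#' @param n_prototypes Prototypes per state (default 100; all windows of a
#'   smaller state are kept with a warning).
#' @param min_overlap Minimum valid-phase overlap for a window PLV entry.
#' @param lowpass_mult Correlogram smoothing cutoff (see [pairwise_lag()]).
#' @return A `state_catalog` object; see Details.
#' @details The catalog holds: `windows` (one row per window: run, start,
#'   end, hub_cluster, lag_cluster, state, typicality, is_prototype),
#'   `plv` (windows x pairs), `hub` (windows x regions), `lag`
#'   (windows x stable pairs), `link_threshold`, `stable_regions`,
#'   `pairs`, `stable_pairs` and the parameters. Used to train the k-NN
#'   state classifier and to plan stimulation experiments.
#' @export
extract_fc_states <- function(runs, spec = windowing_spec(),
                              hub_threshold = 21,
                              n_hub_clusters = 5, n_lag_clusters = 4,
                              n_states = 3, link_percentile = 54,
                              n_prototypes = 100, min_overlap = 10,
                              lowpass_mult = 3) {
  stopifnot(length(runs) >= 1)
  N <- nrow(runs[[1]]$re)
  pairs <- upper_pairs(N)
  win_list <- list(); plv_rows <- list(); run_id <- integer(0)
  phases <- lapply(runs, function(r) suppressWarnings(extract_phase(r)))
  for (ri in seq_along(runs)) {
    w <- sliding_windows(runs[[ri]], spec)
    if (nrow(w) == 0) next
    phi <- phases[[ri]]$phi
    for (i in seq_len(nrow(w))) {
      pm <- window_plv_matrix(phi[, w$start[i]:w$end[i], drop = FALSE],
                              min_overlap)
      plv_rows[[length(plv_rows) + 1]] <- pm[pairs]
    }
    win_list[[length(win_list) + 1]] <- w
    run_id <- c(run_id, rep(ri, nrow(w)))
  }
  windows <- do.call(rbind, win_list)
  windows$run <- run_id
  plv <- do.call(rbind, plv_rows)
  colnames(plv) <- paste0(pairs[, 1], "-", pairs[, 2])
  W <- nrow(windows)

  thr <- link_threshold(plv, link_percentile)

  hub <- matrix(0L, W, N)
  for (i in seq_len(W)) {
    pm <- matrix(NA_real_, N, N)
    pm[pairs] <- plv[i, ]; pm[pairs[, c(2, 1)]] <- plv[i, ]
    hub[i, ] <- hub_vector(pm, thr, hub_threshold)$hub
  }

  hub_cl <- cluster_windows(hub, n_hub_clusters)
  stable <- stable_hub_regions(hub, hub_cl$cluster)
  sp <- upper_pairs(length(stable))
  stable_pairs <- cbind(stable[sp[, 1]], stable[sp[, 2]])

  lag <- matrix(NA_real_, W, nrow(stable_pairs))
  colnames(lag) <- paste0(stable_pairs[, 1], "-", stable_pairs[, 2])
  wi <- 0
  for (ri in seq_along(runs)) {
    w <- sliding_windows(runs[[ri]], spec)
    if (nrow(w) == 0) next
    re <- runs[[ri]]$re
    for (i in seq_len(nrow(w))) {
      wi <- wi + 1
      seg <- re[, w$start[i]:w$end[i], drop = FALSE]
      for (pp in seq_len(nrow(stable_pairs)))
        lag[wi, pp] <- pairwise_lag(seg[stable_pairs[pp, 1], ],
                                    seg[stable_pairs[pp, 2], ],
                                    lowpass_mult = lowpass_mult)
    }
  }
  emb_raw <- lag_embedding(lag)
  emb <- impute_columns(emb_raw)
  lag_cl <- cluster_windows(emb$x, n_lag_clusters)

  st <- derive_states(hub_cl$cluster, lag_cl$cluster, n_states)
  typ <- hub_cl$silhouette + lag_cl$silhouette

  windows$hub_cluster <- hub_cl$cluster
  windows$lag_cluster <- lag_cl$cluster
  windows$state <- st$state
  windows$typicality <- typ
  windows$is_prototype <- FALSE
  for (s in unique(st$state[st$state != "None"])) {
    idx <- which(windows$state == s)
    if (length(idx) < n_prototypes)
      warning("state ", s, " has only ", length(idx),
              " windows (< ", n_prototypes, "); all become prototypes")
    keep <- idx[order(-windows$typicality[idx])][
      seq_len(min(n_prototypes, length(idx)))]
    windows$is_prototype[keep] <- TRUE
  }

  structure(list(windows = windows, plv = plv, hub = hub, lag = lag,
                 lag_emb = emb$x, n_lag_imputed = emb$n_imputed,
                 link_threshold = thr, stable_regions = stable,
                 pairs = pairs, stable_pairs = stable_pairs,
                 contingency = st$contingency, state_cells = st$cells,
                 silhouette_reports = list(hub = hub_cl$report,
                                           lag = lag_cl$report),
                 params = list(spec = spec, hub_threshold = hub_threshold,
                               n_hub_clusters = n_hub_clusters,
                               n_lag_clusters = n_lag_clusters,
                               n_states = n_states,
                               link_percentile = link_percentile,
                               n_prototypes = n_prototypes,
                               min_overlap = min_overlap,
                               lowpass_mult = lowpass_mult,
                               n_regions = N)),
            class = "state_catalog")
}

#' @export
print.state_catalog <- function(x, ...) {
  cat("FC-state catalog:", nrow(x$windows), "windows,",
      length(unique(x$windows$run)), "runs\n")
  print(table(x$windows$state))
  cat(sprintf("link threshold %.3f; %d stable hub regions (%d pairs)\n",
              x$link_threshold, length(x$stable_regions),
              nrow(x$stable_pairs)))
  invisible(x)
}

catalog_features <- function(catalog) {
  cbind(catalog$hub, catalog$lag_emb)
}

#' Fit the k-nearest-neighbour FC-state classifier
#'
#' Training set = the state prototypes (highest-typicality windows per
#' state); feature vector = the binary hub vector concatenated with the
#' unit-circle embedding (cos, sin of 2 pi lag) of the stable-pair lag
#' vector; Euclidean distance. Undefined lag entries of a query are imputed
#' with the prototype-set mean embedding for that pair (and flagged).
#'
#' @param catalog A `state_catalog`.
#' @param k Number of neighbours (default 50, capped at the prototype
#'   count).
#' @return A `state_knn` object.
#' @export
fit_state_classifier <- function(catalog, k = 50) {
  proto <- which(catalog$windows$is_prototype)
  stopifnot(length(proto) > 0)
  feats <- catalog_features(catalog)[proto, , drop = FALSE]
  labels <- catalog$windows$state[proto]
  if (k > length(proto)) {
    warning("k = ", k, " larger than prototype count ", length(proto),
            "; using k = ", length(proto))
    k <- length(proto)
  }
  impute <- colMeans(catalog$lag_emb[proto, , drop = FALSE], na.rm = TRUE)
  impute[is.nan(impute)] <- 0
  structure(list(features = feats, labels = labels, k = as.integer(k),
                 impute = impute, n_hub = ncol(catalog$hub),
                 label_order = c(sort(unique(labels)), "None")),
            class = "state_knn")
}

#' Classify a window's FC state
#'
#' Majority label among the k nearest prototypes (Euclidean distance in the
#' hub + lag-embedding feature space). Ties are broken by the smallest mean
#' neighbour distance among the tied labels, then by fixed label order.
#'
#' @param clf A `state_knn` from [fit_state_classifier()].
#' @param features Numeric feature vector (or matrix, one row per query) in
#'   the classifier's feature space; `NA` lag entries are imputed.
#' @return Character state label(s), with attribute `n_imputed`.
#' @export
classify_state <- function(clf, features) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  stopifnot(ncol(x) == ncol(clf$features))
  n_imp <- 0
  lag_cols <- (clf$n_hub + 1):ncol(x)
  for (i in seq_len(nrow(x))) {
    nas <- which(is.na(x[i, ]))
    nas <- nas[nas %in% lag_cols]
    if (length(nas) > 0) {
      x[i, nas] <- clf$impute[nas - clf$n_hub]
      n_imp <- n_imp + length(nas)
    }
  }
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(clf$features) - x[i, ])^2))
    nb <- order(d)[seq_len(clf$k)]
    votes <- table(clf$labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l) mean(d[nb][clf$labels[nb] == l]),
                       numeric(1))
      top <- top[mean_d == min(mean_d)]
      if (length(top) > 1)
        top <- top[order(match(top, clf$label_order))][1]
    }
    out[i] <- top
  }
  attr(out, "n_imputed") <- n_imp
  out
}

#' Feature vector of an arbitrary signal window
#'
#' Builds the hub-vector + lag-embedding features of a window segment that
#' is not part of the catalog (e.g. a post-stimulation window), using the
#' catalog's global link threshold, hub threshold and stable-pair set.
#' Phases may be supplied from a longer surrounding segment via `phi`
#' (recommended: trough interpolation needs context); otherwise they are
#' extracted from the segment itself.
#'
#' @param segment Region x sample signal matrix (the window).
#' @param catalog The `state_catalog` whose conventions to apply.
#' @param phi Optional phase matrix aligned with `segment` columns.
#' @return Numeric feature vector (hub then lag embedding; lags that could
#'   not be estimated are `NA`, to be imputed by [classify_state()]).
#' @export
window_features <- function(segment, catalog, phi = NULL) {
  N <- catalog$params$n_regions
  stopifnot(nrow(segment) == N)
  if (is.null(phi))
    phi <- suppressWarnings(extract_phase(segment))$phi
  pm <- window_plv_matrix(phi, catalog$params$min_overlap)
  hv <- hub_vector(pm, catalog$link_threshold,
                   catalog$params$hub_threshold)$hub
  sp <- catalog$stable_pairs
  lag <- vapply(seq_len(nrow(sp)), function(pp)
    pairwise_lag(segment[sp[pp, 1], ], segment[sp[pp, 2], ],
                 lowpass_mult = catalog$params$lowpass_mult), numeric(1))
  lagm <- matrix(lag, nrow = 1,
                 dimnames = list(NULL, paste0(sp[, 1], "-", sp[, 2])))
  c(hv, lag_embedding(lagm))
}
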