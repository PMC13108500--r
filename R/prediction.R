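#' Assemble feature blocks for phase-shift prediction
#'
#' Builds the predictor matrix for one stimulated region from a completed
#' experiment set, one row per trial. Available blocks (dimensions for
#' N regions, P = N(N-1)/2 pairs):
#' * `stim_phase` — cos and sin of the stimulation phase (2).
#' * `sc_loc` — outgoing structural connectivity of the stimulated
#'   region (N).
#' * `state_label` — integer code of the FC state at stimulation (1).
#' * `plv_full` — upper triangle of the stimulated window's PLV matrix (P).
#' * `lag_full` — upper triangle of the stimulated window's lag matrix (P).
#' * `plv_loc` / `lag_loc` — PLV / lag between the stimulated region and
#'   the regions it structurally projects to (out-degree dims).
#'
#' The first four state-aware blocks come straight from the catalog;
#' full-pair and local lags are estimated from the stimulated window's
#' signals on demand. Undefined lag or PLV entries are imputed with the
#' column mean and flagged via the `n_imputed` attribute.
#'
#' @param experiments A `stim_experiments`.
#' @param catalog The `state_catalog` behind it.
#' @param runs The resting runs (needed for lag blocks).
#' @param sc The connectome.
#' @param stim_region Stimulated region whose trials to use.
#' @param blocks Character vector of block names, in order.
#' @return List with `x` (trials x dims matrix), `y` (trials x 2 x N array
#'   of cos/sin targets per affected region), `state` (per-trial state),
#'   `trial_rows` (row indices into `experiments$trials`).
#' @export
build_features <- function(experiments, catalog, runs, sc, stim_region,
                           blocks = c("stim_phase", "sc_loc")) {
  known <- c("stim_phase", "sc_loc", "state_label", "plv_full", "lag_full",
             "plv_loc", "lag_loc")
  bad <- setdiff(blocks, known)
  if (length(bad) > 0)
    stop("unknown feature block(s): ", paste(bad, collapse = ", "))
  blocks <- known[known %in% blocks]   # canonical order: scores must not
                                       # depend on how a spec lists blocks
  tr <- experiments$trials
  rows <- which(tr$stim_region == stim_region & tr$status == "ok")
  if (length(rows) == 0) stop("no completed trials for region ", stim_region)
  scm <- as_sc_matrix(sc)
  N <- nrow(scm)
  out_nb <- which(scm[, stim_region] > 0)       # regions the stim region projects to
  cat_rows <- experiments$catalog_row[rows]
  need_lags <- any(c("lag_full", "lag_loc") %in% blocks)
  lag_full_cache <- NULL
  if (need_lags) {
    pairs <- catalog$pairs
    uw <- unique(cat_rows)
    lag_full_cache <- matrix(NA_real_, nrow(catalog$windows), nrow(pairs))
    for (w in uw) {
      ri <- catalog$windows$run[w]
      seg <- runs[[ri]]$re[, catalog$windows$start[w]:catalog$windows$end[w],
                           drop = FALSE]
      lag_full_cache[w, ] <- vapply(seq_len(nrow(pairs)), function(pp)
        pairwise_lag(seg[pairs[pp, 1], ], seg[pairs[pp, 2], ],
                     lowpass_mult = catalog$params$lowpass_mult),
        numeric(1))
    }
  }
  pair_cols_with <- function(region) {
    which(catalog$pairs[, 1] == region | catalog$pairs[, 2] == region)
  }
  loc_cols <- integer(0)
  if (any(c("plv_loc", "lag_loc") %in% blocks)) {
    pc <- pair_cols_with(stim_region)
    other <- ifelse(catalog$pairs[pc, 1] == stim_region,
                    catalog$pairs[pc, 2], catalog$pairs[pc, 1])
    loc_cols <- pc[other %in% out_nb]
  }
  parts <- list(); n_imputed <- 0
  for (b in blocks) {
    part <- switch(b,
      stim_phase = cbind(cos = cos(tr$phase[rows]), sin = sin(tr$phase[rows])),
      sc_loc = {
        m <- matrix(scm[, stim_region], length(rows), N, byrow = TRUE)
        colnames(m) <- paste0("sc_", seq_len(N)); m
      },
      state_label = matrix(match(tr$state[rows],
                                 sort(unique(tr$state[rows]))),
                           ncol = 1, dimnames = list(NULL, "state")),
      plv_full = catalog$plv[cat_rows, , drop = FALSE],
      lag_full = {
        m <- lag_full_cache[cat_rows, , drop = FALSE]
        colnames(m) <- paste0("lag_", colnames(catalog$plv)); m
      },
      plv_loc = catalog$plv[cat_rows, loc_cols, drop = FALSE],
      lag_loc = {
        m <- lag_full_cache[cat_rows, loc_cols, drop = FALSE]
        colnames(m) <- paste0("lag_", colnames(catalog$plv)[loc_cols]); m
      })
    imp <- impute_columns(part)
    n_imputed <- n_imputed + imp$n_imputed
    parts[[b]] <- imp$x
  }
  x <- do.call(cbind, parts)
  y <- array(NA_real_, c(length(rows), 2, N),
             dimnames = list(NULL, c("cos", "sin"), NULL))
  d <- experiments$dphi_late[rows, , drop = FALSE]
  y[, 1, ] <- cos(d); y[, 2, ] <- sin(d)
  structure(list(x = x, y = y, state = tr$state[rows], trial_rows = rows),
            n_imputed = n_imputed)
}

#' Cross-validated random-forest regression of phase shifts
#'
#' The wrapped phase shift is embedded as (cos, sin) and each output
#' dimension is fit by a random forest (100 trees, maximum depth 5).
#' Validation uses `folds` repeated random splits with `train_frac` of the
#' samples in training, stratified by FC state so every fold's training
#' and test parts contain all states (classic disjoint k-fold is available
#' with `scheme = "kfold"`). The score is the coefficient of determination
#' on the test samples, averaged over the two output dimensions; the mean
#' absolute angular error (radians, pi-periodic) is reported alongside.
#'
#' @param x Samples x features matrix.
#' @param y Samples x 2 matrix of (cos, sin) targets.
#' @param state Per-sample stratum (FC state).
#' @param folds Number of folds / repeats (default 10).
#' @param train_frac Training fraction per repeated split (default 0.7).
#' @param max_depth Tree depth cap (default 5).
#' @param num_trees Forest size (default 100).
#' @param seed Integer seed (controls splits and forests).
#' @param scheme `"repeated"` (default) or `"kfold"`.
#' @return Data frame with one row per fold: `fold`, `score`,
#'   `angular_error`, `n_train`, `n_test`.
#' @export
crossvalidated_rfr <- function(x, y, state, folds = 10, train_frac = 0.7,
                               max_depth = 5, num_trees = 100, seed = 1,
                               scheme = c("repeated", "kfold")) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(y) == 2, length(state) == nrow(x))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(x)
  strata <- split(seq_len(n), state)
  if (any(lengths(strata) < 2))
    stop("state(s) with fewer than 2 samples cannot be stratified: ",
         paste(names(strata)[lengths(strata) < 2], collapse = ", "))
  make_split <- function(f) {
    if (scheme == "repeated") {
      train <- unlist(lapply(strata, function(id)
        sample(id, max(1, round(train_frac * length(id))))))
      list(train = train, test = setdiff(seq_len(n), train))
    } else {
      test <- unlist(lapply(strata, function(id) {
        fold_of <- rep_len(seq_len(folds), length(id))[sample(length(id))]
        id[fold_of == f]
      }))
      list(train = setdiff(seq_len(n), test), test = test)
    }
  }
  if (scheme == "kfold") {
    set.seed(as.integer(seed))  # one assignment reused across folds
    assign_cache <- lapply(strata, function(id)
      rep_len(seq_len(folds), length(id))[sample(length(id))])
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  res <- lapply(seq_len(folds), function(f) {
    sp <- if (scheme == "repeated") make_split(f) else {
      test <- unlist(mapply(function(id, a) id[a == f], strata,
                            assign_cache, SIMPLIFY = FALSE))
      list(train = setdiff(seq_len(n), test), test = test)
    }
    if (!setequal(unique(state[sp$train]), unique(state)) ||
        length(sp$test) == 0)
      stop("fold ", f, ": a state is absent from the training part")
    dtrain <- data.frame(x[sp$train, , drop = FALSE])
    dtest <- data.frame(x[sp$test, , drop = FALSE])
    pred <- sapply(1:2, function(dim_) {
      fit <- ranger::ranger(
        y = y[sp$train, dim_], x = dtrain,
        num.trees = num_trees, max.depth = max_depth,
        seed = seed + f, num.threads = 1)
      predict(fit, data = dtest, num.threads = 1)$predictions
    })
    r2 <- sapply(1:2, function(dim_) {
      sst <- sum((y[sp$test, dim_] - mean(y[sp$train, dim_]))^2)
      ssr <- sum((y[sp$test, dim_] - pred[, dim_])^2)
      if (sst == 0) return(NA_real_)
      1 - ssr / sst
    })
    ang_true <- atan2(y[sp$test, 2], y[sp$test, 1])
    ang_pred <- atan2(pred[, 2], pred[, 1])
    data.frame(fold = f, score = mean(r2, na.rm = TRUE),
               angular_error = mean(abs(wrap_phase_shift(ang_pred - ang_true))),
               n_train = length(sp$train), n_test = length(sp$test))
  })
  do.call(rbind, res)
}

#' Compare feature sets for phase-shift prediction
#'
#' Runs the cross-validated forest for each feature set and each affected
#' region, pools the per-fold per-affected-region test scores (folds x
#' affected regions points per set), and tests every pair of feature sets
#' with a Mann-Whitney rank-sum test, Bonferroni-corrected over all
#' pairwise comparisons. Improvement is
#' `(mean score - baseline mean) / |baseline mean| * 100`.
#'
#' @param experiments,catalog,runs,sc,stim_region As in [build_features()].
#' @param feature_sets Named list of block vectors.
#' @param baseline Name of the baseline set (must be in `feature_sets`).
#' @param affected_regions Indices of affected regions to score (default
#'   all N).
#' @param ... Passed to [crossvalidated_rfr()] (folds, seed, ...).
#' @return List with `scores` (long data frame: feature_set,
#'   affected_region, fold, score, angular_error), `summary` (per-set mean
#'   score and improvement), `comparisons` (pair, statistic, p_raw,
#'   p_bonferroni).
#' @export
compare_feature_sets <- function(experiments, catalog, runs, sc,
                                 stim_region, feature_sets, baseline,
                                 affected_regions = NULL, ...) {
  stopifnot(length(feature_sets) >= 2, !is.null(names(feature_sets)))
  if (!baseline %in% names(feature_sets))
    stop("baseline '", baseline, "' not among the feature sets")
  if (is.null(affected_regions))
    affected_regions <- seq_len(catalog$params$n_regions)
  scores <- list()
  for (fs in names(feature_sets)) {
    ds <- build_features(experiments, catalog, runs, sc, stim_region,
                         feature_sets[[fs]])
    for (a in affected_regions) {
      y <- ds$y[, , a]
      keep <- complete.cases(y)
      cv <- crossvalidated_rfr(ds$x[keep, , drop = FALSE],
                               y[keep, , drop = FALSE],
                               ds$state[keep], ...)
      cv$feature_set <- fs; cv$affected_region <- a
      scores[[length(scores) + 1]] <- cv
    }
  }
  scores <- do.call(rbind, scores)
  means <- tapply(scores$score, scores$feature_set,
                  function(v) mean(v, na.rm = TRUE))
  base_mean <- means[[baseline]]
  summary <- data.frame(
    feature_set = names(means), mean_score = as.numeric(means),
    improvement_pct = (as.numeric(means) - base_mean) /
      max(abs(base_mean), .Machine$double.eps) * 100,
    stringsAsFactors = FALSE)
  sets <- names(feature_sets)
  cmb <- utils::combn(sets, 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- scores$score[scores$feature_set == cmb[1, i]]
    b <- scores$score[scores$feature_set == cmb[2, i]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0 || length(b) == 0) {
      return(data.frame(pair = paste(cmb[1, i], "vs", cmb[2, i]),
                        statistic = NA_real_, p_raw = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(wilcox.test(a, b))
    data.frame(pair = paste(cmb[1, i], "vs", cmb[2, i]),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  comparisons$p_bonferroni <- pmin(1, comparisons$p_raw * nrow(comparisons))
  list(scores = scores, summary = summary, comparisons = comparisons)
}
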