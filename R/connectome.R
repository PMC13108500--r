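#' Generate a surrogate structural connectome
#'
#' Emulates the statistics of a dense, weighted, directed retrograde-tracing
#' connectome: a fixed fraction of off-diagonal entries is nonzero, nonzero
#' weights follow a heavy-tailed log-normal law, the matrix is asymmetric
#' and the diagonal is zero. With the default `incoming-sum-to-one`
#' normalization each region's off-diagonal in-weights sum to 1, mimicking
#' fraction-of-labeled-neurons connectomes and keeping total input per
#' region comparable across surrogates.
#'
#' @param n_regions Number of regions (default 29).
#' @param density Fraction of nonzero off-diagonal entries in (0, 1]
#'   (default 0.66).
#' @param meanlog,sdlog Log-normal parameters of the nonzero weights before
#'   normalization (defaults 0, 1.5: heavy-tailed, spanning several decades
#'   as tracer weights do).
#' @param normalization One of `"incoming-sum-to-one"`, `"max-to-one"`,
#'   `"none"`.
#' @param in_strength Overall multiplicative scale applied after
#'   normalization (default 4). With the default normalization every
#'   region's total in-weight equals `in_strength`, so the effective
#'   network coupling is `G_ee * in_strength`. The default places the
#'   study's working point (`G_ee = 80`, `I_ext = 6`) in the partially
#'   synchronized oscillatory regime (see the methods vignette); set
#'   `in_strength = 1` for a pure fraction-of-labeled-neurons-like matrix.
#' @param labels Optional character vector of region names; default
#'   `"R00".."R<N-1>"`.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   matrix.
#' @return An object of class `connectome`: list with `weights` (N x N,
#'   entry \[j, k\] = weight of the projection from source k to target j)
#'   and `labels`.
#' @export
generate_connectome <- function(n_regions = 29, density = 0.66,
                                meanlog = 0, sdlog = 1.5,
                                normalization = c("incoming-sum-to-one",
                                                  "max-to-one", "none"),
                                in_strength = 4, labels = NULL, seed = 1) {
  stopifnot(n_regions >= 2, density > 0, density <= 1, in_strength > 0)
  normalization <- match.arg(normalization)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  N <- n_regions
  off <- which(row(diag(N)) != col(diag(N)))      # column-major order, fixed
  n_nz <- round(density * length(off))
  nz <- sort(sample(off, n_nz))
  w <- matrix(0, N, N)
  w[nz] <- rlnorm(n_nz, meanlog = meanlog, sdlog = sdlog)
  if (normalization == "incoming-sum-to-one") {
    rs <- rowSums(w)
    if (any(rs == 0))
      stop("density too low: region(s) ",
           paste(which(rs == 0), collapse = ", "),
           " received no incoming weight; cannot normalize incoming sums")
    w <- w / rs
  } else if (normalization == "max-to-one") {
    w <- w / max(w)
  }
  w <- w * in_strength
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(N) - 1)
  stopifnot(length(labels) == N)
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, labels = labels,
                 spec = list(n_regions = N, density = density,
                             meanlog = meanlog, sdlog = sdlog,
                             normalization = normalization,
                             in_strength = in_strength, seed = seed)),
            class = "connectome")
}

#' Read a connectome from CSV
#'
#' Expects a square numeric matrix, optionally preceded by a header row of
#' region labels. Negative entries are rejected; nonzero diagonal entries
#' are zeroed with a warning.
#'
#' @param path CSV file path.
#' @return A `connectome` object.
#' @export
load_connectome <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  d <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m))
    stop("connectome must be square; got ", nrow(m), " x ", ncol(m))
  bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop("non-numeric connectome entry at row ", rc[1], ", column ", rc[2])
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) {
    rc <- arrayInd(which(m < 0)[1], dim(m))
    stop("negative connectome weight at row ", rc[1], ", column ", rc[2])
  }
  if (any(diag(m) != 0)) {
    warning("nonzero diagonal entries zeroed (self-connections not allowed)")
    diag(m) <- 0
  }
  labels <- if (has_header) colnames(d) else sprintf("R%02d", seq_len(nrow(m)) - 1)
  dimnames(m) <- list(labels, labels)
  structure(list(weights = m, labels = labels, spec = list(source = path)),
            class = "connectome")
}

#' Write a connectome to CSV (labels as header row)
#' @param con A `connectome`.
#' @param path Output CSV path.
#' @export
write_connectome <- function(con, path) {
  utils::write.csv(as.data.frame(con$weights), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights
  N <- nrow(w)
  dens <- sum(w[row(w) != col(w)] > 0) / (N * (N - 1))
  cat(sprintf("Structural connectome: %d regions, density %.2f, %s\n",
              N, dens,
              if (isTRUE(all.equal(w, t(w)))) "symmetric" else "directed"))
  invisible(x)
}
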