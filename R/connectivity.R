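#' Regional time-series container
#'
#' Bundles an n_regions x n_samples matrix of source-space signals with its
#' sampling rate and region labels.
#'
#' @param data Numeric matrix, regions in rows, samples in columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param region_labels Optional character vector of region names.
#' @return An object of class `regional_ts`.
#' @export
regional_ts <- function(data, sampling_rate, region_labels = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), sampling_rate > 0)
  if (is.null(region_labels)) region_labels <- default_region_labels(nrow(data))
  stopifnot(length(region_labels) == nrow(data))
  structure(
    list(data = data, sampling_rate = sampling_rate,
         region_labels = region_labels),
    class = "regional_ts"
  )
}

#' Functional-connectivity matrix container
#'
#' @param values Square numeric matrix.
#' @param kind Either `"correlation"` (symmetric, unit diagonal, entries in
#'   `[-1, 1]`) or `"binary"` (entries in `{0, 1}`, zero diagonal).
#' @param region_labels Optional character vector of region names.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(values, kind = c("correlation", "binary"),
                      region_labels = NULL) {
  kind <- match.arg(kind)
  check_symmetric(values, "connectivity matrix")
  n <- nrow(values)
  if (kind == "correlation") {
    if (any(abs(diag(values) - 1) > 1e-8)) {
      stop("correlation matrix must have unit diagonal", call. = FALSE)
    }
    if (any(values < -1 - 1e-8) || any(values > 1 + 1e-8)) {
      stop("correlation entries must lie in [-1, 1]", call. = FALSE)
    }
  } else {
    if (!all(values %in% c(0, 1))) {
      stop("binary matrix entries must be 0 or 1", call. = FALSE)
    }
    if (any(diag(values) != 0)) {
      stop("binary matrix must have zero diagonal", call. = FALSE)
    }
  }
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  stopifnot(length(region_labels) == n)
  structure(
    list(values = values, kind = kind, region_labels = region_labels),
    class = "fc_matrix"
  )
}

#' Regional map container
#'
#' One value per region (nodal strength, age-vulnerability, effect sizes,
#' meta-analytic term loadings, ...).
#'
#' @param values Numeric vector, one entry per region.
#' @param name Map name.
#' @param region_labels Optional character vector of region names.
#' @return An object of class `regional_map`.
#' @export
regional_map <- function(values, name = "map", region_labels = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (is.null(region_labels)) region_labels <- default_region_labels(length(values))
  stopifnot(length(region_labels) == length(values))
  structure(
    list(values = as.numeric(values), name = name,
         region_labels = region_labels),
    class = "regional_map"
  )
}

# 3rd-order Bessel analog low-pass prototype, rescaled so the -3 dB point
# sits at omega = 1. The delay-normalized transfer function is
# 15 / (s^3 + 6 s^2 + 15 s + 15).
bessel_prototype <- function(order = 3) {
  if (order != 3) stop("only the 3rd-order Bessel prototype is implemented")
  poles <- polyroot(c(15, 15, 6, 1))
  gain <- 15
  # numeric -3 dB frequency of the delay-normalized prototype
  mag2 <- function(w) {
    h <- gain / ((1i * w)^3 + 6 * (1i * w)^2 + 15 * (1i * w) + 15)
    Mod(h)^2
  }
  w3db <- stats::uniroot(function(w) mag2(w) - 0.5, c(0.1, 10))$root
  list(zero = complex(0), pole = poles / w3db, gain = gain / w3db^3)
}

#' Zero-phase band-pass filter of regional time series
#'
#' Band-pass Bessel filter (analog prototype, low-pass-to-band-pass
#' transform, bilinear discretization) applied forward and backward
#' (`signal::filtfilt`) so the output carries no group delay.
#'
#' @param ts A [regional_ts()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Analog prototype order (3, the only supported value).
#' @return The filtered [regional_ts()].
#' @export
bandpass_filter <- function(ts, low = 8, high = 40, order = 3) {
  stopifnot(inherits(ts, "regional_ts"))
  fs <- ts$sampling_rate
  if (!(low > 0 && low < high)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("band edge at or above Nyquist frequency")
  proto <- bessel_prototype(order)
  # pre-warped band edges for the bilinear transform (T = 2)
  W <- tan(pi * c(low, high) / fs)
  s <- signal::sftrans(proto$zero, proto$pole, proto$gain, W = W, stop = FALSE)
  z <- signal::bilinear(s$zero, s$pole, s$gain, T = 2)
  arma <- signal::as.Arma(signal::Zpg(zero = z$zero, pole = z$pole, gain = z$gain))
  filtered <- t(apply(ts$data, 1, function(x) {
    signal::filtfilt(arma, x)
  }))
  regional_ts(filtered, fs, ts$region_labels)
}

#' Resample regional time series to a target rate
#'
#' Polyphase resampling (`signal::resample`) of every region's signal,
#' preserving total duration to within one sample.
#'
#' @param ts A [regional_ts()].
#' @param target_rate Target sampling rate in Hz.
#' @return The resampled [regional_ts()].
#' @export
resample_ts <- function(ts, target_rate) {
  stopifnot(inherits(ts, "regional_ts"), target_rate > 0)
  if (target_rate == ts$sampling_rate) return(ts)
  ratio <- MASS_fraction(target_rate / ts$sampling_rate)
  out <- t(apply(ts$data, 1, function(x) {
    signal::resample(x, p = ratio$p, q = ratio$q)
  }))
  regional_ts(out, target_rate, ts$region_labels)
}

# small rational approximation p/q of a positive ratio
MASS_fraction <- function(x, max_den = 1024L) {
  best <- c(1L, 1L)
  best_err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    err <- abs(x - p / q)
    if (err < best_err - 1e-15) {
      best <- c(p, q)
      best_err <- err
    }
    if (best_err == 0) break
  }
  list(p = best[1], q = best[2])
}

#' Pearson functional connectivity
#'
#' Correlates every pair of regional signals.
#'
#' @param ts A [regional_ts()].
#' @return A correlation-kind [fc_matrix()].
#' @export
compute_fc <- function(ts) {
  stopifnot(inherits(ts, "regional_ts"))
  v <- apply(ts$data, 1, stats::var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance region(s): %s",
                 paste(ts$region_labels[v == 0], collapse = ", ")),
         call. = FALSE)
  }
  fc <- stats::cor(t(ts$data))
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc_matrix(fc, "correlation", ts$region_labels)
}

#' Nodal strength
#'
#' Per-region sum of off-diagonal connectivity values.
#'
#' @param fc A correlation-kind [fc_matrix()].
#' @return A [regional_map()] named "nodal_strength".
#' @export
nodal_strength <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"), fc$kind == "correlation")
  v <- fc$values
  diag(v) <- 0
  regional_map(rowSums(v), "nodal_strength", fc$region_labels)
}

#' Proportional threshold and binarization
#'
#' Keeps the top `rho` fraction of edges by signed connectivity value,
#' breaking ties by upper-triangle index order, and returns the binary
#' adjacency matrix. The retained edge count is `round(rho * n(n-1)/2)`
#' with round-half-away-from-zero.
#'
#' @param fc A correlation-kind [fc_matrix()].
#' @param rho Proportion of edges to keep, in `(0, 1]`.
#' @param ranking `"signed"` (default) ranks raw correlations, `"absolute"`
#'   ranks their magnitudes.
#' @return A binary-kind [fc_matrix()].
#' @export
proportional_threshold <- function(fc, rho, ranking = c("signed", "absolute")) {
  stopifnot(inherits(fc, "fc_matrix"), fc$kind == "correlation")
  ranking <- match.arg(ranking)
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  n <- nrow(fc$values)
  idx <- upper_tri_index(n)
  vals <- fc$values[idx]
  if (ranking == "absolute") vals <- abs(vals)
  m_total <- length(idx)
  m_keep <- floor(rho * m_total + 0.5)  # round half away from zero
  if (m_keep < 1) stop("rho yields zero retained edges")
  # stable ordering: decreasing value, ties by upper-triangle index
  ord <- order(-vals, seq_along(vals))
  keep <- idx[ord[seq_len(m_keep)]]
  adj <- matrix(0, n, n)
  adj[keep] <- 1
  adj <- adj + t(adj)
  fc_matrix(adj, "binary", fc$region_labels)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Fixed row-major upper-triangle layout of length `n(n-1)/2`; the inverse
#' is [devectorize_fc()].
#'
#' @param fc A correlation-kind [fc_matrix()].
#' @return Numeric feature vector.
#' @export
vectorize_fc <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"), fc$kind == "correlation")
  m <- t(fc$values)  # row-major order of the upper triangle
  m[lower.tri(m)]
}

#' Rebuild a connectivity matrix from its feature vector
#'
#' @param v Feature vector produced by [vectorize_fc()].
#' @param region_labels Optional region labels.
#' @return A correlation-kind [fc_matrix()].
#' @export
devectorize_fc <- function(v, region_labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-8) stop("length is not n(n-1)/2 for integer n")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m <- m + t(m)
  diag(m) <- 1
  fc_matrix(m, "correlation", region_labels)
}

#' Harmonize a set of matrices to a reference mean
#'
#' Edgewise additive shift so the set's mean matrix equals the reference
#' mean, preserving within-set subject differences exactly (before the final
#' clip to `[-1, 1]`).
#'
#' @param target_set List of correlation-kind [fc_matrix()] objects.
#' @param reference_mean Correlation-kind [fc_matrix()] of matching size.
#' @return List of harmonized [fc_matrix()] objects.
#' @export
harmonize_fc <- function(target_set, reference_mean) {
  stopifnot(length(target_set) >= 1, inherits(reference_mean, "fc_matrix"))
  n <- nrow(reference_mean$values)
  for (fc in target_set) {
    if (nrow(fc$values) != n) stop("dimension mismatch in harmonize_fc")
  }
  mean_mat <- Reduce(`+`, lapply(target_set, `[[`, "values")) / length(target_set)
  shift <- reference_mean$values - mean_mat
  lapply(target_set, function(fc) {
    v <- fc$values + shift
    v <- pmin(pmax(v, -1), 1)
    diag(v) <- 1
    fc_matrix((v + t(v)) / 2, "correlation", fc$region_labels)
  })
}
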