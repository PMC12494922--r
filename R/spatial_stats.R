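#' Age-vulnerability map
#'
#' Per region, the Pearson correlation of nodal connectivity strength with
#' chronological age across subjects. Strongly negative regions are the
#' ones most vulnerable to aging.
#'
#' @param cohort A [generate_cohort()] result (or any list with a
#'   `subjects$age` vector).
#' @param strengths Optional list of per-subject [regional_map()] strengths;
#'   computed from the cohort's matrices if missing.
#' @return A [regional_map()]; regions with constant strength across
#'   subjects get value 0 and are flagged in `attr(values, "constant")`.
#' @export
age_vulnerability_map <- function(cohort, strengths = NULL) {
  ages <- cohort$subjects$age
  if (length(ages) < 3) stop("need at least 3 subjects")
  if (stats::sd(ages) == 0) stop("ages must be nonconstant")
  if (is.null(strengths)) {
    strengths <- lapply(cohort$matrices, nodal_strength)
  }
  S <- do.call(rbind, lapply(strengths, `[[`, "values"))
  const <- apply(S, 2, stats::sd) == 0
  vals <- numeric(ncol(S))
  vals[!const] <- apply(S[, !const, drop = FALSE], 2, stats::cor, y = ages)
  m <- regional_map(vals, "age_vulnerability",
                    strengths[[1]]$region_labels)
  attr(m, "constant_regions") <- which(const)
  m
}

#' Regional Cohen's D effect-size map
#'
#' Per region, the pooled-sd Cohen's D of group a minus group b nodal
#' strengths.
#'
#' @param strengths_a,strengths_b Lists of per-subject [regional_map()]
#'   objects (each group >= 2 subjects).
#' @return A [regional_map()] named "effect_size".
#' @export
effect_size_map <- function(strengths_a, strengths_b) {
  stopifnot(length(strengths_a) >= 2, length(strengths_b) >= 2)
  A <- do.call(rbind, lapply(strengths_a, `[[`, "values"))
  B <- do.call(rbind, lapply(strengths_b, `[[`, "values"))
  stopifnot(ncol(A) == ncol(B))
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  if (any(pooled == 0)) stop("zero pooled sd in at least one region")
  regional_map((ma - mb) / pooled, "effect_size",
               strengths_a[[1]]$region_labels)
}

# empirical variogram: mean of 0.5 (z_i - z_j)^2 within distance bins
empirical_variogram <- function(values, D, bins) {
  ut <- upper_tri_index(nrow(D))
  dv <- D[ut]
  half_sq <- 0.5 * (outer(values, values, `-`)[ut])^2
  b <- findInterval(dv, bins, all.inside = TRUE)
  as.numeric(tapply(half_sq, factor(b, levels = seq_len(length(bins) - 1)),
                    mean, default = NA_real_))
}

#' Variogram-matched spatial surrogate maps
#'
#' Spatial-autocorrelation-preserving null maps: each surrogate is a random
#' permutation of the source map, smoothed with a Gaussian distance kernel
#' at the candidate length-scale whose empirical variogram best matches the
#' source map's, then rank-remapped onto the source map's original values
#' (exact value-multiset preservation). Needs only region coordinates, not
#' a spherical surface.
#'
#' @param map A nonconstant [regional_map()] (or numeric vector).
#' @param coordinates `n x 3` region coordinates.
#' @param n Number of surrogates (>= 100 for any p-value use).
#' @param seed Integer seed.
#' @param n_scales Number of candidate smoothing length-scales (default 8,
#'   log-spaced over the distance range).
#' @param n_bins Variogram distance bins (default 20).
#' @return An object of class `surrogate_ensemble`: `surrogates`
#'   (`n x n_regions` matrix), `generator_spec`, `source_map_name`.
#' @export
generate_surrogates <- function(map, coordinates, n = 1000, seed = 1,
                                n_scales = 8, n_bins = 20) {
  vals <- if (inherits(map, "regional_map")) map$values else as.numeric(map)
  name <- if (inherits(map, "regional_map")) map$name else "map"
  stopifnot(n >= 1, is.matrix(coordinates),
            nrow(coordinates) == length(vals))
  if (stats::sd(vals) == 0) stop("cannot build surrogates of a constant map")
  D <- as.matrix(stats::dist(coordinates))
  if (max(D) == 0) stop("degenerate coordinates: all regions coincide")
  nr <- length(vals)
  # variogram fitted on equal-count (quantile) bins of the short-to-mid
  # pair distances; long-range pairs are sparse and dominated by trend
  d_cap <- stats::quantile(D[upper.tri(D)], 0.7)
  qs <- stats::quantile(D[upper.tri(D)][D[upper.tri(D)] <= d_cap],
                        probs = seq(0, 1, length.out = n_bins + 1))
  bins <- unique(as.numeric(qs))
  bins[1] <- 0
  bins[length(bins)] <- bins[length(bins)] * 1.0001
  n_bins <- length(bins) - 1
  scales <- exp(seq(log(max(D) / 50), log(max(D) / 2), length.out = n_scales))
  kernels <- lapply(scales, function(s) {
    K <- exp(-D^2 / (2 * s^2))
    K / rowSums(K)
  })
  sorted_vals <- sort(vals)
  ut <- upper_tri_index(nr)
  ut <- ut[D[ut] <= d_cap]  # fit only on short-to-mid-range pairs
  bfac <- factor(findInterval(D[ut], bins, all.inside = TRUE),
                 levels = seq_len(n_bins))
  # indicator matrix for fast binned variogram of many candidate maps
  Bmat <- stats::model.matrix(~ bfac - 1)
  bin_counts <- colSums(Bmat)
  ii <- ((ut - 1) %% nr) + 1
  jj <- ((ut - 1) %/% nr) + 1
  v_src <- as.vector(crossprod(Bmat, 0.5 * (vals[ii] - vals[jj])^2)) /
    bin_counts
  ok_bin <- is.finite(v_src)
  surr <- matrix(NA_real_, n, nr)
  w_bin <- bin_counts[ok_bin]
  with_local_seed(seed, {
    for (k in seq_len(n)) {
      perm <- vals[sample.int(nr)]
      eps <- stats::rnorm(nr)
      best_sse <- Inf
      best_map <- perm
      for (si in seq_along(kernels)) {
        sm <- as.vector(kernels[[si]] %*% perm)
        sm <- (sm - mean(sm)) / stats::sd(sm)
        half_sq <- 0.5 * (sm[ii] - sm[jj])^2
        v_s <- as.vector(crossprod(Bmat, half_sq)) / bin_counts
        # affine variogram refit: v_src ~ alpha + beta * v_s, alpha acting
        # as a white-noise nugget, pair-count-weighted least squares
        x <- v_s[ok_bin]; y <- v_src[ok_bin]
        xb <- sum(w_bin * x) / sum(w_bin); yb <- sum(w_bin * y) / sum(w_bin)
        beta <- sum(w_bin * (x - xb) * (y - yb)) / sum(w_bin * (x - xb)^2)
        beta <- max(beta, 0)
        alpha <- max(yb - beta * xb, 0)
        sse <- sum(w_bin * (alpha + beta * x - y)^2)
        if (sse < best_sse) {
          best_sse <- sse
          best_map <- sqrt(beta) * sm + sqrt(alpha) * eps
        }
      }
      # rank-remap onto the source values: exact multiset preservation
      surr[k, ] <- sorted_vals[rank(best_map, ties.method = "first")]
    }
  })
  structure(
    list(surrogates = surr,
         generator_spec = list(n = n, seed = seed, scales = scales,
                               bins = bins),
         source_map_name = name),
    class = "surrogate_ensemble"
  )
}

#' Spatially-aware correlation test between two regional maps
#'
#' Pearson correlation of the maps with a two-sided permutation p-value
#' against variogram-matched surrogates of the first map:
#' `p = (1 + #(|r_surr| >= |r|)) / (n_surrogates + 1)`.
#'
#' @param map1,map2 [regional_map()] objects or numeric vectors of equal
#'   length; surrogates are generated from `map1`.
#' @param coordinates `n x 3` region coordinates.
#' @param n_surrogates Number of surrogates (>= 100).
#' @param seed Integer seed.
#' @param surrogates Optional precomputed [generate_surrogates()] ensemble
#'   for `map1` (reused across many tests against the same map).
#' @return List with `r` and `p`.
#' @export
spatial_correlation_test <- function(map1, map2, coordinates,
                                     n_surrogates = 1000, seed = 1,
                                     surrogates = NULL) {
  v1 <- if (inherits(map1, "regional_map")) map1$values else as.numeric(map1)
  v2 <- if (inherits(map2, "regional_map")) map2$values else as.numeric(map2)
  stopifnot(length(v1) == length(v2))
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("cannot test a constant map")
  }
  if (is.null(surrogates)) {
    if (n_surrogates < 100) stop("need at least 100 surrogates")
    surrogates <- generate_surrogates(map1, coordinates, n = n_surrogates,
                                      seed = seed)
  }
  r <- stats::cor(v1, v2)
  r_null <- as.vector(stats::cor(t(surrogates$surrogates), v2))
  p <- (1 + sum(abs(r_null) >= abs(r))) / (nrow(surrogates$surrogates) + 1)
  list(r = r, p = p)
}

#' Term-map association profile
#'
#' Correlates an effect-size map with every term map, reporting per term
#' the absolute Pearson correlation, a surrogate p-value (surrogates built
#' once from the effect map), and Benjamini-Hochberg q-values across terms.
#'
#' @param effect_map A [regional_map()].
#' @param term_maps List of [regional_map()] objects.
#' @param coordinates `n x 3` region coordinates.
#' @param n_surrogates Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @return Data frame with columns `term`, `abs_r`, `p`, `q`.
#' @export
term_association_profile <- function(effect_map, term_maps, coordinates,
                                     n_surrogates = 1000, seed = 1) {
  stopifnot(length(term_maps) >= 1)
  ens <- generate_surrogates(effect_map, coordinates, n = n_surrogates,
                             seed = seed)
  res <- lapply(term_maps, function(tm) {
    out <- spatial_correlation_test(effect_map, tm, coordinates,
                                    surrogates = ens)
    data.frame(term = tm$name, abs_r = abs(out$r), p = out$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  rownames(tab) <- NULL
  tab
}
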