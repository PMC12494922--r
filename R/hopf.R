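#' Hopf (Stuart-Landau) whole-brain model parameters
#'
#' Per-region supercritical Hopf normal-form oscillators coupled diffusively
#' through a structural connectome scaled by a global coupling `G`. The
#' bifurcation parameter `a` switches noise-driven (`a < 0`) versus
#' self-sustained (`a > 0`) oscillation; `f` is the natural frequency in Hz
#' (`w = 2*pi*f`); `beta` is the standard deviation of the additive Gaussian
#' noise on both oscillator components.
#'
#' @param a Bifurcation parameter, scalar or per-region. Default 0.01
#'   (slightly supercritical, self-sustained oscillation).
#' @param f Natural frequency in Hz, scalar or per-region. Default 10.
#' @param beta Noise standard deviation (signal units). Default 0.1.
#' @param G Global coupling (dimensionless). Default 1.
#' @param dt Integration step in seconds. Default 0.001.
#' @param duration Simulated duration in seconds (after transient). Default 60.
#' @param transient Discarded initial transient in seconds. Default 5.
#' @param seed Integer seed for the stochastic integration. Default 1.
#' @param init_sd Standard deviation of the random initial state (0 starts
#'   exactly at the origin). Default 0.1.
#' @return An object of class `hopf_params`.
#' @export
hopf_params <- function(a = 0.01, f = 10, beta = 0.1, G = 1,
                        dt = 0.001, duration = 60, transient = 5, seed = 1,
                        init_sd = 0.1) {
  stopifnot(beta >= 0, dt > 0, duration > dt, all(f > 0), transient >= 0,
            init_sd >= 0)
  structure(
    list(a = a, f = f, beta = beta, G = G, dt = dt,
         duration = duration, transient = transient, seed = seed,
         init_sd = init_sd),
    class = "hopf_params"
  )
}

# Scale connectome weights so the maximum row sum equals 1, making G
# comparable across connectomes. An all-zero matrix (uncoupled nodes) is
# left untouched.
normalize_coupling <- function(weights) {
  s <- max(rowSums(weights))
  if (s <= 0) return(weights)
  weights / s
}

#' Linear drift matrix of the coupled Hopf system
#'
#' Jacobian of the stochastic Stuart-Landau network at the origin, with
#' state ordered `(x_1..x_n, y_1..y_n)`. Each node contributes the 2x2 block
#' `[[a_i - G*s_i, -w_i], [w_i, a_i - G*s_i]]` with `s_i = sum_j M_ij` (the
#' diffusive self-term), and node pairs couple through `G * M_ij * I_2`.
#' Connectome weights are rescaled to unit maximum row sum first.
#'
#' @param connectome A [structural_connectome()].
#' @param params A [hopf_params()].
#' @return A `2n x 2n` numeric drift matrix.
#' @export
build_linear_system <- function(connectome, params) {
  stopifnot(inherits(connectome, "structural_connectome"),
            inherits(params, "hopf_params"))
  M <- normalize_coupling(connectome$weights)
  check_symmetric(M, "connectome")
  n <- nrow(M)
  a <- rep_len(params$a, n)
  w <- 2 * pi * rep_len(params$f, n)
  s <- rowSums(M)
  J <- params$G * M
  diag(J) <- a - params$G * s
  A <- matrix(0, 2 * n, 2 * n)
  A[1:n, 1:n] <- J
  A[(n + 1):(2 * n), (n + 1):(2 * n)] <- J
  A[1:n, (n + 1):(2 * n)] <- -diag(w, n)
  A[(n + 1):(2 * n), 1:n] <- diag(w, n)
  A
}

#' Stability margin of a drift matrix
#'
#' Largest real part over the eigenvalues. The linearized (Lyapunov)
#' connectivity prediction is admissible only when this is negative. Note
#' that with diffusive coupling the uniform mode of the network is never
#' damped by coupling, so the margin is bounded below by `max(a)`: the
#' linear route requires `a < 0` (noise-driven regime).
#'
#' @param drift Square numeric matrix.
#' @return Scalar: max real part of the eigenvalues.
#' @export
stability_margin <- function(drift) {
  stopifnot(is_square_matrix(drift))
  max(Re(eigen(drift, only.values = TRUE)$values))
}

# Solve A S + S A^T + Q = 0 by complex eigendecomposition of A.
solve_lyapunov <- function(A, Q) {
  e <- eigen(A)
  V <- e$vectors
  lam <- e$values
  Vi <- solve(V)
  B <- Vi %*% Q %*% t(Vi)
  denom <- outer(lam, lam, `+`)
  if (any(Mod(denom) < 1e-12)) {
    stop("Lyapunov equation is singular (eigenvalue pair summing to zero)")
  }
  X <- -B / denom
  S <- V %*% X %*% t(V)
  S <- Re(S)
  (S + t(S)) / 2
}

#' Analytic stationary functional connectivity of the linearized Hopf model
#'
#' Solves the continuous Lyapunov equation
#' `drift %*% Sigma + Sigma %*% t(drift) + beta^2 I = 0` for the stationary
#' covariance of the linearized stochastic system and returns the Pearson
#' correlation among the `n` x-components.
#'
#' @param connectome A [structural_connectome()].
#' @param params A [hopf_params()]; the drift must be stable (`a < 0`).
#' @return A correlation-kind [fc_matrix()].
#' @export
linear_fc <- function(connectome, params) {
  A <- build_linear_system(connectome, params)
  margin <- stability_margin(A)
  if (margin >= 0) {
    stop(sprintf(
      "linear approximation invalid: drift is not stable (margin = %.4g >= 0)",
      margin), call. = FALSE)
  }
  n <- nrow(A) / 2
  Q <- diag(params$beta^2, 2 * n)
  S <- solve_lyapunov(A, Q)
  Sx <- S[1:n, 1:n]
  fc <- stats::cov2cor(Sx)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc_matrix(fc, "correlation", connectome$region_labels)
}

# Deterministic drift of the cubic-saturated Stuart-Landau network.
# GM = G * M (normalized weights), Gs = G * rowSums(M).
hopf_drift <- function(x, y, a, w, GM, Gs) {
  r2 <- x * x + y * y
  list(
    dx = (a - r2) * x - w * y + as.vector(GM %*% x) - Gs * x,
    dy = (a - r2) * y + w * x + as.vector(GM %*% y) - Gs * y
  )
}

#' Stochastic simulation of the coupled Hopf model
#'
#' Euler-Maruyama integration of the cubic-saturated Stuart-Landau network:
#' `dx_i = [(a_i - x_i^2 - y_i^2) x_i - w_i y_i + G sum_j M_ij (x_j - x_i)] dt
#' + beta dW`, and symmetrically for `y_i` with rotation `+w_i x_i`. Returns
#' the x-components after discarding the transient.
#'
#' @param connectome A [structural_connectome()].
#' @param params A [hopf_params()].
#' @return A [regional_ts()] with sampling rate `1/dt`.
#' @export
simulate_hopf <- function(connectome, params) {
  stopifnot(inherits(connectome, "structural_connectome"),
            inherits(params, "hopf_params"))
  if (params$dt > 1 / (20 * max(params$f))) {
    stop("dt too coarse for the requested frequencies (need dt <= 1/(20 f))")
  }
  M <- normalize_coupling(connectome$weights)
  n <- nrow(M)
  a <- rep_len(params$a, n)
  w <- 2 * pi * rep_len(params$f, n)
  s <- rowSums(M)
  G <- params$G
  dt <- params$dt
  n_trans <- ceiling(params$transient / dt)
  n_keep <- floor(params$duration / dt)
  n_steps <- n_trans + n_keep
  sqdt <- sqrt(dt)
  out <- matrix(0, n, n_keep)
  with_local_seed(params$seed, {
    x <- stats::rnorm(n, 0, params$init_sd)
    y <- stats::rnorm(n, 0, params$init_sd)
    GM <- G * M
    for (k in seq_len(n_steps)) {
      d <- hopf_drift(x, y, a, w, GM, G * s)
      x <- x + dt * d$dx + params$beta * sqdt * stats::rnorm(n)
      y <- y + dt * d$dy + params$beta * sqdt * stats::rnorm(n)
      if (max(abs(x)) > 1e3) {
        stop("simulation diverged; use a smaller dt", call. = FALSE)
      }
      if (k > n_trans) out[, k - n_trans] <- x
    }
  })
  regional_ts(out, 1 / dt, connectome$region_labels)
}

# Box (uniform) filter with scipy-style 'reflect' padding, used by ssim().
box_filter_reflect <- function(X, win) {
  p <- (win - 1) %/% 2
  n <- nrow(X); m <- ncol(X)
  ri <- c(p:1, 1:n, n:(n - p + 1))
  ci <- c(p:1, 1:m, m:(m - p + 1))
  E <- X[ri, ci, drop = FALSE]
  # separable running sums along rows then columns
  box1 <- function(v) {
    c0 <- c(0, cumsum(v))
    c0[(win + 1):length(c0)] - c0[1:(length(c0) - win)]
  }
  A <- apply(E, 2, box1)            # (n + 2p - win + 1) x (m + 2p) = n x (m + 2p)
  B <- t(apply(A, 1, box1))         # n x m
  B / (win * win)
}

#' Structural similarity index between two connectivity matrices
#'
#' Windowed SSIM (uniform 7x7 window, stabilization constants K1 = 0.01,
#' K2 = 0.03, sample covariances) on the two matrices treated as images over
#' their joint data range, averaged over windows. Equals 1 iff the inputs
#' are identical.
#'
#' @param m1,m2 [fc_matrix()] objects or plain numeric matrices of equal
#'   shape.
#' @param win Window side length (odd, default 7).
#' @param K1,K2 Stabilization constants (defaults 0.01 and 0.03).
#' @return Scalar SSIM in `(-1, 1]`.
#' @export
ssim <- function(m1, m2, win = 7, K1 = 0.01, K2 = 0.03) {
  X <- if (inherits(m1, "fc_matrix")) m1$values else m1
  Y <- if (inherits(m2, "fc_matrix")) m2$values else m2
  stopifnot(is.matrix(X), is.matrix(Y))
  if (!all(dim(X) == dim(Y))) stop("ssim: shape mismatch")
  if (win %% 2 != 1 || win < 3) stop("window side must be odd and >= 3")
  if (min(dim(X)) < win) stop("matrix smaller than the SSIM window")
  R <- max(X, Y) - min(X, Y)
  if (R == 0) {
    # both matrices constant and equal: identical inputs
    return(1)
  }
  C1 <- (K1 * R)^2
  C2 <- (K2 * R)^2
  NP <- win * win
  cov_norm <- NP / (NP - 1)
  ux <- box_filter_reflect(X, win)
  uy <- box_filter_reflect(Y, win)
  uxx <- box_filter_reflect(X * X, win)
  uyy <- box_filter_reflect(Y * Y, win)
  uxy <- box_filter_reflect(X * Y, win)
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  vxy <- cov_norm * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux * ux + uy * uy + C1) * (vx + vy + C2))
  p <- (win - 1) %/% 2
  n <- nrow(S); m <- ncol(S)
  mean(S[(p + 1):(n - p), (p + 1):(m - p)])
}

#' Fit the global coupling by an SSIM grid sweep
#'
#' For every stable value on the coupling grid, predicts functional
#' connectivity with [linear_fc()] and scores it against the empirical
#' matrix with [ssim()]; the fitted coupling maximizes SSIM (ties broken
#' toward the smallest value). Grid values whose linearization is unstable
#' are recorded with `NA` SSIM.
#'
#' @param empirical_fc Correlation-kind [fc_matrix()].
#' @param connectome A [structural_connectome()].
#' @param params A [hopf_params()]; its `G` is ignored in favor of the grid.
#' @param g_grid Coupling grid; default `seq(0, 3, by = 0.1)`.
#' @return A list of class `hopf_fit` with elements `g_grid`, `ssim_curve`,
#'   `stable_mask`, `g_best`.
#' @export
fit_global_coupling <- function(empirical_fc, connectome, params,
                                g_grid = seq(0, 3, by = 0.1)) {
  stopifnot(inherits(empirical_fc, "fc_matrix"),
            empirical_fc$kind == "correlation",
            length(g_grid) >= 1)
  ssim_curve <- rep(NA_real_, length(g_grid))
  stable_mask <- logical(length(g_grid))
  for (i in seq_along(g_grid)) {
    p_i <- params
    p_i$G <- g_grid[i]
    A <- build_linear_system(connectome, p_i)
    if (stability_margin(A) < 0) {
      stable_mask[i] <- TRUE
      ssim_curve[i] <- ssim(linear_fc(connectome, p_i), empirical_fc)
    }
  }
  if (!any(stable_mask)) {
    stop("no stable coupling value on the grid (is a < 0?)", call. = FALSE)
  }
  best <- which(stable_mask)[which.max(ssim_curve[stable_mask])]
  structure(
    list(g_grid = g_grid, ssim_curve = ssim_curve,
         stable_mask = stable_mask, g_best = g_grid[best]),
    class = "hopf_fit"
  )
}
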