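two_node_connectome <- function(w12 = 1) {
  structural_connectome(matrix(c(0, w12, w12, 0), 2),
                        matrix(seq_len(6), 2, 3) * 1.0, c(TRUE, FALSE))
}

single_node_connectome <- function() {
  structural_connectome(matrix(0, 1, 1), matrix(c(1, 2, 3), 1, 3), TRUE)
}

test_that("the linear drift matches the normal form and the simulator Jacobian", {
  A1 <- build_linear_system(single_node_connectome(),
                            hopf_params(a = 0.01, f = 10, G = 0))
  w <- 2 * pi * 10
  expect_equal(A1, matrix(c(0.01, w, -w, 0.01), 2))
  ev <- eigen(A1, only.values = TRUE)$values
  expect_equal(sort(Re(ev)), c(0.01, 0.01))
  expect_equal(sort(abs(Im(ev))), c(w, w))
  # finite-difference Jacobian of the simulator drift at the origin
  sc <- generate_structural_connectome(5, 0.4, 0.8, seed = 2)
  p <- hopf_params(a = 0.01, f = 10, G = 0.7)
  A <- build_linear_system(sc, p)
  M <- brainclocks:::normalize_coupling(sc$weights)
  drift_vec <- function(z) {
    d <- brainclocks:::hopf_drift(z[1:5], z[6:10], rep(0.01, 5),
                                  rep(2 * pi * 10, 5), 0.7 * M,
                                  0.7 * rowSums(M))
    c(d$dx, d$dy)
  }
  J <- matrix(0, 10, 10)
  h <- 1e-7
  for (j in 1:10) {
    e <- numeric(10)
    e[j] <- h
    J[, j] <- (drift_vec(e) - drift_vec(-e)) / (2 * h)
  }
  expect_lt(max(abs(A - J)), 1e-6)
})

test_that("stability margin exposes the undamped uniform mode", {
  expect_equal(stability_margin(build_linear_system(
    single_node_connectome(), hopf_params(a = 0.01, f = 10, G = 0))), 0.01)
  expect_equal(stability_margin(build_linear_system(
    single_node_connectome(), hopf_params(a = -1, f = 10, G = 0))), -1)
  # two coupled nodes: modes at a and a - 2 G M12; the uniform mode keeps
  # the margin at a regardless of coupling strength
  A2 <- build_linear_system(two_node_connectome(),
                            hopf_params(a = 0.01, f = 10, G = 2))
  re <- sort(unique(round(Re(eigen(A2, only.values = TRUE)$values), 10)))
  expect_equal(re, c(0.01 - 2 * 2 * 1, 0.01))  # modes a - 2 G M12 and a
  expect_equal(stability_margin(A2), 0.01)
})

test_that("linear FC solves the Lyapunov equation and matches the closed form", {
  con <- two_node_connectome()
  fc <- linear_fc(con, hopf_params(a = -1, f = 10, beta = 0.1, G = 0.5))
  expect_equal(fc$values[1, 2], 1 / 3, tolerance = 1e-10)
  # no coupling, stable node: uncorrelated noise
  fc0 <- linear_fc(con, hopf_params(a = -1, f = 10, beta = 0.1, G = 0))
  expect_equal(fc0$values[1, 2], 0, tolerance = 1e-10)
  expect_error(linear_fc(con, hopf_params(a = 0.01, G = 1)),
               "linear approximation invalid")
  # Lyapunov residual on random stable systems
  for (s in 1:5) {
    sc <- generate_structural_connectome(12, 0.3, 0.4, seed = s)
    p <- hopf_params(a = -0.1, f = 10, beta = 0.1, G = runif(1, 0, 2))
    A <- build_linear_system(sc, p)
    S <- brainclocks:::solve_lyapunov(A, diag(p$beta^2, 24))
    expect_lt(max(abs(A %*% S + S %*% t(A) + diag(p$beta^2, 24))), 1e-8)
  }
})

test_that("the simulator oscillates at f, sits at the origin without noise, and diverges loudly", {
  p <- hopf_params(a = 0.01, f = 10, beta = 0.1, G = 0, dt = 1 / 512,
                   duration = 30, transient = 2, seed = 3)
  ts <- simulate_hopf(single_node_connectome(), p)
  sp <- spec.pgram(ts$data[1, ], spans = 9, plot = FALSE)
  peak <- sp$freq[which.max(sp$spec)] * 512
  expect_equal(peak, 10, tolerance = 0.5)
  still <- simulate_hopf(single_node_connectome(),
                         hopf_params(a = -0.5, f = 1, beta = 0, G = 0,
                                     dt = 1 / 64, duration = 2,
                                     transient = 0, init_sd = 0))
  expect_equal(max(abs(still$data)), 0)
  expect_error(
    simulate_hopf(two_node_connectome(),
                  hopf_params(a = 0.01, f = 10, G = 1e6, dt = 1 / 512,
                              duration = 2, transient = 0, seed = 1)),
    "smaller dt")
  expect_error(
    simulate_hopf(single_node_connectome(),
                  hopf_params(f = 10, dt = 0.01, duration = 2)),
    "dt too coarse")
  # determinism
  a <- simulate_hopf(single_node_connectome(),
                     hopf_params(duration = 2, transient = 0, seed = 5))
  b <- simulate_hopf(single_node_connectome(),
                     hopf_params(duration = 2, transient = 0, seed = 5))
  expect_identical(a$data, b$data)
})

test_that("linear prediction agrees with long stochastic simulation", {
  sc <- tiny_connectome()
  p_base <- hopf_params(a = -0.2, f = 1, beta = 0.1, G = 1, dt = 1 / 512,
                        transient = 10)
  fc_lin <- linear_fc(sc, p_base)
  sims <- lapply(1:3, function(s) {
    p <- p_base
    p$duration <- 700
    p$seed <- s
    compute_fc(simulate_hopf(sc, p))$values
  })
  fc_sim <- Reduce(`+`, sims) / 3
  ut <- upper.tri(fc_sim)
  expect_gt(cor(fc_lin$values[ut], fc_sim[ut]), 0.95)
})

test_that("SSIM is 1 on identical input and matches the reference value", {
  fc <- training_cohort()$matrices[[1]]
  expect_equal(ssim(fc, fc), 1)
  const <- matrix(0.4, 9, 9)
  expect_equal(ssim(const, const), 1)
  # frozen reference computed with scikit-image structural_similarity
  # (win_size 7, joint data range) on this seeded 8x8 pair
  set.seed(42)
  X <- matrix(round(runif(64), 6), 8, 8)
  Y <- matrix(round(runif(64), 6), 8, 8)
  expect_equal(ssim(X, Y), -0.0569522409, tolerance = 1e-9)
  expect_equal(ssim(Y, X), ssim(X, Y))
  set.seed(43)
  for (k in 1:20) {
    A <- matrix(rnorm(100), 10)
    B <- matrix(rnorm(100), 10)
    expect_lte(ssim(A, B), 1)
    expect_equal(ssim(A, B), ssim(B, A))
  }
  expect_error(ssim(X, Y[1:7, 1:7]), "shape mismatch")
})

test_that("coupling sweep recovers the generating G", {
  sc <- tiny_connectome()
  base <- hopf_params(a = -0.05, f = 10, beta = 0.1)
  gen <- base
  gen$G <- 1.5
  fit <- fit_global_coupling(linear_fc(sc, gen), sc, base)
  expect_equal(fit$g_best, 1.5)
  expect_true(all(fit$stable_mask))
  expect_true(all(fit$ssim_curve <= 1))
  one <- fit_global_coupling(linear_fc(sc, gen), sc, base, g_grid = 0.7)
  expect_equal(one$g_best, 0.7)
  # ties resolve to the smallest coupling
  tie <- fit_global_coupling(linear_fc(sc, gen), sc, base,
                             g_grid = c(1.5, 1.5))
  expect_equal(tie$g_best, 1.5)
  # unstable regime is refused, not silently fitted
  expect_error(fit_global_coupling(linear_fc(sc, gen), sc,
                                   hopf_params(a = 0.01)),
               "no stable")
})

test_that("G recovery tolerates observation noise within one grid step", {
  sc <- tiny_connectome()
  base <- hopf_params(a = -0.05, f = 10, beta = 0.1)
  set.seed(14)
  for (g_true in c(0.5, 1.0, 2.0)) {
    errs <- vapply(1:20, function(k) {
      gen <- base
      gen$G <- g_true
      v <- linear_fc(sc, gen)$values
      ut <- upper.tri(v)
      z <- atanh(pmin(pmax(v[ut], -1 + 1e-12), 1 - 1e-12)) +
        rnorm(sum(ut), 0, 0.03)
      v[ut] <- tanh(z)
      v[lower.tri(v)] <- t(v)[lower.tri(v)]
      noisy <- fc_matrix(v, "correlation")
      abs(fit_global_coupling(noisy, sc, base)$g_best - g_true)
    }, numeric(1))
    expect_true(all(errs <= 0.1 + 1e-12))
  }
})

test_that("cohorts generated at higher coupling fit higher g_best", {
  sc <- tiny_connectome()
  fit_mean_g <- function(g0, seed) {
    coh <- generate_cohort(
      cohort_spec(n_per_group = 5, g0 = g0, g_age = 0.1, g_exp = 0,
                  a = -0.05), sc, seed = seed)
    mean(vapply(coh$matrices, function(m) {
      fit_global_coupling(m, sc, hopf_params(a = -0.05))$g_best
    }, numeric(1)))
  }
  expect_gt(fit_mean_g(1.2, 3), fit_mean_g(0.6, 3))
})
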