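# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 20-region connectome used by most cohort-level tests
small_connectome <- function() {
  fixture("con20", function() generate_structural_connectome(20, 0.25, 0.3,
                                                             seed = 5))
}

tiny_connectome <- function() {
  fixture("con16", function() generate_structural_connectome(16, 0.25, 0.4,
                                                             seed = 9))
}

# training-style cohort: age structure, no expertise effect
training_cohort <- function() {
  fixture("cohort_train", function() {
    generate_cohort(cohort_spec(n_per_group = 60, g_exp = 0),
                    small_connectome(), seed = 11)
  })
}

# expertise cohort: narrow age range, positive expertise effect
expertise_cohort <- function() {
  fixture("cohort_exp", function() {
    generate_cohort(cohort_spec(n_per_group = 30, age_range = c(20, 45),
                                domain = "gaming", g_exp = 0.08),
                    small_connectome(), seed = 21)
  })
}

trained_clock <- function() {
  fixture("clock", function() {
    coh <- training_cohort()
    X <- do.call(rbind, lapply(coh$matrices, vectorize_fc))
    train_brain_clock(X, coh$subjects$age, n_folds = 5, n_reps = 2,
                      grid = list(cost = 1, epsilon = 0.1), seed = 3)
  })
}

feature_matrix <- function(cohort) {
  do.call(rbind, lapply(cohort$matrices, vectorize_fc))
}

mean_hub_strength <- function(cohort, connectome) {
  vapply(cohort$matrices, function(m) {
    mean(nodal_strength(m)$values[connectome$hub_mask])
  }, numeric(1))
}

complete_graph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

# ---- independent graph oracles (algebraic walk counting, no igraph) ----

bf_shortest_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  P <- diag(n)
  for (k in seq_len(n - 1)) {
    P <- P %*% A
    newly <- P > 0 & is.infinite(d)
    d[newly] <- k
  }
  d
}

bf_global_eff <- function(A) {
  n <- nrow(A)
  d <- bf_shortest_paths(A)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

bf_local_eff <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    sub <- A[nb, nb, drop = FALSE]
    d <- bf_shortest_paths(sub)
    tot <- 0
    for (j in seq_len(k)) {
      for (h in seq_len(k)) {
        if (j != h && is.finite(d[j, h])) tot <- tot + 1 / d[j, h]
      }
    }
    vals[i] <- tot / (k * (k - 1))
  }
  mean(vals)
}

adjacency_from_mask <- function(n, mask_bits) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- mask_bits
  a + t(a)
}

# quantile-binned empirical variogram over pairs within a distance cap
variogram_bins <- function(values, D, n_bins = 8, cap_q = 0.7) {
  ut <- upper.tri(D)
  dcap <- quantile(D[ut], cap_q)
  sel <- which(ut & D <= dcap)
  qs <- unique(quantile(D[sel], seq(0, 1, length.out = n_bins + 1)))
  qs[1] <- 0
  qs[length(qs)] <- qs[length(qs)] * 1.0001
  b <- findInterval(D[sel], qs, all.inside = TRUE)
  half_sq <- 0.5 * (outer(values, values, `-`)[sel])^2
  tapply(half_sq, factor(b, levels = seq_len(length(qs) - 1)), mean)
}
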