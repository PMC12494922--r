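# smooth map with a realistic measurement nugget over homogeneous coordinates
noisy_smooth_map <- function(n = 78, smoothness = 25, nugget = 0.2,
                             seed = 10) {
  set.seed(seed)
  coords <- matrix(runif(n * 3, 0, 100), n, 3)
  D <- as.matrix(dist(coords))
  K <- exp(-D^2 / (2 * smoothness^2))
  K <- K / rowSums(K)
  sm <- as.vector(K %*% rnorm(n))
  sm <- (sm - mean(sm)) / sd(sm)
  list(map = sqrt(1 - nugget) * sm + sqrt(nugget) * rnorm(n),
       coords = coords, D = D)
}

test_that("the age-vulnerability map is the strength-age correlation", {
  coh <- training_cohort()
  ages <- coh$subjects$age
  # exact case: strength = -age + c in every region
  fake <- lapply(ages, function(a) regional_map(rep(100 - a, 20)))
  vm <- age_vulnerability_map(coh, fake)
  expect_equal(vm$values, rep(-1, 20))
  # null case: strengths independent of age
  set.seed(5)
  null_str <- lapply(ages, function(a) regional_map(rnorm(20)))
  vn <- age_vulnerability_map(coh, null_str)
  expect_lt(max(abs(vn$values)), 0.4)
  expect_lt(mean(abs(vn$values)), 0.15)
  # generated cohort: hubs decline faster than non-hubs
  sc <- small_connectome()
  vg <- age_vulnerability_map(coh)
  expect_lt(mean(vg$values[sc$hub_mask]), mean(vg$values[!sc$hub_mask]))
  expect_lt(mean(vg$values[sc$hub_mask]), 0)
})

test_that("effect-size maps are pooled-sd Cohen's D with antisymmetry", {
  set.seed(6)
  ga <- lapply(1:10, function(i) regional_map(rnorm(5)))
  expect_equal(effect_size_map(ga, ga)$values, rep(0, 5))
  gb <- lapply(1:10, function(i) regional_map(rnorm(5)))
  ab <- effect_size_map(ga, gb)
  ba <- effect_size_map(gb, ga)
  expect_equal(ab$values, -ba$values)
  # hand case: means 1 vs 0, unit pooled sd
  mk <- function(mu) lapply(seq(-1.5, 1.5, 1), function(d)
    regional_map(mu + d / sd(seq(-1.5, 1.5, 1))))
  d1 <- effect_size_map(mk(1), mk(0))
  expect_equal(d1$values, rep(1, 1), tolerance = 1e-10)
})

test_that("surrogates preserve the value multiset and the variogram", {
  fx <- noisy_smooth_map()
  ens <- generate_surrogates(fx$map, fx$coords, n = 250, seed = 3)
  expect_equal(nrow(ens$surrogates), 250)
  srt <- sort(fx$map)
  for (k in c(1, 50, 250)) {
    expect_equal(sort(ens$surrogates[k, ]), srt)
  }
  again <- generate_surrogates(fx$map, fx$coords, n = 5, seed = 3)
  expect_identical(ens$surrogates[1:5, ], again$surrogates)
  # mean surrogate variogram tracks the source variogram bin by bin
  v_src <- variogram_bins(fx$map, fx$D)
  v_sur <- rowMeans(vapply(seq_len(250), function(i) {
    as.numeric(variogram_bins(ens$surrogates[i, ], fx$D))
  }, numeric(length(v_src))))
  expect_true(all(abs(v_sur - v_src) / v_src < 0.25))
  expect_error(generate_surrogates(rep(1, 78), fx$coords, n = 10),
               "constant")
  expect_error(generate_surrogates(fx$map, fx$coords * 0, n = 10),
               "degenerate")
})

test_that("identity and sign-flip correlations get the smallest possible p", {
  fx <- noisy_smooth_map(seed = 11)
  self <- spatial_correlation_test(fx$map, fx$map, fx$coords,
                                   n_surrogates = 150, seed = 2)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 151)
  flip <- spatial_correlation_test(fx$map, -fx$map, fx$coords,
                                   n_surrogates = 150, seed = 2)
  expect_equal(flip$r, -1)
  expect_equal(flip$p, 1 / 151)
  expect_error(spatial_correlation_test(fx$map, rep(1, 78), fx$coords,
                                        n_surrogates = 150), "constant")
})

test_that("the surrogate test is calibrated under spatially smooth nulls", {
  sc <- generate_structural_connectome(78, 0.2, 0.3, seed = 1)
  set.seed(99)
  rej <- vapply(1:300, function(k) {
    s <- sample.int(1e6, 1)
    maps <- generate_term_maps(2, sc, smoothness = 12, seed = s)
    spatial_correlation_test(maps[[1]], maps[[2]], sc$coordinates,
                             n_surrogates = 200, seed = s + 1)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("the surrogate test detects a genuine r = 0.5 coupling", {
  sc <- generate_structural_connectome(78, 0.2, 0.3, seed = 1)
  set.seed(7)
  rej <- vapply(1:150, function(k) {
    s <- sample.int(1e6, 1)
    maps <- generate_term_maps(2, sc, smoothness = 12, seed = s)
    m2 <- 0.5 * maps[[1]]$values + sqrt(0.75) * maps[[2]]$values
    spatial_correlation_test(maps[[1]]$values, m2, sc$coordinates,
                             n_surrogates = 200, seed = s + 1)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("term profiles report |r|, surrogate p, and monotone BH q", {
  sc <- small_connectome()
  coh <- training_cohort()
  eff <- age_vulnerability_map(coh)
  terms <- generate_term_maps(12, sc, smoothness = 20, seed = 40)
  tab <- term_association_profile(eff, terms, sc$coordinates,
                                  n_surrogates = 200, seed = 4)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$abs_r >= 0 & tab$abs_r <= 1))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  ord <- order(tab$p)
  expect_true(all(diff(tab$q[ord]) >= -1e-12))
  # a term equal to the effect map itself is a perfect association
  tab2 <- term_association_profile(
    eff, c(list(regional_map(eff$values, "self")), terms[1:3]),
    sc$coordinates, n_surrogates = 150, seed = 5)
  expect_equal(tab2$abs_r[tab2$term == "self"], 1)
})

test_that("each expertise domain shows the same vulnerability-effect coupling", {
  sc <- small_connectome()
  vuln <- age_vulnerability_map(training_cohort())
  for (dom in c("dance", "music", "visual", "gaming")) {
    coh <- generate_cohort(
      cohort_spec(n_per_group = 14, age_range = c(20, 45), domain = dom,
                  g_exp = 0.1), sc,
      seed = 100 + match(dom, c("dance", "music", "visual", "gaming")))
    str <- lapply(coh$matrices, nodal_strength)
    ex <- coh$subjects$group == "expert"
    eff <- effect_size_map(str[ex], str[!ex])
    # experts gain most where aging bites most: expert-minus-control
    # effects are anticorrelated with the strength-age correlation map
    expect_lt(cor(eff$values, vuln$values), 0)
  }
})
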