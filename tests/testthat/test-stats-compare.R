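test_that("group comparisons produce the right statistics and effect sizes", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_groups(x, x, "independent_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  expect_equal(same$p, 1)
  # exact D = 1: means 1 vs 0, pooled sd 1, n = 30 per group
  set.seed(1)
  base <- as.numeric(scale(rnorm(30)))
  res <- compare_groups(base + 1, base, "independent_t")
  expect_equal(res$effect_size, 1)
  expect_equal(res$statistic, 1 * sqrt(30 / 2), tolerance = 1e-10)
  expect_equal(res$df, 58)
  expect_true(res$ci_low <= 1 && 1 <= res$ci_high)
  # degenerate paired design is refused
  expect_error(compare_groups(x + 1, x, "paired_t"), "zero variance")
  ok_paired <- compare_groups(x + c(1, 2, 1, 2, 1), x, "paired_t")
  d <- c(1, 2, 1, 2, 1)
  expect_equal(ok_paired$effect_size, mean(d) / sd(d))
  expect_equal(ok_paired$df, 4)
})

test_that("Mann-Whitney requires an explicit direction; chi-square handles counts", {
  set.seed(2)
  a <- rnorm(10, 1)
  b <- rnorm(10)
  expect_error(compare_groups(a, b, "mannwhitney_one_sided"),
               "direction must be supplied")
  mw <- compare_groups(a, b, "mannwhitney_one_sided",
                       alternative = "greater")
  expect_lt(mw$p, 0.5)
  expect_equal(mw$statistic,
               unname(wilcox.test(a, b, alternative = "greater")$statistic))
  tab <- matrix(c(18, 5, 14, 9), 2)
  cs <- compare_groups(tab, NULL, "chi_square")
  expect_equal(cs$statistic, unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(cs$df, 1)
})

test_that("f-squared reproduces the printed correlation effect sizes", {
  expect_equal(effect_size_f2(0), 0)
  expect_equal(round(effect_size_f2(-0.306), 3), 0.103)
  # the published r is itself rounded to 3 decimals, which moves the third
  # decimal of f-squared by up to ~0.001
  expect_lt(abs(effect_size_f2(-0.508) - 0.349), 1.5e-3)
  expect_error(effect_size_f2(1), "below 1")
})

test_that("BH control follows the step-up rule and stays conservative", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(out$reject))
  expect_equal(fdr_bh(rep(1, 6))$reject, rep(FALSE, 6))
  single <- fdr_bh(0.04)
  expect_true(single$reject)
  expect_equal(single$qvals, 0.04)
  set.seed(3)
  p <- runif(40)
  q <- fdr_bh(p)$qvals
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # realized FDR under a mixed signal/null panel stays at or below alpha
  set.seed(4)
  fdp <- replicate(1000, {
    p_null <- runif(15)
    p_sig <- rbeta(5, 0.1, 10)
    rej <- fdr_bh(c(p_null, p_sig), alpha = 0.05)$reject
    if (!any(rej)) 0 else sum(rej[1:15]) / sum(rej)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(1000))
})

test_that("ANCOVA isolates the group effect", {
  set.seed(5)
  n <- 60
  group <- rep(c(0, 1), each = n / 2)
  covs <- data.frame(age = rnorm(n, 40, 10),
                     sex = factor(sample(c("F", "M"), n, TRUE)),
                     education = rnorm(n, 14, 3))
  # exact recovery with zero noise (summary warns about the perfect fit)
  y <- 2 * group + 0.1 * covs$age
  fit <- suppressWarnings(ancova_group_effect(y, group, covs))
  expect_equal(fit$group_coefficient, 2, tolerance = 1e-10)
  expect_lt(fit$p, 1e-10)
  # orthogonal covariates: group p matches the plain t-test
  y2 <- rnorm(n) + 0.8 * group
  covs_orth <- data.frame(age = rep(rnorm(n / 2, 40, 10), 2))
  t_ref <- compare_groups(y2[group == 1], y2[group == 0],
                          "independent_t")
  a_ref <- ancova_group_effect(y2, group, covs_orth["age"])
  expect_equal(a_ref$p, t_ref$p, tolerance = 0.05)
  expect_error(ancova_group_effect(y, rep(1, n), covs), "two levels")
  expect_error(ancova_group_effect(y, group,
                                   data.frame(age = group * 3)),
               "singular")
})

test_that("percentile splits use strict interpolated cutoffs", {
  lab <- percentile_split(1:100)
  expect_equal(sum(lab == "younger"), 35)
  expect_equal(sum(lab == "older"), 35)
  expect_equal(sum(lab == "excluded"), 30)
  all_out <- percentile_split(1:50, lo = 0, hi = 100)
  expect_true(all(all_out == "excluded"))
  set.seed(6)
  v <- rnorm(40)
  expect_equal(percentile_split(v), percentile_split(v + 100))
  expect_error(percentile_split(rep(2, 10)), "distinct")
})

test_that("pooled expertise association z-scores within domain", {
  set.seed(7)
  bags <- list(dance = rnorm(20), music = rnorm(25))
  scores <- lapply(bags, function(b) -b * 3 + 50)  # perfect inverse, own scale
  out <- expertise_bag_association(bags, scores)
  expect_equal(out$r, -1, tolerance = 1e-12)
  expect_equal(out$n, 45)
  # constant-score domain is dropped with a warning, not an error
  scores$music <- rep(4, 25)
  expect_warning(out2 <- expertise_bag_association(bags, scores),
                 "constant")
  expect_equal(out2$n, 20)
})

test_that("experts' gaps track expertise negatively in the synthetic study", {
  clock <- trained_clock()
  coh <- expertise_cohort()
  bags <- compute_bags(predict_age(clock, feature_matrix(coh)),
                       coh$subjects$age, clock,
                       domains = coh$subjects$domain)
  out <- expertise_bag_association(list(gaming = bags$centered_bag),
                                   list(gaming = coh$subjects$expertise_score))
  expect_lt(out$r, 0)
  expect_gt(out$f2, 0)
  # percentile split: the BAG-younger tail is the more expert one
  lab <- percentile_split(bags$centered_bag)
  sc_young <- coh$subjects$expertise_score[lab == "younger"]
  sc_old <- coh$subjects$expertise_score[lab == "older"]
  mw <- compare_groups(sc_young, sc_old, "mannwhitney_one_sided",
                       alternative = "greater")
  expect_lt(mw$p, 0.05)
})

test_that("the independent t-test holds its nominal size on null draws", {
  set.seed(8)
  rej <- replicate(1000, {
    compare_groups(rnorm(30), rnorm(30), "independent_t")$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("null cohorts do not produce spurious group effects", {
  sc <- tiny_connectome()
  set.seed(9)
  pvals <- vapply(1:200, function(k) {
    coh <- generate_cohort(
      cohort_spec(n_per_group = 8, g_age = 0, g_exp = 0), sc,
      seed = 5000 + k)
    hs <- mean_hub_strength(coh, sc)
    ex <- coh$subjects$group == "expert"
    compare_groups(hs[ex], hs[!ex], "independent_t")$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.01)
  expect_lte(mean(pvals < 0.05), 0.10)
})
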