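#!/usr/bin/env Rscript
# Group statistics and the sensitivity battery: per-domain BAG contrasts
# (t-tests, Cohen's D, FDR), the pooled expertise-BAG association on the
# z-score scale, ANCOVA with demographic covariates, the 35th/65th
# percentile BAG split with one-sided Mann-Whitney tests, and
# prediction-slope comparisons across sub-cohorts.
# Writes results/group_stats.csv and results/sensitivity.csv.

source("analysis/00_config.R")

bags <- read.csv(file.path(RESULTS_DIR, "bags.csv"))
expertise_domains <- setdiff(STUDY$domain, "learning")

# --- per-domain BAG contrasts -------------------------------------------
rows <- list()
for (dom in STUDY$domain) {
  b <- bags[bags$domain == dom, ]
  paired <- any(b$group == "post")
  hi <- b$group %in% c("expert", "post")
  res <- compare_groups(b$centered_bag[hi], b$centered_bag[!hi],
                        if (paired) "paired_t" else "independent_t")
  rows[[dom]] <- data.frame(
    domain = dom, contrast = if (paired) "post-pre" else "expert-control",
    delta_bag = mean(b$centered_bag[hi]) - mean(b$centered_bag[!hi]),
    statistic = res$statistic, df = res$df, p = res$p,
    cohens_d = res$effect_size, ci_low = res$ci_low, ci_high = res$ci_high)
}
gs <- do.call(rbind, rows)
gs$q <- fdr_bh(gs$p)$qvals
write.csv(gs, file.path(RESULTS_DIR, "group_stats.csv"), row.names = FALSE)
for (i in seq_len(nrow(gs))) {
  say("%-9s dBAG = %+.2f y, t(%d) = %+.2f, q = %.4f, D = %+.2f",
      gs$domain[i], gs$delta_bag[i], gs$df[i], gs$statistic[i], gs$q[i],
      gs$cohens_d[i])
}

# --- pooled expertise-BAG association (z-scored within domain) ----------
eb <- bags[bags$domain %in% expertise_domains, ]
assoc <- expertise_bag_association(
  split(eb$centered_bag, eb$domain),
  split(eb$expertise_score, eb$domain))
say("pooled expertise vs BAG: r = %+.3f, p = %.2g, f^2 = %.3f (N = %d)",
    assoc$r, assoc$p, assoc$f2, assoc$n)

sens <- list()
sens$pooled_association <- data.frame(
  analysis = "pooled_expertise_bag", estimate = assoc$r, p = assoc$p,
  extra = assoc$f2)

# --- sensitivity 1: ANCOVA with covariates, per domain ------------------
for (dom in expertise_domains) {
  b <- bags[bags$domain == dom, ]
  res <- ancova_group_effect(
    b$centered_bag, factor(b$group, levels = c("non_expert", "expert")),
    data.frame(age = b$chronological_age, sex = factor(b$sex),
               education = b$education_years))
  sens[[paste0("ancova_", dom)]] <- data.frame(
    analysis = paste0("ancova_", dom), estimate = res$group_coefficient,
    p = res$p, extra = res$effect_size)
  say("ANCOVA %-9s group coef = %+.2f y, p = %.4f, partial f^2 = %.3f",
      dom, res$group_coefficient, res$p, res$effect_size)
}

# --- sensitivity 2: group contrasts with and without bias correction ----
sign_match <- TRUE
for (dom in expertise_domains) {
  b <- bags[bags$domain == dom, ]
  hi <- b$group == "expert"
  with_corr <- mean(b$corrected_bag[hi]) - mean(b$corrected_bag[!hi])
  without <- mean(b$raw_bag[hi]) - mean(b$raw_bag[!hi])
  sign_match <- sign_match && sign(with_corr) == sign(without)
}
say("bias-correction sensitivity: group-difference signs consistent = %s",
    sign_match)
sens$bias_correction <- data.frame(
  analysis = "bias_correction_sign_consistency",
  estimate = as.numeric(sign_match), p = NA, extra = NA)

# --- sensitivity 4: percentile split + one-sided Mann-Whitney -----------
for (dom in expertise_domains) {
  b <- bags[bags$domain == dom, ]
  lab <- percentile_split(b$centered_bag)
  mw <- compare_groups(b$expertise_score[lab == "younger"],
                       b$expertise_score[lab == "older"],
                       "mannwhitney_one_sided", alternative = "greater")
  sens[[paste0("split_", dom)]] <- data.frame(
    analysis = paste0("percentile_split_", dom),
    estimate = median(b$expertise_score[lab == "younger"]) -
      median(b$expertise_score[lab == "older"]),
    p = mw$p, extra = mw$statistic)
  say("split %-9s BAG-younger vs BAG-older expertise: U = %.1f, p = %.4f",
      dom, mw$statistic, mw$p)
}

# --- sensitivity 5: prediction slope across sub-cohorts -----------------
tr <- bags[bags$domain == "training", ]
young <- tr$chronological_age <= median(tr$chronological_age)
s_young <- prediction_slope(tr$predicted_age[young],
                            tr$chronological_age[young])
s_old <- prediction_slope(tr$predicted_age[!young],
                          tr$chronological_age[!young])
s_all <- prediction_slope(tr$predicted_age, tr$chronological_age)
say("prediction slope: all %.2f, younger half %.2f, older half %.2f",
    s_all, s_young, s_old)
sens$slopes <- data.frame(analysis = "prediction_slopes",
                          estimate = s_all, p = NA,
                          extra = s_young - s_old)

sens_df <- do.call(rbind, sens)
split_p <- grepl("percentile_split", sens_df$analysis)
sens_df$q <- NA
sens_df$q[split_p] <- fdr_bh(sens_df$p[split_p])$qvals
write.csv(sens_df, file.path(RESULTS_DIR, "sensitivity.csv"),
          row.names = FALSE)
say("sensitivity battery written to results/sensitivity.csv")
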