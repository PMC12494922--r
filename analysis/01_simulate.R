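#!/usr/bin/env Rscript
# Simulate the study: a hub-structured structural connectome, a training
# cohort spanning adulthood (age structure only), four expertise cohorts,
# and a paired pre/post learning cohort. Writes plain-text matrices and
# metadata under results/cohorts/.

source("analysis/00_config.R")

say("building %d-region connectome (hub fraction %.2f, density %.2f)",
    N_REGIONS, HUB_FRACTION, DENSITY)
connectome <- generate_structural_connectome(N_REGIONS, HUB_FRACTION,
                                             DENSITY, seed = MASTER_SEED)
write_connectome(connectome,
                 file.path(RESULTS_DIR, "connectome_weights.tsv"),
                 file.path(RESULTS_DIR, "connectome_coords.csv"))
str_tot <- rowSums(connectome$weights)
say("  hub mean strength %.1f vs non-hub %.1f",
    mean(str_tot[connectome$hub_mask]), mean(str_tot[!connectome$hub_mask]))

say("training cohort: 120 subjects, ages 17-91, no expertise effect")
train_spec <- cohort_spec(n_per_group = 60, age_range = c(17, 91),
                          domain = "learning", g0 = G0, g_age = G_AGE,
                          g_exp = 0)
training <- generate_cohort(train_spec, connectome, seed = MASTER_SEED + 1)
write_cohort(training, file.path(COHORT_DIR, "training"))

for (i in seq_len(nrow(STUDY))) {
  arm <- STUDY[i, ]
  spec <- cohort_spec(n_per_group = arm$n_per_group,
                      age_range = c(arm$age_min, arm$age_max),
                      domain = arm$domain, paired = arm$paired,
                      g0 = G0, g_age = G_AGE, g_exp = G_EXP)
  coh <- generate_cohort(spec, connectome, seed = MASTER_SEED + 10 + i)
  write_cohort(coh, file.path(COHORT_DIR, arm$domain))
  say("%-9s %3d subjects (%s), ages %d-%d", arm$domain,
      2 * arm$n_per_group, if (arm$paired) "pre/post" else "expert/control",
      arm$age_min, arm$age_max)
}
say("cohorts written to %s", COHORT_DIR)
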