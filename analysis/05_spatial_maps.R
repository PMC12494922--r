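#!/usr/bin/env Rscript
# Brain maps: the age-vulnerability map (strength-age correlation on the
# training cohort), expert-vs-control effect-size maps, their spatially-
# aware correlation (variogram-matched surrogates), and association
# profiles against synthetic cognitive term maps with FDR control.
# Writes results/maps/*.csv and results/term_associations.csv.

source("analysis/00_config.R")

maps_dir <- file.path(RESULTS_DIR, "maps")
dir.create(maps_dir, showWarnings = FALSE)

connectome <- read_connectome(
  file.path(RESULTS_DIR, "connectome_weights.tsv"),
  file.path(RESULTS_DIR, "connectome_coords.csv"))
training <- read_cohort(file.path(COHORT_DIR, "training"))

vuln <- age_vulnerability_map(training)
write_regional_map(vuln, file.path(maps_dir, "age_vulnerability.csv"))
hub <- connectome$hub_mask
say("age-vulnerability map: hub mean r = %+.3f, non-hub %+.3f",
    mean(vuln$values[hub]), mean(vuln$values[!hub]))

# pooled expert-vs-control effect map across the four expertise domains
expert_strengths <- list()
control_strengths <- list()
for (dom in setdiff(STUDY$domain, "learning")) {
  coh <- read_cohort(file.path(COHORT_DIR, dom))
  s <- lapply(coh$matrices, nodal_strength)
  ex <- coh$subjects$group == "expert"
  expert_strengths <- c(expert_strengths, s[ex])
  control_strengths <- c(control_strengths, s[!ex])
}
eff <- effect_size_map(expert_strengths, control_strengths)
write_regional_map(eff, file.path(maps_dir, "expertise_effect.csv"))

res <- spatial_correlation_test(vuln, eff, connectome$coordinates,
                                n_surrogates = 1000,
                                seed = MASTER_SEED + 200)
say("vulnerability vs expertise effect: r = %+.3f, surrogate p = %.4f",
    res$r, res$p)

# per-domain replication of the spatial coupling
for (dom in setdiff(STUDY$domain, "learning")) {
  coh <- read_cohort(file.path(COHORT_DIR, dom))
  s <- lapply(coh$matrices, nodal_strength)
  ex <- coh$subjects$group == "expert"
  eff_d <- effect_size_map(s[ex], s[!ex])
  say("  %-9s r(effect, vulnerability) = %+.3f", dom,
      cor(eff_d$values, vuln$values))
}

# synthetic stand-ins for the 89 meta-analytic term maps
terms <- generate_term_maps(89, connectome, smoothness = 20,
                            seed = MASTER_SEED + 300)
tab <- term_association_profile(eff, terms, connectome$coordinates,
                                n_surrogates = 1000,
                                seed = MASTER_SEED + 301)
write.csv(tab, file.path(RESULTS_DIR, "term_associations.csv"),
          row.names = FALSE)
say("term associations: %d/%d raw p < 0.05, %d after FDR",
    sum(tab$p < 0.05), nrow(tab), sum(tab$q <= 0.05))
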