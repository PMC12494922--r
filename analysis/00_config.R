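# Shared configuration for the analysis scripts. Every script can be run
# from the repository root with `Rscript analysis/0X_*.R`; each reads its
# predecessors' outputs from results/ and writes its own there.

library(brainclocks)

MASTER_SEED <- 20260920L
N_REGIONS <- 78L        # cortical parcellation size
HUB_FRACTION <- 0.2     # frontoparietal-like hub system
DENSITY <- 0.3          # structural connectome edge density

RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohorts")

# study arms: expert/non-expert group sizes and age ranges per domain,
# plus the paired pre/post learning arm
STUDY <- default_study_design()

# generative effect sizes (latent coupling model)
G0 <- 0.6
G_AGE <- 0.3
G_EXP <- 0.08

dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(COHORT_DIR, showWarnings = FALSE, recursive = TRUE)

say <- function(...) cat(sprintf(...), "\n")
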