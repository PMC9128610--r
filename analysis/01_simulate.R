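#!/usr/bin/env Rscript
# Stage 1 — simulate the study.
#
# Generates the synthetic two-group (NC vs HFD, n = 9 each) untargeted
# metabolomics study at its default geometry: 1295 plasma and 1868 urine
# features split over positive/negative ion modes, 540 metabolites shared
# between the fluids (8 concordant-up, 4 concordant-down, 2 discordant),
# ~12% differential features at a typical two-fold effect, 40 pathways of
# which 4 trend up and 4 trend down over weeks 0/12/24, and six phenotype
# variables coupled to plasma metabolites. Everything is written as plain
# TSV/GMT/JSON under results/study/.

source(file.path("analysis", "common.R"))

spec <- simulation_spec(rng_seed = stage_seed(config$rng_seed, "simulate"))
study <- simulate_study(spec)
print(study)

write_study(study, study_dir)
cat("study written to", study_dir, "\n")
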