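#!/usr/bin/env Rscript
# Runs the whole analysis end to end: simulate, model, screen, enrich,
# cluster trends, conjoint. Each stage is an ordinary script that can also be
# run (and re-run) on its own; all randomness derives from the single seed in
# analysis/common.R, so the full run is reproducible file-for-file.

scripts <- c("01_simulate.R", "02_models.R", "03_differential.R",
             "04_pathways.R", "05_trends.R", "06_conjoint.R")
for (s in scripts) {
  cat("\n==>", s, "\n")
  status <- system2("Rscript", file.path("analysis", s))
  if (status != 0) stop("stage ", s, " failed with status ", status)
}
cat("\nall stages complete; outputs under results/\n")
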