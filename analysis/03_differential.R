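#!/usr/bin/env Rscript
# Stage 3 — differential metabolites per fluid and week.
#
# Applies the joint screening rule (VIP > 1 from the OPLS-DA model AND raw
# univariate p < 0.05), annotates each selected metabolite with its compound
# name and endogenous/exogenous origin, merges the two ion modes keeping the
# smaller p-value for metabolites detected in both, and writes
# differential_<fluid>_<week>.tsv plus an origin breakdown.

source(file.path("analysis", "common.R"))
study <- load_study()

for (fl in fluids) {
  for (w in as.character(weeks[-1])) {
    recs <- lapply(modes, function(md) {
      r <- read_results(file.path(results_dir,
                                  sprintf("screen_%s_%s_%s.tsv", fl, md, w)))
      classify_origin(r[r$selected, , drop = FALSE], study$annotations)
    })
    merged <- merge_ion_modes(recs[[1]], recs[[2]])
    write_results(merged, file.path(results_dir,
                                    sprintf("differential_%s_%s.tsv", fl, w)))
    tab <- table(merged$origin)
    cat(sprintf("%s week %s: %d differential metabolites (%s)\n", fl, w,
                nrow(merged),
                paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  }
}
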