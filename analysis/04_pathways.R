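#!/usr/bin/env Rscript
# Stage 4 — pathway enrichment and differential-abundance scores.
#
# For each fluid and post-baseline week: hypergeometric over-representation
# of the differential metabolites against the detected background
# (BH-adjusted across pathways) combined with each pathway's DA score, the
# signed fraction of significantly shifted members (+1 = every measured
# member increased in HFD, -1 = every member decreased). Writes
# pathways_<fluid>_<week>.tsv.

source(file.path("analysis", "common.R"))
study <- load_study()

for (fl in fluids) {
  for (w in as.character(weeks[-1])) {
    tbl_pos <- study$tables[[fl]][["positive"]][[w]]
    tbl_neg <- study$tables[[fl]][["negative"]][[w]]
    extra <- setdiff(colnames(tbl_neg$intensities),
                     colnames(tbl_pos$intensities))
    comb <- feature_table(
      cbind(tbl_pos$intensities, tbl_neg$intensities[, extra, drop = FALSE]),
      group = tbl_pos$group, fluid = fl, ion_mode = "positive",
      time_point_weeks = tbl_pos$time_point_weeks)
    background <- intersect(colnames(comb$intensities),
                            study$annotations$metabolite_id)
    diff <- read_results(file.path(results_dir,
                                   sprintf("differential_%s_%s.tsv", fl, w)))
    res <- pathway_analysis(intersect(diff$metabolite_id, background),
                            background, study$pathways, comb,
                            alpha = config$p_threshold)
    write_results(res, file.path(results_dir,
                                 sprintf("pathways_%s_%s.tsv", fl, w)))
    top <- res[1, ]
    cat(sprintf(
      "%s week %s: top pathway %s (p = %.3g, BH %.3g, DA %.2f)\n",
      fl, w, top$pathway_id, top$enrichment_p, top$bh_adjusted_p,
      top$da_score))
  }
}
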