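#!/usr/bin/env Rscript
# Stage 6 — phenotype correlation and the plasma-urine conjoint analysis.
#
# At week 24: (a) Pearson correlation of every plasma metabolite with every
# phenotype variable, starred by raw p-value tier, plus the Venn-style
# intersection of metabolites significant in the physical / blood-routine /
# serum-biochemistry categories; (b) for metabolites detected in both
# biofluids, the cross-fluid correlation flag (|r| > 0.4 and p < 0.05) and
# the direction-concordance class from the two fluids' screening results.
# Writes phenotype_correlations.tsv, phenotype_venn_regions.tsv and
# conjoint.tsv.

source(file.path("analysis", "common.R"))
study <- load_study()
wk <- as.character(max(weeks))

combined <- function(fl) {
  pos <- study$tables[[fl]]$positive[[wk]]
  neg <- study$tables[[fl]]$negative[[wk]]
  extra <- setdiff(colnames(neg$intensities), colnames(pos$intensities))
  feature_table(cbind(pos$intensities, neg$intensities[, extra, drop = FALSE]),
                group = pos$group, fluid = fl, ion_mode = "positive",
                time_point_weeks = pos$time_point_weeks)
}

plasma_tbl <- combined("plasma")
cors <- correlate_metabolites_phenotypes(plasma_tbl, study$phenotypes[[wk]])
write_results(cors, file.path(results_dir, "phenotype_correlations.tsv"))
venn <- multi_phenotype_intersection(cors, alpha = config$p_threshold)
write_results(venn$regions,
              file.path(results_dir, "phenotype_venn_regions.tsv"))
cat("phenotype Venn regions:\n")
print(venn$regions[venn$regions$n > 0, c("region", "n")], row.names = FALSE)

recs <- lapply(stats::setNames(fluids, fluids), function(fl) {
  out <- lapply(modes, function(md) {
    r <- read_results(file.path(results_dir,
                                sprintf("screen_%s_%s_%s.tsv", fl, md, wk)))
    classify_origin(r, study$annotations)
  })
  merge_ion_modes(out[[1]], out[[2]])
})
cj <- conjoint_analysis(recs$plasma, recs$urine, plasma_tbl,
                        combined("urine"), config)
write_results(cj, file.path(results_dir, "conjoint.tsv"))
tab <- table(cj$concordance_class)
cat("conjoint concordance classes:",
    paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
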