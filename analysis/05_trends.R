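#!/usr/bin/env Rscript
# Stage 5 — longitudinal pathway trend clustering (plasma).
#
# Summarizes every pathway as its mean member z-score (shared scaling across
# all time points; the z-score divides by the sample variance, this
# workflow's printed convention) in the HFD group at weeks 0, 12 and 24,
# K-means-partitions the trajectories into 8 clusters, and flags clusters
# whose centroid rises or falls strictly across all three time points.
# Writes trend_clusters.tsv and trend_centroids.tsv.

source(file.path("analysis", "common.R"))
study <- load_study()

weekly <- lapply(stats::setNames(as.character(weeks), as.character(weeks)),
                 function(w) {
  pos <- study$tables$plasma$positive[[w]]
  neg <- study$tables$plasma$negative[[w]]
  extra <- setdiff(colnames(neg$intensities), colnames(pos$intensities))
  feature_table(cbind(pos$intensities, neg$intensities[, extra, drop = FALSE]),
                group = pos$group, fluid = "plasma", ion_mode = "positive",
                time_point_weeks = pos$time_point_weeks)
})
prof <- pathway_trajectories(weekly, study$pathways,
                             denominator = config$zscore_denominator)
tc <- cluster_trends(prof, k = config$kmeans_k,
                     seed = stage_seed(config$rng_seed, "trend"))
print(tc)
mono <- monotone_pathways(tc)

write_results(
  data.frame(pathway_id = names(tc$assignments),
             cluster = unname(tc$assignments),
             monotone = ifelse(names(tc$assignments) %in% mono$up, "up",
                        ifelse(names(tc$assignments) %in% mono$down, "down",
                               "none")),
             stringsAsFactors = FALSE),
  file.path(results_dir, "trend_clusters.tsv"))
write_results(
  cbind(data.frame(cluster = seq_len(nrow(tc$centroids))),
        as.data.frame(tc$centroids)),
  file.path(results_dir, "trend_centroids.tsv"))
cat(sprintf("monotone up: %s\nmonotone down: %s\n",
            paste(mono$up, collapse = ", "),
            paste(mono$down, collapse = ", ")))
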