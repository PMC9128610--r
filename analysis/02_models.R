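#!/usr/bin/env Rscript
# Stage 2 — multivariate models per fluid, ion mode and post-baseline week.
#
# For each feature table: sum-normalize, Pareto-scale, fit an unsupervised
# PCA (overview of the group separation), then an OPLS-DA model with
# automatic orthogonal-component selection, 7-fold stratified cross-validated
# Q2 and a 200-permutation test of R2Y/Q2. Each table's per-feature screening
# records (VIP, univariate p, fold change, selection flag) are written as
# screen_<fluid>_<mode>_<week>.tsv; model quality goes to
# model_summaries.json.

source(file.path("analysis", "common.R"))
study <- load_study()
seed <- stage_seed(config$rng_seed, "multivar")

summaries <- list()
for (fl in fluids) {
  for (w in as.character(weeks[-1])) {
    for (md in modes) {
      ft <- study$tables[[fl]][[md]][[w]]
      sc <- pareto_scale(sum_normalize(ft))
      pca <- fit_pca(sc, n_components = 2)
      model <- fit_oplsda(sc, ft$group, n_orthogonal = "auto",
                          cv_folds = config$cv_folds, seed = seed)
      pt <- permutation_test(sc, ft$group,
                             n_permutations = config$n_permutations,
                             seed = seed, folds = config$cv_folds,
                             n_orthogonal = model$n_orthogonal)
      model$p_R2Y <- pt$p_R2Y
      model$p_Q2 <- pt$p_Q2
      screen <- screen_differential(ft, model, config)
      key <- paste(fl, md, w, sep = "_")
      write_results(screen,
                    file.path(results_dir, sprintf("screen_%s.tsv", key)))
      summaries[[key]] <- list(
        fluid = fl, ion_mode = md, week = as.integer(w),
        pc1_pc2_explained = round(sum(pca$explained), 4),
        R2Y = model$R2Y, Q2 = model$Q2,
        p_R2Y = model$p_R2Y, p_Q2 = model$p_Q2,
        n_orthogonal = model$n_orthogonal,
        n_selected = sum(screen$selected))
      cat(sprintf(
        "%-28s R2Y %.3f  Q2 %.3f  p(Q2) %.4g  selected %d/%d\n",
        key, model$R2Y, model$Q2, model$p_Q2, sum(screen$selected),
        nrow(screen)))
    }
  }
}
jsonlite::write_json(summaries, file.path(results_dir, "model_summaries.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
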