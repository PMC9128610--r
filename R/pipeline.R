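#' Derive a stage seed from the run seed
#'
#' Every stochastic stage gets its own child seed by a fixed derivation from
#' the single run seed, so any stage can be reproduced in isolation.
#'
#' @param seed the run seed.
#' @param stage stage name.
#' @return integer child seed (< 2^31).
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "preprocess", "multivar", "screen", "enrich",
              "trend", "correlate", "conjoint")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage '", stage, "'", call. = FALSE)
  as.integer((as.numeric(seed) + i * 10007) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a simulated (or loaded) study
#'
#' Executes, in fixed order, preprocessing, the multivariate models,
#' differential screening with ion-mode merging and origin classification,
#' pathway enrichment with DA scores, longitudinal trend clustering,
#' metabolite-phenotype correlation with category intersections, and the
#' plasma-urine conjoint analysis. All randomness derives from
#' `config$rng_seed` through [stage_seed()]; rerunning with the same study
#' and config yields byte-identical output files.
#'
#' @param study a `simulated_study` (or an equivalently shaped list built
#'   from files read with the package's readers).
#' @param config an `analysis_config`.
#' @param out_dir directory for the stage outputs (created if needed).
#' @param permutations run the label-permutation model validation (slowest
#'   step; set `FALSE` to skip and leave permutation p-values `NA`).
#' @return run manifest: config snapshot, seed, per-stage timings, output
#'   paths and their md5 digests, package version. Also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(study, config = analysis_config(), out_dir,
                         permutations = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  weeks <- as.character(study$spec$time_points)
  post <- weeks[-1]
  last_wk <- weeks[length(weeks)]
  fluids <- names(study$tables)
  timings <- c()
  outputs <- character()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_results(df, path)
    outputs <<- c(outputs, path)
    path
  }

  ## -- multivariate models + per-mode screening ------------------------
  screens <- list()
  summaries <- list()
  tick("multivar", {
    for (fl in fluids) {
      for (w in post) {
        for (md in names(study$tables[[fl]])) {
          ft <- study$tables[[fl]][[md]][[w]]
          sc <- pareto_scale(sum_normalize(ft))
          pca <- fit_pca(sc, n_components = 2)
          model <- fit_oplsda(sc, ft$group, n_orthogonal = "auto",
                              cv_folds = config$cv_folds,
                              seed = stage_seed(config$rng_seed, "multivar"))
          if (permutations) {
            pt <- permutation_test(sc, ft$group,
                                   n_permutations = config$n_permutations,
                                   seed = stage_seed(config$rng_seed,
                                                     "multivar"),
                                   folds = config$cv_folds,
                                   n_orthogonal = model$n_orthogonal)
            model$p_R2Y <- pt$p_R2Y
            model$p_Q2 <- pt$p_Q2
          }
          key <- paste(fl, md, w, sep = "_")
          screens[[key]] <- screen_differential(ft, model, config)
          summaries[[key]] <- list(
            fluid = fl, ion_mode = md, week = as.integer(w),
            pc1_pc2_explained = round(sum(pca$explained[1:2]), 4),
            R2Y = model$R2Y, Q2 = model$Q2,
            p_R2Y = model$p_R2Y, p_Q2 = model$p_Q2,
            n_orthogonal = model$n_orthogonal,
            n_selected = sum(screens[[key]]$selected))
          emit(screens[[key]], paste0("screen_", key, ".tsv"))
        }
      }
    }
  })
  mv_path <- file.path(out_dir, "model_summaries.json")
  jsonlite::write_json(summaries, mv_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, mv_path)

  ## -- ion-mode merge + origin ----------------------------------------
  merged <- list()
  tick("screen", {
    for (fl in fluids) {
      for (w in post) {
        pos <- classify_origin(screens[[paste(fl, "positive", w, sep = "_")]],
                               study$annotations)
        neg <- classify_origin(screens[[paste(fl, "negative", w, sep = "_")]],
                               study$annotations)
        key <- paste(fl, w, sep = "_")
        merged[[key]] <- merge_ion_modes(pos[pos$selected, , drop = FALSE],
                                         neg[neg$selected, , drop = FALSE])
        emit(merged[[key]], paste0("differential_", key, ".tsv"))
      }
    }
  })

  ## -- pathway enrichment + DA scores ----------------------------------
  tick("enrich", {
    for (fl in fluids) {
      for (w in post) {
        tbl <- combined_mode_table(study, fl, w)
        background <- intersect(colnames(tbl$intensities),
                                study$annotations$metabolite_id)
        diff_ids <- intersect(merged[[paste(fl, w, sep = "_")]]$metabolite_id,
                              background)
        res <- pathway_analysis(diff_ids, background, study$pathways, tbl,
                                alpha = config$p_threshold)
        emit(res, paste0("pathways_", fl, "_", w, ".tsv"))
      }
    }
  })

  ## -- longitudinal trend clustering (plasma) --------------------------
  trend_out <- tick("trend", {
    plasma_weekly <- lapply(stats::setNames(weeks, weeks), function(w) {
      combined_mode_table(study, "plasma", w)
    })
    prof <- suppressWarnings(pathway_trajectories(
      plasma_weekly, study$pathways,
      denominator = config$zscore_denominator))
    tc <- cluster_trends(prof, k = config$kmeans_k,
                         seed = stage_seed(config$rng_seed, "trend"))
    emit(data.frame(pathway_id = names(tc$assignments),
                    cluster = unname(tc$assignments),
                    monotone = ifelse(tc$assignments %in% tc$monotone_up, "up",
                             ifelse(tc$assignments %in% tc$monotone_down,
                                    "down", "none")),
                    stringsAsFactors = FALSE),
         "trend_clusters.tsv")
    emit(cbind(data.frame(cluster = seq_len(nrow(tc$centroids))),
               as.data.frame(tc$centroids)), "trend_centroids.tsv")
    tc
  })

  ## -- phenotype correlation -------------------------------------------
  tick("correlate", {
    tbl <- combined_mode_table(study, "plasma", last_wk)
    cors <- correlate_metabolites_phenotypes(tbl,
                                             study$phenotypes[[last_wk]])
    emit(cors, "phenotype_correlations.tsv")
    venn <- multi_phenotype_intersection(cors, alpha = config$p_threshold)
    emit(venn$regions, "phenotype_venn_regions.tsv")
  })

  ## -- plasma-urine conjoint -------------------------------------------
  tick("conjoint", {
    if (all(c("plasma", "urine") %in% fluids)) {
      recs <- lapply(c(plasma = "plasma", urine = "urine"), function(fl) {
        pos <- classify_origin(screens[[paste(fl, "positive", last_wk,
                                              sep = "_")]], study$annotations)
        neg <- classify_origin(screens[[paste(fl, "negative", last_wk,
                                              sep = "_")]], study$annotations)
        merge_ion_modes(pos, neg)     # all records, selected flag retained
      })
      cj <- conjoint_analysis(recs$plasma, recs$urine,
                              combined_mode_table(study, "plasma", last_wk),
                              combined_mode_table(study, "urine", last_wk),
                              config)
      emit(cj, "conjoint.tsv")
    }
  })

  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    stage_seconds = as.list(timings),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))),
    version = as.character(utils::packageVersion("metaboflow")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
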