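# Shared helpers for the numbered analysis scripts: locations of the study
# fixture and results, and a loader that reconstructs the study object from
# the TSV/GMT files written by 01_simulate.R.

suppressMessages(library(metaboflow))

study_dir <- file.path("results", "study")
results_dir <- "results"
weeks <- c(0, 12, 24)
fluids <- c("plasma", "urine")
modes <- c("positive", "negative")

config <- analysis_config(rng_seed = 20240901)

load_study <- function(dir = study_dir) {
  if (!dir.exists(dir)) {
    stop("study fixture not found at '", dir,
         "'; run analysis/01_simulate.R first", call. = FALSE)
  }
  tables <- list()
  for (fl in fluids) {
    tables[[fl]] <- list()
    for (md in modes) {
      tables[[fl]][[md]] <- list()
      for (w in weeks) {
        path <- file.path(dir, sprintf("features_%s_%s_wk%d.tsv", fl, md, w))
        tables[[fl]][[md]][[as.character(w)]] <-
          read_feature_table(path, fluid = fl, ion_mode = md,
                             time_point_weeks = w)
      }
    }
  }
  phenotypes <- lapply(stats::setNames(as.character(weeks),
                                       as.character(weeks)), function(w) {
    read_phenotype_table(file.path(dir, sprintf("phenotypes_wk%s.tsv", w)))
  })
  list(tables = tables,
       annotations = read_annotation_table(file.path(dir, "annotations.tsv")),
       pathways = read_pathway_sets(file.path(dir, "pathways.gmt")),
       phenotypes = phenotypes,
       spec = list(time_points = weeks))
}
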