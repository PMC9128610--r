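test_that("the generator is deterministic in its seed", {
  a <- simulate_study(small_spec(seed = 11))
  b <- simulate_study(small_spec(seed = 11))
  c <- simulate_study(small_spec(seed = 12))
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$tables$plasma$positive[["24"]]$intensities,
                         c$tables$plasma$positive[["24"]]$intensities))
})

test_that("simulated studies have the requested geometry", {
  sp <- small_spec(seed = 3)
  st <- simulate_study(sp)
  for (fl in c("plasma", "urine")) {
    ids <- unique(unlist(lapply(st$tables[[fl]], function(md)
      colnames(md[["0"]]$intensities))))
    expect_length(ids, sp$n_features[[fl]])
    for (md in names(st$tables[[fl]])) {
      expect_named(st$tables[[fl]][[md]],
                   as.character(sp$time_points))
      ft <- st$tables[[fl]][[md]][["12"]]
      expect_s3_class(ft, "feature_table")
      expect_equal(nrow(ft$intensities), 2 * sp$n_per_group)
      expect_equal(sort(unique(ft$group)), c("HFD", "NC"))
    }
  }
  shared_plasma <- intersect(st$annotations$name, st$truth$shared_names)
  expect_length(st$truth$shared_names, sp$n_shared)
  expect_length(shared_plasma, sp$n_shared)
})

test_that("ground truth is internally coherent", {
  sp <- small_spec(seed = 5)
  st <- simulate_study(sp)
  shared <- st$truth$shared_names
  conc <- st$truth$concordance
  # the concordance table covers every shared name with the injected counts
  expect_setequal(conc$name, shared)
  expect_equal(sum(conc$class == "concordant_up"), sp$n_concordant_up)
  expect_equal(sum(conc$class == "concordant_down"), sp$n_concordant_down)
  expect_equal(sum(conc$class == "discordant"), sp$n_discordant)
  class_names <- conc$name[conc$class != "unclassified"]
  for (fl in c("plasma", "urine")) {
    wk <- as.character(max(sp$time_points))
    d <- st$truth$differential[[fl]][[wk]]
    measured <- unique(unlist(lapply(st$tables[[fl]], function(md)
      colnames(md[[wk]]$intensities))))
    expect_true(all(d$metabolite_id %in% measured))
    # baseline carries no injected group effects
    expect_equal(nrow(st$truth$differential[[fl]][["0"]]), 0L)
    # non-class (fill) differentials never use shared names, so injected
    # classes are the only possible cross-fluid differentials
    fills <- setdiff(d$name, class_names)
    expect_length(intersect(fills, shared), 0L)
    expect_true(all(class_names %in% d$name))
  }
})

test_that("impossible specs are rejected with spec errors", {
  expect_error(simulation_spec(n_shared = 100,
                               n_features = c(plasma = 50, urine = 80)),
               "n_shared", class = "metaboflow_spec_error")
  expect_error(simulation_spec(frac_differential = 1.5),
               class = "metaboflow_spec_error")
  expect_error(simulation_spec(n_concordant_up = 40, n_shared = 30),
               class = "metaboflow_spec_error")
  # differential budget beyond the classes must fit the non-shared pool
  expect_error(simulation_spec(n_features = c(plasma = 100, urine = 100),
                               n_shared = 95, frac_differential = 0.3),
               "exclusive", class = "metaboflow_spec_error")
})

test_that("injected effects are realized at the requested magnitude", {
  sp <- small_spec(seed = 9, effect_log_mean = log(4), effect_log_sd = 0.05)
  st <- simulate_study(sp)
  wk <- "24"
  d <- st$truth$differential$plasma[[wk]]
  tbl <- combined_mode_table(st, "plasma", wk)
  hfd <- tbl$group == "HFD"
  for (i in seq_len(nrow(d))) {
    raw_fc <- mean(tbl$intensities[hfd, d$metabolite_id[i]]) /
      mean(tbl$intensities[!hfd, d$metabolite_id[i]])
    target <- if (d$direction[i] == "up") d$fold[i] else 1 / d$fold[i]
    expect_gt(raw_fc / target, 0.6)
    expect_lt(raw_fc / target, 1.7)
  }
  # baseline tables carry no group effect
  tbl0 <- combined_mode_table(st, "plasma", "0")
  fc0 <- colMeans(tbl0$intensities[hfd, d$metabolite_id, drop = FALSE]) /
    colMeans(tbl0$intensities[!hfd, d$metabolite_id, drop = FALSE])
  expect_true(all(fc0 > 0.5 & fc0 < 2))
})

test_that("per-ion-mode total signal stays balanced between groups", {
  st <- simulate_study(small_spec(seed = 21))
  for (fl in c("plasma", "urine")) {
    for (md in c("positive", "negative")) {
      ft <- st$tables[[fl]][[md]][["24"]]
      tot <- rowSums(ft$intensities)
      ratio <- mean(tot[ft$group == "HFD"]) / mean(tot[ft$group == "NC"])
      expect_gt(ratio, 0.8)
      expect_lt(ratio, 1.25)
    }
  }
})

test_that("cross-fluid coupling holds for class metabolites only", {
  sp <- small_spec(seed = 2)
  st <- simulate_study(sp)
  pl <- combined_mode_table(st, "plasma", "0")
  ur <- combined_mode_table(st, "urine", "0")
  conc <- st$truth$concordance
  r_of <- function(nm) {
    stats::cor(log(pl$intensities[, paste0("P_", nm)]),
               log(ur$intensities[, paste0("U_", nm)]))
  }
  class_r <- vapply(conc$name[conc$class != "unclassified"], r_of, numeric(1))
  null_r <- vapply(conc$name[conc$class == "unclassified"], r_of, numeric(1))
  expect_gt(min(class_r), 0.5)
  expect_lt(mean(abs(null_r)), 0.3)
})

test_that("a fully null study (no differential signal) simulates cleanly", {
  sp <- simulation_spec(n_per_group = 6,
                        n_features = c(plasma = 30, urine = 30),
                        n_shared = 10, frac_differential = 0,
                        n_concordant_up = 0, n_concordant_down = 0,
                        n_discordant = 0, n_trend_up = 0, n_trend_down = 0,
                        n_pathways = 3, pathway_size_range = c(3, 6),
                        rng_seed = 8)
  st <- simulate_study(sp)
  expect_equal(nrow(st$truth$differential$plasma[["24"]]), 0L)
  expect_true(all(st$truth$concordance$class == "unclassified"))
  expect_true(all(st$truth$trend$label == "none"))
})

test_that("phenotypes track their driver metabolites at the target strength", {
  st <- simulate_study(small_spec(seed = 4))
  ph <- st$truth$phenotype_spec
  wk <- "24"
  pt <- st$phenotypes[[wk]]
  tbl <- combined_mode_table(st, "plasma", wk)
  for (q in seq_len(nrow(ph))) {
    r <- stats::cor(pt$values[, ph$phenotype[q]],
                    tbl$intensities[pt$sample_ids,
                                    paste0("P_", ph$metabolite[q])])
    expect_gt(r, ph$target_r[q] - 0.35)
  }
})

test_that("a study written to disk reads back equivalently", {
  st <- simulate_study(small_spec(seed = 6))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  ft <- read_feature_table(file.path(dir, "features_plasma_positive_wk12.tsv"),
                           "plasma", "positive", 12)
  expect_identical(ft$intensities,
                   st$tables$plasma$positive[["12"]]$intensities)
  pws <- read_pathway_sets(file.path(dir, "pathways.gmt"))
  expect_equal(pws, st$pathways)
  pt <- read_phenotype_table(file.path(dir, "phenotypes_wk24.tsv"))
  expect_identical(pt$values, st$phenotypes[["24"]]$values)
})
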