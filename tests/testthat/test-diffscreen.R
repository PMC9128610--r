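test_that("the univariate test matches the base-R oracles", {
  metaboflow:::with_seed(61, {
    x_nc <- rnorm(9, 10, 1)
    x_hfd <- rnorm(9, 12, 1)
  })
  ut <- univariate_test(x_nc, x_hfd)
  expect_equal(ut$test_used, "t")
  expect_equal(ut$p_value,
               stats::t.test(x_nc, x_hfd, var.equal = FALSE)$p.value)
  # heavily skewed data fails the Shapiro gate and falls back to Mann-Whitney
  metaboflow:::with_seed(62, {
    s_nc <- exp(rnorm(9, 0, 2))
    s_hfd <- exp(rnorm(9, 2, 2))
  })
  us <- univariate_test(s_nc, s_hfd)
  expect_equal(us$test_used, "mann_whitney")
  expect_equal(us$p_value,
               suppressWarnings(stats::wilcox.test(s_nc, s_hfd)$p.value))
})

test_that("degenerate and undersized inputs are handled explicitly", {
  ut <- univariate_test(rep(2, 5), rep(2, 6))
  expect_true(ut$degenerate)
  expect_equal(ut$p_value, 1)
  # one constant group is not Shapiro-testable: falls back to Mann-Whitney
  uc <- univariate_test(rep(2, 5), c(3, 4, 5, 6, 7))
  expect_equal(uc$test_used, "mann_whitney")
  expect_error(univariate_test(c(1, 2), c(1, 2, 3)), ">= 3 values")
})

test_that("screening applies the joint VIP-and-p rule on normalized data", {
  ft <- make_ft(n_per_group = 9, n_features = 30, n_effect = 5, fold = 4,
                seed = 67)
  sc <- pareto_scale(sum_normalize(ft))
  model <- fit_oplsda(sc, ft$group, n_orthogonal = 0, cv_folds = 7)
  cfg <- analysis_config()
  out <- screen_differential(ft, model, cfg)
  expect_identical(out$selected,
                   out$vip > cfg$vip_threshold & out$p_value < cfg$p_threshold)
  expect_false(is.unsorted(rev(out$vip)))     # sorted by VIP descending
  # p-values and fold changes computed on the sum-normalized matrix
  norm <- sum_normalize(ft)$matrix
  j <- out$metabolite_id[1]
  hfd <- ft$group == "HFD"
  expect_equal(out$fold_change[1],
               mean(norm[hfd, j]) / mean(norm[!hfd, j]))
  expect_identical(out$direction, ifelse(out$fold_change > 1, "up", "down"))
  # the five injected features dominate the selection
  expect_true(all(sprintf("m%03d", 1:5) %in% out$metabolite_id[out$selected]))
})

test_that("screening rejects a model fitted on different features", {
  ft <- make_ft(n_per_group = 5, n_features = 10, seed = 71)
  other <- make_ft(n_per_group = 5, n_features = 11, seed = 71)
  sc <- pareto_scale(sum_normalize(other))
  model <- fit_oplsda(sc, other$group, n_orthogonal = 0, cv_folds = 3)
  expect_error(screen_differential(ft, model), "do not match")
})

test_that("ion-mode merging deduplicates by name keeping the smaller p", {
  pos <- data.frame(metabolite_id = c("P1", "P2"), ion_mode = "positive",
                    vip = c(2, 1.5), p_value = c(0.01, 0.2),
                    name = c("carnitine", "glucose"),
                    stringsAsFactors = FALSE)
  neg <- data.frame(metabolite_id = c("N1", "N3"), ion_mode = "negative",
                    vip = c(1.8, 1.2), p_value = c(0.001, 0.03),
                    name = c("carnitine", "urea"),
                    stringsAsFactors = FALSE)
  mg <- merge_ion_modes(pos, neg)
  expect_equal(nrow(mg), 3)
  kept <- mg[mg$name == "carnitine", ]
  expect_equal(kept$ion_mode, "negative")   # smaller p wins
  expect_equal(kept$p_value, 0.001)
  expect_false(is.unsorted(rev(mg$vip)))
  # without names, IDs are the merge key
  mg2 <- merge_ion_modes(pos[, 1:4], neg[, 1:4])
  expect_equal(nrow(mg2), 4)
})

test_that("origin classification joins annotations with unknown fallback", {
  ann <- annotation_table(c("P1", "P2"), c("carnitine", "glucose"),
                          c("endogenous", "exogenous"),
                          c("Organic acids and derivatives", NA))
  rec <- data.frame(metabolite_id = c("P1", "P2", "P9"),
                    stringsAsFactors = FALSE)
  out <- classify_origin(rec, ann)
  expect_equal(out$origin, c("endogenous", "exogenous", "unknown"))
  expect_equal(out$name, c("carnitine", "glucose", "P9"))
})

test_that("the truth confusion summary gets its arithmetic right", {
  screen <- data.frame(metabolite_id = sprintf("m%d", 1:10),
                       selected = c(rep(TRUE, 4), rep(FALSE, 6)),
                       stringsAsFactors = FALSE)
  truth <- c("m1", "m2", "m5")           # m3, m4 are false positives
  cf <- truth_confusion(screen, truth)
  expect_equal(cf$tp, 2)
  expect_equal(cf$fp, 2)
  expect_equal(cf$fn, 1)
  expect_equal(cf$tn, 5)
  expect_equal(cf$sensitivity, 2 / 3)
  expect_equal(cf$fdr, 1 / 2)
  expect_equal(cf$specificity, 5 / 7)
  expect_error(truth_confusion(screen, truth, universe = c("z1", "z2")),
               "share no metabolite")
})
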