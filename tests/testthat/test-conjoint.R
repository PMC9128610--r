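make_pheno <- function(ft, seed = 151) {
  metaboflow:::with_seed(seed, {
    n <- length(ft$sample_ids)
    # weight tracks m001 tightly; wbc and tg are pure noise
    vals <- cbind(weight = as.numeric(scale(ft$intensities[, "m001"])) +
                    rnorm(n, 0, 0.2),
                  wbc = rnorm(n), tg = rnorm(n))
    rownames(vals) <- ft$sample_ids
    phenotype_table(ft$sample_ids, vals,
                    c("physical", "blood_routine", "serum_biochemistry"))
  })
}

test_that("metabolite-phenotype correlations match the cor.test oracle", {
  ft <- make_ft(n_per_group = 8, n_features = 5, seed = 149)
  pt <- make_pheno(ft)
  rec <- correlate_metabolites_phenotypes(ft, pt)
  expect_equal(nrow(rec), 5 * 3)
  row <- rec[rec$metabolite_id == "m001" & rec$phenotype == "weight", ]
  ct <- stats::cor.test(ft$intensities[, "m001"], pt$values[, "weight"])
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p_value, ct$p.value)
  expect_equal(row$category, "physical")
  expect_equal(row$significance_tier,
               if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
               else if (ct$p.value < 0.05) "*" else "ns")
})

test_that("significance tiers follow the star convention", {
  expect_equal(metaboflow:::significance_tier(0.0005), "***")
  expect_equal(metaboflow:::significance_tier(0.005), "**")
  expect_equal(metaboflow:::significance_tier(0.03), "*")
  expect_equal(metaboflow:::significance_tier(0.2), "ns")
  expect_equal(metaboflow:::significance_tier(NA), "ns")
})

test_that("Venn regions are an exclusive partition of the metabolites", {
  ft <- make_ft(n_per_group = 8, n_features = 6, seed = 157)
  pt <- make_pheno(ft, seed = 158)
  rec <- correlate_metabolites_phenotypes(ft, pt)
  venn <- multi_phenotype_intersection(rec)
  k <- length(unique(rec$category))
  expect_equal(nrow(venn$regions), 2^k - 1)
  # exclusive regions plus the none-region cover every metabolite once
  in_any <- rowSums(venn$membership) > 0
  expect_equal(sum(venn$regions$n), sum(in_any))
  ids <- unlist(strsplit(venn$regions$metabolite_ids[venn$regions$n > 0], ";"))
  expect_false(anyDuplicated(ids) > 0)
  expect_error(multi_phenotype_intersection(rec, categories = "bogus"),
               "unknown category")
})

test_that("the all-variables rule is stricter than the any-variable rule", {
  rec <- data.frame(
    metabolite_id = rep(c("mA", "mB"), each = 2),
    phenotype = rep(c("p1", "p2"), 2),
    category = "physical",
    p_value = c(0.01, 0.02, 0.01, 0.8),   # mA: both sig; mB: one sig
    stringsAsFactors = FALSE)
  any_rule <- multi_phenotype_intersection(rec, rule = "any")
  all_rule <- multi_phenotype_intersection(rec, rule = "all")
  expect_true(all(any_rule$membership[c("mA", "mB"), "physical"]))
  expect_true(all_rule$membership["mA", "physical"])
  expect_false(all_rule$membership["mB", "physical"])
})

test_that("conjoint concordance classes follow the two fluids' directions", {
  mk <- function(names, dirs, sel) {
    data.frame(metabolite_id = paste0("id_", names, "_", seq_along(names)),
               name = names, direction = dirs, selected = sel,
               p_value = 0.01, vip = 2, stringsAsFactors = FALSE)
  }
  nms <- c("cu", "cd", "dis", "un")
  plasma <- mk(nms, c("up", "down", "up", "up"), c(TRUE, TRUE, TRUE, FALSE))
  urine <- mk(nms, c("up", "down", "down", "up"), c(TRUE, TRUE, TRUE, TRUE))
  p_ft <- make_ft(n_per_group = 5, n_features = 4, seed = 163)
  u_ft <- make_ft(n_per_group = 5, n_features = 4, seed = 164,
                  fluid = "urine")
  colnames(p_ft$intensities) <- plasma$metabolite_id
  colnames(u_ft$intensities) <- urine$metabolite_id
  cj <- conjoint_analysis(plasma, urine, p_ft, u_ft)
  got <- stats::setNames(cj$concordance_class, cj$name)
  expect_equal(got[["cu"]], "concordant_up")
  expect_equal(got[["cd"]], "concordant_down")
  expect_equal(got[["dis"]], "discordant")
  expect_equal(got[["un"]], "unclassified")
})

test_that("cross-fluid flags demand both |r| above threshold and p < 0.05", {
  n <- 12
  metaboflow:::with_seed(167, {
    base <- rnorm(n)
    pmat <- cbind(pos = base, nil = rnorm(n))
    umat <- cbind(pos = base + rnorm(n, 0, 0.1), nil = rnorm(n))
  })
  rownames(pmat) <- rownames(umat) <- sprintf("s%02d", 1:n)
  p_ft <- feature_table(abs(pmat) + 5, rep(c("NC", "HFD"), each = 6),
                        "plasma", "positive", 24)
  u_ft <- feature_table(abs(umat) + 5, rep(c("NC", "HFD"), each = 6),
                        "urine", "positive", 24)
  p_ft$intensities[, "pos"] <- exp(pmat[, "pos"])
  u_ft$intensities[, "pos"] <- exp(umat[, "pos"])
  rec <- function(ft) data.frame(
    metabolite_id = colnames(ft$intensities), name = colnames(ft$intensities),
    direction = "up", selected = FALSE, stringsAsFactors = FALSE)
  cj <- conjoint_analysis(rec(p_ft), rec(u_ft), p_ft, u_ft)
  flags <- stats::setNames(cj$flag, cj$name)
  expect_equal(flags[["pos"]], "positive")
  expect_equal(flags[["nil"]], "none")
  expect_equal(stats::setNames(cj$concordance_class, cj$name)[["pos"]],
               "unclassified")   # flags are independent of selection
})
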