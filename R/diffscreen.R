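#' Normality-gated two-group univariate test
#'
#' Shapiro-Wilk at alpha = 0.05 on each group decides the test: if both
#' groups look normal, a two-tailed Welch t-test; otherwise a Mann-Whitney U
#' test (exact where sample sizes permit and there are no ties). Degenerate
#' input where every pooled value is identical returns p = 1 with a
#' degeneracy flag rather than an error.
#'
#' @param x_nc,x_hfd numeric vectors (>= 3 values each).
#' @return list with `p_value`, `test_used` (`"t"` or `"mann_whitney"`),
#'   `degenerate` flag.
#' @export
univariate_test <- function(x_nc, x_hfd) {
  if (length(x_nc) < 3 || length(x_hfd) < 3) {
    stop("need >= 3 values per group", call. = FALSE)
  }
  pooled <- c(x_nc, x_hfd)
  if (length(unique(pooled)) == 1L) {
    return(list(p_value = 1, test_used = "mann_whitney", degenerate = TRUE))
  }
  normal <- function(v) {
    if (length(unique(v)) == 1L) return(FALSE)   # constant: not testable
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (normal(x_nc) && normal(x_hfd)) {
    p <- stats::t.test(x_nc, x_hfd, var.equal = FALSE)$p.value
    list(p_value = p, test_used = "t", degenerate = FALSE)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x_nc, x_hfd, exact = NULL)$p.value)
    list(p_value = min(p, 1), test_used = "mann_whitney", degenerate = FALSE)
  }
}

#' Screen metabolites for significant group differences
#'
#' Applies the joint rule: a metabolite is selected when its VIP from the
#' OPLS-DA model exceeds `vip_threshold` AND its univariate P value falls
#' below `p_threshold`. P values and fold changes are computed on
#' sum-normalized intensities (Pareto scaling destroys ratios); P values are
#' deliberately unadjusted, mirroring common metabolomics practice of pairing
#' VIP > 1 with raw P < 0.05.
#'
#' @param ft a `feature_table`.
#' @param model the `opls_model` fitted on the same features.
#' @param config an `analysis_config`.
#' @return data frame of screening records, one row per feature, sorted by
#'   VIP descending: `metabolite_id`, `ion_mode`, `vip`, `p_value`,
#'   `test_used`, `fold_change` (mean HFD / mean NC), `direction`, `selected`.
#' @export
screen_differential <- function(ft, model, config = analysis_config()) {
  if (!identical(sort(colnames(ft$intensities)), sort(model$feature_ids))) {
    stop("feature sets of the table and the model do not match", call. = FALSE)
  }
  norm <- sum_normalize(ft)$matrix
  gi <- group_indices(ft)
  if (length(gi$NC) < 3 || length(gi$HFD) < 3) {
    stop("need >= 3 samples per group for screening", call. = FALSE)
  }
  ids <- colnames(norm)
  vip <- model$vip[ids]
  p <- numeric(length(ids))
  test_used <- character(length(ids))
  fc <- numeric(length(ids))
  for (j in seq_along(ids)) {
    ut <- univariate_test(norm[gi$NC, j], norm[gi$HFD, j])
    p[j] <- ut$p_value
    test_used[j] <- ut$test_used
    m_nc <- mean(norm[gi$NC, j])
    fc[j] <- if (m_nc > 0) mean(norm[gi$HFD, j]) / m_nc else Inf
  }
  rec <- data.frame(
    metabolite_id = ids,
    ion_mode = ft$ion_mode,
    vip = unname(vip),
    p_value = p,
    test_used = test_used,
    fold_change = fc,
    direction = ifelse(fc > 1, "up", "down"),
    selected = unname(vip) > config$vip_threshold & p < config$p_threshold,
    stringsAsFactors = FALSE)
  rec[order(-rec$vip), , drop = FALSE]
}

#' Merge screening records from positive and negative ion modes
#'
#' Union of the two record sets from the same fluid/time point. Metabolites
#' detected in both modes (matched by compound name when names are attached,
#' else by metabolite ID) are deduplicated keeping the record with the
#' smaller P value; the provenance ion mode is retained on the kept record.
#'
#' @param records_pos,records_neg screening data frames
#'   (from [screen_differential()], optionally after [classify_origin()]).
#' @return merged data frame sorted by VIP descending.
#' @export
merge_ion_modes <- function(records_pos, records_neg) {
  both <- rbind(records_pos, records_neg)
  if (nrow(both) == 0L) return(both)
  key <- if ("name" %in% colnames(both)) both$name else both$metabolite_id
  keep <- logical(nrow(both))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep[idx[which.min(both$p_value[idx])]] <- TRUE
  }
  out <- both[keep, , drop = FALSE]
  out <- out[order(-out$vip), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach endogenous/exogenous origin to screening records
#'
#' Joins the annotation table on `metabolite_id`, populating `name`,
#' `origin` and `superclass`; metabolites without an annotation get origin
#' `"unknown"` and keep their ID as name.
#'
#' @param records a screening data frame.
#' @param annotations an `annotation_table`.
#' @return `records` with `name`, `origin`, `superclass` columns.
#' @export
classify_origin <- function(records, annotations) {
  idx <- match(records$metabolite_id, annotations$metabolite_id)
  records$name <- ifelse(is.na(idx), records$metabolite_id,
                         annotations$name[idx])
  records$origin <- ifelse(is.na(idx), "unknown", annotations$origin[idx])
  records$superclass <- ifelse(is.na(idx), NA_character_,
                               annotations$superclass[idx])
  records
}

#' Confusion summary of a screen against simulation ground truth
#'
#' @param screen_output screening data frame with `metabolite_id` and
#'   `selected` columns.
#' @param truth_ids character vector of truly differential metabolite IDs.
#' @param universe optional full ID universe; defaults to the screen's IDs.
#' @return list with `sensitivity`, `specificity`, `fdr` and the 2x2 counts.
#' @export
truth_confusion <- function(screen_output, truth_ids, universe = NULL) {
  if (is.null(universe)) universe <- screen_output$metabolite_id
  truth_ids <- intersect(truth_ids, universe)
  sel <- intersect(screen_output$metabolite_id[screen_output$selected],
                   universe)
  if (length(intersect(screen_output$metabolite_id, universe)) == 0L) {
    stop("screen output and truth share no metabolite IDs", call. = FALSE)
  }
  tp <- length(intersect(sel, truth_ids))
  fp <- length(setdiff(sel, truth_ids))
  fn <- length(setdiff(truth_ids, sel))
  tn <- length(universe) - tp - fp - fn
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
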