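#' Metabolite-phenotype Pearson correlation
#'
#' Pearson r and two-sided p for every (metabolite, phenotype) pair over
#' aligned samples, with significance tiers as starred in correlation
#' heatmaps: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, else `ns`. Raw
#' (unadjusted) p-values drive the tiers by design; apply [stats::p.adjust]
#' downstream if a corrected view is wanted. Pairs with fewer than 3
#' complete observations yield `r = NA` and tier `ns`.
#'
#' @param ft a `feature_table` (intensities used as-is; pass a normalized
#'   table if desired).
#' @param pt a `phenotype_table` over the same samples.
#' @return long-format data frame: `metabolite_id`, `phenotype`, `category`,
#'   `r`, `p_value`, `significance_tier`.
#' @export
correlate_metabolites_phenotypes <- function(ft, pt) {
  common <- intersect(ft$sample_ids, pt$sample_ids)
  if (length(common) < 3) stop("fewer than 3 aligned samples", call. = FALSE)
  M <- ft$intensities[common, , drop = FALSE]
  P <- pt$values[common, , drop = FALSE]
  out <- vector("list", ncol(M) * ncol(P))
  idx <- 0L
  for (j in seq_len(ncol(M))) {
    for (q in seq_len(ncol(P))) {
      ok <- stats::complete.cases(M[, j], P[, q])
      if (sum(ok) < 3 || stats::sd(M[ok, j]) == 0 ||
          stats::sd(P[ok, q]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(M[ok, j], P[ok, q], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        metabolite_id = colnames(M)[j], phenotype = colnames(P)[q],
        category = unname(pt$category[colnames(P)[q]]),
        r = r, p_value = p,
        significance_tier = significance_tier(p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

significance_tier <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Multi-phenotype category intersections (Venn logic)
#'
#' A metabolite belongs to a phenotype category when it has at least one
#' significant (p < `alpha`) correlation with any variable of that category
#' (`rule = "any"`; `rule = "all"` requires every variable of the category).
#' All `2^k - 1` intersection regions over the k categories are reported.
#'
#' @param records output of [correlate_metabolites_phenotypes()].
#' @param categories category labels to intersect (default: those present).
#' @param alpha significance cut-off (default 0.05).
#' @param rule `"any"` (default) or `"all"`.
#' @return list with `membership` (data frame metabolite x category logical)
#'   and `regions` (data frame: region label, metabolite count, IDs).
#' @export
multi_phenotype_intersection <- function(records, categories = NULL,
                                         alpha = 0.05,
                                         rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (is.null(categories)) categories <- sort(unique(records$category))
  unknown <- setdiff(categories, unique(records$category))
  if (length(unknown)) {
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mets <- unique(records$metabolite_id)
  member <- matrix(FALSE, length(mets), length(categories),
                   dimnames = list(mets, categories))
  for (cg in categories) {
    sub <- records[records$category == cg, , drop = FALSE]
    sig <- !is.na(sub$p_value) & sub$p_value < alpha
    agg <- tapply(sig, sub$metabolite_id,
                  if (rule == "any") any else all)
    member[names(agg), cg] <- as.logical(agg)
  }
  # every non-empty subset of categories is one exclusive Venn region
  k <- length(categories)
  regions <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    in_region <- apply(member, 1, function(row) all(row == inset))
    ids <- rownames(member)[in_region]
    regions[[length(regions) + 1L]] <- data.frame(
      region = paste(categories[inset], collapse = "&"),
      n = length(ids), metabolite_ids = paste(ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(membership = as.data.frame(member),
       regions = do.call(rbind, regions))
}

#' Plasma-urine conjoint concordance analysis
#'
#' For metabolites detected in both biofluids (matched by compound name),
#' computes the cross-fluid Pearson correlation of per-animal abundances,
#' flags metabolites with |r| above the threshold and p < 0.05 as
#' positively/negatively correlated, and classifies direction concordance
#' from the two fluids' screening results: `concordant_up` if selected and
#' up in both fluids, `concordant_down` if down in both, `discordant` if
#' selected with opposite directions, else `unclassified`.
#'
#' @param plasma_records,urine_records screening records (after
#'   [classify_origin()], so a `name` column is present) for the two fluids
#'   at the same time point.
#' @param plasma_ft,urine_ft the corresponding feature tables over the same
#'   animals (ion modes column-bound beforehand if both are wanted).
#' @param config an `analysis_config` (`cross_fluid_r_threshold` used).
#' @return data frame, one row per shared metabolite name: directions per
#'   fluid, `cross_fluid_r`, `cross_fluid_p`, `flag`
#'   (`positive`/`negative`/`none`), `concordance_class`.
#' @export
conjoint_analysis <- function(plasma_records, urine_records,
                              plasma_ft, urine_ft,
                              config = analysis_config()) {
  stopifnot("name" %in% colnames(plasma_records),
            "name" %in% colnames(urine_records))
  shared <- intersect(plasma_records$name, urine_records$name)
  if (!length(shared)) {
    warning("no metabolites shared between the fluids", call. = FALSE)
    return(data.frame())
  }
  animals <- intersect(plasma_ft$sample_ids, urine_ft$sample_ids)
  if (length(animals) < 3) stop("fewer than 3 shared animals", call. = FALSE)
  dir_of <- function(rec) if (rec$selected) rec$direction else "ns"
  out <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    nm <- shared[i]
    pr <- plasma_records[plasma_records$name == nm, , drop = FALSE][1, ]
    ur <- urine_records[urine_records$name == nm, , drop = FALSE][1, ]
    pvec <- plasma_ft$intensities[animals, pr$metabolite_id]
    uvec <- urine_ft$intensities[animals, ur$metabolite_id]
    if (stats::sd(pvec) == 0 || stats::sd(uvec) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(pvec, uvec, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    dp <- dir_of(pr); du <- dir_of(ur)
    klass <- if (dp == "up" && du == "up") "concordant_up"
      else if (dp == "down" && du == "down") "concordant_down"
      else if (dp != "ns" && du != "ns") "discordant"
      else "unclassified"
    flag <- if (!is.na(r) && !is.na(p) && p < 0.05 &&
                r > config$cross_fluid_r_threshold) "positive"
      else if (!is.na(r) && !is.na(p) && p < 0.05 &&
               r < -config$cross_fluid_r_threshold) "negative"
      else "none"
    out[[i]] <- data.frame(
      name = nm, plasma_direction = dp, urine_direction = du,
      cross_fluid_r = r, cross_fluid_p = p, flag = flag,
      concordance_class = klass, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
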