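#' Pathway over-representation analysis
#'
#' One-sided hypergeometric test per pathway: does the differential set hit
#' the pathway's members more often than random draws from the background
#' would? Pathway membership is intersected with the background before
#' testing; pathways with no background overlap are skipped. P values are
#' Benjamini-Hochberg adjusted across the tested pathways.
#'
#' @param differential_ids IDs of the screened differential metabolites
#'   (must be a subset of `background_ids`).
#' @param background_ids the detected-metabolite background universe.
#' @param pathways list of `pathway_set`.
#' @return data frame: `pathway_id`, `pathway_name`,
#'   `n_background_in_pathway`, `n_differential_in_pathway`, `enrichment_p`,
#'   `bh_adjusted_p`.
#' @export
enrich_pathways <- function(differential_ids, background_ids, pathways) {
  differential_ids <- unique(differential_ids)
  background_ids <- unique(background_ids)
  if (length(setdiff(differential_ids, background_ids))) {
    stop("differential set is not a subset of the background", call. = FALSE)
  }
  N <- length(background_ids)
  n <- length(differential_ids)
  rows <- lapply(pathways, function(pw) {
    members <- intersect(pw$members, background_ids)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, differential_ids))
    # P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pw$pathway_id, pathway_name = pw$pathway_name,
               n_background_in_pathway = K, n_differential_in_pathway = k,
               enrichment_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      n_background_in_pathway = integer(),
                      n_differential_in_pathway = integer(),
                      enrichment_p = numeric(), bh_adjusted_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$bh_adjusted_p <- stats::p.adjust(out$enrichment_p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Differential-abundance (DA) score of a pathway
#'
#' Captures the overall direction of change of a pathway's metabolites
#' between groups. Each member measured in the table gets a Mann-Whitney U
#' test; the p-values are Benjamini-Hochberg corrected within the pathway,
#' and members with adjusted p < `alpha` are counted as increased (HFD group
#' median above NC) or decreased. The score is
#' `(n_increased - n_decreased) / n_measured_members`, so +1 means every
#' measured member increased significantly and -1 means every one decreased;
#' the denominator counts members actually measured in the data.
#'
#' @param pathway a `pathway_set`.
#' @param ft a `feature_table` holding both groups.
#' @param alpha adjusted-p significance cut-off (default 0.05).
#' @param bh_family `"pathway"` (adjust within this pathway's members,
#'   default) or `"global"` (p-values assumed pre-adjusted by the caller).
#' @return one-row data frame: `pathway_id`, `n_measured`, `n_increased`,
#'   `n_decreased`, `da_score`; or `NULL` (with a warning) if no member is
#'   measured.
#' @export
da_score <- function(pathway, ft, alpha = 0.05,
                     bh_family = c("pathway", "global")) {
  bh_family <- match.arg(bh_family)
  members <- intersect(pathway$members, colnames(ft$intensities))
  if (!length(members)) {
    warning("pathway '", pathway$pathway_id,
            "' has no measured members; skipped", call. = FALSE)
    return(NULL)
  }
  gi <- group_indices(ft)
  p <- med_diff <- numeric(length(members))
  for (j in seq_along(members)) {
    x_nc <- ft$intensities[gi$NC, members[j]]
    x_hfd <- ft$intensities[gi$HFD, members[j]]
    p[j] <- if (length(unique(c(x_nc, x_hfd))) == 1L) 1 else {
      suppressWarnings(stats::wilcox.test(x_nc, x_hfd)$p.value)
    }
    med_diff[j] <- stats::median(x_hfd) - stats::median(x_nc)
  }
  padj <- if (bh_family == "pathway") stats::p.adjust(p, method = "BH") else p
  sig <- padj < alpha
  n_inc <- sum(sig & med_diff > 0)
  n_dec <- sum(sig & med_diff < 0)
  data.frame(pathway_id = pathway$pathway_id,
             pathway_name = pathway$pathway_name,
             n_measured = length(members), n_increased = n_inc,
             n_decreased = n_dec,
             da_score = (n_inc - n_dec) / length(members),
             stringsAsFactors = FALSE)
}

#' Combined pathway analysis: enrichment plus DA scores
#'
#' Convenience wrapper producing one row per pathway with both the
#' over-representation fields and the DA-score fields, ready for a bubble
#' plot (pathway, -log10 p, member count, DA score).
#'
#' @inheritParams enrich_pathways
#' @param ft the `feature_table` the DA scores are computed on.
#' @param alpha DA-score significance cut-off.
#' @return data frame of pathway results.
#' @export
pathway_analysis <- function(differential_ids, background_ids, pathways, ft,
                             alpha = 0.05) {
  enr <- enrich_pathways(differential_ids, background_ids, pathways)
  das <- do.call(rbind, lapply(pathways, function(pw) {
    suppressWarnings(da_score(pw, ft, alpha = alpha))
  }))
  out <- merge(enr, das[, c("pathway_id", "n_measured", "n_increased",
                            "n_decreased", "da_score")],
               by = "pathway_id", all.x = TRUE)
  out$neg_log10_p <- -log10(out$enrichment_p)
  out[order(out$enrichment_p), , drop = FALSE]
}
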