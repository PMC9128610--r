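#' Pathway-level longitudinal trajectories
#'
#' Summarizes each pathway as one value per time point so its temporal trend
#' can be clustered. Every metabolite is first z-score transformed across
#' *all* samples of *all* time points (shared scaling, so levels are
#' comparable over time), then the pathway's value at a time point is the
#' mean member z-score over the chosen group's samples at that time point.
#' The alternative `mode = "dascore"` uses the per-time-point DA score
#' instead.
#'
#' @param tables named list of `feature_table`s, one per time point (names =
#'   weeks, e.g. `"0"`, `"12"`, `"24"`), same metabolite columns throughout.
#' @param pathways list of `pathway_set`; pathways with no measured member
#'   are excluded with a warning.
#' @param group group whose samples define the trajectory (default `"HFD"`).
#' @param mode `"zscore"` (default) or `"dascore"`.
#' @param denominator z-score denominator convention, see [zscore_profile()].
#' @param alpha DA-score significance cut-off (mode `"dascore"` only).
#' @return numeric matrix, rows = pathways (rownames = pathway IDs),
#'   columns = time points in the order given.
#' @export
pathway_trajectories <- function(tables, pathways, group = "HFD",
                                 mode = c("zscore", "dascore"),
                                 denominator = c("variance", "sd"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  stopifnot(length(tables) >= 2)
  mets <- colnames(tables[[1]]$intensities)
  for (tb in tables) {
    if (!identical(colnames(tb$intensities), mets)) {
      stop("all time points must share the same metabolite columns",
           call. = FALSE)
    }
  }
  if (mode == "dascore") {
    rows <- lapply(pathways, function(pw) {
      vals <- vapply(tables, function(tb) {
        d <- suppressWarnings(da_score(pw, tb, alpha = alpha))
        if (is.null(d)) NA_real_ else d$da_score
      }, numeric(1))
      vals
    })
  } else {
    pooled <- do.call(rbind, lapply(tables, function(tb) tb$intensities))
    z <- apply(pooled, 2, zscore_profile, denominator = denominator)
    offsets <- c(0, cumsum(vapply(tables, function(tb)
      nrow(tb$intensities), numeric(1))))
    rows <- lapply(pathways, function(pw) {
      members <- intersect(pw$members, mets)
      if (!length(members)) return(rep(NA_real_, length(tables)))
      vapply(seq_along(tables), function(i) {
        sel <- offsets[i] + which(tables[[i]]$group == group)
        mean(z[sel, members, drop = FALSE])
      }, numeric(1))
    })
  }
  prof <- do.call(rbind, rows)
  rownames(prof) <- vapply(pathways, `[[`, character(1), "pathway_id")
  colnames(prof) <- names(tables)
  drop_rows <- apply(prof, 1, function(v) any(!is.finite(v)))
  if (any(drop_rows)) {
    warning(sum(drop_rows), " pathway(s) not measured at every time point; ",
            "excluded", call. = FALSE)
    prof <- prof[!drop_rows, , drop = FALSE]
  }
  prof
}

#' K-means clustering of pathway trajectories with monotone-cluster selection
#'
#' Partitions the trajectory profiles into `k` clusters by K-means (seeded,
#' best of `restarts` random starts by within-cluster sum of squares) and
#' flags clusters whose centroid is *strictly* increasing across all time
#' points as `monotone_up`, strictly decreasing as `monotone_down`. Strict —
#' not weak — monotonicity is used deliberately: with three time points, weak
#' monotonicity would flag essentially flat centroids.
#'
#' @param profiles trajectory matrix from [pathway_trajectories()].
#' @param k number of clusters (default 8).
#' @param seed RNG seed for the restarts.
#' @param restarts random restarts (default 50).
#' @return object of class `trend_clusters`: `assignments` (named cluster id
#'   per pathway), `centroids` (k x time matrix), `monotone_up`,
#'   `monotone_down` (cluster id vectors), `inertia`, `restart_inertias`.
#' @export
cluster_trends <- function(profiles, k = 8, seed = 1L, restarts = 50) {
  if (nrow(profiles) < k) {
    stop("fewer profiles (", nrow(profiles), ") than clusters (", k,
         "); use a smaller k", call. = FALSE)
  }
  k_eff <- min(k, nrow(unique(profiles)))
  best <- NULL
  inertias <- numeric(restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      km <- stats::kmeans(profiles, centers = k_eff, nstart = 1,
                          iter.max = 100)
      inertias[r] <- km$tot.withinss
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  cent <- best$centers
  mono_up <- which(apply(cent, 1, function(v) all(diff(v) > 0)))
  mono_down <- which(apply(cent, 1, function(v) all(diff(v) < 0)))
  structure(list(
    assignments = stats::setNames(best$cluster, rownames(profiles)),
    centroids = cent,
    monotone_up = as.integer(mono_up),
    monotone_down = as.integer(mono_down),
    inertia = best$tot.withinss,
    restart_inertias = inertias,
    k = k_eff
  ), class = "trend_clusters")
}

#' @export
print.trend_clusters <- function(x, ...) {
  cat(sprintf(
    "<trend_clusters> k = %d over %d pathways; monotone up: %s; down: %s\n",
    x$k, length(x$assignments),
    if (length(x$monotone_up)) paste(x$monotone_up, collapse = ",") else "none",
    if (length(x$monotone_down)) paste(x$monotone_down, collapse = ",") else "none"))
  invisible(x)
}

#' Pathways assigned to monotone clusters
#'
#' @param tc a `trend_clusters` object.
#' @return list with character vectors `up` and `down` of pathway IDs whose
#'   cluster centroid rises (falls) strictly across all time points.
#' @export
monotone_pathways <- function(tc) {
  list(up = names(tc$assignments)[tc$assignments %in% tc$monotone_up],
       down = names(tc$assignments)[tc$assignments %in% tc$monotone_down])
}
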