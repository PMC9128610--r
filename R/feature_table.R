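#' Construct a feature table
#'
#' A feature table holds a dense samples x metabolites matrix of non-negative
#' peak intensities together with the sample metadata the downstream analysis
#' needs: group membership (NC vs HFD), biofluid, electrospray ion mode, and
#' the sampling time point in weeks.
#'
#' @param intensities numeric matrix, rows = samples, columns = metabolites;
#'   must be non-negative and finite, with unique row and column names.
#' @param group character vector of per-sample group labels, one of
#'   `"NC"`/`"HFD"`, aligned with the rows of `intensities`.
#' @param fluid `"plasma"` or `"urine"`.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param time_point_weeks integer time point (0, 12 or 24 in the study design,
#'   but any non-negative integer is accepted).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, group, fluid, ion_mode,
                          time_point_weeks) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("`intensities` must carry sample row names and metabolite column names",
         call. = FALSE)
  }
  ft <- structure(
    list(
      sample_ids = rownames(intensities),
      group = as.character(group),
      fluid = match.arg(fluid, c("plasma", "urine")),
      ion_mode = match.arg(ion_mode, c("positive", "negative")),
      time_point_weeks = as.integer(time_point_weeks),
      intensities = intensities
    ),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

#' Validate a feature table
#'
#' Checks the structural invariants: unique sample and metabolite identifiers,
#' metadata aligned with the matrix, and all intensities finite and
#' non-negative. Missing values are rejected outright; the upstream
#' peak-extraction pipeline this format models emits complete matrices, so a
#' hole is a data error, not something to impute.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly, if valid; otherwise an error of class
#'   `metaboflow_format_error`.
#' @export
validate_feature_table <- function(ft) {
  ids <- ft$sample_ids
  mets <- colnames(ft$intensities)
  if (anyDuplicated(ids)) {
    format_error("duplicate sample IDs: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(mets)) {
    format_error("duplicate metabolite IDs: ",
                 paste(unique(mets[duplicated(mets)]), collapse = ", "))
  }
  if (length(ft$group) != length(ids)) {
    format_error("group vector length (", length(ft$group),
                 ") does not match sample count (", length(ids), ")")
  }
  bad <- !is.finite(ft$intensities) | ft$intensities < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    format_error("non-finite or negative intensity at sample '",
                 ids[idx[1]], "', metabolite '", mets[idx[2]], "'")
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %s / %s mode / week %d: %d samples x %d metabolites (%s)\n",
    x$fluid, x$ion_mode, x$time_point_weeks,
    nrow(x$intensities), ncol(x$intensities),
    paste(sprintf("%s n=%d", names(table(x$group)), table(x$group)),
          collapse = ", ")))
  invisible(x)
}

#' Group membership indices of a feature table
#' @param ft a `feature_table`.
#' @return named list with integer indices `NC` and `HFD`.
#' @keywords internal
group_indices <- function(ft) {
  list(NC = which(ft$group == "NC"), HFD = which(ft$group == "HFD"))
}

format_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("metaboflow_format_error", "error")))
}

spec_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("metaboflow_spec_error", "error")))
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

#' Read a feature table from delimited text
#'
#' Expected layout: header row, first column `sample_id`, second column
#' `group`, remaining columns one metabolite each. The delimiter (TAB or
#' comma) is sniffed from the first line unless given explicitly.
#'
#' @param path file path.
#' @param fluid,ion_mode,time_point_weeks sample metadata (not encoded in the
#'   file; explicit beats filename conventions).
#' @param delim optional explicit delimiter override.
#' @return a `feature_table`; column order of the file is preserved.
#' @export
read_feature_table <- function(path, fluid, ion_mode, time_point_weeks,
                               delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 3L) format_error("feature table needs sample_id, group and ",
                                  "at least one metabolite column")
  mets <- colnames(df)[-(1:2)]
  if (anyDuplicated(mets)) {
    format_error("duplicate metabolite column(s): ",
                 paste(unique(mets[duplicated(mets)]), collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(mets),
                dimnames = list(df[[1]], mets))
  for (j in seq_along(mets)) {
    v <- suppressWarnings(as.numeric(df[[j + 2L]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      format_error("non-numeric or missing intensity at sample '",
                   df[[1]][bad[1]], "', metabolite '", mets[j], "'")
    }
    mat[, j] <- v
  }
  feature_table(mat, group = df[[2]], fluid = fluid, ion_mode = ion_mode,
                time_point_weeks = time_point_weeks)
}

#' Write a feature table as TSV
#'
#' Numeric values are serialized with 17 significant digits so that a
#' write/read round trip reproduces the matrix bit-exactly.
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(sample_id = ft$sample_ids, group = ft$group,
                   check.names = FALSE, stringsAsFactors = FALSE)
  num <- as.data.frame(apply(ft$intensities, 2, num_to_chr),
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(cbind(df, num), path)
}

num_to_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_tsv_raw <- function(df, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a stage's result records as TSV
#'
#' Generic writer used by every pipeline stage: stable column order (the
#' data frame's own), full-precision floats, missing optional fields as empty
#' cells. An empty record set yields a header-only file.
#'
#' @param records a data frame of result records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- num_to_chr(out[[j]])
    }
  }
  write_tsv_raw(out, path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path file path.
#' @param delim optional delimiter override (sniffed otherwise).
#' @return data frame with type-converted columns.
#' @export
read_results <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}
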