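#' Construct a metabolite annotation table
#'
#' Carries, per metabolite identifier, its compound name, HMDB-style origin
#' (endogenous / exogenous / unknown) and optional chemical superclass. The
#' identifier-to-name mapping is what lets the pipeline merge ion modes and
#' match metabolites across biofluids.
#'
#' @param metabolite_id unique identifiers.
#' @param name compound names.
#' @param origin one of `"endogenous"`, `"exogenous"`, `"unknown"`.
#' @param superclass chemical taxonomy label or `NA`.
#' @return data frame of class `annotation_table`.
#' @export
annotation_table <- function(metabolite_id, name, origin,
                             superclass = NA_character_) {
  origin <- as.character(origin)
  bad <- setdiff(unique(origin), c("endogenous", "exogenous", "unknown"))
  if (length(bad)) {
    format_error("invalid origin value(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(metabolite_id)) {
    format_error("duplicate metabolite_id in annotation table")
  }
  structure(
    data.frame(metabolite_id = as.character(metabolite_id),
               name = as.character(name), origin = origin,
               superclass = as.character(superclass),
               stringsAsFactors = FALSE),
    class = c("annotation_table", "data.frame"))
}

#' Read an annotation table (TSV/CSV)
#'
#' Columns: `metabolite_id`, `name`, `origin`, `superclass` (optional).
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return an `annotation_table`.
#' @export
read_annotation_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("metabolite_id", "name", "origin")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) format_error("annotation table missing column(s): ",
                                 paste(miss, collapse = ", "))
  sc <- if ("superclass" %in% colnames(df)) df$superclass else NA_character_
  annotation_table(df$metabolite_id, df$name, df$origin, sc)
}

#' Read pathway membership sets from a GMT-like file
#'
#' One pathway per line: `pathway_id TAB pathway_name TAB member TAB member...`
#' Duplicate members within a line are deduplicated; empty lines skipped.
#'
#' @param path file path.
#' @return list of pathway sets, each a list with `pathway_id`,
#'   `pathway_name`, `members` (character vector of unique metabolite IDs).
#' @export
read_pathway_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      format_error("GMT line ", i, " has fewer than 3 fields")
    }
    out[[i]] <- pathway_set(f[1], f[2], f[-(1:2)])
  }
  out
}

#' Construct a pathway set
#' @param pathway_id,pathway_name identifiers.
#' @param members metabolite IDs (deduplicated; may include IDs absent from a
#'   given feature table).
#' @return list of class `pathway_set`.
#' @export
pathway_set <- function(pathway_id, pathway_name, members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (!length(members)) format_error("pathway '", pathway_id, "' has no members")
  structure(list(pathway_id = as.character(pathway_id),
                 pathway_name = as.character(pathway_name),
                 members = members),
            class = "pathway_set")
}

#' Write pathway sets as GMT
#' @param pathways list of `pathway_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_sets <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    paste(c(p$pathway_id, p$pathway_name, p$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a phenotype table
#'
#' Per-animal phenotype measurements (body metrics, blood counts, serum
#' biochemistry) with a category per variable, used for metabolite-phenotype
#' correlation and the multi-phenotype intersection.
#'
#' @param sample_ids sample labels, aligned with a feature table.
#' @param values numeric matrix, rows = samples, columns = phenotype
#'   variables.
#' @param category per-variable category, one of `"physical"`,
#'   `"blood_routine"`, `"serum_biochemistry"`.
#' @return object of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_ids, values, category) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (length(category) != ncol(values)) {
    format_error("one category per phenotype variable required")
  }
  bad <- setdiff(unique(category),
                 c("physical", "blood_routine", "serum_biochemistry"))
  if (length(bad)) format_error("invalid phenotype category: ",
                                paste(bad, collapse = ", "))
  if (any(apply(values, 2, function(v) all(is.na(v))))) {
    format_error("phenotype table has an all-missing variable")
  }
  rownames(values) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), values = values,
                 category = stats::setNames(as.character(category),
                                            colnames(values))),
            class = "phenotype_table")
}

#' Read a phenotype table
#'
#' TSV/CSV keyed by `sample_id`; a leading header line of the form
#' `#category<TAB>-<TAB>cat1<TAB>cat2...` assigns categories, otherwise all
#' variables default to `"physical"`.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return a `phenotype_table`.
#' @export
read_phenotype_table <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  lines <- readLines(path)
  cat_line <- startsWith(lines, "#category")
  df <- utils::read.table(text = lines[!cat_line], sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  category <- rep("physical", ncol(vals))
  if (any(cat_line)) {
    f <- strsplit(lines[which(cat_line)[1]], delim, fixed = TRUE)[[1]]
    category <- f[-(1:2)]
  }
  phenotype_table(df[[1]], vals, category)
}

#' Write a phenotype table as TSV
#' @param pt a `phenotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(pt, path) {
  hdr <- paste(c("#category", "-", unname(pt$category)), collapse = "\t")
  df <- data.frame(sample_id = pt$sample_ids,
                   apply(pt$values, 2, num_to_chr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the workflow with the defaults the
#' analysis uses throughout: the VIP > 1 and P < 0.05 screening rule, the
#' |r| > 0.4 cross-fluid flag, 200 permutations, 7-fold cross-validation,
#' 8 K-means clusters, and the z-score denominator convention.
#'
#' @param vip_threshold VIP cut-off for screening (default 1).
#' @param p_threshold univariate P cut-off (default 0.05).
#' @param cross_fluid_r_threshold |Pearson r| cut-off for the cross-fluid
#'   correlation flag (default 0.4).
#' @param n_permutations label permutations for model validation (default 200).
#' @param cv_folds cross-validation folds for Q2 (default 7).
#' @param kmeans_k number of trajectory clusters (default 8).
#' @param zscore_denominator `"variance"` (the study's printed formula) or
#'   `"sd"` (the conventional z-score).
#' @param rng_seed integer seed driving all stochastic steps.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(vip_threshold = 1, p_threshold = 0.05,
                            cross_fluid_r_threshold = 0.4,
                            n_permutations = 200, cv_folds = 7,
                            kmeans_k = 8,
                            zscore_denominator = c("variance", "sd"),
                            rng_seed = 1L) {
  zscore_denominator <- match.arg(zscore_denominator)
  if (vip_threshold <= 0 || p_threshold <= 0 || cross_fluid_r_threshold <= 0) {
    spec_error("thresholds must be positive")
  }
  if (cv_folds < 2) spec_error("cv_folds must be >= 2")
  if (kmeans_k < 2) spec_error("kmeans_k must be >= 2")
  structure(list(vip_threshold = vip_threshold, p_threshold = p_threshold,
                 cross_fluid_r_threshold = cross_fluid_r_threshold,
                 n_permutations = as.integer(n_permutations),
                 cv_folds = as.integer(cv_folds),
                 kmeans_k = as.integer(kmeans_k),
                 zscore_denominator = zscore_denominator,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}
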