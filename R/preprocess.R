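#' Sum-normalize a feature table
#'
#' Rescales every sample row so its intensities sum to 1, removing gross
#' per-sample loading differences while preserving relative abundances within
#' each sample. Idempotent: normalizing an already-normalized matrix is a
#' no-op.
#'
#' @param ft a `feature_table`, or a bare numeric matrix (rows = samples).
#' @return object of class `scaled_matrix`: the normalized matrix plus the
#'   method tag and the row totals used.
#' @export
sum_normalize <- function(ft) {
  mat <- if (inherits(ft, "feature_table")) ft$intensities else ft
  totals <- rowSums(mat)
  zero <- which(totals <= 0)
  if (length(zero)) {
    stop("sample '", rownames(mat)[zero[1]],
         "' has zero total intensity; cannot sum-normalize", call. = FALSE)
  }
  scaled_matrix(mat / totals, method = "sum_norm",
                params = list(row_totals = totals))
}

#' Pareto-scale a matrix
#'
#' Centers each feature column to mean zero and divides by the square root of
#' its sample standard deviation — the intermediate between no scaling and
#' unit-variance scaling that is standard for LC-MS intensity data, damping
#' high-abundance features without inflating pure noise. Constant columns are
#' mapped to all-zeros with a warning rather than dividing by zero.
#'
#' @param x numeric matrix (rows = samples) or a `scaled_matrix`.
#' @return a `scaled_matrix` with per-feature `center` and `scale` stored so
#'   the transform is reproducible.
#' @export
pareto_scale <- function(x) {
  mat <- if (inherits(x, "scaled_matrix")) x$matrix else x
  if (nrow(mat) < 2) stop("Pareto scaling needs >= 2 samples", call. = FALSE)
  ctr <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)   # sample SD (n-1)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) mapped to zero under Pareto ",
            "scaling", call. = FALSE)
  }
  scl <- sqrt(sds)
  scl[const] <- 1
  out <- sweep(mat, 2, ctr, "-")
  out <- sweep(out, 2, scl, "/")
  out[, const] <- 0
  scaled_matrix(out, method = "pareto", params = list(center = ctr,
                                                      scale = scl))
}

#' Z-score profile transform
#'
#' Centers a vector and divides by its spread. The default denominator is the
#' sample *variance*, reproducing the transform as this workflow defines it
#' for pathway-profile normalization; `denominator = "sd"` gives the
#' conventional standard-deviation z-score. Sample (n-1) estimators are used
#' in both cases.
#'
#' @param values numeric vector of length >= 2.
#' @param denominator `"variance"` (default) or `"sd"`.
#' @return transformed numeric vector.
#' @export
zscore_profile <- function(values, denominator = c("variance", "sd")) {
  denominator <- match.arg(denominator)
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  v <- stats::var(values)
  if (!is.finite(v) || v == 0) {
    stop("zero or undefined spread; z-score profile undefined", call. = FALSE)
  }
  den <- if (denominator == "variance") v else sqrt(v)
  (values - mean(values)) / den
}

#' Construct a scaled-matrix container
#' @param matrix numeric matrix.
#' @param method one of `"sum_norm"`, `"pareto"`, `"zscore"`.
#' @param params transform parameters sufficient to re-apply it.
#' @return object of class `scaled_matrix`.
#' @export
scaled_matrix <- function(matrix, method, params = list()) {
  stopifnot(method %in% c("sum_norm", "pareto", "zscore"))
  structure(list(matrix = matrix, method = method, params = params),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %s: %d x %d\n", x$method, nrow(x$matrix),
              ncol(x$matrix)))
  invisible(x)
}
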