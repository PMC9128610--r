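#' Principal component analysis of a scaled matrix
#'
#' Thin wrapper over the singular-value decomposition of the (already
#' centered, e.g. Pareto-scaled) matrix. Scores are `U %*% D`, loadings the
#' right singular vectors, and the explained-variance fraction of component
#' i is `d_i^2 / sum(d^2)`. A deterministic sign convention is applied: the
#' largest-magnitude element of every loading vector is positive.
#'
#' @param scaled a `scaled_matrix` (column means ~ 0) or numeric matrix.
#' @param n_components number of components to retain.
#' @return object of class `pca_model` with `scores`, `loadings`,
#'   `explained` (fractions for the retained components).
#' @export
fit_pca <- function(scaled, n_components = 2) {
  X <- if (inherits(scaled, "scaled_matrix")) scaled$matrix else scaled
  k <- min(nrow(X), ncol(X))
  if (n_components > k) {
    stop("n_components (", n_components, ") exceeds min(n_samples, n_features)",
         call. = FALSE)
  }
  s <- svd(X)
  expl <- s$d^2 / sum(s$d^2)
  idx <- seq_len(n_components)
  load <- s$v[, idx, drop = FALSE]
  scores <- s$u[, idx, drop = FALSE] %*% diag(s$d[idx], n_components)
  for (j in idx) {
    flip <- sign(load[which.max(abs(load[, j])), j])
    if (flip < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(load) <- colnames(X)
  structure(list(scores = scores, loadings = load, explained = expl[idx],
                 singular_values = s$d),
            class = "pca_model")
}

# ---- O-PLS core -----------------------------------------------------------

#' Encode a two-class label vector as a centered +/-1 response
#' @keywords internal
class_response <- function(labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) {
    stop("exactly two classes required, got ", length(lv), call. = FALSE)
  }
  y <- ifelse(labels == lv[2], 1, -1)
  list(y = y - mean(y), levels = lv, raw = y)
}

# Single-response orthogonal projections to latent structures: strips class-
# orthogonal variation from X component by component, then fits a one-
# component PLS on the deflated matrix. Returns enough to project new data.
opls_core <- function(X, y, n_orthogonal) {
  Xd <- X
  w_ortho <- p_ortho <- t_ortho <- list()
  for (i in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xd, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, tt)) / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break   # nothing orthogonal left to remove
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    w_ortho[[i]] <- wo
    p_ortho[[i]] <- po
    t_ortho[[i]] <- to
  }
  w <- drop(crossprod(Xd, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {          # degenerate: no class-covarying variation at all
    w <- rep(0, ncol(X))
    tt <- rep(0, nrow(X))
    cc <- 0
  } else {
    w <- w / nw
    tt <- drop(Xd %*% w)
    cc <- sum(y * tt) / sum(tt^2)
  }
  list(w = w, t = tt, c = cc,
       p = if (sum(tt^2) > 0) drop(crossprod(Xd, tt)) / sum(tt^2) else w,
       w_ortho = w_ortho, p_ortho = p_ortho, t_ortho = t_ortho,
       deflated = Xd)
}

# Remove the fitted orthogonal components from new observations, then predict
# the centered class response.
opls_predict <- function(fit, Xnew) {
  Xd <- Xnew
  for (i in seq_along(fit$w_ortho)) {
    to <- drop(Xd %*% fit$w_ortho[[i]])
    Xd <- Xd - tcrossprod(to, fit$p_ortho[[i]])
  }
  drop(Xd %*% fit$w) * fit$c
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis for a two-group
#' design: class-orthogonal variation is removed from the (Pareto-scaled)
#' matrix, and a single predictive latent component is fit to the centered
#' +/-1 class response. Model quality is summarized by R2Y (fraction of
#' class-response variance explained) and stratified k-fold cross-validated
#' Q2; per-feature VIP scores quantify each metabolite's contribution to the
#' discrimination.
#'
#' With `n_orthogonal = "auto"`, orthogonal components are added one at a
#' time while cross-validated Q2 improves by at least 0.01, up to a cap of 3.
#'
#' @param scaled a `scaled_matrix` (centered; typically [pareto_scale()]
#'   output) or numeric matrix.
#' @param labels two-level group vector aligned with the rows.
#' @param n_orthogonal `"auto"` or a fixed non-negative integer.
#' @param cv_folds folds for Q2 (default 7, stratified by group).
#' @param seed seed for the fold assignment.
#' @param vip_mode `"predictive"` (VIP on the predictive component only,
#'   default) or `"total"` (all components, SSY-weighted).
#' @return object of class `opls_model`: predictive scores/weights/loadings,
#'   orthogonal scores/loadings, `R2Y`, `Q2`, `vip`, `n_orthogonal`, and
#'   `p_R2Y`/`p_Q2` slots (NA until [permutation_test()] fills them).
#' @export
fit_oplsda <- function(scaled, labels, n_orthogonal = "auto", cv_folds = 7,
                       seed = 1L, vip_mode = c("predictive", "total")) {
  vip_mode <- match.arg(vip_mode)
  X <- if (inherits(scaled, "scaled_matrix")) scaled$matrix else scaled
  resp <- class_response(labels)
  y <- resp$y
  if (stats::sd(y) == 0) stop("constant class vector", call. = FALSE)

  if (identical(n_orthogonal, "auto")) {
    q_prev <- cross_validated_q2(X, labels, folds = cv_folds, seed = seed,
                                 n_orthogonal = 0)
    n_ortho <- 0L
    for (cand in 1:3) {
      q_new <- cross_validated_q2(X, labels, folds = cv_folds, seed = seed,
                                  n_orthogonal = cand)
      if (q_new - q_prev >= 0.01) {
        n_ortho <- cand
        q_prev <- q_new
      } else break
    }
  } else {
    n_ortho <- as.integer(n_orthogonal)
    stopifnot(n_ortho >= 0)
  }

  fit <- opls_core(X, y, n_ortho)
  yhat <- fit$t * fit$c
  r2y <- 1 - sum((y - yhat)^2) / sum(y^2)
  q2 <- cross_validated_q2(X, labels, folds = cv_folds, seed = seed,
                           n_orthogonal = length(fit$w_ortho))

  model <- structure(list(
    weights = stats::setNames(fit$w, colnames(X)),
    loadings = stats::setNames(fit$p, colnames(X)),
    scores = stats::setNames(fit$t, rownames(X)),
    coef_c = fit$c,
    ortho_weights = fit$w_ortho, ortho_loadings = fit$p_ortho,
    ortho_scores = fit$t_ortho,
    n_orthogonal = length(fit$w_ortho),
    R2Y = r2y, Q2 = q2, p_R2Y = NA_real_, p_Q2 = NA_real_,
    y = y, levels = resp$levels, labels = as.character(labels),
    cv_folds = cv_folds, seed = seed, vip_mode = vip_mode,
    feature_ids = colnames(X)
  ), class = "opls_model")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal component(s); R2Y = %.3f, Q2 = %.3f\n",
    x$n_orthogonal, x$R2Y, x$Q2))
  if (!is.na(x$p_Q2)) {
    cat(sprintf("  permutation p: R2Y %.4g, Q2 %.4g\n", x$p_R2Y, x$p_Q2))
  }
  invisible(x)
}

#' Stratified k-fold cross-validated Q2
#'
#' Q2 = 1 - PRESS/TSS, where PRESS accumulates squared held-out prediction
#' errors of the centered class response over stratified folds and TSS is the
#' total sum of squares of that response. Fold assignment is seeded; each
#' fold must retain both classes.
#'
#' @param scaled matrix or `scaled_matrix`.
#' @param labels two-level group vector.
#' @param folds number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @param n_orthogonal orthogonal components in the per-fold refits.
#' @return Q2 (can be negative for uninformative models).
#' @export
cross_validated_q2 <- function(scaled, labels, folds = 7, seed = 1L,
                               n_orthogonal = 0) {
  X <- if (inherits(scaled, "scaled_matrix")) scaled$matrix else scaled
  resp <- class_response(labels)
  y <- resp$y
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  fold_id <- make_stratified_folds(as.character(labels), folds, seed)
  press <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (length(unique(labels[!test])) < 2) {
      stop("fold ", f, " removes an entire class; reduce folds", call. = FALSE)
    }
    ytr <- class_response(labels[!test])
    fit <- opls_core(X[!test, , drop = FALSE], ytr$y, n_orthogonal)
    # held-out samples coded on the training response scale
    ycode <- ifelse(labels[test] == ytr$levels[2], 1, -1)
    ycode <- ycode - mean(ifelse(labels[!test] == ytr$levels[2], 1, -1))
    pred <- opls_predict(fit, X[test, , drop = FALSE])
    press <- press + sum((ycode - pred)^2)
  }
  1 - press / sum(y^2)
}

# Seeded stratified fold assignment; errors if any fold would lack a class.
make_stratified_folds <- function(labels, folds, seed) {
  if (min(table(labels)) < folds) {
    stop("folds (", folds, ") exceeds the smallest group size; a fold would ",
         "lose an entire class — reduce folds", call. = FALSE)
  }
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold_id
}

#' Permutation test of OPLS-DA model quality
#'
#' Group labels are shuffled `n_permutations` times, the model refit each
#' time, and one-sided permutation probabilities computed for R2Y and Q2
#' with the add-one rule `p = (1 + #{perm >= observed}) / (1 + n)`, so p is
#' never exactly zero.
#'
#' @param scaled matrix or `scaled_matrix`.
#' @param labels two-level group vector.
#' @param n_permutations number of shuffles (>= 20).
#' @param seed permutation seed.
#' @param folds,n_orthogonal model settings, as in the observed fit.
#' @return list with `p_R2Y`, `p_Q2`, `observed` (R2Y, Q2) and the
#'   permutation statistic matrix.
#' @export
permutation_test <- function(scaled, labels, n_permutations = 200, seed = 1L,
                             folds = 7, n_orthogonal = 0) {
  if (n_permutations < 20) {
    stop("n_permutations must be >= 20 for usable p-value resolution",
         call. = FALSE)
  }
  X <- if (inherits(scaled, "scaled_matrix")) scaled$matrix else scaled
  stat <- function(lab, s) {
    y <- class_response(lab)$y
    fit <- opls_core(X, y, n_orthogonal)
    r2 <- if (sum(fit$t^2) > 0) {
      1 - sum((y - fit$t * fit$c)^2) / sum(y^2)
    } else 0
    q2 <- cross_validated_q2(X, lab, folds = folds, seed = s,
                             n_orthogonal = n_orthogonal)
    c(R2Y = r2, Q2 = q2)
  }
  obs <- stat(labels, seed)
  perms <- matrix(NA_real_, n_permutations, 2,
                  dimnames = list(NULL, c("R2Y", "Q2")))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perms[b, ] <- stat(sample(labels), seed)
    }
  })
  eps <- 1e-12
  list(p_R2Y = (1 + sum(perms[, 1] >= obs[1] - eps)) / (1 + n_permutations),
       p_Q2 = (1 + sum(perms[, 2] >= obs[2] - eps)) / (1 + n_permutations),
       observed = obs, permuted = perms)
}

#' Variable importance for the projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ) with p
#' the number of features and SSY_a the class-response sum of squares
#' explained by component a. By default only the predictive component enters
#' (mode `"predictive"`); mode `"total"` also includes the orthogonal
#' components with their (near-zero) SSY weights. In either mode the mean of
#' squared VIPs is exactly 1.
#'
#' @param model a fitted `opls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "opls_model")) stop("not a fitted opls_model",
                                           call. = FALSE)
  p <- length(model$weights)
  ssy_of <- function(tt) {
    if (sum(tt^2) == 0) return(0)
    cc <- sum(model$y * tt) / sum(tt^2)
    sum((cc * tt)^2)
  }
  W <- list(model$weights)
  ssy <- ssy_of(model$scores)
  if (identical(model$vip_mode, "total") && model$n_orthogonal > 0) {
    W <- c(W, model$ortho_weights)
    ssy <- c(ssy, vapply(model$ortho_scores, ssy_of, numeric(1)))
  }
  if (sum(ssy) == 0) {               # degenerate, class-uninformative matrix
    return(stats::setNames(rep(0, p), model$feature_ids))
  }
  acc <- 0
  for (a in seq_along(W)) {
    wa <- W[[a]]
    nw2 <- sum(wa^2)
    if (nw2 > 0) acc <- acc + ssy[a] * wa^2 / nw2
  }
  stats::setNames(sqrt(p * acc / sum(ssy)), model$feature_ids)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}
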