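# Shared fixture builders. Everything is generated in code at run time;
# no binary or on-disk fixtures.

# A small two-group feature table with optional multiplicative effects on the
# first `n_effect` features (HFD intensities multiplied by `fold`).
make_ft <- function(n_per_group = 6, n_features = 20, n_effect = 0,
                    fold = 3, seed = 42, fluid = "plasma",
                    ion_mode = "positive", week = 24) {
  metaboflow:::with_seed(seed, {
    n <- 2 * n_per_group
    mat <- matrix(exp(rnorm(n * n_features, 8, 0.4)), n, n_features,
                  dimnames = list(sprintf("s%02d", seq_len(n)),
                                  sprintf("m%03d", seq_len(n_features))))
    if (n_effect > 0) {
      hfd <- seq_len(n_per_group) + n_per_group
      mat[hfd, seq_len(n_effect)] <- mat[hfd, seq_len(n_effect)] * fold
    }
    feature_table(mat,
                  group = rep(c("NC", "HFD"), each = n_per_group),
                  fluid = fluid, ion_mode = ion_mode,
                  time_point_weeks = week)
  })
}

# A compact simulated study for integration-level tests.
small_spec <- function(seed = 1, ...) {
  simulation_spec(n_per_group = 9,
                  n_features = c(plasma = 60, urine = 50), n_shared = 20,
                  n_concordant_up = 2, n_concordant_down = 2, n_discordant = 1,
                  n_trend_up = 2, n_trend_down = 2, n_pathways = 8,
                  pathway_size_range = c(3, 10), rng_seed = seed, ...)
}

# Step-up Benjamini-Hochberg, written independently of stats::p.adjust:
# sort ascending, multiply by N / rank, enforce monotonicity from the largest
# p downwards, undo the sort.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exhaustive hypergeometric tail: over every size-n subset of the background,
# the fraction containing at least k pathway members.
exhaustive_tail <- function(background, pathway_members, n, k) {
  draws <- utils::combn(background, n)
  hits <- apply(draws, 2, function(d) sum(d %in% pathway_members) >= k)
  mean(hits)
}

# Power iteration for the dominant eigenvector of a symmetric PSD matrix.
power_iteration <- function(M, iters = 500, tol = 1e-12) {
  v <- rep(1, ncol(M)) / sqrt(ncol(M))
  for (i in seq_len(iters)) {
    v_new <- drop(M %*% v)
    v_new <- v_new / sqrt(sum(v_new^2))
    if (sum((v_new - v)^2) < tol^2) break
    v <- v_new
  }
  v_new
}
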