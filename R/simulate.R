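#' Specification of a synthetic two-group metabolomics study
#'
#' Describes the full statistical structure a synthetic study should carry:
#' study geometry (two groups of 9 animals; ~1300 plasma and ~1900 urine
#' features in two electrospray modes; three time points), log-normal
#' intensities, a designated fraction of truly differential metabolites with
#' multiplicative group effects, pathway structure with monotone time trends,
#' endogenous/exogenous annotation, phenotypes built to hit target
#' correlations, and a shared plasma-urine metabolite subset with prescribed
#' concordance classes. Defaults reproduce the geometry of the canine
#' high-fat-diet study design this workflow targets.
#'
#' @param n_per_group animals per group (default 9).
#' @param n_features named vector `c(plasma = , urine = )` of feature counts
#'   per fluid, split across ion modes.
#' @param frac_positive_mode fraction of each fluid's features acquired in
#'   positive mode (default 0.5).
#' @param mode_overlap_frac fraction of metabolites detected in *both* modes
#'   (default 0.03), to exercise ion-mode merging.
#' @param frac_differential fraction of each fluid's features with a true
#'   group effect (default 0.12).
#' @param effect_log_mean,effect_log_sd log-normal parameters of the
#'   multiplicative group fold change for true positives (defaults log(2)
#'   and 0.25, i.e. typical fold ~2).
#' @param base_intensity_log_mean,base_intensity_log_sd across-feature
#'   spread of baseline log-intensities (defaults 10 and 0.5). The spread is
#'   deliberately moderate: it emulates the mid-abundance bulk of a feature
#'   table, where VIP-based screening operates, and keeps any single peak
#'   from dominating the summed signal that sum-normalization divides by.
#' @param within_sample_log_sd within-feature, across-sample biological plus
#'   technical noise on the log scale (default 0.3, ~30% CV, typical of
#'   QC-corrected LC-MS intensities).
#' @param n_pathways,pathway_size_range pathway count and member-count range
#'   (defaults 40 and 3-50).
#' @param frac_endogenous fraction of metabolites annotated endogenous
#'   (default 0.85).
#' @param time_points sampling weeks (default 0, 12, 24); group effects act
#'   at weeks > 0, the first time point is baseline.
#' @param n_trend_up,n_trend_down pathways given a strictly monotone
#'   multiplicative drift in the HFD arm across time points (defaults 4 + 4).
#' @param trend_fold_per_step drift fold per time step (default 1.5).
#' @param n_shared metabolites present in both fluids (default 540).
#' @param n_concordant_up,n_concordant_down,n_discordant shared metabolites
#'   with prescribed cross-fluid direction classes (defaults 8, 4, 2).
#' @param cross_fluid_target_r target cross-fluid Pearson correlation of the
#'   class metabolites' abundances (default 0.85); other shared metabolites
#'   are left uncoupled.
#' @param phenotype_spec data frame `phenotype`, `category`, `target_r`
#'   (optionally `metabolite` naming the driving plasma metabolite); `NULL`
#'   builds a default panel of six variables tied to differential
#'   metabolites.
#' @param rng_seed integer seed; the whole study is reproducible from it.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_per_group = 9,
                            n_features = c(plasma = 1295, urine = 1868),
                            frac_positive_mode = 0.5,
                            mode_overlap_frac = 0.03,
                            frac_differential = 0.12,
                            effect_log_mean = log(2), effect_log_sd = 0.25,
                            base_intensity_log_mean = 10,
                            base_intensity_log_sd = 0.5,
                            within_sample_log_sd = 0.3,
                            n_pathways = 40,
                            pathway_size_range = c(3, 50),
                            frac_endogenous = 0.85,
                            time_points = c(0, 12, 24),
                            n_trend_up = 4, n_trend_down = 4,
                            trend_fold_per_step = 1.5,
                            n_shared = 540,
                            n_concordant_up = 8, n_concordant_down = 4,
                            n_discordant = 2,
                            cross_fluid_target_r = 0.85,
                            phenotype_spec = NULL,
                            rng_seed = 1L) {
  spec <- as.list(environment())
  class(spec) <- "simulation_spec"
  fr <- c(frac_positive_mode, mode_overlap_frac, frac_differential,
          frac_endogenous)
  if (any(fr < 0 | fr > 1)) spec_error("fractions must lie in [0, 1]")
  if (n_per_group < 2) spec_error("need >= 2 animals per group")
  if (any(n_features <= 0) || length(n_features) != 2 ||
      !all(c("plasma", "urine") %in% names(n_features))) {
    spec_error("n_features must be positive and named plasma/urine")
  }
  if (n_shared > min(n_features)) {
    spec_error("n_shared exceeds the smaller fluid's feature count")
  }
  n_class <- n_concordant_up + n_concordant_down + n_discordant
  if (n_class > n_shared) {
    spec_error("concordance-class counts exceed the shared-metabolite count")
  }
  n_diff <- round(frac_differential * n_features)
  if (n_class > min(n_diff)) {
    spec_error("concordance-class counts (", n_class, ") exceed the ",
               "differential budget of a fluid (", min(n_diff), ")")
  }
  if (any(n_diff - n_class > n_features - n_shared)) {
    spec_error("differential budget beyond the concordance classes exceeds ",
               "a fluid's exclusive (non-shared) feature count")
  }
  if (trend_fold_per_step <= 1) spec_error("trend_fold_per_step must be > 1")
  spec
}

default_phenotype_spec <- function() {
  data.frame(
    phenotype = c("body_weight", "bmi", "wbc", "lymphocytes", "tc", "tg"),
    category = c("physical", "physical", "blood_routine", "blood_routine",
                 "serum_biochemistry", "serum_biochemistry"),
    target_r = c(0.8, 0.7, 0.6, 0.5, 0.7, 0.6),
    stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study with ground truth
#'
#' Draws every feature table (fluid x ion mode x time point), the annotation
#' table, the pathway sets, per-time-point phenotype tables, and the full
#' ground-truth bookkeeping (differential IDs with signed directions per
#' fluid and time point, trend labels per pathway, concordance class per
#' shared metabolite). Bit-identical under a fixed `rng_seed`.
#'
#' Generative model: log-intensity of metabolite m in sample i at time t is
#' `mu_m + e_it` with `e ~ N(0, within_sample_log_sd)`; true positives gain
#' `+/- log(fold_m)` in the HFD arm at post-baseline time points; members of
#' trend pathways gain `t_index * log(trend_fold_per_step)` (HFD arm);
#' concordance-class metabolites share a per-animal latent across fluids
#' with mixing weight chosen in closed form for the target correlation.
#' Phenotypes are scaled metabolite signals plus Gaussian noise, again with
#' the closed-form mixing weight.
#'
#' @param spec a `simulation_spec`.
#' @return list of class `simulated_study` with elements `tables`
#'   (`tables[[fluid]][[mode]][[week]]`), `annotations`, `pathways`,
#'   `phenotypes` (per week), `truth`, and the `spec`.
#' @export
simulate_study <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$rng_seed, simulate_study_impl(spec))
}

simulate_study_impl <- function(spec) {
  n <- spec$n_per_group
  animals <- sprintf("D%02d", seq_len(2 * n))
  group <- rep(c("NC", "HFD"), each = n)
  fluids <- c("plasma", "urine")
  weeks <- spec$time_points

  ## ---- metabolite universe -------------------------------------------
  n_shared <- spec$n_shared
  shared_names <- sprintf("met_s%04d", seq_len(n_shared))
  only <- lapply(fluids, function(fl) {
    k <- spec$n_features[[fl]] - n_shared
    if (k > 0) sprintf("met_%s%04d", substr(fl, 1, 1), seq_len(k))
    else character()
  })
  names(only) <- fluids
  names_by_fluid <- lapply(fluids, function(fl) c(shared_names, only[[fl]]))
  names(names_by_fluid) <- fluids
  id_of <- function(fl, nm) {
    if (!length(nm)) return(character())
    paste0(toupper(substr(fl, 1, 1)), "_", nm)
  }

  ## ---- truth: concordance classes and differential sets ---------------
  n_class <- spec$n_concordant_up + spec$n_concordant_down + spec$n_discordant
  class_names <- if (n_class > 0) sample(shared_names, n_class) else character()
  class_tbl <- data.frame(
    name = class_names,
    class = rep(c("concordant_up", "concordant_down", "discordant"),
                times = c(spec$n_concordant_up, spec$n_concordant_down,
                          spec$n_discordant)),
    stringsAsFactors = FALSE)
  class_dir <- function(fl, cls) {
    switch(cls,
           concordant_up = "up", concordant_down = "down",
           discordant = if (fl == "plasma") "up" else "down")
  }

  all_names <- unique(unlist(names_by_fluid))
  mu_of_name <- stats::setNames(
    stats::rnorm(length(all_names), spec$base_intensity_log_mean,
                 spec$base_intensity_log_sd), all_names)

  mode_of <- list()
  for (fl in fluids) {
    nmf <- names_by_fluid[[fl]]
    n_pos <- round(spec$frac_positive_mode * length(nmf))
    pos <- sample(nmf, n_pos)
    overlap <- sample(nmf, round(spec$mode_overlap_frac * length(nmf)))
    mode_of[[fl]] <- list(positive = union(pos, overlap),
                          negative = union(setdiff(nmf, pos), overlap))
  }

  n_diff <- round(spec$frac_differential * spec$n_features)
  diff_by_fluid <- list()
  for (fl in fluids) {
    # Fill differentials are drawn from fluid-exclusive names only, so the
    # injected concordance classes are, by construction, the only metabolite
    # names that can be truly differential in more than one fluid and the
    # concordance truth table is complete.
    pool <- setdiff(names_by_fluid[[fl]], shared_names)
    extra <- n_diff[[fl]] - n_class
    fill <- if (extra > 0) sample(pool, extra) else character()
    nm <- c(class_names, fill)
    folds <- exp(stats::rnorm(length(nm), spec$effect_log_mean,
                              spec$effect_log_sd))
    dirs <- c(vapply(class_tbl$class, class_dir, character(1), fl = fl),
              rep(NA_character_, length(fill)))
    # Fill directions are assigned to cancel the expected total-signal shift
    # of the differential effects within each ion-mode table: sum-
    # normalization is applied per mode and presumes the summed signal is
    # group-invariant; an unbalanced injection would smear a spurious
    # compositional shift across every null feature of that mode.
    a <- exp(mu_of_name[nm])
    up_mass <- a * (folds - 1)          # expected raw-mass gain if "up"
    down_mass <- a * (1 - 1 / folds)    # expected raw-mass loss if "down"
    in_mode <- cbind(positive = nm %in% mode_of[[fl]]$positive,
                     negative = nm %in% mode_of[[fl]]$negative)
    bal <- c(positive = 0, negative = 0)
    for (md in c("positive", "negative")) {
      ci <- seq_len(n_class)
      sel <- ci[in_mode[ci, md]]
      bal[md] <- sum(ifelse(dirs[sel] == "up", up_mass[sel],
                            -down_mass[sel]))
    }
    if (length(fill)) {
      for (j in (n_class + order(-a[n_class + seq_along(fill)]))) {
        mds <- colnames(in_mode)[in_mode[j, ]]
        cost_up <- sum(abs(bal[mds] + up_mass[j]))
        cost_down <- sum(abs(bal[mds] - down_mass[j]))
        if (cost_up < cost_down) {
          dirs[j] <- "up"; bal[mds] <- bal[mds] + up_mass[j]
        } else {
          dirs[j] <- "down"; bal[mds] <- bal[mds] - down_mass[j]
        }
      }
    }
    diff_by_fluid[[fl]] <- data.frame(
      name = nm, metabolite_id = id_of(fl, nm), direction = unname(dirs),
      fold = folds, stringsAsFactors = FALSE)
  }

  ## ---- pathways (over names; members stored as per-fluid IDs) ---------
  null_names <- setdiff(unique(unlist(names_by_fluid)),
                        unlist(lapply(diff_by_fluid, `[[`, "name")))
  n_trend <- spec$n_trend_up + spec$n_trend_down
  if (spec$n_pathways < n_trend) {
    spec_error("n_pathways smaller than the number of trend pathways")
  }
  sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
                  spec$n_pathways, replace = TRUE)
  pw_members <- vector("list", spec$n_pathways)
  # trend pathways drawn from null metabolites measured in plasma, the fluid
  # whose longitudinal tables the trajectory analysis runs on
  trend_pool <- intersect(null_names, names_by_fluid$plasma)
  for (i in seq_len(spec$n_pathways)) {
    if (i <= n_trend) {
      sz <- min(sizes[i], length(trend_pool))
      pw_members[[i]] <- sample(trend_pool, sz)
      trend_pool <- setdiff(trend_pool, pw_members[[i]])  # trends disjoint
    } else {
      pw_members[[i]] <- sample(all_names, min(sizes[i], length(all_names)))
    }
  }
  pw_ids <- sprintf("pw%03d", seq_len(spec$n_pathways))
  trend_label <- rep("none", spec$n_pathways)
  if (spec$n_trend_up > 0) trend_label[seq_len(spec$n_trend_up)] <- "up"
  if (spec$n_trend_down > 0) {
    trend_label[spec$n_trend_up + seq_len(spec$n_trend_down)] <- "down"
  }
  pathways <- lapply(seq_len(spec$n_pathways), function(i) {
    members <- unlist(lapply(fluids, function(fl) {
      id_of(fl, intersect(pw_members[[i]], names_by_fluid[[fl]]))
    }))
    pathway_set(pw_ids[i], paste0("Pathway ", i, " (", trend_label[i], ")"),
                members)
  })
  trend_dir_of_name <- stats::setNames(rep(0, length(all_names)), all_names)
  for (i in which(trend_label != "none")) {
    trend_dir_of_name[pw_members[[i]]] <-
      if (trend_label[i] == "up") 1 else -1
  }

  ## ---- annotations ----------------------------------------------------
  superclasses <- c("Lipids and lipid-like molecules",
                    "Organic acids and derivatives",
                    "Organoheterocyclic compounds",
                    "Benzenoids", "Nucleosides and analogues")
  ann_rows <- do.call(rbind, lapply(fluids, function(fl) {
    nm <- names_by_fluid[[fl]]
    data.frame(metabolite_id = id_of(fl, nm), name = nm,
               stringsAsFactors = FALSE)
  }))
  origin_of_name <- stats::setNames(
    sample(c("endogenous", "exogenous"), length(all_names), replace = TRUE,
           prob = c(spec$frac_endogenous, 1 - spec$frac_endogenous)),
    all_names)
  superclass_of_name <- stats::setNames(
    sample(superclasses, length(all_names), replace = TRUE), all_names)
  annotations <- annotation_table(
    ann_rows$metabolite_id, ann_rows$name,
    origin_of_name[ann_rows$name], superclass_of_name[ann_rows$name])

  ## ---- intensities ----------------------------------------------------
  sw <- spec$within_sample_log_sd
  r_t <- spec$cross_fluid_target_r
  coupled <- class_tbl$name
  # per-animal, per-week, per-coupled-metabolite latent shared across fluids
  latent <- list()
  for (w in as.character(weeks)) {
    latent[[w]] <- matrix(stats::rnorm(2 * n * length(coupled)), nrow = 2 * n,
                          ncol = length(coupled),
                          dimnames = list(animals, coupled))
  }

  tables <- list()
  for (fl in fluids) {
    diff_tbl <- diff_by_fluid[[fl]]
    eff_of_name <- stats::setNames(rep(0, length(all_names)), all_names)
    eff_of_name[diff_tbl$name] <-
      ifelse(diff_tbl$direction == "up", 1, -1) * log(diff_tbl$fold)
    tables[[fl]] <- list()
    for (md in c("positive", "negative")) {
      nm <- mode_of[[fl]][[md]]
      tables[[fl]][[md]] <- list()
      for (wi in seq_along(weeks)) {
        w <- as.character(weeks[wi])
        logm <- matrix(stats::rnorm(2 * n * length(nm), 0, sw), 2 * n,
                       length(nm), dimnames = list(animals, nm))
        cp <- intersect(nm, coupled)
        if (length(cp)) {
          # variance-preserving mix: shared latent carries fraction r_t of
          # the within-sample noise variance, so cross-fluid log-scale
          # correlation is r_t while detection power is unchanged
          logm[, cp] <- sqrt(1 - r_t) * logm[, cp, drop = FALSE] +
            sqrt(r_t) * sw * latent[[w]][, cp, drop = FALSE]
        }
        logm <- sweep(logm, 2, mu_of_name[nm], "+")
        hfd <- group == "HFD"
        if (wi > 1) {                         # group effect post-baseline
          logm[hfd, ] <- sweep(logm[hfd, , drop = FALSE], 2,
                               eff_of_name[nm], "+")
        }
        # monotone time drift of trend-pathway members: a shared (both-group)
        # time effect, so it never confounds the two-group contrast
        tr <- trend_dir_of_name[nm] * (wi - 1) * log(spec$trend_fold_per_step)
        logm <- sweep(logm, 2, tr, "+")
        mat <- exp(logm)
        colnames(mat) <- id_of(fl, nm)
        tables[[fl]][[md]][[w]] <- feature_table(
          mat, group = group, fluid = fl, ion_mode = md,
          time_point_weeks = weeks[wi])
      }
    }
  }

  ## ---- phenotypes ----------------------------------------------------
  ph_spec <- spec$phenotype_spec
  if (is.null(ph_spec)) ph_spec <- default_phenotype_spec()
  if (!"metabolite" %in% colnames(ph_spec)) {
    drivers <- diff_by_fluid$plasma$name
    if (length(drivers) < nrow(ph_spec)) {
      drivers <- c(drivers, setdiff(names_by_fluid$plasma, drivers))
    }
    ph_spec$metabolite <- drivers[seq_len(nrow(ph_spec))]
  }
  phenotypes <- list()
  for (w in as.character(weeks)) {
    vals <- matrix(NA_real_, 2 * n, nrow(ph_spec),
                   dimnames = list(animals, ph_spec$phenotype))
    for (q in seq_len(nrow(ph_spec))) {
      id <- id_of("plasma", ph_spec$metabolite[q])
      md <- if (ph_spec$metabolite[q] %in% mode_of$plasma$positive) {
        "positive"
      } else "negative"
      m <- tables$plasma[[md]][[w]]$intensities[, id]
      zm <- as.numeric(scale(m))
      r <- ph_spec$target_r[q]
      vals[, q] <- r * zm + sqrt(1 - r^2) * stats::rnorm(2 * n)
    }
    phenotypes[[w]] <- phenotype_table(animals, vals, ph_spec$category)
  }

  ## ---- truth bookkeeping ---------------------------------------------
  diff_truth <- list()
  for (fl in fluids) {
    diff_truth[[fl]] <- lapply(stats::setNames(as.character(weeks),
                                               as.character(weeks)),
      function(w) {
        if (w == as.character(weeks[1])) {
          diff_by_fluid[[fl]][0, , drop = FALSE]   # baseline: no effects
        } else diff_by_fluid[[fl]]
      })
  }
  concordance_truth <- data.frame(
    name = shared_names,
    class = rep("unclassified", n_shared),
    stringsAsFactors = FALSE)
  concordance_truth$class[match(class_tbl$name, shared_names)] <-
    class_tbl$class

  structure(list(
    tables = tables, annotations = annotations, pathways = pathways,
    phenotypes = phenotypes,
    truth = list(differential = diff_truth,
                 trend = data.frame(pathway_id = pw_ids, label = trend_label,
                                    stringsAsFactors = FALSE),
                 concordance = concordance_truth,
                 phenotype_spec = ph_spec,
                 shared_names = shared_names),
    spec = spec
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> %d+%d animals; plasma %d / urine %d features; %d pathways; weeks %s\n",
    x$spec$n_per_group, x$spec$n_per_group, x$spec$n_features[["plasma"]],
    x$spec$n_features[["urine"]], length(x$pathways),
    paste(x$spec$time_points, collapse = "/")))
  invisible(x)
}

#' Column-bind the two ion-mode tables of one fluid/week
#'
#' Metabolites detected in both modes keep the positive-mode column, so the
#' combined table has unique metabolite IDs.
#'
#' @param study a `simulated_study`.
#' @param fluid,week which table pair to combine.
#' @return a `feature_table` with ion mode `"positive"` (tag of the leading
#'   block).
#' @export
combined_mode_table <- function(study, fluid, week) {
  w <- as.character(week)
  pos <- study$tables[[fluid]][["positive"]][[w]]
  neg <- study$tables[[fluid]][["negative"]][[w]]
  extra <- setdiff(colnames(neg$intensities), colnames(pos$intensities))
  mat <- cbind(pos$intensities, neg$intensities[, extra, drop = FALSE])
  feature_table(mat, group = pos$group, fluid = fluid,
                ion_mode = "positive", time_point_weeks = pos$time_point_weeks)
}

#' Write a simulated study to a fixture directory
#'
#' Emits every feature table, the annotation TSV, the pathway GMT, the
#' phenotype tables and the ground truth (JSON) under `dir`.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fl in names(study$tables)) {
    for (md in names(study$tables[[fl]])) {
      for (w in names(study$tables[[fl]][[md]])) {
        write_feature_table(
          study$tables[[fl]][[md]][[w]],
          file.path(dir, sprintf("features_%s_%s_wk%s.tsv", fl, md, w)))
      }
    }
  }
  write_results(study$annotations, file.path(dir, "annotations.tsv"))
  write_pathway_sets(study$pathways, file.path(dir, "pathways.gmt"))
  for (w in names(study$phenotypes)) {
    write_phenotype_table(study$phenotypes[[w]],
                          file.path(dir, sprintf("phenotypes_wk%s.tsv", w)))
  }
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
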