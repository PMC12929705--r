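# End-to-end orchestration: culture analysis (gating -> traits -> integrated
# phenotype -> per-replicate hypervolumes -> treatment comparisons) and the
# field fingerprint assessment, both deterministic under one master seed.

#' Run the full culture analysis
#'
#' For every treatment x replicate sample: gate the target population on the
#' log10(x+1)-transformed channels by density clustering, back-transform,
#' derive the eight functional traits; then pool all events, log10
#' z-standardise, test per-trait treatment differences (ANOVA), build the
#' treatment-replicate profile matrix and its k-means functional clusters,
#' fit the integrated-phenotype PCA with a permutation test for significant
#' axes, build one KDE hypervolume per replicate in the significant-axis
#' space and tabulate functional richness/evenness/dispersion, compare the
#' indices across treatments (Kruskal-Wallis + Conover-Iman, BH at 0.01),
#' and compute the treatment-level hypervolume Jaccard matrix.
#'
#' @param config a [synth_config()] describing the design, or a list of
#'   [event_table()]s (with `treatment` attributes and one entry per
#'   replicate) via `events`.
#' @param events optional pre-made list of event tables; when `NULL` the
#'   synthetic generator supplies `config$n_replicates` replicates per
#'   treatment.
#' @param n_perm permutations for the axis-significance test.
#' @param q hypervolume quantile threshold.
#' @param n_support support points per hypervolume.
#' @param alpha_pairwise significance threshold of the Conover-Iman flags.
#' @param min_axes lower bound on the number of axes used for hypervolumes
#'   (the first two axes are used even if fewer reach significance).
#' @param output_dir optional directory; when given, tables are written as
#'   CSV and the manifest as JSON.
#' @return object of class `culture_analysis`; see Details for fields.
#' @details Fields: `traits` (pooled unstandardised [trait_matrix()]),
#'   `treatment`/`replicate` per pooled event, `standardization`, `anova`,
#'   `profiles`, `clusters`, `space`, `fd` (one row per replicate),
#'   `kruskal` and `pairwise` (per index), `treatment_hypervolumes`,
#'   `jaccard` (treatment x treatment), `gate_stats`, `manifest`.
#' @export
run_culture_analysis <- function(config, events = NULL, n_perm = 199,
                                 q = 0.95, n_support = NULL,
                                 alpha_pairwise = 0.01, min_axes = 2L,
                                 output_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  treatments <- config$treatments
  if (length(treatments) < 2 || config$n_replicates < 2) {
    stopf("need >= 2 treatments and >= 2 replicates")
  }
  ## stage 1: gate and derive traits per replicate -------------------------
  trait_blocks <- list()
  treat_lab <- character(0); rep_lab <- character(0)
  gate_stats <- list()
  for (tr in treatments) {
    for (rp in seq_len(config$n_replicates)) {
      ev <- if (is.null(events)) {
        generate_culture_events(config, tr, rp)
      } else {
        events[[sprintf("%s_R%d", tr, rp)]]
      }
      if (is.null(ev)) {
        warnf("missing replicate %s R%d; n reported accordingly", tr, rp)
        next
      }
      gated <- tryCatch(
        cluster_events(log_transform(ev)),
        error = function(e) stopf("gating stage failed for %s R%d: %s",
                                  tr, rp, conditionMessage(e)))
      tm <- derive_traits(gated_events_original(gated))
      trait_blocks[[sprintf("%s_R%d", tr, rp)]] <- tm$values
      n_ev <- nrow(tm$values)
      treat_lab <- c(treat_lab, rep(tr, n_ev))
      rep_lab <- c(rep_lab, rep(sprintf("R%d", rp), n_ev))
      gate_stats[[sprintf("%s_R%d", tr, rp)]] <-
        data.frame(treatment = tr, replicate = rp,
                   n_total = nrow(ev$values),
                   n_gated = length(gated$member_index))
    }
  }
  pooled <- trait_matrix(do.call(rbind, trait_blocks),
                         sample_id = "culture_pooled")
  gate_stats <- do.call(rbind, gate_stats)
  rownames(gate_stats) <- NULL

  ## stage 2: standardise, single-trait tests, profiles, clusters ----------
  std <- standardize_traits(pooled)
  anova_tab <- anova_per_trait(std$traits$values, treat_lab)
  profiles <- treatment_profiles(std$traits, treat_lab, rep_lab)
  clusters <- functional_clusters(profiles,
                                  seed = derive_seed(config$seed, 201))

  ## stage 3: integrated phenotype -----------------------------------------
  space <- fit_pca(std$traits)
  sig <- test_axes_significance(std$traits, n_perm = n_perm,
                                seed = derive_seed(config$seed, 202))
  space$significant_axes <- sort(union(seq_len(min(min_axes,
                                                   ncol(space$loadings))),
                                       sig))
  axes <- space$significant_axes
  sc <- space$scores[, axes, drop = FALSE]

  ## stage 4: per-replicate hypervolumes and FD indices --------------------
  fd <- fd_per_replicate(sc, treat_lab, rep_lab, q = q,
                         n_support = n_support,
                         seed = derive_seed(config$seed, 203))

  ## stage 5: treatment comparisons ----------------------------------------
  kruskal <- lapply(c(richness = "richness", evenness = "evenness",
                      dispersion = "dispersion"), function(ix) {
    kruskal_wallis(fd[[ix]], fd$treatment)
  })
  pairwise <- lapply(c(richness = "richness", evenness = "evenness",
                       dispersion = "dispersion"), function(ix) {
    conover_iman(fd[[ix]], fd$treatment, alpha = alpha_pairwise)
  })

  ## stage 6: treatment-level hypervolumes and Jaccard ---------------------
  tr_hvs <- list()
  for (i in seq_along(treatments)) {
    tr <- treatments[i]
    tr_hvs[[tr]] <- build_hypervolume(sc[treat_lab == tr, , drop = FALSE],
                                      q = q, n_support = n_support,
                                      seed = derive_seed(config$seed,
                                                         300 + i))
  }
  jac <- matrix(1, length(treatments), length(treatments),
                dimnames = list(treatments, treatments))
  for (i in seq_along(treatments)) {
    for (j in seq_along(treatments)) {
      if (j > i) {
        jac[i, j] <- jac[j, i] <- hv_jaccard(tr_hvs[[i]], tr_hvs[[j]])
      }
    }
  }

  manifest <- list(package_version = as.character(
                     utils::packageVersion("cytotraits")),
                   seed = config$seed, n_perm = n_perm, q = q,
                   n_support = n_support %||% (500 * length(axes)),
                   axes = axes, alpha_pairwise = alpha_pairwise,
                   n_replicate_groups = nrow(fd),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(list(traits = pooled, treatment = treat_lab,
                        replicate = rep_lab, standardization = std$model,
                        standardized = std$traits, anova = anova_tab,
                        profiles = profiles, clusters = clusters,
                        space = space, fd = fd, kruskal = kruskal,
                        pairwise = pairwise,
                        treatment_hypervolumes = tr_hvs, jaccard = jac,
                        gate_stats = gate_stats, config = config,
                        manifest = manifest),
                   class = "culture_analysis")
  if (!is.null(output_dir)) write_culture_artifacts(out, output_dir)
  out
}

# gated population on transformed scale -> original-scale event table
gated_events_original <- function(gated) {
  ev <- gated_events(gated)
  if (ev$transformed) ev <- back_transform(ev)
  ev
}

#' @export
print.culture_analysis <- function(x, ...) {
  cat(sprintf(
    "culture_analysis: %d treatments, %d FD rows, axes %s (%s var)\n",
    length(unique(x$fd$treatment)), nrow(x$fd),
    paste(x$space$significant_axes, collapse = "+"),
    paste(sprintf("%.1f%%",
                  100 * x$space$variance_fraction[x$space$significant_axes]),
          collapse = "/")))
  invisible(x)
}

write_culture_artifacts <- function(x, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$fd, file.path(output_dir, "fd_indices.csv"), row.names = FALSE)
  write.csv(x$anova, file.path(output_dir, "anova.csv"), row.names = FALSE)
  write.csv(as.data.frame(x$profiles),
            file.path(output_dir, "profiles.csv"))
  write.csv(as.data.frame(x$jaccard), file.path(output_dir, "jaccard.csv"))
  for (ix in names(x$pairwise)) {
    write.csv(x$pairwise[[ix]],
              file.path(output_dir, sprintf("pairwise_%s.csv", ix)),
              row.names = FALSE)
  }
  jsonlite::write_json(x$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' Run the field fingerprint assessment
#'
#' Calibrates the bead size mapping, size-gates each field sample to the
#' 0.5-10 um single-cell fraction, removes debris by density clustering,
#' derives traits, builds the joint culture + field PCA space, places
#' culture treatment centroids and hypervolumes in it, and assigns each
#' field sample to its nearest treatment fingerprint with its TN:light
#' covariate.
#'
#' @param culture a [run_culture_analysis()] result.
#' @param config the [synth_config()] describing the field series (usually
#'   `culture$config`).
#' @param field optional pre-made field series (list of
#'   `list(events, metadata)`), else generated from `config`.
#' @param bead_sizes_um bead diameters for the size calibration.
#' @param lo_um,hi_um size-gate bounds.
#' @param q,n_support hypervolume parameters for the treatment fingerprints.
#' @param output_dir optional artifact directory.
#' @return object of class `field_assessment`: `reports` (one row per field
#'   sample), `space` (joint PCA), `treatment_centroids`,
#'   `gradient_association`, `calibration`.
#' @export
run_field_assessment <- function(culture, config = culture$config,
                                 field = NULL,
                                 bead_sizes_um = c(1, 2, 5, 10),
                                 lo_um = 0.5, hi_um = 10, q = 0.95,
                                 n_support = NULL, output_dir = NULL) {
  if (!inherits(culture, "culture_analysis")) {
    stopf("run the culture analysis first: run_culture_analysis()")
  }
  stopifnot(inherits(config, "synth_config"))
  if (is.null(field)) field <- generate_field_series(config)
  if (length(field) == 0) {
    return(structure(list(reports = data.frame(), space = NULL,
                          treatment_centroids = NULL,
                          gradient_association = NULL),
                     class = "field_assessment"))
  }
  beads <- generate_beads(bead_sizes_um, config)
  cal <- calibrate_size(beads, bead_sizes_um)

  ## gate and derive traits per field sample --------------------------------
  blocks <- list(); sample_lab <- character(0)
  meta_rows <- list()
  for (fs in field) {
    meta <- fs$metadata
    if (is.null(meta) || !all(c("sample_id", "TN", "light") %in% names(meta))) {
      stopf("corrupted metadata for a field sample%s",
            if (!is.null(meta$sample_id)) paste0(" (", meta$sample_id, ")")
            else "")
    }
    sg <- size_gate(fs$events, cal, lo_um, hi_um)
    if (is.null(sg)) next
    sized <- gated_events(sg)
    gated <- cluster_events(log_transform(sized))
    tm <- derive_traits(gated_events_original(gated))
    blocks[[meta$sample_id]] <- tm$values
    sample_lab <- c(sample_lab, rep(meta$sample_id, nrow(tm$values)))
    meta_rows[[meta$sample_id]] <- meta
  }
  field_traits <- trait_matrix(do.call(rbind, blocks),
                               sample_id = "field_pooled")
  metadata <- do.call(rbind, meta_rows)

  ## joint space and treatment fingerprints ---------------------------------
  space <- joint_space(culture$traits, field_traits)
  space$significant_axes <- culture$space$significant_axes
  axes <- space$significant_axes
  is_culture <- space$origin == "culture"
  cul_scores <- space$scores[is_culture, axes, drop = FALSE]
  fld_scores <- space$scores[!is_culture, axes, drop = FALSE]
  tr_centroids <- sample_centroids(
    structure(list(scores = cul_scores,
                   significant_axes = seq_along(axes)),
              class = "phenotype_space"),
    culture$treatment)
  treatments <- config$treatments
  tr_centroids <- tr_centroids[treatments, , drop = FALSE]
  tr_hvs <- list()
  for (i in seq_along(treatments)) {
    tr <- treatments[i]
    tr_hvs[[tr]] <- build_hypervolume(
      cul_scores[culture$treatment == tr, , drop = FALSE], q = q,
      n_support = n_support, seed = derive_seed(config$seed, 400 + i))
  }

  ## per-sample reports ------------------------------------------------------
  reports <- list()
  centroids <- list()
  for (id in rownames(metadata)) {
    sel <- sample_lab == id
    cen <- colMeans(fld_scores[sel, , drop = FALSE])
    centroids[[id]] <- cen
    rep_row <- assign_fingerprint(cen, tr_centroids, tr_hvs,
                                  metadata[id, ], sample_id = id)
    d <- attr(rep_row, "distances")
    for (tr in treatments) rep_row[[paste0("dist_", tr)]] <- unname(d[tr])
    inside <- attr(rep_row, "inside_hypervolume")
    for (tr in treatments) {
      rep_row[[paste0("inside_", tr)]] <- unname(inside[tr])
    }
    reports[[id]] <- as.data.frame(rep_row)
  }
  reports <- do.call(rbind, reports)
  rownames(reports) <- NULL
  cen_mat <- do.call(rbind, centroids)
  assoc <- if (sum(is.finite(reports$gradient_value)) >= 5 &&
               length(unique(reports$gradient_value)) > 1) {
    gradient_association(cen_mat, reports$gradient_value)
  } else {
    NULL
  }
  out <- structure(list(reports = reports, space = space,
                        treatment_centroids = tr_centroids,
                        treatment_hypervolumes = tr_hvs,
                        field_centroids = cen_mat,
                        gradient_association = assoc, calibration = cal,
                        metadata = metadata),
                   class = "field_assessment")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(reports, file.path(output_dir, "fingerprint_reports.csv"),
              row.names = FALSE)
  }
  out
}

#' @export
print.field_assessment <- function(x, ...) {
  cat(sprintf("field_assessment: %d samples; nearest treatments: %s\n",
              nrow(x$reports),
              paste(names(table(x$reports$nearest_treatment)),
                    table(x$reports$nearest_treatment),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
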