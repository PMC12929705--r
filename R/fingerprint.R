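# Joint culture + field trait space and assignment of field samples to
# laboratory-derived treatment fingerprints along the nitrogen:light
# gradient.

#' Joint culture + field phenotype space
#'
#' Standardises the concatenated culture and field trait events (pooled
#' log10 z-model by default, or anchored to a culture-only model) and fits a
#' single PCA; provenance labels distinguish culture from field events.
#'
#' @param culture_traits unstandardised [trait_matrix()] of pooled culture
#'   events.
#' @param field_traits unstandardised [trait_matrix()] of pooled field
#'   events, same trait set; may have zero rows (`NULL`) for the degenerate
#'   culture-only case.
#' @param standardize_mode `"pooled"` (fit the z-model on culture + field
#'   together) or `"culture"` (fit on culture, apply to field unchanged).
#' @return a `phenotype_space` with extra fields `origin` (per-event
#'   `"culture"`/`"field"`), `standardization` (the fitted model).
#' @export
joint_space <- function(culture_traits, field_traits = NULL,
                        standardize_mode = c("pooled", "culture")) {
  standardize_mode <- match.arg(standardize_mode)
  stopifnot(inherits(culture_traits, "trait_matrix"))
  if (culture_traits$standardized) {
    stopf("joint_space expects unstandardised traits")
  }
  if (!is.null(field_traits)) {
    stopifnot(inherits(field_traits, "trait_matrix"))
    if (!identical(colnames(culture_traits$values),
                   colnames(field_traits$values))) {
      stopf("trait-set mismatch between culture and field: %s vs %s",
            paste(colnames(culture_traits$values), collapse = ","),
            paste(colnames(field_traits$values), collapse = ","))
    }
  }
  n_cul <- nrow(culture_traits$values)
  n_fld <- if (is.null(field_traits)) 0L else nrow(field_traits$values)
  pooled_vals <- rbind(culture_traits$values,
                       if (n_fld) field_traits$values)
  pooled <- trait_matrix(pooled_vals, sample_id = "culture+field")
  if (standardize_mode == "pooled") {
    std <- standardize_traits(pooled)
  } else {
    cul_std <- standardize_traits(culture_traits)
    std <- standardize_traits(pooled, model = cul_std$model)
  }
  space <- fit_pca(std$traits)
  space$origin <- rep(c("culture", "field"), c(n_cul, n_fld))
  space$standardization <- std$model
  space$fitted_on <- "culture+field"
  space
}

#' Per-sample centroids in a phenotype space
#'
#' Mean score vector per sample over the significant axes; samples with
#' fewer than `min_events` events are skipped with a warning.
#'
#' @param space a `phenotype_space`.
#' @param grouping per-event sample label (length = rows of `space$scores`).
#' @param min_events smallest sample size retained (default 10; a forced
#'   single-event sample simply returns that event's scores when
#'   `min_events = 1`).
#' @return matrix (samples x significant axes) with sample rownames.
#' @export
sample_centroids <- function(space, grouping, min_events = 10) {
  stopifnot(inherits(space, "phenotype_space"))
  axes <- space$significant_axes
  sc <- space$scores[, axes, drop = FALSE]
  grouping <- factor(grouping)
  sizes <- table(grouping)
  small <- names(sizes)[sizes < min_events]
  if (length(small)) {
    warnf("skipping samples with < %d events: %s", min_events,
          paste(small, collapse = ", "))
  }
  keep <- setdiff(levels(grouping), small)
  cent <- t(vapply(keep, function(k) {
    colMeans(sc[grouping == k, , drop = FALSE])
  }, numeric(length(axes))))
  colnames(cent) <- colnames(space$scores)[axes]
  cent
}

#' Assign a field sample to its nearest treatment fingerprint
#'
#' Euclidean nearest treatment centroid on the significant axes; ties are
#' broken deterministically by treatment label order and flagged. Hypervolume
#' membership (centroid density above each treatment hypervolume's
#' threshold) is reported alongside; the nitrogen:light covariate is
#' TN / light from the metadata when both are available.
#'
#' @param centroid numeric vector, the field sample's centroid.
#' @param treatment_centroids matrix (treatments x axes) with treatment
#'   rownames.
#' @param treatment_hypervolumes optional named list of
#'   [build_hypervolume()] objects in the same space.
#' @param metadata optional one-row data.frame with `TN` and `light`.
#' @param sample_id sample label.
#' @return object of class `fingerprint_report`: a one-row data.frame
#'   `sample_id, nearest_treatment, distance, gradient_value, tie` plus
#'   attributes `distances` and `inside_hypervolume`.
#' @export
assign_fingerprint <- function(centroid, treatment_centroids,
                               treatment_hypervolumes = NULL,
                               metadata = NULL, sample_id = "field") {
  centroid <- as.numeric(centroid)
  tc <- as.matrix(treatment_centroids)
  if (ncol(tc) != length(centroid)) stopf("centroid dimension mismatch")
  dists <- sqrt(rowSums(sweep(tc, 2, centroid)^2))
  o <- order(dists, rownames(tc))
  nearest <- rownames(tc)[o[1]]
  tie <- length(dists) > 1 &&
    isTRUE(all.equal(unname(dists[o[1]]), unname(dists[o[2]])))
  inside <- if (!is.null(treatment_hypervolumes)) {
    vapply(treatment_hypervolumes, function(hv) {
      kde_density(hv, matrix(centroid, nrow = 1)) >= hv$threshold_density
    }, logical(1))
  } else {
    NULL
  }
  gradient_value <- NA_real_
  if (!is.null(metadata) && all(c("TN", "light") %in% names(metadata)) &&
      isTRUE(metadata$light[1] > 0)) {
    gradient_value <- metadata$TN[1] / metadata$light[1]
  }
  rep <- data.frame(sample_id = sample_id, nearest_treatment = nearest,
                    distance = unname(dists[o[1]]),
                    gradient_value = gradient_value, tie = tie)
  attr(rep, "distances") <- dists
  attr(rep, "inside_hypervolume") <- inside
  class(rep) <- c("fingerprint_report", "data.frame")
  rep
}

#' Rank correlation of centroid coordinates with the TN:light gradient
#'
#' Spearman rho and p per significant axis across a field series.
#'
#' @param centroids matrix (samples x axes).
#' @param gradient_values TN:light covariate per sample.
#' @return data.frame `axis, rho, p`; requires >= 5 samples with defined
#'   gradient values; a constant gradient is reported as absent (`NA` rows).
#' @export
gradient_association <- function(centroids, gradient_values) {
  centroids <- as.matrix(centroids)
  ok <- is.finite(gradient_values)
  if (sum(ok) < 5) stopf("need >= 5 samples with gradient values")
  g <- gradient_values[ok]
  cen <- centroids[ok, , drop = FALSE]
  if (length(unique(g)) == 1) {
    return(data.frame(axis = seq_len(ncol(cen)), rho = NA_real_,
                      p = NA_real_))
  }
  res <- lapply(seq_len(ncol(cen)), function(j) {
    ct <- suppressWarnings(cor.test(cen[, j], g, method = "spearman"))
    data.frame(axis = j, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
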