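# Conversion of gated optical channels into the eight functional traits,
# collinearity pruning of candidate optical traits, log10 z-standardisation,
# and per-trait one-way ANOVA across treatments.

#' Canonical functional trait names, in order
#' @return character vector of the eight trait labels.
#' @export
trait_names <- function() {
  c("cell_size", "granularity", "gas_vesicle", "phycocyanin", "pc_per_size",
    "chlorophyll_a", "chla_per_size", "pc_chla")
}

#' Per-event functional trait matrix
#'
#' @param values events x traits numeric matrix with columns named as in
#'   [trait_names()].
#' @param sample_id sample label.
#' @param treatment optional treatment label.
#' @param standardized logical; `TRUE` once log10 z-standardised.
#' @return object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, sample_id = "sample", treatment = NULL,
                         standardized = FALSE) {
  values <- as.matrix(values)
  if (!identical(colnames(values), trait_names())) {
    stopf("trait columns must be exactly: %s",
          paste(trait_names(), collapse = ", "))
  }
  if (!standardized && any(!is.finite(values) | values <= 0)) {
    stopf("unstandardised traits must be finite and positive")
  }
  structure(list(values = values, sample_id = sample_id,
                 treatment = treatment, standardized = isTRUE(standardized)),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix '%s'%s: %d events x %d traits%s\n", x$sample_id,
              if (!is.null(x$treatment)) paste0(" [", x$treatment, "]") else "",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardised)" else ""))
  invisible(x)
}

#' Derive the eight functional traits from gated optical channels
#'
#' Maps scatter and pigment channels to functional traits: cell size (FSC),
#' granularity (SSC), gas-vesicle fraction (cell-volume proxy FSC^beta
#' divided by granularity), phycocyanin (FL670) and chlorophyll-a (FL692)
#' fluorescence per cell, both pigments normalised to size (FL/FSC), and the
#' phycocyanin:chlorophyll-a ratio. Events with a zero in a denominator
#' channel are dropped and counted.
#'
#' @param gated a [gated_population()] (original-scale values) or an
#'   [event_table()].
#' @param volume_exponent exponent beta of the FSC-based cell-volume proxy
#'   in the gas-vesicle trait; default 1 (pure FSC/SSC ratio).
#' @return a [trait_matrix()] with attribute `dropped_events` (count).
#' @export
derive_traits <- function(gated, volume_exponent = 1) {
  ev <- if (inherits(gated, "gated_population")) gated_events(gated) else gated
  stopifnot(inherits(ev, "event_table"))
  if (ev$transformed) {
    stopf("derive_traits expects original-scale values; see back_transform()")
  }
  need <- c("FSC", "SSC", "FL670", "FL692")
  missing <- setdiff(need, ev$channels)
  if (length(missing)) stopf("missing channels: %s",
                             paste(missing, collapse = ", "))
  v <- ev$values[, need, drop = FALSE]
  ok <- rowSums(v <= 0) == 0
  dropped <- sum(!ok)
  if (!any(ok)) stopf("all events dropped (zero-valued channels)")
  v <- v[ok, , drop = FALSE]
  fsc <- v[, "FSC"]; ssc <- v[, "SSC"]
  pc <- v[, "FL670"]; chla <- v[, "FL692"]
  out <- cbind(cell_size = fsc,
               granularity = ssc,
               gas_vesicle = fsc^volume_exponent / ssc,
               phycocyanin = pc,
               pc_per_size = pc / fsc,
               chlorophyll_a = chla,
               chla_per_size = chla / fsc,
               pc_chla = pc / chla)
  tm <- trait_matrix(out, sample_id = ev$sample_id,
                     treatment = attr(gated, "treatment", exact = TRUE))
  attr(tm, "dropped_events") <- dropped
  tm
}

#' Greedy collinearity filter on candidate optical traits
#'
#' Computes absolute Pearson correlations between log10-transformed
#' candidates and greedily resolves each pair exceeding the threshold
#' (strongest pair first) by dropping the member with the larger mean
#' absolute correlation to all other remaining candidates. Members of
#' `keep_list` are never dropped (ecological-relevance override, e.g. keeping
#' both chlorophyll-a and phycocyanin fluorescence despite their strong
#' correlation); a pair of two protected traits is left in place.
#'
#' @param candidates numeric matrix (observations x candidate traits) of
#'   positive values, with column names.
#' @param r_threshold absolute-correlation threshold in (0, 1); default 0.8.
#' @param keep_list labels never to drop.
#' @return character vector of retained column names, in input order.
#' @export
collinearity_filter <- function(candidates, r_threshold = 0.8,
                                keep_list = character()) {
  candidates <- as.matrix(candidates)
  if (ncol(candidates) < 2) stopf("need at least 2 candidate traits")
  if (r_threshold <= 0 || r_threshold >= 1) {
    stopf("r_threshold must be in (0, 1)")
  }
  absent <- setdiff(keep_list, colnames(candidates))
  if (length(absent)) stopf("keep_list entries absent from candidates: %s",
                            paste(absent, collapse = ", "))
  lx <- log10(candidates)
  r <- abs(cor(lx))
  diag(r) <- 0
  retained <- colnames(candidates)
  repeat {
    sub <- r[retained, retained, drop = FALSE]
    sub_pairs <- which(sub > r_threshold, arr.ind = TRUE)
    sub_pairs <- sub_pairs[sub_pairs[, 1] < sub_pairs[, 2], , drop = FALSE]
    if (nrow(sub_pairs) == 0) break
    droppable <- vapply(seq_len(nrow(sub_pairs)), function(i) {
      a <- retained[sub_pairs[i, 1]]; b <- retained[sub_pairs[i, 2]]
      !(a %in% keep_list && b %in% keep_list)
    }, logical(1))
    if (!any(droppable)) break
    sub_pairs <- sub_pairs[droppable, , drop = FALSE]
    top <- sub_pairs[which.max(sub[sub_pairs]), ]
    a <- retained[top[1]]; b <- retained[top[2]]
    drop <- if (a %in% keep_list) b
            else if (b %in% keep_list) a
            else if (mean(sub[a, ]) >= mean(sub[b, ])) a
            else b
    retained <- setdiff(retained, drop)
    if (length(retained) < 2) break
  }
  retained
}

#' Fit or apply the log10 z-standardisation of a trait matrix
#'
#' Each trait is log10-transformed and z-standardised. With `model = NULL`
#' the per-trait mean and population sd (ddof 0, for bitwise reproducibility)
#' are fitted on the input and returned; with a supplied model (e.g. when
#' projecting field traits into a culture-fitted space) they are applied
#' unchanged.
#'
#' @param traits an unstandardised [trait_matrix()].
#' @param model optional `standardization_model` from a previous fit.
#' @return list with elements `traits` (standardised [trait_matrix()]) and
#'   `model` (class `standardization_model`: per-trait `mean` and `sd` on the
#'   log10 scale).
#' @export
standardize_traits <- function(traits, model = NULL) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (traits$standardized) stopf("traits are already standardised")
  lx <- log10(traits$values)
  if (is.null(model)) {
    mu <- colMeans(lx)
    sdv <- apply(lx, 2, pop_sd)
    bad <- names(sdv)[sdv <= 0]
    if (length(bad)) stopf("trait '%s' is constant (sd = 0)", bad[1])
    model <- structure(list(mean = mu, sd = sdv),
                       class = "standardization_model")
  } else {
    stopifnot(inherits(model, "standardization_model"))
    if (any(model$sd <= 0)) stopf("standardization model has sd <= 0")
  }
  z <- sweep(sweep(lx, 2, model$mean), 2, model$sd, "/")
  out <- traits
  out$values <- z
  out$standardized <- TRUE
  list(traits = out, model = model)
}

#' Invert a log10 z-standardisation
#'
#' @param traits a standardised [trait_matrix()].
#' @param model the `standardization_model` used to standardise.
#' @return unstandardised [trait_matrix()] on the original scale.
#' @export
unstandardize_traits <- function(traits, model) {
  stopifnot(inherits(traits, "trait_matrix"),
            inherits(model, "standardization_model"))
  if (!traits$standardized) stopf("traits are not standardised")
  lx <- sweep(sweep(traits$values, 2, model$sd, "*"), 2, model$mean, "+")
  out <- traits
  out$values <- 10^lx
  out$standardized <- FALSE
  out
}

#' One-way ANOVA of each trait across treatments
#'
#' @param values numeric matrix (observations x traits) or a
#'   [trait_matrix()]'s values.
#' @param treatment factor-like treatment label per observation.
#' @return data.frame with one row per trait: `trait, F, p`.
#' @export
anova_per_trait <- function(values, treatment) {
  if (inherits(values, "trait_matrix")) values <- values$values
  values <- as.matrix(values)
  treatment <- factor(treatment)
  if (nlevels(treatment) < 2) stopf("need >= 2 treatment groups")
  if (any(table(treatment) < 2)) stopf("each group needs >= 2 observations")
  res <- lapply(colnames(values), function(tr) {
    fit <- summary(aov(values[, tr] ~ treatment))[[1]]
    data.frame(trait = tr, F = fit[["F value"]][1], p = fit[["Pr(>F)"]][1])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
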