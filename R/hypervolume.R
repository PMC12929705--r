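# Gaussian kernel-density hypervolumes at a probability-mass quantile
# threshold, the kernel functional diversity indices (richness, evenness,
# dispersion) and the n-dimensional Jaccard overlap between hypervolumes.
#
# Construction: a product (axis-aligned) Gaussian KDE with per-dimension
# Silverman bandwidths is thresholded so that the retained high-density
# region holds a fraction `q` (default 95%) of the KDE's probability mass.
# Points sampled from the KDE each carry equal probability mass, so the
# threshold is the (1 - q) quantile of the density evaluated at KDE-drawn
# sample points. KDE samples falling inside the region feed the
# inverse-density volume estimator volume = q * mean(1 / f); the stored
# support points are additionally thinned with probability t / f(x), which
# makes them uniformly distributed inside the region (the constant-density
# representation the downstream indices assume).

#' Per-dimension Silverman bandwidths
#'
#' `h_j = sd_j * (4 / ((d + 2) n))^(1 / (d + 4))`.
#'
#' @param scores numeric matrix (n x d) of PCA scores, n >= 10.
#' @return positive numeric vector of d bandwidths.
#' @export
estimate_bandwidth <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); d <- ncol(scores)
  if (n < 10) stopf("bandwidth estimation needs n >= 10")
  sds <- apply(scores, 2, sd)
  if (any(sds <= 0)) {
    stopf("zero-variance dimension %d", which(sds <= 0)[1])
  }
  sds * (4 / ((d + 2) * n))^(1 / (d + 4))
}

#' KDE density of a hypervolume's kernel at query points
#'
#' @param hv a [build_hypervolume()] object, or a list with `data_points`
#'   and `bandwidths`.
#' @param query numeric matrix (m x d) of query points.
#' @return density values at the query points.
#' @export
kde_density <- function(hv, query) {
  query <- rbind(as.matrix(query))
  .kde_gaussian(query, hv$data_points, hv$bandwidths)
}

# Draw m points from the KDE mixture (pick a data point, add kernel noise).
.kde_sample <- function(data, h, m) {
  n <- nrow(data); d <- ncol(data)
  idx <- sample.int(n, m, replace = TRUE)
  noise <- matrix(rnorm(m * d), nrow = m)
  data[idx, , drop = FALSE] + sweep(noise, 2, h, "*")
}

#' Build a Gaussian-KDE hypervolume
#'
#' @param scores numeric matrix (n x d) of points in trait space (PCA
#'   scores), n >= 10.
#' @param q quantile threshold in (0, 1): the retained region holds this
#'   fraction of the KDE's probability mass (default 0.95).
#' @param n_support number of uniformly distributed support points retained
#'   inside the thresholded region; default `500 * d`.
#' @param seed RNG seed (mandatory: the estimator is stochastic).
#' @param n_threshold KDE sample size used to locate the density threshold
#'   (and the floor of the volume-estimator sample).
#' @param bandwidths optional per-dimension bandwidths; default
#'   [estimate_bandwidth()].
#' @return object of class `hypervolume_kde`: `dims`, `data_points`,
#'   `bandwidths`, `threshold_density`, `support_points` (uniform inside the
#'   region), `support_density` (KDE density at those points), `volume`,
#'   `q`, `seed`.
#' @export
build_hypervolume <- function(scores, q = 0.95, n_support = NULL, seed = 1L,
                              n_threshold = 10000L, bandwidths = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores); d <- ncol(scores)
  if (n < 10) stopf("hypervolume needs n >= 10 points")
  if (q <= 0 || q >= 1) stopf("q must be in (0, 1)")
  if (is.null(n_support)) n_support <- 500L * d
  h <- bandwidths %||% estimate_bandwidth(scores)
  if (length(h) != d || any(h <= 0)) stopf("invalid bandwidths")
  with_seed(seed, {
    # threshold: (1 - q) quantile of density at KDE-drawn points, so that
    # the region {f >= t} holds fraction q of the KDE's probability mass
    thr_pts <- .kde_sample(scores, h, n_threshold)
    thr_dens <- .kde_gaussian(thr_pts, scores, h)
    threshold <- quantile(thr_dens, probs = 1 - q, names = FALSE)
    # in-region KDE samples drive the inverse-density volume estimator;
    # thinning with probability t / f(x) flattens them to uniform support
    inv_dens_sum <- 0; inv_dens_n <- 0
    sup_pts <- matrix(numeric(0), ncol = d)
    sup_dens <- numeric(0)
    take <- function(pts, dens) {
      ok <- dens >= threshold
      inv_dens_sum <<- inv_dens_sum + sum(1 / dens[ok])
      inv_dens_n <<- inv_dens_n + sum(ok)
      thin <- ok & (runif(length(dens)) < threshold / dens)
      sup_pts <<- rbind(sup_pts, pts[thin, , drop = FALSE])
      sup_dens <<- c(sup_dens, dens[thin])
    }
    take(thr_pts, thr_dens)
    proposed <- n_threshold
    acc_rate <- max(nrow(sup_pts), 1) / proposed
    while (nrow(sup_pts) < n_support) {
      batch <- min(50000L,
                   max(2000L, ceiling((n_support - nrow(sup_pts)) / acc_rate)))
      pts <- .kde_sample(scores, h, batch)
      take(pts, .kde_gaussian(pts, scores, h))
      proposed <- proposed + batch
      acc_rate <- max(nrow(sup_pts), 1) / proposed
      if (acc_rate < 1e-4 && proposed > 2e6) {
        stopf("acceptance rate below 1e-4; increase q or the bandwidths")
      }
    }
    keep <- seq_len(n_support)
    volume <- q * inv_dens_sum / inv_dens_n
    structure(list(dims = d, data_points = scores, bandwidths = h,
                   threshold_density = threshold,
                   support_points = sup_pts[keep, , drop = FALSE],
                   support_density = sup_dens[keep], volume = volume, q = q,
                   seed = as.integer(seed)),
              class = "hypervolume_kde")
  })
}

#' @export
print.hypervolume_kde <- function(x, ...) {
  cat(sprintf(
    "hypervolume_kde: d = %d, n = %d, q = %.2f, volume = %.4g (%d support)\n",
    x$dims, nrow(x$data_points), x$q, x$volume, nrow(x$support_points)))
  invisible(x)
}

#' Functional richness (hypervolume size)
#'
#' @param hv a [build_hypervolume()] object.
#' @return the hypervolume's volume, in trait-space units^d.
#' @export
hv_richness <- function(hv) {
  stopifnot(inherits(hv, "hypervolume_kde"))
  hv$volume
}

#' Functional evenness
#'
#' Overlap between the KDE restricted to the thresholded region (normalised
#' to integrate to 1) and the uniform density on that region:
#' `integral of min(f_restricted, u)`, estimated over the support points.
#' 1 means a perfectly regular occupation of the region.
#'
#' @param hv a [build_hypervolume()] object.
#' @return evenness in `[0, 1]`.
#' @export
hv_evenness <- function(hv) {
  stopifnot(inherits(hv, "hypervolume_kde"))
  # support is uniform on the region: integral of min(g, u) with
  # g = f/q (restricted KDE) and u = 1/volume is volume * E[min(g, u)]
  g <- hv$support_density / hv$q
  u <- 1 / hv$volume
  min(1, max(0, hv$volume * mean(pmin(g, u))))
}

#' Functional dispersion
#'
#' Mean Euclidean distance of the support points from their centroid.
#'
#' @param hv a [build_hypervolume()] object.
#' @return nonnegative dispersion in trait-space units.
#' @export
hv_dispersion <- function(hv) {
  stopifnot(inherits(hv, "hypervolume_kde"))
  s <- hv$support_points
  centroid <- colMeans(s)
  mean(sqrt(rowSums(sweep(s, 2, centroid)^2)))
}

#' Jaccard similarity of two hypervolumes
#'
#' Intersection volume estimated symmetrically by Monte-Carlo membership:
#' `vol(A) * frac(A's support inside B)` averaged with
#' `vol(B) * frac(B's support inside A)`; union is
#' `vol(A) + vol(B) - intersection`; the ratio is clipped to `[0, 1]`.
#'
#' @param hv_a,hv_b [build_hypervolume()] objects with equal `dims`.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
hv_jaccard <- function(hv_a, hv_b) {
  stopifnot(inherits(hv_a, "hypervolume_kde"),
            inherits(hv_b, "hypervolume_kde"))
  if (hv_a$dims != hv_b$dims) stopf("hypervolume dimension mismatch")
  in_b <- kde_density(hv_b, hv_a$support_points) >= hv_b$threshold_density
  in_a <- kde_density(hv_a, hv_b$support_points) >= hv_a$threshold_density
  inter <- (hv_a$volume * mean(in_b) + hv_b$volume * mean(in_a)) / 2
  union <- hv_a$volume + hv_b$volume - inter
  if (union <= 0) return(1)
  min(1, max(0, inter / union))
}

#' Functional diversity indices of one hypervolume
#'
#' @param hv a [build_hypervolume()] object.
#' @return data.frame with columns `richness, evenness, dispersion`.
#' @export
fd_indices <- function(hv) {
  data.frame(richness = hv_richness(hv), evenness = hv_evenness(hv),
             dispersion = hv_dispersion(hv))
}

#' Per-replicate hypervolumes and FD indices in a shared space
#'
#' Builds one hypervolume per treatment-replicate group of scores (all in
#' the same, already-fitted PCA space) and tabulates the three kernel FD
#' indices; replicates with fewer than 10 events are skipped with a warning.
#'
#' @param scores numeric matrix (events x axes) restricted to the axes the
#'   hypervolumes should use.
#' @param treatment,replicate per-event labels.
#' @param q quantile threshold.
#' @param n_support support points per hypervolume.
#' @param seed master seed; each replicate gets a derived substream seed.
#' @return data.frame `treatment, replicate, richness, evenness, dispersion`
#'   with attribute `hypervolumes` (named list).
#' @export
fd_per_replicate <- function(scores, treatment, replicate, q = 0.95,
                             n_support = NULL, seed = 1L) {
  scores <- as.matrix(scores)
  key <- interaction(treatment, replicate, sep = "_", lex.order = TRUE,
                     drop = TRUE)
  if (nlevels(key) < 2) stopf("need >= 2 treatment-replicate groups")
  hvs <- list()
  rows <- list()
  for (i in seq_along(levels(key))) {
    kk <- levels(key)[i]
    sel <- key == kk
    if (sum(sel) < 10) {
      warnf("replicate group '%s' has < 10 events; skipped", kk)
      next
    }
    hv <- build_hypervolume(scores[sel, , drop = FALSE], q = q,
                            n_support = n_support,
                            seed = derive_seed(seed, i))
    hvs[[kk]] <- hv
    rows[[kk]] <- data.frame(treatment = as.character(treatment[sel][1]),
                             replicate = as.character(replicate[sel][1]),
                             fd_indices(hv))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hypervolumes") <- hvs
  out
}
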