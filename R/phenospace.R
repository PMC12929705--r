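# The integrated phenotype: PCA on standardised traits, a permutation test
# for axis significance, treatment-by-replicate trait profiles, and k-means
# functional clustering of those profiles with an explicit elbow rule.

#' Fit the integrated-phenotype PCA
#'
#' Eigendecomposition of the standardised trait matrix (uncentred, since
#' standardisation already removes the fitted means): axes are ordered by
#' decreasing variance and the sign convention fixes the largest-magnitude
#' loading of each axis to be positive, so repeated runs are comparable.
#'
#' @param traits a standardised [trait_matrix()], or a plain numeric matrix
#'   of standardised values; events must be >= traits.
#' @return object of class `phenotype_space`: `loadings` (traits x axes,
#'   orthonormal columns), `scores` (events x axes), `variance_fraction`
#'   (sums to 1), `significant_axes` (filled by
#'   [test_axes_significance()], default first two axes), `fitted_on`.
#' @export
fit_pca <- function(traits) {
  x <- if (inherits(traits, "trait_matrix")) {
    if (!traits$standardized) stopf("fit_pca expects standardised traits")
    traits$values
  } else {
    as.matrix(traits)
  }
  if (nrow(x) < ncol(x)) stopf("need at least as many events as traits")
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  # sign convention: largest-|loading| entry of each axis is positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  vf <- ev / sum(ev)
  rank_def <- sum(ev < max(ev) * 1e-12)
  if (rank_def > 0) {
    message(sprintf("rank-deficient input: %d axes carry ~zero variance",
                    rank_def))
  }
  structure(list(loadings = load, scores = scores, variance_fraction = vf,
                 eigenvalues = ev,
                 significant_axes = seq_len(min(2L, ncol(load))),
                 fitted_on = if (inherits(traits, "trait_matrix"))
                   traits$sample_id else "matrix"),
            class = "phenotype_space")
}

#' @export
print.phenotype_space <- function(x, ...) {
  cat(sprintf("phenotype_space: %d axes, variance fractions %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$variance_fraction),
                    collapse = ", ")))
  cat("significant axes:", paste(x$significant_axes, collapse = ", "), "\n")
  invisible(x)
}

#' Project new standardised traits into a fitted phenotype space
#'
#' @param space a [fit_pca()] result.
#' @param values standardised trait values (events x traits) or a
#'   standardised [trait_matrix()].
#' @return events x axes score matrix.
#' @export
project_scores <- function(space, values) {
  stopifnot(inherits(space, "phenotype_space"))
  if (inherits(values, "trait_matrix")) values <- values$values
  as.matrix(values) %*% space$loadings
}

# Eigenvalues of the uncentred second-moment matrix, cheap path used by the
# permutation test (d is small, n can be large).
.pca_eigenvalues <- function(x) {
  s <- crossprod(x) / (nrow(x) - 1)
  sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Permutation test for significant PCA axes
#'
#' Builds a null by independently permuting each trait column (destroying
#' between-trait correlation while keeping marginals) and declares axis j
#' significant when the observed j-th eigenvalue exceeds the (1 - alpha)
#' quantile of the permuted j-th eigenvalues.
#'
#' @param traits standardised [trait_matrix()] or numeric matrix.
#' @param n_perm number of permutations (>= 99).
#' @param alpha significance level; requires `alpha >= 1 / (n_perm + 1)`.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return integer vector of significant axis indices (possibly empty), with
#'   attribute `null_quantiles`.
#' @export
test_axes_significance <- function(traits, n_perm = 999, alpha = 0.05,
                                   seed = 1L) {
  x <- if (inherits(traits, "trait_matrix")) traits$values else
    as.matrix(traits)
  if (n_perm < 99) stopf("n_perm must be >= 99")
  if (alpha < 1 / (n_perm + 1)) {
    stopf("n_perm = %d cannot resolve alpha = %g (need alpha >= %.3g)",
          n_perm, alpha, 1 / (n_perm + 1))
  }
  d <- ncol(x); n <- nrow(x)
  obs <- .pca_eigenvalues(x)
  null_ev <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- apply(x, 2, sample)
      .pca_eigenvalues(xp)
    }, numeric(d))
  })
  qs <- apply(null_ev, 1, quantile, probs = 1 - alpha, names = FALSE)
  sig <- which(obs > qs)
  attr(sig, "null_quantiles") <- qs
  attr(sig, "observed") <- obs
  sig
}

#' Treatment-by-replicate mean trait profiles
#'
#' One row per treatment-replicate pair, one column per trait, entries are
#' the replicate's mean standardised trait value (the heatmap input of the
#' culture analysis).
#'
#' @param values standardised trait values (events x traits) or a
#'   standardised [trait_matrix()].
#' @param treatment per-event treatment label.
#' @param replicate per-event replicate label.
#' @return numeric matrix with rownames `treatment_replicate`, plus
#'   attributes `treatment` and `replicate` giving each row's labels.
#' @export
treatment_profiles <- function(values, treatment, replicate) {
  if (inherits(values, "trait_matrix")) values <- values$values
  values <- as.matrix(values)
  key <- interaction(treatment, replicate, sep = "_", lex.order = TRUE,
                     drop = TRUE)
  prof <- t(vapply(levels(key), function(k) {
    colMeans(values[key == k, , drop = FALSE])
  }, numeric(ncol(values))))
  colnames(prof) <- colnames(values)
  first <- !duplicated(key)
  map <- data.frame(key = as.character(key[first]),
                    treatment = as.character(treatment[first]),
                    replicate = as.character(replicate[first]))
  map <- map[match(rownames(prof), map$key), ]
  attr(prof, "treatment") <- map$treatment
  attr(prof, "replicate") <- map$replicate
  prof
}

#' k-means functional clustering with an explicit elbow rule
#'
#' Runs k-means for k = 1..k_max (multiple restarts; each k additionally
#' warm-started from the previous solution plus the farthest point, which
#' guarantees a non-increasing within-cluster sum-of-squares curve) and
#' chooses the k maximising the second difference of that curve. Identical
#' profiles yield k = 1 with a note.
#'
#' @param profiles numeric matrix (profiles x traits).
#' @param k_max largest k to try (<= number of profiles).
#' @param seed RNG seed.
#' @param nstart random restarts per k.
#' @return object of class `functional_clusters`: `k`, `assignments`,
#'   `within_ss_by_k`, `centers`.
#' @export
functional_clusters <- function(profiles, k_max = NULL, seed = 1L,
                                nstart = 25) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (is.null(k_max)) k_max <- min(8L, n - 1L)
  if (k_max > n) stopf("k_max must be <= number of profiles (%d)", n)
  total_ss <- sum(sweep(profiles, 2, colMeans(profiles))^2)
  if (total_ss < 1e-12) {
    message("identical profiles: k = 1")
    return(structure(list(k = 1L, assignments = rep(1L, n),
                          within_ss_by_k = total_ss,
                          centers = matrix(colMeans(profiles), nrow = 1)),
                     class = "functional_clusters"))
  }
  fits <- vector("list", k_max)
  wss <- numeric(k_max)
  with_seed(seed, {
    for (k in seq_len(k_max)) {
      if (k == 1) {
        fits[[k]] <- list(cluster = rep(1L, n),
                          centers = matrix(colMeans(profiles), nrow = 1),
                          tot.withinss = total_ss)
        wss[k] <- total_ss
        next
      }
      best <- tryCatch(kmeans(profiles, centers = k, nstart = nstart,
                              iter.max = 50),
                       error = function(e) NULL)
      # warm start: previous centers + farthest point from its center
      prev <- fits[[k - 1]]
      assigned <- prev$centers[prev$cluster, , drop = FALSE]
      far <- which.max(rowSums((profiles - assigned)^2))
      init <- rbind(prev$centers, profiles[far, ])
      if (anyDuplicated(init) == 0) {
        warm <- tryCatch(kmeans(profiles, centers = init, iter.max = 50),
                         error = function(e) NULL)
        if (!is.null(warm) &&
            (is.null(best) || warm$tot.withinss < best$tot.withinss)) {
          best <- warm
        }
      }
      if (is.null(best)) { # more centers than distinct points
        k_max <- k - 1L
        break
      }
      fits[[k]] <- best
      wss[k] <- best$tot.withinss
    }
  })
  wss <- wss[seq_len(k_max)]
  k_best <- if (k_max < 3) k_max else {
    second_diff <- wss[seq_len(k_max - 2)] - 2 * wss[2:(k_max - 1)] +
      wss[3:k_max]
    which.max(second_diff) + 1L
  }
  structure(list(k = k_best, assignments = fits[[k_best]]$cluster,
                 within_ss_by_k = wss, centers = fits[[k_best]]$centers),
            class = "functional_clusters")
}

#' @export
print.functional_clusters <- function(x, ...) {
  cat(sprintf("functional_clusters: k = %d (elbow on %d-point WSS curve)\n",
              x$k, length(x$within_ss_by_k)))
  invisible(x)
}
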