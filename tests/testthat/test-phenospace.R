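# Integrated phenotype: PCA structure, permutation axis test, treatment
# profiles, and the k-means elbow rule.

std_matrix <- function(x) {
  # column-wise z-score with population sd, as the trait pipeline produces
  sweep(sweep(x, 2, colMeans(x)), 2,
        apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))), "/")
}

test_that("PCA degenerate and isotropic variance structure", {
  # two perfectly correlated traits: first axis carries everything
  set.seed(1)
  z <- rnorm(200)
  x <- std_matrix(cbind(z, z))
  sp <- suppressMessages(fit_pca(x))
  expect_equal(sp$variance_fraction[1], 1, tolerance = 1e-12)

  # isotropic noise: fractions ~ 1/d
  set.seed(2)
  iso <- matrix(rnorm(50000 * 4), ncol = 4)
  sp2 <- fit_pca(std_matrix(iso))
  expect_equal(sp2$variance_fraction, rep(0.25, 4), tolerance = 0.02)
  expect_equal(sum(sp2$variance_fraction), 1, tolerance = 1e-9)
})

test_that("scores and loadings reconstruct the input orthogonally", {
  set.seed(3)
  x <- std_matrix(matrix(rnorm(500 * 5), ncol = 5) %*%
                    matrix(rnorm(25), 5, 5))
  sp <- fit_pca(x)
  expect_lt(max(abs(sp$scores %*% t(sp$loadings) - x)), 1e-8)
  expect_equal(crossprod(sp$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: dominant loading of each axis is positive
  for (j in 1:5) expect_gt(sp$loadings[which.max(abs(sp$loadings[, j])), j], 0)
  # variance fractions invariant to event order
  sp_perm <- fit_pca(x[sample(nrow(x)), ])
  expect_equal(sp_perm$variance_fraction, sp$variance_fraction,
               tolerance = 1e-9)
})

test_that("axis permutation test has power and guards its resolution", {
  set.seed(4)
  f <- rnorm(300)
  x <- matrix(rnorm(300 * 6), ncol = 6) + f %o% rep(1, 6)
  sig <- test_axes_significance(std_matrix(x), n_perm = 199, seed = 7)
  expect_true(1 %in% sig)
  expect_error(test_axes_significance(std_matrix(x), n_perm = 99,
                                      alpha = 0.001), "resolve")
  expect_error(test_axes_significance(std_matrix(x), n_perm = 50), ">= 99")
  # determinism under a fixed seed
  sig2 <- test_axes_significance(std_matrix(x), n_perm = 199, seed = 7)
  expect_identical(as.integer(sig), as.integer(sig2))
})

test_that("treatment profiles are replicate means and linear in pooling", {
  set.seed(5)
  x <- matrix(rnorm(120 * 3), ncol = 3,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  tr <- rep(c("a", "b"), each = 60)
  rp <- rep(rep(c("R1", "R2"), each = 30), 2)
  prof <- treatment_profiles(x, tr, rp)
  expect_equal(dim(prof), c(4, 3))
  expect_equal(unname(prof["a_R1", ]),
               unname(colMeans(x[tr == "a" & rp == "R1", ])))
  # pooled profile equals the mean of equal-size replicate profiles
  pooled <- treatment_profiles(x, tr, rep("all", 120))
  expect_equal(unname(pooled["a_all", ]),
               unname(colMeans(prof[c("a_R1", "a_R2"), ])))
})

test_that("elbow rule finds planted centroid counts", {
  set.seed(6)
  # symmetric well-separated centroids (equilateral triangle)
  cen <- matrix(c(0, 0, 10, 0, 5, 8.66), ncol = 2, byrow = TRUE)
  prof <- cen[rep(1:3, each = 6), ] + matrix(rnorm(36, 0, 0.2), ncol = 2)
  fc <- functional_clusters(prof, k_max = 8, seed = 2)
  expect_equal(fc$k, 3)
  expect_equal(length(unique(fc$assignments[1:6])), 1)
  expect_equal(adjusted_rand_index(fc$assignments, rep(1:3, each = 6)), 1)
  # WSS curve is non-increasing
  expect_true(all(diff(fc$within_ss_by_k) <= 1e-8))
  # identical profiles collapse to k = 1
  same <- matrix(1, 10, 2)
  expect_message(fc1 <- functional_clusters(same, seed = 1), "k = 1")
  expect_equal(fc1$k, 1L)
  expect_error(functional_clusters(prof, k_max = 99), "k_max")
})
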