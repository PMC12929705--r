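# Bandwidths, hypervolume construction, the three FD indices and Jaccard
# overlap; the heavy oracle comparisons live in the acceptance tests.

test_that("Silverman bandwidth matches its closed form and scales", {
  set.seed(1)
  x <- matrix(rnorm(100), ncol = 1)
  h <- estimate_bandwidth(x)
  expect_equal(h, sd(x) * (4 / 300)^(1 / 5))
  expect_equal(sd(x) * (4 / 300)^(1 / 5) / sd(x), 0.4217, tolerance = 1e-4)
  # homogeneity: scaling the scores scales the bandwidths
  x2 <- matrix(rnorm(200), ncol = 2)
  expect_equal(estimate_bandwidth(3 * x2), 3 * estimate_bandwidth(x2))
  expect_error(estimate_bandwidth(cbind(x2, 1)), "zero-variance")
  expect_error(estimate_bandwidth(x2[1:5, , drop = FALSE]), "n >= 10")
})

test_that("hypervolumes are deterministic and density-invariant", {
  set.seed(2)
  x <- matrix(rnorm(800), ncol = 2)
  a <- build_hypervolume(x, seed = 5)
  b <- build_hypervolume(x, seed = 5)
  expect_identical(a$support_points, b$support_points)
  expect_identical(a$volume, b$volume)
  # duplicating every point leaves the density (hence volume) ~unchanged
  dup <- build_hypervolume(x[rep(1:400, 2), ], seed = 6,
                           bandwidths = a$bandwidths)
  expect_equal(dup$volume, a$volume, tolerance = 0.05)
  expect_error(build_hypervolume(x, q = 1.2), "q must be")
})

test_that("richness is the volume and obeys the scaling law", {
  set.seed(3)
  x <- matrix(rnorm(1000), ncol = 2)
  hv <- build_hypervolume(x, seed = 1)
  expect_identical(hv_richness(hv), hv$volume)
  # widening the cloud by c multiplies the volume by ~c^d
  hv3 <- build_hypervolume(3 * x, seed = 1)
  expect_equal(hv_richness(hv3) / hv_richness(hv), 9, tolerance = 0.1)
  # tight cluster occupies less space than a dispersed one
  hv_tight <- build_hypervolume(0.1 * x, seed = 2)
  expect_lt(hv_richness(hv_tight), hv_richness(hv))
})

test_that("richness shrinks as the quantile threshold drops", {
  set.seed(4)
  x <- matrix(rnorm(600), ncol = 2)
  vols <- vapply(c(0.99, 0.9, 0.7, 0.5), function(q)
    build_hypervolume(x, q = q, seed = 3)$volume, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("evenness is bounded and ranks uniform above clumped", {
  set.seed(5)
  u <- matrix(runif(8000), ncol = 2)
  hv_u <- build_hypervolume(u, seed = 4)
  e_u <- hv_evenness(hv_u)
  expect_gte(e_u, 0.85)
  expect_lte(e_u, 1)
  clumps <- rbind(matrix(rnorm(4000, 0, 0.05), ncol = 2),
                  matrix(rnorm(4000, 5, 0.05), ncol = 2))
  e_c <- hv_evenness(build_hypervolume(clumps, seed = 5))
  expect_lt(e_c, e_u - 0.15)
})

test_that("dispersion matches the 1-D uniform closed form", {
  set.seed(6)
  hv1 <- build_hypervolume(matrix(runif(5000), ncol = 1), seed = 7)
  expect_equal(hv_dispersion(hv1), 0.25, tolerance = 0.03)
  # translation invariance
  x <- matrix(rnorm(800), ncol = 2)
  d0 <- hv_dispersion(build_hypervolume(x, seed = 8))
  d1 <- hv_dispersion(build_hypervolume(x + 100, seed = 8))
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("jaccard respects identity, disjointness and symmetry", {
  set.seed(7)
  a <- matrix(rnorm(600), ncol = 2)
  hv_a <- build_hypervolume(a, seed = 1)
  hv_a2 <- build_hypervolume(a, seed = 1)
  expect_identical(hv_jaccard(hv_a, hv_a2), 1)
  far <- build_hypervolume(a + 100 * max(apply(a, 2, sd)), seed = 2)
  expect_lt(hv_jaccard(hv_a, far), 0.01)
  b <- matrix(rnorm(600), ncol = 2) + 0.5
  hv_b <- build_hypervolume(b, seed = 3)
  expect_lt(abs(hv_jaccard(hv_a, hv_b) - hv_jaccard(hv_b, hv_a)), 0.02)
  hv_1d <- build_hypervolume(matrix(rnorm(100), ncol = 1), seed = 4)
  expect_error(hv_jaccard(hv_a, hv_1d), "dimension mismatch")
})

test_that("per-replicate FD table covers the design and skips tiny groups", {
  set.seed(8)
  sc <- matrix(rnorm(5 * 4 * 60 * 2), ncol = 2)
  tr <- rep(paste0("t", 1:5), each = 4 * 60)
  rp <- rep(rep(paste0("R", 1:4), each = 60), 5)
  fd <- fd_per_replicate(sc, tr, rp, n_support = 200, seed = 9)
  expect_equal(nrow(fd), 20)
  expect_named(fd, c("treatment", "replicate", "richness", "evenness",
                     "dispersion"))
  expect_length(attr(fd, "hypervolumes"), 20)
  # identical replicate data with the same seed give identical indices
  fd2 <- fd_per_replicate(sc, tr, rp, n_support = 200, seed = 9)
  expect_identical(fd$richness, fd2$richness)
  # a tiny group is skipped with a warning
  rp_bad <- rp
  rp_bad[tr == "t1" & rp == "R1"][-(1:5)] <- "R2"
  expect_warning(fd3 <- fd_per_replicate(sc, tr, rp_bad, n_support = 200,
                                         seed = 9), "skipped")
  expect_equal(nrow(fd3), 19)
})
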