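# Joint culture + field space, sample centroids, fingerprint assignment
# and the gradient association.

toy_trait_matrix <- function(n, seed, shift = 1) {
  set.seed(seed)
  trait_matrix(matrix(exp(rnorm(n * 8)) * shift, ncol = 8,
                      dimnames = list(NULL, trait_names())))
}

test_that("joint space degenerates to the culture-only PCA", {
  cul <- toy_trait_matrix(300, 1)
  sp_joint <- suppressMessages(joint_space(cul, NULL))
  std <- standardize_traits(cul)
  sp_solo <- suppressMessages(fit_pca(std$traits))
  expect_equal(sp_joint$loadings, sp_solo$loadings, tolerance = 1e-9)
  # duplicating culture events as field leaves the correlation structure
  dup <- toy_trait_matrix(300, 1)
  sp_dup <- suppressMessages(joint_space(cul, dup))
  expect_equal(abs(sp_dup$loadings), abs(sp_solo$loadings), tolerance = 1e-6)
  expect_equal(table(sp_dup$origin)[["field"]], 300)
  # mismatched trait sets are rejected
  bad <- cul
  colnames(bad$values)[1] <- "other"
  class(bad) <- "trait_matrix"
  expect_error(joint_space(cul, bad), "mismatch")
})

test_that("sample centroids are means with small-sample guards", {
  set.seed(2)
  sc <- matrix(rnorm(200), ncol = 2)
  sp <- structure(list(scores = sc, significant_axes = 1:2),
                  class = "phenotype_space")
  grp <- rep(c("s1", "s2"), each = 50)
  cen <- sample_centroids(sp, grp)
  expect_equal(unname(cen["s1", ]), colMeans(sc[1:50, ]))
  # linearity: pooled centroid is the mean of equal-size halves
  cen_all <- sample_centroids(sp, rep("all", 100))
  expect_equal(unname(cen_all[1, ]), unname(colMeans(cen)))
  # forced single-event sample returns that event's scores
  cen1 <- sample_centroids(sp, c("one", rep("rest", 99)), min_events = 1)
  expect_equal(unname(cen1["one", ]), sc[1, ])
  expect_warning(sample_centroids(sp, c("tiny", rep("rest", 99))),
                 "skipping")
})

test_that("fingerprint assignment is nearest-centroid with a stable tie rule", {
  tc <- rbind(control = c(0, 0), low_N = c(1, 0), low_L = c(0, 2))
  r <- assign_fingerprint(c(1, 0), tc, sample_id = "f1")
  expect_equal(r$nearest_treatment, "low_N")
  expect_equal(r$distance, 0)
  # equidistant tie: deterministic label-order tie-break, flagged
  tie <- assign_fingerprint(c(0.5, 0), tc[c("control", "low_N"), ])
  expect_equal(tie$nearest_treatment, "control")
  expect_true(tie$tie)
  # metadata without light: assignment still made, gradient absent
  r2 <- assign_fingerprint(c(1, 0), tc, metadata = data.frame(TN = 5))
  expect_true(is.na(r2$gradient_value))
  r3 <- assign_fingerprint(c(1, 0), tc,
                           metadata = data.frame(TN = 60, light = 30))
  expect_equal(r3$gradient_value, 2)
})

test_that("gradient association recovers planted trends and guards input", {
  set.seed(3)
  g <- seq(0.1, 5, length.out = 20)
  cen <- cbind(2 * g + rnorm(20, 0, 0.1), rnorm(20))
  res <- gradient_association(cen, g)
  expect_gt(res$rho[1], 0.9)
  expect_lt(res$p[1], 0.001)
  expect_lt(abs(res$rho[2]), 0.5)
  # null: rho near zero on independent data
  res0 <- gradient_association(matrix(rnorm(60), ncol = 2), rnorm(30))
  expect_lt(max(abs(res0$rho)), 0.5)
  expect_error(gradient_association(cen[1:4, ], g[1:4]), ">= 5 samples")
  resc <- gradient_association(cen, rep(1, 20))
  expect_true(all(is.na(resc$rho)))
})
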