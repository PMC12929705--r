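# Trait derivation arithmetic, the collinearity filter, standardisation
# and the per-trait ANOVA.

toy_events <- function(fsc, ssc, fl670, fl692) {
  event_table(cbind(FSC = fsc, SSC = ssc, FL670 = fl670, FL692 = fl692))
}

test_that("trait derivation matches its closed forms", {
  tm <- derive_traits(toy_events(100, 50, 200, 100))
  expect_identical(colnames(tm$values), trait_names())
  expect_equal(unname(tm$values[1, ]),
               c(100, 50, 2, 200, 2, 100, 1, 2))
  tm2 <- derive_traits(toy_events(100, 50, 200, 100), volume_exponent = 1.5)
  expect_equal(unname(tm2$values[1, "gas_vesicle"]), 100^1.5 / 50)
})

test_that("zero-denominator events are dropped and counted", {
  ev <- toy_events(c(100, 50), c(50, 0), c(200, 10), c(100, 5))
  tm <- derive_traits(ev)
  expect_equal(nrow(tm$values), 1)
  expect_equal(attr(tm, "dropped_events"), 1)
  expect_error(derive_traits(toy_events(1, 0, 1, 1)), "all events dropped")
})

test_that("pigment ratio is scale-consistent", {
  set.seed(1)
  fsc <- 10^runif(50, 1, 3); ssc <- 10^runif(50, 1, 3)
  fl670 <- 10^runif(50, 1, 3); fl692 <- 10^runif(50, 1, 3)
  a <- derive_traits(toy_events(fsc, ssc, fl670, fl692))
  b <- derive_traits(toy_events(fsc, ssc, 7 * fl670, 7 * fl692))
  expect_equal(a$values[, "pc_chla"], b$values[, "pc_chla"])
})

test_that("collinearity filter prunes pairs and honours the keep list", {
  set.seed(5)
  z <- rnorm(500)
  m <- cbind(a = exp(z), b = exp(z + 0.01 * rnorm(500)), c = exp(rnorm(500)))
  kept <- collinearity_filter(m, 0.8)
  expect_length(intersect(kept, c("a", "b")), 1)
  expect_true("c" %in% kept)

  # correlated pigment channels both survive when protected
  z2 <- rnorm(500)
  m2 <- cbind(FL670 = exp(z2),
              FL692 = exp(0.9 * z2 + sqrt(1 - 0.81) * rnorm(500)),
              junk = exp(rnorm(500)))
  expect_gt(abs(cor(log10(m2[, 1]), log10(m2[, 2]))), 0.8)
  kept2 <- collinearity_filter(m2, 0.8, keep_list = c("FL670", "FL692"))
  expect_true(all(c("FL670", "FL692") %in% kept2))

  # nothing above threshold: identity
  set.seed(6)
  m3 <- matrix(exp(rnorm(900)), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(collinearity_filter(m3, 0.8), c("x", "y", "z"))
  expect_error(collinearity_filter(m, keep_list = "nope"), "absent")
})

test_that("standardisation fits, applies, transports and inverts", {
  set.seed(4)
  v <- matrix(exp(rnorm(200 * 8)), ncol = 8,
              dimnames = list(NULL, trait_names()))
  st <- standardize_traits(trait_matrix(v))
  expect_lt(max(abs(colMeans(st$traits$values))), 1e-8)
  expect_lt(max(abs(apply(st$traits$values, 2,
                          function(x) sqrt(mean((x - mean(x))^2))) - 1)),
            1e-8)
  # affine transport: a doubled copy shifts every column by log10(2)/sd
  st2 <- standardize_traits(trait_matrix(2 * v), model = st$model)
  expect_equal(colMeans(st2$traits$values),
               colMeans(st$traits$values) + log10(2) / st$model$sd)
  # inverse restores inputs
  back <- unstandardize_traits(st$traits, st$model)
  expect_lt(max(abs(back$values - v) / v), 1e-9)
  # constant trait rejected
  vc <- v; vc[, 3] <- 1
  expect_error(standardize_traits(trait_matrix(vc)), "gas_vesicle")
})

test_that("one-way ANOVA matches brute force and the t-test identity", {
  # worked 2-treatment x 3-observation toy table vs brute-force sums of squares
  y <- c(1, 2, 3, 6, 7, 11)
  g <- rep(c("a", "b"), each = 3)
  ssb <- sum(3 * (tapply(y, g, mean) - mean(y))^2)
  ssw <- sum((y - ave(y, g))^2)
  f_brute <- (ssb / 1) / (ssw / 4)
  res <- anova_per_trait(matrix(y, ncol = 1, dimnames = list(NULL, "t")), g)
  expect_equal(res$F, f_brute)
  # two groups: F = t^2 of the pooled-variance t-test
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
  expect_equal(res$p, tt$p.value)
  expect_error(anova_per_trait(matrix(y, ncol = 1, dimnames = list(NULL, "t")),
                               c(1, 1, 1, 1, 1, 2)), ">= 2 observations")
})
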