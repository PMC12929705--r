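# Synthetic-data generator: distributional contracts, determinism,
# effect-sign structure, field interpolation, beads and bioassay.

test_that("culture generator hits its designed medians", {
  cfg <- synth_config(n_events = 10000, seed = 42)
  inf <- c("FSC", "SSC", "FL670", "FL692")

  ev <- generate_culture_events(cfg, "control", 1)
  target <- attr(ev, "truth") == "target"
  med <- apply(ev$values[target, inf], 2, median)
  expect_true(all(abs(med / cfg$baseline_medians[inf] - 1) < 0.05))

  # analytic lognormal median: median = baseline * effect factor
  ev_n <- generate_culture_events(cfg, "low_N", 1)
  target_n <- attr(ev_n, "truth") == "target"
  med670 <- median(ev_n$values[target_n, "FL670"])
  expect_equal(med670 / cfg$baseline_medians[["FL670"]],
               cfg$effect_matrix["low_N", "FL670"], tolerance = 0.05)
})

test_that("generator outputs are deterministic and validated", {
  cfg <- synth_config(n_events = 500, seed = 3)
  a <- generate_culture_events(cfg, "low_P", 2)
  b <- generate_culture_events(cfg, "low_P", 2)
  expect_identical(a$values, b$values)
  c <- generate_culture_events(cfg, "low_P", 3)
  expect_false(identical(a$values, c$values))

  expect_error(generate_culture_events(cfg, "no_such_treatment", 1),
               "unknown treatment")
  expect_error(synth_config(debris_fraction = 1), "debris_fraction")
  bad_eff <- synth_config()$effect_matrix
  bad_eff["control", "FSC"] <- 2
  expect_error(synth_config(effect_matrix = bad_eff), "control row")
})

test_that("effect signs are recoverable and debris is separable", {
  cfg <- synth_config(n_events = 6000, seed = 9)
  inf <- c("FSC", "SSC", "FL670", "FL692")
  ctrl <- generate_culture_events(cfg, "control", 1)
  med_c <- apply(ctrl$values[attr(ctrl, "truth") == "target", inf], 2, median)
  for (tr in setdiff(cfg$treatments, "control")) {
    ev <- generate_culture_events(cfg, tr, 1)
    tg <- attr(ev, "truth") == "target"
    med_t <- apply(ev$values[tg, inf], 2, median)
    le <- log(cfg$effect_matrix[tr, inf])
    nz <- abs(le) > 1e-8
    expect_true(all(sign(log(med_t / med_c))[nz] == sign(le)[nz]),
                label = sprintf("sign recovery for %s", tr))
    # target vs debris separation: >= 10x in at least one channel
    med_d <- apply(ev$values[!tg, inf], 2, median)
    expect_true(any(med_t / med_d >= 10))
  }
})

test_that("field series interpolates between the low_N and low_L effects", {
  cfg <- synth_config(n_events = 8000, n_field_samples = 3,
                      gradient = c(0.2, 2.6, 5), colony_fraction = 0,
                      debris_fraction = 0, seed = 5)
  fs <- generate_field_series(cfg)
  expect_length(fs, 3)
  inf <- c("FSC", "SSC", "FL670", "FL692")
  med <- lapply(fs, function(s) apply(s$events$values[, inf], 2, median))
  base <- cfg$baseline_medians[inf]
  # endpoints match the culture effect rows
  expect_equal(med[[1]] / base, cfg$effect_matrix["low_N", inf],
               tolerance = 0.05)
  expect_equal(med[[3]] / base, cfg$effect_matrix["low_L", inf],
               tolerance = 0.05)
  # midpoint of the gradient: geometric mean of the endpoint medians
  expect_equal(med[[2]], sqrt(med[[1]] * med[[3]]), tolerance = 0.05)
  # metadata tracks the gradient: TN / light equals the covariate
  tn_light <- vapply(fs, function(s) s$metadata$TN / s$metadata$light,
                     numeric(1))
  expect_equal(tn_light, cfg$gradient)
})

test_that("a 28-sample field series yields 28 table/metadata pairs", {
  cfg <- synth_config(n_events = 50, n_field_samples = 28, seed = 2)
  fs <- generate_field_series(cfg)
  expect_length(fs, 28)
  expect_true(all(vapply(fs, function(s)
    inherits(s$events, "event_table") && is.data.frame(s$metadata),
    logical(1))))
  expect_error(generate_field_series(
    synth_config(n_field_samples = 0, gradient = numeric(0))), "non-empty")
})

test_that("bead events have tight increasing FSC modes", {
  cfg <- synth_config(n_events = 900, seed = 8)
  for (sizes in list(c(1, 10), c(0.5, 2, 10))) {
    beads <- generate_beads(sizes, cfg)
    fsc <- beads$values[, "FSC"]
    grp <- attr(beads, "bead_size")
    meds <- tapply(fsc, grp, median)[as.character(sort(sizes))]
    expect_true(all(diff(meds) > 0))
    cvs <- tapply(fsc, grp, function(x) sd(x) / mean(x))
    expect_true(all(cvs < 0.05))
  }
  expect_identical(generate_beads(c(1, 10), cfg)$values,
                   generate_beads(c(1, 10), cfg)$values)
  expect_error(generate_beads(5, cfg), "2 distinct sizes")
})

test_that("bioassay growth structure follows the designed limitation", {
  cfg <- synth_config(n_events = 10, seed = 4)
  ba_none <- generate_bioassay(cfg, "none")
  expect_true(all(ba_none$day0 > 0))
  g <- log(ba_none$day4 / ba_none$day0) / 4
  by_tr <- tapply(g, ba_none$treatment, mean)
  expect_true(max(by_tr) - min(by_tr) < 0.1) # no designed contrast

  ba_n <- generate_bioassay(cfg, "N")
  g_n <- log(ba_n$day4 / ba_n$day0) / 4
  by_n <- tapply(g_n, ba_n$treatment, mean)
  expect_gt(by_n[["+N"]], by_n[["control"]] + 0.1)
  expect_lt(abs(by_n[["+P"]] - by_n[["control"]]), 0.1)
  expect_error(generate_bioassay(cfg, "K"), "unknown limitation")
})
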