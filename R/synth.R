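# Synthetic flow-cytometry data with the statistical structure the analysis
# assumes: lognormal optical channels, a dominant pigment-bright target
# population plus a broad low-signal debris cloud, treatment-specific
# multiplicative channel effects, bead calibration events, a field series
# along a nitrogen:light gradient, and nutrient-addition bioassay readings.

# Channel layout: four informative channels (FSC, SSC, FL670 = phycocyanin
# fluorescence 670/40 @ 640 nm, FL692 = chlorophyll-a fluorescence
# 692/30 @ 488 nm) plus 14 distractor channels so the collinearity filter has
# realistic input. Four distractors are noisy transforms of an informative
# parent (area vs. height signals, strongly collinear); the rest are
# independent noise channels.
.synth_channels <- function() {
  informative <- c("FSC", "SSC", "FL670", "FL692")
  derived <- c(FSC_area = "FSC", SSC_area = "SSC",
               FL640_670_area = "FL670", FL488_695_area = "FL692")
  noise <- c("FL355_460", "FL457_480", "FL488_530", "FL488_580", "FL532_560",
             "FL532_610", "FL640_730", "FL355_530", "FL488_710", "FL532_710")
  list(informative = informative, derived = derived, noise = noise,
       all = c(informative, names(derived), noise))
}

#' Configuration for the synthetic flow-cytometry generator
#'
#' Bundles every free parameter of the synthetic-data module: the treatment
#' design (five treatments, four replicates, matching a resource-limitation
#' culture experiment), per-channel lognormal baselines, a treatment-by-channel
#' matrix of multiplicative effects whose sign pattern follows the nitrogen /
#' phosphorus / light-limitation and high-pCO2 responses of *Microcystis*
#' (nitrogen limitation lowers pigment channels and raises forward scatter;
#' light limitation raises pigment channels), per-treatment spread multipliers
#' that set the designed ordering of trait-space size across treatments, a
#' debris fraction, and the field-series nitrogen:light gradient.
#'
#' @param n_events events per generated sample.
#' @param treatments treatment labels; the first must be the control.
#' @param n_replicates replicate cultures per treatment.
#' @param baseline_medians named positive vector of per-channel medians
#'   (instrument units); defaults cover the full 18-channel layout.
#' @param effect_matrix treatment x channel matrix of multiplicative factors
#'   (all > 0, control row all ones). Defaults encode the treatment sign
#'   pattern described above.
#' @param cv named per-channel lognormal coefficient of variation
#'   (sd of log-intensity).
#' @param spread named per-treatment multiplier on the log-scale sd; sets the
#'   designed rank order of functional richness (smallest under low_N,
#'   largest under low_P).
#' @param debris_fraction fraction of events drawn from the broad low-signal
#'   debris cloud, in `[0, 1)`.
#' @param n_field_samples number of field samples in the generated series.
#' @param gradient per-field-sample nitrogen:light covariate (TN / light,
#'   dimensionless); low values put the sample at the nitrogen-limited end of
#'   the effect interpolation, high values at the light-limited end.
#' @param colony_fraction fraction of large-colony events added to field
#'   samples (removed downstream by the size gate).
#' @param seed master seed; all generator outputs are pure functions of
#'   `(config, seed, indices)`.
#' @return object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_events = 500, seed = 1)
#' ev <- generate_culture_events(cfg, "control", 1)
#' dim(ev$values)
synth_config <- function(n_events = 2000,
                         treatments = c("control", "high_pCO2", "low_N",
                                        "low_P", "low_L"),
                         n_replicates = 4,
                         baseline_medians = NULL,
                         effect_matrix = NULL,
                         cv = NULL,
                         spread = NULL,
                         debris_fraction = 0.1,
                         n_field_samples = 28,
                         gradient = NULL,
                         colony_fraction = 0.05,
                         seed = 1L) {
  ch <- .synth_channels()
  if (is.null(baseline_medians)) {
    baseline_medians <- c(FSC = 5000, SSC = 2000, FL670 = 8000, FL692 = 4000,
                          FSC_area = 5000, SSC_area = 2000,
                          FL640_670_area = 8000, FL488_695_area = 4000)
    baseline_medians[ch$noise] <- seq(300, 800, length.out = length(ch$noise))
    baseline_medians <- baseline_medians[ch$all]
  }
  if (is.null(effect_matrix)) {
    effect_matrix <- matrix(1, nrow = length(treatments),
                            ncol = length(ch$all),
                            dimnames = list(treatments, ch$all))
    set_eff <- function(tr, fsc, ssc, pc, chla) {
      effect_matrix[tr, c("FSC", "SSC", "FL670", "FL692")] <<-
        c(fsc, ssc, pc, chla)
    }
    # Sign pattern: -N lowers granularity and both pigments (phycocyanin
    # more strongly) and raises cell size; -P and -L raise pigments and
    # granularity and lower cell size; high pCO2 is a mild control-like shift.
    if ("high_pCO2" %in% treatments) set_eff("high_pCO2", 1.05, 1.10, 1.10, 1.05)
    if ("low_N" %in% treatments)     set_eff("low_N",     1.50, 0.50, 0.20, 0.35)
    if ("low_P" %in% treatments)     set_eff("low_P",     0.80, 1.30, 1.30, 0.90)
    if ("low_L" %in% treatments)     set_eff("low_L",     0.80, 1.20, 1.80, 1.60)
  }
  if (is.null(cv)) {
    cv <- rep(0.5, length(ch$all))
    names(cv) <- ch$all
    cv[ch$informative] <- 0.35
    cv[names(ch$derived)] <- 0.10 # noise on top of the collinear parent
  }
  if (is.null(spread)) {
    spread <- c(control = 0.85, high_pCO2 = 1.15, low_N = 0.5,
                low_P = 1.4, low_L = 1.0)[treatments]
    spread[is.na(spread)] <- 1
    names(spread) <- treatments
  }
  if (is.null(gradient)) {
    gradient <- seq(0.2, 5, length.out = n_field_samples)
  }
  cfg <- list(n_events = as.integer(n_events), treatments = treatments,
              n_replicates = as.integer(n_replicates),
              baseline_medians = baseline_medians,
              effect_matrix = effect_matrix, cv = cv, spread = spread,
              debris_fraction = debris_fraction,
              n_field_samples = as.integer(n_field_samples),
              gradient = gradient, colony_fraction = colony_fraction,
              seed = as.integer(seed), channels = ch)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_events < 1) stopf("n_events must be positive")
  if (cfg$n_replicates < 1) stopf("n_replicates must be positive")
  if (any(cfg$effect_matrix <= 0)) stopf("all effect factors must be > 0")
  if (cfg$debris_fraction < 0 || cfg$debris_fraction >= 1) {
    stopf("debris_fraction must lie in [0, 1)")
  }
  ctrl <- cfg$treatments[1]
  if (any(cfg$effect_matrix[ctrl, ] != 1)) {
    stopf("control row of effect_matrix must be all ones")
  }
  if (any(cfg$baseline_medians <= 0)) stopf("baseline medians must be > 0")
  invisible(cfg)
}

# Draw one sample's event matrix for a given effect row and spread multiplier.
# Pigment channels are correlated (rho = 0.8) on the log scale; the four
# derived "area" channels are their parent channel times small lognormal
# noise; debris events form a broad uniform-on-log low-intensity cloud.
.draw_events <- function(cfg, effect_row, spread_mult, n, seed) {
  ch <- cfg$channels
  med <- cfg$baseline_medians * effect_row
  with_seed(seed, {
    n_debris <- round(cfg$debris_fraction * n)
    n_target <- n - n_debris
    vals <- matrix(NA_real_, nrow = n, ncol = length(ch$all),
                   dimnames = list(NULL, ch$all))
    rho <- 0.8
    z670 <- rnorm(n_target)
    z692 <- rho * z670 + sqrt(1 - rho^2) * rnorm(n_target)
    zs <- list(FL670 = z670, FL692 = z692)
    for (cn in c(ch$informative, ch$noise)) {
      z <- zs[[cn]] %||% rnorm(n_target)
      sdl <- cfg$cv[cn] * spread_mult
      vals[seq_len(n_target), cn] <- exp(log(med[cn]) + sdl * z)
    }
    for (cn in names(ch$derived)) {
      parent <- ch$derived[[cn]]
      ratio <- med[cn] / med[parent]
      vals[seq_len(n_target), cn] <- vals[seq_len(n_target), parent] * ratio *
        exp(cfg$cv[cn] * rnorm(n_target))
    }
    if (n_debris > 0) {
      rows <- n_target + seq_len(n_debris)
      for (cn in ch$all) {
        b <- cfg$baseline_medians[cn]
        lo <- log10(b / 1000)
        hi <- log10(b / 10)
        vals[rows, cn] <- 10^runif(n_debris, lo, hi)
      }
    }
    truth <- rep(c("target", "debris"), c(n_target, n_debris))
    perm <- sample.int(n)
    list(values = vals[perm, , drop = FALSE], truth = truth[perm])
  })
}

#' Generate one synthetic culture replicate
#'
#' Target-population channels are lognormal with median equal to the baseline
#' median times the treatment's effect factor; a `debris_fraction` of events
#' comes from a broad low-signal cloud. Output is deterministic given
#' `(config$seed, treatment, replicate)`.
#'
#' @param config a [synth_config()].
#' @param treatment one of `config$treatments`.
#' @param replicate replicate index in `1:config$n_replicates`.
#' @return an [event_table()] with attributes `truth` (per-event
#'   `"target"`/`"debris"` label) and `treatment`.
#' @export
generate_culture_events <- function(config, treatment, replicate) {
  validate_synth_config(config)
  ti <- match(treatment, config$treatments)
  if (is.na(ti)) {
    stopf("unknown treatment label '%s' (expected one of: %s)", treatment,
          paste(config$treatments, collapse = ", "))
  }
  if (replicate < 1 || replicate > config$n_replicates) {
    stopf("replicate must be in 1..%d", config$n_replicates)
  }
  seed <- derive_seed(config$seed, ti * 1000 + replicate)
  drawn <- .draw_events(config, config$effect_matrix[treatment, ],
                        config$spread[[treatment]], config$n_events, seed)
  ev <- event_table(drawn$values,
                    sample_id = sprintf("%s_R%d", treatment, replicate))
  attr(ev, "truth") <- drawn$truth
  attr(ev, "treatment") <- treatment
  ev
}

#' Generate a synthetic field series along a nitrogen:light gradient
#'
#' Each field sample's effect vector interpolates geometrically (log-linearly)
#' between the nitrogen-limited and light-limited culture effect rows: samples
#' at the low end of the TN:light gradient receive the nitrogen-limitation
#' effects, samples at the high end the light-limitation effects. Metadata
#' (TN, TP, light, date) is consistent with the gradient: light is held at a
#' typical summer water-column value and TN = gradient * light. A
#' `colony_fraction` of large-colony events (forward scatter equivalent to
#' ~14 um) is added; the downstream size gate removes them.
#'
#' @param config a [synth_config()]; `config$gradient` supplies one covariate
#'   value per sample.
#' @return list with one element per field sample, each a
#'   `list(events = event_table, metadata = data.frame)`; metadata columns are
#'   `sample_id, date, TN, TP, light`.
#' @export
generate_field_series <- function(config) {
  validate_synth_config(config)
  g <- config$gradient
  if (length(g) < 1) stopf("gradient list must be non-empty")
  if (config$n_field_samples != length(g)) {
    stopf("n_field_samples (%d) must match length(gradient) (%d)",
          config$n_field_samples, length(g))
  }
  for (tr in c("low_N", "low_L")) {
    if (!tr %in% config$treatments) {
      stopf("field interpolation requires treatment '%s' in the design", tr)
    }
  }
  e_n <- log(config$effect_matrix["low_N", ])
  e_l <- log(config$effect_matrix["low_L", ])
  s_n <- config$spread[["low_N"]]
  s_l <- config$spread[["low_L"]]
  # Weight 1 at the nitrogen-limited (low TN:light) end, 0 at the
  # light-limited (high TN:light) end, linear in the gradient covariate.
  rng <- range(g)
  w_n <- if (diff(rng) == 0) rep(0.5, length(g)) else (rng[2] - g) / diff(rng)
  light <- 30 # umol photons m-2 s-1
  dates <- as.Date("2023-04-12") + 7 * (seq_along(g) - 1)
  lapply(seq_along(g), function(i) {
    eff <- exp(w_n[i] * e_n + (1 - w_n[i]) * e_l)
    spread <- w_n[i] * s_n + (1 - w_n[i]) * s_l
    seed <- derive_seed(config$seed, 90000 + i)
    drawn <- .draw_events(config, eff, spread, config$n_events, seed)
    n_col <- round(config$colony_fraction * config$n_events)
    vals <- drawn$values
    truth <- drawn$truth
    if (n_col > 0) {
      col_vals <- with_seed(derive_seed(config$seed, 95000 + i), {
        m <- vals[seq_len(n_col), , drop = FALSE]
        fsc_col <- (config$baseline_medians[["FSC"]] / 25) * 14^2
        m[, "FSC"] <- exp(log(fsc_col) + 0.15 * rnorm(n_col))
        m[, "FSC_area"] <- m[, "FSC"] * exp(0.1 * rnorm(n_col))
        m
      })
      vals <- rbind(vals, col_vals)
      truth <- c(truth, rep("colony", n_col))
    }
    id <- sprintf("field_%02d", i)
    ev <- event_table(vals, sample_id = id)
    attr(ev, "truth") <- truth
    meta <- data.frame(sample_id = id, date = dates[i], TN = g[i] * light,
                       TP = 50, light = light)
    list(events = ev, metadata = meta)
  })
}

#' Generate synthetic calibration-bead events
#'
#' Bead forward scatter scales with the square of bead diameter (optical
#' cross-section), with a tight (< 5%) coefficient of variation, so FSC
#' medians are strictly increasing in bead size.
#'
#' @param sizes_um at least two distinct bead diameters (um).
#' @param config a [synth_config()].
#' @return an [event_table()] with attribute `bead_size` giving each event's
#'   true bead diameter.
#' @export
generate_beads <- function(sizes_um, config) {
  validate_synth_config(config)
  sizes_um <- as.numeric(sizes_um)
  if (length(unique(sizes_um)) < 2) {
    stopf("bead calibration needs at least 2 distinct sizes")
  }
  if (any(sizes_um <= 0)) stopf("bead sizes must be positive")
  ch <- config$channels
  fsc_per_um2 <- config$baseline_medians[["FSC"]] / 25
  n_per <- max(100L, ceiling(config$n_events / length(sizes_um)))
  with_seed(derive_seed(config$seed, 70001), {
    blocks <- lapply(sizes_um, function(s) {
      vals <- matrix(NA_real_, nrow = n_per, ncol = length(ch$all),
                     dimnames = list(NULL, ch$all))
      for (cn in ch$all) {
        med <- if (cn %in% c("FSC", "FSC_area")) fsc_per_um2 * s^2 else 50
        vals[, cn] <- exp(log(med) + 0.03 * rnorm(n_per))
      }
      vals
    })
    ev <- event_table(do.call(rbind, blocks), sample_id = "beads")
    attr(ev, "bead_size") <- rep(sizes_um, each = n_per)
    ev
  })
}

#' Generate a synthetic nutrient-addition bioassay
#'
#' Emulates a 4-day bottle bioassay: chlorophyll-a fluorescence read on day 0
#' and day 4 for control, +N, +P and +NP treatments with three replicates.
#' Additions relieving the designed limitation grow at an elevated rate
#' (0.35 vs 0.10 per day); day-4 readings carry lognormal replicate noise, so
#' per-replicate log growth rates are exactly normal.
#'
#' @param config a [synth_config()].
#' @param limiting designed limitation: `"N"`, `"P"`, `"N+P"` (co-limitation:
#'   only the combined addition responds) or `"none"`.
#' @return data.frame with columns `treatment, replicate, day0, day4`
#'   (class `bioassay_table`).
#' @export
generate_bioassay <- function(config, limiting = "none") {
  validate_synth_config(config)
  if (!limiting %in% c("N", "P", "N+P", "none")) {
    stopf("unknown limitation label '%s' (use N, P, N+P or none)", limiting)
  }
  treatments <- c("control", "+N", "+P", "+NP")
  base_rate <- 0.10
  boost_rate <- 0.35
  rate <- c(control = base_rate, `+N` = base_rate, `+P` = base_rate,
            `+NP` = base_rate)
  if (limiting == "N") rate[c("+N", "+NP")] <- boost_rate
  if (limiting == "P") rate[c("+P", "+NP")] <- boost_rate
  if (limiting == "N+P") rate["+NP"] <- boost_rate
  n_rep <- 3L
  lim_idx <- match(limiting, c("N", "P", "N+P", "none"))
  with_seed(derive_seed(config$seed, 80000 + lim_idx), {
    rows <- expand.grid(replicate = seq_len(n_rep), treatment = treatments,
                        stringsAsFactors = FALSE)[, c(2, 1)]
    day0 <- exp(log(100) + 0.05 * rnorm(nrow(rows)))
    day4 <- day0 * exp(4 * rate[rows$treatment]) * exp(0.1 * rnorm(nrow(rows)))
    out <- data.frame(treatment = rows$treatment, replicate = rows$replicate,
                      day0 = day0, day4 = day4)
    class(out) <- c("bioassay_table", "data.frame")
    attr(out, "limiting") <- limiting
    out
  })
}
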