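# Event-table container, IO, log10(x+1) transform, density-based gating of
# the target population, and the bead-calibrated size gate for field samples.

#' Per-event flow-cytometry table
#'
#' One row per detected event (a single cell or small colony), one column per
#' optical channel, values are nonnegative peak heights in instrument units.
#'
#' @param values numeric matrix (events x channels) with unique column names.
#' @param sample_id sample label.
#' @param transformed logical; `TRUE` once values are on the log10(x+1) scale.
#' @return object of class `event_table`: a list with elements `sample_id`,
#'   `channels`, `values`, `transformed`.
#' @export
event_table <- function(values, sample_id = "sample", transformed = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) < 1) stopf("event table needs at least one event")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stopf("channel names must be present and unique")
  }
  storage.mode(values) <- "double"
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopf("negative value in channel '%s', row %d",
          colnames(values)[neg[1, 2]], neg[1, 1])
  }
  structure(list(sample_id = sample_id, channels = colnames(values),
                 values = values, transformed = isTRUE(transformed)),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table '%s': %d events x %d channels%s\n", x$sample_id,
              nrow(x$values), length(x$channels),
              if (x$transformed) " (log10(x+1) scale)" else ""))
  cat("channels:", paste(head(x$channels, 8), collapse = ", "),
      if (length(x$channels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

#' Read an event table from disk
#'
#' @param path file path.
#' @param format `"csv"`: header row of channel names, one row per event.
#' @param sample_id sample label; defaults to the file name.
#' @return an [event_table()].
#' @export
read_events <- function(path, format = "csv", sample_id = NULL) {
  if (!identical(format, "csv")) {
    stopf("unknown format '%s' (supported: csv)", format)
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  event_table(as.matrix(df),
              sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an event table as CSV
#'
#' @param events an [event_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  write.csv(as.data.frame(events$values), path, row.names = FALSE)
  invisible(path)
}

#' log10(x + 1) transform of an event table
#'
#' Reduces the right skew of optical intensities before density clustering;
#' [back_transform()] restores the original values to machine precision.
#'
#' @param events an [event_table()] on the original scale.
#' @return transformed [event_table()].
#' @export
log_transform <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (events$transformed) stopf("events are already log-transformed")
  out <- events
  out$values <- log10(events$values + 1)
  out$transformed <- TRUE
  out
}

#' Invert the log10(x + 1) transform
#'
#' @param events a transformed [event_table()].
#' @return [event_table()] on the original scale.
#' @export
back_transform <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (!events$transformed) stopf("events are not log-transformed")
  out <- events
  out$values <- 10^events$values - 1
  out$values[out$values < 0] <- 0 # guard tiny negative rounding
  out$transformed <- FALSE
  out
}

#' Gated subset of an event table
#'
#' @param parent the parent [event_table()].
#' @param member_index indices of retained events.
#' @param cluster_labels optional per-event integer labels (-1 = noise).
#' @return object of class `gated_population`.
#' @export
gated_population <- function(parent, member_index, cluster_labels = NULL) {
  stopifnot(inherits(parent, "event_table"))
  member_index <- as.integer(member_index)
  if (length(member_index) < 1) stopf("member_index must be nonempty")
  if (any(member_index < 1 | member_index > nrow(parent$values))) {
    stopf("member_index out of range")
  }
  structure(list(parent = parent, member_index = member_index,
                 cluster_labels = cluster_labels),
            class = "gated_population")
}

#' @export
print.gated_population <- function(x, ...) {
  cat(sprintf("gated_population: %d / %d events retained from '%s'\n",
              length(x$member_index), nrow(x$parent$values),
              x$parent$sample_id))
  invisible(x)
}

#' Extract the gated events as an event table
#'
#' @param gated a [gated_population()].
#' @return an [event_table()] restricted to the gate members.
#' @export
gated_events <- function(gated) {
  stopifnot(inherits(gated, "gated_population"))
  ev <- gated$parent
  event_table(ev$values[gated$member_index, , drop = FALSE],
              sample_id = ev$sample_id, transformed = ev$transformed)
}

#' Isolate the target population by hierarchical density clustering
#'
#' Runs density-based hierarchical clustering (HDBSCAN: core distances,
#' mutual-reachability minimum spanning tree, condensed cluster tree,
#' excess-of-mass cluster selection) on the log-transformed channels and
#' selects the target cyanobacterial population among the resulting clusters.
#' Selection rule: among clusters holding at least `min_cluster_frac` of the
#' events, prefer the largest cluster whose median phycocyanin fluorescence
#' (`target_channel`) exceeds the overall clustered median; if no cluster is
#' that bright, fall back to the cluster with the highest median
#' `target_channel`. Noise events are labelled -1 and excluded.
#'
#' @param events a log-transformed [event_table()].
#' @param min_cluster_size smallest cluster size considered a cluster;
#'   default 1% of events with a floor of 25.
#' @param min_samples neighbourhood size for the density (core-distance)
#'   estimate.
#' @param min_cluster_frac minimum relative size for a cluster to be a target
#'   candidate.
#' @param target_channel channel whose median identifies the pigment-bright
#'   target population.
#' @param channels channels used for clustering; default all.
#' @return a [gated_population()] whose members form the target cluster;
#'   `cluster_labels` holds all cluster labels (-1 = noise).
#' @export
cluster_events <- function(events,
                           min_cluster_size = NULL,
                           min_samples = 10L,
                           min_cluster_frac = 0.05,
                           target_channel = "FL670",
                           channels = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (!events$transformed) {
    stopf("cluster_events expects log-transformed events; see log_transform()")
  }
  x <- events$values
  if (!is.null(channels)) {
    missing <- setdiff(channels, colnames(x))
    if (length(missing)) stopf("unknown channels: %s",
                               paste(missing, collapse = ", "))
    x <- x[, channels, drop = FALSE]
  }
  n <- nrow(x)
  if (is.null(min_cluster_size)) {
    min_cluster_size <- max(25L, ceiling(0.01 * n))
  }
  if (min_cluster_size < 2) stopf("min_cluster_size must be >= 2")
  labels <- hdbscan_labels(x, min_cluster_size = min_cluster_size,
                           min_samples = min_samples)
  keep <- labels != -1L
  if (!any(keep)) stopf("no target population found")
  if (!target_channel %in% colnames(events$values)) {
    stopf("target channel '%s' absent", target_channel)
  }
  tc <- events$values[, target_channel]
  ids <- sort(unique(labels[keep]))
  sizes <- vapply(ids, function(k) sum(labels == k), integer(1))
  meds <- vapply(ids, function(k) median(tc[labels == k]), numeric(1))
  cand <- sizes >= min_cluster_frac * n
  if (!any(cand)) stopf("no target population found")
  overall_med <- median(tc[keep])
  bright <- cand & meds > overall_med
  pick <- if (any(bright)) {
    ord <- order(-sizes, -meds)
    ord[ord %in% which(bright)][1]
  } else {
    which(cand)[which.max(meds[cand])]
  }
  target <- ids[pick]
  gated_population(events, which(labels == target), cluster_labels = labels)
}

#' Fit the bead size calibration
#'
#' Least-squares line through (log FSC median, log size) for each bead
#' population; the fitted mapping is `size = exp(intercept + slope * log FSC)`
#' and must be monotone increasing (slope > 0).
#'
#' @param beads an [event_table()] of bead events; populations are identified
#'   by the `bead_size` attribute when present, otherwise by k-means on
#'   log FSC with `length(known_sizes_um)` groups.
#' @param known_sizes_um bead diameters (um), ascending or any order.
#' @param fsc_channel forward-scatter channel name.
#' @return object of class `size_calibration` with `slope` and `intercept`.
#' @export
calibrate_size <- function(beads, known_sizes_um, fsc_channel = "FSC") {
  stopifnot(inherits(beads, "event_table"))
  known_sizes_um <- as.numeric(known_sizes_um)
  if (length(unique(known_sizes_um)) < 2) {
    stopf("calibration needs >= 2 distinct bead sizes")
  }
  fsc <- beads$values[, fsc_channel]
  grp <- attr(beads, "bead_size")
  if (!is.null(grp)) {
    meds <- tapply(fsc, grp, median)
    sizes <- as.numeric(names(meds))
    if (!setequal(round(sizes, 8), round(known_sizes_um, 8))) {
      stopf("bead_size attribute does not match known_sizes_um")
    }
  } else {
    km <- with_seed(1L, kmeans(log(fsc), centers = length(known_sizes_um),
                               nstart = 10))
    meds <- tapply(fsc, km$cluster, median)
    sizes <- sort(known_sizes_um)[rank(meds)]
  }
  o <- order(sizes)
  sizes <- sizes[o]
  meds <- as.numeric(meds)[o]
  if (any(diff(meds) <= 0)) {
    stopf("bead FSC medians are not increasing with bead size; check labels")
  }
  fit <- stats::lm.fit(cbind(1, log(meds)), log(sizes))
  cal <- structure(list(slope = unname(fit$coefficients[2]),
                        intercept = unname(fit$coefficients[1]),
                        fsc_channel = fsc_channel),
                   class = "size_calibration")
  if (cal$slope <= 0) stopf("calibration slope must be positive")
  cal
}

#' Map forward scatter to calibrated particle size
#'
#' @param cal a [calibrate_size()] fit.
#' @param fsc forward-scatter values (original scale).
#' @return particle diameters in um.
#' @export
predict_size <- function(cal, fsc) {
  stopifnot(inherits(cal, "size_calibration"))
  exp(cal$intercept + cal$slope * log(fsc))
}

#' Size-gate an event table
#'
#' Retains events whose bead-calibrated diameter lies in the closed interval
#' `[lo_um, hi_um]` (used on field samples to keep the 0.5-10 um single-cell
#' fraction and exclude large colonies or aggregates).
#'
#' @param events an [event_table()] on the original scale.
#' @param cal a [calibrate_size()] fit.
#' @param lo_um,hi_um gate bounds in um (closed on both ends).
#' @return a [gated_population()]; an empty gate raises a warning and returns
#'   `NULL`.
#' @export
size_gate <- function(events, cal, lo_um = 0.5, hi_um = 10) {
  stopifnot(inherits(events, "event_table"))
  if (events$transformed) stopf("size_gate expects original-scale events")
  if (!(lo_um < hi_um)) stopf("lo_um must be < hi_um")
  sizes <- predict_size(cal, events$values[, cal$fsc_channel])
  idx <- which(sizes >= lo_um & sizes <= hi_um)
  if (length(idx) == 0) {
    warnf("size gate [%g, %g] um retained no events in '%s'",
          lo_um, hi_um, events$sample_id)
    return(NULL)
  }
  gated_population(events, idx)
}
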