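# Independent brute-force oracles used to validate the Monte-Carlo
# hypervolume estimators, plus small shared utilities.

# Dense-grid evaluation of the same KDE a hypervolume uses (2-D only):
# region volume, evenness and dispersion by direct integration.
grid_fd_oracle <- function(hv, n_grid = 400, pad = 4) {
  stopifnot(hv$dims == 2)
  h <- hv$bandwidths
  X <- hv$data_points
  lo <- apply(X, 2, min) - pad * h
  hi <- apply(X, 2, max) + pad * h
  gx <- seq(lo[1], hi[1], length.out = n_grid)
  gy <- seq(lo[2], hi[2], length.out = n_grid)
  cell <- diff(gx)[1] * diff(gy)[1]
  pts <- as.matrix(expand.grid(gx, gy))
  f <- kde_density(hv, pts)
  reg <- f >= hv$threshold_density
  vol <- sum(reg) * cell
  mass <- sum(f[reg]) * cell
  f_res <- f[reg] / mass
  evenness <- sum(pmin(f_res, 1 / vol)) * cell
  cen <- c(mean(pts[reg, 1]), mean(pts[reg, 2]))
  dispersion <- mean(sqrt((pts[reg, 1] - cen[1])^2 +
                            (pts[reg, 2] - cen[2])^2))
  list(volume = vol, evenness = evenness, dispersion = dispersion)
}

# Grid Jaccard of two 2-D hypervolumes on a shared bounding box.
grid_jaccard_oracle <- function(hv_a, hv_b, n_grid = 400, pad = 4) {
  h <- pmax(hv_a$bandwidths, hv_b$bandwidths)
  lo <- pmin(apply(hv_a$data_points, 2, min),
             apply(hv_b$data_points, 2, min)) - pad * h
  hi <- pmax(apply(hv_a$data_points, 2, max),
             apply(hv_b$data_points, 2, max)) + pad * h
  gx <- seq(lo[1], hi[1], length.out = n_grid)
  gy <- seq(lo[2], hi[2], length.out = n_grid)
  pts <- as.matrix(expand.grid(gx, gy))
  in_a <- kde_density(hv_a, pts) >= hv_a$threshold_density
  in_b <- kde_density(hv_b, pts) >= hv_b$threshold_density
  sum(in_a & in_b) / sum(in_a | in_b)
}

# Adjusted Rand index between two labellings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Per-trait multiplicative effect implied by a channel effect row, in the
# order of trait_names(); the generator's ground truth for sign-recovery
# checks (volume exponent 1).
trait_effect_row <- function(config, treatment) {
  e <- config$effect_matrix[treatment, ]
  c(cell_size = unname(e["FSC"]), granularity = unname(e["SSC"]),
    gas_vesicle = unname(e["FSC"] / e["SSC"]),
    phycocyanin = unname(e["FL670"]),
    pc_per_size = unname(e["FL670"] / e["FSC"]),
    chlorophyll_a = unname(e["FL692"]),
    chla_per_size = unname(e["FL692"] / e["FSC"]),
    pc_chla = unname(e["FL670"] / e["FL692"]))
}
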