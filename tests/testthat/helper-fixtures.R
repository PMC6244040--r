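# Shared fixtures: everything is generated in code at test time.

# a small but fully featured field (plots, alleys, all four stages)
tiny_scene_cfg <- function(...) {
  scene_config(n_plot_rows = 2, n_plot_cols = 2, ...)
}

# a one-plant plot: single sowing row, single position, fixed apex height
single_plant_cfg <- function(apex = 150, ...) {
  scene_config(n_plot_rows = 1, n_plot_cols = 1,
               plot_depth = 1.0, row_spacing = 0.6, plant_density = 0.1,
               stages = data.frame(stage = "S4", das = 84),
               height_range = list(c(apex, apex)),
               noise_sd = 0, ...)
}

# planted 4-point prototypes: a common range of 10 (one noise scale means
# the same relative perturbation everywhere) and pairwise well separated
# under the shape-based distance in both orientations (no prototype is a
# shift or a mirror of another, which squared-NCC centroids would conflate)
proto_rise <- c(0, 10 / 3, 20 / 3, 10)
proto_peak_mid <- c(2, 6, 10, 0)
proto_zigzag <- c(0, 10, 0, 10)
proto_peak_early <- c(3, 10, 4, 0)

# open rectangle ring (counter-clockwise), as plot_roi expects
rect_ring_test <- function(xr, yr) {
  cbind(x = c(xr[1], xr[2], xr[2], xr[1]),
        y = c(yr[1], yr[1], yr[2], yr[2]))
}

# flat raster helper
flat_raster <- function(value, nr = 10, nc = 10, cell = 2,
                        origin = c(0, nr * cell / 100)) {
  trait_raster(matrix(value, nr, nc), cell, origin)
}

# independent brute-force shape-based distance: enumerate all 2T-1 shifts
# directly from the definition (kept free of package internals)
sbd_brute <- function(x, y) {
  zn <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
  x <- zn(x); y <- zn(y)
  t_len <- length(x)
  den <- sqrt(sum(x^2) * sum(y^2))
  if (den == 0) return(1)
  cc <- sapply(-(t_len - 1):(t_len - 1), function(s) {
    xs <- rep(0, t_len)
    if (s >= 0) xs[(1 + s):t_len] <- x[1:(t_len - s)]
    else xs[1:(t_len + s)] <- x[(1 - s):t_len]
    sum(xs * y)
  })
  1 - max(cc) / den
}

# long trait table with given group sizes and 4 stages of plausible values
synthetic_trait_table <- function(group_sizes = c(GRP1 = 107, GRP2 = 28,
                                                  GRP3 = 163, GRP4 = 90),
                                  seed = 1) {
  set.seed(seed)
  n <- sum(group_sizes)
  cal <- stage_calendar()
  plots <- sprintf("P%03d", seq_len(n))
  groups <- rep(names(group_sizes), group_sizes)
  tabs <- lapply(seq_len(nrow(cal)), function(s) {
    base_ph <- c(10, 125, 186, 253)[s]
    data.frame(plot_id = plots, genotype = sprintf("G%03d", seq_len(n)),
               group = groups, stage = cal$stage[s],
               cc = pmin(1, pmax(0.02, c(0.18, 0.68, 1.0, 0.94)[s] +
                                   rnorm(n, 0, 0.05))),
               ndvi = pmin(1, pmax(0, c(0.21, 0.29, 0.51, 0.40)[s] +
                                     rnorm(n, 0, 0.04))),
               ph = pmax(1, base_ph + rnorm(n, 0, base_ph * 0.1)),
               stringsAsFactors = FALSE)
  })
  build_trait_table(tabs, cal)
}
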