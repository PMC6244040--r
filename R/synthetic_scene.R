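#' Configuration of a synthetic breeding-field scene
#'
#' Describes a rectangular field of small breeding plots, the growth-stage
#' calendar, the bare-soil terrain and the optical contrast between plants
#' and soil. Defaults emulate a dense maize breeding trial: 2.4 m x 2 m
#' plots sown at 6 plants/m^2 in rows 0.6 m apart, four growth stages at
#' 24/44/57/84 days after sowing, nearly flat terrain (2 cm relief), and
#' reflectances that separate plants from soil with margin under both the
#' NGRDI sign rule and the NDVI > 0.1 rule.
#'
#' @param n_plot_rows,n_plot_cols plot grid layout.
#' @param plot_width,plot_depth plot size in m.
#' @param border_shrink inward ROI shrink in m.
#' @param row_spacing sowing row spacing in m.
#' @param plant_density sowing density, plants/m^2.
#' @param cell_size raster resolution, cm/pixel.
#' @param stages data.frame with columns `stage` and `das` (days after
#'   sowing, strictly increasing).
#' @param dem_relief_amplitude peak-to-mean amplitude of the smooth terrain
#'   undulation, cm.
#' @param plant_reflectance,soil_reflectance named numeric
#'   (`green`, `red`, `nir`) in `[0, 1]`.
#' @param height_range list, one `(min, max)` pair (cm) per stage: the range
#'   the tallest plant of a plot is drawn from.
#' @param crown_radius maximum crown radius of a full-height plant, m.
#' @param noise_sd standard deviation of per-plant apex jitter, cm.
#' @param alley spacing between adjacent plots, m.
#' @return An object of class `scene_config` (a validated list).
#' @export
scene_config <- function(n_plot_rows = 5, n_plot_cols = 4,
                         plot_width = 2.4, plot_depth = 2.0,
                         border_shrink = 0.25,
                         row_spacing = 0.6, plant_density = 6,
                         cell_size = 2,
                         stages = data.frame(
                           stage = c("S1", "S2", "S3", "S4"),
                           das = c(24, 44, 57, 84)),
                         dem_relief_amplitude = 2,
                         plant_reflectance = c(green = 0.12, red = 0.06,
                                               nir = 0.45),
                         soil_reflectance = c(green = 0.10, red = 0.12,
                                              nir = 0.14),
                         height_range = list(c(1, 26), c(69, 184),
                                             c(117, 251), c(148, 365)),
                         crown_radius = 0.35, noise_sd = 2, alley = 0.4) {
  cfg <- list(n_plot_rows = n_plot_rows, n_plot_cols = n_plot_cols,
              plot_width = plot_width, plot_depth = plot_depth,
              border_shrink = border_shrink, row_spacing = row_spacing,
              plant_density = plant_density, cell_size = cell_size,
              stages = stages, dem_relief_amplitude = dem_relief_amplitude,
              plant_reflectance = plant_reflectance,
              soil_reflectance = soil_reflectance,
              height_range = height_range, crown_radius = crown_radius,
              noise_sd = noise_sd, alley = alley)
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    if (n_plot_rows < 1 || n_plot_cols < 1)
      stop("need at least one plot row and column")
    if (plot_width <= 0 || plot_depth <= 0 || cell_size <= 0 ||
        row_spacing <= 0 || crown_radius <= 0 || alley < 0)
      stop("field dimensions, cell size, row spacing and crown radius must be positive")
    if (plot_width - 2 * border_shrink <= 0 ||
        plot_depth - 2 * border_shrink <= 0)
      stop("border_shrink must leave a non-empty inner plot")
    if (plant_density < 0) stop("plant_density must be non-negative")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    if (!all(c("stage", "das") %in% names(stages)) ||
        any(diff(stages$das) <= 0))
      stop("stages must have columns stage, das with strictly increasing das")
    if (length(height_range) != nrow(stages))
      stop("height_range needs one (min, max) pair per stage")
    need <- c("green", "red", "nir")
    if (!all(need %in% names(plant_reflectance)) ||
        !all(need %in% names(soil_reflectance)))
      stop("reflectances must name green, red and nir bands")
    refl <- c(plant_reflectance[need], soil_reflectance[need])
    if (any(refl < 0) || any(refl > 1))
      stop("reflectances must lie in [0, 1]")
    ngrdi <- function(v) (v[["green"]] - v[["red"]]) /
      (v[["green"]] + v[["red"]])
    ndvi <- function(v) (v[["nir"]] - v[["red"]]) / (v[["nir"]] + v[["red"]])
    if (!(ngrdi(plant_reflectance) > 0 && ngrdi(soil_reflectance) <= 0))
      stop("reflectances must give NGRDI > 0 for plant and <= 0 for soil")
    if (!(ndvi(plant_reflectance) > 0.1 && ndvi(soil_reflectance) <= 0.1))
      stop("reflectances must give NDVI > 0.1 for plant and <= 0.1 for soil")
  })
  invisible(cfg)
}

#' Generate a synthetic field scene
#'
#' Builds a complete multi-stage scene with known ground truth: a smooth
#' bare-soil DEM; per-stage DSMs in which every plant is a truncated
#' paraboloid crown (height `H * max(0, 1 - (r/R)^2)`) and the canopy is the
#' pointwise maximum over plants; per-stage green/red/NIR reflectance bands
#' that take the plant reflectance exactly where canopy height is positive
#' and the soil reflectance elsewhere; plot polygons with genotype and group
#' labels; and a truth table of the per-plot maximum plant height and
#' plant-pixel fraction at every stage.
#'
#' Within each plot, sowing rows run along the plot width at `row_spacing`;
#' plant positions are jittered and then snapped to pixel centres so the
#' rendered canopy attains each plant's apex height exactly. One plant near
#' the plot centre carries the plot's drawn stage maximum; the rest sit at
#' 60-95% of it with `noise_sd` jitter. Group labels are drawn with
#' probabilities 107:28:163:90 (GRP1:GRP2:GRP3:GRP4), the composition of a
#' 388-plot maize trial.
#'
#' @param cfg a [scene_config()].
#' @param seed integer seed; the only source of randomness.
#' @return An object of class `field_scene`: list with `cfg`, `dem`
#'   ([trait_raster()], cm), `stages` (per stage: `dsm` and `bands$green/
#'   red/nir` rasters), `plots` (list of [plot_roi()]) and `truth`
#'   (data.frame `plot_id`, `stage`, `das`, `true_ph`, `true_cc`).
#' @export
generate_field_scene <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "scene_config") || is.list(cfg))
  validate_scene_config(cfg)
  set.seed(seed)

  cs_m <- cfg$cell_size / 100
  fw <- cfg$n_plot_cols * (cfg$plot_width + cfg$alley) + cfg$alley
  fd <- cfg$n_plot_rows * (cfg$plot_depth + cfg$alley) + cfg$alley
  nc <- max(1L, round(fw / cs_m))
  nr <- max(1L, round(fd / cs_m))
  origin <- c(0, nr * cs_m)
  xs <- (seq_len(nc) - 0.5) * cs_m
  ys <- origin[2] - (seq_len(nr) - 0.5) * cs_m

  dem_v <- smooth_relief(xs, ys, cfg$dem_relief_amplitude)
  dem <- trait_raster(dem_v, cfg$cell_size, origin)

  n_stage <- nrow(cfg$stages)
  grp_w <- c(GRP1 = 107, GRP2 = 28, GRP3 = 163, GRP4 = 90)

  plots <- list()
  plants <- list()   # per plot: matrix (x, y) of snapped positions
  apex <- list()     # per plot: n_plants x n_stage apex heights (cm)
  k <- 0L
  for (pr in seq_len(cfg$n_plot_rows)) {
    for (pc in seq_len(cfg$n_plot_cols)) {
      k <- k + 1L
      x0 <- cfg$alley + (pc - 1) * (cfg$plot_width + cfg$alley)
      y1 <- fd - (cfg$alley + (pr - 1) * (cfg$plot_depth + cfg$alley))
      y0 <- y1 - cfg$plot_depth
      poly <- rect_ring(c(x0, x0 + cfg$plot_width), c(y0, y1))
      plots[[k]] <- plot_roi(sprintf("P%03d", k), sprintf("G%03d", k),
                             sample(names(grp_w), 1, prob = grp_w),
                             poly, border_shrink = cfg$border_shrink)
      pos <- sow_plants(x0, y0, cfg)
      if (nrow(pos)) {
        # snap to pixel centres so every apex is attained on the grid
        pos[, 1] <- xs[pmin(nc, pmax(1, round(pos[, 1] / cs_m + 0.5)))]
        pos[, 2] <- ys[pmin(nr, pmax(1, round((origin[2] - pos[, 2]) / cs_m + 0.5)))]
      }
      plants[[k]] <- pos
      vigor <- stats::runif(1)
      ap <- matrix(0, nrow(pos), n_stage)
      if (nrow(pos)) {
        cx <- x0 + cfg$plot_width / 2
        cy <- y0 + cfg$plot_depth / 2
        lead <- which.min((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2)
        for (s in seq_len(n_stage)) {
          hr <- cfg$height_range[[s]]
          hmax <- hr[1] + vigor * (hr[2] - hr[1])
          h <- hmax * stats::runif(nrow(pos), 0.6, 0.95) +
            stats::rnorm(nrow(pos), 0, cfg$noise_sd)
          h <- pmin(pmax(h, 0), hmax)
          h[lead] <- hmax
          ap[, s] <- h
        }
      }
      apex[[k]] <- ap
    }
  }

  hmax_ref <- max(vapply(cfg$height_range, max, 0))
  stage_out <- vector("list", n_stage)
  names(stage_out) <- cfg$stages$stage
  truth <- NULL
  plot_masks <- lapply(plots, function(p) polygon_mask(dem, p$polygon))
  roi_masks <- lapply(plots, function(p) polygon_mask(dem, p$roi_plot))

  for (s in seq_len(n_stage)) {
    canopy <- matrix(0, nr, nc)
    for (k in seq_along(plots)) {
      pos <- plants[[k]]
      for (i in seq_len(nrow(pos))) {
        h <- apex[[k]][i, s]
        if (h <= 0) next
        # crown radius grows with the square root of height, capped at R
        re <- cfg$crown_radius * min(1, sqrt(h / 150))
        jr <- which(abs(xs - pos[i, 1]) <= re)
        ir <- which(abs(ys - pos[i, 2]) <= re)
        if (!length(jr) || !length(ir)) next
        d2 <- outer((ys[ir] - pos[i, 2])^2, (xs[jr] - pos[i, 1])^2, `+`)
        crown <- h * pmax(0, 1 - d2 / re^2)
        canopy[ir, jr] <- pmax(canopy[ir, jr], crown)
      }
    }
    is_plant <- canopy > 0
    band <- function(b) {
      v <- matrix(cfg$soil_reflectance[[b]], nr, nc)
      v[is_plant] <- cfg$plant_reflectance[[b]]
      trait_raster(v, cfg$cell_size, origin)
    }
    stage_out[[s]] <- list(
      dsm = trait_raster(dem_v + canopy, cfg$cell_size, origin),
      bands = list(green = band("green"), red = band("red"),
                   nir = band("nir"))
    )
    truth <- rbind(truth, data.frame(
      plot_id = vapply(plots, `[[`, "", "plot_id"),
      stage = cfg$stages$stage[s],
      das = cfg$stages$das[s],
      true_ph = vapply(seq_along(plots), function(k) {
        m <- plot_masks[[k]]
        if (!any(m)) 0 else max(canopy[m])
      }, 0),
      true_cc = vapply(seq_along(plots), function(k) {
        m <- roi_masks[[k]]
        if (!any(m)) NA_real_ else mean(is_plant[m])
      }, 0),
      stringsAsFactors = FALSE
    ))
  }

  structure(
    list(cfg = cfg, dem = dem, stages = stage_out, plots = plots,
         truth = truth, seed = seed),
    class = "field_scene"
  )
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene> %d plots, %d stages, %d x %d cells at %.3g cm/pixel (seed %d)\n",
              length(x$plots), length(x$stages), nrow(x$dem$values),
              ncol(x$dem$values), x$cfg$cell_size, x$seed))
  invisible(x)
}

# smooth low-frequency terrain: a few random cosine waves scaled to amplitude
smooth_relief <- function(xs, ys, amplitude) {
  v <- matrix(0, length(ys), length(xs))
  if (amplitude <= 0) return(v)
  ext <- max(max(xs) - min(xs), max(ys) - min(ys), 1)
  for (w in 1:4) {
    wl <- stats::runif(1, ext / 3, ext)       # wavelength 1/3 to 1 field
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    fx <- cos(th) / wl
    fy <- sin(th) / wl
    v <- v + stats::runif(1, 0.5, 1) *
      cos(2 * pi * (outer(ys * fy, xs * fx, `+`)) + ph)
  }
  v * amplitude / max(abs(v))
}

# deterministic row layout + jittered in-row positions for one plot
sow_plants <- function(x0, y0, cfg) {
  n_rows <- max(1L, floor(cfg$plot_depth / cfg$row_spacing))
  if (cfg$plant_density <= 0) return(matrix(numeric(0), 0, 2))
  row_y <- y0 + cfg$row_spacing * (seq_len(n_rows) - 0.5)
  total <- cfg$plant_density * cfg$plot_width * cfg$plot_depth
  per_row <- max(1L, round(total / n_rows))
  dx <- cfg$plot_width / per_row
  pos <- NULL
  for (y in row_y) {
    px <- x0 + dx * (seq_len(per_row) - 0.5) +
      stats::runif(per_row, -0.2, 0.2) * dx
    py <- rep(y, per_row) + stats::runif(per_row, -0.05, 0.05)
    pos <- rbind(pos, cbind(px, py))
  }
  pos[, 1] <- pmin(pmax(pos[, 1], x0), x0 + cfg$plot_width)
  pos[, 2] <- pmin(pmax(pos[, 2], y0), y0 + cfg$plot_depth)
  unname(pos)
}

#' Write/read a field scene to/from a directory
#'
#' Rasters go to ESRI ASCII grids (`dem.asc`, `<stage>_dsm.asc`,
#' `<stage>_<band>.asc`), plot polygons with attributes to `plots.geojson`,
#' the truth table to `truth.csv` and the stage calendar to `stages.csv`.
#' All files are plain text.
#'
#' @param scene a `field_scene`.
#' @param dir output directory (created if missing).
#' @return `write_scene` returns `dir` invisibly; `read_scene` returns a
#'   `field_scene` (without the generating config).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(scene$dem, file.path(dir, "dem.asc"))
  for (s in names(scene$stages)) {
    st <- scene$stages[[s]]
    write_ascii_grid(st$dsm, file.path(dir, sprintf("%s_dsm.asc", s)))
    for (b in names(st$bands))
      write_ascii_grid(st$bands[[b]], file.path(dir, sprintf("%s_%s.asc", s, b)))
  }
  write_plots_geojson(scene$plots, file.path(dir, "plots.geojson"))
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$cfg$stages, file.path(dir, "stages.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  stages_tab <- utils::read.csv(file.path(dir, "stages.csv"),
                                stringsAsFactors = FALSE)
  stage_out <- lapply(stages_tab$stage, function(s) {
    list(dsm = read_ascii_grid(file.path(dir, sprintf("%s_dsm.asc", s))),
         bands = list(
           green = read_ascii_grid(file.path(dir, sprintf("%s_green.asc", s))),
           red = read_ascii_grid(file.path(dir, sprintf("%s_red.asc", s))),
           nir = read_ascii_grid(file.path(dir, sprintf("%s_nir.asc", s)))))
  })
  names(stage_out) <- stages_tab$stage
  structure(
    list(cfg = list(stages = stages_tab),
         dem = read_ascii_grid(file.path(dir, "dem.asc")),
         stages = stage_out,
         plots = read_plots_geojson(file.path(dir, "plots.geojson")),
         truth = utils::read.csv(file.path(dir, "truth.csv"),
                                 stringsAsFactors = FALSE),
         seed = NA_integer_),
    class = "field_scene"
  )
}

#' Specification of labelled synthetic trait time series
#'
#' Defines planted cluster structure for clustering and recognition-rate
#' tests: one prototype curve per intended cluster, member counts, i.i.d.
#' Gaussian noise, and a per-cluster mixture over genetic-background groups.
#'
#' @param prototypes list of numeric prototype curves, all the same length
#'   (one value per growth stage).
#' @param members_per_cluster integer vector (recycled) of members per
#'   cluster.
#' @param noise_sd standard deviation of the additive noise, trait units.
#' @param group_mixture numeric matrix, one row per cluster over groups
#'   GRP1..GRP4; rows must sum to 1. Default: every cluster uniform.
#' @param seed integer seed.
#' @return An object of class `trait_series_spec`.
#' @export
trait_series_spec <- function(prototypes, members_per_cluster = 30,
                              noise_sd = 0, group_mixture = NULL, seed = 1) {
  if (!length(prototypes)) stop("at least one prototype curve is required")
  len <- unique(vapply(prototypes, length, 0L))
  if (length(len) != 1L || len < 2L)
    stop("prototypes must share one length >= 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  nc <- length(prototypes)
  members <- rep_len(as.integer(members_per_cluster), nc)
  if (any(members < 1)) stop("members_per_cluster must be positive")
  if (is.null(group_mixture))
    group_mixture <- matrix(1 / 4, nc, 4)
  group_mixture <- as.matrix(group_mixture)
  if (nrow(group_mixture) != nc || ncol(group_mixture) != 4 ||
      any(group_mixture < 0) ||
      any(abs(rowSums(group_mixture) - 1) > 1e-8))
    stop("group_mixture must be clusters x 4 with rows summing to 1")
  structure(list(prototypes = prototypes, members = members,
                 noise_sd = noise_sd, group_mixture = group_mixture,
                 seed = seed),
            class = "trait_series_spec")
}

#' Generate a labelled trait matrix from planted prototypes
#'
#' Each member series is its cluster prototype plus i.i.d. Gaussian noise;
#' its group label is drawn from the cluster's mixture row. Deterministic
#' for a fixed spec (the seed lives in the spec).
#'
#' @param spec a [trait_series_spec()].
#' @return list with `series` (members x stages matrix, rows named
#'   `G0001`...), `true_labels` (integer cluster of origin) and
#'   `group_labels` (character `GRP1`..`GRP4`).
#' @export
generate_trait_matrix <- function(spec) {
  stopifnot(inherits(spec, "trait_series_spec"))
  set.seed(spec$seed)
  groups <- paste0("GRP", 1:4)
  series <- NULL; true_labels <- integer(0); group_labels <- character(0)
  for (cl in seq_along(spec$prototypes)) {
    n <- spec$members[cl]
    p <- spec$prototypes[[cl]]
    block <- matrix(rep(p, each = n), n, length(p)) +
      matrix(stats::rnorm(n * length(p), 0, spec$noise_sd), n, length(p))
    series <- rbind(series, block)
    true_labels <- c(true_labels, rep(cl, n))
    group_labels <- c(group_labels,
                      sample(groups, n, replace = TRUE,
                             prob = spec$group_mixture[cl, ]))
  }
  rownames(series) <- sprintf("G%04d", seq_len(nrow(series)))
  list(series = series, true_labels = true_labels,
       group_labels = group_labels)
}
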