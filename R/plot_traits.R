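#' Vegetation indices
#'
#' `compute_ngrdi` is the normalized green-red difference index
#' `(g - r) / (g + r)`; vegetation is positive, bare soil non-positive.
#' `compute_ndvi` is the normalized difference vegetation index
#' `(nir - r) / (nir + r)`. Pixels whose band sum is zero become nodata.
#' Both outputs lie in `[-1, 1]` where defined.
#'
#' @param green,red,nir co-registered reflectance rasters in `[0, 1]`.
#' @return a [trait_raster()] of index values.
#' @export
compute_ngrdi <- function(green, red) {
  normalized_difference(green, red)
}

#' @rdname compute_ngrdi
#' @export
compute_ndvi <- function(nir, red) {
  normalized_difference(nir, red)
}

normalized_difference <- function(a, b) {
  stopifnot(is_trait_raster(a), is_trait_raster(b))
  check_same_grid(a, b)
  s <- a$values + b$values
  v <- (a$values - b$values) / s
  v[!is.na(s) & s == 0] <- NA_real_
  trait_raster(v, a$cell_size, a$origin)
}

#' Plant/soil segmentation masks
#'
#' `plant_mask_from_ngrdi` classifies a pixel as plant iff NGRDI is strictly
#' positive; `plant_mask_from_ndvi` iff NDVI strictly exceeds `threshold`
#' (default 0.1). Values exactly on the boundary are soil. Nodata stays
#' nodata.
#'
#' @param ngrdi,ndvi index rasters.
#' @param threshold NDVI plant threshold (strict).
#' @return binary [trait_raster()] (1 = plant, 0 = soil, `NA` = nodata).
#' @export
plant_mask_from_ngrdi <- function(ngrdi) {
  stopifnot(is_trait_raster(ngrdi))
  trait_raster((ngrdi$values > 0) * 1, ngrdi$cell_size, ngrdi$origin)
}

#' @rdname plant_mask_from_ngrdi
#' @export
plant_mask_from_ndvi <- function(ndvi, threshold = 0.1) {
  stopifnot(is_trait_raster(ndvi))
  trait_raster((ndvi$values > threshold) * 1, ndvi$cell_size, ndvi$origin)
}

#' Crop surface model
#'
#' Canopy height above ground: the per-pixel difference DSM minus DEM, in
#' the elevation rasters' units (cm).
#'
#' @param dsm digital surface model (top of canopy).
#' @param dem digital elevation model (bare ground).
#' @return a [trait_raster()] of canopy heights.
#' @export
compute_csm <- function(dsm, dem) {
  stopifnot(is_trait_raster(dsm), is_trait_raster(dem))
  check_same_grid(dsm, dem)
  trait_raster(dsm$values - dem$values, dsm$cell_size, dsm$origin)
}

no_plant_error <- function(plot_id) {
  structure(
    class = c("no_plant_error", "error", "condition"),
    list(message = sprintf("no plant pixels in ROI of plot %s",
                           plot_id %||% "?"),
         call = NULL, plot_id = plot_id)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Neighbourhood maxima of a masked canopy surface
#'
#' First step of the plot-height method. The plant-masked canopy raster is
#' resampled to a coarser cell by max-aggregation (each coarse cell keeps
#' its highest native pixel, carrying that pixel's world coordinates), then
#' tiled into non-overlapping `window` x `window` blocks; each block with at
#' least one valid pixel emits the coordinates and value of its maximum.
#' Max-aggregation (rather than averaging) keeps the upper-leaf pixels the
#' method relies on; partial edge blocks are kept.
#'
#' @param csm_ph canopy raster already masked to plant pixels inside the
#'   plot ROI (everything else `NA`).
#' @param roi a [plot_roi()]; used for the error message and to restrict
#'   the search to the ROI bounding box.
#' @param resample_cell target cell size in cm (>= native cell size).
#' @param window block edge in resampled pixels (default 3).
#' @return data.frame with columns `x`, `y` (m) and `z` (cm): the maximum
#'   point set.
#' @export
block_maxima <- function(csm_ph, roi = NULL, resample_cell = 5, window = 3) {
  stopifnot(is_trait_raster(csm_ph))
  if (resample_cell < csm_ph$cell_size)
    stop("resample_cell must be at least the native cell size")
  if (window < 1) stop("window must be >= 1")
  v <- csm_ph$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  if (!nrow(idx)) stop(no_plant_error(if (!is.null(roi)) roi$plot_id))
  cc <- cell_centers(csm_ph)
  # super-cell index at the resampled grid, then at the window tiling
  f <- resample_cell / csm_ph$cell_size
  ci <- floor((idx[, 1] - 1) / f)
  cj <- floor((idx[, 2] - 1) / f)
  bi <- floor(ci / window)
  bj <- floor(cj / window)
  key <- paste(bi, bj)
  z <- v[idx]
  best <- vapply(split(seq_along(z), key),
                 function(ii) ii[which.max(z[ii])], 0L)
  data.frame(x = cc$x[idx[best, 2]], y = cc$y[idx[best, 1]], z = z[best],
             row.names = NULL)
}

#' Plot-scale plant height by ordinary kriging of canopy maxima
#'
#' Second step of the plot-height method: the maximum points are
#' interpolated by ordinary kriging over a grid covering the plot ROI, and
#' the maximum of the interpolated surface is the representative plot
#' height. The variogram is a spherical model (nugget, partial sill, range)
#' fitted by least squares to the binned empirical semivariogram, falling
#' back to a linear model when the fit degenerates. Kriging with
#' `gamma(0) = 0` on the diagonal is an exact interpolator, so the result
#' is never below the highest input point; with fewer than 5 points (too
#' few for a variogram) the maximum point value is returned directly.
#'
#' @param points data.frame `x`, `y` (m), `z` (cm) from [block_maxima()].
#' @param roi a [plot_roi()]; the prediction grid covers its shrunk
#'   rectangle. `NULL` uses the points' bounding box.
#' @param grid_cell prediction grid spacing in cm.
#' @return representative plant height in cm (scalar).
#' @export
krige_plot_height <- function(points, roi = NULL, grid_cell = 5) {
  if (is.null(points) || !nrow(points)) stop("empty point set")
  z <- points$z
  if (nrow(points) < 5 || stats::var(z) == 0) return(max(z))

  # deduplicate coincident locations (keep the higher point)
  ord <- order(points$x, points$y, -points$z)
  points <- points[ord, ]
  dup <- duplicated(points[, c("x", "y")])
  points <- points[!dup, ]
  z <- points$z
  if (nrow(points) < 5) return(max(z))

  vg <- fit_variogram(points)
  n <- nrow(points)
  dmat <- as.matrix(stats::dist(points[, c("x", "y")]))
  A <- rbind(cbind(vg$fn(dmat), 1), c(rep(1, n), 0))
  diag(A)[seq_len(n)] <- 0   # gamma(0) = 0: exact interpolation

  if (is.null(roi)) {
    xr <- range(points$x); yr <- range(points$y)
  } else {
    xr <- range(roi$roi_plot[, 1]); yr <- range(roi$roi_plot[, 2])
  }
  gc <- grid_cell / 100
  gx <- seq(xr[1] + gc / 2, xr[2], by = gc)
  gy <- seq(yr[1] + gc / 2, yr[2], by = gc)
  px <- c(rep(gx, each = length(gy)), points$x)
  py <- c(rep(gy, times = length(gx)), points$y)

  d0 <- sqrt(outer(points$x, px, `-`)^2 + outer(points$y, py, `-`)^2)
  g0 <- rbind(vg$fn(d0), 1)
  w <- tryCatch(solve(A, g0),
                error = function(e) solve(A + diag(1e-8, n + 1), g0))
  pred <- drop(crossprod(w[seq_len(n), , drop = FALSE], z))
  max(pred)
}

# least-squares spherical variogram fit on the binned empirical
# semivariogram; linear-through-origin fallback. Returns gamma(h) closure.
fit_variogram <- function(points, n_bins = 12) {
  d <- stats::dist(points[, c("x", "y")])
  g <- stats::dist(points$z)^2 / 2
  dmax <- max(d)
  keep <- d <= 0.75 * dmax & d > 0
  db <- as.numeric(d)[keep]; gb <- as.numeric(g)[keep]
  br <- seq(0, max(db), length.out = n_bins + 1)
  bin <- cut(db, br, include.lowest = TRUE)
  h <- tapply(db, bin, mean)
  gamma_h <- tapply(gb, bin, mean)
  ok <- is.finite(h) & is.finite(gamma_h)
  h <- h[ok]; gamma_h <- gamma_h[ok]

  spherical <- function(p) {
    c0 <- p[1]; c1 <- p[2]; a <- p[3]
    function(x) {
      s <- pmin(x / a, 1)
      out <- c0 + c1 * (1.5 * s - 0.5 * s^3)
      out[x == 0] <- 0
      out
    }
  }
  fit <- NULL
  if (length(h) >= 3) {
    obj <- function(p) sum((spherical(p)(h) - gamma_h)^2)
    init <- c(0, max(gamma_h), max(h) / 2)
    fit <- tryCatch(
      stats::optim(init, obj, method = "L-BFGS-B",
                   lower = c(0, 1e-12, 1e-6),
                   upper = c(max(gamma_h), 2 * max(gamma_h), 4 * dmax)),
      error = function(e) NULL)
  }
  if (!is.null(fit) && fit$par[2] > 0) {
    return(list(model = "spherical", par = fit$par,
                fn = spherical(fit$par)))
  }
  # linear fallback: gamma(h) = b h fitted through the origin
  b <- sum(gamma_h * h) / sum(h^2)
  if (!is.finite(b) || b <= 0) b <- 1
  list(model = "linear", par = c(slope = b), fn = function(x) b * x)
}

#' Plot-scale plant height from co-registered rasters
#'
#' The full height chain for one plot: CSM differencing, NGRDI plant
#' segmentation, clipping to the inward-shrunk plot ROI, neighbourhood
#' maxima, and ordinary kriging. A plot with no plant pixels yields a
#' missing-height record rather than an error.
#'
#' @param dsm,dem,green,red co-registered [trait_raster()]s.
#' @param roi a [plot_roi()].
#' @param resample_cell,window,grid_cell see [block_maxima()] and
#'   [krige_plot_height()].
#' @return one-row data.frame: `plot_id`, `ph` (cm, `NA` when missing),
#'   `ph_status` (`"ok"` or `"no-plant"`), `n_points` (maxima used).
#' @export
extract_plot_ph <- function(dsm, dem, green, red, roi,
                            resample_cell = 5, window = 3, grid_cell = 5) {
  stopifnot(inherits(roi, "plot_roi"))
  csm <- compute_csm(dsm, dem)
  mask <- plant_mask_from_ngrdi(compute_ngrdi(green, red))
  roi_m <- polygon_mask(csm, roi$roi_plot)
  v <- csm$values
  v[!(roi_m & !is.na(mask$values) & mask$values == 1)] <- NA_real_
  csm_ph <- trait_raster(v, csm$cell_size, csm$origin)
  tryCatch({
    pts <- block_maxima(csm_ph, roi, resample_cell = resample_cell,
                        window = window)
    data.frame(plot_id = roi$plot_id,
               ph = krige_plot_height(pts, roi, grid_cell = grid_cell),
               ph_status = "ok", n_points = nrow(pts),
               stringsAsFactors = FALSE)
  }, no_plant_error = function(e) {
    data.frame(plot_id = roi$plot_id, ph = NA_real_,
               ph_status = "no-plant", n_points = 0L,
               stringsAsFactors = FALSE)
  })
}

#' Canopy cover and mean NDVI of a plot
#'
#' `plot_cc` is the fraction of ROI pixels classified as plant: the area
#' ratio between the plant region and the whole (shrunk) plot. `plot_mean_ndvi`
#' is the arithmetic mean NDVI over those plant pixels; a plot with an empty
#' plant mask yields `NA` with a `"no-plant"` status attribute.
#'
#' @param ndvi_mask binary plant mask raster (from [plant_mask_from_ndvi()]).
#' @param ndvi NDVI raster.
#' @param roi a [plot_roi()]; its shrunk rectangle defines the ROI.
#' @return `plot_cc`: fraction in `[0, 1]`. `plot_mean_ndvi`: scalar mean
#'   (possibly `NA`).
#' @export
plot_cc <- function(ndvi_mask, roi) {
  stopifnot(is_trait_raster(ndvi_mask))
  m <- polygon_mask(ndvi_mask, roi)
  if (!any(m)) stop("ROI covers no pixel centres")
  mean(ndvi_mask$values[m] == 1, na.rm = TRUE)
}

#' @rdname plot_cc
#' @export
plot_mean_ndvi <- function(ndvi, ndvi_mask, roi) {
  stopifnot(is_trait_raster(ndvi), is_trait_raster(ndvi_mask))
  check_same_grid(ndvi, ndvi_mask)
  m <- polygon_mask(ndvi, roi)
  sel <- m & !is.na(ndvi_mask$values) & ndvi_mask$values == 1
  if (!any(sel)) {
    out <- NA_real_
    attr(out, "status") <- "no-plant"
    return(out)
  }
  mean(ndvi$values[sel], na.rm = TRUE)
}

#' Extract all plot traits for one growth stage of a scene
#'
#' Runs the full per-plot extraction (canopy cover, mean NDVI, kriged plant
#' height) over every plot of a [generate_field_scene()] scene (or one read
#' back with [read_scene()]).
#'
#' @param scene a `field_scene`.
#' @param stage stage id, e.g. `"S2"`.
#' @param resample_cell,window,grid_cell height-method parameters, see
#'   [block_maxima()] and [krige_plot_height()].
#' @return data.frame with one row per plot: `plot_id`, `genotype`, `group`,
#'   `stage`, `das`, `cc`, `ndvi`, `ph`, `ph_status`, `n_points`.
#' @export
extract_stage_traits <- function(scene, stage, resample_cell = 5,
                                 window = 3, grid_cell = 5) {
  stopifnot(inherits(scene, "field_scene"))
  st <- scene$stages[[stage]]
  if (is.null(st)) stop("unknown stage: ", stage)
  das <- scene$cfg$stages$das[match(stage, scene$cfg$stages$stage)]
  ndvi <- compute_ndvi(st$bands$nir, st$bands$red)
  nmask <- plant_mask_from_ndvi(ndvi)
  out <- lapply(scene$plots, function(p) {
    ph <- extract_plot_ph(st$dsm, scene$dem, st$bands$green, st$bands$red,
                          p, resample_cell = resample_cell, window = window,
                          grid_cell = grid_cell)
    mn <- plot_mean_ndvi(ndvi, nmask, p)
    data.frame(plot_id = p$plot_id, genotype = p$genotype, group = p$group,
               stage = stage, das = das,
               cc = plot_cc(nmask, p), ndvi = as.numeric(mn),
               ph = ph$ph, ph_status = ph$ph_status,
               n_points = ph$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
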