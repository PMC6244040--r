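#' Plot region of interest
#'
#' A breeding plot: identifier, genotype, genetic-background group, the full
#' plot rectangle and the analysis rectangle shrunk inward from every border.
#' Shrinking discards the border strip where leaves of adjacent plots cross,
#' which otherwise contaminates height and index extraction; 0.25 m is the
#' working default for tightly packed breeding plots.
#'
#' @param plot_id plot identifier (character).
#' @param genotype genotype label.
#' @param group genetic-background group label (`"GRP1"`..`"GRP4"`).
#' @param polygon 4x2 numeric matrix of rectangle corner coordinates (m),
#'   axis-aligned, any corner order; the ring is not closed.
#' @param border_shrink inward shrink distance in m (default 0.25); must
#'   leave positive width and depth.
#' @return An object of class `plot_roi` with elements `plot_id`, `genotype`,
#'   `group`, `polygon` and `roi_plot` (the shrunk rectangle).
#' @export
plot_roi <- function(plot_id, genotype = NA_character_, group = NA_character_,
                     polygon, border_shrink = 0.25) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 4L)
    stop("polygon must be a matrix of at least 4 corner coordinates (x, y)")
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  if (!all(polygon[, 1] %in% xr) || !all(polygon[, 2] %in% yr))
    stop("plot polygons must be axis-aligned rectangles")
  if (diff(xr) - 2 * border_shrink <= 0 || diff(yr) - 2 * border_shrink <= 0)
    stop("border_shrink too large: shrunk plot would be empty")
  structure(
    list(plot_id = as.character(plot_id), genotype = genotype, group = group,
         polygon = rect_ring(xr, yr),
         roi_plot = rect_ring(xr + c(1, -1) * border_shrink,
                              yr + c(1, -1) * border_shrink),
         border_shrink = border_shrink),
    class = "plot_roi"
  )
}

#' @export
print.plot_roi <- function(x, ...) {
  xr <- range(x$polygon[, 1]); yr <- range(x$polygon[, 2])
  cat(sprintf("<plot_roi> %s (%s, %s): %.2f x %.2f m at (%.2f, %.2f), shrink %.2f m\n",
              x$plot_id, x$genotype, x$group, diff(xr), diff(yr),
              xr[1], yr[1], x$border_shrink))
  invisible(x)
}

# counter-clockwise open ring for an axis-aligned rectangle
rect_ring <- function(xr, yr) {
  cbind(x = c(xr[1], xr[2], xr[2], xr[1]),
        y = c(yr[1], yr[1], yr[2], yr[2]))
}

#' Pixel mask of a polygon on a raster grid
#'
#' A pixel belongs to the polygon iff its centre lies inside (even-odd rule,
#' delegated to [mgcv::in.out()]). This centre rule is the fixed convention
#' for every mask in the package so that masks are bit-reproducible.
#'
#' @param r a [trait_raster()] supplying the grid.
#' @param polygon 2-column coordinate matrix (open ring), or a [plot_roi()]
#'   (its shrunk `roi_plot` is used).
#' @return logical matrix with the raster's dimensions.
#' @export
polygon_mask <- function(r, polygon) {
  stopifnot(is_trait_raster(r))
  if (inherits(polygon, "plot_roi")) polygon <- polygon$roi_plot
  polygon <- as.matrix(polygon)
  cc <- cell_centers(r)
  # restrict point-in-polygon test to the polygon's bounding box
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  jin <- which(cc$x >= xr[1] & cc$x <= xr[2])
  iin <- which(cc$y >= yr[1] & cc$y <= yr[2])
  m <- matrix(FALSE, nrow(r$values), ncol(r$values))
  if (!length(jin) || !length(iin)) return(m)
  pts <- cbind(rep(cc$x[jin], each = length(iin)),
               rep(cc$y[iin], times = length(jin)))
  bnd <- rbind(polygon, polygon[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, pts)
  m[iin, jin] <- inside
  m
}

#' Write/read plot polygons as GeoJSON
#'
#' Each plot becomes a Polygon feature with `plot_id`, `genotype`, `group`
#' and `border_shrink` properties. Coordinates are field metres.
#'
#' @param plots list of [plot_roi()] objects.
#' @param path output path.
#' @return `write_plots_geojson` returns `path` invisibly;
#'   `read_plots_geojson` returns a list of [plot_roi()].
#' @export
write_plots_geojson <- function(plots, path) {
  features <- lapply(plots, function(p) {
    ring <- rbind(p$polygon, p$polygon[1, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(ring, 1, as.list)))),
      properties = list(plot_id = p$plot_id, genotype = p$genotype,
                        group = p$group, border_shrink = p$border_shrink)
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plots_geojson
#' @export
read_plots_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) unlist(pt)))
    ring <- ring[-nrow(ring), , drop = FALSE]
    pr <- f$properties
    plot_roi(pr$plot_id, pr$genotype, pr$group, ring,
             border_shrink = pr$border_shrink)
  })
}
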