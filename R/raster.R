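#' Lightweight single-band raster
#'
#' A minimal in-memory raster: a numeric matrix plus a cell size and a world
#' origin. Rows run top to bottom, columns left to right; `NA` marks nodata.
#' World coordinates are metres; cell values carry their own units (cm for
#' elevation/height surfaces, dimensionless reflectance or index values for
#' band maps).
#'
#' The world position of the centre of cell `(i, j)` (row `i` from the top)
#' is `x = origin[1] + (j - 0.5) * cell_size / 100` and
#' `y = origin[2] - (i - 0.5) * cell_size / 100`, i.e. `origin` is the
#' top-left corner of the grid.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_size cell edge length in cm/pixel; must be positive.
#' @param origin length-2 numeric, world coordinates (m) of the top-left
#'   corner of the grid.
#' @return An object of class `trait_raster`.
#' @export
trait_raster <- function(values, cell_size, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number (cm/pixel)")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be a length-2 numeric vector")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "trait_raster"
  )
}

#' @export
print.trait_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<trait_raster> %d x %d cells, %.3g cm/pixel, origin (%.3f, %.3f) m\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (all(is.finite(rng)))
    cat(sprintf("  values in [%.4g, %.4g], %d nodata\n", rng[1], rng[2],
                sum(is.na(v))))
  else cat("  all nodata\n")
  invisible(x)
}

#' @export
dim.trait_raster <- function(x) dim(x$values)

is_trait_raster <- function(x) inherits(x, "trait_raster")

#' World coordinates of cell centres
#'
#' @param r a [trait_raster()].
#' @return list with numeric vectors `x` (per column) and `y` (per row), in m.
#' @keywords internal
cell_centers <- function(r) {
  cs <- r$cell_size / 100
  list(
    x = r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * cs,
    y = r$origin[2] - (seq_len(nrow(r$values)) - 0.5) * cs
  )
}

# All rasters entering one map-algebra op must share grid and extent.
check_same_grid <- function(...) {
  rs <- list(...)
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        !isTRUE(all.equal(r$cell_size, ref$cell_size)) ||
        !isTRUE(all.equal(r$origin, ref$origin)))
      stop("rasters do not share the same grid (dimensions, cell size, origin)")
  }
  invisible(TRUE)
}

#' Read/write rasters as ESRI ASCII grid
#'
#' Plain-text raster exchange format; the header records the lower-left
#' corner, cell size (m) and nodata marker, so the georeferencing round-trips.
#'
#' @param r a [trait_raster()].
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [trait_raster()].
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  stopifnot(is_trait_raster(r))
  v <- r$values
  cs_m <- r$cell_size / 100
  nodata <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$origin[1]),
    sprintf("yllcorner %.10g", r$origin[2] - nrow(v) * cs_m),
    sprintf("cellsize %.10g", cs_m),
    sprintf("NODATA_value %d", nodata)
  )
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(signif(v, digits), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == val[["nrows"]], ncol(v) == val[["ncols"]])
  v[v == val[["nodata_value"]]] <- NA_real_
  trait_raster(v, cell_size = val[["cellsize"]] * 100,
               origin = c(val[["xllcorner"]],
                          val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]]))
}
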