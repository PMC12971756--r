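#' Landcover codes
#'
#' Integer codes for the five landcover classes of the study mosaic:
#' mature forest (1), regenerating forest (2), narrow forest elements such
#' as living fencerows and riparian strips (3), arable land (4) and
#' pasture (5). `NA` cells are nodata.
#'
#' @format Named integer vector of length 5.
#' @export
LANDCOVER_CODES <- c(
  MATURE      = 1L,
  REGEN       = 2L,
  NARROW_ELEM = 3L,
  ARABLE      = 4L,
  PASTURE     = 5L
)

#' Create a landcover raster
#'
#' A minimal in-memory raster: an integer matrix of landcover codes plus
#' square-cell geometry in a projected metric CRS. Row 1 is the top
#' (northernmost) row, matching the Esri ASCII grid convention used by
#' [read_landcover()].
#'
#' @param grid Integer matrix of codes in `LANDCOVER_CODES`; `NA` = nodata.
#' @param cell_size Cell edge length in metres (default 10).
#' @param origin Numeric `(x, y)` of the lower-left corner of the grid.
#' @param crs Free-text identifier of the projected CRS.
#' @return An object of class `landcover_raster`.
#' @export
landcover_raster <- function(grid, cell_size = 10, origin = c(0, 0),
                             crs = "local-metric") {
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  bad <- !is.na(grid) & !(grid %in% LANDCOVER_CODES)
  if (any(bad))
    stop("unknown landcover code(s): ",
         paste(unique(grid[bad]), collapse = ", "), call. = FALSE)
  structure(
    list(grid = matrix(as.integer(grid), nrow(grid), ncol(grid)),
         cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = crs),
    class = "landcover_raster")
}

#' @export
print.landcover_raster <- function(x, ...) {
  cat(sprintf("<landcover_raster> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              x$origin[1], x$origin[2]))
  print(table(factor(x$grid, levels = LANDCOVER_CODES,
                     labels = names(LANDCOVER_CODES)), useNA = "ifany"))
  invisible(x)
}

#' Create a binary trapliner-habitat raster
#'
#' Same geometry as a landcover raster, but with cells coded 1 (habitat)
#' or 0 (non-habitat) under a recorded habitat definition.
#'
#' @param grid Binary matrix (0/1).
#' @param definition `"NARROW"` or `"BROAD"`.
#' @inheritParams landcover_raster
#' @return An object of class `habitat_raster`.
#' @export
habitat_raster <- function(grid, definition, cell_size = 10,
                           origin = c(0, 0), crs = "local-metric") {
  definition <- match.arg(definition, c("NARROW", "BROAD"))
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  if (!all(grid %in% c(0L, 1L)))
    stop("habitat grid must be binary 0/1", call. = FALSE)
  structure(
    list(grid = matrix(as.integer(grid), nrow(grid), ncol(grid)),
         definition = definition, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs = crs),
    class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf(
    "<habitat_raster:%s> %d x %d cells @ %g m, %d habitat cells (%.1f ha)\n",
    x$definition, nrow(x$grid), ncol(x$grid), x$cell_size,
    sum(x$grid), sum(x$grid) * x$cell_size^2 / 1e4))
  invisible(x)
}

#' Classify landcover into trapliner habitat
#'
#' Applies one of the two habitat definitions for traplining hummingbirds:
#' `"NARROW"` counts only mature forest as habitat; `"BROAD"` additionally
#' counts regenerating forest and narrow forest elements. Arable land,
#' pasture and nodata cells are never habitat.
#'
#' @param landcover A [landcover_raster()].
#' @param definition `"NARROW"` or `"BROAD"`.
#' @return A [habitat_raster()] with the same geometry.
#' @export
classify_habitat <- function(landcover, definition = c("NARROW", "BROAD")) {
  stopifnot(inherits(landcover, "landcover_raster"))
  definition <- match.arg(definition)
  codes <- if (definition == "NARROW") LANDCOVER_CODES["MATURE"] else
    LANDCOVER_CODES[c("MATURE", "REGEN", "NARROW_ELEM")]
  g <- landcover$grid
  hab <- matrix(0L, nrow(g), ncol(g))
  hab[!is.na(g) & g %in% codes] <- 1L
  habitat_raster(hab, definition, landcover$cell_size, landcover$origin,
                 landcover$crs)
}

# grid matrix of a raster-like object (habitat/landcover grid or patch labels)
grid_of <- function(x) if (!is.null(x$grid)) x$grid else x$labels

# centre coordinates of every cell; row 1 is the top row
cell_centres <- function(raster) {
  g <- grid_of(raster)
  cs <- raster$cell_size
  xs <- raster$origin[1] + (seq_len(ncol(g)) - 0.5) * cs
  ys <- raster$origin[2] + (nrow(g) - seq_len(nrow(g)) + 0.5) * cs
  list(x = xs, y = ys)
}

# (row, col) of the cell containing point (x, y); errors outside the extent
point_to_pixel <- function(raster, x, y) {
  g <- grid_of(raster)
  cs <- raster$cell_size
  col <- floor((x - raster$origin[1]) / cs) + 1
  row <- nrow(g) - floor((y - raster$origin[2]) / cs)
  if (any(col < 1 | col > ncol(g) | row < 1 | row > nrow(g)))
    stop("point falls outside the raster extent", call. = FALSE)
  cbind(row = row, col = col)
}

# centre (x, y) of pixel (row, col)
pixel_centre <- function(raster, row, col) {
  g <- grid_of(raster)
  cs <- raster$cell_size
  cbind(x = raster$origin[1] + (col - 0.5) * cs,
        y = raster$origin[2] + (nrow(g) - row + 0.5) * cs)
}

#' Create a sampling site
#'
#' A sampling site is a point in the raster CRS (typically the median
#' coordinate of the site's maternal plants); its pixel is derived on
#' construction and must fall inside the raster extent.
#'
#' @param site_id Site identifier.
#' @param x,y Coordinates in metres.
#' @param raster A raster object used to derive the pixel.
#' @return An object of class `sampling_site` with fields `site_id`, `x`,
#'   `y`, `pixel` (row, col).
#' @export
sampling_site <- function(site_id, x, y, raster) {
  px <- point_to_pixel(raster, x, y)
  structure(list(site_id = as.character(site_id), x = x, y = y,
                 pixel = c(row = unname(px[1, "row"]),
                           col = unname(px[1, "col"]))),
            class = "sampling_site")
}

#' Component-wise median coordinate of maternal plants
#'
#' The site centre is the per-axis median of the sampled maternal-plant
#' coordinates; for an even number of plants, the mean of the two central
#' order statistics per axis.
#'
#' @param coords Two-column matrix or data frame of `(x, y)` coordinates.
#' @return Numeric vector `c(x, y)`.
#' @export
median_site_coordinate <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("at least one coordinate required", call. = FALSE)
  c(x = stats::median(coords[, 1]), y = stats::median(coords[, 2]))
}

#' Clip a habitat raster to the local landscape
#'
#' Retains habitat cells whose centre lies within `radius` metres of the
#' centre of the site pixel; all other cells become non-habitat. The grid
#' geometry is unchanged, so patch labels and distances remain comparable.
#'
#' @param habitat A [habitat_raster()].
#' @param site A [sampling_site()].
#' @param radius Radius in metres (default 1000, the maximum daily movement
#'   range of traplining hummingbirds).
#' @return A clipped [habitat_raster()].
#' @export
clip_local_landscape <- function(habitat, site, radius = 1000) {
  stopifnot(inherits(habitat, "habitat_raster"),
            inherits(site, "sampling_site"))
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be positive", call. = FALSE)
  ctr <- pixel_centre(habitat, site$pixel["row"], site$pixel["col"])
  cc <- cell_centres(habitat)
  dx2 <- (cc$x - ctr[1, "x"])^2
  dy2 <- (cc$y - ctr[1, "y"])^2
  inside <- outer(dy2, dx2, `+`) <= radius^2
  g <- habitat$grid
  g[!inside] <- 0L
  habitat_raster(g, habitat$definition, habitat$cell_size, habitat$origin,
                 habitat$crs)
}
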