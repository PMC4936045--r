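# Landscape layers are plain numeric matrices indexed [row, col]; row 1 lies at
# the southern edge and column 1 at the western edge. A grid_spec carries the
# georeferencing shared by every layer of a stack. Coordinates are planar
# metres throughout; distances are stored in kilometres.

#' Regular planar grid specification
#'
#' Describes the common raster grid on which all landscape layers live:
#' origin (south-west corner), square cell size in metres, and dimensions.
#'
#' @param n_rows,n_cols Number of rows (south to north) and columns (west to
#'   east); both at least 1.
#' @param cell_size Cell edge length in metres (default 25 m, the resolution
#'   of the topographic source layers the covariates emulate).
#' @param origin_x,origin_y Planar coordinates (m) of the grid's south-west
#'   corner.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 25, origin_x = 0, origin_y = 0) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("`n_rows` and `n_cols` must be integers >= 1")
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("<grid_spec> %d x %d cells of %g m, extent x [%g, %g] y [%g, %g]\n",
              x$n_rows, x$n_cols, x$cell_size, ext[1], ext[2], ext[3], ext[4]))
  invisible(x)
}

#' Grid extent
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
grid_extent <- function(grid) {
  c(grid$origin_x, grid$origin_x + grid$n_cols * grid$cell_size,
    grid$origin_y, grid$origin_y + grid$n_rows * grid$cell_size)
}

#' Cell-centre coordinates
#'
#' @param grid A [grid_spec()].
#' @return List with `x` (length `n_cols`) and `y` (length `n_rows`) centre
#'   coordinates in metres.
#' @export
cell_centers <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

# Half-open cell assignment: a coordinate on a cell boundary belongs to the
# cell on its east/north side, i.e. cell j covers [x_j, x_j + cell_size).
# Returns NA row/col for points outside the extent.
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Land-cover class labels
#'
#' The seven land-cover classes used throughout: bog, tree-rich bog (TRB),
#' clearcut, young forest, mid-aged forest, old forest and the implicit
#' reference class "other". The first six enter models as dummy indicators;
#' "other" is the baseline.
#' @export
landcover_classes <- function() {
  c("bog", "TRB", "clearcut", "young", "mid_aged", "old", "other")
}

landcover_indicator_classes <- function() landcover_classes()[1:6]

#' Bundle co-registered landscape layers
#'
#' @param grid A [grid_spec()] shared by all layers.
#' @param continuous Named list of numeric matrices (`n_rows` x `n_cols`).
#'   Layers whose names start with `dist_` must be non-negative (kilometres);
#'   a layer named `ndvi` must lie in \[-1, 1\].
#' @param landcover Integer matrix of class codes 1..7 indexing
#'   [landcover_classes()].
#' @return An object of class `landscape_stack`.
#' @export
landscape_stack <- function(grid, continuous, landcover) {
  stopifnot(inherits(grid, "grid_spec"), is.list(continuous))
  dims <- c(grid$n_rows, grid$n_cols)
  for (nm in names(continuous)) {
    m <- continuous[[nm]]
    if (!is.matrix(m) || !all(dim(m) == dims))
      stop("layer '", nm, "' does not match the grid dimensions")
    if (startsWith(nm, "dist_") && any(m < 0, na.rm = TRUE))
      stop("distance layer '", nm, "' has negative values")
    if (nm == "ndvi" && any(m < -1 | m > 1, na.rm = TRUE))
      stop("ndvi layer outside [-1, 1]")
  }
  if (!all(dim(landcover) == dims))
    stop("landcover layer does not match the grid dimensions")
  codes <- unique(as.vector(landcover))
  if (!all(codes %in% seq_along(landcover_classes())))
    stop("landcover codes outside 1..", length(landcover_classes()))
  structure(list(grid = grid, continuous = continuous,
                 landcover = landcover),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d cells of %g m\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size))
  cat("  continuous layers:", paste(names(x$continuous), collapse = ", "), "\n")
  tab <- table(factor(landcover_classes()[x$landcover],
                      levels = landcover_classes()))
  cat("  landcover:", paste(sprintf("%s %.2f", names(tab),
                                    as.numeric(tab) / sum(tab)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Normalized difference vegetation index
#'
#' Computes `(NIR - Red) / (NIR + Red)` per cell; cells where both bands are
#' zero get `NA`.
#'
#' @param nir,red Co-registered non-negative reflectance matrices.
#' @return Matrix of NDVI values in \[-1, 1\] (NA where undefined).
#' @export
compute_ndvi <- function(nir, red) {
  if (!is.matrix(nir) || !is.matrix(red) || !all(dim(nir) == dim(red)))
    stop("`nir` and `red` must be matrices on the same grid")
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE))
    stop("reflectance bands must be non-negative")
  denom <- nir + red
  out <- (nir - red) / denom
  out[denom == 0] <- NA_real_
  out
}

#' Linear landscape features
#'
#' @param habitations Two-column matrix (x, y) of habitation points, in metres.
#' @param roads,forest_roads Lists of polylines; each polyline a two-column
#'   matrix of vertices.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(habitations = NULL, roads = list(), forest_roads = list()) {
  as_pts <- function(p) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p); stopifnot(ncol(p) == 2); storage.mode(p) <- "double"; p
  }
  structure(list(habitations = as_pts(habitations),
                 roads = lapply(roads, as_pts),
                 forest_roads = lapply(forest_roads, as_pts)),
            class = "feature_set")
}

# Squared distance from points (px, py) to one segment, vectorized over points.
dist2_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

polyline_segments <- function(lines) {
  segs <- lapply(lines, function(l) {
    k <- nrow(l)
    if (k < 2) return(NULL)
    cbind(l[-k, 1], l[-k, 2], l[-1, 1], l[-1, 2])
  })
  do.call(rbind, segs)
}

# Minimum distance (m) from arbitrary points to a feature class.
min_dist_to_class <- function(px, py, features, which) {
  which <- match.arg(which, c("habitation", "road", "forest_road"))
  d2 <- rep(Inf, length(px))
  if (which == "habitation") {
    pts <- features$habitations
    if (is.null(pts) || nrow(pts) == 0)
      stop("no features of class 'habitation'")
    for (i in seq_len(nrow(pts)))
      d2 <- pmin(d2, (px - pts[i, 1])^2 + (py - pts[i, 2])^2)
  } else {
    lines <- if (which == "road") features$roads else features$forest_roads
    segs <- polyline_segments(lines)
    if (is.null(segs) || nrow(segs) == 0)
      stop("no features of class '", which, "'")
    for (i in seq_len(nrow(segs)))
      d2 <- pmin(d2, dist2_to_segment(px, py, segs[i, 1], segs[i, 2],
                                      segs[i, 3], segs[i, 4]))
  }
  sqrt(d2)
}

#' Distance-to-feature raster
#'
#' For each cell centre, the Euclidean distance to the nearest feature of the
#' requested class (habitation points, or road / forest-road polylines),
#' in kilometres.
#'
#' @param grid A [grid_spec()].
#' @param features A [feature_set()].
#' @param which One of `"habitation"`, `"road"`, `"forest_road"`.
#' @return Matrix (`n_rows` x `n_cols`) of distances in km.
#' @export
distance_to_features <- function(grid, features,
                                 which = c("habitation", "road", "forest_road")) {
  which <- match.arg(which)
  cc <- cell_centers(grid)
  px <- rep(cc$x, each = grid$n_rows)
  py <- rep(cc$y, times = grid$n_cols)
  d <- min_dist_to_class(px, py, features, which)
  matrix(d / 1000, nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Extract covariate rows at points
#'
#' Nearest-cell lookup of every continuous layer plus expansion of the
#' land-cover code into the six dummy indicators (`other` is the all-zero
#' baseline). Cell assignment uses half-open intervals, so a point exactly on
#' a boundary belongs to the cell to its east/north.
#'
#' @param stack A [landscape_stack()].
#' @param points Two-column matrix or data frame of planar coordinates (m).
#' @return A [tibble::tibble] with one row per point: `x`, `y`, every
#'   continuous layer, `landcover` (class label) and the six indicators.
#' @export
extract_at_points <- function(stack, points) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  idx <- cell_index(stack$grid, pts[, 1], pts[, 2])
  bad <- which(is.na(idx$row))
  if (length(bad))
    stop(sprintf("point (%g, %g) lies outside the grid extent",
                 pts[bad[1], 1], pts[bad[1], 2]))
  lin <- cbind(idx$row, idx$col)
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2])
  for (nm in names(stack$continuous)) out[[nm]] <- stack$continuous[[nm]][lin]
  code <- stack$landcover[lin]
  out$landcover <- landcover_classes()[code]
  for (cl in landcover_indicator_classes())
    out[[cl]] <- as.numeric(out$landcover == cl)
  out
}

#' Write / read a layer as ESRI ASCII grid
#'
#' Plain-text raster interchange for single layers.
#'
#' @param layer Numeric matrix as stored in a [landscape_stack()].
#' @param grid The [grid_spec()].
#' @param path Output file.
#' @export
write_ascii_grid <- function(layer, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$n_cols), paste("nrows", grid$n_rows),
               paste("xllcorner", grid$origin_x), paste("yllcorner", grid$origin_y),
               paste("cellsize", grid$cell_size), "NODATA_value -9999"), con)
  m <- layer; m[is.na(m)] <- -9999
  # ASCII grids are written north-to-south
  for (i in rev(seq_len(grid$n_rows)))
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                          tolower(vapply(kv, `[`, "", 1)))
  body <- utils::read.table(path, skip = 6)
  m <- as.matrix(body)
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(layer = m,
       grid = grid_spec(n_rows = vals[["nrows"]], n_cols = vals[["ncols"]],
                        cell_size = vals[["cellsize"]],
                        origin_x = vals[["xllcorner"]],
                        origin_y = vals[["yllcorner"]]))
}
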