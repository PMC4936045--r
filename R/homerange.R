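# 100% minimum convex polygon home ranges and availability sampling.
# Geometry is planar; polygons are open rings (first vertex not repeated),
# counter-clockwise.

cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

#' Convex hull (100% minimum convex polygon)
#'
#' Andrew's monotone-chain hull. Collinear points on a hull edge are not
#' vertices (strict-turn tie-break), so the vertex list is the unique minimal
#' one.
#'
#' @param points Two-column matrix or data frame of planar coordinates (m).
#' @return Matrix of hull vertices in counter-clockwise order (open ring),
#'   class `mcp_ring`, with attribute `area` (m^2).
#' @export
convex_hull <- function(points) {
  pts <- unique(as.matrix(points[, 1:2, drop = FALSE]))
  if (nrow(pts) < 3) stop("degenerate hull: fewer than 3 distinct points")
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  n <- nrow(pts)
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross2(pts[h[length(h) - 1], 1], pts[h[length(h) - 1], 2],
                    pts[h[length(h)], 1], pts[h[length(h)], 2],
                    pts[i, 1], pts[i, 2]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3) stop("degenerate hull: all points collinear")
  ring <- pts[hull, , drop = FALSE]
  colnames(ring) <- c("x", "y")
  structure(ring, class = c("mcp_ring", class(ring)),
            area = polygon_area(ring))
}

#' Polygon area (shoelace formula)
#'
#' @param ring Open polygon ring (two-column matrix of vertices).
#' @return Area in the square of the coordinate unit.
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Point-in-polygon test
#'
#' Ray-crossing test, vectorized over points. Points on the boundary count as
#' inside, so hull vertices are themselves valid availability draws.
#'
#' @param px,py Point coordinates (numeric vectors).
#' @param ring Open polygon ring.
#' @param eps Boundary tolerance in coordinate units.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, ring, eps = 1e-9) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    # boundary check: distance to edge within eps
    d2 <- dist2_to_segment(px, py, xi, yi, xj, yj)
    on_edge <- on_edge | d2 <= eps^2
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Estimate per-bear-year MCP home ranges
#'
#' @param bear_years List of [bear_year_record()]s; the hull is taken over all
#'   of each record's current relocations (by default the annual, DOP-filtered
#'   set, before season truncation).
#' @return Named list of `mcp_ring`s, keyed `bear_id/year`.
#' @export
mcp_home_ranges <- function(bear_years) {
  out <- lapply(bear_years, function(b)
    convex_hull(cbind(b$relocations$x, b$relocations$y)))
  names(out) <- vapply(bear_years, function(b)
    paste0(b$bear_id, "/", b$year), "")
  out
}

#' Sample availability points
#'
#' Uniform rejection sampling from the region's bounding box until `n` points
#' fall inside. For third-order selection the region is a bear-year's MCP;
#' for second-order selection pass the study-area extent (or any polygon).
#'
#' @param n Number of points (matched to the bear-year's retained used
#'   points).
#' @param region An `mcp_ring` polygon or a length-4 extent
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param seed Integer seed (a separate stream from the telemetry generator,
#'   so availability never leaks information about used points).
#' @param max_tries Safety cap on proposals; exceeding it (acceptance below
#'   ~1e-4) signals a degenerate sliver region.
#' @return Two-column matrix of points.
#' @export
sample_availability <- function(n, region, seed = 1, max_tries = 1e4 * max(n, 1)) {
  set.seed(seed)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (is.matrix(region) || is.data.frame(region)) {
    ring <- as.matrix(region)
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    test <- function(px, py) point_in_polygon(px, py, ring)
  } else {
    stopifnot(length(region) == 4)
    bb <- c(region[1], region[2], region[3], region[4])
    test <- function(px, py) rep(TRUE, length(px))
  }
  xs <- numeric(0); ys <- numeric(0); tries <- 0
  while (length(xs) < n) {
    m <- max(1000L, 2L * (n - length(xs)))
    tries <- tries + m
    if (tries > max_tries)
      stop("availability sampling acceptance rate too low; degenerate region?")
    px <- stats::runif(m, bb[1], bb[2])
    py <- stats::runif(m, bb[3], bb[4])
    ok <- test(px, py)
    xs <- c(xs, px[ok]); ys <- c(ys, py[ok])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Matched availability for every bear-year
#'
#' Third-order: one availability point per retained used point, drawn inside
#' the bear-year's MCP. Second-order: the same counts drawn over the study
#' area (union bounding extent of all MCPs, or a supplied polygon).
#'
#' @param bear_years Retained, truncated [bear_year_record()]s.
#' @param home_ranges Result of [mcp_home_ranges()] (on the annual fixes).
#' @param order `"third"` (within home range, default) or `"second"` (study
#'   area).
#' @param study_area Optional polygon for second-order sampling.
#' @param seed Integer seed.
#' @return Named list (keyed `bear_id/year`) of point matrices.
#' @export
sample_study_availability <- function(bear_years, home_ranges,
                                      order = c("third", "second"),
                                      study_area = NULL, seed = 1) {
  order <- match.arg(order)
  keys <- vapply(bear_years, function(b) paste0(b$bear_id, "/", b$year), "")
  set.seed(seed)
  seeds <- sample.int(2^20, length(keys))
  if (order == "second" && is.null(study_area)) {
    allv <- do.call(rbind, lapply(home_ranges, unclass))
    study_area <- c(range(allv[, 1]), range(allv[, 2]))
  }
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    n <- nrow(bear_years[[i]]$relocations)
    region <- if (order == "third") home_ranges[[keys[i]]] else study_area
    out[[i]] <- sample_availability(n, region, seed = seeds[i])
  }
  names(out) <- keys
  out
}

#' Write polygons as GeoJSON
#'
#' @param rings Named list of `mcp_ring`s.
#' @param path Output file.
#' @export
write_geojson_polygons <- function(rings, path) {
  feats <- lapply(names(rings), function(nm) {
    ring <- unclass(rings[[nm]])
    closed <- rbind(ring, ring[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(id = nm, area_m2 = attr(rings[[nm]], "area")),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(i) closed[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
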