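#' Rectangular prediction grid over the study area
#'
#' An `nx` x `ny` lattice of evenly spaced points spanning the dataset's
#' coordinate bounding box (corner points coincide with the box corners). The
#' same grid should be reused for every time window so maps are comparable.
#'
#' @param data an [ed_dataset()] (or anything with `x`, `y` columns).
#' @param nx,ny lattice nodes per axis, each >= 2.
#' @return object of class `ed_grid`: `points` (data.frame `x`, `y`, row-major
#'   with x varying fastest), `active` (logical mask), `nx`, `ny`, `xs`, `ys`.
#' @export
make_grid <- function(data, nx = 50, ny = 50) {
  stopifnot(nx >= 2, ny >= 2)
  rx <- range(data$x)
  ry <- range(data$y)
  if (rx[1] == rx[2] || ry[1] == ry[2])
    stop("degenerate bounding box: zero extent along an axis", call. = FALSE)
  xs <- seq(rx[1], rx[2], length.out = nx)
  ys <- seq(ry[1], ry[2], length.out = ny)
  pts <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  structure(list(points = pts, active = rep(TRUE, nrow(pts)),
                 nx = nx, ny = ny, xs = xs, ys = ys),
            class = "ed_grid")
}

#' @export
print.ed_grid <- function(x, ...) {
  cat(sprintf("prediction grid: %d x %d = %d points, %d active\n",
              x$nx, x$ny, x$nx * x$ny, sum(x$active)))
  invisible(x)
}

#' Clip a prediction grid to the study area
#'
#' Deactivates grid points outside the study-area polygon (if one is given)
#' and points farther than `max_mask_distance` from every data point — the
#' low-population-density edges where a loess GAM is least reliable. Both
#' filters are optional; masked points are excluded from prediction, testing
#' and display.
#'
#' @param grid an [make_grid()] object.
#' @param polygon an `ed_polygon` from [read_mask()], a list of ring matrices,
#'   a single 2-column matrix, or `NULL` for no polygon clipping.
#' @param data dataset whose point density defines the distance mask (`NULL`
#'   to skip).
#' @param max_mask_distance retain grid points within this distance of at
#'   least `min_points` data point(s); `Inf` disables the filter.
#' @param min_points minimum number of records within `max_mask_distance` for
#'   a grid point to stay active (default 1; larger values clip low-density
#'   edges more aggressively).
#' @return the grid with its `active` flags updated.
#' @export
apply_mask <- function(grid, polygon = NULL, data = NULL,
                       max_mask_distance = Inf, min_points = 1L) {
  stopifnot(inherits(grid, "ed_grid"), max_mask_distance > 0, min_points >= 1)
  active <- grid$active
  if (!is.null(polygon))
    active <- active & point_in_polygon(grid$points, as_ed_polygon(polygon))
  if (!is.null(data) && is.finite(max_mask_distance)) {
    px <- grid$points$x
    py <- grid$points$y
    near <- logical(length(px))
    r2 <- max_mask_distance^2
    chunk <- max(1L, floor(2e6 / nrow(data)))
    for (i0 in seq(1L, length(px), by = chunk)) {
      ii <- i0:min(i0 + chunk - 1L, length(px))
      d2 <- outer(px[ii], data$x, "-")^2 + outer(py[ii], data$y, "-")^2
      near[ii] <- rowSums(d2 <= r2) >= min_points
    }
    active <- active & near
  }
  if (!any(active)) stop("mask excludes every grid point", call. = FALSE)
  grid$active <- active
  grid
}

as_ed_polygon <- function(polygon) {
  if (inherits(polygon, "ed_polygon")) return(polygon)
  if (is.matrix(polygon)) polygon <- list(polygon)
  rings <- lapply(polygon, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    r
  })
  structure(rings, class = "ed_polygon")
}

# Even-odd (ray casting) point-in-polygon over all rings, so holes are
# excluded automatically. Points on a ring edge count as inside (closed
# boundary convention).
point_in_polygon <- function(points, polygon, eps = 1e-12) {
  px <- points$x
  py <- points$y
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in polygon) {
    xs <- ring[, 1]
    ys <- ring[, 2]
    m <- length(xs)
    if (xs[1] == xs[m] && ys[1] == ys[m]) m <- m - 1L  # drop closing vertex
    j <- m
    for (i in seq_len(m)) {
      x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
      # boundary: point within eps of segment (x1,y1)-(x2,y2)
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      on_edge <- on_edge | d2 <= eps
      # crossing test (half-open rule)
      cross <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside | on_edge
}

#' Read a study-area polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon`, `MultiPolygon`, `Feature` or
#' `FeatureCollection` (first feature used). All rings — outer boundaries and
#' holes — are kept; point-in-polygon uses the even-odd rule, so holes are
#' excluded. Boundary points count as inside. Coordinates must be in the same
#' planar units as the dataset.
#'
#' @param path path to a GeoJSON file.
#' @return object of class `ed_polygon`: a list of 2-column ring matrices.
#' @export
read_mask <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  if (identical(g$type, "Feature")) g <- g$geometry
  rings <- switch(
    g$type %||% "",
    Polygon = g$coordinates,
    MultiPolygon = do.call(c, g$coordinates),
    stop("unsupported GeoJSON geometry type: ", g$type %||% "(missing)",
         call. = FALSE))
  rings <- lapply(rings, function(r)
    do.call(rbind, lapply(r, function(p) as.numeric(p[1:2]))))
  for (r in rings) if (nrow(r) < 3 || anyNA(r))
    stop("invalid GeoJSON ring geometry", call. = FALSE)
  structure(rings, class = "ed_polygon")
}
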