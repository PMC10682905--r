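# Planar geometry primitives: convex hulls, convex clipping and
# point-in-polygon tests.  Everything works on plain 2-column matrices; the
# same code serves PCA space (envelope overlap) and lon/lat space (model-area
# cropping), where degrees are treated as planar units.

#' Minimum convex hull of a 2-D point set
#'
#' @param points2d 2-column matrix or data frame of coordinates.
#' @return matrix of hull vertices in counter-clockwise order (no repeated
#'   closing vertex), class `convex_polygon`.
#' @export
convex_hull <- function(points2d) {
  p <- as.matrix(points2d)
  if (ncol(p) != 2) abort_input("convex_hull expects 2-D points")
  p <- p[stats::complete.cases(p), , drop = FALSE]
  up <- unique(p)
  if (nrow(up) < 3) abort_input("convex hull needs >= 3 distinct points")
  idx <- grDevices::chull(p[, 1], p[, 2])  # clockwise order
  hull <- p[rev(idx), , drop = FALSE]      # counter-clockwise
  if (polygon_area(hull) <= 0) abort_input("degenerate (collinear) point set")
  structure(unname(hull), class = c("convex_polygon", "matrix", "array"))
}

#' Signed area of a simple polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly vertex matrix (not closed).
#' @return numeric scalar in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  p <- as.matrix(poly)
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# Even-odd ray-crossing test for simple polygons; boundary points count as
# inside (up to `tol` in cross-product units).  Vectorized over query points.
#' Point-in-polygon test
#' @param x,y query coordinates.
#' @param poly vertex matrix of a simple polygon.
#' @param tol boundary tolerance.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-12) {
  p <- as.matrix(poly)
  n <- nrow(p)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    # boundary: point within the edge's bounding box and collinear
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- x >= pmin(xi, xj) - tol & x <= pmax(xi, xj) + tol &
      y >= pmin(yi, yj) - tol & y <= pmax(yi, yj) + tol
    on_edge <- on_edge | (abs(cross) <= tol * (1 + abs(xj - xi) + abs(yj - yi)) & within)
    j <- i
  }
  inside | on_edge
}

# Sutherland-Hodgman clipping of (convex) subject polygon against a convex
# clip polygon; both counter-clockwise.  Returns NULL when the intersection
# is empty or degenerate.
#' Intersection of two convex polygons
#' @param subject,clip counter-clockwise vertex matrices.
#' @return vertex matrix of the intersection polygon, or `NULL` if empty.
#' @export
clip_convex <- function(subject, clip) {
  out <- as.matrix(subject)
  cp <- as.matrix(clip)
  n_clip <- nrow(cp)
  for (e in seq_len(n_clip)) {
    a <- cp[e, ]; b <- cp[if (e == n_clip) 1 else e + 1, ]
    if (nrow(out) == 0) return(NULL)
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    n_in <- nrow(inp)
    for (i in seq_len(n_in)) {
      cur <- inp[i, ]; prev <- inp[if (i == 1) n_in else i - 1, ]
      s_cur <- side(cur); s_prev <- side(prev)
      if (s_cur >= 0) {
        if (s_prev < 0) out <- rbind(out, seg_intersect(prev, cur, a, b))
        out <- rbind(out, cur)
      } else if (s_prev >= 0) {
        out <- rbind(out, seg_intersect(prev, cur, a, b))
      }
    }
  }
  if (nrow(out) < 3 || abs(polygon_area(out)) < 1e-300) return(NULL)
  unname(out)
}

seg_intersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1; d2 <- b - a
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / denom
  p1 + t * d1
}

# Distance from points to a convex polygon (0 inside).  Used to realize
# "buffered hull" membership: a point is within the hull buffered by r iff
# its distance to the hull is <= r (disk-Minkowski buffer, round joins).
dist_to_polygon <- function(x, y, poly) {
  p <- as.matrix(poly)
  n <- nrow(p)
  d2 <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- p[j, 1]; ay <- p[j, 2]; bx <- p[i, 1]; by <- p[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  d <- sqrt(d2)
  d[point_in_polygon(x, y, p)] <- 0
  d
}

#' Mask an environment stack to a buffered convex hull of points
#'
#' Reproduces the study-area construction used before model fitting: the
#' minimum convex polygon of all (thinned) occurrence points, buffered by
#' `buffer_deg` degrees.  Cells whose centers fall outside the buffered hull
#' are masked; the grid geometry itself is unchanged (mask-only crop).  The
#' buffer is a true disk buffer (round joins): a cell center is retained iff
#' its planar distance to the hull polygon is at most `buffer_deg`.
#'
#' @param stack an [env_stack()].
#' @param points 2-column matrix/data.frame of lon/lat, or an occurrence set.
#' @param buffer_deg buffer radius in degrees; the pipeline default is 3.
#' @return a new [env_stack()] with additional cells masked.
#' @export
crop_to_hull <- function(stack, points, buffer_deg = 3) {
  if (is.data.frame(points) && all(c("lon", "lat") %in% names(points))) {
    points <- cbind(points$lon, points$lat)
  }
  if (buffer_deg < 0) abort_input("buffer_deg must be >= 0")
  hull <- convex_hull(points)
  cc <- cell_centers(stack$geometry)
  keep <- dist_to_polygon(as.vector(cc$xm), as.vector(cc$ym), hull) <= buffer_deg
  keep_m <- matrix(keep, stack$geometry$n_rows, stack$geometry$n_cols)
  layers <- lapply(stack$layers, function(l) {
    env_layer(l$name, l$geometry, l$values, l$nodata_mask | !keep_m)
  })
  env_stack(layers)
}
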