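# Segments are stored as n x 4 matrices (x1, y1, x2, y2). Thin interior
# walls are stored as two superimposed segments so that horizontal-ray
# parity tests are unaffected while collision tests still see them; hole
# loops are stored once so their interior correctly tests as outside.

.stock_arenas <- c("square", "large_square", "rectangle", "circle",
                   "square_wall", "square_hole")

.loop_segments <- function(verts) {
  n <- nrow(verts)
  cbind(verts, verts[c(2:n, 1), , drop = FALSE])
}

.shoelace <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Construct one of the six stock arenas
#'
#' Builds an arena geometry as a set of wall segments with a unique
#' context index. The six stock arenas are a square (2.2 x 2.2, centered
#' at the origin), a large square (3.3 x 3.3), a rectangle (2.2 x 1.1),
#' a circle (radius 1.1), the square with a thin central dividing wall
#' from (0, 1.1) to (0, 0), and the square with a centered 0.73 x 0.73
#' hole. All dimensions are in arena units and can be overridden via
#' `scale`.
#'
#' @param name one of `"square"`, `"large_square"`, `"rectangle"`,
#'   `"circle"`, `"square_wall"`, `"square_hole"`.
#' @param scale optional multiplicative rescaling of all coordinates.
#' @return an object of class `"arena"`: a list with elements `name`,
#'   `context_index` (0-based, unique across the six stock arenas),
#'   `outer_walls`, `inner_walls`, `walls`, `bounding_box`
#'   (`c(xmin, xmax, ymin, ymax)`), `is_circle`, `center`, `radius`,
#'   and `area`.
#' @export
#' @examples
#' env <- make_environment("square")
#' point_inside(c(0, 0), env)
make_environment <- function(name, scale = 1) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .stock_arenas))
    stop("unknown arena name: ", paste(name, collapse = ", "),
         " (expected one of ", paste(.stock_arenas, collapse = ", "), ")")
  ctx <- match(name, .stock_arenas) - 1L
  half <- 1.1 * scale
  sq <- rbind(c(-half, -half), c(half, -half), c(half, half), c(-half, half))
  inner <- matrix(numeric(0), 0, 4)
  hole_area <- 0
  is_circle <- FALSE
  center <- c(0, 0); radius <- NA_real_
  if (name == "square") {
    outer <- .loop_segments(sq)
  } else if (name == "large_square") {
    h <- 1.65 * scale
    outer <- .loop_segments(rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h)))
  } else if (name == "rectangle") {
    hy <- 0.55 * scale
    outer <- .loop_segments(rbind(c(-half, -hy), c(half, -hy),
                                  c(half, hy), c(-half, hy)))
  } else if (name == "circle") {
    is_circle <- TRUE
    radius <- 1.1 * scale
    outer <- matrix(numeric(0), 0, 4)
  } else if (name == "square_wall") {
    outer <- .loop_segments(sq)
    w <- c(0, half, 0, 0)
    inner <- rbind(w, w)  # superimposed pair: parity-neutral, collision-active
  } else if (name == "square_hole") {
    outer <- .loop_segments(sq)
    hh <- 0.365 * scale
    hole <- rbind(c(-hh, -hh), c(hh, -hh), c(hh, hh), c(-hh, hh))
    inner <- .loop_segments(hole)
    hole_area <- .shoelace(hole)
  }
  walls <- rbind(outer, inner)
  if (is_circle) {
    bb <- c(-radius, radius, -radius, radius) + c(center[1], center[1],
                                                  center[2], center[2])
    area <- pi * radius^2
  } else {
    xs <- c(walls[, 1], walls[, 3]); ys <- c(walls[, 2], walls[, 4])
    bb <- c(min(xs), max(xs), min(ys), max(ys))
    verts <- outer[, 1:2, drop = FALSE]
    area <- .shoelace(verts) - hole_area
  }
  structure(list(name = name, context_index = ctx,
                 outer_walls = outer, inner_walls = inner, walls = walls,
                 bounding_box = bb, is_circle = is_circle,
                 center = center, radius = radius, area = area),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat("<arena>", x$name, " context:", x$context_index,
      if (x$is_circle) sprintf(" circle r=%.3g", x$radius)
      else sprintf(" %d wall segments", nrow(x$walls)),
      sprintf(" area=%.4g\n", x$area))
  invisible(x)
}

#' One-hot context signal of an arena
#'
#' @param env an `arena`.
#' @param n_contexts total number of contexts (default 6).
#' @return numeric one-hot vector of length `n_contexts`.
#' @export
context_onehot <- function(env, n_contexts = 6L) {
  v <- numeric(n_contexts)
  v[env$context_index + 1L] <- 1
  v
}

# Horizontal-ray parity test, vectorized over rows of P (n x 2).
# Boundary points count as inside. When a ray would pass exactly through
# a wall vertex the point's y is jittered by 1e-9 to avoid degenerate
# parity counts.
.points_inside_poly <- function(P, walls, tol = 1e-12) {
  n <- nrow(P)
  if (n == 0L) return(logical(0))
  px <- P[, 1]; py <- P[, 2]
  vy <- c(walls[, 2], walls[, 4])
  graze <- py %in% vy
  py[graze] <- py[graze] + 1e-9
  crossings <- integer(n)
  on_wall <- logical(n)
  for (k in seq_len(nrow(walls))) {
    x1 <- walls[k, 1]; y1 <- walls[k, 2]; x2 <- walls[k, 3]; y2 <- walls[k, 4]
    straddle <- (y1 > py) != (y2 > py)
    if (any(straddle)) {
      xint <- x1 + (py[straddle] - y1) * (x2 - x1) / (y2 - y1)
      hit <- xint > px[straddle]
      crossings[straddle] <- crossings[straddle] + hit
    }
    # on-segment check against the *unjittered* coordinates
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((P[, 1] - x1) * dx + (P[, 2] - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (P[, 1] - (x1 + t * dx))^2 + (P[, 2] - (y1 + t * dy))^2
      on_wall <- on_wall | d2 < tol^2
    }
  }
  (crossings %% 2L == 1L) | on_wall
}

#' Test whether points lie inside an arena
#'
#' Uses a horizontal ray-casting parity test for polygonal arenas (a
#' point is inside when a +x ray crosses the wall set an odd number of
#' times) and a radius test for the circle. Points inside a hole loop
#' are outside; points exactly on a wall count as inside.
#'
#' @param P an n x 2 matrix of points (a single point may be given as a
#'   length-2 vector).
#' @param env an `arena`.
#' @return logical vector of length n.
#' @export
points_inside <- function(P, env) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 2)
  if (env$is_circle) {
    d2 <- (P[, 1] - env$center[1])^2 + (P[, 2] - env$center[2])^2
    return(d2 <= env$radius^2 + 1e-12)
  }
  .points_inside_poly(P, env$walls)
}

#' @rdname points_inside
#' @param p a single 2-D point.
#' @export
point_inside <- function(p, env) {
  points_inside(matrix(p, ncol = 2), env)[1]
}

#' Test whether a step segment crosses any arena wall
#'
#' Returns `TRUE` when the segment from `a` to `b` intersects a wall
#' segment (or exits the circle). The start point is nudged by 1e-9
#' toward `b` so a step launched from a wall-touching position is not
#' flagged by its own starting contact.
#'
#' @param a,b 2-D points; `a` is assumed inside `env`.
#' @param env an `arena`.
#' @return logical scalar.
#' @export
segment_hits_wall <- function(a, b, env) {
  if (env$is_circle) {
    d2 <- sum((b - env$center)^2)
    return(d2 > env$radius^2 + 1e-12)
  }
  a <- a + 1e-9 * (b - a)
  w <- env$walls
  if (nrow(w) == 0L) return(FALSE)
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  d1 <- abx * (w[, 2] - a[2]) - aby * (w[, 1] - a[1])
  d2 <- abx * (w[, 4] - a[2]) - aby * (w[, 3] - a[1])
  wx <- w[, 3] - w[, 1]; wy <- w[, 4] - w[, 2]
  d3 <- wx * (a[2] - w[, 2]) - wy * (a[1] - w[, 1])
  d4 <- wx * (b[2] - w[, 2]) - wy * (b[1] - w[, 1])
  if (any((d1 * d2 < 0) & (d3 * d4 < 0))) return(TRUE)
  # collinear / endpoint contact counts as a hit
  on_seg <- function(px, py, qx, qy, rx, ry) {
    rx >= pmin(px, qx) & rx <= pmax(px, qx) &
      ry >= pmin(py, qy) & ry <= pmax(py, qy)
  }
  any((d1 == 0 & on_seg(a[1], a[2], b[1], b[2], w[, 1], w[, 2])) |
      (d2 == 0 & on_seg(a[1], a[2], b[1], b[2], w[, 3], w[, 4])) |
      (d3 == 0 & on_seg(w[, 1], w[, 2], w[, 3], w[, 4], a[1], a[2])) |
      (d4 == 0 & on_seg(w[, 1], w[, 2], w[, 3], w[, 4], b[1], b[2])))
}

#' Sample points uniformly from the interior of an arena
#'
#' Rejection sampling: candidates are drawn uniformly from the smallest
#' axis-aligned rectangle covering the arena and kept when they pass the
#' inside test.
#'
#' @param env an `arena`.
#' @param n number of points (>= 1).
#' @return an n x 2 matrix of interior points.
#' @export
sample_uniform <- function(env, n) {
  stopifnot(n >= 1)
  bb <- env$bounding_box
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
    ok <- points_inside(cand, env)
    keep <- which(ok)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n - got))]
      out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

#' Fraction of a circle boundary lying inside an arena
#'
#' Computes |db(x, r) inside| / |db(x, r)| by dense angular sampling of
#' the circle of radius `r` about `x` (used by the edge correction of
#' Ripley's K). The result is floored at `1/n_samples` so downstream
#' reciprocals stay finite.
#'
#' @param x 2-D point inside `env`.
#' @param r radius (> 0).
#' @param env an `arena` (or a rectangle given as
#'   `c(xmin, xmax, ymin, ymax)`).
#' @param n_samples number of equally spaced boundary samples.
#' @return fraction in (0, 1].
#' @export
arc_inside_fraction <- function(x, r, env, n_samples = 720L) {
  stopifnot(r > 0)
  th <- (seq_len(n_samples) - 0.5) * (2 * pi / n_samples)
  P <- cbind(x[1] + r * cos(th), x[2] + r * sin(th))
  inside <- if (inherits(env, "arena")) points_inside(P, env)
            else .points_in_rect(P, env)
  max(mean(inside), 1 / n_samples)
}

.points_in_rect <- function(P, rect) {
  P[, 1] >= rect[1] & P[, 1] <= rect[2] & P[, 2] >= rect[3] & P[, 2] <= rect[4]
}

#' Geometric manipulations of a familiar arena
#'
#' Produces a transformed copy of a stock arena while *retaining* the
#' original context index, as used in the geometric-manipulation
#' experiments: axis elongation, joint elongation, uniform circle
#' expansion, and removal of the central hole.
#'
#' @param env a stock `arena`.
#' @param kind one of `"elongate_x"`, `"elongate_xy"`, `"expand_circle"`,
#'   `"fill_hole"`.
#' @param factor stretch factor (1, 2, or 3); ignored for `"fill_hole"`.
#' @return an `arena` with transformed walls and the original
#'   `context_index`.
#' @export
transform_environment <- function(env, kind = c("elongate_x", "elongate_xy",
                                                "expand_circle", "fill_hole"),
                                  factor = 2) {
  kind <- match.arg(kind)
  stopifnot(factor %in% c(1, 2, 3))
  out <- env
  scale_walls <- function(w, fx, fy) {
    if (nrow(w) == 0L) return(w)
    w[, c(1, 3)] <- w[, c(1, 3)] * fx
    w[, c(2, 4)] <- w[, c(2, 4)] * fy
    w
  }
  if (kind == "expand_circle") {
    if (!env$is_circle) stop("expand_circle requires the circular arena")
    out$radius <- env$radius * factor
    out$bounding_box <- c(-1, 1, -1, 1) * out$radius
    out$area <- pi * out$radius^2
  } else if (kind == "fill_hole") {
    if (env$name != "square_hole") stop("fill_hole requires the square_hole arena")
    base <- make_environment("square")
    out$outer_walls <- base$outer_walls
    out$inner_walls <- base$inner_walls
    out$walls <- base$walls
    out$bounding_box <- base$bounding_box
    out$area <- base$area
  } else {
    if (env$is_circle) stop(kind, " requires a polygonal arena")
    fx <- factor; fy <- if (kind == "elongate_xy") factor else 1
    out$outer_walls <- scale_walls(env$outer_walls, fx, fy)
    out$inner_walls <- scale_walls(env$inner_walls, fx, fy)
    out$walls <- rbind(out$outer_walls, out$inner_walls)
    out$bounding_box <- env$bounding_box * c(fx, fx, fy, fy)
    out$area <- env$area * fx * fy  # affine scaling; any hole scales with it
  }
  out$name <- paste0(env$name, "_", kind, if (kind != "fill_hole") factor else "")
  out
}

#' Serialize / deserialize an arena
#'
#' Arenas round-trip through a structured JSON config (name, context
#' index, wall vertex lists, circle parameters).
#'
#' @param env an `arena`.
#' @param path file path.
#' @return `read_environment` returns an `arena`.
#' @export
write_environment <- function(env, path) {
  obj <- list(name = env$name, context_index = env$context_index,
              is_circle = env$is_circle, center = env$center,
              radius = env$radius,
              outer_walls = env$outer_walls, inner_walls = env$inner_walls)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(w) {
    if (is.null(w) || length(w) == 0L) return(matrix(numeric(0), 0, 4))
    matrix(as.numeric(unlist(w)), ncol = 4,
           byrow = !is.matrix(w))
  }
  outer <- if (is.matrix(obj$outer_walls)) obj$outer_walls else as_mat(obj$outer_walls)
  inner <- if (is.matrix(obj$inner_walls)) obj$inner_walls else as_mat(obj$inner_walls)
  if (length(outer) == 0) outer <- matrix(numeric(0), 0, 4)
  if (length(inner) == 0) inner <- matrix(numeric(0), 0, 4)
  walls <- rbind(outer, inner)
  is_circle <- isTRUE(obj$is_circle)
  radius <- if (is_circle) as.numeric(obj$radius) else NA_real_
  center <- as.numeric(obj$center)
  if (is_circle) {
    bb <- c(-radius, radius, -radius, radius) + center[c(1, 1, 2, 2)]
    area <- pi * radius^2
  } else {
    xs <- c(walls[, 1], walls[, 3]); ys <- c(walls[, 2], walls[, 4])
    bb <- c(min(xs), max(xs), min(ys), max(ys))
    # recompute area from the reference constructor when possible
    area <- if (obj$name %in% .stock_arenas) make_environment(obj$name)$area
            else .shoelace(outer[, 1:2, drop = FALSE])
  }
  structure(list(name = obj$name, context_index = as.integer(obj$context_index),
                 outer_walls = outer, inner_walls = inner, walls = walls,
                 bounding_box = bb, is_circle = is_circle, center = center,
                 radius = radius, area = area),
            class = "arena")
}

#' Read / write 2-D point sets as CSV
#'
#' Two-column (x, y) CSV with a header, the exchange format for field
#' centers and generic point patterns.
#'
#' @param points an n x 2 matrix.
#' @param path file path.
#' @export
write_pointset <- function(points, path) {
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pointset
#' @export
read_pointset <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, 1:2])
}
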