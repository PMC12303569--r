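# Independent oracles used across tests. These deliberately use
# different algorithms than the package implementation.

# winding number of a closed vertex loop about point p
winding_number <- function(verts, p) {
  n <- nrow(verts)
  total <- 0
  for (i in seq_len(n)) {
    a <- verts[i, ] - p
    b <- verts[if (i == n) 1 else i + 1, ] - p
    total <- total + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
  }
  round(total / (2 * pi))
}

# inside test from winding numbers: |wn(outer)| == 1 and wn of every
# closed hole loop == 0. Thin (zero-area) interior walls are ignored.
oracle_inside <- function(p, env) {
  if (env$is_circle) return(sqrt(sum((p - env$center)^2)) <= env$radius)
  outer_verts <- env$outer_walls[, 1:2, drop = FALSE]
  if (abs(winding_number(outer_verts, p)) != 1) return(FALSE)
  if (env$name == "square_hole") {
    hole_verts <- env$inner_walls[, 1:2, drop = FALSE]
    if (winding_number(hole_verts, p) != 0) return(FALSE)
  }
  TRUE
}

# segment intersection by solving the 2x2 parametric system
oracle_segments_intersect <- function(a, b, c, d) {
  r <- b - a; s <- d - c
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-14) return(FALSE)  # parallel: measure-zero for random segs
  t <- ((c[1] - a[1]) * s[2] - (c[2] - a[2]) * s[1]) / den
  u <- ((c[1] - a[1]) * r[2] - (c[2] - a[2]) * r[1]) / den
  t >= 0 && t <= 1 && u >= 0 && u <= 1
}

oracle_hits_any_wall <- function(a, b, env) {
  if (env$is_circle) return(sum((b - env$center)^2) > env$radius^2)
  for (k in seq_len(nrow(env$walls))) {
    if (oracle_segments_intersect(a, b, env$walls[k, 1:2], env$walls[k, 3:4]))
      return(TRUE)
  }
  FALSE
}

# numerical von Mises CDF on (-pi, pi]
oracle_vm_cdf <- function(q, kappa) {
  vapply(q, function(x) {
    stats::integrate(function(t) exp(kappa * cos(t)), -pi, x)$value /
      stats::integrate(function(t) exp(kappa * cos(t)), -pi, pi)$value
  }, numeric(1))
}

# direct NaN-aware renormalized Gaussian convolution (quartic loop)
oracle_nan_smooth <- function(g, sigma) {
  nx <- nrow(g); ny <- ncol(g)
  out <- matrix(NaN, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    wsum <- 0; vsum <- 0
    for (a in seq_len(nx)) for (b in seq_len(ny)) {
      if (!is.finite(g[a, b])) next
      w <- exp(-((i - a)^2 + (j - b)^2) / (2 * sigma^2))
      wsum <- wsum + w; vsum <- vsum + w * g[a, b]
    }
    if (wsum > 0) out[i, j] <- vsum / wsum
  }
  out
}
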