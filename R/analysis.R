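# Ratemap statistics, remapping measures with shuffled nulls,
# population-vector correlations, spatial information, PCA spectra,
# weight diagnostics, and Ripley K/H point-pattern statistics.

.bin_edges <- function(bb, nx, ny) {
  list(x = seq(bb[1], bb[2], length.out = nx + 1L),
       y = seq(bb[3], bb[4], length.out = ny + 1L))
}

# flat bin index (column-major over x then y), positions clamped to grid
.bin_index <- function(x, y, bb, nx, ny) {
  ix <- pmin(nx, pmax(1L, 1L + floor((x - bb[1]) / (bb[2] - bb[1]) * nx)))
  iy <- pmin(ny, pmax(1L, 1L + floor((y - bb[3]) / (bb[4] - bb[3]) * ny)))
  as.integer(ix + (iy - 1L) * nx)
}

#' Occupancy-normalized ratemap of one unit
#'
#' Discretizes the arena bounding box into `bins x bins` square cells
#' and divides summed unit activity by the visit count per cell.
#' Unvisited bins are `NaN` (undefined, never zero). A burn-in prefix
#' can be excluded so only steady-state behavior enters (500 steps is
#' the convention for long single trajectories; 0 for aggregated short
#' trajectories).
#'
#' @param activity per-step rates of one unit (length T).
#' @param positions T x 2 positions.
#' @param env an `arena` (or bounding box `c(xmin, xmax, ymin, ymax)`).
#' @param bins grid resolution per axis (default 16).
#' @param burn_in initial timesteps to drop (default 0).
#' @return object of class `"ratemap"`: list with `grid` (bins x bins,
#'   x indexes rows), `occupancy`, `edges`, `bb`.
#' @export
compute_ratemap <- function(activity, positions, env, bins = 16L,
                            burn_in = 0L) {
  stopifnot(length(activity) == nrow(positions))
  if (burn_in >= length(activity))
    stop("burn-in leaves no samples for the ratemap")
  if (burn_in > 0L) {
    keep <- (burn_in + 1L):length(activity)
    activity <- activity[keep]
    positions <- positions[keep, , drop = FALSE]
  }
  bb <- if (inherits(env, "arena")) env$bounding_box else env
  ix <- .bin_index(positions[, 1], positions[, 2], bb, bins, bins)
  occ <- tabulate(ix, bins * bins)
  sums <- numeric(bins * bins)
  agg <- rowsum(activity, ix)
  sums[as.integer(rownames(agg))] <- agg
  grid <- matrix(ifelse(occ > 0, sums / pmax(occ, 1L), NaN), bins, bins)
  structure(list(grid = grid, occupancy = matrix(occ, bins, bins),
                 edges = .bin_edges(bb, bins, bins), bb = bb),
            class = "ratemap")
}

.as_grid <- function(rm) if (inherits(rm, "ratemap")) rm$grid else rm

# dense symmetric Gaussian weight matrix for 1-D smoothing along an axis
.gauss_mat <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  exp(-d^2 / (2 * sigma^2))
}

# NaN-aware renormalized Gaussian smoothing of a stack of grids sharing
# one validity mask; A: nx x ny x k array with zeros at invalid bins
.smooth_stack <- function(A, mask, sigma) {
  nx <- dim(A)[1]; ny <- dim(A)[2]; k <- dim(A)[3]
  Sx <- .gauss_mat(nx, sigma); Sy <- .gauss_mat(ny, sigma)
  den <- Sx %*% mask %*% Sy
  tmp <- Sx %*% matrix(A, nx, ny * k)
  tmp <- array(tmp, c(nx, ny, k))
  tmp <- aperm(tmp, c(2, 1, 3))
  tmp <- Sy %*% matrix(tmp, ny, nx * k)
  num <- aperm(array(tmp, c(ny, nx, k)), c(2, 1, 3))
  out <- array(NaN, dim(A))
  pos <- den > 0
  for (j in seq_len(k)) out[, , j] <- ifelse(pos, num[, , j] / den, NaN)
  out
}

#' Gaussian smoothing with NaN interpolation
#'
#' Smooths a ratemap with a Gaussian kernel of standard deviation
#' `sigma_px` pixels, filling undefined (unvisited) bins from their
#' neighbors by renormalizing the kernel over defined bins. A uniform
#' map passes through unchanged; the result is fully defined unless the
#' whole map is undefined (an error).
#'
#' @param rm a `ratemap` (or bare matrix with `NaN` for undefined bins).
#' @param sigma_px kernel standard deviation in pixels (default 1).
#' @return same type as the input with a smoothed, fully defined grid.
#' @export
smooth_ratemap <- function(rm, sigma_px = 1) {
  g <- .as_grid(rm)
  defined <- is.finite(g)
  if (!any(defined)) stop("cannot smooth an all-undefined ratemap")
  A <- array(ifelse(defined, g, 0), c(dim(g), 1L))
  out <- .smooth_stack(A, defined * 1, sigma_px)[, , 1]
  if (inherits(rm, "ratemap")) { rm$grid <- out; rm } else out
}

.rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Spatial correlation between two ratemaps
#'
#' Pearson correlation of the flattened, jointly defined bins; when both
#' grids are square the correlation is maximized over relative rotations
#' of 0, 90, 180, and 270 degrees (0 and 180 for non-square grids), to
#' allow for remapping by rigid rotation.
#'
#' @param rm_a,rm_b ratemaps (or matrices) of identical shape.
#' @param try_rotations search over rotations (default TRUE).
#' @return correlation in `[-1, 1]`, or `NA` when fewer than 3 jointly
#'   defined bins exist or a map is constant.
#' @export
spatial_correlation <- function(rm_a, rm_b, try_rotations = TRUE) {
  a <- .as_grid(rm_a); b <- .as_grid(rm_b)
  stopifnot(all(dim(a) == dim(b)))
  rots <- if (!try_rotations) list(b)
          else if (nrow(b) == ncol(b))
            list(b, .rot90(b), .rot90(.rot90(b)), .rot90(.rot90(.rot90(b))))
          else list(b, .rot90(.rot90(b)))
  best <- NA_real_
  for (bb in rots) {
    ok <- is.finite(a) & is.finite(bb)
    if (sum(ok) < 3L) next
    if (stats::sd(a[ok]) == 0 || stats::sd(bb[ok]) == 0) next
    r <- stats::cor(a[ok], bb[ok])
    if (is.na(best) || r > best) best <- r
  }
  best
}

#' Shuffled null distribution for remapping measures
#'
#' Correlation mode pairs every active unit in condition A with every
#' *other* active unit in condition B; overlap/difference modes draw
#' `n_pairings` random unit pairings and pool the resulting values.
#' Returns the distribution together with its 95th percentile (the
#' conventional remapping threshold).
#'
#' @param units_a,units_b for `mode = "correlation"`, lists of ratemaps
#'   (active units only); for the rate modes, numeric vectors of mean
#'   rates.
#' @param mode `"correlation"`, `"overlap"`, or `"difference"`.
#' @param n_pairings random pairings for the rate modes (default 1000).
#' @param try_rotations passed to [spatial_correlation()].
#' @return list with `values` and `q95`.
#' @export
shuffled_null <- function(units_a, units_b,
                          mode = c("correlation", "overlap", "difference"),
                          n_pairings = 1000L, try_rotations = TRUE) {
  mode <- match.arg(mode)
  if (mode == "correlation") {
    stopifnot(length(units_a) >= 2L, length(units_b) >= 2L)
    vals <- c()
    for (i in seq_along(units_a)) {
      for (j in seq_along(units_b)) {
        if (i == j) next
        vals <- c(vals, spatial_correlation(units_a[[i]], units_b[[j]],
                                            try_rotations))
      }
    }
    vals <- vals[!is.na(vals)]
  } else {
    f <- if (mode == "overlap") rate_overlap else rate_difference
    n <- length(units_a)
    stopifnot(length(units_b) == n, n >= 2L)
    vals <- unlist(lapply(seq_len(n_pairings), function(s) {
      perm <- sample.int(n)
      mapply(f, units_a, units_b[perm])
    }))
  }
  list(values = vals, q95 = stats::quantile(vals, 0.95, names = FALSE))
}

#' Rate overlap between two conditions
#'
#' Mean activity in the least active condition divided by that in the
#' most active; in `[0, 1]`.
#'
#' @param mean_a,mean_b mean rates (at least one positive).
#' @export
rate_overlap <- function(mean_a, mean_b) {
  stopifnot(mean_a > 0 || mean_b > 0)
  min(mean_a, mean_b) / max(mean_a, mean_b)
}

#' Signed normalized rate difference
#'
#' `(a - b) / (a + b)`; in `[-1, 1]`, keeping the sign of the change.
#'
#' @param mean_a,mean_b mean rates with `a + b > 0`.
#' @export
rate_difference <- function(mean_a, mean_b) {
  stopifnot(mean_a + mean_b > 0)
  (mean_a - mean_b) / (mean_a + mean_b)
}

#' Population-vector correlation
#'
#' Pearson correlation between two stacked population vectors (the
#' flattened ratemaps of every unit concatenated in a fixed order,
#' dimension N_units * N_x * N_y), over jointly finite entries.
#'
#' @param stack_a,stack_b numeric vectors of equal length (use
#'   [stack_ratemaps()]).
#' @return correlation in `[-1, 1]`.
#' @export
pv_correlation <- function(stack_a, stack_b) {
  stopifnot(length(stack_a) == length(stack_b))
  ok <- is.finite(stack_a) & is.finite(stack_b)
  stats::cor(stack_a[ok], stack_b[ok])
}

#' Stack a list of ratemaps into one population vector
#' @param maps list of ratemaps or matrices (identical shapes).
#' @return numeric vector of length `N_units * N_x * N_y`.
#' @export
stack_ratemaps <- function(maps) {
  unlist(lapply(maps, function(m) as.numeric(.as_grid(m))))
}

#' Skaggs spatial information of a ratemap
#'
#' `S = sum_i p_i (f_i / fbar) log2(f_i / fbar)` in bits, with `p_i` the
#' occupancy distribution over visited bins, `f_i` the bin rates, and
#' `fbar` the occupancy-weighted mean rate. Zero-rate bins contribute 0;
#' a silent map has `S = 0`.
#'
#' @param rm a `ratemap` (occupancy taken from it), or a matrix together
#'   with `occupancy`.
#' @param occupancy optional visit counts matching a bare-matrix `rm`.
#' @return non-negative spatial information in bits.
#' @export
spatial_information <- function(rm, occupancy = NULL) {
  g <- .as_grid(rm)
  occ <- if (inherits(rm, "ratemap")) rm$occupancy else occupancy
  if (is.null(occ)) stop("occupancy required")
  ok <- is.finite(g) & occ > 0
  if (!any(ok)) return(0)
  p <- occ[ok] / sum(occ[ok])
  f <- g[ok]
  fbar <- sum(p * f)
  if (fbar <= 0) return(0)
  r <- f / fbar
  terms <- ifelse(f > 0, p * r * log2(r), 0)
  sum(terms)
}

#' Units with high spatial information in every environment
#'
#' Keeps the units whose spatial information exceeds the
#' per-environment `percentile` in *all* environments (the intersection
#' across environments).
#'
#' @param si_matrix units x environments matrix of spatial information.
#' @param percentile percentile threshold in `[0, 100)` (default 2.5).
#' @return integer vector of unit indices.
#' @export
high_si_units <- function(si_matrix, percentile = 2.5) {
  si_matrix <- as.matrix(si_matrix)
  keep <- rep(TRUE, nrow(si_matrix))
  for (j in seq_len(ncol(si_matrix))) {
    thr <- stats::quantile(si_matrix[, j], percentile / 100, names = FALSE,
                           na.rm = TRUE)
    above <- if (percentile == 0) si_matrix[, j] >= thr
             else si_matrix[, j] > thr
    keep <- keep & !is.na(si_matrix[, j]) & above
  }
  which(keep)
}

#' PCA explained-variance spectrum of network states
#'
#' @param states samples x units matrix.
#' @param threshold cumulative explained-variance level for the
#'   component count (default 0.9).
#' @return list with `fractions`, `cumulative`, `n_components`
#'   (components needed to pass `threshold`).
#' @export
pca_spectrum <- function(states, threshold = 0.9) {
  stopifnot(nrow(states) >= 2L)
  pc <- stats::prcomp(states, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  fr <- v / sum(v)
  cum <- cumsum(fr)
  list(fractions = fr, cumulative = cum,
       n_components = which(cum >= threshold)[1])
}

#' Diagnostics of trained weights
#'
#' Eigenvalue spectrum of the recurrent matrix, pairwise Pearson
#' correlations between the six context columns of the input matrix,
#' and the per-context fraction of negative weights (negative context
#' weights acting on non-negative context signals implement inhibition
#' of unit subsets).
#'
#' @param params a `pc_network`.
#' @return list with `eigenvalues` (complex), `context_correlation`
#'   (6 x 6), `frac_negative` (length 6).
#' @export
weight_diagnostics <- function(params) {
  ctx <- params$W_I[, 3:params$n_inputs, drop = FALSE]
  list(eigenvalues = as.complex(eigen(params$W_R, only.values = TRUE)$values),
       context_correlation = stats::cor(ctx),
       frac_negative = colMeans(ctx < 0))
}

# ---- Ripley's K / H ------------------------------------------------------

.domain_area <- function(domain) {
  if (inherits(domain, "arena")) domain$area
  else (domain[2] - domain[1]) * (domain[4] - domain[3])
}

.domain_bb <- function(domain) {
  if (inherits(domain, "arena")) domain$bounding_box else domain
}

# distance from a point to the domain boundary (conservative lower
# bound; used only to skip arc sampling for fully interior balls)
.boundary_clearance <- function(x, domain) {
  if (inherits(domain, "arena")) {
    if (domain$is_circle)
      return(domain$radius - sqrt(sum((x - domain$center)^2)))
    w <- domain$walls
    dx <- w[, 3] - w[, 1]; dy <- w[, 4] - w[, 2]
    len2 <- pmax(dx^2 + dy^2, 1e-300)
    t <- pmin(1, pmax(0, ((x[1] - w[, 1]) * dx + (x[2] - w[, 2]) * dy) / len2))
    min(sqrt((x[1] - (w[, 1] + t * dx))^2 + (x[2] - (w[, 2] + t * dy))^2))
  } else {
    min(x[1] - domain[1], domain[2] - x[1], x[2] - domain[3], domain[4] - x[2])
  }
}

#' Log-spaced Ripley radii
#'
#' 50 radii (by default) log-spaced from `eps = 1e-8` to a quarter of
#' the diagonal of the domain bounding box.
#'
#' @param domain an `arena` or rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param n number of radii.
#' @param eps smallest radius.
#' @export
ripley_radii <- function(domain, n = 50L, eps = 1e-8) {
  bb <- .domain_bb(domain)
  rmax <- sqrt((bb[2] - bb[1])^2 + (bb[4] - bb[3])^2) / 4
  exp(seq(log(eps), log(rmax), length.out = n))
}

#' Edge-corrected Ripley's K
#'
#' `K(R) = |Omega| / (N (N - 1)) * sum over distinct pairs closer than
#' R of f(x, y)`, with the boundary correction
#' `f(x, y) = (k(x, y) + k(y, x)) / 2` and `k(x, y)` the reciprocal of
#' the fraction of the circle about `x` through `y` that lies inside
#' the domain (computed by [arc_inside_fraction()]).
#'
#' @param points n x 2 matrix of points inside `domain` (n >= 2).
#' @param domain an `arena` or rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param radii increasing radius grid (see [ripley_radii()]).
#' @param arc_samples angular resolution of the edge correction.
#' @return numeric vector `K(radii)`, non-decreasing.
#' @export
ripleys_K <- function(points, domain, radii = ripley_radii(domain),
                      arc_samples = 720L) {
  n <- nrow(points)
  if (is.null(n) || n < 2L) stop("Ripley's K needs at least 2 points")
  area <- .domain_area(domain)
  clear <- apply(points, 1, .boundary_clearance, domain = domain)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((points[pr[, 1], 1] - points[pr[, 2], 1])^2 +
              (points[pr[, 1], 2] - points[pr[, 2], 2])^2)
  f <- numeric(nrow(pr))
  for (q in seq_len(nrow(pr))) {
    i <- pr[q, 1]; j <- pr[q, 2]; dij <- d[q]
    ki <- if (clear[i] >= dij) 1
          else 1 / arc_inside_fraction(points[i, ], dij, domain, arc_samples)
    kj <- if (clear[j] >= dij) 1
          else 1 / arc_inside_fraction(points[j, ], dij, domain, arc_samples)
    f[q] <- (ki + kj) / 2
  }
  vapply(radii, function(R) {
    2 * sum(f[d < R]) * area / (n * (n - 1))
  }, numeric(1))
}

#' Ripley's H transform
#'
#' `H(R) = sqrt(K(R) / pi) - R`; zero under complete spatial
#' randomness, positive under clustering.
#'
#' @param K values of Ripley's K on `radii`.
#' @param radii radius grid.
#' @export
ripleys_H <- function(K, radii) {
  stopifnot(all(K >= 0), length(K) == length(radii))
  sqrt(K / pi) - radii
}

#' Uniform grid-sampling baseline envelope for Ripley's H
#'
#' Draws `n_sets` point sets of `n_points` placed uniformly at random on
#' the centers of a `grid x grid` discretization of the domain (without
#' replacement, matching ratemap-derived centers), computes H for each,
#' and returns the mean with a two-standard-deviation envelope.
#'
#' @param domain an `arena` or rectangle.
#' @param n_points points per set.
#' @param radii radius grid.
#' @param n_sets number of samplings (default 100).
#' @param grid grid resolution (default 15).
#' @param arc_samples angular resolution of the edge correction.
#' @return list with `mean`, `sd`, `lo`, `hi` (mean +/- 2 sd), `H_all`
#'   (n_sets x length(radii)).
#' @export
uniform_baseline <- function(domain, n_points, radii = ripley_radii(domain),
                             n_sets = 100L, grid = 15L, arc_samples = 180L) {
  bb <- .domain_bb(domain)
  cx <- bb[1] + (seq_len(grid) - 0.5) * (bb[2] - bb[1]) / grid
  cy <- bb[3] + (seq_len(grid) - 0.5) * (bb[4] - bb[3]) / grid
  cells <- as.matrix(expand.grid(x = cx, y = cy))
  if (inherits(domain, "arena"))
    cells <- cells[points_inside(cells, domain), , drop = FALSE]
  stopifnot(n_points <= nrow(cells))
  H_all <- matrix(NA_real_, n_sets, length(radii))
  for (s in seq_len(n_sets)) {
    pts <- cells[sample.int(nrow(cells), n_points), , drop = FALSE]
    H_all[s, ] <- ripleys_H(ripleys_K(pts, domain, radii, arc_samples), radii)
  }
  m <- colMeans(H_all)
  s <- apply(H_all, 2, stats::sd)
  list(mean = m, sd = s, lo = m - 2 * s, hi = m + 2 * s, H_all = H_all)
}

#' Analytic complete-spatial-randomness envelope for Ripley's H
#'
#' Under CSR, `K(R) = pi R^2` and `H = 0`. Treating the indicator of
#' each distinct pair as Bernoulli with success probability
#' `p = pi R^2 / |Omega|` gives the leading-order standard deviation of
#' the K estimator, `sd_K = |Omega| sqrt(p (1 - p) / u)` with
#' `u = N (N - 1) / 2` pairs; the delta method at `K = pi R^2` converts
#' it to an H-scale band `+/- 2 sd_K / (2 pi R)`.
#'
#' @param radii radius grid.
#' @param n_points number of points.
#' @param area domain area.
#' @return list with `lo`, `hi` (band about 0), `sd_H`.
#' @export
csr_envelope <- function(radii, n_points, area) {
  u <- n_points * (n_points - 1) / 2
  p <- pmin(1, pi * radii^2 / area)
  sd_K <- area * sqrt(p * (1 - p) / u)
  sd_H <- sd_K / (2 * pi * radii)
  list(lo = -2 * sd_H, hi = 2 * sd_H, sd_H = sd_H)
}

#' Field centers from smoothed ratemaps
#'
#' Decodes one field center per map as the location of the maximum
#' firing bin of the smoothed ratemap; when a spatial-information vector
#' is supplied only maps above the `si_percentile` are kept. Argmax ties
#' break deterministically to the first bin in column-major scan order.
#'
#' @param maps list of smoothed ratemaps (or matrices).
#' @param bb bounding box of the maps (taken from the first `ratemap`
#'   when available).
#' @param si optional spatial information per map.
#' @param si_percentile percentile filter in `[0, 100)` (default 75).
#' @return n x 2 matrix of field-center coordinates.
#' @export
field_centers_from_ratemaps <- function(maps, bb = NULL, si = NULL,
                                        si_percentile = 75) {
  if (is.null(bb)) {
    stopifnot(inherits(maps[[1]], "ratemap"))
    bb <- maps[[1]]$bb
  }
  keep <- seq_along(maps)
  if (!is.null(si)) {
    thr <- stats::quantile(si, si_percentile / 100, names = FALSE)
    keep <- which(si > thr)
  }
  out <- matrix(NA_real_, length(keep), 2)
  for (q in seq_along(keep)) {
    g <- .as_grid(maps[[keep[q]]])
    k <- which.max(g)        # first maximum in column-major scan order
    ix <- (k - 1L) %% nrow(g) + 1L
    iy <- (k - 1L) %/% nrow(g) + 1L
    out[q, 1] <- bb[1] + (ix - 0.5) * (bb[2] - bb[1]) / nrow(g)
    out[q, 2] <- bb[3] + (iy - 0.5) * (bb[4] - bb[3]) / ncol(g)
  }
  out
}

#' Gaussian kernel density estimate of a point set
#'
#' Isotropic Gaussian mixture over the points (bandwidth in the units of
#' the points), evaluated on a regular grid over the domain bounding
#' box; integrates to ~1 for points away from the domain edge.
#'
#' @param points n x 2 matrix.
#' @param bandwidth kernel standard deviation (default 0.2).
#' @param grid grid resolution per axis (default 64).
#' @param bb evaluation bounding box (defaults to the point range
#'   padded by 3 bandwidths).
#' @return list with `x`, `y` (grid coordinates) and `z` (grid x grid
#'   density matrix, x indexes rows).
#' @export
kde_centers <- function(points, bandwidth = 0.2, grid = 64L, bb = NULL) {
  if (is.null(bb)) {
    pad <- 3 * bandwidth
    bb <- c(range(points[, 1]) + c(-pad, pad),
            range(points[, 2]) + c(-pad, pad))
  }
  gx <- seq(bb[1], bb[2], length.out = grid)
  gy <- seq(bb[3], bb[4], length.out = grid)
  z <- matrix(0, grid, grid)
  for (i in seq_len(nrow(points))) {
    z <- z + outer(stats::dnorm(gx, points[i, 1], bandwidth),
                   stats::dnorm(gy, points[i, 2], bandwidth))
  }
  list(x = gx, y = gy, z = z / nrow(points))
}

#' Write a ratemap (or density grid) as CSV with a JSON sidecar
#'
#' @param rm a `ratemap` or bare matrix.
#' @param path CSV path; the sidecar is `path` + `".json"`.
#' @param meta optional named list merged into the sidecar.
#' @export
write_ratemap <- function(rm, path, meta = list()) {
  g <- .as_grid(rm)
  utils::write.table(g, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- meta
  if (inherits(rm, "ratemap")) side <- c(side, list(bb = rm$bb))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
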