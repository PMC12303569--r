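test_that("ratemaps are occupancy-normalized with undefined unvisited bins", {
  sq <- make_environment("square")
  pos <- rbind(c(0, 0), c(0, 0), c(0.9, 0.9))
  rm <- compute_ratemap(c(1, 3, 5), pos, sq, bins = 4L)
  center_bin <- placenet:::.bin_index(0, 0, sq$bounding_box, 4L, 4L)
  expect_equal(as.numeric(rm$grid)[center_bin], 2)  # (1 + 3) / 2 visits
  expect_equal(sum(rm$occupancy), 3)
  expect_true(is.nan(rm$grid[1, 4]))                # never visited
  # constant activity gives 1 in every visited bin
  set.seed(71)
  tr <- simulate_trajectory(sq, 400L)
  rm1 <- compute_ratemap(rep(1, 400), tr$positions, sq)
  expect_true(all(rm1$grid[is.finite(rm1$grid)] == 1))
  # burn-in excludes the prefix
  act <- c(rep(100, 100), rep(1, 300))
  rmb <- compute_ratemap(act, tr$positions, sq, burn_in = 100L)
  expect_true(all(rmb$grid[is.finite(rmb$grid)] == 1))
  expect_error(compute_ratemap(1:5, matrix(0, 5, 2), sq, burn_in = 5L),
               "burn-in")
})

test_that("NaN-aware smoothing preserves uniform maps and fills gaps", {
  u <- matrix(2.5, 8, 8)
  expect_equal(smooth_ratemap(u), u, tolerance = 1e-12)
  u1 <- u; u1[3, 5] <- NaN
  sm <- smooth_ratemap(u1)
  expect_equal(sm[3, 5], 2.5, tolerance = 1e-12)
  expect_true(all(is.finite(sm)))
  # impulse map against the brute-force renormalized-kernel oracle
  set.seed(72)
  g <- matrix(0, 7, 7); g[3, 4] <- 1; g[c(2, 40)] <- NaN
  expect_equal(smooth_ratemap(g), oracle_nan_smooth(g, 1), tolerance = 1e-10)
  expect_error(smooth_ratemap(matrix(NaN, 3, 3)), "all-undefined")
})

test_that("spatial correlation maximizes over rotations and handles ties", {
  set.seed(73)
  a <- matrix(runif(64), 8, 8)
  expect_equal(spatial_correlation(a, a), 1.0)
  expect_equal(spatial_correlation(a, placenet:::.rot90(a)), 1.0)
  b <- matrix(runif(64), 8, 8)
  expect_equal(spatial_correlation(a, b, try_rotations = FALSE),
               cor(as.numeric(a), as.numeric(b)))
  # joint-definedness: fewer than 3 shared bins gives NA
  a2 <- matrix(NaN, 8, 8); a2[1:2] <- 1
  expect_true(is.na(spatial_correlation(a2, b, try_rotations = FALSE)))
  # rectangle maps only search 0 and 180 degrees
  ra <- matrix(runif(24), 4, 6)
  expect_equal(spatial_correlation(ra, placenet:::.rot90(placenet:::.rot90(ra))),
               1.0)
})

test_that("shuffled nulls use cross pairs and order-statistic percentiles", {
  set.seed(74)
  maps <- lapply(1:6, function(i) matrix(runif(16), 4, 4))
  nl <- shuffled_null(maps, maps, "correlation", try_rotations = FALSE)
  expect_length(nl$values, 30L)            # 6 * 6 minus the 6 matched pairs
  expect_true(all(nl$values >= -1 & nl$values <= 1))
  expect_equal(nl$q95, quantile(nl$values, 0.95, names = FALSE))
  a <- runif(8) + 0.2; b <- runif(8) + 0.2
  no <- shuffled_null(a, b, "overlap", n_pairings = 100L)
  expect_length(no$values, 800L)
  expect_true(all(no$values >= 0 & no$values <= 1))
  nd <- shuffled_null(a, b, "difference", n_pairings = 50L)
  expect_true(all(abs(nd$values) <= 1))
})

test_that("rate overlap and difference follow their closed forms", {
  expect_equal(rate_overlap(3, 3), 1.0)
  expect_equal(rate_overlap(0, 4), 0.0)
  expect_equal(rate_overlap(2, 4), 0.5)
  expect_equal(rate_difference(4, 2), 1 / 3)
  expect_equal(rate_difference(2, 4), -1 / 3)
  expect_equal(rate_difference(5, 0), 1.0)
  expect_error(rate_overlap(0, 0))
  expect_error(rate_difference(0, 0))
})

test_that("population-vector correlation is Pearson on stacked maps", {
  set.seed(75)
  maps1 <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  s1 <- stack_ratemaps(maps1)
  expect_length(s1, 48L)
  expect_equal(pv_correlation(s1, s1), 1.0)
  expect_equal(pv_correlation(s1, -s1), -1.0)
  s2 <- rnorm(48)
  expect_equal(pv_correlation(s1, s2), cor(s1, s2))
  # NaN entries are dropped pairwise
  s1n <- s1; s1n[5] <- NaN
  expect_equal(pv_correlation(s1n, s2), cor(s1[-5], s2[-5]))
})

test_that("spatial information matches its closed forms", {
  occ <- matrix(1, 4, 4)
  expect_equal(spatial_information(matrix(2, 4, 4), occ), 0)
  for (M in c(4L, 16L, 25L)) {
    g <- matrix(0, M, 1); g[3] <- 7
    expect_equal(spatial_information(g, matrix(1, M, 1)), log2(M),
                 tolerance = 1e-10)
  }
  expect_equal(spatial_information(matrix(0, 4, 4), occ), 0)
  set.seed(76)
  for (i in 1:20) {
    g <- matrix(rexp(16), 4, 4)
    o <- matrix(rpois(16, 5) + 1, 4, 4)
    expect_gte(spatial_information(g, o), 0)
  }
})

test_that("high-SI selection intersects per-environment percentiles", {
  si <- cbind(1:10, 1:10)
  expect_equal(high_si_units(si, 0), 1:10)
  expect_equal(high_si_units(cbind(1:10), 50), 6:10)
  si2 <- cbind(1:10, c(6:10, 1:5))   # top halves disagree across envs
  expect_equal(high_si_units(si2, 50), which(si2[, 1] > 5.5 & si2[, 2] > 5.5))
})

test_that("PCA spectra behave on degenerate and isotropic data", {
  set.seed(77)
  v <- rnorm(5)
  states <- outer(rnorm(40), v)          # rank-1
  sp <- pca_spectrum(states)
  expect_equal(sp$fractions[1], 1.0, tolerance = 1e-12)
  expect_equal(sp$n_components, 1L)
  iso <- matrix(rnorm(4000 * 4), 4000, 4)
  spi <- pca_spectrum(iso)
  expect_equal(spi$fractions, rep(0.25, 4), tolerance = 0.05)
  expect_true(all(diff(spi$cumulative) >= -1e-15))
  expect_equal(spi$cumulative[4], 1.0)
})

test_that("weight diagnostics expose spectrum and context structure", {
  set.seed(78)
  p <- init_network(12L, 5L)
  wd <- weight_diagnostics(p)
  expect_equal(wd$eigenvalues, rep(1 + 0i, 12L))   # fresh identity
  expect_equal(dim(wd$context_correlation), c(6L, 6L))
  expect_equal(diag(wd$context_correlation), rep(1, 6))
  expect_length(wd$frac_negative, 6L)
  # eigenvalues against a characteristic-polynomial oracle: W_R block
  # diagonal with a random 4x4 block A and an 8x8 identity, so the
  # spectrum is eig(A) plus eight ones
  A <- matrix(rnorm(16), 4, 4)
  p2 <- p; p2$W_R <- diag(12)
  p2$W_R[1:4, 1:4] <- A
  ev <- weight_diagnostics(p2)$eigenvalues
  coef <- numeric(5); coef[1] <- 1   # Faddeev-LeVerrier char. polynomial
  Mk <- A
  for (k in 1:4) {
    ck <- -sum(diag(Mk)) / k
    coef[k + 1] <- ck
    Mk <- A %*% (Mk + ck * diag(4))
  }
  roots <- polyroot(rev(coef))
  expect_equal(sort(c(Mod(roots), rep(1, 8))), sort(Mod(ev)),
               tolerance = 1e-8)
})

test_that("Ripley's K matches brute force and is monotone", {
  dom <- c(0, 10, 0, 10)
  radii <- c(0.5, 1, 2, 4)
  pts <- rbind(c(4, 5), c(6, 5))        # distance 2 apart, deep interior
  K <- ripleys_K(pts, dom, radii)
  expect_equal(K[1:2], c(0, 0))          # R < d counts nothing (strict)
  expect_equal(K[4], 100 / (2 * 1) * 2 * 1)  # both ordered pairs, f = 1
  expect_true(all(diff(K) >= 0))
  # interior-only configuration equals uncorrected brute-force counting
  set.seed(79)
  pts <- cbind(runif(40, 4, 6), runif(40, 4, 6))
  radii <- seq(0.1, 1.5, length.out = 10)  # balls never reach the border
  K <- ripleys_K(pts, dom, radii)
  D <- as.matrix(dist(pts))
  brute <- vapply(radii, function(R)
    100 / (40 * 39) * sum(D < R & upper.tri(D)) * 2, numeric(1))
  expect_equal(K, brute, tolerance = 1e-9)
  expect_error(ripleys_K(matrix(c(1, 1), 1, 2), dom), "at least 2")
})

test_that("Ripley's H centers K and calibrates under CSR", {
  radii <- seq(0.2, 3, length.out = 15)
  expect_equal(ripleys_H(pi * radii^2, radii), rep(0, 15))
  # CSR points stay within the uniform-baseline 2-SD envelope almost
  # everywhere
  set.seed(80)
  dom <- c(0, 75, 0, 75)
  radii <- ripley_radii(dom, n = 25L)
  bl <- uniform_baseline(dom, n_points = 60L, radii = radii, n_sets = 40L,
                         grid = 15L, arc_samples = 120L)
  pts <- cbind(runif(60, 0, 75), runif(60, 0, 75))
  H <- ripleys_H(ripleys_K(pts, dom, radii, arc_samples = 120L), radii)
  inside <- H >= bl$lo - 1e-9 & H <= bl$hi + 1e-9
  expect_gte(mean(inside), 0.8)
  # radii span the quarter diagonal
  expect_equal(max(ripley_radii(dom)), sqrt(2) * 75 / 4)
  expect_equal(min(ripley_radii(dom)), 1e-8)
})

test_that("field centers and KDE localize single peaks", {
  g <- matrix(0, 15, 15); g[4, 9] <- 2
  bb <- c(0, 75, 0, 75)
  ctr <- field_centers_from_ratemaps(list(g), bb = bb)
  expect_equal(ctr[1, ], c((4 - 0.5) * 5, (9 - 0.5) * 5))
  # SI percentile filter keeps only top maps
  maps <- list(g, g, g, g)
  si <- c(1, 2, 3, 4)
  expect_equal(nrow(field_centers_from_ratemaps(maps, bb = bb, si = si,
                                                si_percentile = 75)), 1L)
  kd <- kde_centers(matrix(c(37.5, 37.5), 1, 2), bandwidth = 2, grid = 64L,
                    bb = bb)
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)
  expect_equal(kd$x[peak[1]], 37.5, tolerance = 1.5)
  expect_equal(kd$y[peak[2]], 37.5, tolerance = 1.5)
  # quadrature: density integrates to ~1 for interior points
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  expect_equal(sum(kd$z) * cell, 1, tolerance = 0.02)
})
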