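small_net <- function(seed = 51, N_g = 16L, N_p = 8L) {
  set.seed(seed)
  init_network(N_g, N_p)
}

test_that("episode runs carry state, stay in bounds, and freeze weights", {
  params <- small_net()
  before <- params
  sq <- make_environment("square")
  sw <- make_environment("square_wall")
  spec <- episode_spec(list(list(env = sq, T = 60L),
                            list(env = sw, T = 60L)))
  set.seed(52)
  ep <- run_episode(params, spec, n_traj = 4L, keep_states = TRUE)
  expect_identical(params, before)       # frozen-weights contract
  expect_length(ep$segments, 2L)
  for (s in seq_along(ep$segments)) {
    seg <- ep$segments[[s]]
    env <- spec$segments[[s]]$env
    for (b in 1:4)
      expect_true(all(points_inside(t(seg$positions[, , b]), env)))
    expect_true(all(seg$rate_sum >= 0))
    expect_equal(sum(seg$occ), 60 * 4)
  }
  # with carry_state off, each segment starts from the zero state and
  # matches an independent zero-state run under the same RNG stream
  spec0 <- episode_spec(list(list(env = sq, T = 40L),
                             list(env = sq, T = 40L)), carry_state = FALSE)
  set.seed(53)
  ep0 <- run_episode(params, spec0, n_traj = 3L)
  set.seed(53)
  g0 <- matrix(0, params$N_g, 3L)
  s1 <- placenet:::.run_segment(params, sq, sq$context_index, 40L, 3L, g0)
  s2 <- placenet:::.run_segment(params, sq, sq$context_index, 40L, 3L, g0)
  expect_equal(ep0$segments[[1]]$rate_sum, s1$rate_sum)
  expect_equal(ep0$segments[[2]]$rate_sum, s2$rate_sum)
})

test_that("segment ratemaps are occupancy-normalized and undefined off-path", {
  params <- small_net(54)
  sq <- make_environment("square")
  set.seed(54)
  ep <- run_episode(params, episode_spec(list(list(env = sq, T = 100L))),
                    n_traj = 2L)
  maps <- segment_ratemaps(ep$segments[[1]])
  occ <- ep$segments[[1]]$occ
  g <- maps[[1]]$grid
  expect_true(all(is.nan(g[matrix(occ == 0, 16, 16)])))
  expect_true(all(g[matrix(occ > 0, 16, 16)] >= 0))
})

test_that("manipulation runs simulate the transformed arena with the old context", {
  params <- small_net(55)
  sq <- make_environment("square")
  set.seed(55)
  res <- run_manipulation(params, sq, "elongate_x", 2, n_traj = 2L, T = 80L,
                          keep_states = TRUE)
  expect_equal(res$bb, c(-2.2, 2.2, -1.1, 1.1))
  expect_equal(res$ctx_index, sq$context_index)
  expect_true(any(abs(res$positions[, 1, ]) > 1.1))  # visits new territory
  sh <- make_environment("square_hole")
  set.seed(56)
  filled <- run_manipulation(params, sh, "fill_hole", n_traj = 4L, T = 400L,
                             keep_states = TRUE)
  # the formerly forbidden central region is now visited
  central <- abs(filled$positions[, 1, ]) < 0.3 &
    abs(filled$positions[, 2, ]) < 0.3
  expect_gt(sum(central), 0)
  expect_equal(filled$ctx_index, sh$context_index)
  expect_error(run_manipulation(params, make_environment("circle"),
                                "fill_hole"))
})

test_that("noise injection perturbs exactly at tau and stays rectified", {
  params <- small_net(57)
  sq <- make_environment("square")
  # fixed trajectories so runs differ only in the injected noise
  set.seed(57)
  B <- 3L; Tn <- 60L
  V <- array(NA_real_, c(Tn, 2, B)); X <- array(NA_real_, c(Tn, 2, B))
  for (b in 1:B) {
    tr <- simulate_trajectory(sq, Tn)
    V[, , b] <- tr$velocities; X[, , b] <- tr$positions
  }
  paths <- list(V = V, X = X)
  nr0 <- run_noise_injection(params, sq, sigma = 0, tau = 30L, T = Tn,
                             n_traj = B, trajectories = paths)
  nr_ref <- run_noise_injection(params, sq, sigma = 0, tau = 59L, T = Tn,
                                n_traj = B, trajectories = paths)
  expect_equal(nr0$R_t, nr_ref$R_t)   # sigma = 0 leaves the run unchanged
  nr1 <- run_noise_injection(params, sq, sigma = 1, tau = 30L, T = Tn,
                             n_traj = B, trajectories = paths,
                             noise_seed = 99L)
  expect_true(all(nr1$R_t >= 0))      # rectification after injection
  expect_equal(nr1$R_t[, , 1:29], nr0$R_t[, , 1:29])  # identical pre-tau
  expect_false(isTRUE(all.equal(nr1$R_t[, , 30:Tn], nr0$R_t[, , 30:Tn])))
  # a separate noise seed decouples noise from the trajectory stream
  nr1b <- run_noise_injection(params, sq, sigma = 1, tau = 30L, T = Tn,
                              n_traj = B, trajectories = paths,
                              noise_seed = 99L)
  expect_equal(nr1$R_t, nr1b$R_t)
})

test_that("velocity ablation yields autonomous decaying dynamics", {
  # contractive autonomous recurrence: after ablation with no noise the
  # state halves each step, so binned activity decays geometrically
  params <- small_net(58)
  params$W_R <- diag(params$N_g) * 0.5
  params$W_I[, 3:8] <- 0            # no context drive: purely velocity-driven
  params$W_p <- abs(params$W_p)
  sq <- make_environment("square")
  set.seed(58)
  B <- 2L; Tn <- 40L
  V <- array(NA_real_, c(Tn, 2, B)); X <- array(NA_real_, c(Tn, 2, B))
  for (b in 1:B) {
    tr <- simulate_trajectory(sq, Tn)
    V[, , b] <- tr$velocities; X[, , b] <- tr$positions
  }
  nr <- run_velocity_ablation(params, sq, sigma = 0, tau = 20L, T = Tn,
                              n_traj = B, trajectories = list(V = V, X = X))
  tot <- colSums(apply(nr$R_t, 3, rowSums))  # total output activity per step
  post <- tot[21:30]
  expect_true(all(diff(post) <= 1e-12))      # monotone decay, no new input
})

test_that("context mismatch feeds the foreign constant context", {
  params <- small_net(59)
  sq <- make_environment("square")
  sw <- make_environment("square_wall")
  set.seed(60)
  mm <- run_context_mismatch(params, sq, sw, n_traj = 2L, T = 50L)
  expect_equal(mm$ctx_index, sw$context_index)
  expect_equal(mm$env$name, "square")
  # matched context reduces to a plain single-segment episode
  set.seed(61)
  mm_matched <- run_context_mismatch(params, sq, sq, n_traj = 2L, T = 50L)
  set.seed(61)
  ep <- run_episode(params, episode_spec(list(list(env = sq, T = 50L))),
                    n_traj = 2L)
  expect_equal(mm_matched$rate_sum, ep$segments[[1]]$rate_sum)
})

test_that("PV timecourse machinery recovers perfect correlation for static maps", {
  # construct a noise_run whose per-time maps are identical up to scale
  bins <- 4L; N_p <- 3L; Tn <- 6L
  base <- matrix(runif(N_p * bins * bins), N_p)
  nr <- structure(list(
    R_t = array(rep(base, Tn), c(N_p, bins * bins, Tn)),
    occ_t = matrix(1, bins * bins, Tn),
    bins = bins, tau = 3L, sigma = 0, T = Tn, n_traj = 1L),
    class = "noise_run")
  C <- pv_time_matrix(nr)
  expect_equal(max(abs(C - 1)), 0, tolerance = 1e-10)
  s <- noise_recovery_summary(C, tau = 3L, pre = 2L, dip = 2L, tail = 2L)
  expect_equal(s$recovery_ratio, 1, tolerance = 1e-10)
})

test_that("decoded center clouds have the right shape and guard silent units", {
  set.seed(62)
  params <- init_network(10L, 4L)
  params$W_p[1, ] <- -abs(params$W_p[1, ])  # unit 1 silent forever
  sq <- make_environment("square")
  centers <- decoded_center_aggregation(params, sq, n_traj = 3L, T = 60L)
  expect_equal(dim(centers), c(4L, 2L, 3L))
  expect_true(all(centers[1, , ] == 0))     # guard point for the silent unit
  sub <- decoded_center_aggregation(params, sq, n_traj = 2L, T = 40L,
                                    units = c(2L, 3L))
  expect_equal(dim(sub), c(2L, 2L, 2L))
})
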