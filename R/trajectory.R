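# Constrained foraging random walk: Rayleigh step sizes, von Mises
# heading persistence, wall collisions resolved by heading resampling.

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Used for heading persistence in
#' the trajectory simulator.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); `kappa = 0` gives the uniform
#'   distribution on the circle.
#' @return numeric vector of angles in (-pi, pi] + mu.
#' @export
rvonmises <- function(n, mu = 0, kappa = 4) {
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(n - got, 8L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- which(ok)
    if (length(k)) {
      take <- k[seq_len(min(length(k), n - got))]
      out[(got + 1L):(got + length(take))] <-
        sign(u3[take] - 0.5) * acos(pmin(1, pmax(-1, f[take])))
      got <- got + length(take)
    }
  }
  out + mu
}

#' Rayleigh step-size draws
#' @param n number of draws.
#' @param sigma Rayleigh scale.
#' @return non-negative numeric vector.
#' @export
rrayleigh <- function(n, sigma = 0.5) {
  sigma * sqrt(-2 * log(stats::runif(n)))
}

#' Simulator configuration
#'
#' @param sigma_step Rayleigh scale of the speed distribution (default
#'   0.5, arena units per unit time).
#' @param kappa von Mises concentration of the heading about the
#'   previous heading (default 4).
#' @param dt forward-Euler integration step (default 0.1).
#' @param max_heading_resamples number of fresh heading draws attempted
#'   when a proposed step crosses a wall before the escape rule kicks in
#'   (default 100).
#' @return a list of class `"sim_config"`.
#' @export
simulator_config <- function(sigma_step = 0.5, kappa = 4, dt = 0.1,
                             max_heading_resamples = 100L) {
  stopifnot(sigma_step > 0, kappa >= 0, dt > 0, max_heading_resamples >= 1)
  structure(list(sigma_step = sigma_step, kappa = kappa, dt = dt,
                 max_heading_resamples = as.integer(max_heading_resamples)),
            class = "sim_config")
}

#' One step of the foraging walk
#'
#' Draws a speed from Rayleigh(`sigma_step`) and a heading from a von
#' Mises centered at the previous heading. If the Euler step segment
#' crosses a wall the *heading* (never the speed) is redrawn, up to
#' `max_heading_resamples` times; past the cap the heading is reversed
#' and the step re-attempted with the speed halved (halving again in the
#' degenerate corner case) so the walker always moves.
#'
#' @param pos current 2-D position (inside `env`).
#' @param heading current heading (radians).
#' @param cfg a `sim_config`.
#' @param env an `arena`.
#' @return list with `pos` (new position), `heading`, `velocity`
#'   (realized displacement / dt).
#' @export
traj_step <- function(pos, heading, cfg, env) {
  speed <- rrayleigh(1L, cfg$sigma_step)
  step_len <- speed * cfg$dt
  th <- rvonmises(1L, heading, cfg$kappa)
  prop <- pos + step_len * c(cos(th), sin(th))
  if (segment_hits_wall(pos, prop, env)) {
    ok <- FALSE
    for (i in seq_len(cfg$max_heading_resamples - 1L)) {
      th <- rvonmises(1L, heading, cfg$kappa)
      prop <- pos + step_len * c(cos(th), sin(th))
      if (!segment_hits_wall(pos, prop, env)) { ok <- TRUE; break }
    }
    if (!ok) {
      th <- heading + pi
      repeat {
        step_len <- step_len / 2
        prop <- pos + step_len * c(cos(th), sin(th))
        if (!segment_hits_wall(pos, prop, env) || step_len < 1e-12) break
      }
    }
  }
  list(pos = prop, heading = th, velocity = (prop - pos) / cfg$dt)
}

#' Simulate a foraging trajectory
#'
#' Start location uniform over the arena interior unless supplied;
#' initial heading uniform on `[0, 2*pi)`. Velocities are stored as the
#' realized displacement divided by `dt`:
#' `velocities[t, ] == (x[t+1] - x[t]) / dt`.
#'
#' @param env an `arena`.
#' @param T number of timesteps (>= 2).
#' @param cfg a `sim_config`.
#' @param start optional 2-D start point.
#' @return object of class `"trajectory"`: list with `env_id`,
#'   `context_index`, `context` (one-hot, length 6), `positions` (T x 2),
#'   `velocities` (T x 2), `dt`.
#' @export
simulate_trajectory <- function(env, T, cfg = simulator_config(),
                                start = NULL) {
  stopifnot(T >= 2)
  if (is.null(start)) start <- sample_uniform(env, 1L)[1, ]
  pos <- matrix(NA_real_, T + 1L, 2)
  pos[1, ] <- start
  heading <- stats::runif(1, 0, 2 * pi)
  speeds <- rrayleigh(T, cfg$sigma_step)
  deltas <- rvonmises(T, 0, cfg$kappa)
  dt <- cfg$dt
  p <- start
  # blocks of proposals are screened against the walls in vectorized form;
  # only flagged steps get the exact scalar test, and a confirmed hit
  # truncates the block at the colliding step
  block <- 64L
  t <- 1L
  while (t <= T) {
    nb <- min(block, T - t + 1L)
    idx <- t:(t + nb - 1L)
    ths <- heading + cumsum(deltas[idx])
    sl <- speeds[idx] * dt
    X <- p[1] + cumsum(sl * cos(ths))
    Y <- p[2] + cumsum(sl * sin(ths))
    Ax <- c(p[1], X[-nb]); Ay <- c(p[2], Y[-nb])
    flagged <- .screen_wall_hits(Ax, Ay, X, Y, env)
    stop_at <- 0L
    for (k in which(flagged)) {
      if (segment_hits_wall(c(Ax[k], Ay[k]), c(X[k], Y[k]), env)) {
        stop_at <- k; break
      }
    }
    if (stop_at == 0L) {
      pos[idx + 1L, 1] <- X; pos[idx + 1L, 2] <- Y
      p <- c(X[nb], Y[nb]); heading <- ths[nb]
      t <- t + nb
    } else {
      if (stop_at > 1L) {
        acc <- seq_len(stop_at - 1L)
        pos[t + acc, 1] <- X[acc]; pos[t + acc, 2] <- Y[acc]
        p <- c(X[stop_at - 1L], Y[stop_at - 1L])
        heading <- ths[stop_at - 1L]
      }
      # resolve the colliding step scalar-side: fresh heading draws, then
      # the reversal/halving escape
      tk <- t + stop_at - 1L
      step_len <- speeds[tk] * dt
      ok <- FALSE
      th <- NA_real_
      for (i in seq_len(cfg$max_heading_resamples - 1L)) {
        th <- heading + rvonmises(1L, 0, cfg$kappa)
        prop <- p + step_len * c(cos(th), sin(th))
        if (!segment_hits_wall(p, prop, env)) { ok <- TRUE; break }
      }
      if (!ok) {
        th <- heading + pi
        repeat {
          step_len <- step_len / 2
          prop <- p + step_len * c(cos(th), sin(th))
          if (!segment_hits_wall(p, prop, env) || step_len < 1e-12) break
        }
      }
      heading <- th
      p <- prop
      pos[tk + 1L, ] <- p
      t <- tk + 1L
    }
  }
  positions <- pos[seq_len(T), , drop = FALSE]
  velocities <- (pos[2:(T + 1L), , drop = FALSE] - positions) / dt
  structure(list(env_id = env$name, context_index = env$context_index,
                 context = context_onehot(env),
                 positions = positions, velocities = velocities, dt = dt),
            class = "trajectory")
}

#' Write a trajectory as CSV (t, x, y, vx, vy)
#' @param traj a `trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = seq_len(nrow(traj$positions)),
                   x = traj$positions[, 1], y = traj$positions[, 2],
                   vx = traj$velocities[, 1], vy = traj$velocities[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Build a multi-environment trajectory dataset
#'
#' Assembles `n_total` trajectories of length `T`, split 80/20 (by
#' default) into train and validation *by chain*. Within each split the
#' per-environment counts are exactly equal; environment identities are
#' randomly permuted across chain slots so the environment switches
#' randomly from one trajectory to the next inside a chain of
#' `chain_length` trajectories (the unit over which the recurrent state
#' is carried during stateful training).
#'
#' @param envs list of `arena`s (default: all six stock arenas).
#' @param n_total total number of trajectories (default 15000).
#' @param T timesteps per trajectory (default 500).
#' @param split train fraction (default 0.8).
#' @param chain_length trajectories per stateful chain (default 10).
#' @param cfg a `sim_config`.
#' @return object of class `"pc_dataset"`: list with arrays `positions`
#'   and `velocities` (T x 2 x n_total), `env_index` (0-based context
#'   per trajectory), `chain_id`, `chain_split` (`"train"`/`"validation"`
#'   per chain), `envs`, `T`, `dt`, `n_contexts`.
#' @export
build_dataset <- function(envs = lapply(.stock_arenas, make_environment),
                          n_total = 15000L, T = 500L, split = 0.8,
                          chain_length = 10L, cfg = simulator_config()) {
  n_env <- length(envs)
  n_train <- round(n_total * split)
  n_val <- n_total - n_train
  if (n_total %% n_env != 0L)
    stop("n_total must be divisible by the number of environments")
  if (n_train %% n_env != 0L || n_val %% n_env != 0L ||
      n_train %% chain_length != 0L || n_val %% chain_length != 0L)
    stop("train/validation sizes must be divisible by both the number of ",
         "environments and the chain length")
  assign_split <- function(n) {
    ids <- sample(rep(seq_len(n_env), n / n_env))  # balanced, random order
    ids
  }
  env_train <- assign_split(n_train)
  env_val <- assign_split(n_val)
  env_of <- c(env_train, env_val)
  n_chain <- n_total %/% chain_length
  chain_id <- rep(seq_len(n_chain), each = chain_length)
  chain_split <- rep(c("train", "validation"),
                     c(n_train %/% chain_length, n_val %/% chain_length))
  positions <- array(NA_real_, c(T, 2L, n_total))
  velocities <- array(NA_real_, c(T, 2L, n_total))
  for (i in seq_len(n_total)) {
    tr <- simulate_trajectory(envs[[env_of[i]]], T, cfg)
    positions[, , i] <- tr$positions
    velocities[, , i] <- tr$velocities
  }
  env_index <- vapply(envs, function(e) e$context_index, integer(1))[env_of]
  structure(list(positions = positions, velocities = velocities,
                 env_index = env_index, chain_id = chain_id,
                 chain_split = chain_split, chain_length = chain_length,
                 envs = envs, T = T, dt = cfg$dt, n_contexts = 6L),
            class = "pc_dataset")
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat("<pc_dataset>", dim(x$positions)[3], "trajectories of", x$T, "steps;",
      length(unique(x$env_index)), "environments;",
      sum(x$chain_split == "train"), "train /",
      sum(x$chain_split == "validation"), "validation chains of",
      x$chain_length, "\n")
  invisible(x)
}

# Conservative vectorized screening of step segments against the wall
# set: returns TRUE for any step that *might* cross a wall (exact test
# done scalar-side). Circle arenas use the exact radius test directly.
.screen_wall_hits <- function(Ax, Ay, Bx, By, env) {
  if (env$is_circle) {
    return((Bx - env$center[1])^2 + (By - env$center[2])^2 >
             env$radius^2 + 1e-12)
  }
  w <- env$walls
  out <- logical(length(Ax))
  dABx <- Bx - Ax; dABy <- By - Ay
  for (k in seq_len(nrow(w))) {
    x1 <- w[k, 1]; y1 <- w[k, 2]; x2 <- w[k, 3]; y2 <- w[k, 4]
    d1 <- dABx * (y1 - Ay) - dABy * (x1 - Ax)
    d2 <- dABx * (y2 - Ay) - dABy * (x2 - Ax)
    wx <- x2 - x1; wy <- y2 - y1
    d3 <- wx * (Ay - y1) - wy * (Ax - x1)
    d4 <- wx * (By - y1) - wy * (Bx - x1)
    out <- out | ((d1 * d2 <= 0) & (d3 * d4 <= 0))
  }
  out
}

# trajectory indices (columns of the data arrays) belonging to the chains
# of one split, as a chain-major matrix [chain_length x n_chains]
.split_chain_matrix <- function(ds, split) {
  chains <- which(ds$chain_split == split)
  vapply(chains, function(cid) which(ds$chain_id == cid),
         integer(ds$chain_length))
}
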