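# Frozen-weight protocols: cross-environment episodes, geometric
# manipulations, noise injection, context mismatch, velocity ablation.
# The streaming engine accumulates binned activity on the fly so long
# multi-trajectory runs never materialize full state tensors.

#' Specify a multi-segment episode
#'
#' @param segments list of segments, each a list with `env` (an
#'   `arena`), `T` (duration in steps, >= 1), and optionally `context`
#'   (0-based context index override; defaults to the segment arena's
#'   own context).
#' @param carry_state carry the recurrent state across segment
#'   boundaries (default TRUE); the first segment always starts from
#'   the zero state.
#' @return list of class `"episode_spec"`.
#' @export
episode_spec <- function(segments, carry_state = TRUE) {
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, function(s) s$T >= 1, logical(1))))
  structure(list(segments = segments, carry_state = carry_state),
            class = "episode_spec")
}

# run one segment for B lanes: simulate B fresh trajectories (or use
# supplied ones), roll the network, and accumulate binned output
# activity. Returns aggregate (and optionally per-time) bin sums.
.run_segment <- function(params, env, ctx_index, Tn, B, g, bins = 16L,
                         per_time = FALSE, keep_states = FALSE,
                         inject_at = NULL, inject_sigma = 0,
                         noise_seed = NULL, ablate_from = NULL,
                         trajectories = NULL, burn_in = 0L) {
  stopifnot(burn_in >= 0L, burn_in < Tn)
  N_p <- params$N_p
  nb <- bins * bins
  bb <- env$bounding_box
  if (is.null(trajectories)) {
    V <- array(NA_real_, c(Tn, 2, B))
    X <- array(NA_real_, c(Tn, 2, B))
    for (b in seq_len(B)) {
      tr <- simulate_trajectory(env, Tn)
      V[, , b] <- tr$velocities
      X[, , b] <- tr$positions
    }
  } else {
    V <- trajectories$V; X <- trajectories$X
    stopifnot(dim(V)[1] == Tn, dim(V)[3] == B)
  }
  cvec <- numeric(params$n_inputs - 2L); cvec[ctx_index + 1L] <- 1
  ctx_term <- as.vector(params$W_I[, 3:params$n_inputs, drop = FALSE] %*% cvec)
  W_R <- params$W_R; W_Iv <- params$W_I[, 1:2]; W_p <- params$W_p
  S <- matrix(0, N_p, nb)
  occ <- numeric(nb)
  p_sum <- numeric(N_p)
  active <- logical(N_p)
  R_t <- if (per_time) array(0, c(N_p, nb, Tn)) else NULL
  occ_t <- if (per_time) matrix(0, nb, Tn) else NULL
  P <- if (keep_states) array(NA_real_, c(N_p, B, Tn)) else NULL
  chi <- NULL
  if (!is.null(inject_at)) {
    if (!is.null(noise_seed)) {
      # independent noise stream so realizations vary at fixed paths
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                         .GlobalEnv) else NULL
      set.seed(noise_seed)
      chi <- matrix(stats::rnorm(params$N_g * B), params$N_g, B)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    } else {
      chi <- matrix(stats::rnorm(params$N_g * B), params$N_g, B)
    }
  }
  for (t in seq_len(Tn)) {
    Vt <- if (B == 1L) matrix(V[t, , 1], 2, 1) else V[t, , , drop = TRUE]
    if (!is.null(ablate_from) && t >= ablate_from) Vt <- Vt * 0
    g <- pmax(W_R %*% g + W_Iv %*% Vt + ctx_term, 0)
    if (!is.null(inject_at) && t == inject_at)
      g <- pmax(g + inject_sigma * chi, 0)
    p <- pmax(W_p %*% g, 0)
    bix <- .bin_index(X[t, 1, ], X[t, 2, ], bb, bins, bins)
    Z <- matrix(0, B, nb)
    Z[cbind(seq_len(B), bix)] <- 1
    pz <- p %*% Z
    if (per_time) { R_t[, , t] <- pz; occ_t[, t] <- tabulate(bix, nb) }
    if (keep_states) P[, , t] <- p
    if (t > burn_in) {
      S <- S + pz
      occ <- occ + tabulate(bix, nb)
      p_sum <- p_sum + rowSums(p)
      active <- active | (rowSums(p > 0) > 0)
    }
  }
  list(env = env, ctx_index = ctx_index, bins = bins, bb = bb,
       rate_sum = S, occ = occ, mean_rate = p_sum / ((Tn - burn_in) * B),
       active = active, g_final = g, Tn = Tn, B = B,
       R_t = R_t, occ_t = occ_t, P = P,
       positions = if (keep_states) X else NULL)
}

#' Per-unit ratemaps of a segment run
#'
#' @param seg one segment result from [run_episode()] and friends.
#' @param units unit indices (default all output units).
#' @param smooth apply [smooth_ratemap()] with `sigma_px = 1`.
#' @return list of `ratemap` objects.
#' @export
segment_ratemaps <- function(seg, units = seq_len(nrow(seg$rate_sum)),
                             smooth = FALSE) {
  occ <- matrix(seg$occ, seg$bins, seg$bins)
  lapply(units, function(i) {
    grid <- matrix(ifelse(seg$occ > 0, seg$rate_sum[i, ] / pmax(seg$occ, 1),
                          NaN), seg$bins, seg$bins)
    rm <- structure(list(grid = grid, occupancy = occ,
                         edges = .bin_edges(seg$bb, seg$bins, seg$bins),
                         bb = seg$bb), class = "ratemap")
    if (smooth) smooth_ratemap(rm) else rm
  })
}

#' Run a frozen network through a sequence of environments
#'
#' Rolls the trained network along `n_traj` independent lanes through
#' the segments of an [episode_spec()]: start positions are re-sampled
#' uniformly per segment, the recurrent state is carried across segment
#' boundaries (unless `carry_state` is off), and the first segment
#' starts from the zero state. Binned output activity is aggregated per
#' segment for ratemap construction. Weights are never modified.
#'
#' @param params a trained `pc_network`.
#' @param spec an `episode_spec`.
#' @param n_traj number of independent lanes (e.g. 500 distinct
#'   trajectories for remapping ratemaps).
#' @param bins ratemap resolution (default 16).
#' @param keep_states also store per-step output activity and positions
#'   (memory-heavy; for small runs).
#' @param burn_in per-segment steps excluded from the aggregated
#'   ratemaps and rate statistics (default 0), so that per-condition
#'   maps capture the steady state after a zero reset or a context
#'   transfer; the recurrent state still evolves through burn-in steps.
#' @return list of class `"episode_run"` with one segment-stats entry
#'   per segment (see [segment_ratemaps()]).
#' @export
run_episode <- function(params, spec, n_traj = 1L, bins = 16L,
                        keep_states = FALSE, burn_in = 0L) {
  g <- matrix(0, params$N_g, n_traj)
  out <- vector("list", length(spec$segments))
  for (s in seq_along(spec$segments)) {
    seg <- spec$segments[[s]]
    ctx <- if (!is.null(seg$context)) seg$context else seg$env$context_index
    if (!spec$carry_state && s > 1L) g <- matrix(0, params$N_g, n_traj)
    res <- .run_segment(params, seg$env, ctx, seg$T, n_traj, g, bins,
                        keep_states = keep_states, burn_in = burn_in)
    g <- res$g_final
    out[[s]] <- res
  }
  structure(list(segments = out, spec = spec, n_traj = n_traj),
            class = "episode_run")
}

#' Run a frozen network in a geometrically manipulated arena
#'
#' Simulates fresh trajectories in the transformed geometry while
#' feeding the *familiar* context signal of the base arena, for
#' inspecting field elongation, completion, and doubling.
#'
#' @param params a trained `pc_network`.
#' @param base_env the familiar stock `arena`.
#' @param kind,factor see [transform_environment()].
#' @param n_traj,T,bins run shape.
#' @param keep_states store activity and positions.
#' @return segment stats (as in [run_episode()]) plus the transformed
#'   arena under `$env`.
#' @export
run_manipulation <- function(params, base_env, kind, factor = 2,
                             n_traj = 100L, T = 800L, bins = 16L,
                             keep_states = FALSE) {
  env2 <- transform_environment(base_env, kind, factor)
  g <- matrix(0, params$N_g, n_traj)
  .run_segment(params, env2, base_env$context_index, T, n_traj, g, bins,
               keep_states = keep_states)
}

#' Noise injection into the recurrent state
#'
#' Evaluates the frozen network on `n_traj` trajectories in `env`; at
#' timestep `tau` the recurrent state is replaced by
#' `relu(g + sigma * chi)` with `chi` i.i.d. standard normal, then the
#' run continues normally. Binned output activity is stored per
#' timestep (aggregated across trajectories) for population-vector
#' correlation matrices.
#'
#' @param params a trained `pc_network`.
#' @param env an `arena` (the square, canonically).
#' @param sigma noise scale (0, 0.01, 0.1, or 1.0 in the standard
#'   protocol).
#' @param tau injection timestep (default 400).
#' @param T trajectory length (default 800).
#' @param n_traj number of trajectories (default 1000).
#' @param bins ratemap resolution.
#' @param noise_seed optional separate seed for the noise draw so noise
#'   realizations can be varied at fixed trajectories.
#' @param trajectories optional list(V, X) of pre-simulated paths.
#' @param ablate_velocity zero the velocity input from `tau` onward.
#' @return list of class `"noise_run"`: per-time binned activity `R_t`
#'   (N_p x bins^2 x T), per-time occupancy `occ_t`, and metadata.
#' @export
run_noise_injection <- function(params, env, sigma, tau = 400L, T = 800L,
                                n_traj = 1000L, bins = 16L,
                                noise_seed = NULL, trajectories = NULL,
                                ablate_velocity = FALSE) {
  stopifnot(tau < T)
  g <- matrix(0, params$N_g, n_traj)
  res <- .run_segment(params, env, env$context_index, T, n_traj, g, bins,
                      per_time = TRUE, inject_at = tau,
                      inject_sigma = sigma, noise_seed = noise_seed,
                      ablate_from = if (ablate_velocity) tau else NULL,
                      trajectories = trajectories)
  structure(c(res[c("R_t", "occ_t", "bins", "bb", "mean_rate", "active")],
              list(tau = tau, sigma = sigma, T = T, n_traj = n_traj,
                   env = env, ablate_velocity = ablate_velocity)),
            class = "noise_run")
}

#' Velocity ablation at noise injection
#'
#' Same protocol as [run_noise_injection()] but the velocity input is
#' zeroed from `tau` onward, isolating autonomous (attractor) dynamics
#' from error correction driven by boundary interactions.
#'
#' @inheritParams run_noise_injection
#' @export
run_velocity_ablation <- function(params, env, sigma = 0, tau = 400L,
                                  T = 800L, n_traj = 1000L, bins = 16L,
                                  noise_seed = NULL, trajectories = NULL) {
  run_noise_injection(params, env, sigma, tau, T, n_traj, bins,
                      noise_seed, trajectories, ablate_velocity = TRUE)
}

#' Context mismatch: geometry A, context B
#'
#' Simulates trajectories in `geometry_env` while feeding the constant
#' one-hot context of `context_env`, probing whether the context signal
#' or the geometry determines the representation.
#'
#' @param params a trained `pc_network`.
#' @param geometry_env arena the walker moves in.
#' @param context_env arena whose context signal is fed.
#' @param n_traj,T,bins run shape.
#' @param keep_states store activity and positions.
#' @return segment stats (see [segment_ratemaps()]).
#' @export
run_context_mismatch <- function(params, geometry_env, context_env,
                                 n_traj = 100L, T = 800L, bins = 16L,
                                 keep_states = FALSE) {
  g <- matrix(0, params$N_g, n_traj)
  .run_segment(params, geometry_env, context_env$context_index, T, n_traj,
               g, bins, keep_states = keep_states)
}

#' Population-vector correlation timecourse of a noise run
#'
#' For every timestep, the per-unit ratemaps aggregated across
#' trajectories at that timestep are smoothed (shared occupancy mask,
#' Gaussian sigma one pixel) and stacked into a population vector; the
#' full Pearson correlation matrix between timesteps is returned.
#'
#' @param nr a `noise_run`.
#' @param sigma_px smoothing kernel width in pixels.
#' @return T x T correlation matrix.
#' @export
pv_time_matrix <- function(nr, sigma_px = 1) {
  Tn <- dim(nr$R_t)[3]
  N_p <- dim(nr$R_t)[1]
  bins <- nr$bins
  feats <- matrix(NA_real_, N_p * bins * bins, Tn)
  for (t in seq_len(Tn)) {
    occ <- matrix(nr$occ_t[, t], bins, bins)
    mask <- (occ > 0) * 1
    rate <- nr$R_t[, , t] / rep(pmax(nr$occ_t[, t], 1), each = N_p)
    A <- array(t(rate), c(bins, bins, N_p))  # zeros at unvisited bins
    sm <- .smooth_stack(A, mask, sigma_px)
    feats[, t] <- as.numeric(sm)
  }
  stats::cor(feats, use = "pairwise.complete.obs")
}

#' Dip-and-recovery summary of a PV correlation matrix
#'
#' Correlates every timestep against the last pre-injection timestep:
#' reports the pre-injection plateau (mean over the `pre` steps before
#' `tau`), the post-injection dip (minimum over the `dip` steps from
#' `tau`), the recovery level (mean over the final `tail` steps), and
#' the recovery ratio relative to the plateau.
#'
#' @param C T x T PV correlation matrix (from [pv_time_matrix()]).
#' @param tau injection timestep.
#' @param pre,dip,tail window sizes in steps.
#' @return list with `plateau`, `dip`, `recovery`, `recovery_ratio`.
#' @export
noise_recovery_summary <- function(C, tau, pre = 100L, dip = 50L,
                                   tail = 100L) {
  Tn <- nrow(C)
  ref <- tau - 1L
  plateau <- mean(C[ref, max(1L, tau - pre):(tau - 1L)], na.rm = TRUE)
  dip_v <- min(C[ref, tau:min(Tn, tau + dip)], na.rm = TRUE)
  recov <- mean(C[ref, (Tn - tail + 1L):Tn], na.rm = TRUE)
  list(plateau = plateau, dip = dip_v, recovery = recov,
       recovery_ratio = recov / plateau)
}

#' Per-trajectory decoded center clouds
#'
#' Decodes every unit's center once per trajectory (activity-weighted
#' mean position over that trajectory) from fresh simulated
#' trajectories with the frozen network, the aggregation behind the
#' hexagonal center-arrangement inspection.
#'
#' @param params a trained `pc_network`.
#' @param env an `arena`.
#' @param n_traj number of trajectories (100 in the full protocol).
#' @param T steps per trajectory (30000 in the full protocol).
#' @param units optional unit subset (e.g. from [high_si_units()]).
#' @param epsilon decoder guard.
#' @return array `centers` of dim (units, 2, n_traj).
#' @export
decoded_center_aggregation <- function(params, env, n_traj = 100L,
                                       T = 30000L, units = NULL,
                                       epsilon = 1e-8) {
  if (is.null(units)) units <- seq_len(params$N_p)
  cvec <- context_onehot(env)
  ctx_term <- as.vector(params$W_I[, 3:params$n_inputs, drop = FALSE] %*% cvec)
  W_R <- params$W_R; W_Iv <- params$W_I[, 1:2]; W_p <- params$W_p
  centers <- array(NA_real_, c(length(units), 2, n_traj))
  for (j in seq_len(n_traj)) {
    tr <- simulate_trajectory(env, T)
    g <- numeric(params$N_g)
    num <- matrix(0, params$N_p, 2)
    den <- numeric(params$N_p)
    for (t in seq_len(T)) {
      g <- pmax(as.vector(W_R %*% g + W_Iv %*% tr$velocities[t, ]) +
                  ctx_term, 0)
      p <- pmax(as.vector(W_p %*% g), 0)
      num <- num + outer(p, tr$positions[t, ])
      den <- den + p
    }
    centers[, , j] <- (num / pmax(den, epsilon))[units, , drop = FALSE]
  }
  centers
}
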