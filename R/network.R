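# Recurrent path-integration network with a fixed center-of-mass
# readout. The decoder has no trainable parameters but is differentiable
# end-to-end; the backward pass below propagates gradients through both
# the per-time position estimate and the trajectory-wide unit centers.

#' Initialize network parameters
#'
#' Recurrent weights start at the identity (mitigates exploding and
#' vanishing gradients over long sequences); feedforward weights are
#' drawn from U(-k, k) with k = 1/sqrt(fan-in). No biases anywhere.
#'
#' @param N_g number of recurrent units (default 500).
#' @param N_p number of output units (default 100).
#' @param n_inputs input dimension (2 velocity + 6 context = 8).
#' @return object of class `"pc_network"`: list with `W_R` (N_g x N_g),
#'   `W_I` (N_g x n_inputs), `W_p` (N_p x N_g), `N_g`, `N_p`, `n_inputs`.
#' @export
init_network <- function(N_g = 500L, N_p = 100L, n_inputs = 8L) {
  kI <- 1 / sqrt(n_inputs)
  kp <- 1 / sqrt(N_g)
  structure(list(
    W_R = diag(N_g),
    W_I = matrix(stats::runif(N_g * n_inputs, -kI, kI), N_g, n_inputs),
    W_p = matrix(stats::runif(N_p * N_g, -kp, kp), N_p, N_g),
    N_g = as.integer(N_g), N_p = as.integer(N_p),
    n_inputs = as.integer(n_inputs)), class = "pc_network")
}

#' @export
print.pc_network <- function(x, ...) {
  cat("<pc_network>", x$N_g, "recurrent units ->", x$N_p,
      "output units; inputs:", x$n_inputs, "\n")
  invisible(x)
}

#' One recurrent update
#'
#' `g' = relu(W_R g + W_I cat(v, c))`. Accepts a single state vector or
#' a column-batched state matrix (N_g x B).
#'
#' @param g recurrent state (length N_g vector or N_g x B matrix).
#' @param v 2-D velocity (vector, or 2 x B matrix for a batch).
#' @param ctx context signal (length 6 vector, or 6 x B matrix).
#' @param params a `pc_network`.
#' @return updated state, same shape as `g`.
#' @export
rnn_step <- function(g, v, ctx, params) {
  single <- is.null(dim(g))
  if (single) { g <- matrix(g); v <- matrix(v); ctx <- matrix(ctx) }
  if (nrow(g) != params$N_g || nrow(v) + nrow(ctx) != params$n_inputs)
    stop("shape mismatch in rnn_step")
  out <- pmax(params$W_R %*% g + params$W_I %*% rbind(v, ctx), 0)
  if (single) drop(out) else out
}

#' Linear rectified readout
#'
#' `p = relu(W_p g)`.
#'
#' @inheritParams rnn_step
#' @return output activity, length N_p (or N_p x B).
#' @export
readout <- function(g, params) {
  single <- is.null(dim(g))
  if (single) g <- matrix(g)
  if (nrow(g) != params$N_g) stop("shape mismatch in readout")
  out <- pmax(params$W_p %*% g, 0)
  if (single) drop(out) else out
}

#' Loss configuration
#'
#' @param lambda_l1 L1 coefficient on recurrent activity (default 10).
#' @param epsilon zero-division guard shared with the decoder
#'   (default 1e-8).
#' @param normalize_l1 if `TRUE` (default) the penalty is
#'   `lambda_l1 * mean_t(|g_t|_1 / N_g)`, keeping it commensurate with a
#'   squared position error of order one; `FALSE` uses the raw 1-norm.
#' @param detach_centers if `TRUE`, unit centers are treated as
#'   constants in the backward pass (stop-gradient variant).
#' @return list of class `"loss_config"`.
#' @export
loss_config <- function(lambda_l1 = 10, epsilon = 1e-8,
                        normalize_l1 = TRUE, detach_centers = FALSE) {
  stopifnot(lambda_l1 >= 0, epsilon > 0)
  structure(list(lambda_l1 = lambda_l1, epsilon = epsilon,
                 normalize_l1 = normalize_l1,
                 detach_centers = detach_centers), class = "loss_config")
}

#' Decode unit centers from a trajectory
#'
#' Center of unit i is its activity-weighted average position:
#' `mu_i = sum_t p_i(t) x_t / max(eps, sum_t p_i(t))` (the time means of
#' the defining expectations cancel to sums). All-silent units get the
#' zero point via the guard.
#'
#' @param P T x N_p activity matrix.
#' @param X T x 2 position matrix.
#' @param epsilon zero-division guard.
#' @return N_p x 2 matrix of centers.
#' @export
decode_centers <- function(P, X, epsilon = 1e-8) {
  stopifnot(nrow(P) == nrow(X))
  num <- t(P) %*% X              # N_p x 2
  den <- pmax(colSums(P), epsilon)
  num / den
}

#' Decode a position from instantaneous activity
#'
#' `xhat = sum_i p_i mu_i / max(eps, sum_i p_i)` — the activity-weighted
#' center of mass of the unit centers.
#'
#' @param p length-N_p activity vector.
#' @param mu N_p x 2 matrix of unit centers.
#' @param epsilon zero-division guard.
#' @return 2-D position estimate.
#' @export
decode_position <- function(p, mu, epsilon = 1e-8) {
  stopifnot(length(p) == nrow(mu))
  drop(crossprod(mu, p)) / max(sum(p), epsilon)
}

#' Training objective
#'
#' Mean over time of the squared Euclidean position error plus the L1
#' penalty on recurrent activity (see [loss_config()]); batches are
#' reduced by the mean.
#'
#' @param X T x 2 true positions.
#' @param Xhat T x 2 decoded positions.
#' @param G T x N_g recurrent states.
#' @param cfg a `loss_config`.
#' @return scalar loss.
#' @export
pi_objective <- function(X, Xhat, G, cfg = loss_config()) {
  stopifnot(nrow(X) == nrow(Xhat), nrow(X) == nrow(G))
  mse <- mean(rowSums((X - Xhat)^2))
  l1 <- mean(rowSums(abs(G)))
  if (cfg$normalize_l1) l1 <- l1 / ncol(G)
  mse + cfg$lambda_l1 * l1
}

# ---- batched forward / backward core ------------------------------------
# V: T x 2 x B velocities; Cmat: 6 x B contexts; X: T x 2 x B positions;
# g0: N_g x B initial state. Returns caches needed by .backward_batch.
.forward_batch <- function(params, V, Cmat, X, g0, cfg = loss_config(),
                           keep_G = TRUE) {
  Tn <- dim(V)[1]; B <- dim(V)[3]
  N_g <- params$N_g; N_p <- params$N_p
  G <- array(NA_real_, c(N_g, B, Tn))
  I <- array(NA_real_, c(params$n_inputs, B, Tn))
  g <- g0
  W_R <- params$W_R; W_I <- params$W_I
  for (t in seq_len(Tn)) {
    It <- if (B == 1L) matrix(c(V[t, , 1], Cmat), ncol = 1)
          else rbind(V[t, , , drop = TRUE], Cmat)
    g <- pmax(W_R %*% g + W_I %*% It, 0)
    G[, , t] <- g
    I[, , t] <- It
  }
  P <- array(pmax(params$W_p %*% matrix(G, N_g, B * Tn), 0), c(N_p, B, Tn))
  eps <- cfg$epsilon
  # trajectory-wide centers, per batch lane
  Dmu <- matrix(0, N_p, B)            # sum_t p
  M1 <- matrix(0, N_p, B); M2 <- matrix(0, N_p, B)  # sum_t p * x_d
  for (t in seq_len(Tn)) {
    Pt <- P[, , t, drop = TRUE]; if (B == 1L) Pt <- matrix(Pt, ncol = 1)
    Dmu <- Dmu + Pt
    M1 <- M1 + Pt * rep(X[t, 1, ], each = N_p)
    M2 <- M2 + Pt * rep(X[t, 2, ], each = N_p)
  }
  DmuC <- pmax(Dmu, eps)
  MU1 <- M1 / DmuC; MU2 <- M2 / DmuC   # N_p x B
  # per-time decoded positions
  Xhat <- array(NA_real_, c(Tn, 2, B))
  Den <- matrix(NA_real_, Tn, B)
  for (t in seq_len(Tn)) {
    Pt <- P[, , t, drop = TRUE]; if (B == 1L) Pt <- matrix(Pt, ncol = 1)
    den <- pmax(colSums(Pt), eps)
    Den[t, ] <- den
    Xhat[t, 1, ] <- colSums(Pt * MU1) / den
    Xhat[t, 2, ] <- colSums(Pt * MU2) / den
  }
  err2 <- (X - Xhat)^2
  mse <- sum(err2) / (Tn * B)
  l1 <- sum(G) / (Tn * B)
  if (cfg$normalize_l1) l1 <- l1 / N_g
  loss <- mse + cfg$lambda_l1 * l1
  list(params = params, cfg = cfg, V = V, Cmat = Cmat, X = X, g0 = g0,
       G = G, I = I, P = P, MU1 = MU1, MU2 = MU2, Dmu = Dmu, DmuC = DmuC,
       Den = Den, Xhat = Xhat, loss = loss, mse = mse,
       err_euclid = mean(sqrt(err2[, 1, , drop = FALSE] +
                                err2[, 2, , drop = FALSE])),
       Tn = Tn, B = B)
}

.backward_batch <- function(fw) {
  params <- fw$params; cfg <- fw$cfg
  Tn <- fw$Tn; B <- fw$B
  N_g <- params$N_g; N_p <- params$N_p
  eps <- cfg$epsilon
  P <- fw$P; G <- fw$G; X <- fw$X; Xhat <- fw$Xhat
  MU1 <- fw$MU1; MU2 <- fw$MU2
  mu_act1 <- (fw$Dmu > eps) * MU1     # mu contributes to d(num)/dp only
  mu_act2 <- (fw$Dmu > eps) * MU2     # when the denominator is unclamped
  dP <- array(0, c(N_p, B, Tn))
  dMU1 <- matrix(0, N_p, B); dMU2 <- matrix(0, N_p, B)
  for (t in seq_len(Tn)) {
    Pt <- P[, , t, drop = TRUE]; if (B == 1L) Pt <- matrix(Pt, ncol = 1)
    den <- fw$Den[t, ]
    act <- as.numeric(colSums(Pt) > eps)
    r1 <- (2 / (Tn * B)) * (Xhat[t, 1, ] - X[t, 1, ])  # length B
    r2 <- (2 / (Tn * B)) * (Xhat[t, 2, ] - X[t, 2, ])
    # direct path through xhat_t
    dP[, , t] <- (MU1 - rep(act * Xhat[t, 1, ], each = N_p)) *
      rep(r1 / den, each = N_p) +
      (MU2 - rep(act * Xhat[t, 2, ], each = N_p)) * rep(r2 / den, each = N_p)
    # accumulate gradient wrt centers
    dMU1 <- dMU1 + Pt * rep(r1 / den, each = N_p)
    dMU2 <- dMU2 + Pt * rep(r2 / den, each = N_p)
  }
  if (!cfg$detach_centers) {
    for (t in seq_len(Tn)) {
      dP[, , t] <- dP[, , t] +
        dMU1 * (rep(X[t, 1, ], each = N_p) - mu_act1) / fw$DmuC +
        dMU2 * (rep(X[t, 2, ], each = N_p) - mu_act2) / fw$DmuC
    }
  }
  # through the readout rectification
  dAp <- matrix(dP, N_p, B * Tn) * (matrix(P, N_p, B * Tn) > 0)
  Gf <- matrix(G, N_g, B * Tn)
  dW_p <- dAp %*% t(Gf)
  dG_flat <- crossprod(params$W_p, dAp)      # N_g x (B*Tn)
  # L1 penalty (g >= 0 so |g|' = 1 on the active set)
  l1_coef <- cfg$lambda_l1 / (Tn * B)
  if (cfg$normalize_l1) l1_coef <- l1_coef / N_g
  dG_flat <- dG_flat + l1_coef * (Gf > 0)
  dG <- array(dG_flat, c(N_g, B, Tn))
  # truncated BPTT within the trajectory
  dW_R <- matrix(0, N_g, N_g)
  dW_I <- matrix(0, N_g, params$n_inputs)
  carry <- matrix(0, N_g, B)
  W_Rt <- t(params$W_R)
  for (t in rev(seq_len(Tn))) {
    Gt <- G[, , t, drop = TRUE]; if (B == 1L) Gt <- matrix(Gt, ncol = 1)
    delta <- (dG[, , t, drop = TRUE] + carry)
    if (B == 1L) delta <- matrix(delta, ncol = 1)
    delta <- delta * (Gt > 0)
    Gprev <- if (t == 1L) fw$g0 else G[, , t - 1L, drop = TRUE]
    if (B == 1L) Gprev <- matrix(Gprev, ncol = 1)
    It <- fw$I[, , t, drop = TRUE]
    if (B == 1L) It <- matrix(It, ncol = 1)
    dW_R <- dW_R + delta %*% t(Gprev)
    dW_I <- dW_I + delta %*% t(It)
    carry <- W_Rt %*% delta
  }
  list(W_R = dW_R, W_I = dW_I, W_p = dW_p)
}

#' Run the network over one trajectory
#'
#' Rolls the recurrent update and readout along a trajectory, computes
#' unit centers from that same trajectory's output activity and
#' positions, decodes the per-time position estimate, and evaluates the
#' objective.
#'
#' @param traj a `trajectory`.
#' @param params a `pc_network`.
#' @param g0 initial recurrent state (default zero: no positional
#'   information at trajectory start).
#' @param cfg a `loss_config`.
#' @return list with `G` (T x N_g recurrent states), `P` (T x N_p
#'   output states), `mu` (N_p x 2 centers), `Xhat` (T x 2 decoded
#'   positions), `loss`, `error` (mean Euclidean decoding error),
#'   `per_time_error` (length-T vector), `g_final`.
#' @export
forward_trajectory <- function(traj, params, g0 = NULL,
                               cfg = loss_config()) {
  Tn <- nrow(traj$positions)
  if (is.null(g0)) g0 <- numeric(params$N_g)
  V <- array(traj$velocities, c(Tn, 2, 1))
  X <- array(traj$positions, c(Tn, 2, 1))
  Cmat <- matrix(traj$context, ncol = 1)
  fw <- .forward_batch(params, V, Cmat, X, matrix(g0, ncol = 1), cfg)
  per_t <- sqrt((X[, 1, 1] - fw$Xhat[, 1, 1])^2 +
                  (X[, 2, 1] - fw$Xhat[, 2, 1])^2)
  list(G = t(fw$G[, 1, ]), P = t(fw$P[, 1, ]),
       mu = cbind(fw$MU1[, 1], fw$MU2[, 1]),
       Xhat = fw$Xhat[, , 1], loss = fw$loss, error = mean(per_t),
       per_time_error = per_t, g_final = fw$G[, 1, Tn])
}

#' Save / load network parameters
#'
#' Parameters are written as an RDS container with a JSON sidecar
#' recording shapes and an optional config fingerprint.
#'
#' @param params a `pc_network`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` +
#'   `".json"`.
#' @param meta optional named list stored in the sidecar.
#' @export
save_checkpoint <- function(params, path, meta = list()) {
  saveRDS(params, path)
  side <- c(list(N_g = params$N_g, N_p = params$N_p,
                 n_inputs = params$n_inputs,
                 shapes = lapply(params[c("W_R", "W_I", "W_p")], dim)),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
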