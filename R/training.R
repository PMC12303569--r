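# Stateful multi-environment training. Each minibatch lane carries its
# own recurrent state across the 10 trajectories of a chain (detached at
# trajectory boundaries: truncated BPTT), resetting to zero at chain
# boundaries. One Adam step per trajectory position.

#' Training configuration
#'
#' Defaults follow the full-scale protocol: 100 epochs, minibatch 64,
#' Adam with learning rate 1e-4 and default moments, chains of 10.
#'
#' @param epochs number of passes over the training chains.
#' @param batch_size chains per minibatch.
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param seed optional RNG seed set at the start of training.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L, lr = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         seed = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = seed), class = "train_config")
}

#' Scaled desk-size preset
#'
#' A reduced protocol for testing on a single CPU: a 128-unit recurrent
#' layer with 64 output units, two environments (square and
#' square_wall), 1200 trajectories of 250 steps, 25 epochs. Batch size
#' 16 and learning rate 5e-4 give roughly 2000 optimizer steps, a
#' standard budget for a network of this size.
#'
#' @return list with `N_g`, `N_p`, `env_names`, `n_traj`, `T`,
#'   `train_cfg`.
#' @export
scaled_preset <- function() {
  list(N_g = 128L, N_p = 64L, env_names = c("square", "square_wall"),
       n_traj = 1200L, T = 250L,
       train_cfg = train_config(epochs = 25L, batch_size = 16L, lr = 5e-4))
}

.adam_init <- function(params) {
  lapply(params[c("W_R", "W_I", "W_p")], function(W) {
    list(m = W * 0, v = W * 0)
  })
}

.adam_step <- function(params, grads, state, step, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2
  for (nm in c("W_R", "W_I", "W_p")) {
    g <- grads[[nm]]
    state[[nm]]$m <- b1 * state[[nm]]$m + (1 - b1) * g
    state[[nm]]$v <- b2 * state[[nm]]$v + (1 - b2) * g * g
    mhat <- state[[nm]]$m / (1 - b1^step)
    vhat <- state[[nm]]$v / (1 - b2^step)
    params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

.context_matrix <- function(env_index, n_contexts = 6L) {
  B <- length(env_index)
  Cmat <- matrix(0, n_contexts, B)
  Cmat[cbind(env_index + 1L, seq_len(B))] <- 1
  Cmat
}

#' Train the network on a precomputed dataset
#'
#' Iterates training chains in minibatches. Within a batch, lane b runs
#' the trajectories of its chain in order, carrying the recurrent state
#' forward (detached) and taking one Adam step on the per-trajectory
#' objective; the state resets to zero at chain boundaries. Epochs
#' permute the chain order only, so every epoch replays the same
#' precomputed chains.
#'
#' @param dataset a `pc_dataset`.
#' @param params a `pc_network` (fresh from [init_network()] or a
#'   checkpoint).
#' @param cfg a `train_config`.
#' @param loss_cfg a `loss_config`.
#' @param verbose print per-epoch errors.
#' @return list with `params` (trained) and `log`, a data.frame with
#'   per-epoch `train_error` and `val_error` (mean Euclidean decoding
#'   error).
#' @export
train <- function(dataset, params, cfg = train_config(),
                  loss_cfg = loss_config(), verbose = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  chains <- .split_chain_matrix(dataset, "train")   # chain_length x n_chain
  n_chain <- ncol(chains)
  stopifnot(nrow(chains) == dataset$chain_length)
  opt <- .adam_init(params)
  step <- 0L
  log <- data.frame(epoch = seq_len(cfg$epochs), train_error = NA_real_,
                    val_error = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_chain)
    errs <- c(); wts <- c()
    for (b0 in seq(1L, n_chain, by = cfg$batch_size)) {
      cols <- ord[b0:min(b0 + cfg$batch_size - 1L, n_chain)]
      B <- length(cols)
      g <- matrix(0, params$N_g, B)
      for (k in seq_len(dataset$chain_length)) {
        idx <- chains[k, cols]
        V <- dataset$velocities[, , idx, drop = FALSE]
        X <- dataset$positions[, , idx, drop = FALSE]
        Cmat <- .context_matrix(dataset$env_index[idx], dataset$n_contexts)
        fw <- .forward_batch(params, V, Cmat, X, g, loss_cfg)
        if (!is.finite(fw$loss))
          stop(sprintf("non-finite loss at epoch %d, step %d (|g| max %.3g)",
                       ep, step + 1L, max(abs(fw$G))))
        gr <- .backward_batch(fw)
        step <- step + 1L
        upd <- .adam_step(params, gr, opt, step, cfg)
        params <- upd$params; opt <- upd$state
        g <- matrix(fw$G[, , fw$Tn], params$N_g, B)  # detached carry
        errs <- c(errs, fw$err_euclid); wts <- c(wts, B)
      }
    }
    log$train_error[ep] <- sum(errs * wts) / sum(wts)
    log$val_error[ep] <- evaluate(params, dataset, split = "validation",
                                  loss_cfg = loss_cfg)$overall
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f",
                      ep, log$train_error[ep], log$val_error[ep]))
  }
  list(params = params, log = log)
}

#' Evaluate decoding error on a dataset split
#'
#' Runs the network statefully over the chains of a split (zero reset at
#' chain boundaries, state carried between trajectories within a chain,
#' mirroring training) and reports the mean Euclidean distance between
#' true and decoded positions: overall, per environment, and per
#' timestep. Initial timesteps, where the network has no positional
#' information, are included.
#'
#' @param params a `pc_network`.
#' @param dataset a `pc_dataset`.
#' @param split `"validation"` (default) or `"train"`.
#' @param loss_cfg a `loss_config`.
#' @return list with `overall` (scalar), `per_env` (named vector),
#'   `per_time` (length-T vector), `per_traj` (one mean error per
#'   trajectory), `env_index` (0-based context per trajectory).
#' @export
evaluate <- function(params, dataset, split = "validation",
                     loss_cfg = loss_config()) {
  chains <- .split_chain_matrix(dataset, split)
  Tn <- dataset$T
  per_time_sum <- numeric(Tn)
  per_traj <- numeric(0)
  env_of <- integer(0)
  n_done <- 0L
  for (b0 in seq(1L, ncol(chains), by = 64L)) {
    cols <- b0:min(b0 + 63L, ncol(chains))
    B <- length(cols)
    g <- matrix(0, params$N_g, B)
    for (k in seq_len(nrow(chains))) {
      idx <- chains[k, cols]
      V <- dataset$velocities[, , idx, drop = FALSE]
      X <- dataset$positions[, , idx, drop = FALSE]
      Cmat <- .context_matrix(dataset$env_index[idx], dataset$n_contexts)
      fw <- .forward_batch(params, V, Cmat, X, g, loss_cfg)
      d <- sqrt((X[, 1, ] - fw$Xhat[, 1, ])^2 +
                  (X[, 2, ] - fw$Xhat[, 2, ])^2)  # T x B
      d <- matrix(d, Tn, B)
      per_time_sum <- per_time_sum + rowSums(d)
      per_traj <- c(per_traj, colMeans(d))
      env_of <- c(env_of, dataset$env_index[idx])
      n_done <- n_done + B
      g <- matrix(fw$G[, , Tn], params$N_g, B)
    }
  }
  per_env <- tapply(per_traj, env_of, mean)
  list(overall = mean(per_traj), per_env = per_env,
       per_time = per_time_sum / n_done, per_traj = per_traj,
       env_index = env_of)
}
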