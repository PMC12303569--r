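# Trained scaled model shared by the long-protocol tests: built once per
# test session and cached. Seed fixed so every run of the suite trains
# the identical model.
.placenet_cache <- new.env(parent = emptyenv())

scaled_model_fixture <- function() {
  if (!is.null(.placenet_cache$fit)) return(.placenet_cache$fit)
  set.seed(101)
  pre <- scaled_preset()
  envs <- lapply(pre$env_names, make_environment)
  ds <- build_dataset(envs, n_total = pre$n_traj, T = pre$T)
  params0 <- init_network(pre$N_g, pre$N_p)
  baseline <- evaluate(params0, ds)
  fit <- train(ds, params0, pre$train_cfg)
  out <- list(params = fit$params, log = fit$log, ds = ds,
              baseline = baseline, envs = envs, preset = pre)
  .placenet_cache$fit <- out
  out
}

# Fig-3-style A -> B -> A' episode on the trained scaled model (500
# trajectories, 800 steps per segment, steady-state burn-in), cached.
remap_episode_fixture <- function() {
  if (!is.null(.placenet_cache$episode)) return(.placenet_cache$episode)
  fit <- scaled_model_fixture()
  set.seed(202)
  spec <- episode_spec(list(list(env = fit$envs[[1]], T = 800L),
                            list(env = fit$envs[[2]], T = 800L),
                            list(env = fit$envs[[1]], T = 800L)))
  ep <- run_episode(fit$params, spec, n_traj = 500L, burn_in = 500L)
  .placenet_cache$episode <- ep
  ep
}
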