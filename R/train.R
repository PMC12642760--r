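# Multi-agent PPO training loop: collect -> GAE -> clipped-surrogate update,
# with a shared parameter set updated from all agents' experience.

#' Train a shared recurrent policy with multi-agent PPO
#'
#' Repeats rollout collection across parallel environments, generalized
#' advantage estimation, and clipped-surrogate updates on the shared
#' recurrent actor-critic until `total_steps` environment steps have been
#' consumed.  All randomness derives from `train_cfg$seed`; in
#' single-threaded R the run is bit-reproducible.
#'
#' @param arena An [arena_config()].
#' @param policy_cfg A [policy_config()]; by default a 64-unit policy on the
#'   arena's observation space (use 512 for full-scale runs).  When
#'   `train_cfg$centralized_critic` is `TRUE` the config must carry
#'   `global_input_dim = obs_dim * n_agents` (done automatically for the
#'   default).
#' @param train_cfg A [train_config()].
#' @param checkpoint_dir Optional directory for periodic checkpoints.
#' @param checkpoint_every Iterations between checkpoints (0 = none).
#' @param verbose Print per-iteration telemetry.
#' @return A list of class `efish_training`: `policy`, `log` (tibble with
#'   one row per iteration: env steps, mean episode reward and food of
#'   episodes finished that iteration, mean per-step EOD rate, loss
#'   diagnostics), `arena`, `train_cfg`.
#' @export
train <- function(arena, policy_cfg = NULL, train_cfg = train_config(),
                  checkpoint_dir = NULL, checkpoint_every = 0L,
                  verbose = FALSE) {
  D <- obs_dim(arena)
  if (is.null(policy_cfg)) {
    gdim <- if (train_cfg$centralized_critic) D * arena$n_agents else 0L
    policy_cfg <- policy_config(D, rnn_width = 64L, global_input_dim = gdim)
  }
  if (train_cfg$centralized_critic && policy_cfg$global_input_dim == 0L)
    stop("train(): centralized_critic requires policy_cfg with ",
         "global_input_dim = obs_dim * n_agents", call. = FALSE)
  if (policy_cfg$obs_dim != D)
    stop("train(): policy obs_dim ", policy_cfg$obs_dim,
         " does not match arena observation dimension ", D, call. = FALSE)

  policy <- init_policy(policy_cfg, seed = derive_seed(train_cfg$seed, "init"))
  envs <- lapply(seq_len(train_cfg$n_envs), function(i)
    .env_new(arena, derive_seed(train_cfg$seed, paste0("env", i))))
  hidden <- init_hidden(policy, train_cfg$n_envs * arena$n_agents)
  act_stream <- rng_stream(train_cfg$seed, "actions")
  shuffle_stream <- rng_stream(train_cfg$seed, "ppo_shuffle")
  opt_state <- NULL

  steps_per_iter <- train_cfg$rollout_T * train_cfg$n_envs
  n_iter <- max(0L, as.integer(ceiling(train_cfg$total_steps / steps_per_iter)))
  log_rows <- vector("list", n_iter)

  for (it in seq_len(n_iter)) {
    col <- collect_rollouts(envs, policy, hidden, train_cfg, act_stream)
    envs <- col$envs; hidden <- col$hidden
    upd <- ppo_update(policy, col$batch, train_cfg, opt_state, shuffle_stream)
    policy <- upd$policy; opt_state <- upd$opt_state

    eps <- col$episodes
    log_rows[[it]] <- tibble::tibble(
      iteration = it, env_steps = it * steps_per_iter,
      episodes_done = nrow(eps),
      mean_reward = if (nrow(eps)) mean(eps$mean_reward) else NA_real_,
      mean_food = if (nrow(eps)) mean(eps$mean_food) else NA_real_,
      mean_eod_rate = mean(col$batch$eod),
      loss = upd$stats$loss, pg_loss = upd$stats$pg_loss,
      v_loss = upd$stats$v_loss, entropy = upd$stats$entropy,
      initial_ratio_dev = upd$stats$initial_ratio_dev)
    if (verbose)
      message(sprintf("iter %d  steps %d  food %.2f  eod %.3f  loss %.4f",
                      it, it * steps_per_iter,
                      log_rows[[it]]$mean_food, log_rows[[it]]$mean_eod_rate,
                      upd$stats$loss))
    if (checkpoint_every > 0L && !is.null(checkpoint_dir) &&
        it %% checkpoint_every == 0L) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_policy(policy, file.path(checkpoint_dir,
                                    sprintf("checkpoint_%06d.rds", it)))
    }
  }
  structure(list(policy = policy,
                 log = if (n_iter) dplyr::bind_rows(log_rows) else tibble::tibble(),
                 arena = arena, train_cfg = train_cfg),
            class = "efish_training")
}

#' @export
print.efish_training <- function(x, ...) {
  cat(sprintf("<efish_training> %d iterations, %s env steps\n",
              nrow(x$log),
              format(x$train_cfg$total_steps, big.mark = ",")))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final: mean food %.2f, mean EOD rate %.3f\n",
                last$mean_food, last$mean_eod_rate))
  }
  invisible(x)
}

#' Evaluate a policy (or controller) over seeded episodes
#'
#' @param policy A `policy_state`, [scripted_controller()], or `"random"`.
#' @param config An [arena_config()].
#' @param n_episodes Number of evaluation episodes.
#' @param seed Root seed; episode `k` uses a sub-seed derived from it.
#' @param deterministic Act by the distribution mean/mode.
#' @param n_steps Episode length (default `config$max_steps`).
#' @return Tibble with one row per (episode, agent): `food_eaten`,
#'   `reward`, `eod_rate`.
#' @export
evaluate_policy <- function(policy, config, n_episodes = 20, seed = 0L,
                            deterministic = FALSE,
                            n_steps = config$max_steps) {
  rows <- lapply(seq_len(n_episodes), function(k) {
    tr <- run_episode(config, policy,
                      seed = derive_seed(seed, paste0("eval_ep", k)),
                      n_steps = n_steps, record_obs = FALSE,
                      deterministic = deterministic)
    fin <- dplyr::filter(tr$states, .data$step == max(.data$step))
    tibble::tibble(episode = k, agent_id = fin$agent_id,
                   food_eaten = fin$food_eaten,
                   reward = vapply(split(tr$states$reward, tr$states$agent_id),
                                   sum, numeric(1)),
                   eod_rate = vapply(split(tr$actions$eod, tr$actions$agent_id),
                                     mean, numeric(1)))
  })
  dplyr::bind_rows(rows)
}
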