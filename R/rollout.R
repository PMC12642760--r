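# Episode runners.
#
# A "controller" maps observations to actions for all agents.  Three kinds
# are supported: a trained `policy_state`, a `scripted_controller` (one
# function per agent; used by the two-fish assay and by tests), and the
# stock random controller.

#' Scripted controller
#'
#' @param fns List of per-agent functions `f(world, agent_id, obs, stream)`
#'   returning an action vector `c(thrust, turn, eod, bite)`.
#' @return A `scripted_controller`.
#' @export
scripted_controller <- function(fns) {
  stopifnot(is.list(fns), all(vapply(fns, is.function, logical(1))))
  structure(list(fns = fns), class = "scripted_controller")
}

#' Stock random controller
#'
#' Uniform thrust and turn, Bernoulli EOD at rate `p_eod`, Bernoulli bite at
#' `p_bite`; used as a behaviour-free reference.
#'
#' @param p_eod,p_bite Per-step discharge / bite probabilities.
#' @return A `scripted_controller` factory applied to every agent.
#' @export
random_controller <- function(p_eod = 0.1, p_bite = 0) {
  f <- function(world, agent_id, obs, stream) {
    with_stream(stream, c(stats::runif(1), stats::runif(1, -1, 1),
                          as.numeric(stats::runif(1) < p_eod),
                          as.numeric(stats::runif(1) < p_bite)))
  }
  structure(list(fns = NULL, fn = f), class = "scripted_controller")
}

.controller_fn <- function(ctrl, agent_id) {
  if (!is.null(ctrl$fns)) ctrl$fns[[agent_id]] else ctrl$fn
}

.global_obs <- function(obs) {
  # concatenated observations of all agents in the env, one copy per agent
  flat <- as.vector(t(obs))
  matrix(rep(flat, nrow(obs)), nrow = nrow(obs), byrow = TRUE)
}

#' Run one episode and record it as an `episode_trace`
#'
#' Runs `n_steps` of the world under a controller and records per-step
#' agent states, actions, rewards, food-patch summaries, and (optionally)
#' observation vectors.  Fully deterministic given (config, seed,
#' controller parameters).
#'
#' @param config An [arena_config()].
#' @param controller A `policy_state`, a [scripted_controller()], or
#'   `"random"`.
#' @param seed Episode seed.
#' @param n_steps Steps to run (default `config$max_steps`).
#' @param record_obs Record observation vectors in the trace.
#' @param deterministic For policy controllers: act by the distribution
#'   mean/mode instead of sampling.
#' @param dominance Optional per-agent dominance vector (see
#'   [world_reset()]).
#' @return An `episode_trace` (see [episode_trace()]).
#' @export
run_episode <- function(config, controller = "random", seed = config$seed,
                        n_steps = config$max_steps, record_obs = TRUE,
                        deterministic = FALSE, dominance = NULL) {
  if (identical(controller, "random")) controller <- random_controller()
  is_policy <- inherits(controller, "policy_state")
  n_steps <- min(n_steps, config$max_steps)
  world <- world_reset(config, seed, dominance = dominance)
  n <- config$n_agents
  act_stream <- rng_stream(seed, "actions")
  obs_stream <- rng_stream(seed, "sensor_noise")
  hidden <- if (is_policy) init_hidden(controller, n)

  D <- obs_dim(config)
  nrec <- n_steps * n
  states <- matrix(NA_real_, nrec, 11)
  colnames(states) <- c("step", "agent_id", "x", "y", "heading", "speed",
                        "dominance", "eod", "bite", "food_eaten", "reward")
  acts_rec <- matrix(NA_real_, nrec, 7)
  colnames(acts_rec) <- c("step", "agent_id", "thrust", "turn", "eod",
                          "bite", "log_prob")
  obs_rec <- if (record_obs) matrix(NA_real_, nrec, D)
  np <- max(nrow(world$food$centers), 1L)
  food_rec <- matrix(NA_real_, n_steps * np, 3)
  colnames(food_rec) <- c("step", "patch", "items_remaining")

  for (t in seq_len(n_steps)) {
    obs <- observe_all(world, obs_stream)
    if (is_policy) {
      gobs <- if (controller$config$global_input_dim > 0L) .global_obs(obs)
      f <- policy_forward(controller, obs, hidden, gobs)
      hidden <- f$hidden
      sa <- sample_actions_matrix(f$out, act_stream, deterministic)
      actions <- sa$actions
      logp <- sa$log_prob
    } else {
      actions <- t(vapply(seq_len(n), function(i)
        .controller_fn(controller, i)(world, i, obs[i, ], act_stream),
        numeric(4)))
      logp <- rep(NA_real_, n)
    }
    res <- world_step(world, actions)
    world <- res$world
    rows <- (t - 1L) * n + seq_len(n)
    ag <- world$agents
    states[rows, ] <- cbind(t, seq_len(n), ag[, "x"], ag[, "y"],
                            ag[, "heading"], ag[, "speed"], ag[, "dominance"],
                            ag[, "eod"], ag[, "bite"], ag[, "food_eaten"],
                            res$rewards)
    acts_rec[rows, ] <- cbind(t, seq_len(n), actions, logp)
    if (record_obs) obs_rec[rows, ] <- obs
    npz <- nrow(world$food$centers)
    if (npz > 0L) {
      frows <- (t - 1L) * np + seq_len(npz)
      food_rec[frows, ] <- cbind(t, seq_len(npz),
                                 tabulate(world$food$items[, "patch"], npz))
    }
    if (res$done) break
  }
  episode_trace(config = config, seed = seed,
                states = tibble::as_tibble(states),
                actions = tibble::as_tibble(acts_rec),
                food = tibble::as_tibble(food_rec[!is.na(food_rec[, 1]), ,
                                                  drop = FALSE]),
                observations = obs_rec,
                n_steps = as.integer(max(states[, "step"], na.rm = TRUE)))
}

# --- training rollout collection -------------------------------------------

.env_new <- function(config, base_seed) {
  list(world = world_reset(config, derive_seed(base_seed, "ep1")),
       base_seed = base_seed, ep = 1L,
       ep_reward = numeric(config$n_agents),
       ep_food = numeric(config$n_agents), ep_len = 0L)
}

#' Collect a rollout batch from parallel environments
#'
#' Steps `n_envs` environments for `rollout_T` steps under the shared
#' policy, recording everything a PPO update needs: observations, actions,
#' log-probabilities, rewards, values, done flags, and per-step hidden
#' states (segment-initial states are read from these at update time).
#' Episodes that end mid-rollout are reset with a fresh deterministic seed
#' and the corresponding hidden rows zeroed.
#'
#' @param envs List of environment containers (internal; from [train()]).
#' @param policy A `policy_state`.
#' @param hidden `B x rnn_width` hidden matrix (`B = n_envs * n_agents`).
#' @param tcfg A [train_config()].
#' @param act_stream [rng_stream()] for action sampling.
#' @return List with the batch, updated `envs`, `hidden`, and a tibble of
#'   episodes completed during collection.
#' @export
collect_rollouts <- function(envs, policy, hidden, tcfg, act_stream) {
  n_envs <- length(envs)
  na <- envs[[1]]$world$config$n_agents
  B <- n_envs * na
  T_ <- tcfg$rollout_T
  centralized <- policy$config$global_input_dim > 0L

  obs_l <- vector("list", T_); gobs_l <- if (centralized) vector("list", T_)
  act_l <- vector("list", T_); h_pre <- vector("list", T_)
  logp <- rew <- val <- don <- eodm <- matrix(0, T_, B)
  done_eps <- list()

  for (t in seq_len(T_)) {
    obs <- matrix(0, B, policy$config$obs_dim)
    for (e in seq_len(n_envs))
      obs[(e - 1L) * na + seq_len(na), ] <- observe_all(envs[[e]]$world)
    gobs <- if (centralized) {
      g <- matrix(0, B, policy$config$global_input_dim)
      for (e in seq_len(n_envs)) {
        rows <- (e - 1L) * na + seq_len(na)
        g[rows, ] <- .global_obs(obs[rows, , drop = FALSE])
      }
      g
    }
    h_pre[[t]] <- hidden
    f <- policy_forward(policy, obs, hidden, gobs)
    hidden <- f$hidden
    sa <- sample_actions_matrix(f$out, act_stream)
    obs_l[[t]] <- obs; act_l[[t]] <- sa$actions
    if (centralized) gobs_l[[t]] <- gobs
    logp[t, ] <- sa$log_prob; val[t, ] <- f$value
    eodm[t, ] <- sa$actions[, 3]

    for (e in seq_len(n_envs)) {
      rows <- (e - 1L) * na + seq_len(na)
      res <- world_step(envs[[e]]$world, sa$actions[rows, , drop = FALSE])
      envs[[e]]$world <- res$world
      rew[t, rows] <- res$rewards
      envs[[e]]$ep_reward <- envs[[e]]$ep_reward + res$rewards
      envs[[e]]$ep_len <- envs[[e]]$ep_len + 1L
      if (res$done) {
        don[t, rows] <- 1
        envs[[e]]$ep_food <- res$world$agents[, "food_eaten"]
        done_eps[[length(done_eps) + 1L]] <- tibble::tibble(
          env = e, episode = envs[[e]]$ep,
          mean_reward = mean(envs[[e]]$ep_reward),
          mean_food = mean(envs[[e]]$ep_food),
          length = envs[[e]]$ep_len)
        envs[[e]]$ep <- envs[[e]]$ep + 1L
        envs[[e]]$world <- world_reset(
          envs[[e]]$world$config,
          derive_seed(envs[[e]]$base_seed, paste0("ep", envs[[e]]$ep)))
        envs[[e]]$ep_reward <- numeric(na)
        envs[[e]]$ep_food <- numeric(na)
        envs[[e]]$ep_len <- 0L
        hidden[rows, ] <- 0
      }
    }
  }
  # bootstrap value for the state after the last step
  obs <- matrix(0, B, policy$config$obs_dim)
  for (e in seq_len(n_envs))
    obs[(e - 1L) * na + seq_len(na), ] <- observe_all(envs[[e]]$world)
  gobs <- if (centralized) {
    g <- matrix(0, B, policy$config$global_input_dim)
    for (e in seq_len(n_envs)) {
      rows <- (e - 1L) * na + seq_len(na)
      g[rows, ] <- .global_obs(obs[rows, , drop = FALSE])
    }
    g
  }
  fb <- policy_forward(policy, obs, hidden, gobs)

  batch <- list(obs = obs_l, gobs = gobs_l, actions = act_l, h_pre = h_pre,
                log_prob = logp, rewards = rew, values = val, dones = don,
                bootstrap_value = fb$value, eod = eodm, T = T_, B = B,
                n_envs = n_envs, n_agents = na)
  list(batch = batch, envs = envs, hidden = hidden,
       episodes = if (length(done_eps)) dplyr::bind_rows(done_eps)
                  else tibble::tibble())
}
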