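# Recurrent actor-critic policy.
#
# Architecture: a plain tanh recurrent core followed by parallel actor and
# critic two-layer feedforward heads (hidden tanh layer + linear output).
# All agents share one parameter collection; each agent owns a private
# recurrent state vector.  Continuous actions (thrust, turn) use Beta
# distributions on their bounded supports; EOD and bite are Bernoulli.
#
# The actor output row has 6 columns:
#   1 thrust_u, 2 thrust_v   (Beta params via alpha = 1 + softplus(u), ...)
#   3 turn_u,   4 turn_v
#   5 eod_logit, 6 bite_logit

.PARAM_NAMES <- c("Wx", "Wh", "bh", "Wa1", "ba1", "Wa2", "ba2",
                  "Wc1", "bc1", "Wc2", "bc2")

#' Policy configuration
#'
#' @param obs_dim Observation dimension (see [obs_dim()]).
#' @param rnn_width Recurrent state width (512 for full runs; small widths
#'   for fast experiments and tests).
#' @param head_width Width of the actor/critic hidden layers.
#' @param global_input_dim If positive, the critic hidden layer additionally
#'   receives a global-state vector of this dimension (the concatenated
#'   observations of all agents in the environment; MAPPO-style centralized
#'   critic).  Zero (default) gives a fully decentralized critic.
#' @return A list of class `policy_config`.
#' @export
policy_config <- function(obs_dim, rnn_width = 512L, head_width = rnn_width,
                          global_input_dim = 0L) {
  stopifnot(obs_dim >= 1, rnn_width >= 1, head_width >= 1,
            global_input_dim >= 0)
  structure(list(obs_dim = as.integer(obs_dim),
                 rnn_width = as.integer(rnn_width),
                 head_width = as.integer(head_width),
                 global_input_dim = as.integer(global_input_dim),
                 head_depth = 2L, nonlinearity = "tanh",
                 n_actor_out = 6L),
            class = "policy_config")
}

.orthogonal_init <- function(nr, nc, gain = 1) {
  a <- matrix(stats::rnorm(max(nr, nc)^2), max(nr, nc))
  q <- qr.Q(qr(a))[seq_len(nr), seq_len(nc), drop = FALSE]
  gain * q
}

.glorot_init <- function(nr, nc, gain = 1) {
  lim <- gain * sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a policy
#'
#' Orthogonal initialization for the recurrent matrix, scaled-uniform
#' (Glorot) for feedforward layers, small-scale output layers so the
#' initial policy is near-uniform (EOD probability starts near 0.5); hidden
#' state starts at zero.
#'
#' @param config A [policy_config()].
#' @param seed Integer seed.
#' @return A list of class `policy_state` with elements `params`, `config`,
#'   and `fingerprint`.
#' @export
init_policy <- function(config, seed = 0L) {
  stopifnot(inherits(config, "policy_config"))
  s <- rng_stream(seed, "policy_init")
  D <- config$obs_dim; W <- config$rnn_width; H <- config$head_width
  params <- with_stream(s, {
    pr <- list(
      Wx = .glorot_init(W, D), Wh = .orthogonal_init(W, W), bh = numeric(W),
      Wa1 = .glorot_init(H, W), ba1 = numeric(H),
      Wa2 = 0.01 * .glorot_init(6L, H), ba2 = numeric(6L),
      Wc1 = .glorot_init(H, W), bc1 = numeric(H),
      Wc2 = 0.01 * .glorot_init(1L, H), bc2 = numeric(1L)
    )
    if (config$global_input_dim > 0L)
      pr$Wc1o <- .glorot_init(H, config$global_input_dim)
    pr
  })
  structure(list(params = params, config = config,
                 fingerprint = rlang::hash(unclass(config))),
            class = "policy_state")
}

#' Fresh (zero) hidden states for a set of agents
#'
#' @param policy A `policy_state`.
#' @param n Number of agents.
#' @return Numeric matrix `n x rnn_width`.
#' @export
init_hidden <- function(policy, n) matrix(0, n, policy$config$rnn_width)

# Batched forward pass: obs (B x D), hidden (B x W) -> list(out B x 6,
# value B, hidden B x W).  Pure function of (params, hidden, obs).
policy_forward <- function(policy, obs, hidden, global_obs = NULL) {
  p <- policy$params
  obs <- matrix(obs, ncol = policy$config$obs_dim)
  h <- tanh(obs %*% t(p$Wx) + hidden %*% t(p$Wh) +
              rep(p$bh, each = nrow(obs)))
  a1 <- tanh(h %*% t(p$Wa1) + rep(p$ba1, each = nrow(h)))
  out <- a1 %*% t(p$Wa2) + rep(p$ba2, each = nrow(h))
  c1_pre <- h %*% t(p$Wc1) + rep(p$bc1, each = nrow(h))
  if (policy$config$global_input_dim > 0L) {
    if (is.null(global_obs))
      stop("policy_forward(): centralized critic needs global_obs", call. = FALSE)
    c1_pre <- c1_pre + global_obs %*% t(p$Wc1o)
  }
  c1 <- tanh(c1_pre)
  v <- drop(c1 %*% t(p$Wc2)) + p$bc2
  list(out = out, value = as.numeric(v), hidden = h)
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.out_to_dist <- function(out_row) {
  structure(list(
    thrust = c(alpha = 1 + softplus(out_row[1]), beta = 1 + softplus(out_row[2])),
    turn = c(alpha = 1 + softplus(out_row[3]), beta = 1 + softplus(out_row[4])),
    eod = stats::plogis(out_row[5]),
    bite = stats::plogis(out_row[6])
  ), class = "action_distribution")
}

#' One policy step for a single agent
#'
#' Updates the recurrent state once from the observation and maps it through
#' the actor head (action distribution) and critic head (state value).
#' Deterministic given (parameters, hidden, obs); no side effects.
#'
#' @param policy A `policy_state`.
#' @param hidden Numeric vector of length `rnn_width` (the agent's private
#'   recurrent state).
#' @param obs Observation vector of length `obs_dim`.
#' @return List with `dist` (class `action_distribution`: Beta parameters
#'   for thrust and turn, Bernoulli probabilities for eod and bite),
#'   `value`, and the new `hidden` vector.
#' @export
policy_step <- function(policy, hidden, obs) {
  if (length(obs) != policy$config$obs_dim)
    stop("policy_step(): obs length ", length(obs), " != obs_dim ",
         policy$config$obs_dim, call. = FALSE)
  f <- policy_forward(policy, matrix(obs, 1), matrix(hidden, 1))
  list(dist = .out_to_dist(f$out[1, ]), value = f$value[1],
       hidden = f$hidden[1, ])
}

# Batched sampling from actor outputs.  Returns actions (B x 4) in the
# action parameterization (thrust in [0,1], turn in [-1,1], eod/bite binary)
# and the joint log-probability per row.
sample_actions_matrix <- function(out, stream, deterministic = FALSE) {
  B <- nrow(out)
  a_t <- 1 + softplus(out[, 1]); b_t <- 1 + softplus(out[, 2])
  a_r <- 1 + softplus(out[, 3]); b_r <- 1 + softplus(out[, 4])
  p_e <- stats::plogis(out[, 5]); p_b <- stats::plogis(out[, 6])
  if (deterministic) {
    xt <- a_t / (a_t + b_t); xr <- a_r / (a_r + b_r)
    eod <- as.numeric(p_e > 0.5); bite <- as.numeric(p_b > 0.5)
  } else {
    draws <- with_stream(stream, {
      list(xt = stats::rbeta(B, a_t, b_t), xr = stats::rbeta(B, a_r, b_r),
           eod = as.numeric(stats::runif(B) < p_e),
           bite = as.numeric(stats::runif(B) < p_b))
    })
    xt <- draws$xt; xr <- draws$xr; eod <- draws$eod; bite <- draws$bite
  }
  eps <- 1e-6
  xt <- pmin(pmax(xt, eps), 1 - eps)
  xr <- pmin(pmax(xr, eps), 1 - eps)
  actions <- cbind(thrust = xt, turn = 2 * xr - 1, eod = eod, bite = bite)
  logp <- action_log_prob_matrix(out, actions)
  list(actions = actions, log_prob = logp)
}

# Joint log-probability of actions (B x 4) under actor outputs (B x 6).
action_log_prob_matrix <- function(out, actions) {
  a_t <- 1 + softplus(out[, 1]); b_t <- 1 + softplus(out[, 2])
  a_r <- 1 + softplus(out[, 3]); b_r <- 1 + softplus(out[, 4])
  xt <- pmin(pmax(actions[, 1], 1e-6), 1 - 1e-6)
  xr <- pmin(pmax((actions[, 2] + 1) / 2, 1e-6), 1 - 1e-6)
  lp <- stats::dbeta(xt, a_t, b_t, log = TRUE) +
    stats::dbeta(xr, a_r, b_r, log = TRUE) - log(2) +
    actions[, 3] * out[, 5] - softplus(out[, 5]) +
    actions[, 4] * out[, 6] - softplus(out[, 6])
  as.numeric(lp)
}

#' Sample an action from an action distribution
#'
#' @param dist An `action_distribution` from [policy_step()].
#' @param stream An [rng_stream()].
#' @param deterministic If `TRUE`, return the distribution mean/mode
#'   (Beta mean; Bernoulli thresholded at 0.5) for evaluation.
#' @return List with `action` (named: thrust, turn, eod, bite) and
#'   `log_prob` (joint log-probability; for the deterministic mode the
#'   log-probability of the returned action).
#' @export
sample_action <- function(dist, stream = NULL, deterministic = FALSE) {
  stopifnot(inherits(dist, "action_distribution"))
  if (deterministic) {
    xt <- dist$thrust[["alpha"]] / sum(dist$thrust)
    xr <- dist$turn[["alpha"]] / sum(dist$turn)
    eod <- as.numeric(dist$eod > 0.5); bite <- as.numeric(dist$bite > 0.5)
  } else {
    d <- with_stream(stream, list(
      xt = stats::rbeta(1, dist$thrust[["alpha"]], dist$thrust[["beta"]]),
      xr = stats::rbeta(1, dist$turn[["alpha"]], dist$turn[["beta"]]),
      eod = as.numeric(stats::runif(1) < dist$eod),
      bite = as.numeric(stats::runif(1) < dist$bite)))
    xt <- d$xt; xr <- d$xr; eod <- d$eod; bite <- d$bite
  }
  eps <- 1e-6
  xt <- min(max(xt, eps), 1 - eps); xr <- min(max(xr, eps), 1 - eps)
  action <- c(thrust = xt, turn = 2 * xr - 1, eod = eod, bite = bite)
  lp <- stats::dbeta(xt, dist$thrust[["alpha"]], dist$thrust[["beta"]], log = TRUE) +
    stats::dbeta(xr, dist$turn[["alpha"]], dist$turn[["beta"]], log = TRUE) - log(2) +
    stats::dbinom(eod, 1, dist$eod, log = TRUE) +
    stats::dbinom(bite, 1, dist$bite, log = TRUE)
  list(action = action, log_prob = as.numeric(lp))
}

#' Save / load a policy checkpoint
#'
#' The checkpoint embeds a fingerprint of the policy configuration;
#' [load_policy()] refuses to load a checkpoint whose fingerprint does not
#' match `expect_config` when one is supplied.
#'
#' @param policy A `policy_state`.
#' @param path File path.
#' @export
save_policy <- function(policy, path) {
  stopifnot(inherits(policy, "policy_state"))
  saveRDS(policy, path)
  invisible(path)
}

#' @rdname save_policy
#' @param expect_config Optional [policy_config()] that the checkpoint must
#'   match.
#' @export
load_policy <- function(path, expect_config = NULL) {
  p <- readRDS(path)
  if (!inherits(p, "policy_state"))
    stop("load_policy(): not a policy checkpoint", call. = FALSE)
  if (!is.null(expect_config) &&
      !identical(p$fingerprint, rlang::hash(unclass(expect_config))))
    stop("load_policy(): checkpoint was trained under a different policy ",
         "configuration", call. = FALSE)
  p
}
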