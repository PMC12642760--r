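# PPO machinery: generalized advantage estimation, the clipped-surrogate
# loss with analytic gradients (backprop through the recurrent core within
# stored segments), and Adam.
#
# Gradients are derived by hand and verified against finite differences in
# the test suite.  Per actor-output column (see policy.R for the layout):
#   Beta heads:  alpha = 1 + softplus(u);  dlogp/dalpha = log x - psi(alpha)
#                + psi(alpha+beta), chained through sigmoid(u).
#   Bernoulli heads (logit z): dlogp/dz = a - sigmoid(z).

#' Generalized advantage estimation
#'
#' Computes TD residuals `delta_t = r_t + gamma * V_{t+1} * (1 - done_t) -
#' V_t` and advantages `A_t = delta_t + gamma * lambda * (1 - done_t) *
#' A_{t+1}`; returns are `A + V`.
#'
#' @param rewards Numeric vector of length `T`.
#' @param values Numeric vector of length `T + 1` (bootstrap value
#'   appended).
#' @param dones Binary vector of length `T` (1 where the episode ended at
#'   step `t`).
#' @param gamma Discount factor in `(0, 1]`.
#' @param lambda GAE mixing parameter in `[0, 1]`.
#' @return List with `advantages` and `returns`, each of length `T`.
#' @export
#' @examples
#' gae(c(1, 0, 1), c(0.5, 0.4, 0.3, 0.2), c(0, 0, 0), 0.99, 0.95)
gae <- function(rewards, values, dones, gamma, lambda) {
  T_ <- length(rewards)
  if (length(values) != T_ + 1L || length(dones) != T_)
    stop("gae(): rewards/dones must have length T and values length T + 1",
         call. = FALSE)
  adv <- numeric(T_)
  acc <- 0
  for (t in T_:1) {
    nd <- 1 - dones[t]
    delta <- rewards[t] + gamma * values[t + 1L] * nd - values[t]
    acc <- delta + gamma * lambda * nd * acc
    adv[t] <- acc
  }
  list(advantages = adv, returns = adv + values[seq_len(T_)])
}

# Columnwise GAE over T x B matrices; values is (T+1) x B.
.gae_matrix <- function(rewards, values, dones, gamma, lambda) {
  T_ <- nrow(rewards); B <- ncol(rewards)
  adv <- matrix(0, T_, B)
  acc <- numeric(B)
  for (t in T_:1) {
    nd <- 1 - dones[t, ]
    delta <- rewards[t, ] + gamma * values[t + 1L, ] * nd - values[t, ]
    acc <- delta + gamma * lambda * nd * acc
    adv[t, ] <- acc
  }
  list(advantages = adv, returns = adv + values[seq_len(T_), , drop = FALSE])
}

#' Training configuration for multi-agent PPO
#'
#' @param total_steps Total environment steps (summed over parallel envs;
#'   each multi-agent step counts once per env).
#' @param gamma,gae_lambda Discount and GAE parameters.
#' @param clip_eps PPO clipping radius.
#' @param epochs_per_batch Optimization epochs per collected batch.
#' @param n_minibatches Minibatches (of recurrent segments) per epoch.
#' @param lr Adam learning rate.
#' @param entropy_coef,value_coef Loss coefficients.
#' @param rollout_T Rollout length per environment.
#' @param n_envs Parallel environments.
#' @param seg_len Recurrent segment length for BPTT (must divide
#'   `rollout_T`); segment-initial hidden states are stored during
#'   collection and replayed exactly (burn-in 0).
#' @param max_grad_norm Global gradient-norm clip.
#' @param centralized_critic If `TRUE`, the critic additionally receives the
#'   concatenated observations of all agents in the environment (MAPPO-style
#'   global state); the actor remains decentralized.
#' @param seed Root seed for all training randomness.
#' @return A list of class `train_config`.
#' @export
train_config <- function(total_steps = 2e5, gamma = 0.99, gae_lambda = 0.95,
                         clip_eps = 0.2, epochs_per_batch = 4L,
                         n_minibatches = 2L, lr = 3e-4, entropy_coef = 0.01,
                         value_coef = 0.5, rollout_T = 128L, n_envs = 8L,
                         seg_len = 32L, max_grad_norm = 0.5,
                         centralized_critic = FALSE, seed = 0L) {
  stopifnot(gamma > 0, gamma <= 1, gae_lambda >= 0, gae_lambda <= 1,
            clip_eps > 0, rollout_T >= 2, rollout_T %% seg_len == 0)
  structure(as.list(environment()), class = "train_config")
}

.zero_like <- function(params) lapply(params, function(p) p * 0)

.adam_init <- function(params) {
  list(m = .zero_like(params), v = .zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

.clip_grads <- function(grads, max_norm) {
  gn <- .grad_global_norm(grads)
  if (is.finite(gn) && gn > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

# Loss and analytic gradients for one minibatch of recurrent segments.
#
# mb fields (L = segment length, S = number of segments in the minibatch):
#   obs      : list of L matrices (S x D)
#   gobs     : list of L matrices (S x G) or NULL   (centralized critic)
#   h0       : S x W hidden states at segment starts
#   done     : L x S (hidden is zeroed after a done, as during collection)
#   actions  : list of L matrices (S x 4)
#   old_logp, adv, ret : L x S
#
# Returns loss, gradients, and per-sample diagnostics (ratios, clip mask).
.ppo_loss_grad <- function(policy, mb, clip_eps, value_coef, entropy_coef) {
  p <- policy$params
  L <- length(mb$obs); S <- nrow(mb$h0)
  W <- policy$config$rnn_width
  centralized <- !is.null(mb$gobs)

  # ---- forward: recurrent core over the segment ----
  # hin[[t]] is the hidden state fed into step t (zeroed after a done, as
  # during collection); hout[[t]] is the state the heads read at step t.
  hin <- vector("list", L); hout <- vector("list", L)
  hcur <- mb$h0
  for (t in seq_len(L)) {
    hin[[t]] <- hcur
    hout[[t]] <- tanh(mb$obs[[t]] %*% t(p$Wx) + hcur %*% t(p$Wh) +
                        rep(p$bh, each = S))
    hcur <- hout[[t]] * (1 - mb$done[t, ])
  }

  Hall <- do.call(rbind, hout)                      # (L*S) x W, t-major
  N <- L * S
  A1 <- tanh(Hall %*% t(p$Wa1) + rep(p$ba1, each = N))
  Out <- A1 %*% t(p$Wa2) + rep(p$ba2, each = N)
  if (centralized) {
    Gall <- do.call(rbind, mb$gobs)
    C1 <- tanh(Hall %*% t(p$Wc1) + Gall %*% t(p$Wc1o) + rep(p$bc1, each = N))
  } else {
    C1 <- tanh(Hall %*% t(p$Wc1) + rep(p$bc1, each = N))
  }
  V <- drop(C1 %*% t(p$Wc2)) + p$bc2

  Acts <- do.call(rbind, mb$actions)                # (L*S) x 4
  old_lp <- as.vector(t(mb$old_logp))
  adv <- as.vector(t(mb$adv))
  ret <- as.vector(t(mb$ret))

  # ---- distribution quantities ----
  sig <- function(z) stats::plogis(z)
  u_t <- Out[, 1]; v_t <- Out[, 2]; u_r <- Out[, 3]; v_r <- Out[, 4]
  z_e <- Out[, 5]; z_b <- Out[, 6]
  a_t <- 1 + softplus(u_t); b_t <- 1 + softplus(v_t)
  a_r <- 1 + softplus(u_r); b_r <- 1 + softplus(v_r)
  xt <- pmin(pmax(Acts[, 1], 1e-6), 1 - 1e-6)
  xr <- pmin(pmax((Acts[, 2] + 1) / 2, 1e-6), 1 - 1e-6)
  a_e <- Acts[, 3]; a_b <- Acts[, 4]

  lp <- stats::dbeta(xt, a_t, b_t, log = TRUE) +
    stats::dbeta(xr, a_r, b_r, log = TRUE) - log(2) +
    a_e * z_e - softplus(z_e) + a_b * z_b - softplus(z_b)

  ratio <- exp(lp - old_lp)
  unclipped <- ratio * adv
  clipped <- pmin(pmax(ratio, 1 - clip_eps), 1 + clip_eps) * adv
  use_unclipped <- as.numeric(unclipped <= clipped)
  pg_loss <- -mean(pmin(unclipped, clipped))
  v_loss <- 0.5 * mean((V - ret)^2)

  beta_entropy <- function(a, b) {
    lbeta(a, b) - (a - 1) * digamma(a) - (b - 1) * digamma(b) +
      (a + b - 2) * digamma(a + b)
  }
  bern_entropy <- function(z) softplus(z) - z * sig(z)
  ent <- beta_entropy(a_t, b_t) + (beta_entropy(a_r, b_r) + log(2)) +
    bern_entropy(z_e) + bern_entropy(z_b)
  entropy <- mean(ent)

  loss <- pg_loss + value_coef * v_loss - entropy_coef * entropy
  if (!is.finite(loss))
    stop("ppo: non-finite loss (pg=", pg_loss, ", v=", v_loss,
         ", H=", entropy, "); aborting update", call. = FALSE)

  # ---- backward ----
  dlp <- -(use_unclipped * ratio * adv) / N         # d pg_loss / d lp
  dV <- value_coef * (V - ret) / N
  dent <- -entropy_coef / N                         # d loss / d ent_row

  dBetaH_da <- function(a, b) -(a - 1) * trigamma(a) + (a + b - 2) * trigamma(a + b)
  dOut <- matrix(0, N, 6L)
  # thrust Beta
  dlp_da <- log(xt) - digamma(a_t) + digamma(a_t + b_t)
  dlp_db <- log(1 - xt) - digamma(b_t) + digamma(a_t + b_t)
  dOut[, 1] <- (dlp * dlp_da + dent * dBetaH_da(a_t, b_t)) * sig(u_t)
  dOut[, 2] <- (dlp * dlp_db + dent * dBetaH_da(b_t, a_t)) * sig(v_t)
  # turn Beta
  dlp_da <- log(xr) - digamma(a_r) + digamma(a_r + b_r)
  dlp_db <- log(1 - xr) - digamma(b_r) + digamma(a_r + b_r)
  dOut[, 3] <- (dlp * dlp_da + dent * dBetaH_da(a_r, b_r)) * sig(u_r)
  dOut[, 4] <- (dlp * dlp_db + dent * dBetaH_da(b_r, a_r)) * sig(v_r)
  # Bernoulli heads: dH/dz = -z p (1 - p)
  dOut[, 5] <- dlp * (a_e - sig(z_e)) + dent * (-z_e * sig(z_e) * (1 - sig(z_e)))
  dOut[, 6] <- dlp * (a_b - sig(z_b)) + dent * (-z_b * sig(z_b) * (1 - sig(z_b)))

  g <- .zero_like(p)
  # actor head
  dA1 <- (dOut %*% p$Wa2) * (1 - A1^2)
  g$Wa2 <- t(dOut) %*% A1; g$ba2 <- colSums(dOut)
  g$Wa1 <- t(dA1) %*% Hall; g$ba1 <- colSums(dA1)
  dHall <- dA1 %*% p$Wa1
  # critic head
  dC1 <- (dV %o% drop(p$Wc2)) * (1 - C1^2)
  g$Wc2 <- matrix(colSums(dV * C1), 1); g$bc2 <- sum(dV)
  g$Wc1 <- t(dC1) %*% Hall; g$bc1 <- colSums(dC1)
  dHall <- dHall + dC1 %*% p$Wc1
  if (centralized) g$Wc1o <- t(dC1) %*% Gall

  # BPTT through the recurrent core
  dh_next <- matrix(0, S, W)                        # grad w.r.t. hout[[t]]
  for (t in L:1) {
    # dh_next arrives as grad w.r.t. hcur fed into t+1 = hout[[t]] * mask
    dh <- dHall[(t - 1L) * S + seq_len(S), , drop = FALSE] + dh_next
    dpre <- dh * (1 - hout[[t]]^2)
    g$Wx <- g$Wx + t(dpre) %*% mb$obs[[t]]
    g$Wh <- g$Wh + t(dpre) %*% hin[[t]]
    g$bh <- g$bh + colSums(dpre)
    if (t > 1L)
      dh_next <- (dpre %*% p$Wh) * (1 - mb$done[t - 1L, ])
  }

  list(loss = loss, pg_loss = pg_loss, v_loss = v_loss, entropy = entropy,
       grads = g, ratio = ratio, use_unclipped = use_unclipped,
       log_prob = lp, value = V)
}

# Slice a rollout batch into recurrent segments and build minibatch tensors.
# Returns a list of segment descriptors (b = env-agent column, t0 = start).
.make_segments <- function(batch, seg_len) {
  stopifnot(batch$T %% seg_len == 0L)
  n_seg_t <- batch$T %/% seg_len
  expand.grid(b = seq_len(batch$B), k = seq_len(n_seg_t))
}

.gather_minibatch <- function(batch, segs, adv, ret, seg_len) {
  S <- nrow(segs)
  L <- seg_len
  obs <- vector("list", L); gobs <- NULL
  acts <- vector("list", L)
  centralized <- !is.null(batch$gobs)
  if (centralized) gobs <- vector("list", L)
  done <- old_lp <- A <- R <- matrix(0, L, S)
  h0 <- matrix(0, S, ncol(batch$h_pre[[1]]))
  for (s in seq_len(S)) {
    t0 <- (segs$k[s] - 1L) * L
    h0[s, ] <- batch$h_pre[[t0 + 1L]][segs$b[s], ]
  }
  for (t in seq_len(L)) {
    obs_t <- matrix(0, S, ncol(batch$obs[[1]]))
    act_t <- matrix(0, S, 4L)
    if (centralized) gobs_t <- matrix(0, S, ncol(batch$gobs[[1]]))
    for (s in seq_len(S)) {
      tt <- (segs$k[s] - 1L) * L + t
      b <- segs$b[s]
      obs_t[s, ] <- batch$obs[[tt]][b, ]
      act_t[s, ] <- batch$actions[[tt]][b, ]
      if (centralized) gobs_t[s, ] <- batch$gobs[[tt]][b, ]
      done[t, s] <- batch$dones[tt, b]
      old_lp[t, s] <- batch$log_prob[tt, b]
      A[t, s] <- adv[tt, b]
      R[t, s] <- ret[tt, b]
    }
    obs[[t]] <- obs_t; acts[[t]] <- act_t
    if (centralized) gobs[[t]] <- gobs_t
  }
  list(obs = obs, gobs = gobs, h0 = h0, done = done, actions = acts,
       old_logp = old_lp, adv = A, ret = R)
}

#' One PPO update from a collected rollout batch
#'
#' Computes GAE advantages and returns, normalizes advantages over the
#' batch, then runs `epochs_per_batch` epochs of minibatched clipped-
#' surrogate updates with Adam.  Recurrent segments are replayed from their
#' stored segment-initial hidden states, so values and log-probabilities are
#' recomputed exactly.
#'
#' @param policy A `policy_state`.
#' @param batch A rollout batch from [collect_rollouts()].
#' @param config A [train_config()].
#' @param opt_state Optional Adam state carried across updates.
#' @param stream [rng_stream()] for minibatch shuffling.
#' @return List with updated `policy`, `opt_state`, and `stats` (loss
#'   components, entropy, and `initial_ratio_dev`: the maximum `|ratio - 1|`
#'   over the batch before any gradient step, which is 0 up to floating
#'   point when the batch was collected under the current parameters).
#' @export
ppo_update <- function(policy, batch, config, opt_state = NULL,
                       stream = rng_stream(config$seed, "ppo_shuffle")) {
  ga <- .gae_matrix(batch$rewards,
                    rbind(batch$values, batch$bootstrap_value),
                    batch$dones, config$gamma, config$gae_lambda)
  adv <- ga$advantages
  adv_n <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
  ret <- ga$returns

  segs_all <- .make_segments(batch, config$seg_len)
  if (is.null(opt_state)) opt_state <- .adam_init(policy$params)

  # diagnostic pass before any update: ratios must be 1 for on-policy data
  mb_all <- .gather_minibatch(batch, segs_all, adv_n, ret, config$seg_len)
  pre <- .ppo_loss_grad(policy, mb_all, config$clip_eps, config$value_coef,
                        config$entropy_coef)
  initial_ratio_dev <- max(abs(pre$ratio - 1))

  n_seg <- nrow(segs_all)
  mb_sizes <- rep(n_seg %/% config$n_minibatches, config$n_minibatches)
  mb_sizes[seq_len(n_seg %% config$n_minibatches)] <-
    mb_sizes[seq_len(n_seg %% config$n_minibatches)] + 1L
  stats_acc <- c(loss = 0, pg_loss = 0, v_loss = 0, entropy = 0)
  n_upd <- 0L
  for (ep in seq_len(config$epochs_per_batch)) {
    ord <- with_stream(stream, sample.int(n_seg))
    off <- 0L
    for (sz in mb_sizes) {
      if (sz == 0L) next
      idx <- ord[off + seq_len(sz)]; off <- off + sz
      mb <- .gather_minibatch(batch, segs_all[idx, , drop = FALSE],
                              adv_n, ret, config$seg_len)
      res <- .ppo_loss_grad(policy, mb, config$clip_eps, config$value_coef,
                            config$entropy_coef)
      grads <- .clip_grads(res$grads, config$max_grad_norm)
      st <- .adam_step(policy$params, grads, opt_state, config$lr)
      policy$params <- st$params; opt_state <- st$state
      stats_acc <- stats_acc + c(res$loss, res$pg_loss, res$v_loss, res$entropy)
      n_upd <- n_upd + 1L
    }
  }
  stats <- as.list(stats_acc / max(n_upd, 1L))
  stats$initial_ratio_dev <- initial_ratio_dev
  list(policy = policy, opt_state = opt_state, stats = stats)
}
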