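# Discrete-time 2D arena: agent kinematics, patchy replenishing food, bite
# resolution with dominance-asymmetric penalties, and the episode lifecycle.
#
# World state is a plain list (hot path: matrices, not data frames):
#   config  : arena_config
#   t       : completed steps
#   agents  : n x 10 matrix, columns .AGENT_COLS
#   food    : list(centers [n_patches x 2], items [m x 5: x,y,patch,mx,my],
#             spawned [per-patch spawn log incl. initial fill])
#   stream  : rng_stream driving all world randomness
#   done    : episode finished flag

.AGENT_COLS <- c("x", "y", "heading", "speed", "dominance", "eod", "bite",
                 "last_turn", "food_eaten", "cum_reward")

wrap_angle <- function(a) a %% (2 * pi)

.spawn_items <- function(n, center, radius, passive_amp, patch) {
  if (n <= 0L) return(NULL)
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  phi <- stats::runif(n, 0, 2 * pi)  # static prey-dipole orientation
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th),
        patch = rep(patch, n),
        mx = passive_amp * cos(phi), my = passive_amp * sin(phi))
}

.empty_items <- function() {
  matrix(numeric(0), ncol = 5,
         dimnames = list(NULL, c("x", "y", "patch", "mx", "my")))
}

#' Initialize a world state
#'
#' Places agents uniformly at random inside the arena (the two-fish preset
#' overrides placement: agent A inside the single patch, agent B within
#' communication radius of A), initializes every food patch at capacity,
#' and derives all world RNG streams deterministically from `seed`.
#'
#' @param config An [arena_config()].
#' @param seed Integer episode seed (defaults to `config$seed`).
#' @param dominance Optional numeric vector of per-agent dominance levels in
#'   `[0, 1]`; by default sampled uniformly at reset.
#' @return A world-state list.
#' @export
#' @examples
#' w <- world_reset(make_scenario("noncompetitive", n_agents = 2), seed = 1)
#' nrow(w$agents)
world_reset <- function(config, seed = config$seed, dominance = NULL) {
  validate_arena_config(config)
  stream <- rng_stream(seed, "world")
  n <- config$n_agents
  two_fish <- identical(config$scenario, "two_fish")

  with_stream(stream, {
    # patch centers: fully inside the arena (margin = patch radius)
    pr <- config$patch_radius_cm
    if (two_fish) {
      centers <- matrix(c(config$width_cm / 2, config$height_cm / 2), ncol = 2)
    } else if (config$n_patches > 0L) {
      centers <- cbind(stats::runif(config$n_patches, pr, config$width_cm - pr),
                       stats::runif(config$n_patches, pr, config$height_cm - pr))
    } else {
      centers <- matrix(numeric(0), ncol = 2)
    }

    # agent placement
    if (two_fish) {
      ra <- pr * sqrt(stats::runif(1)); ta <- stats::runif(1, 0, 2 * pi)
      ax <- centers[1, 1] + ra * cos(ta); ay <- centers[1, 2] + ra * sin(ta)
      repeat {
        rb <- config$comm_radius_cm * sqrt(stats::runif(1))
        tb <- stats::runif(1, 0, 2 * pi)
        bx <- ax + rb * cos(tb); by <- ay + rb * sin(tb)
        if (bx >= 0 && bx <= config$width_cm && by >= 0 && by <= config$height_cm)
          break
      }
      xs <- c(ax, bx); ys <- c(ay, by)
    } else {
      xs <- stats::runif(n, 0, config$width_cm)
      ys <- stats::runif(n, 0, config$height_cm)
    }
    headings <- stats::runif(n, 0, 2 * pi)
    if (is.null(dominance)) dominance <- stats::runif(n)
    stopifnot(length(dominance) == n, all(dominance >= 0 & dominance <= 1))

    agents <- matrix(0, nrow = n, ncol = length(.AGENT_COLS),
                     dimnames = list(NULL, .AGENT_COLS))
    agents[, "x"] <- xs; agents[, "y"] <- ys
    agents[, "heading"] <- headings
    agents[, "dominance"] <- dominance

    items <- .empty_items()
    np <- nrow(centers)
    spawned <- integer(np)
    for (p in seq_len(np)) {
      it <- .spawn_items(config$patch_capacity, centers[p, ], pr,
                         config$passive_amplitude, p)
      items <- rbind(items, it)
      spawned[p] <- config$patch_capacity
    }

    list(config = config, t = 0L, agents = agents,
         food = list(centers = centers, items = items, spawned = spawned),
         stream = stream, done = FALSE, seed = as.integer(seed))
  })
}

#' Kinematic update for a single agent
#'
#' Heading advances by `turn * omega_max * dt` (wrapped to `[0, 2*pi)`);
#' position advances by `thrust * v_max * dt` along the new heading and is
#' clamped componentwise to the arena (velocity into a wall is zeroed, the
#' tangential component slides).
#'
#' @param state Named numeric vector or 1-row matrix with at least `x`, `y`,
#'   `heading`.
#' @param action Named list/vector with `thrust` in `[0,1]`, `turn` in
#'   `[-1,1]`.
#' @param config An [arena_config()].
#' @return The updated state (same shape), with `speed` and `last_turn` set.
#' @export
move_agent <- function(state, action, config) {
  s <- if (is.matrix(state)) state[1, ] else state
  thrust <- min(max(action[["thrust"]], 0), 1)
  turn <- min(max(action[["turn"]], -1), 1)
  h <- wrap_angle(s[["heading"]] + turn * config$omega_max_rads * config$dt_s)
  v <- thrust * config$v_max_cms
  s[["x"]] <- min(max(s[["x"]] + v * config$dt_s * cos(h), 0), config$width_cm)
  s[["y"]] <- min(max(s[["y"]] + v * config$dt_s * sin(h), 0), config$height_cm)
  s[["heading"]] <- h
  if ("speed" %in% names(s)) s[["speed"]] <- v
  if ("last_turn" %in% names(s)) s[["last_turn"]] <- turn
  s
}

.move_all <- function(agents, actions, config) {
  thrust <- pmin(pmax(actions[, 1], 0), 1)
  turn <- pmin(pmax(actions[, 2], -1), 1)
  h <- wrap_angle(agents[, "heading"] + turn * config$omega_max_rads * config$dt_s)
  v <- thrust * config$v_max_cms
  agents[, "x"] <- pmin(pmax(agents[, "x"] + v * config$dt_s * cos(h), 0),
                        config$width_cm)
  agents[, "y"] <- pmin(pmax(agents[, "y"] + v * config$dt_s * sin(h), 0),
                        config$height_cm)
  agents[, "heading"] <- h
  agents[, "speed"] <- v
  agents[, "last_turn"] <- turn
  agents
}

#' Replenish food patches
#'
#' In competitive mode each patch below capacity gains one item with
#' probability `min(1, replenish_rate_per_s * dt_s)` per step, at a uniform
#' position inside the patch.  In non-competitive mode capacity acts as an
#' unbounded target: every patch is instantly refilled to capacity.
#'
#' @param food The world's food list (`centers`, `items`, `spawned`).
#' @param config An [arena_config()].
#' @param stream An [rng_stream()] supplying randomness.
#' @return The updated food list.
#' @export
update_food <- function(food, config, stream) {
  np <- nrow(food$centers)
  if (np == 0L) return(food)
  counts <- tabulate(food$items[, "patch"], nbins = np)
  with_stream(stream, {
    for (p in seq_len(np)) {
      deficit <- config$patch_capacity - counts[p]
      if (deficit <= 0L) next
      add <- if (!config$competition) deficit
             else if (stats::runif(1) < min(1, config$replenish_rate_per_s * config$dt_s)) 1L
             else 0L
      if (add > 0L) {
        food$items <- rbind(food$items,
                            .spawn_items(add, food$centers[p, ],
                                         config$patch_radius_cm,
                                         config$passive_amplitude, p))
        food$spawned[p] <- food$spawned[p] + add
      }
    }
    food
  })
}

#' Resolve bite attempts into reward deltas
#'
#' A bite lands iff the biter chose `bite = 1` and a conspecific lies within
#' `bite_radius_cm` in the biter's frontal half-plane (nearest such
#' conspecific is the victim).  With biter dominance `d_b` and victim
#' dominance `d_v`, the victim's reward delta is
#' `-c_bite * sigma(k * (d_b - d_v))` and the biter's is
#' `-c_bite * sigma(k * (d_v - d_b))` with `sigma` the logistic function:
#' the more dominant party in the encounter loses less, and at equal
#' dominance both lose `c_bite / 2`.
#'
#' @param world A world state (post-move positions are used).
#' @param actions Action matrix (columns thrust, turn, eod, bite).
#' @param config An [arena_config()].
#' @return Numeric vector of per-agent reward deltas.
#' @export
resolve_bites <- function(world, actions, config) {
  ag <- world$agents
  n <- nrow(ag)
  deltas <- numeric(n)
  biters <- which(actions[, 4] == 1)
  if (!length(biters) || n < 2L) return(deltas)
  sig <- function(z) 1 / (1 + exp(-z))
  for (i in biters) {
    dx <- ag[, "x"] - ag[i, "x"]
    dy <- ag[, "y"] - ag[i, "y"]
    d <- sqrt(dx^2 + dy^2)
    frontal <- dx * cos(ag[i, "heading"]) + dy * sin(ag[i, "heading"]) > 0
    cand <- which(frontal & d <= config$bite_radius_cm & seq_len(n) != i)
    if (!length(cand)) next
    v <- cand[which.min(d[cand])]
    db <- ag[i, "dominance"]; dv <- ag[v, "dominance"]
    deltas[v] <- deltas[v] - config$c_bite * sig(config$bite_k * (db - dv))
    deltas[i] <- deltas[i] - config$c_bite * sig(config$bite_k * (dv - db))
  }
  deltas
}

# Items within eat radius of any agent are consumed by the nearest such
# agent.  Returns list(items, eaten_per_agent).
.resolve_eating <- function(items, agents, config) {
  n <- nrow(agents)
  eaten <- integer(n)
  m <- nrow(items)
  if (m == 0L) return(list(items = items, eaten = eaten))
  dx <- outer(items[, "x"], agents[, "x"], "-")
  dy <- outer(items[, "y"], agents[, "y"], "-")
  d <- sqrt(dx^2 + dy^2)                      # m x n
  nearest <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(m), nearest)]
  gone <- dmin <= config$eat_radius_cm
  if (any(gone)) {
    eaten <- tabulate(nearest[gone], nbins = n)
    items <- items[!gone, , drop = FALSE]
  }
  list(items = items, eaten = eaten)
}

#' Advance the world by one timestep
#'
#' Applies, in order: agent kinematics ([move_agent()] semantics), food
#' replenishment ([update_food()]), bite resolution ([resolve_bites()]),
#' eating (any item within `eat_radius_cm` of an agent is consumed,
#' `+r_food` reward), and the per-EOD energetic cost `-c_eod`.
#'
#' @param world A world state.
#' @param actions Numeric matrix `n_agents x 4` (thrust, turn, eod, bite);
#'   continuous entries are clipped, binary entries rounded to `{0,1}`.
#' @return A list with `world` (updated), `rewards` (per-agent), `done`.
#' @export
world_step <- function(world, actions) {
  cfg <- world$config
  actions <- matrix(as.numeric(actions), ncol = 4)
  if (nrow(actions) != nrow(world$agents))
    stop("world_step(): need exactly one action per agent", call. = FALSE)
  actions[, 3] <- as.numeric(actions[, 3] >= 0.5)
  actions[, 4] <- as.numeric(actions[, 4] >= 0.5)

  world$agents <- .move_all(world$agents, actions, cfg)
  world$agents[, "eod"] <- actions[, 3]
  world$agents[, "bite"] <- actions[, 4]
  world$food <- update_food(world$food, cfg, world$stream)
  bite_deltas <- resolve_bites(world, actions, cfg)
  fe <- .resolve_eating(world$food$items, world$agents, cfg)
  world$food$items <- fe$items

  rewards <- cfg$r_food * fe$eaten - cfg$c_eod * actions[, 3] + bite_deltas
  world$agents[, "food_eaten"] <- world$agents[, "food_eaten"] + fe$eaten
  world$agents[, "cum_reward"] <- world$agents[, "cum_reward"] + rewards
  world$t <- world$t + 1L
  world$done <- world$t >= cfg$max_steps
  list(world = world, rewards = rewards, done = world$done)
}

#' Per-step reward decomposition
#'
#' Assembles the reward from its three terms: `r_food` per item eaten, the
#' per-EOD energetic cost `-c_eod`, and the dominance-asymmetric bite
#' deltas.  No term rewards proximity, coordination, or communication; all
#' social structure must emerge from individual fitness.
#'
#' @param eaten Integer vector: items eaten per agent this step.
#' @param eod Binary vector: EOD flag per agent.
#' @param bite_deltas Numeric vector from [resolve_bites()].
#' @param config An [arena_config()].
#' @return Per-agent reward vector.
#' @export
reward_fn <- function(eaten, eod, bite_deltas, config) {
  config$r_food * eaten - config$c_eod * eod + bite_deltas
}
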