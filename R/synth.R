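# Synthetic-trace generator: scripted EOD trains, trajectories, interaction
# windows, and consumption tallies with exactly known (planted) structure,
# emitted in the same EpisodeTrace schema as the simulator.  This is what
# makes the analytics suite testable without training.

#' Specify a synthetic episode trace
#'
#' Each agent gets an EOD process and a trajectory script; optional
#' interaction windows place a pair of agents at a fixed distance for a
#' span of steps (overriding their trajectories), and an optional
#' consumption vector plants final per-agent food tallies.
#'
#' EOD processes: `list(type = "bernoulli", p = )`,
#' `list(type = "renewal", sampler = function(n) )` (interval draws in
#' seconds, quantized to steps), or `list(type = "scripted", pattern = )`
#' (binary string, recycled to `n_steps`).
#'
#' Trajectories: `list(type = "stationary", at = c(x, y))`,
#' `list(type = "straight", from = c(x, y), heading = , speed_cms = )`, or
#' `list(type = "waypoints", points = matrix, speed_cms = )` (piecewise
#' linear at constant speed).  Default: stationary, on a widely spaced grid
#' so no unplanned interactions occur.
#'
#' @param n_agents,n_steps Trace dimensions.
#' @param eod List of per-agent EOD process specs (recycled if length 1).
#' @param trajectory List of per-agent trajectory specs (recycled).
#' @param interactions List of `list(pair = c(a, b), start = , end = ,
#'   distance_cm = )` windows.
#' @param consumption Optional numeric vector of final per-agent food
#'   tallies.
#' @param config Optional [arena_config()] (defaults to a quiet arena of
#'   matching size).
#' @param seed Generator seed.
#' @return A list of class `synthetic_trace_spec`.
#' @export
synthetic_trace_spec <- function(n_agents, n_steps,
                                 eod = list(list(type = "bernoulli", p = 0.1)),
                                 trajectory = list(list(type = "stationary")),
                                 interactions = list(),
                                 consumption = NULL,
                                 config = NULL, seed = 0L) {
  stopifnot(n_agents >= 1, n_steps >= 1)
  if (length(eod) == 1L) eod <- rep(eod, n_agents)
  if (length(trajectory) == 1L) trajectory <- rep(trajectory, n_agents)
  stopifnot(length(eod) == n_agents, length(trajectory) == n_agents)
  for (w in interactions) {
    if (!all(c("pair", "start", "end") %in% names(w)))
      stop("interaction window needs pair, start, end", call. = FALSE)
    if (w$start < 1 || w$end > n_steps || w$start > w$end)
      stop("interaction window [", w$start, ", ", w$end,
           "] outside 1..", n_steps, call. = FALSE)
    if (length(w$pair) != 2 || w$pair[1] == w$pair[2] ||
        any(w$pair < 1) || any(w$pair > n_agents))
      stop("interaction window pair must name two distinct agents",
           call. = FALSE)
  }
  if (!is.null(consumption))
    stopifnot(length(consumption) == n_agents, all(consumption >= 0))
  if (is.null(config))
    config <- arena_config(n_agents = n_agents, max_steps = n_steps,
                           n_patches = 0L)
  structure(list(n_agents = as.integer(n_agents),
                 n_steps = as.integer(n_steps), eod = eod,
                 trajectory = trajectory, interactions = interactions,
                 consumption = consumption, config = config,
                 seed = as.integer(seed)),
            class = "synthetic_trace_spec")
}

.synth_eod_train <- function(proc, n_steps, dt, stream) {
  switch(proc$type,
    bernoulli = with_stream(stream,
      as.numeric(stats::runif(n_steps) < proc$p)),
    renewal = {
      # draw intervals (s) until the episode is covered, quantize to steps
      tmax <- n_steps * dt
      draws <- numeric(0); tot <- 0
      while (tot < tmax) {
        new <- with_stream(stream, proc$sampler(256L))
        draws <- c(draws, new); tot <- sum(draws)
      }
      # epsilon guard: an event at an exact step boundary belongs to that
      # step, not the next (cumsum/division float noise)
      steps <- unique(ceiling(cumsum(draws) / dt - 1e-9))
      train <- numeric(n_steps)
      train[steps[steps >= 1 & steps <= n_steps]] <- 1
      train
    },
    scripted = {
      bits <- as.numeric(strsplit(proc$pattern, "")[[1]])
      stopifnot(all(bits %in% c(0, 1)))
      rep_len(bits, n_steps)
    },
    stop("unknown EOD process type: ", proc$type, call. = FALSE))
}

.synth_positions <- function(traj, n_steps, dt, default_at, config) {
  switch(traj$type,
    stationary = {
      at <- if (!is.null(traj$at)) traj$at else default_at
      cbind(x = rep(at[1], n_steps), y = rep(at[2], n_steps),
            heading = rep(0, n_steps))
    },
    straight = {
      v <- traj$speed_cms
      tt <- seq_len(n_steps) * dt
      cbind(x = pmin(pmax(traj$from[1] + v * tt * cos(traj$heading), 0),
                     config$width_cm),
            y = pmin(pmax(traj$from[2] + v * tt * sin(traj$heading), 0),
                     config$height_cm),
            heading = rep(traj$heading, n_steps))
    },
    waypoints = {
      pts <- traj$points
      seg <- diff(pts)
      seg_len <- sqrt(rowSums(seg^2))
      cum <- c(0, cumsum(seg_len))
      s <- pmin(seq_len(n_steps) * dt * traj$speed_cms, max(cum))
      idx <- findInterval(s, cum, rightmost.closed = TRUE)
      idx <- pmin(idx, nrow(pts) - 1L)
      frac <- (s - cum[idx]) / pmax(seg_len[idx], 1e-12)
      cbind(x = pts[idx, 1] + frac * seg[idx, 1],
            y = pts[idx, 2] + frac * seg[idx, 2],
            heading = atan2(seg[idx, 2], seg[idx, 1]))
    },
    stop("unknown trajectory type: ", traj$type, call. = FALSE))
}

#' Generate a synthetic episode trace from a specification
#'
#' The planted structure (EOD trains, positions, interaction windows,
#' consumption tallies) is exactly recoverable from the emitted trace by
#' the analytics module; the trace is schema-identical to simulator output.
#'
#' @param spec A [synthetic_trace_spec()].
#' @return An `episode_trace`.
#' @export
#' @examples
#' sp <- synthetic_trace_spec(1, 10,
#'   eod = list(list(type = "scripted", pattern = "0101010101")))
#' tr <- generate_synthetic_trace(sp)
#' extract_spi(tr, 1)$intervals_s
generate_synthetic_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trace_spec"))
  cfg <- spec$config
  n <- spec$n_agents; T_ <- spec$n_steps; dt <- cfg$dt_s
  stream <- rng_stream(spec$seed, "synth")

  # widely spaced default anchor points (>= 40 cm apart on a grid)
  ncol_grid <- max(1L, floor(cfg$width_cm / 40))
  gx <- 20 + 40 * ((seq_len(n) - 1L) %% ncol_grid)
  gy <- 20 + 40 * ((seq_len(n) - 1L) %/% ncol_grid)
  gx <- pmin(gx, cfg$width_cm); gy <- pmin(gy, cfg$height_cm)

  pos <- lapply(seq_len(n), function(i)
    .synth_positions(spec$trajectory[[i]], T_, dt, c(gx[i], gy[i]), cfg))
  eod <- lapply(seq_len(n), function(i)
    .synth_eod_train(spec$eod[[i]], T_, dt, stream))

  # interaction windows override the second agent's position: at the
  # planted distance from the first, along +x
  for (w in spec$interactions) {
    a <- w$pair[1]; b <- w$pair[2]
    d <- if (!is.null(w$distance_cm)) w$distance_cm else 10
    idx <- w$start:w$end
    pos[[b]][idx, "x"] <- pmin(pos[[a]][idx, "x"] + d, cfg$width_cm)
    pos[[b]][idx, "y"] <- pos[[a]][idx, "y"]
  }

  tally <- matrix(0, T_, n)
  if (!is.null(spec$consumption))
    for (i in seq_len(n))
      tally[, i] <- floor(seq_len(T_) / T_ * spec$consumption[i])

  states <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    eaten_i <- tally[, i]
    tibble::tibble(step = seq_len(T_), agent_id = i,
                   x = pos[[i]][, "x"], y = pos[[i]][, "y"],
                   heading = pos[[i]][, "heading"],
                   speed = c(0, sqrt(diff(pos[[i]][, "x"])^2 +
                                       diff(pos[[i]][, "y"])^2) / dt),
                   dominance = 0.5, eod = eod[[i]], bite = 0,
                   food_eaten = eaten_i,
                   reward = cfg$r_food * c(eaten_i[1], diff(eaten_i)) -
                     cfg$c_eod * eod[[i]])
  })) |> dplyr::arrange(.data$step, .data$agent_id)

  actions <- tibble::tibble(step = states$step, agent_id = states$agent_id,
                            thrust = 0, turn = 0, eod = states$eod,
                            bite = 0, log_prob = NA_real_)
  food <- tibble::tibble(step = integer(), patch = integer(),
                         items_remaining = integer())
  episode_trace(config = cfg, seed = spec$seed, states = states,
                actions = actions, food = food, n_steps = T_)
}
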