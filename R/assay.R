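# Minimal two-fish social foraging assay.
#
# Agent A sits inside a fully-replenishing food patch; agent B starts at a
# random position within communication radius of A.  Conditions vary the
# presence of A and of B's Knollenorgan, and the A/B dominance levels; the
# outcome measures are whether B reaches the patch and how much it eats.

#' Scripted patch-resident controller (agent A)
#'
#' Stays in place and discharges every `eod_period` steps — a periodic
#' beacon whose pulses B can detect through its Knollenorgan.
#'
#' @param eod_period Steps between discharges.
#' @return A per-agent controller function.
#' @export
ctrl_patch_resident <- function(eod_period = 5L) {
  function(world, agent_id, obs, stream) {
    c(0, 0, as.numeric(world$t %% eod_period == 0L), 0)
  }
}

#' Scripted Knollenorgan-homing controller (agent B)
#'
#' Memoryless pulse-taxis: on steps where any Knollenorgan bin is active,
#' turn toward the strongest bin's center direction at full thrust; on
#' silent steps keep going straight.  With the Knollenorgan disabled the
#' controller never receives a bearing and simply runs straight from its
#' random initial heading.
#'
#' @param thrust Forward drive in `[0, 1]`.
#' @return A per-agent controller function.
#' @export
ctrl_ko_homing <- function(thrust = 1) {
  function(world, agent_id, obs, stream) {
    cfg <- world$config
    ko <- obs[obs_layout(cfg)$knollenorgan]
    turn <- 0
    if (any(ko > 0)) {
      bin <- which.max(ko)
      rel <- (bin - 0.5) * 2 * pi / cfg$n_ko_bins   # bin-center bearing
      if (rel > pi) rel <- rel - 2 * pi             # to (-pi, pi]
      turn <- min(max(rel / (cfg$omega_max_rads * cfg$dt_s), -1), 1)
    }
    c(thrust, turn, 0, 0)
  }
}

# One-agent variant of the two-fish world: reset the 2-agent assay with the
# same seed, then keep only B (same start pose and dominance), so "A
# removed" changes nothing else.
.assay_world_config <- function(config) {
  cfg1 <- config
  cfg1$n_agents <- 1L
  cfg1$scenario <- "two_fish_solo"
  cfg1
}

.run_assay_episode <- function(config, controllers, seed, dominance,
                               remove_a = FALSE, n_steps = config$max_steps) {
  world <- world_reset(config, seed, dominance = dominance)
  patch_center <- world$food$centers[1, ]
  pr <- config$patch_radius_cm
  b_row <- 2L
  if (remove_a) {
    keep <- world$agents[2L, , drop = FALSE]
    world$config <- .assay_world_config(config)
    world$agents <- keep
    controllers <- controllers[2L]
    b_row <- 1L
  }
  start <- world$agents[b_row, c("x", "y")]
  act_stream <- rng_stream(seed, "actions")
  reached <- FALSE
  for (t in seq_len(n_steps)) {
    obs <- observe_all(world)
    actions <- t(vapply(seq_len(nrow(world$agents)), function(i)
      controllers[[i]](world, i, obs[i, ], act_stream), numeric(4)))
    res <- world_step(world, actions)
    world <- res$world
    db <- sqrt(sum((world$agents[b_row, c("x", "y")] - patch_center)^2))
    if (db <= pr) reached <- TRUE
    if (res$done) break
  }
  tibble::tibble(
    reached = reached,
    food_b = world$agents[b_row, "food_eaten"],
    start_distance_cm = sqrt(sum((start - patch_center)^2)),
    start_bearing_rad = atan2(start[2] - patch_center[2],
                              start[1] - patch_center[1]))
}

#' Run the two-fish social foraging assay
#'
#' For each dominance pair and each condition (`baseline`: A present and
#' B's Knollenorgan on; `a_removed`: A deleted from the arena, everything
#' else identical; `ko_off`: A present but B's Knollenorgan disabled), runs
#' `n_runs` episodes with paired seeds (run `r` uses the same seed in every
#' condition, so initial geometry matches across conditions) and reports
#' the fraction of episodes in which B enters the patch disc and the mean
#' number of items B eats.
#'
#' @param controllers A 2-element list of per-agent controller functions
#'   (`list(A, B)`), a [scripted_controller()], or a trained
#'   `policy_state` driving both agents.  Default: scripted periodic
#'   beacon A and Knollenorgan-homing B.
#' @param config A two-fish [arena_config()] (default
#'   `make_scenario("two_fish")`).
#' @param dominance_pairs Tibble/data.frame with columns `dom_a`, `dom_b`.
#' @param n_runs Episodes per condition and dominance pair.
#' @param conditions Subset of `c("baseline", "a_removed", "ko_off")`.
#' @param seed Root seed.
#' @param n_steps Episode length.
#' @return A list of class `two_fish_assay`: `runs` (one row per episode)
#'   and `summary` (per condition x dominance pair: `reach_rate`,
#'   `mean_food_b`).
#' @export
two_fish_assay <- function(controllers = NULL,
                           config = make_scenario("two_fish"),
                           dominance_pairs = tibble::tibble(dom_a = 0.5,
                                                            dom_b = 0.5),
                           n_runs = 100,
                           conditions = c("baseline", "a_removed", "ko_off"),
                           seed = 0L, n_steps = config$max_steps) {
  if (!identical(config$scenario, "two_fish"))
    stop("two_fish_assay(): config must come from make_scenario('two_fish')",
         call. = FALSE)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(controllers))
    controllers <- list(ctrl_patch_resident(), ctrl_ko_homing())
  runs <- list()
  for (dp in seq_len(nrow(dominance_pairs))) {
    dom <- c(dominance_pairs$dom_a[dp], dominance_pairs$dom_b[dp])
    for (cond in conditions) {
      cfg <- config
      if (cond == "ko_off") cfg$knollenorgan_enabled <- FALSE
      ctrl <- .resolve_assay_controllers(controllers, cfg)
      for (r in seq_len(n_runs)) {
        ep_seed <- derive_seed(seed, paste0("assay_run", r))
        row <- .run_assay_episode(cfg, ctrl, ep_seed, dom,
                                  remove_a = cond == "a_removed",
                                  n_steps = n_steps)
        runs[[length(runs) + 1L]] <- dplyr::mutate(
          row, condition = cond, run = r,
          dom_a = dom[1], dom_b = dom[2], .before = 1)
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$condition, .data$dom_a, .data$dom_b) |>
    dplyr::summarise(reach_rate = mean(.data$reached),
                     mean_food_b = mean(.data$food_b),
                     n_runs = dplyr::n(), .groups = "drop")
  structure(list(runs = runs, summary = summary), class = "two_fish_assay")
}

.resolve_assay_controllers <- function(controllers, cfg) {
  if (inherits(controllers, "policy_state")) {
    pol <- controllers
    hidden_env <- new.env(parent = emptyenv())
    mk <- function(i) function(world, agent_id, obs, stream) {
      key <- paste0("h", agent_id)
      if (is.null(hidden_env[[key]]) || world$t == 0L)
        hidden_env[[key]] <- numeric(pol$config$rnn_width)
      st <- policy_step(pol, hidden_env[[key]], obs)
      hidden_env[[key]] <- st$hidden
      sample_action(st$dist, stream)$action
    }
    list(mk(1L), mk(2L))
  } else if (inherits(controllers, "scripted_controller")) {
    list(.controller_fn(controllers, 1L), .controller_fn(controllers, 2L))
  } else {
    stopifnot(is.list(controllers), length(controllers) == 2L)
    controllers
  }
}

#' @export
print.two_fish_assay <- function(x, ...) {
  cat("<two_fish_assay>\n")
  print(x$summary)
  invisible(x)
}

#' Paired sign test for a condition contrast in an assay
#'
#' Compares a binary outcome between two conditions across paired runs
#' (same seed) with an exact binomial sign test on the discordant pairs.
#'
#' @param assay A [two_fish_assay()] result.
#' @param cond_pos,cond_neg Condition labels; the alternative is that
#'   `cond_pos` succeeds more often.
#' @param outcome Column of `assay$runs` to compare (default `"reached"`).
#' @return One-row tibble: discordant counts and the one-sided p-value.
#' @export
assay_sign_test <- function(assay, cond_pos = "baseline",
                            cond_neg = "ko_off", outcome = "reached") {
  r <- assay$runs
  a <- r[r$condition == cond_pos, ]
  b <- r[r$condition == cond_neg, ]
  key <- c("run", "dom_a", "dom_b")
  m <- dplyr::inner_join(a[, c(key, outcome)], b[, c(key, outcome)],
                         by = key, suffix = c("_pos", "_neg"))
  xp <- m[[paste0(outcome, "_pos")]]
  xn <- m[[paste0(outcome, "_neg")]]
  n_pos <- sum(xp > xn); n_neg <- sum(xn > xp)
  p <- if (n_pos + n_neg == 0) 1 else
    stats::binom.test(n_pos, n_pos + n_neg, alternative = "greater")$p.value
  tibble::tibble(cond_pos = cond_pos, cond_neg = cond_neg,
                 n_pairs = nrow(m), n_pos = n_pos, n_neg = n_neg,
                 p_value = p)
}
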