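# Arena configuration: geometry, kinematics, food dynamics, field physics,
# sensor layout, and reward constants.  All lengths cm, times s, angles rad.

.arena_defaults <- function() {
  list(
    # geometry & episode
    width_cm = 200, height_cm = 200, dt_s = 0.04, max_steps = 1500L,
    n_agents = 4L, seed = 0L,
    # food
    n_patches = 3L, patch_radius_cm = 10, patch_capacity = 5L,
    replenish_rate_per_s = 0.25, competition = TRUE,
    # kinematics
    v_max_cms = 20, omega_max_rads = pi,
    eat_radius_cm = 2, bite_radius_cm = 4,
    # rewards
    r_food = 1.0, c_eod = 0.01, c_bite = 1.0, bite_k = 6,
    # field physics (arbitrary field units; only ratios reach the policy)
    kappa = 1, r_min_cm = 1, eod_amplitude = 100,
    alpha_food = 10, alpha_body = 20, passive_amplitude = 6,
    reflections_enabled = TRUE,
    # sensors
    n_receptors = 8L, n_ko_bins = 8L,
    body_semi_major_cm = 3, body_semi_minor_cm = 1,
    knollenorgan_enabled = TRUE, knollenorgan_amplitude = 50,
    collective_sensing_enabled = TRUE, comm_radius_cm = 50,
    obs_log_scale = 1, sensor_noise_sd = 0,
    # scenario bookkeeping
    scenario = "custom"
  )
}

#' Construct and validate an arena configuration
#'
#' Builds the full configuration of the 2D foraging arena: geometry and
#' timestep, agent count and kinematic limits, patchy food dynamics
#' (competitive = finite replenishment vs non-competitive = instantly
#' refilled patches), the dipole field-physics constants, the biomimetic
#' sensor layout, and the reward constants.  Any field can be overridden by
#' name; unknown names are rejected.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Key fields: `width_cm`, `height_cm`, `dt_s`, `max_steps`,
#'   `n_agents`; food: `n_patches`, `patch_radius_cm`, `patch_capacity`,
#'   `replenish_rate_per_s`, `competition`; kinematics: `v_max_cms`,
#'   `omega_max_rads`, `eat_radius_cm`, `bite_radius_cm`; rewards: `r_food`,
#'   `c_eod` (per-discharge energetic cost), `c_bite`, `bite_k` (logistic
#'   steepness of the dominance asymmetry); field: `kappa`, `r_min_cm`
#'   (softening radius), `eod_amplitude`, `alpha_food`/`alpha_body`
#'   (polarizabilities), `passive_amplitude` (static prey dipole moment),
#'   `reflections_enabled`; sensors: `n_receptors`, `n_ko_bins`,
#'   `knollenorgan_enabled`, `knollenorgan_amplitude`,
#'   `collective_sensing_enabled`, `comm_radius_cm`, `obs_log_scale`,
#'   `sensor_noise_sd`.
#' @return A list of class `arena_config`.
#' @export
#' @examples
#' cfg <- arena_config(n_agents = 2, width_cm = 100, height_cm = 100)
#' cfg$n_agents
arena_config <- function(...) {
  defaults <- .arena_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("arena_config(): all overrides must be named", call. = FALSE)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("arena_config(): unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  for (f in c("max_steps", "n_agents", "n_patches", "patch_capacity",
              "n_receptors", "n_ko_bins", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "arena_config"
  validate_arena_config(cfg)
  cfg
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %s: %gx%g cm, dt %g s, %d agents, %d patches (%s)\n",
              x$scenario, x$width_cm, x$height_cm, x$dt_s, x$n_agents,
              x$n_patches,
              if (x$competition) "competitive" else "non-competitive"))
  invisible(x)
}

validate_arena_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("arena_config: ", msg, call. = FALSE)
  chk(cfg$width_cm > 0 && cfg$height_cm > 0, "arena dimensions must be positive")
  chk(cfg$dt_s > 0, "dt_s must be positive")
  chk(cfg$max_steps > 0, "max_steps must be positive")
  chk(cfg$n_agents >= 1, "n_agents must be >= 1")
  chk(cfg$replenish_rate_per_s >= 0, "replenish_rate_per_s must be >= 0")
  chk(cfg$patch_capacity >= 1, "patch_capacity must be >= 1")
  chk(cfg$n_patches >= 0, "n_patches must be >= 0")
  chk(2 * cfg$patch_radius_cm <= min(cfg$width_cm, cfg$height_cm),
      "patch diameter exceeds arena: patches cannot lie fully inside")
  chk(cfg$v_max_cms > 0 && cfg$omega_max_rads > 0, "kinematic limits must be positive")
  chk(cfg$r_min_cm > 0, "softening radius r_min_cm must be positive")
  chk(cfg$n_receptors >= 1 && cfg$n_ko_bins >= 1, "sensor counts must be >= 1")
  chk(cfg$comm_radius_cm > 0, "comm_radius_cm must be positive")
  invisible(cfg)
}

#' Build an arena configuration from a named scenario preset
#'
#' Presets reproduce the study conditions: `"competitive"` (finite, slowly
#' replenishing patches; zero-sum foraging), `"noncompetitive"` (patches
#' refill instantly, food effectively unlimited), and `"two_fish"` (minimal
#' social foraging assay: two agents, one fully-replenishing patch at the
#' arena center; agent A starts inside the patch and agent B within
#' communication radius of A).
#'
#' @param preset One of `"competitive"`, `"noncompetitive"`, `"two_fish"`,
#'   `"solo_forage"` (a single-agent 50 x 50 cm dense-food arena with
#'   instantly refilling patches — the learning sanity task: any policy
#'   that outperforms an untrained one here has learned to exploit its
#'   sensors and kinematics).
#' @param ... Named overrides applied after the preset.
#' @return An `arena_config`.
#' @export
#' @examples
#' make_scenario("noncompetitive")$competition
#' make_scenario("two_fish", knollenorgan_enabled = FALSE)$n_agents
make_scenario <- function(preset = c("competitive", "noncompetitive",
                                     "two_fish", "solo_forage"),
                          ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    competitive = list(competition = TRUE, replenish_rate_per_s = 0.25),
    noncompetitive = list(competition = FALSE),
    two_fish = list(n_agents = 2L, n_patches = 1L, competition = FALSE,
                    patch_radius_cm = 10, patch_capacity = 3L,
                    max_steps = 500L),
    solo_forage = list(n_agents = 1L, width_cm = 50, height_cm = 50,
                       n_patches = 6L, patch_radius_cm = 6,
                       patch_capacity = 2L, competition = FALSE,
                       max_steps = 500L, knollenorgan_enabled = FALSE,
                       collective_sensing_enabled = FALSE)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(.arena_defaults()))
  if (length(unknown))
    stop("make_scenario(): unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- utils::modifyList(c(base, list(scenario = preset)), over)
  do.call(arena_config, args)
}

#' Read / write an arena configuration as YAML
#'
#' The YAML document is a flat mapping that mirrors the `arena_config`
#' fields one-to-one.  Unknown keys are rejected on read.
#'
#' @param path File path.
#' @return `read_arena_yaml` returns an `arena_config`.
#' @export
read_arena_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) stop("config YAML must be a mapping", call. = FALSE)
  do.call(arena_config, doc)
}

#' @rdname read_arena_yaml
#' @param cfg An `arena_config` to write.
#' @export
write_arena_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "arena_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
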