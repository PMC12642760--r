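# Biomimetic sensor channels: active electrosensing (perturbations of the
# illuminating EOD fields), passive low-frequency sensing (static prey
# dipoles), Knollenorgan social sensing (binned conspecific EOD pulses), and
# proprioception.  All channels are egocentric.

#' Receptor positions for an agent
#'
#' `n_receptors` electroreceptors sit on a body ellipse (semi-axes
#' `body_semi_major_cm` x `body_semi_minor_cm`) at uniformly spaced body
#' angles; world-frame positions are the pose-transformed offsets.
#'
#' @param agent Named vector/1-row matrix with `x`, `y`, `heading`.
#' @param config An [arena_config()].
#' @return Numeric matrix `n_receptors x 2` of world-frame positions (cm).
#' @export
receptor_positions <- function(agent, config) {
  s <- if (is.matrix(agent)) agent[1, ] else agent
  th <- 2 * pi * (seq_len(config$n_receptors) - 1L) / config$n_receptors
  bx <- config$body_semi_major_cm * cos(th)
  by <- config$body_semi_minor_cm * sin(th)
  h <- s[["heading"]]
  cbind(s[["x"]] + bx * cos(h) - by * sin(h),
        s[["y"]] + bx * sin(h) + by * cos(h))
}

# Emitters illuminating agent i's active channels: its own EOD plus, when
# collective sensing is enabled, conspecific EODs this step.
.illuminators <- function(world, i) {
  cfg <- world$config
  emitting <- which(world$agents[, "eod"] == 1)
  if (!cfg$collective_sensing_enabled) emitting <- intersect(emitting, i)
  emitting
}

#' Active electrosensing channels
#'
#' For each receptor, the perturbation magnitude `|E_total| - |E_direct|`,
#' where `E_direct` is the field of the illuminating emitter dipoles alone
#' and `E_total` additionally includes the dipoles they induce on food items
#' and conspecific bodies, plus first-order wall images.  Illuminators are
#' the agent's own EOD and, when `collective_sensing_enabled`, conspecific
#' EODs this step (the collective-sensing pathway).  Zero vector when
#' nothing illuminates.
#'
#' @param world A world state.
#' @param agent_id Focal agent index.
#' @return Numeric vector of length `n_receptors`.
#' @export
active_channels <- function(world, agent_id) {
  cfg <- world$config
  rec <- receptor_positions(world$agents[agent_id, , drop = FALSE], cfg)
  lit <- .illuminators(world, agent_id)
  if (!length(lit)) return(numeric(cfg$n_receptors))

  ag <- world$agents
  em_pos <- cbind(ag[lit, "x"], ag[lit, "y"])
  em_mom <- cfg$eod_amplitude * cbind(cos(ag[lit, "heading"]),
                                      sin(ag[lit, "heading"]))
  ind_pos <- NULL; ind_mom <- NULL
  for (k in seq_along(lit)) {
    sc <- .scatterers_mat(world, emitter_owner = lit[k],
                          exclude_agent = agent_id)
    if (is.null(sc$pos) || nrow(sc$pos) == 0L) next
    e <- .field_mat(sc$pos, em_pos[k, , drop = FALSE],
                    em_mom[k, , drop = FALSE], cfg$kappa, cfg$r_min_cm)
    ind_pos <- rbind(ind_pos, sc$pos)
    ind_mom <- rbind(ind_mom, sc$alpha * e)
  }
  tot_pos <- rbind(em_pos, ind_pos)
  tot_mom <- rbind(em_mom, ind_mom)
  if (cfg$reflections_enabled) {
    img <- .images_mat(tot_pos, tot_mom, cfg$width_cm, cfg$height_cm)
    tot_pos <- rbind(tot_pos, img$pos)
    tot_mom <- rbind(tot_mom, img$mom)
  }
  e_tot <- .fieldmag_mat(rec, tot_pos, tot_mom, cfg$kappa, cfg$r_min_cm)
  e_dir <- .fieldmag_mat(rec, em_pos, em_mom, cfg$kappa, cfg$r_min_cm)
  e_tot - e_dir
}

#' Passive electrosensing channels
#'
#' Each food item carries a weak static dipole (fixed moment
#' `passive_amplitude`, orientation drawn at spawn) standing in for prey
#' bioelectric fields; the passive channel is the field magnitude of these
#' static sources at each receptor, independent of any EOD.  With the
#' default amplitude the 1/r^3 decay makes the effective range about 5 cm.
#'
#' @inheritParams active_channels
#' @return Numeric vector of length `n_receptors`.
#' @export
passive_channels <- function(world, agent_id) {
  cfg <- world$config
  items <- world$food$items
  if (nrow(items) == 0L) return(numeric(cfg$n_receptors))
  rec <- receptor_positions(world$agents[agent_id, , drop = FALSE], cfg)
  .fieldmag_mat(rec, cbind(items[, "x"], items[, "y"]),
                cbind(items[, "mx"], items[, "my"]),
                cfg$kappa, cfg$r_min_cm)
}

#' Knollenorgan social-sensing channels
#'
#' For each conspecific that discharged this step within `comm_radius_cm`,
#' an amplitude `A0 / max(d, r_min)^2` is added to the egocentric direction
#' bin containing it (`n_ko_bins` uniform angular bins relative to the
#' agent's heading; bin 1 starts at the heading direction).  The agent's own
#' EODs are excluded; the whole block is zero when
#' `knollenorgan_enabled = FALSE`.  The slow 1/r^2 falloff (vs the ~1/r^6
#' round-trip of active sensing) makes this the long-range social channel.
#'
#' @inheritParams active_channels
#' @return Numeric vector of length `n_ko_bins`.
#' @export
knollenorgan_channels <- function(world, agent_id) {
  cfg <- world$config
  out <- numeric(cfg$n_ko_bins)
  if (!cfg$knollenorgan_enabled) return(out)
  ag <- world$agents
  others <- which(ag[, "eod"] == 1 & seq_len(nrow(ag)) != agent_id)
  if (!length(others)) return(out)
  dx <- ag[others, "x"] - ag[agent_id, "x"]
  dy <- ag[others, "y"] - ag[agent_id, "y"]
  d <- sqrt(dx^2 + dy^2)
  keep <- d <= cfg$comm_radius_cm
  if (!any(keep)) return(out)
  dx <- dx[keep]; dy <- dy[keep]; d <- d[keep]
  rel <- wrap_angle(atan2(dy, dx) - ag[agent_id, "heading"])
  bin <- pmin(floor(rel / (2 * pi / cfg$n_ko_bins)) + 1L, cfg$n_ko_bins)
  amp <- cfg$knollenorgan_amplitude / pmax(d, cfg$r_min_cm)^2
  for (k in seq_along(bin)) out[bin[k]] <- out[bin[k]] + amp[k]
  out
}

#' Observation block layout
#'
#' @param config An [arena_config()].
#' @return Named list of index ranges (`active`, `passive`, `knollenorgan`,
#'   `proprio`) into the observation vector, plus attribute `"obs_dim"`.
#' @export
obs_layout <- function(config) {
  nr <- config$n_receptors; nb <- config$n_ko_bins
  l <- list(active = seq_len(nr),
            passive = nr + seq_len(nr),
            knollenorgan = 2L * nr + seq_len(nb),
            proprio = 2L * nr + nb + 1:3)
  attr(l, "obs_dim") <- 2L * nr + nb + 3L
  l
}

#' Observation dimension for a configuration
#' @param config An [arena_config()].
#' @return Integer: `2 * n_receptors + n_ko_bins + 3`.
#' @export
obs_dim <- function(config) attr(obs_layout(config), "obs_dim")

.signed_log <- function(x, s) sign(x) * log1p(abs(x) / s)

#' Assemble an agent's egocentric observation vector
#'
#' Concatenates the active, passive, Knollenorgan, and proprioceptive
#' (speed, last turn command, own EOD flag) blocks in that fixed order and
#' applies signed-log compression `y = sign(x) * log(1 + |x| / s)` with
#' scale `s = obs_log_scale` (field magnitudes span decades).  When
#' `sensor_noise_sd > 0`, i.i.d. Gaussian noise is added to the three field
#' blocks before compression.
#'
#' @inheritParams active_channels
#' @param stream Optional [rng_stream()] for sensor noise.
#' @return Numeric observation vector of length [obs_dim()].
#' @export
assemble_observation <- function(world, agent_id, stream = NULL) {
  cfg <- world$config
  act <- active_channels(world, agent_id)
  pas <- passive_channels(world, agent_id)
  ko <- knollenorgan_channels(world, agent_id)
  if (cfg$sensor_noise_sd > 0 && !is.null(stream)) {
    nf <- with_stream(stream,
                      stats::rnorm(length(act) + length(pas) + length(ko),
                                   0, cfg$sensor_noise_sd))
    act <- act + nf[seq_along(act)]
    pas <- pas + nf[length(act) + seq_along(pas)]
    ko <- ko + nf[length(act) + length(pas) + seq_along(ko)]
  }
  ag <- world$agents
  proprio <- c(ag[agent_id, "speed"], ag[agent_id, "last_turn"],
               ag[agent_id, "eod"])
  unname(.signed_log(c(act, pas, ko, proprio), cfg$obs_log_scale))
}

#' Observations for all agents
#'
#' @param world A world state.
#' @param stream Optional [rng_stream()] for sensor noise.
#' @return Numeric matrix `n_agents x obs_dim(config)`.
#' @export
observe_all <- function(world, stream = NULL) {
  n <- nrow(world$agents)
  t(vapply(seq_len(n), function(i) assemble_observation(world, i, stream),
           numeric(obs_dim(world$config))))
}
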