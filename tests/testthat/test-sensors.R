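# Helper: a quiet world with agents/food placed by hand.
manual_world <- function(cfg, agent_pose_mat, items = NULL) {
  w <- world_reset(cfg, 1)
  w$agents[, c("x", "y", "heading")] <- agent_pose_mat
  w$agents[, "eod"] <- 0
  if (is.null(items)) {
    w$food$items <- w$food$items[0, , drop = FALSE]
  } else {
    w$food$items <- items
  }
  w
}

test_that("active channels see scatterers only when something illuminates", {
  cfg <- small_config(n_agents = 1, reflections_enabled = FALSE)
  item <- function(d) cbind(x = 50 + d, y = 50, patch = 1, mx = 0, my = 0)
  w <- manual_world(cfg, cbind(50, 50, 0), item(10))
  # no EOD by anyone: zero vector
  expect_identical(active_channels(w, 1), numeric(cfg$n_receptors))
  # own EOD with no scatterers and reflections off: exactly zero
  w2 <- manual_world(cfg, cbind(50, 50, 0))
  w2$agents[1, "eod"] <- 1
  expect_equal(active_channels(w2, 1), numeric(cfg$n_receptors))
  # own EOD at the arena center with walls on: images only, tiny signal
  cfg3 <- small_config(n_agents = 1, reflections_enabled = TRUE)
  w3 <- manual_world(cfg3, cbind(50, 50, 0))
  w3$agents[1, "eod"] <- 1
  expect_lt(max(abs(active_channels(w3, 1))), 1e-2)
  # food swept from 2 to 30 cm: total response strictly decreasing
  resp <- vapply(seq(4, 30, by = 2), function(d) {
    wi <- manual_world(cfg, cbind(50, 50, 0), item(d))
    wi$agents[1, "eod"] <- 1
    sum(abs(active_channels(wi, 1)))
  }, numeric(1))
  expect_true(all(diff(resp) < 0))
})

test_that("passive channels follow the static prey dipoles and 1/r^3 decay", {
  cfg <- small_config(n_agents = 1, reflections_enabled = FALSE)
  w <- manual_world(cfg, cbind(50, 50, 0))
  expect_identical(passive_channels(w, 1), numeric(cfg$n_receptors))
  mk_item <- function(d) cbind(x = 50 + d, y = 50, patch = 1,
                               mx = cfg$passive_amplitude, my = 0)
  # ratio of responses at 6 cm vs 60 cm ~ 10^3 (receptor offsets blur it)
  w1 <- manual_world(cfg, cbind(50, 50, 0), mk_item(6))
  w2 <- manual_world(cfg, cbind(50, 50, 0), mk_item(60))
  expect_gt(max(passive_channels(w1, 1)) / max(passive_channels(w2, 1)), 500)
  # values equal direct field evaluation over the static source list
  it <- rbind(mk_item(7), cbind(x = 44, y = 58, patch = 1, mx = 1, my = -2))
  w3 <- manual_world(cfg, cbind(50, 50, 0.4), it)
  rec <- receptor_positions(w3$agents[1, , drop = FALSE], cfg)
  src <- data.frame(kind = "static", x = it[, "x"], y = it[, "y"],
                    mx = it[, "mx"], my = it[, "my"], owner = NA_integer_)
  e <- field_at(rec, src, cfg$kappa, cfg$r_min_cm)
  expect_equal(passive_channels(w3, 1), sqrt(rowSums(e^2)), tolerance = 1e-12)
})

test_that("knollenorgan bins conspecific pulses by egocentric bearing", {
  cfg <- small_config(n_agents = 2)
  w <- manual_world(cfg, rbind(c(50, 50, 0), c(70, 50, 0)))
  # silent conspecific: zero vector
  expect_identical(knollenorgan_channels(w, 1), numeric(cfg$n_ko_bins))
  w$agents[2, "eod"] <- 1
  # geometry oracle over random placements
  set.seed(31)
  for (rep in 1:40) {
    d <- runif(1, 3, cfg$comm_radius_cm - 1)
    ang <- runif(1, 0, 2 * pi)
    hd <- runif(1, 0, 2 * pi)
    w$agents[1, "heading"] <- hd
    w$agents[2, c("x", "y")] <- c(50 + d * cos(ang), 50 + d * sin(ang))
    ko <- knollenorgan_channels(w, 1)
    rel <- (ang - hd) %% (2 * pi)
    bin <- min(floor(rel / (2 * pi / cfg$n_ko_bins)) + 1, cfg$n_ko_bins)
    expect_equal(ko[bin], cfg$knollenorgan_amplitude / max(d, cfg$r_min_cm)^2,
                 tolerance = 1e-12)
    expect_equal(sum(ko > 0), 1L)
  }
  # just beyond the communication radius: silence
  w$agents[1, "heading"] <- 0
  w$agents[2, c("x", "y")] <- c(50 + cfg$comm_radius_cm + 0.1, 50)
  expect_identical(knollenorgan_channels(w, 1), numeric(cfg$n_ko_bins))
  # own EODs are never heard
  w$agents[1, "eod"] <- 1
  w$agents[2, "eod"] <- 0
  expect_identical(knollenorgan_channels(w, 1), numeric(cfg$n_ko_bins))
  # disabled sensor: zero block regardless of pulses
  cfg2 <- small_config(n_agents = 2, knollenorgan_enabled = FALSE)
  w2 <- manual_world(cfg2, rbind(c(50, 50, 0), c(60, 50, 0)))
  w2$agents[2, "eod"] <- 1
  expect_identical(knollenorgan_channels(w2, 1), numeric(cfg2$n_ko_bins))
})

test_that("observation vector has fixed layout and block isolation", {
  cfg <- small_config(n_agents = 2)
  lay <- obs_layout(cfg)
  expect_identical(obs_dim(cfg), 2L * cfg$n_receptors + cfg$n_ko_bins + 3L)
  w <- manual_world(cfg, rbind(c(50, 50, 0), c(58, 50, 0)))
  # all-silent empty world: zeros except proprioception
  obs <- assemble_observation(w, 1)
  expect_true(all(obs[c(lay$active, lay$passive, lay$knollenorgan)] == 0))
  # toggling the knollenorgan changes exactly its block
  w$agents[2, "eod"] <- 1
  w$agents[1, "eod"] <- 1
  obs_on <- assemble_observation(w, 1)
  cfg_off <- small_config(n_agents = 2, knollenorgan_enabled = FALSE)
  w_off <- w; w_off$config <- cfg_off
  obs_off <- assemble_observation(w_off, 1)
  expect_true(all(obs_off[lay$knollenorgan] == 0))
  expect_false(all(obs_on[lay$knollenorgan] == 0))
  expect_equal(obs_on[-lay$knollenorgan], obs_off[-lay$knollenorgan])
  # signed-log compression applied: a large raw magnitude is compressed
  raw_ko <- knollenorgan_channels(w, 1)
  expect_equal(obs_on[lay$knollenorgan],
               sign(raw_ko) * log1p(abs(raw_ko) / cfg$obs_log_scale))
})

test_that("observations are egocentric: rotating world + agent changes nothing", {
  # arbitrary rotation with reflections disabled (no wall geometry involved)
  cfg <- small_config(n_agents = 2, reflections_enabled = FALSE)
  rot <- function(p, th, c0 = c(50, 50))
    c0 + c(cos(th) * (p[1] - c0[1]) - sin(th) * (p[2] - c0[2]),
           sin(th) * (p[1] - c0[1]) + cos(th) * (p[2] - c0[2]))
  build <- function(th) {
    a1 <- rot(c(58, 46), th); a2 <- rot(c(43, 55), th)
    i1 <- rot(c(54, 50), th); m1 <- rot(c(50 + 2, 50 + 1), th) - rot(c(50, 50), th)
    w <- manual_world(cfg, rbind(c(a1, 0.7 + th), c(a2, 2.1 + th)),
                      cbind(x = i1[1], y = i1[2], patch = 1,
                            mx = m1[1], my = m1[2]))
    w$agents[, "eod"] <- 1
    w
  }
  base <- assemble_observation(build(0), 1)
  for (th in c(0.3, 1.2, 2.5)) {
    expect_equal(assemble_observation(build(th), 1), base, tolerance = 1e-8)
  }
  # quarter-turn rotation of the full square arena with reflections on:
  # exact symmetry including images
  cfg2 <- small_config(n_agents = 2, reflections_enabled = TRUE)
  rot90 <- function(p) c(100 - p[2], p[1])
  w0 <- manual_world(cfg2, rbind(c(58, 46, 0.7), c(43, 55, 2.1)),
                     cbind(x = 54, y = 50, patch = 1, mx = 2, my = 1))
  w0$agents[, "eod"] <- 1
  a1 <- rot90(c(58, 46)); a2 <- rot90(c(43, 55)); i1 <- rot90(c(54, 50))
  w1 <- manual_world(cfg2, rbind(c(a1, 0.7 + pi / 2), c(a2, 2.1 + pi / 2)),
                     cbind(x = i1[1], y = i1[2], patch = 1, mx = -1, my = 2))
  w1$agents[, "eod"] <- 1
  expect_equal(assemble_observation(w1, 1), assemble_observation(w0, 1),
               tolerance = 1e-8)
})

test_that("collective sensing lets a silent agent see through a neighbor's EOD", {
  base <- function(cs) small_config(n_agents = 2,
                                    collective_sensing_enabled = cs,
                                    reflections_enabled = FALSE)
  mk <- function(cs) {
    w <- manual_world(base(cs), rbind(c(50, 50, 0), c(60, 50, 0)),
                      cbind(x = 55, y = 52, patch = 1, mx = 0, my = 0))
    w$agents[2, "eod"] <- 1  # neighbor discharges near the food item
    w
  }
  on <- active_channels(mk(TRUE), 1)
  off <- active_channels(mk(FALSE), 1)
  expect_gt(max(abs(on)), 0)
  expect_identical(off, numeric(8))
})
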