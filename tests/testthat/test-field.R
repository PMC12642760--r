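test_that("single-dipole field matches the closed form on- and off-axis", {
  src <- emitter_source(agent_pose(0, 0, 0), amplitude = 3)
  # on-axis: E = 2 kappa p / r^3 along the moment
  for (r in c(2, 5, 20)) {
    e <- field_at(rbind(c(r, 0)), src, kappa = 1, r_min = 1)
    expect_equal(e[1, 1], 2 * 3 / r^3, tolerance = 1e-12)
    expect_equal(e[1, 2], 0, tolerance = 1e-15)
  }
  # broadside: E = -kappa p / r^3
  e <- field_at(rbind(c(0, 10)), src)
  expect_equal(e[1, ], c(-3 / 1000, 0), tolerance = 1e-12)
  # heading rotates the moment
  s90 <- emitter_source(agent_pose(0, 0, pi / 2), 3)
  expect_equal(c(s90$mx, s90$my), c(0, 3), tolerance = 1e-15)
  # zero amplitude: zero field everywhere
  s0 <- emitter_source(agent_pose(0, 0, 1.2), 0)
  expect_equal(field_at(rbind(c(3, 4), c(-1, 7)), s0),
               matrix(0, 2, 2))
  # emitter requires an actual discharge
  quiet <- agent_pose(0, 0, 0); quiet$eod <- 0L
  expect_error(emitter_source(quiet, 1), "did not emit")
})

test_that("superposition holds against a brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(1:6, 1)
    src <- field_sources <- data.frame(
      kind = "emitter", x = runif(n, 0, 100), y = runif(n, 0, 100),
      mx = rnorm(n), my = rnorm(n), owner = NA_integer_)
    pts <- cbind(runif(4, 0, 100), runif(4, 0, 100))
    expect_equal(field_at(pts, src), oracle_dipole_field(pts, src),
                 tolerance = 1e-12)
    # field of the set equals the sum of single-source fields
    single <- Reduce(`+`, lapply(seq_len(n), function(j)
      field_at(pts, src[j, ])))
    expect_equal(field_at(pts, src), single, tolerance = 1e-12)
  }
})

test_that("induced dipoles are linear in polarizability and field", {
  em <- emitter_source(agent_pose(10, 10, 0.3), 5)
  obj <- data.frame(x = c(20, 30, 15), y = c(12, 25, 40),
                    alpha = c(2, 0, 1))
  ind <- induced_sources(em, obj)
  expect_equal(nrow(ind), 3)
  expect_equal(c(ind$mx[2], ind$my[2]), c(0, 0))  # alpha = 0
  # doubling alpha doubles the moment exactly
  obj2 <- obj; obj2$alpha <- obj$alpha * 2
  ind2 <- induced_sources(em, obj2)
  expect_equal(cbind(ind2$mx, ind2$my), 2 * cbind(ind$mx, ind$my))
  # direct oracle: alpha * field_at at each object
  e <- field_at(cbind(obj$x, obj$y), em)
  expect_equal(cbind(ind$mx, ind$my), obj$alpha * e, tolerance = 1e-12)
  # multiple emitters
  ems <- rbind(em, emitter_source(agent_pose(40, 5, 2), 3),
               emitter_source(agent_pose(5, 45, -1), 2))
  ind3 <- induced_sources(ems, obj)
  e3 <- field_at(cbind(obj$x, obj$y), ems)
  expect_equal(cbind(ind3$mx, ind3$my), obj$alpha * e3, tolerance = 1e-12)
})

test_that("image sources mirror geometry and cancel the wall-normal field", {
  cfg <- arena_config(width_cm = 100, height_cm = 80, n_patches = 0)
  src <- data.frame(kind = "emitter", x = 30, y = 40, mx = 2, my = 5,
                    owner = NA_integer_)
  img <- image_sources(src, cfg)
  expect_equal(nrow(img), 4)
  # left-wall image: mirrored position, normal moment negated
  expect_equal(c(img$x[1], img$y[1], img$mx[1], img$my[1]), c(-30, 40, -2, 5))
  # bottom-wall image: tangential preserved, normal negated
  expect_equal(c(img$x[3], img$y[3], img$mx[3], img$my[3]), c(30, -40, 2, -5))
  # boundary condition at the left wall (x = 0): source + its image only
  set.seed(7)
  wall_pts <- cbind(rep(0, 20), runif(20, 10, 70))
  both <- rbind(src, img[1, ])
  e <- field_at(wall_pts, both, r_min = 0.5)
  expect_lt(max(abs(e[, 1])) / max(sqrt(rowSums(e^2))), 1e-10)
})

test_that("snapshot assembles emitters, induced, and images per contract", {
  cfg <- small_config(n_agents = 2, reflections_enabled = TRUE)
  w <- world_reset(cfg, 9)
  w$agents[, "eod"] <- c(1, 0)
  snap <- field_snapshot(w)
  f <- nrow(w$food$items)
  # 1 emitter + (F food + 1 other body) induced + 4 * (all of those) images
  n_base <- 1L + f + 1L
  expect_equal(nrow(snap$sources), n_base * 5L)
  expect_equal(sum(snap$sources$kind == "emitter"), 1L)
  expect_equal(sum(snap$sources$kind == "induced"), f + 1L)
  expect_equal(sum(snap$sources$kind == "image"), 4L * n_base)
  # no discharge: empty snapshot
  w$agents[, "eod"] <- 0
  expect_identical(nrow(field_snapshot(w)$sources), 0L)
  # snapshot field equals a hand-assembled source list
  w$agents[, "eod"] <- c(1, 0)
  set.seed(1)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  em <- emitter_source(list(x = w$agents[1, "x"], y = w$agents[1, "y"],
                            heading = w$agents[1, "heading"], agent_id = 1L,
                            eod = 1L), cfg$eod_amplitude)
  objs <- data.frame(x = c(w$food$items[, "x"], w$agents[2, "x"]),
                     y = c(w$food$items[, "y"], w$agents[2, "y"]),
                     alpha = c(rep(cfg$alpha_food, f), cfg$alpha_body))
  ind <- induced_sources(em, objs, cfg$kappa, cfg$r_min_cm)
  base <- rbind(em, ind)
  hand <- rbind(base, image_sources(base, cfg))
  expect_equal(field_at(pts, snap$sources, cfg$kappa, cfg$r_min_cm),
               field_at(pts, hand, cfg$kappa, cfg$r_min_cm),
               tolerance = 1e-12)
})

test_that("field magnitude decays monotonically and the grid peaks at the emitter", {
  src <- emitter_source(agent_pose(100, 100, 0.7), 10)
  d <- seq(2, 60, by = 1)
  for (ang in c(0, 0.9, 2.2)) {
    mags <- sqrt(rowSums(field_at(cbind(100 + d * cos(ang),
                                        100 + d * sin(ang)), src)^2))
    expect_true(all(diff(mags) < 0))
  }
  cfg <- arena_config(width_cm = 200, height_cm = 200, n_patches = 0)
  g <- render_grid(src, cfg, resolution = 81)
  peak <- which(g$z == max(g$z), arr.ind = TRUE)
  cell <- 200 / 80
  expect_lte(abs(g$x[peak[1]] - 100), cell + 1e-9)
  expect_lte(abs(g$y[peak[2]] - 100), cell + 1e-9)
  # linearity: doubling all moments doubles every grid value
  src2 <- src; src2$mx <- src2$mx * 2; src2$my <- src2$my * 2
  g2 <- render_grid(src2, cfg, resolution = 81)
  expect_equal(g2$z, 2 * g$z, tolerance = 1e-12)
  # empty snapshot renders an all-zero grid
  empty <- structure(list(step = 0L,
                          sources = src[0, ]), class = "field_snapshot")
  expect_true(all(render_grid(empty, cfg, 8)$z == 0))
  expect_error(render_grid(src, cfg, resolution = 1), "resolution")
})
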