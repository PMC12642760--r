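test_that("SPI extraction reduces to diffs of flagged steps", {
  sp <- synthetic_trace_spec(1, 20, eod = list(list(
    type = "scripted", pattern = "00000000010100010000")))
  tr <- generate_synthetic_trace(sp)
  spi <- extract_spi(tr, 1)
  expect_identical(spi$eod_steps, c(10L, 12L, 16L))
  expect_equal(spi$intervals_s, c(0.08, 0.16))
  # boundary: one or zero discharges give an empty interval list
  sp2 <- synthetic_trace_spec(1, 10, eod = list(list(type = "scripted",
                                                     pattern = "0000100000")))
  expect_length(extract_spi(generate_synthetic_trace(sp2), 1)$intervals_s, 0)
  expect_error(extract_spi(tr, 5), "no agent")
  # random train matches a brute-force diff oracle
  sp3 <- synthetic_trace_spec(1, 5000, eod = list(list(type = "bernoulli",
                                                       p = 0.15)), seed = 2)
  tr3 <- generate_synthetic_trace(sp3)
  a <- tr3$actions[tr3$actions$agent_id == 1, ]
  oracle <- diff(sort(a$step[a$eod == 1])) * tr3$config$dt_s
  expect_equal(extract_spi(tr3, 1)$intervals_s, oracle)
})

test_that("tail fit recovers exponential slope and flags mixture tails", {
  s <- rng_stream(77, "tailfit")
  mu <- 8
  x <- with_stream(s, rexp(1e4, mu))
  fit <- fit_spi_tail(spi_series(x))
  expect_lt(abs(fit$slope + mu) / mu, 0.05)
  expect_lt(fit$excess_mass, 0.05)
  # two-exponential mixture (rates 10 and 0.5, weights 0.9/0.1): heavy tail
  xm <- with_stream(s, {
    comp <- runif(1e4) < 0.9
    ifelse(comp, rexp(1e4, 10), rexp(1e4, 0.5))
  })
  fitm <- fit_spi_tail(spi_series(xm))
  expect_gt(fitm$excess_mass, 0.5)
  expect_lt(fitm$slope, 0)
  # degenerate constant train: finite slope, no error
  fitc <- fit_spi_tail(spi_series(rep(0.2, 100)))
  expect_true(is.finite(fitc$slope))
  expect_lt(fitc$slope, 0)
  expect_error(fit_spi_tail(spi_series(rexp(10, 1))), "at least 50")
  # tidy/glance accessors
  expect_identical(glance(fit)$slope, fit$slope)
  td <- tidy(fitm)
  expect_true(all(c("interval_s", "log_survival", "fitted") %in% names(td)))
})

test_that("EOD probability is the per-range discharge fraction", {
  mk <- function(pattern) generate_synthetic_trace(synthetic_trace_spec(
    1, nchar(pattern), eod = list(list(type = "scripted", pattern = pattern))))
  expect_identical(eod_probability(mk("000000"))$eod_prob, 0)
  expect_identical(eod_probability(mk("111111"))$eod_prob, 1)
  tr <- mk("0101100100")
  expect_equal(eod_probability(tr)$eod_prob, 4 / 10)
  expect_equal(eod_probability(tr, steps = 1:4)$eod_prob, 2 / 4)
  expect_error(eod_probability(tr, steps = 100:200), "empty step range")
  # pooled bootstrap over episodes is seeded and bounded
  traces <- lapply(1:6, function(k) generate_synthetic_trace(
    synthetic_trace_spec(1, 500, eod = list(list(type = "bernoulli",
                                                 p = 0.1 + 0.02 * k)),
                         seed = k)))
  pl <- pooled_eod_probability(traces, n_boot = 200, seed = 1)
  expect_lt(pl$ci_lo, pl$mean); expect_gt(pl$ci_hi, pl$mean)
  expect_identical(pl, pooled_eod_probability(traces, n_boot = 200, seed = 1))
})

test_that("displacement windows measure start-to-end distance per window", {
  # stationary agent: all zeros
  tr <- generate_synthetic_trace(synthetic_trace_spec(1, 50))
  dw <- displacement_windows(tr, window_steps = 9)
  expect_true(all(dw$displacement_cm == 0))
  # straight line at constant speed: v * window * dt each
  sp <- synthetic_trace_spec(1, 100, trajectory = list(list(
    type = "straight", from = c(0, 50), heading = 0, speed_cms = 10)),
    config = arena_config(n_agents = 1, max_steps = 100, n_patches = 0,
                          width_cm = 1000, height_cm = 100))
  tr2 <- generate_synthetic_trace(sp)
  dw2 <- displacement_windows(tr2, window_steps = 9)
  expect_equal(dw2$displacement_cm,
               rep(10 * 9 * 0.04, nrow(dw2)), tolerance = 1e-9)
  # the default window spans 0.36 s at the default timestep
  expect_equal(9 * tr2$config$dt_s, 0.36)
  # windows are non-overlapping and contiguous
  expect_equal(diff(dw2$t_start), rep(9, nrow(dw2) - 1))
})

test_that("Theil index attains its analytic extremes and matches a dual implementation", {
  expect_equal(theil_index(c(3, 3, 3, 3)), 0)
  expect_equal(theil_index(c(1, 0, 0, 0)), log(4), tolerance = 1e-12)
  expect_error(theil_index(c(0, 0)), "all-zero")
  expect_error(theil_index(c(-1, 2)), "negative")
  set.seed(14)
  for (k in 1:1000) {
    x <- rgamma(sample(2:12, 1), shape = 0.7)
    ti <- theil_index(x)
    expect_equal(ti, oracle_theil(x), tolerance = 1e-12)
    expect_gte(ti, -1e-12)
    expect_lte(ti, log(length(x)) + 1e-12)
  }
})

test_that("motif mining equals exhaustive enumeration on random traces", {
  for (seed in 1:6) {
    n_ag <- sample(2:4, 1)
    # random walks that wander in and out of interaction range
    sp <- synthetic_trace_spec(
      n_ag, 200,
      eod = list(list(type = "bernoulli", p = 0.3)),
      trajectory = lapply(seq_len(n_ag), function(i)
        list(type = "waypoints",
             points = cbind(runif(8, 40, 70), runif(8, 40, 70)),
             speed_cms = 15)),
      seed = seed)
    tr <- generate_synthetic_trace(sp)
    mt <- mine_social_motifs(tr, top_k = 1e6)
    oracle <- oracle_motifs(tr)
    expect_identical(sum(mt$count), sum(unlist(oracle)))
    for (r in seq_len(nrow(mt))) {
      key <- paste(mt$motif_a[r], mt$motif_b[r], sep = "|")
      expect_identical(as.integer(mt$count[r]), as.integer(oracle[[key]]))
    }
  }
  # no interaction: empty table; too-short window contributes nothing
  far <- generate_synthetic_trace(synthetic_trace_spec(2, 100))
  expect_identical(nrow(mine_social_motifs(far)), 0L)
  short <- generate_synthetic_trace(synthetic_trace_spec(
    2, 50, interactions = list(list(pair = c(1, 2), start = 10, end = 12))))
  expect_identical(nrow(mine_social_motifs(short)), 0L)
})

test_that("freeloading scores capture planted EOD-rate asymmetry", {
  # both silent: 0; one silent, one active: 1
  mk <- function(pa, pb) generate_synthetic_trace(synthetic_trace_spec(
    2, 400, eod = list(list(type = "bernoulli", p = pa),
                       list(type = "bernoulli", p = pb)),
    interactions = list(list(pair = c(1, 2), start = 1, end = 400,
                             distance_cm = 10)), seed = 5))
  silent <- mk(0, 0)
  expect_equal(freeloading_scores(silent)$score, 0)
  onesided <- mk(0.4, 0)
  expect_equal(freeloading_scores(onesided)$score, 1)
  # planted 3:1 asymmetry: score -> |3p - p| / (3p + p) = 0.5
  asym <- mk(0.3, 0.1)
  expect_lt(abs(freeloading_scores(asym)$score - 0.5), 0.1)
})

test_that("SPI condition comparison detects a planted interval shift", {
  mk <- function(p, seed) generate_synthetic_trace(synthetic_trace_spec(
    1, 3000, eod = list(list(type = "bernoulli", p = p)), seed = seed))
  slow <- lapply(1:3, function(k) mk(0.08, k))        # longer intervals
  fast <- lapply(1:3, function(k) mk(0.25, 10 + k))   # shorter intervals
  cmp <- compare_spi_conditions(slow, fast, "cs", "no_cs")
  expect_gt(cmp$median_a, cmp$median_b)
  expect_lt(cmp$p_value, 0.01)
})

test_that("analytics are pure functions of the trace", {
  sp <- synthetic_trace_spec(2, 300,
    eod = list(list(type = "bernoulli", p = 0.2)),
    interactions = list(list(pair = c(1, 2), start = 100, end = 160,
                             distance_cm = 12)), seed = 3)
  tr <- generate_synthetic_trace(sp)
  expect_identical(mine_social_motifs(tr), mine_social_motifs(tr))
  expect_identical(freeloading_scores(tr), freeloading_scores(tr))
  expect_identical(displacement_windows(tr), displacement_windows(tr))
  expect_identical(extract_spi(tr, 2), extract_spi(tr, 2))
})
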