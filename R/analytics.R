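# Behavioral analytics over episode traces: SPI distributions and
# heavy-tail fits, condition-wise EOD probabilities, displacement windows,
# Theil inequality, social EOD motifs, and freeloading metrics.  All
# functions are pure functions of their trace inputs.

#' @importFrom rlang .data
NULL

#' Extract the sequential pulse interval (SPI) series of an agent
#'
#' Collects the step indices where the agent discharged and the intervals
#' between successive discharges in seconds (`diff(steps) * dt_s`).
#'
#' @param trace An `episode_trace`.
#' @param agent_id Agent index.
#' @return A list of class `spi_series`: `agent_id`, `eod_steps`,
#'   `intervals_s`, `dt_s`.
#' @export
#' @examples
#' sp <- synthetic_trace_spec(1, 20,
#'   eod = list(list(type = "scripted", pattern = "00000000010100010000")))
#' extract_spi(generate_synthetic_trace(sp), 1)$intervals_s
extract_spi <- function(trace, agent_id) {
  stopifnot(inherits(trace, "episode_trace"))
  if (!agent_id %in% unique(trace$actions$agent_id))
    stop("extract_spi(): no agent ", agent_id, " in trace", call. = FALSE)
  a <- trace$actions[trace$actions$agent_id == agent_id, ]
  steps <- sort(a$step[a$eod == 1])
  spi_series(diff(steps) * trace$config$dt_s, agent_id = agent_id,
             eod_steps = steps, dt_s = trace$config$dt_s)
}

#' Construct an SPI series from raw intervals
#'
#' @param intervals_s Positive interval samples (seconds).
#' @param agent_id,eod_steps,dt_s Optional provenance metadata.
#' @return An `spi_series`.
#' @export
spi_series <- function(intervals_s, agent_id = NA_integer_,
                       eod_steps = NULL, dt_s = NA_real_) {
  stopifnot(all(intervals_s > 0))
  structure(list(agent_id = agent_id, eod_steps = eod_steps,
                 intervals_s = as.numeric(intervals_s), dt_s = dt_s),
            class = "spi_series")
}

#' Fit the tail of an SPI distribution on the log-survival scale
#'
#' Computes the empirical survival function of the intervals, fits a
#' least-squares line to `log S(t)` over intervals below the
#' `cut_quantile` quantile, and measures `excess_mass`: the mean positive
#' deviation of the empirical log-survival above the fitted line beyond the
#' cut.  For exponential intervals with rate `mu` the slope estimates
#' `-mu` and the excess mass is ~0; a heavy (e.g. mixture-of-exponentials)
#' tail produces positive excess mass.
#'
#' @param spi An `spi_series` (needs >= 50 intervals).
#' @param cut_quantile Fit/tail split quantile (default 0.9).
#' @return A list of class `spi_tail_fit`: `bin_centers_s`, `log_survival`,
#'   `slope`, `intercept`, `excess_mass`, `cut_value_s`, `n_intervals`.
#' @export
fit_spi_tail <- function(spi, cut_quantile = 0.9) {
  stopifnot(inherits(spi, "spi_series"))
  x <- sort(spi$intervals_s)
  n <- length(x)
  if (n < 50)
    stop("fit_spi_tail(): need at least 50 intervals, got ", n, call. = FALSE)
  tu <- unique(x)
  surv <- vapply(tu, function(t) mean(x > t), numeric(1))
  keep <- surv > 0
  tu <- tu[keep]; ls <- log(surv[keep])
  cut <- stats::quantile(x, cut_quantile, names = FALSE)
  fit_pts <- tu <= cut
  if (sum(fit_pts) >= 2L) {
    co <- stats::coef(stats::lm(ls[fit_pts] ~ tu[fit_pts]))
    intercept <- co[[1]]; slope <- co[[2]]
  } else {
    # degenerate train (e.g. constant intervals): fall back to the
    # exponential with the same mean
    slope <- -1 / mean(x); intercept <- 0
  }
  tail_pts <- tu > cut
  excess <- if (any(tail_pts))
    mean(pmax(ls[tail_pts] - (intercept + slope * tu[tail_pts]), 0))
  else 0
  structure(list(bin_centers_s = tu, log_survival = ls,
                 slope = unname(slope), intercept = unname(intercept),
                 excess_mass = excess, cut_quantile = cut_quantile,
                 cut_value_s = cut, n_intervals = n),
            class = "spi_tail_fit")
}

#' @export
print.spi_tail_fit <- function(x, ...) {
  cat(sprintf("<spi_tail_fit> n = %d, slope = %.3f /s, excess mass = %.4f\n",
              x$n_intervals, x$slope, x$excess_mass))
  invisible(x)
}

#' Per-episode, per-agent EOD probability
#'
#' Fraction of steps with an EOD over a step range, per agent and episode.
#'
#' @param traces An `episode_trace` or a list of them (episodes).
#' @param agent_ids Agents to include (default all).
#' @param steps Optional step range (integer vector).
#' @return Tibble with columns `episode`, `agent_id`, `eod_prob`, `n_steps`.
#' @export
eod_probability <- function(traces, agent_ids = NULL, steps = NULL) {
  if (inherits(traces, "episode_trace")) traces <- list(traces)
  dplyr::bind_rows(lapply(seq_along(traces), function(k) {
    a <- traces[[k]]$actions
    if (!is.null(steps)) {
      a <- a[a$step %in% steps, ]
      if (!nrow(a)) stop("eod_probability(): empty step range", call. = FALSE)
    }
    if (!is.null(agent_ids)) a <- a[a$agent_id %in% agent_ids, ]
    a |>
      dplyr::group_by(.data$agent_id) |>
      dplyr::summarise(eod_prob = mean(.data$eod), n_steps = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(episode = k, .before = 1)
  }))
}

#' Pooled EOD probability with a bootstrap confidence interval
#'
#' Pools per-episode means (the bootstrap unit is the episode) and
#' resamples episodes with replacement.
#'
#' @inheritParams eod_probability
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return One-row tibble: `mean`, `ci_lo`, `ci_hi`, `n_episodes`.
#' @export
pooled_eod_probability <- function(traces, agent_ids = NULL, steps = NULL,
                                   n_boot = 1000, seed = 0L, conf = 0.95) {
  per <- eod_probability(traces, agent_ids, steps) |>
    dplyr::group_by(.data$episode) |>
    dplyr::summarise(p = mean(.data$eod_prob), .groups = "drop")
  s <- rng_stream(seed, "eod_bootstrap")
  bs <- with_stream(s, vapply(seq_len(n_boot), function(i)
    mean(sample(per$p, replace = TRUE)), numeric(1)))
  qs <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  tibble::tibble(mean = mean(per$p), ci_lo = qs[1], ci_hi = qs[2],
                 n_episodes = nrow(per))
}

#' Per-window agent displacement
#'
#' Splits each agent's trajectory into consecutive non-overlapping windows
#' of `window_steps` steps and reports the Euclidean distance between the
#' first and last position of each window.  At the default timestep
#' (0.04 s) the default window of 9 steps spans 0.36 s.
#'
#' @param trace An `episode_trace`.
#' @param window_steps Window length in steps (>= 1).
#' @return Tibble: `agent_id`, `window`, `t_start`, `displacement_cm`.
#' @export
displacement_windows <- function(trace, window_steps = 9) {
  stopifnot(window_steps >= 1)
  trace$states |>
    dplyr::group_by(.data$agent_id) |>
    dplyr::arrange(.data$step, .by_group = TRUE) |>
    dplyr::reframe({
      x <- .data$x; y <- .data$y; stp <- .data$step
      n <- length(x)
      if (n <= window_steps) {
        tibble::tibble(window = integer(), t_start = integer(),
                       displacement_cm = numeric())
      } else {
        starts <- seq(1L, n - window_steps, by = window_steps)
        ends <- starts + window_steps
        tibble::tibble(window = seq_along(starts),
                       t_start = stp[starts],
                       displacement_cm = sqrt((x[ends] - x[starts])^2 +
                                                (y[ends] - y[starts])^2))
      }
    })
}

#' Theil index of consumption inequality
#'
#' `T = (1/N) * sum((x_i / mu) * log(x_i / mu))` with `0 * log(0) := 0`.
#' Ranges from 0 (perfect equality) to `log(N)` (all consumption by one
#' agent).
#'
#' @param consumption Non-negative per-agent consumption tallies, at least
#'   one strictly positive.
#' @return The index (scalar).
#' @export
#' @examples
#' theil_index(c(1, 1, 1, 1))  # 0
#' theil_index(c(1, 0, 0, 0))  # log(4)
theil_index <- function(consumption) {
  x <- as.numeric(consumption)
  if (any(x < 0)) stop("theil_index(): negative consumption", call. = FALSE)
  if (!any(x > 0))
    stop("theil_index(): undefined for all-zero consumption", call. = FALSE)
  mu <- mean(x)
  r <- x / mu
  mean(ifelse(r > 0, r * log(r), 0))
}

#' Pairwise interaction windows
#'
#' Maximal runs of consecutive steps during which a pair of agents stays
#' within `dist_thresh_cm`, kept if at least `min_len_steps` long.
#'
#' @param trace An `episode_trace` with >= 2 agents.
#' @param dist_thresh_cm Interaction distance threshold (cm).
#' @param min_len_steps Minimum run length (steps).
#' @return Tibble: `agent_a` < `agent_b`, `start`, `end`, `length`.
#' @export
interaction_windows <- function(trace, dist_thresh_cm = 15,
                                min_len_steps = 4) {
  st <- trace$states
  agents <- sort(unique(st$agent_id))
  if (length(agents) < 2)
    stop("interaction_windows(): need at least 2 agents", call. = FALSE)
  pos <- lapply(agents, function(i) {
    s <- st[st$agent_id == i, ]
    s[order(s$step), c("x", "y")]
  })
  out <- list()
  for (ii in seq_along(agents)) for (jj in seq_along(agents)) {
    if (jj <= ii) next
    d <- sqrt((pos[[ii]]$x - pos[[jj]]$x)^2 + (pos[[ii]]$y - pos[[jj]]$y)^2)
    r <- rle(d <= dist_thresh_cm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len_steps
    if (any(keep))
      out[[length(out) + 1L]] <- tibble::tibble(
        agent_a = agents[ii], agent_b = agents[jj],
        start = starts[keep], end = ends[keep],
        length = r$lengths[keep])
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(agent_a = integer(), agent_b = integer(),
                      start = integer(), end = integer(), length = integer())
}

#' Mine pairwise social EOD motifs
#'
#' A social EOD motif is the joint binary EOD pattern of two agents over a
#' `motif_len`-step window inside an interaction window (pair within
#' `dist_thresh_cm` for at least `min_len_steps` consecutive steps).  A
#' window of length `motif_len` slides over each interaction window; each
#' position yields an ordered pair of binary strings, canonicalized so the
#' lexicographically smaller string comes first.  Patterns are counted and
#' the `top_k` most common returned.
#'
#' @inheritParams interaction_windows
#' @param motif_len Motif window length (steps).
#' @param top_k Number of motifs to return.
#' @return Tibble of class `motif_table`: `motif_a`, `motif_b`, `count`,
#'   `rank` (count-descending, ties broken lexicographically); parameters
#'   attached as attributes.
#' @export
mine_social_motifs <- function(trace, dist_thresh_cm = 15, min_len_steps = 4,
                               motif_len = 4, top_k = 6) {
  wins <- interaction_windows(trace, dist_thresh_cm, min_len_steps)
  eods <- trace$actions |>
    dplyr::arrange(.data$agent_id, .data$step)
  train <- split(eods$eod, eods$agent_id)
  counts <- new.env(parent = emptyenv())
  if (nrow(wins)) for (w in seq_len(nrow(wins))) {
    ta <- train[[as.character(wins$agent_a[w])]]
    tb <- train[[as.character(wins$agent_b[w])]]
    lo <- wins$start[w]; hi <- wins$end[w]
    if (hi - lo + 1L < motif_len) next
    for (t0 in lo:(hi - motif_len + 1L)) {
      sa <- paste(ta[t0:(t0 + motif_len - 1L)], collapse = "")
      sb <- paste(tb[t0:(t0 + motif_len - 1L)], collapse = "")
      key <- if (sa <= sb) paste(sa, sb, sep = "|") else paste(sb, sa, sep = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  tab <- if (length(keys)) {
    cnt <- vapply(keys, function(k) counts[[k]], integer(1))
    parts <- strsplit(keys, "|", fixed = TRUE)
    tibble::tibble(motif_a = vapply(parts, `[`, "", 1),
                   motif_b = vapply(parts, `[`, "", 2),
                   count = cnt) |>
      dplyr::arrange(dplyr::desc(.data$count), .data$motif_a, .data$motif_b) |>
      utils::head(top_k) |>
      dplyr::mutate(rank = dplyr::row_number())
  } else {
    tibble::tibble(motif_a = character(), motif_b = character(),
                   count = integer(), rank = integer())
  }
  structure(tab, class = c("motif_table", class(tab)),
            dist_thresh_cm = dist_thresh_cm, min_len_steps = min_len_steps,
            motif_len = motif_len)
}

#' Per-window freeloading (EOD-rate asymmetry) scores
#'
#' Within each interaction window, compares the two agents' EOD rates:
#' `|rate_a - rate_b| / (rate_a + rate_b)` (0 when both are silent).  A
#' score near 1 means one agent discharges while the other stays silent —
#' the freeloading signature under collective sensing.
#'
#' @inheritParams interaction_windows
#' @return Tibble: window columns plus `rate_a`, `rate_b`, `score`.
#' @export
freeloading_scores <- function(trace, dist_thresh_cm = 15,
                               min_len_steps = 4) {
  wins <- interaction_windows(trace, dist_thresh_cm, min_len_steps)
  eods <- trace$actions |> dplyr::arrange(.data$agent_id, .data$step)
  train <- split(eods$eod, eods$agent_id)
  if (!nrow(wins))
    return(dplyr::mutate(wins, rate_a = numeric(0), rate_b = numeric(0),
                         score = numeric(0)))
  wins |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rate_a = mean(train[[as.character(.data$agent_a)]][.data$start:.data$end]),
      rate_b = mean(train[[as.character(.data$agent_b)]][.data$start:.data$end]),
      score = if (.data$rate_a + .data$rate_b == 0) 0 else
        abs(.data$rate_a - .data$rate_b) / (.data$rate_a + .data$rate_b)) |>
    dplyr::ungroup()
}

#' Compare SPI distributions between two condition sets
#'
#' Pools the SPI intervals of all agents across the traces of each
#' condition and compares the two samples with a Wilcoxon rank-sum test.
#' Used to test the collective-sensing interval shift (intervals lengthen,
#' i.e. EOD rates drop, when agents can exploit neighbors' discharges).
#'
#' @param traces_a,traces_b Lists of `episode_trace` (or single traces).
#' @param label_a,label_b Condition labels for the output.
#' @return One-row tibble: medians, rank-sum statistic, p-value.
#' @export
compare_spi_conditions <- function(traces_a, traces_b,
                                   label_a = "A", label_b = "B") {
  pool <- function(traces) {
    if (inherits(traces, "episode_trace")) traces <- list(traces)
    unlist(lapply(traces, function(tr)
      unlist(lapply(unique(tr$actions$agent_id), function(i)
        extract_spi(tr, i)$intervals_s))))
  }
  a <- pool(traces_a); b <- pool(traces_b)
  wt <- stats::wilcox.test(a, b)
  tibble::tibble(condition_a = label_a, condition_b = label_b,
                 n_a = length(a), n_b = length(b),
                 median_a = stats::median(a), median_b = stats::median(b),
                 statistic = unname(wt$statistic), p_value = wt$p.value)
}
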