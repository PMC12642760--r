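# EpisodeTrace: the interchange format between the simulator and the
# analytics suite.  One table per record kind (states, actions, food), an
# optional observation matrix with a documented block layout, plus the
# arena config and episode seed.  The on-disk container is versioned RDS
# (exact round trip); a JSON-Lines export (one step per line) is provided
# for portability.

TRACE_SCHEMA_VERSION <- 1L

#' Construct an episode trace
#'
#' @param config The [arena_config()] the episode ran under.
#' @param seed Episode seed.
#' @param states Tibble: step, agent_id, x, y, heading, speed, dominance,
#'   eod, bite, food_eaten, reward (one row per step x agent).
#' @param actions Tibble: step, agent_id, thrust, turn, eod, bite, log_prob.
#' @param food Tibble: step, patch, items_remaining.
#' @param observations Optional numeric matrix (rows aligned with `states`)
#'   of observation vectors; block layout from [obs_layout()].
#' @param n_steps Number of executed steps.
#' @return A list of class `episode_trace`.
#' @export
episode_trace <- function(config, seed, states, actions, food,
                          observations = NULL, n_steps) {
  stopifnot(inherits(config, "arena_config"))
  need <- c("step", "agent_id", "x", "y", "heading", "speed", "dominance",
            "eod", "bite", "food_eaten", "reward")
  if (!all(need %in% names(states)))
    stop("episode_trace(): states is missing columns: ",
         paste(setdiff(need, names(states)), collapse = ", "), call. = FALSE)
  structure(list(schema_version = TRACE_SCHEMA_VERSION,
                 config = config, seed = as.integer(seed),
                 n_steps = as.integer(n_steps),
                 n_agents = config$n_agents,
                 states = tibble::as_tibble(states),
                 actions = tibble::as_tibble(actions),
                 food = tibble::as_tibble(food),
                 observations = observations,
                 obs_layout = obs_layout(config)),
            class = "episode_trace")
}

#' @export
print.episode_trace <- function(x, ...) {
  cat(sprintf("<episode_trace> %d agents x %d steps (dt %g s), seed %d%s\n",
              x$n_agents, x$n_steps, x$config$dt_s, x$seed,
              if (is.null(x$observations)) "" else ", with observations"))
  invisible(x)
}

#' Write / read an episode trace
#'
#' The container embeds an integer schema version; [read_trace()] rejects
#' unknown versions and corrupt files rather than guessing.  Round trip is
#' exact: `read_trace(write_trace(tr, p))` is identical to `tr`
#' field-for-field.
#'
#' @param trace An `episode_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "episode_trace"))
  saveRDS(trace, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- tryCatch(readRDS(path),
                 error = function(e) stop("read_trace(): cannot read '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (!inherits(tr, "episode_trace"))
    stop("read_trace(): '", path, "' is not an episode trace", call. = FALSE)
  if (!identical(tr$schema_version, TRACE_SCHEMA_VERSION))
    stop("read_trace(): unsupported trace schema version ",
         tr$schema_version, " (reader supports ", TRACE_SCHEMA_VERSION, ")",
         call. = FALSE)
  tr
}

#' Export / import a trace as JSON-Lines
#'
#' Line 1 is a header object (schema version, config, seed, n_steps);
#' every following line is one step holding that step's agent states,
#' actions, and food summaries.  Doubles are written at full precision, so
#' shared fields survive a round trip exactly up to floating-point text
#' representation.
#'
#' @param trace An `episode_trace`.
#' @param path Output path (`.jsonl`).
#' @export
export_trace_jsonl <- function(trace, path) {
  stopifnot(inherits(trace, "episode_trace"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- list(kind = "efish_trace_header",
                 schema_version = trace$schema_version,
                 config = unclass(trace$config), seed = trace$seed,
                 n_steps = trace$n_steps, n_agents = trace$n_agents)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (t in seq_len(trace$n_steps)) {
    line <- list(
      step = t,
      states = trace$states[trace$states$step == t, ],
      actions = trace$actions[trace$actions$step == t, ],
      food = trace$food[trace$food$step == t, ])
    writeLines(jsonlite::toJSON(line, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"), con)
  }
  invisible(path)
}

#' @rdname export_trace_jsonl
#' @return `import_trace_jsonl()` returns an `episode_trace` (without
#'   observation vectors, which the JSONL export does not carry).
#' @export
import_trace_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("import_trace_jsonl(): empty file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$kind, "efish_trace_header"))
    stop("import_trace_jsonl(): missing header line", call. = FALSE)
  if (!identical(as.integer(header$schema_version), TRACE_SCHEMA_VERSION))
    stop("import_trace_jsonl(): unsupported schema version ",
         header$schema_version, call. = FALSE)
  cfg <- do.call(arena_config,
                 header$config[setdiff(names(header$config), "scenario")])
  cfg$scenario <- header$config$scenario
  steps <- lapply(lines[-1], jsonlite::fromJSON)
  states <- dplyr::bind_rows(lapply(steps, function(s)
    tibble::as_tibble(s$states)))
  actions <- dplyr::bind_rows(lapply(steps, function(s)
    tibble::as_tibble(s$actions)))
  food <- dplyr::bind_rows(lapply(steps, function(s)
    if (length(s$food)) tibble::as_tibble(s$food)))
  episode_trace(config = cfg, seed = header$seed, states = states,
                actions = actions, food = food,
                n_steps = header$n_steps)
}
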