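# Forward model of the electric landscape.
#
# Sources are represented as a plain data.frame with columns
#   kind   : "emitter" | "induced" | "image" | "static"
#   x, y   : position (cm)
#   mx, my : dipole moment (field units * cm)
#   owner  : owning agent id (NA for food/static sources)
# "static" sources are the weak prey dipoles carried by food items (passive
# sensing); they are not part of an EOD snapshot but share the field law.

empty_sources <- function() {
  data.frame(kind = character(), x = double(), y = double(),
             mx = double(), my = double(), owner = integer())
}

field_sources <- function(kind, x, y, mx, my, owner = NA_integer_) {
  data.frame(kind = kind, x = x, y = y, mx = mx, my = my,
             owner = as.integer(owner))
}

#' Evaluate the electric field of a set of dipole sources
#'
#' Superposition of ideal point-dipole fields,
#' \deqn{E(r) = \kappa \frac{3(\hat r \cdot p)\hat r - p}{\max(|r|, r_{min})^3},}
#' with \eqn{r} the vector from source to evaluation point and a softening
#' radius \eqn{r_{min}} preventing the singularity at the source.
#'
#' @param points Numeric matrix (n x 2) of evaluation points (cm).
#' @param sources Source data.frame (see [emitter_source()]).
#' @param kappa Field constant (arbitrary units).
#' @param r_min Softening radius (cm).
#' @return Numeric matrix (n x 2) of field vectors.
#' @export
#' @examples
#' src <- emitter_source(agent_pose(10, 10, 0), amplitude = 1)
#' field_at(rbind(c(15, 10)), src)  # on-axis: magnitude 2*|p|/r^3
field_at <- function(points, sources, kappa = 1, r_min = 1) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (is.null(sources) || nrow(sources) == 0L)
    return(matrix(0, nrow(points), 2))
  .dipole_field_cpp(points,
                    cbind(sources$x, sources$y),
                    cbind(sources$mx, sources$my),
                    kappa, r_min)
}

field_magnitude_at <- function(points, sources, kappa = 1, r_min = 1) {
  e <- field_at(points, sources, kappa, r_min)
  sqrt(rowSums(e^2))
}

# --- matrix fast path (hot loop; no data.frame construction) ---------------
# pos, mom: n x 2 matrices.

.field_mat <- function(points, pos, mom, kappa, r_min) {
  if (is.null(pos) || nrow(pos) == 0L) return(matrix(0, nrow(points), 2))
  .dipole_field_cpp(points, pos, mom, kappa, r_min)
}

.fieldmag_mat <- function(points, pos, mom, kappa, r_min) {
  e <- .field_mat(points, pos, mom, kappa, r_min)
  sqrt(e[, 1]^2 + e[, 2]^2)
}

# first-order wall images: returns list(pos, mom) with 4n rows
.images_mat <- function(pos, mom, w, h) {
  x <- pos[, 1]; y <- pos[, 2]; mx <- mom[, 1]; my <- mom[, 2]
  list(pos = rbind(cbind(-x, y), cbind(2 * w - x, y),
                   cbind(x, -y), cbind(x, 2 * h - y)),
       mom = rbind(cbind(-mx, my), cbind(-mx, my),
                   cbind(mx, -my), cbind(mx, -my)))
}

# scatterer positions/polarizabilities as matrices (cf. field_scatterers)
.scatterers_mat <- function(world, emitter_owner, exclude_agent = NULL) {
  cfg <- world$config
  it <- world$food$items
  ag <- world$agents
  keep <- setdiff(seq_len(nrow(ag)), c(emitter_owner, exclude_agent))
  pos <- rbind(if (nrow(it)) cbind(it[, "x"], it[, "y"]),
               if (length(keep)) cbind(ag[keep, "x"], ag[keep, "y"]))
  alpha <- c(rep(cfg$alpha_food, nrow(it)), rep(cfg$alpha_body, length(keep)))
  list(pos = pos, alpha = alpha)
}

#' Minimal agent pose helper
#'
#' @param x,y Position (cm).
#' @param heading Heading angle (rad, CCW from +x).
#' @param agent_id Integer id.
#' @return A list with `x`, `y`, `heading`, `agent_id`, `eod`.
#' @export
agent_pose <- function(x, y, heading, agent_id = 1L) {
  list(x = x, y = y, heading = heading, agent_id = as.integer(agent_id),
       eod = 1L)
}

#' Dipole source of an emitted EOD
#'
#' The discharge is modeled as a point dipole at the agent's center with
#' moment along the head-to-tail body axis:
#' `amplitude * (cos(heading), sin(heading))`.
#'
#' @param agent An agent pose (list with `x`, `y`, `heading`, `agent_id`,
#'   `eod`), e.g. from [agent_pose()].
#' @param amplitude Dipole moment magnitude.
#' @return A one-row source data.frame.
#' @export
emitter_source <- function(agent, amplitude) {
  if (is.null(agent$eod) || agent$eod != 1L)
    stop("emitter_source(): agent did not emit an EOD this step", call. = FALSE)
  field_sources("emitter", agent$x, agent$y,
                amplitude * cos(agent$heading),
                amplitude * sin(agent$heading),
                owner = agent$agent_id)
}

#' Induced dipole sources on polarizable objects
#'
#' Each object (food item or conspecific body) acquires an induced dipole
#' moment `p = alpha * E(object position)` where `E` is the field of the
#' emitter sources alone (first Born approximation: objects do not
#' re-induce on each other, and images do not contribute to induction).
#'
#' @param emitters Emitter source data.frame.
#' @param objects Data.frame with columns `x`, `y`, `alpha` (polarizability)
#'   and optionally `owner`.
#' @param kappa,r_min Field constants, see [field_at()].
#' @return Source data.frame of kind `"induced"`, one row per object.
#' @export
induced_sources <- function(emitters, objects, kappa = 1, r_min = 1) {
  if (is.null(objects) || nrow(objects) == 0L) return(empty_sources())
  e <- field_at(cbind(objects$x, objects$y), emitters, kappa, r_min)
  field_sources("induced", objects$x, objects$y,
                objects$alpha * e[, 1], objects$alpha * e[, 2],
                owner = if ("owner" %in% names(objects)) objects$owner
                        else NA_integer_)
}

#' First-order image sources for the insulating arena walls
#'
#' For each source and each of the four walls of the rectangular arena, a
#' mirror source is placed by reflection across the wall plane with the
#' tangential moment component preserved and the normal component negated,
#' so the wall-normal field component cancels at the wall (insulating /
#' Neumann boundary).  First order only: no images of images.
#'
#' @param sources Source data.frame.
#' @param config An [arena_config()] (uses `width_cm`, `height_cm`).
#' @return Source data.frame of kind `"image"` with `4 * nrow(sources)` rows.
#' @export
image_sources <- function(sources, config) {
  if (is.null(sources) || nrow(sources) == 0L) return(empty_sources())
  w <- config$width_cm; h <- config$height_cm
  x <- sources$x; y <- sources$y; mx <- sources$mx; my <- sources$my
  own <- sources$owner
  rbind(
    field_sources("image", -x,        y,        -mx,  my, own),  # left  x=0
    field_sources("image", 2 * w - x, y,        -mx,  my, own),  # right x=w
    field_sources("image", x,        -y,         mx, -my, own),  # bottom y=0
    field_sources("image", x, 2 * h - y,         mx, -my, own)   # top   y=h
  )
}

# Scatterer table for a given set of emitters: food items plus the bodies of
# agents other than each emitter's owner.  For a single-owner emitter set the
# body of the owner is excluded entirely; `exclude_agent` additionally drops
# the focal receiver's own body (its receptors sit on that body).
field_scatterers <- function(world, emitter_owner, exclude_agent = NULL) {
  cfg <- world$config
  obs <- NULL
  if (nrow(world$food$items) > 0L) {
    it <- world$food$items
    obs <- data.frame(x = it[, "x"], y = it[, "y"],
                      alpha = cfg$alpha_food, owner = NA_integer_)
  }
  ag <- world$agents
  keep <- setdiff(seq_len(nrow(ag)), c(emitter_owner, exclude_agent))
  if (length(keep)) {
    bodies <- data.frame(x = ag[keep, "x"], y = ag[keep, "y"],
                         alpha = cfg$alpha_body, owner = as.integer(keep))
    obs <- rbind(obs, bodies)
  }
  if (is.null(obs)) data.frame(x = double(), y = double(),
                               alpha = double(), owner = integer())
  else obs
}

#' Assemble the field snapshot for the current step
#'
#' Collects emitter dipoles for every agent that discharged this step,
#' induced dipoles on all food items and on all other agents' bodies, and
#' (if `reflections_enabled`) first-order wall images of both.
#'
#' @param world A world state from [world_reset()] / [world_step()].
#' @return A list of class `field_snapshot` with elements `step` and
#'   `sources`.
#' @export
field_snapshot <- function(world) {
  cfg <- world$config
  ag <- world$agents
  emitting <- which(ag[, "eod"] == 1)
  src <- empty_sources()
  for (i in emitting) {
    em <- emitter_source(list(x = ag[i, "x"], y = ag[i, "y"],
                              heading = ag[i, "heading"],
                              agent_id = i, eod = 1L),
                         cfg$eod_amplitude)
    ind <- induced_sources(em, field_scatterers(world, emitter_owner = i),
                           cfg$kappa, cfg$r_min_cm)
    src <- rbind(src, em, ind)
  }
  if (cfg$reflections_enabled && nrow(src) > 0L)
    src <- rbind(src, image_sources(src, cfg))
  structure(list(step = world$t, sources = src), class = "field_snapshot")
}

#' Render the field magnitude on a regular grid
#'
#' Samples `|E|` of a snapshot's sources on a `resolution x resolution`
#' grid covering the arena; intended for visualization.
#'
#' @param snapshot A `field_snapshot` (or a source data.frame).
#' @param config An [arena_config()].
#' @param resolution Grid points per axis (>= 2).
#' @return A list with `x`, `y` (axis coordinates) and `z` (magnitude
#'   matrix, `z[i, j]` at `(x[i], y[j])`), class `field_grid`.
#' @export
render_grid <- function(snapshot, config, resolution = 64) {
  stopifnot(resolution >= 2)
  sources <- if (inherits(snapshot, "field_snapshot")) snapshot$sources
             else snapshot
  gx <- seq(0, config$width_cm, length.out = resolution)
  gy <- seq(0, config$height_cm, length.out = resolution)
  pts <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))
  mag <- field_magnitude_at(pts, sources, config$kappa, config$r_min_cm)
  structure(list(x = gx, y = gy,
                 z = matrix(mag, nrow = resolution, ncol = resolution)),
            class = "field_grid")
}
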