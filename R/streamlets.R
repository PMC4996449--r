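#' Seed a streamlet population
#'
#' The animated flow visualization advects a fixed-size population of
#' streamlets -- short, aging streamline segments -- through the
#' reconstructed velocity field. Seeding places `n` streamlets (450 by
#' default) at uniform-random points in a bounding box, with ages drawn
#' uniformly in `[0, max_age)` so deaths are staggered from the first frame.
#' Each streamlet gets its own lifespan, drawn uniformly from
#' `max_age_range` frames.
#'
#' All randomness flows from `seed` through a private RNG stream carried in
#' the state, so replaying from the same seed yields bit-identical frame
#' geometry regardless of the caller's RNG.
#'
#' @param domain Length-4 numeric `c(xmin, xmax, ymin, ymax)`, km: the
#'   seeding bounding box, e.g. from [field_domain()].
#' @param band_floor Altitude-band floor (m) this animation tracks.
#' @param seed Integer seed.
#' @param n Population size.
#' @param max_age_range Integer range of streamlet lifespans, frames.
#' @param fade Per-frame opacity decay factor applied to every existing
#'   trail segment.
#' @param speed_scale Animation exaggeration factor: displayed displacement
#'   is true displacement times this (flow speed is deliberately faster than
#'   measured speeds, for legibility).
#' @param dt_frame_s Simulated seconds per frame.
#' @param frames_per_interval Frames drawn before the field advances to the
#'   next aggregation interval.
#' @return An object of class `flow_state`.
#' @export
seed_streamlets <- function(domain, band_floor, seed,
                            n = 450,
                            max_age_range = c(30, 90),
                            fade = 0.95,
                            speed_scale = 30,
                            dt_frame_s = 60,
                            frames_per_interval = 120) {
  stopifnot(length(domain) == 4, n >= 1)
  if (!(domain[2] > domain[1]) || !(domain[4] > domain[3])) {
    rlang::abort("seeding domain must have positive area",
                 class = "radarflow_config_error")
  }
  state <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  state$x <- stats::runif(n, domain[1], domain[2])
  state$y <- stats::runif(n, domain[3], domain[4])
  state$max_age <- sample_range(max_age_range, n)
  state$age <- floor(stats::runif(n) * state$max_age)
  state$rng <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
  state$trail <- replicate(n, matrix(numeric(), ncol = 2), simplify = FALSE)
  state$opacity <- replicate(n, numeric(), simplify = FALSE)
  state$frozen <- rep(FALSE, n)
  state$n <- n
  state$domain <- domain
  state$band_floor <- band_floor
  state$max_age_range <- max_age_range
  state$fade <- fade
  state$speed_scale <- speed_scale
  state$dt_frame_s <- dt_frame_s
  state$frames_per_interval <- frames_per_interval
  state$frame_index <- 0L
  state$interval_index <- 1L
  class(state) <- "flow_state"
  state
}

#' Seeding domain covering a field's radar layout
#'
#' Bounding box of the projected radar sites, padded on every side.
#'
#' @param field A [flow_field()].
#' @param pad_km Padding, km.
#' @return Length-4 numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
field_domain <- function(field, pad_km = 50) {
  c(min(field$sites$x) - pad_km, max(field$sites$x) + pad_km,
    min(field$sites$y) - pad_km, max(field$sites$y) + pad_km)
}

#' @export
print.flow_state <- function(x, ...) {
  cat("<flow_state> ", x$n, " streamlets, frame ", x$frame_index,
      ", interval ", x$interval_index, ", band floor ", x$band_floor, " m\n", sep = "")
  invisible(x)
}

# uniform integer draw from [a, b]; safe when a == b (sample() would
# misread a single value as 1:a)
sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}

with_state_rng <- function(state, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state$rng, globalenv())
  on.exit({
    state$rng <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Advance the streamlet population by one frame
#'
#' One animation frame: (1) each head moves along the interpolated velocity
#' at its position, scaled by `dt_frame_s * speed_scale`, and its previous
#' position joins the trail; (2) streamlets that have reached their lifespan
#' are removed; (3) a fresh streamlet is seeded for each removed one, so the
#' population size is conserved; (4) every existing trail segment's opacity
#' is multiplied by `fade`. After `frames_per_interval` frames, the state
#' advances to the field's next aggregation interval (holding at the last).
#' Heads where the field is undefined (no vector-bearing radar in the
#' snapshot) freeze for the frame and are flagged.
#'
#' Bird density is deliberately not used by this engine; the animation
#' encodes velocity only.
#'
#' @param state A [seed_streamlets()] state. Modified in place and
#'   (invisibly) returned, as the state is an environment.
#' @param field The [flow_field()] to advect through, or a
#'   `function(x, y, t)` returning `list(u, v)` in m/s (analytic field;
#'   time is then frames elapsed times `dt_frame_s`).
#' @return The updated `flow_state`.
#' @export
step_streamlets <- function(state, field) {
  t <- if (is.function(field)) {
    state$frame_index * state$dt_frame_s
  } else {
    field$intervals[min(state$interval_index, length(field$intervals))]
  }
  vel <- field_velocity(field, state$x, state$y, t, state$band_floor)
  state$frozen <- is.na(vel$u) | is.na(vel$v)
  scale_km <- state$dt_frame_s * state$speed_scale / 1000
  dx <- ifelse(state$frozen, 0, vel$u) * scale_km
  dy <- ifelse(state$frozen, 0, vel$v) * scale_km
  min_op <- 1 / 255
  for (i in seq_len(state$n)) {
    trail <- rbind(state$trail[[i]], c(state$x[i], state$y[i]))
    opac <- c(state$opacity[[i]] * state$fade, 1)
    # opacity rises with segment index (older segments faded more): trimming
    # fully faded segments drops a prefix only
    if (opac[1] < min_op) {
      first <- which(opac >= min_op)[1]
      trail <- trail[first:nrow(trail), , drop = FALSE]
      opac <- opac[first:length(opac)]
    }
    state$trail[[i]] <- trail
    state$opacity[[i]] <- opac
  }
  state$x <- state$x + dx
  state$y <- state$y + dy
  state$age <- state$age + 1L
  dead <- which(state$age >= state$max_age)
  if (length(dead) > 0) {
    with_state_rng(state, {
      state$x[dead] <- stats::runif(length(dead), state$domain[1], state$domain[2])
      state$y[dead] <- stats::runif(length(dead), state$domain[3], state$domain[4])
      state$max_age[dead] <- sample_range(state$max_age_range, length(dead))
    })
    state$age[dead] <- 0L
    for (i in dead) {
      state$trail[[i]] <- matrix(numeric(), ncol = 2)
      state$opacity[[i]] <- numeric()
    }
  }
  state$frame_index <- state$frame_index + 1L
  if (!is.function(field) && state$frame_index %% state$frames_per_interval == 0) {
    state$interval_index <- min(state$interval_index + 1L, length(field$intervals))
  }
  invisible(state)
}

#' Per-frame streamlet geometry
#'
#' Extracts the drawable geometry of the current frame: one polyline per
#' streamlet (trail plus head) with per-segment opacity. A streamlet with an
#' empty trail contributes a single point and zero segments.
#'
#' @param state A `flow_state`.
#' @return Tibble with columns `streamlet`, `vertex` (order along the
#'   polyline), `x`, `y` (km), and `opacity` of the segment ending at this
#'   vertex (`NA` for the first vertex of each polyline).
#' @export
frame_geometry <- function(state) {
  parts <- purrr::map(seq_len(state$n), function(i) {
    m <- rbind(state$trail[[i]], c(state$x[i], state$y[i]))
    tibble::tibble(
      streamlet = i,
      vertex = seq_len(nrow(m)),
      x = m[, 1], y = m[, 2],
      opacity = c(NA_real_, state$opacity[[i]])
    )
  })
  dplyr::bind_rows(parts)
}
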