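#' Inverse-distance-weighted interpolation at query points
#'
#' The spatial workhorse: given sparse samples (one per radar), evaluate an
#' inverse squared distance weighted mean of the `k` nearest samples at each
#' query point. Weights are `d^-p` with `p = 2` by default; a query point
#' coinciding with a sample (zero distance) returns that sample's value
#' exactly. Ties at the k-th distance are all included, so the result does
#' not depend on sample order.
#'
#' @param qx,qy Query coordinates, km.
#' @param sx,sy Sample coordinates, km.
#' @param values Numeric matrix with one row per sample (columns are
#'   interpolated independently, e.g. u and v), or a vector for a scalar.
#' @param k Number of nearest samples used (default 5).
#' @param p Weighting exponent (default 2: inverse squared distance).
#' @return Matrix with one row per query point (or vector if `values` was a
#'   vector). With zero samples, every value is `NA`.
#' @export
idw <- function(qx, qy, sx, sy, values, k = 5, p = 2) {
  vec_in <- is.null(dim(values))
  vals <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  nq <- length(qx)
  ns <- length(sx)
  out <- matrix(NA_real_, nrow = nq, ncol = ncol(vals))
  if (ns == 0) return(if (vec_in) out[, 1] else out)
  stopifnot(k >= 1, length(sy) == ns, nrow(vals) == ns)
  d2 <- outer(qx, sx, "-")^2 + outer(qy, sy, "-")^2
  for (i in seq_len(nq)) {
    di <- d2[i, ]
    if (any(di == 0)) {
      out[i, ] <- vals[which(di == 0)[1], ]
      next
    }
    keep <- if (ns > k) di <= sort(di, partial = k)[k] else rep(TRUE, ns)
    w <- di[keep]^(-p / 2)
    out[i, ] <- colSums(vals[keep, , drop = FALSE] * w) / sum(w)
  }
  if (vec_in) out[, 1] else out
}

#' Interpolate the velocity vector at query points
#'
#' Evaluates the reconstructed (u, v) field at points from the vector-bearing
#' samples of one interval/band snapshot: samples with a measured velocity,
#' including zero-velocity-convention ones (u = v = 0 means "measured, no
#' migration"), which deliberately pull the field toward zero. Samples with
#' missing velocity are excluded entirely.
#'
#' @param qx,qy Query coordinates, km.
#' @param samples Snapshot tibble from [field_at()] (columns `x`, `y`, `u`,
#'   `v`, `density`).
#' @inheritParams idw
#' @return Tibble with columns `u` and `v` (m/s), one row per query point.
#'   If the snapshot has no vector-bearing sample, an error of class
#'   `radarflow_field_undefined` is signalled (callers render no flow).
#' @export
interpolate_vector <- function(qx, qy, samples, k = 5, p = 2) {
  s <- samples[!is.na(samples$u) & !is.na(samples$v), , drop = FALSE]
  if (nrow(s) == 0) {
    rlang::abort("field undefined: no vector-bearing samples",
                 class = "radarflow_field_undefined")
  }
  m <- idw(qx, qy, s$x, s$y, cbind(s$u, s$v), k = k, p = p)
  tibble::tibble(u = m[, 1], v = m[, 2])
}

#' Interpolate the density scalar at query points
#'
#' As [interpolate_vector()], for the bird-density scalar field; samples with
#' missing density are excluded.
#'
#' @inheritParams interpolate_vector
#' @return Numeric vector of densities, birds/km^3.
#' @export
interpolate_scalar <- function(qx, qy, samples, k = 5, p = 2) {
  s <- samples[!is.na(samples$density), , drop = FALSE]
  if (nrow(s) == 0) {
    rlang::abort("field undefined: no density-bearing samples",
                 class = "radarflow_field_undefined")
  }
  idw(qx, qy, s$x, s$y, s$density, k = k, p = p)
}

#' Reconstruct the time-varying flow field of a case
#'
#' Projects the radar sites into the case plane and indexes the aggregated
#' records by (interval, band) so the continuous velocity and density fields
#' can be evaluated anywhere, at any covered time. Spatial evaluation uses
#' inverse squared distance weighting over the `k` nearest radars
#' ([interpolate_vector()], [interpolate_scalar()]); temporal behaviour is
#' piecewise-constant per aggregation interval, mirroring the stepwise field
#' updates of the animated visualization. Optional linear-in-time blending
#' of evaluated values between consecutive intervals is available for
#' smoother animation (`time_blend = TRUE`).
#'
#' @param records Aggregated tibble ([aggregate_profiles()] /
#'   [read_profile_table()]).
#' @param sites Radar-site tibble.
#' @param k Neighbour count for interpolation (default 5).
#' @param p Weighting exponent (fixed at 2 in the standard method).
#' @param interval_minutes Interval length, minutes; defaults to the spacing
#'   of the record timestamps (20 in the standard pipeline).
#' @param center Projection origin; defaults to the site centroid.
#' @param time_blend Linear-in-time blending flag.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(records, sites, k = 5, p = 2,
                       interval_minutes = NULL,
                       center = site_centroid(sites),
                       time_blend = FALSE) {
  stopifnot(nrow(sites) >= 1)
  unresolved <- setdiff(unique(records$radar_id), sites$radar_id)
  if (length(unresolved) > 0) {
    rlang::abort(
      paste0("records reference unknown radar_id: ", paste(unresolved, collapse = ", ")),
      class = "radarflow_validation_error"
    )
  }
  proj <- project_sites(sites, center)
  samples <- records |>
    dplyr::left_join(proj[, c("radar_id", "x", "y")], by = "radar_id") |>
    dplyr::transmute(
      interval_start_time = .data$interval_start_time,
      band_floor_m = .data$band_floor_m,
      band_ceiling_m = .data$band_ceiling_m,
      radar_id = .data$radar_id,
      x = .data$x, y = .data$y,
      u = .data$avg_u_speed, v = .data$avg_v_speed,
      density = .data$avg_bird_density
    )
  intervals <- sort(unique(as.numeric(samples$interval_start_time)))
  if (is.null(interval_minutes)) {
    interval_minutes <- if (length(intervals) > 1) {
      min(diff(intervals)) / 60
    } else {
      20
    }
  }
  bands <- samples |>
    dplyr::distinct(.data$band_floor_m, .data$band_ceiling_m) |>
    dplyr::arrange(.data$band_floor_m)
  structure(
    list(
      samples = samples, sites = proj, center = center,
      intervals = intervals, interval_s = interval_minutes * 60,
      bands = bands, k = k, p = p, time_blend = time_blend
    ),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field>\n")
  cat("  radars:    ", nrow(x$sites), "\n", sep = "")
  cat("  intervals: ", length(x$intervals), " x ", x$interval_s / 60, " min\n", sep = "")
  cat("  bands (m): ", paste(band_label(x$bands$band_floor_m, x$bands$band_ceiling_m),
                             collapse = ", "), "\n", sep = "")
  cat("  IDW:       k = ", x$k, ", p = ", x$p, "\n", sep = "")
  invisible(x)
}

#' Time coverage of a flow field
#'
#' @param field A [flow_field()].
#' @return POSIXct vector `c(start, end)`: first interval start to last
#'   interval end.
#' @export
field_time_range <- function(field) {
  as.POSIXct(
    c(min(field$intervals), max(field$intervals) + field$interval_s),
    origin = "1970-01-01", tz = "UTC"
  )
}

match_band <- function(field, band_floor) {
  i <- which(abs(field$bands$band_floor_m - band_floor) < 1e-9)
  if (length(i) != 1) {
    rlang::abort(
      paste0("no altitude band with floor ", band_floor, " m in field (have: ",
             paste(field$bands$band_floor_m, collapse = ", "), ")"),
      class = "radarflow_range_error"
    )
  }
  field$bands[i, ]
}

#' Snapshot of a flow field at an instant
#'
#' Returns the sample set of the aggregation interval enclosing `t` for one
#' altitude band. The field is piecewise-constant in time: any `t` within
#' `[start, start + interval)` returns the same snapshot.
#'
#' @param field A [flow_field()].
#' @param t POSIXct instant (or epoch seconds) within the covered range.
#' @param band_floor Floor (m) identifying the altitude band.
#' @return Snapshot tibble (columns `radar_id`, `x`, `y`, `u`, `v`,
#'   `density`); possibly zero rows if no radar reported in that interval.
#' @export
field_at <- function(field, t, band_floor) {
  tn <- as.numeric(t)
  rng <- as.numeric(field_time_range(field))
  if (tn < rng[1] || tn >= rng[2]) {
    rlang::abort(
      paste0("time ", format_utc(as.POSIXct(tn, origin = "1970-01-01", tz = "UTC")),
             " outside field coverage"),
      class = "radarflow_range_error"
    )
  }
  band <- match_band(field, band_floor)
  idx <- findInterval(tn, field$intervals)
  start <- field$intervals[idx]
  field$samples[
    as.numeric(field$samples$interval_start_time) == start &
      field$samples$band_floor_m == band$band_floor_m, ,
    drop = FALSE
  ]
}

# Evaluate velocity (m/s) at points/time; NA rows where the snapshot has no
# vector-bearing samples. Used by the particle engines. `field` may also be
# a function(x, y, t) returning list/tibble(u, v) in m/s: an analytic field,
# used for convergence checks and demos against closed-form flows.
field_velocity <- function(field, qx, qy, t, band_floor) {
  if (is.function(field)) {
    val <- field(qx, qy, as.numeric(t))
    return(tibble::tibble(u = rep_len(val$u, length(qx)),
                          v = rep_len(val$v, length(qx))))
  }
  eval_one <- function(tt) {
    snap <- field_at(field, tt, band_floor)
    tryCatch(
      interpolate_vector(qx, qy, snap, k = field$k, p = field$p),
      radarflow_field_undefined = function(e) {
        tibble::tibble(u = rep(NA_real_, length(qx)), v = rep(NA_real_, length(qx)))
      }
    )
  }
  if (!field$time_blend) return(eval_one(t))
  # blend between the midpoints of consecutive intervals
  tn <- as.numeric(t)
  mids <- field$intervals + field$interval_s / 2
  i <- findInterval(tn, mids)
  if (i == 0 || i >= length(mids)) return(eval_one(t))
  a <- eval_one(mids[i])
  b <- eval_one(mids[i + 1])
  w <- (tn - mids[i]) / (mids[i + 1] - mids[i])
  tibble::tibble(u = (1 - w) * a$u + w * b$u, v = (1 - w) * a$v + w * b$v)
}

field_density <- function(field, qx, qy, t, band_floor) {
  if (is.function(field)) return(rep(NA_real_, length(qx)))
  snap <- field_at(field, t, band_floor)
  tryCatch(
    interpolate_scalar(qx, qy, snap, k = field$k, p = field$p),
    radarflow_field_undefined = function(e) rep(NA_real_, length(qx))
  )
}
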