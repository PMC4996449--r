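#' TIMAMP configuration
#'
#' Parameters of a Time Integrated Multi-Altitude Migration Patterns
#' computation: a static pathline visualization in which each drawn path
#' stands for a fixed number of migrants, so that the paths' number and
#' spatial distribution together approximate the amount and distribution of
#' migration observed during the selected window.
#'
#' @param window_start POSIXct UTC start of the selected time window.
#' @param duration_hours Window length, whole hours 1 to 8.
#' @param strata_count Number of even altitude strata, 1 to 6.
#' @param migrants_per_path Migrants represented by one pathline. The
#'   interactive menu this mirrors offers 10, 25, 50, 100, 250 and 500
#'   thousand; any positive value is accepted here.
#' @param cell_km Lattice cell edge, km: 10 for a European-style case, 20
#'   for a US-style one.
#' @param radius_km Cells are kept only within this distance of the nearest
#'   radar (default 75 km, the radius over which a profile measurement is
#'   taken to be representative).
#' @param step_minutes Integration time increment, matching the temporal
#'   aggregation interval (default 20).
#' @param spline_tension Cardinal-spline tension in `[0, 1]`; 1 is the
#'   Catmull-Rom limit, 0 draws straight segments. Default 0.5.
#' @param altitude_ceiling Top of the stratified column, m.
#' @param seed Integer seed for anchor drawing.
#' @param thickness_range Drawn line thickness `c(min, max)` (render units).
#' @param density_scale Density (birds/km^3) mapped to maximum thickness.
#' @return A list of class `timamp_config`.
#' @export
timamp_config <- function(window_start,
                          duration_hours = 6,
                          strata_count = 2,
                          migrants_per_path = 50000,
                          cell_km = 10,
                          radius_km = 75,
                          step_minutes = 20,
                          spline_tension = 0.5,
                          altitude_ceiling = 4000,
                          seed = 1,
                          thickness_range = c(0.5, 4),
                          density_scale = 400) {
  if (!is.numeric(duration_hours) || duration_hours != round(duration_hours) ||
      duration_hours < 1 || duration_hours > 8) {
    rlang::abort("duration_hours must be a whole number of hours between 1 and 8",
                 class = "radarflow_config_error")
  }
  if (!strata_count %in% 1:6) {
    rlang::abort("strata_count must be between 1 and 6",
                 class = "radarflow_config_error")
  }
  if (!is.numeric(migrants_per_path) || migrants_per_path <= 0) {
    rlang::abort("migrants_per_path must be positive",
                 class = "radarflow_config_error")
  }
  if (duration_hours * 60 < step_minutes) {
    rlang::abort("window must cover at least one integration step",
                 class = "radarflow_config_error")
  }
  if (spline_tension < 0 || spline_tension > 1) {
    rlang::abort("spline_tension must be in [0, 1]", class = "radarflow_config_error")
  }
  structure(
    list(
      window_start = as.POSIXct(window_start, tz = "UTC"),
      duration_hours = duration_hours,
      strata_count = strata_count,
      migrants_per_path = migrants_per_path,
      cell_km = cell_km,
      radius_km = radius_km,
      step_minutes = step_minutes,
      spline_tension = spline_tension,
      altitude_ceiling = altitude_ceiling,
      seed = seed,
      thickness_range = thickness_range,
      density_scale = density_scale,
      strata = even_strata(strata_count, altitude_ceiling)
    ),
    class = "timamp_config"
  )
}

#' @export
print.timamp_config <- function(x, ...) {
  cat("<timamp_config> ", format_utc(x$window_start), " + ", x$duration_hours,
      " h, ", x$strata_count, " strata, ", x$migrants_per_path,
      " migrants/path, ", x$cell_km, " km cells within ", x$radius_km,
      " km of a radar\n", sep = "")
  invisible(x)
}

#' Build the analysis lattice around the radars
#'
#' Segments the projected plane into square cells of edge `cell_km`,
#' axis-aligned and anchored at the projection origin, and keeps the cells
#' whose centre lies within `radius_km` of the nearest radar. Crossing the
#' retained cells with the altitude strata yields the grid of rectangular
#' volumes over which expected migrant numbers are computed.
#'
#' @param sites Projected site tibble ([project_sites()]) or a site tibble
#'   with `lon`/`lat` (projected about its centroid).
#' @param config A [timamp_config()].
#' @return Tibble of volumes: `i`, `j` (cell indices), `cx`, `cy` (cell
#'   centre, km), `band_floor_m`, `band_ceiling_m`, `thickness_km`.
#' @export
build_lattice <- function(sites, config) {
  stopifnot(nrow(sites) >= 1)
  if (!all(c("x", "y") %in% names(sites))) sites <- project_sites(sites)
  h <- config$cell_km
  r <- config$radius_km
  ix <- seq(floor((min(sites$x) - r) / h), ceiling((max(sites$x) + r) / h))
  iy <- seq(floor((min(sites$y) - r) / h), ceiling((max(sites$y) + r) / h))
  cells <- tidyr::expand_grid(i = ix, j = iy) |>
    dplyr::mutate(cx = (.data$i + 0.5) * h, cy = (.data$j + 0.5) * h)
  d2 <- outer(cells$cx, sites$x, "-")^2 + outer(cells$cy, sites$y, "-")^2
  cells <- cells[sqrt(apply(d2, 1, min)) <= r, , drop = FALSE]
  strata <- config$strata
  tidyr::expand_grid(
    cells,
    tibble::tibble(
      band_floor_m = strata$band_floor_m,
      band_ceiling_m = strata$band_ceiling_m
    )
  ) |>
    dplyr::mutate(thickness_km = (.data$band_ceiling_m - .data$band_floor_m) / 1000)
}

#' Expected migrants per lattice volume
#'
#' For each volume, interpolates the bird density at the cell centre in each
#' aggregation interval of the window (inverse squared distance weighting
#' over the nearest radars), averages over the window, and multiplies by the
#' volume (cell area x stratum thickness) to estimate the average number of
#' migrants observed in that volume during the window. Intervals where the
#' density field is undefined are skipped; if it is undefined throughout,
#' the expectation is 0.
#'
#' @param volumes [build_lattice()] tibble.
#' @param field A [flow_field()] whose bands match the config's strata.
#' @param config A [timamp_config()].
#' @return `volumes` with `mean_density` (birds/km^3) and
#'   `expected_migrants` columns appended.
#' @export
volume_migrants <- function(volumes, field, config) {
  step_s <- config$step_minutes * 60
  times <- as.numeric(config$window_start) +
    seq(0, config$duration_hours * 3600 - step_s, by = step_s) + step_s / 2
  out <- volumes |>
    dplyr::group_by(.data$band_floor_m) |>
    dplyr::group_modify(function(df, key) {
      dens <- matrix(NA_real_, nrow = nrow(df), ncol = length(times))
      for (ti in seq_along(times)) {
        dens[, ti] <- tryCatch(
          field_density(field, df$cx, df$cy, times[ti], key$band_floor_m),
          radarflow_range_error = function(e) rep(NA_real_, nrow(df))
        )
      }
      df$mean_density <- rowMeans(dens, na.rm = TRUE)
      df$mean_density[is.nan(df$mean_density)] <- 0
      df
    }) |>
    dplyr::ungroup()
  out$expected_migrants <-
    out$mean_density * config$cell_km^2 * out$thickness_km
  out
}

#' Draw pathline anchors proportional to migrant numbers
#'
#' Each volume's expected migrants, divided by `migrants_per_path`, is the
#' expected number of pathlines anchored in it; that expectation is
#' apportioned uniformly over the window's time steps. Per volume and step,
#' `floor(lambda)` anchors are placed plus one more with probability
#' `frac(lambda)`, which keeps the expected count unbiased for any lambda.
#' Anchor points are uniform within the cell footprint (random placement
#' avoids lattice artefacts) and each anchor is stamped with the midpoint of
#' its time step.
#'
#' @param volumes Output of [volume_migrants()].
#' @param config A [timamp_config()]; `config$seed` seeds the draw.
#' @return Tibble of anchors: `path_id`, `x`, `y` (km), `band_floor_m`,
#'   `step` (1-based window step), `anchor_time` (POSIXct step midpoint).
#' @export
draw_anchors <- function(volumes, config) {
  if (config$migrants_per_path <= 0) {
    rlang::abort("migrants_per_path must be positive", class = "radarflow_config_error")
  }
  step_s <- config$step_minutes * 60
  n_steps <- floor(config$duration_hours * 3600 / step_s)
  lambda <- volumes$expected_migrants / config$migrants_per_path / n_steps
  per <- tidyr::expand_grid(vol = seq_len(nrow(volumes)), step = seq_len(n_steps))
  lam <- lambda[per$vol]
  counts <- floor(lam) + (stats::runif(nrow(per)) < (lam - floor(lam)))
  idx <- rep(seq_len(nrow(per)), counts)
  if (length(idx) == 0) {
    return(tibble::tibble(
      path_id = integer(), x = numeric(), y = numeric(),
      band_floor_m = numeric(), step = integer(),
      anchor_time = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC")
    ))
  }
  vol <- per$vol[idx]
  h <- config$cell_km
  tibble::tibble(
    path_id = seq_along(idx),
    x = volumes$cx[vol] + stats::runif(length(idx), -h / 2, h / 2),
    y = volumes$cy[vol] + stats::runif(length(idx), -h / 2, h / 2),
    band_floor_m = volumes$band_floor_m[vol],
    step = per$step[idx],
    anchor_time = config$window_start + (per$step[idx] - 0.5) * step_s
  )
}

#' One Heun (two-stage Runge-Kutta) integration step
#'
#' Advances positions through the time-varying velocity field by a signed
#' duration `h_s` (seconds; negative integrates backward): predictor
#' `k1 = V(t, x)`, corrector `k2 = V(t + h, x + h k1)`, update
#' `x + (h/2)(k1 + k2)`. Velocities are interpolated in m/s and converted to
#' km; positions are km in the case plane. Exact for fields constant over
#' the step; locally third-order otherwise.
#'
#' @param x,y Positions, km.
#' @param t Time (POSIXct or epoch seconds).
#' @param h_s Signed step, seconds.
#' @param field A [flow_field()], or a `function(x, y, t)` returning
#'   `list(u, v)` in m/s -- an analytic field, convenient for checking the
#'   integrator against closed-form trajectories.
#' @param band_floor Altitude-band floor, m (ignored for analytic fields).
#' @return Tibble `x`, `y`, `ok`: `ok` is FALSE where the field was
#'   undefined or out of range at either stage (callers truncate there).
#' @export
heun_step <- function(x, y, t, h_s, field, band_floor) {
  tn <- as.numeric(t)
  vel_or_na <- function(qx, qy, tt) {
    tryCatch(
      field_velocity(field, qx, qy, tt, band_floor),
      radarflow_range_error = function(e) {
        tibble::tibble(u = rep(NA_real_, length(qx)), v = rep(NA_real_, length(qx)))
      }
    )
  }
  k1 <- vel_or_na(x, y, tn)
  x1 <- x + h_s * k1$u / 1000
  y1 <- y + h_s * k1$v / 1000
  k2 <- vel_or_na(x1, y1, tn + h_s)
  ok <- !is.na(k1$u) & !is.na(k2$u)
  tibble::tibble(
    x = ifelse(ok, x + (h_s / 2) * (k1$u + k2$u) / 1000, x),
    y = ifelse(ok, y + (h_s / 2) * (k1$v + k2$v) / 1000, y),
    ok = ok
  )
}

#' Integrate a centrally anchored pathline
#'
#' From an anchor at its central time, integrates `ceiling(n/2)` Heun steps
#' backward and `floor(n/2)` forward, where `n = duration / step` is the
#' window's step count, yielding a pathline centred on the anchor. Vertices
#' carry the interpolated bird density at their position and time. Where
#' the field is undefined (no data, or a predictor time outside coverage)
#' the pathline is truncated on that side and flagged.
#'
#' @param anchor One-row tibble (or list) with `x`, `y`, `band_floor_m`,
#'   `anchor_time` (see [draw_anchors()]).
#' @param field A [flow_field()].
#' @param config A [timamp_config()].
#' @return Tibble of vertices in time order: `step` (signed, 0 = anchor),
#'   `time`, `x`, `y`, `density`; attribute `truncated` TRUE if either side
#'   stopped early.
#' @export
integrate_pathline <- function(anchor, field, config) {
  h <- config$step_minutes * 60
  n <- floor(config$duration_hours * 3600 / h)
  n_back <- ceiling(n / 2)
  n_fwd <- floor(n / 2)
  t0 <- as.numeric(anchor$anchor_time)
  band <- anchor$band_floor_m
  run <- function(n_steps, sign) {
    px <- anchor$x; py <- anchor$y; tt <- t0
    out <- vector("list", n_steps)
    trunc <- FALSE
    for (s in seq_len(n_steps)) {
      stepped <- heun_step(px, py, tt, sign * h, field, band)
      if (!stepped$ok) {
        trunc <- TRUE
        break
      }
      px <- stepped$x; py <- stepped$y; tt <- tt + sign * h
      out[[s]] <- c(step = sign * s, time = tt, x = px, y = py)
    }
    list(m = do.call(rbind, out[!vapply(out, is.null, logical(1))]), truncated = trunc)
  }
  back <- run(n_back, -1)
  fwd <- run(n_fwd, +1)
  rows <- rbind(
    if (!is.null(back$m)) back$m[rev(seq_len(nrow(back$m))), , drop = FALSE],
    c(step = 0, time = t0, x = anchor$x, y = anchor$y),
    fwd$m
  )
  dens <- vapply(seq_len(nrow(rows)), function(r) {
    tryCatch(
      field_density(field, rows[r, "x"], rows[r, "y"], rows[r, "time"], band),
      radarflow_range_error = function(e) NA_real_
    )
  }, numeric(1))
  out <- tibble::tibble(
    step = as.integer(rows[, "step"]),
    time = as.POSIXct(rows[, "time"], origin = "1970-01-01", tz = "UTC"),
    x = rows[, "x"], y = rows[, "y"],
    density = dens
  )
  attr(out, "truncated") <- back$truncated || fwd$truncated
  out
}

#' Cardinal-spline smoothing of a polyline
#'
#' Interpolating cubic Hermite spline through every control vertex with
#' tangents `tension * (P[i+1] - P[i-1]) / 2` (one-sided at the ends);
#' `tension = 1` is the Catmull-Rom spline, `tension = 0` straight
#' segments. Collinear input stays collinear.
#'
#' @param x,y Control vertices (length >= 2).
#' @param tension Tension in `[0, 1]`.
#' @param n_per_seg Interpolated points per segment.
#' @return Tibble `x`, `y` of the dense curve (passes through every control
#'   vertex), plus a `seg`/`s` parameterization: `seg` is the segment index
#'   and `s` the local parameter in `[0, 1]`.
#' @export
cardinal_spline <- function(x, y, tension = 0.5, n_per_seg = 12) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  px <- c(x[1], x, x[n])
  py <- c(y[1], y, y[n])
  mx <- tension * (px[3:(n + 2)] - px[1:n]) / 2
  my <- tension * (py[3:(n + 2)] - py[1:n]) / 2
  # one-sided tangents at the ends
  mx[1] <- tension * (x[2] - x[1]); my[1] <- tension * (y[2] - y[1])
  mx[n] <- tension * (x[n] - x[n - 1]); my[n] <- tension * (y[n] - y[n - 1])
  segs <- purrr::map(seq_len(n - 1), function(i) {
    s <- seq(0, 1, length.out = n_per_seg + 1)
    if (i < n - 1) s <- s[-length(s)]
    h00 <- 2 * s^3 - 3 * s^2 + 1
    h10 <- s^3 - 2 * s^2 + s
    h01 <- -2 * s^3 + 3 * s^2
    h11 <- s^3 - s^2
    tibble::tibble(
      seg = i, s = s,
      x = h00 * x[i] + h10 * mx[i] + h01 * x[i + 1] + h11 * mx[i + 1],
      y = h00 * y[i] + h10 * my[i] + h01 * y[i + 1] + h11 * my[i + 1]
    )
  })
  dplyr::bind_rows(segs)
}

#' Smooth and style a pathline for drawing
#'
#' Applies cardinal-spline smoothing to the pathline's vertices and maps
#' per-vertex bird density linearly to a drawing thickness,
#' `t_min + (t_max - t_min) * density / density_scale` clipped to
#' `[t_min, t_max]`; thickness is interpolated along the spline. The
#' temporally last vertex is the endpoint marker: a dot drawn there shows
#' the direction toward which birds are moving. Degenerate pathlines
#' (a single distinct vertex) yield the dot only.
#'
#' @param pathline Vertex tibble from [integrate_pathline()].
#' @param config A [timamp_config()].
#' @return Tibble `x`, `y`, `thickness` of the dense styled curve (zero
#'   rows when degenerate), with the endpoint marker position and the
#'   anchor row as attributes `endpoint` and `anchor`.
#' @export
smooth_and_style <- function(pathline, config) {
  v <- pathline
  endpoint <- c(x = v$x[nrow(v)], y = v$y[nrow(v)])
  distinct <- !duplicated(round(cbind(v$x, v$y), 9))
  thick_of <- function(d) {
    tr <- config$thickness_range
    d <- ifelse(is.na(d), 0, d)
    pmin(tr[2], pmax(tr[1], tr[1] + (tr[2] - tr[1]) * d / config$density_scale))
  }
  if (sum(distinct) < 2) {
    out <- tibble::tibble(x = numeric(), y = numeric(), thickness = numeric())
    attr(out, "endpoint") <- endpoint
    attr(out, "anchor") <- v[v$step == 0, , drop = FALSE]
    return(out)
  }
  vs <- v[distinct, , drop = FALSE]
  sp <- cardinal_spline(vs$x, vs$y, tension = config$spline_tension)
  th <- thick_of(vs$density)
  out <- tibble::tibble(
    x = sp$x, y = sp$y,
    thickness = (1 - sp$s) * th[sp$seg] + sp$s * th[sp$seg + 1]
  )
  attr(out, "endpoint") <- endpoint
  attr(out, "anchor") <- v[v$step == 0, , drop = FALSE]
  out
}

#' Compute a TIMAMP pathline set
#'
#' The full pipeline: re-aggregate the case's raw profiles into the
#' requested altitude strata (or use matching pre-aggregated records),
#' reconstruct the time-varying field, build the lattice of volumes within
#' reach of the radars, estimate expected migrants per volume, draw anchors
#' with probability proportional to those expectations, and integrate a
#' centrally anchored Heun pathline per anchor.
#'
#' @param case A `radar_case` (see [read_case()], [generate_case()]), or a
#'   [flow_field()] whose bands already match the strata.
#' @param config A [timamp_config()].
#' @return Object of class `timamp`: list with `volumes`, `anchors`,
#'   `paths` (one row per pathline: `path_id`, `band_floor_m`, `anchor_time`,
#'   `n_vertices`, `truncated`, `chord_bearing_deg`), `vertices` (all
#'   pathline vertices, keyed by `path_id`), `config`, `field`, and the
#'   case `sites`/`basemap` when available.
#' @export
timamp <- function(case, config) {
  if (inherits(case, "flow_field")) {
    field <- case
    sites <- field$sites
    basemap <- NULL
  } else {
    sites <- case$sites
    basemap <- case$basemap
    pcfg <- case$config
    pcfg$bands <- config$strata
    recs <- if (!is.null(case$raw)) {
      preprocess(case$raw, pcfg)
    } else {
      have <- sort(unique(case$records$band_floor_m))
      if (!isTRUE(all.equal(have, config$strata$band_floor_m))) {
        rlang::abort(
          "case has no raw profiles and its aggregated bands do not match the requested strata",
          class = "radarflow_config_error"
        )
      }
      case$records
    }
    field <- flow_field(recs, sites, center = case$center)
  }
  sites <- field$sites # projected in the field's plane
  volumes <- volume_migrants(build_lattice(sites, config), field, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  anchors <- draw_anchors(volumes, config)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  paths <- vector("list", nrow(anchors))
  verts <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    pl <- integrate_pathline(anchors[i, ], field, config)
    chord <- if (nrow(pl) >= 2) {
      bearing_deg(pl$x[nrow(pl)] - pl$x[1], pl$y[nrow(pl)] - pl$y[1])
    } else {
      NA_real_
    }
    paths[[i]] <- tibble::tibble(
      path_id = anchors$path_id[i],
      band_floor_m = anchors$band_floor_m[i],
      anchor_time = anchors$anchor_time[i],
      n_vertices = nrow(pl),
      truncated = attr(pl, "truncated"),
      chord_bearing_deg = chord
    )
    verts[[i]] <- dplyr::mutate(pl, path_id = anchors$path_id[i], .before = 1)
  }
  empty_paths <- tibble::tibble(
    path_id = integer(), band_floor_m = numeric(),
    anchor_time = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
    n_vertices = integer(), truncated = logical(), chord_bearing_deg = numeric()
  )
  structure(
    list(
      volumes = volumes,
      anchors = anchors,
      paths = dplyr::bind_rows(empty_paths, paths),
      vertices = dplyr::bind_rows(verts),
      config = config,
      field = field,
      sites = sites,
      basemap = basemap
    ),
    class = "timamp"
  )
}

# bearing in degrees clockwise from north of a displacement (dx east, dy north)
bearing_deg <- function(dx, dy) {
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' @export
print.timamp <- function(x, ...) {
  g <- glance(x)
  cat("<timamp> ", format_utc(x$config$window_start), " + ",
      x$config$duration_hours, " h, ", x$config$strata_count, " strata\n", sep = "")
  cat("  volumes: ", nrow(x$volumes), "; expected migrants: ",
      format(round(g$total_expected_migrants), big.mark = ","), "\n", sep = "")
  cat("  pathlines: ", g$n_paths, " x ", x$config$migrants_per_path,
      " migrants/path\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TIMAMP result: one row per pathline
#'
#' @param x A `timamp` object.
#' @param ... Unused.
#' @return The `paths` tibble: `path_id`, `band_floor_m`, `anchor_time`,
#'   `n_vertices`, `truncated`, `chord_bearing_deg`.
#' @export
tidy.timamp <- function(x, ...) {
  x$paths
}

#' One-row summary of a TIMAMP result
#'
#' @param x A `timamp` object.
#' @param ... Unused.
#' @return Tibble with `n_paths`, `n_volumes`, `total_expected_migrants`,
#'   `migrants_represented` (paths x migrants_per_path),
#'   `mean_chord_bearing_deg` (circular mean over pathlines).
#' @export
glance.timamp <- function(x, ...) {
  b <- x$paths$chord_bearing_deg[!is.na(x$paths$chord_bearing_deg)] * pi / 180
  mean_bearing <- if (length(b) > 0) {
    (atan2(mean(sin(b)), mean(cos(b))) * 180 / pi) %% 360
  } else {
    NA_real_
  }
  tibble::tibble(
    n_paths = nrow(x$paths),
    n_volumes = nrow(x$volumes),
    total_expected_migrants = sum(x$volumes$expected_migrants),
    migrants_represented = nrow(x$paths) * x$config$migrants_per_path,
    mean_chord_bearing_deg = mean_bearing
  )
}

#' Export a TIMAMP pathline set as GeoJSON
#'
#' One LineString feature per pathline (vertex coordinates unprojected to
#' longitude/latitude), with `band_floor_m`, `anchor_time` and the
#' per-vertex density profile as properties, for reuse in GIS tools.
#'
#' @param x A `timamp` object.
#' @param path Output file.
#' @export
timamp_geojson <- function(x, path) {
  center <- x$field$center
  feats <- purrr::map(split(x$vertices, x$vertices$path_id), function(v) {
    ll <- unproject_aeqd(v$x, v$y, center)
    meta <- x$paths[x$paths$path_id == v$path_id[1], ]
    list(
      type = "Feature",
      properties = list(
        path_id = meta$path_id,
        band_floor_m = meta$band_floor_m,
        anchor_time = format_utc(meta$anchor_time),
        density = v$density
      ),
      geometry = list(
        type = "LineString",
        coordinates = purrr::map2(ll$lon, ll$lat, ~ c(.x, .y))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
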