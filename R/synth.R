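#' Ground-truth flow specifications for synthetic cases
#'
#' Describes an analytic, time-varying layered flow plus a density model
#' from which synthetic radar cases are sampled. Kinds:
#' `uniform` (constant bearing/speed), `rotation` (rigid rotation about a
#' centre), `shear` (eastward speed proportional to northing),
#' `layered` (bearing and speed per altitude layer, emulating directions
#' that change with altitude), and `time_shift` (a bearing drifting
#' clockwise through the night, emulating the nocturnal veer of migration
#' headings).
#'
#' The density model is layered (a base density per altitude layer, so
#' upper layers can carry more migration than lower ones) with an optional
#' linear north-south gradient. Noise is zero-mean Gaussian jitter applied
#' by the generator to velocities (`sigma_v`, m/s) and densities
#' (`sigma_d`, birds/km^3, clipped at zero).
#'
#' @param kind One of `"uniform"`, `"rotation"`, `"shear"`, `"layered"`,
#'   `"time_shift"`.
#' @param bearing_deg Flow bearing, degrees clockwise from north.
#' @param speed_ms Flow speed, m/s.
#' @param center_km Rotation centre `c(x, y)`, km.
#' @param omega_per_hour Rotation rate, radians/hour (positive
#'   counter-clockwise).
#' @param shear_per_km d(u)/d(y), (m/s) per km of northing.
#' @param drift_deg_per_hour Clockwise bearing drift, degrees/hour
#'   (`time_shift`).
#' @param layer_floors Altitude-layer floors, m, for layered parameters.
#' @param layer_bearings_deg,layer_speeds_ms Per-layer bearing/speed
#'   (`layered`; recycled if length 1).
#' @param density_base Base density per layer (recycled), birds/km^3.
#' @param density_ns_gradient Relative density change per km northing
#'   (density is multiplied by `1 + gradient * y`, clipped at 0).
#' @param sigma_v,sigma_d Noise standard deviations.
#' @return A list of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("uniform", "rotation", "shear", "layered", "time_shift"),
                      bearing_deg = 41,
                      speed_ms = 10,
                      center_km = c(0, 0),
                      omega_per_hour = 0.2,
                      shear_per_km = 0.05,
                      drift_deg_per_hour = 5,
                      layer_floors = c(0, 1600),
                      layer_bearings_deg = c(30, 60),
                      layer_speeds_ms = c(8, 14),
                      density_base = 100,
                      density_ns_gradient = 0,
                      sigma_v = 0,
                      sigma_d = 0) {
  kind <- match.arg(kind)
  stopifnot(speed_ms >= 0, all(layer_speeds_ms >= 0), all(density_base >= 0))
  structure(
    list(
      kind = kind, bearing_deg = bearing_deg, speed_ms = speed_ms,
      center_km = center_km, omega_per_hour = omega_per_hour,
      shear_per_km = shear_per_km, drift_deg_per_hour = drift_deg_per_hour,
      layer_floors = layer_floors,
      layer_bearings_deg = rep_len(layer_bearings_deg, length(layer_floors)),
      layer_speeds_ms = rep_len(layer_speeds_ms, length(layer_floors)),
      density_base = rep_len(density_base, length(layer_floors)),
      density_ns_gradient = density_ns_gradient,
      sigma_v = sigma_v, sigma_d = sigma_d
    ),
    class = "flow_spec"
  )
}

# (u, v) m/s from a bearing (deg clockwise from north) and speed
bearing_to_uv <- function(bearing_deg, speed_ms) {
  rad <- bearing_deg * pi / 180
  list(u = speed_ms * sin(rad), v = speed_ms * cos(rad))
}

#' Noiseless ground truth of a synthetic flow
#'
#' Evaluates the analytic flow and density model of a [flow_spec()]:
#' the reference that recovery tests compare reconstructions against.
#'
#' @param spec A [flow_spec()].
#' @param x,y Positions in the case plane, km.
#' @param t_hours Hours since the case start.
#' @param alt_m Altitude above the surface, m (selects the layer).
#' @return Tibble `u`, `v` (m/s), `density` (birds/km^3).
#' @export
truth_at <- function(spec, x, y, t_hours = 0, alt_m = 500) {
  layer <- pmax(findInterval(alt_m, spec$layer_floors), 1)
  n <- max(length(x), length(y), length(layer))
  x <- rep_len(x, n); y <- rep_len(y, n); layer <- rep_len(layer, n)
  uv <- switch(spec$kind,
    uniform = {
      b <- bearing_to_uv(spec$bearing_deg, spec$speed_ms)
      list(u = rep_len(b$u, n), v = rep_len(b$v, n))
    },
    rotation = {
      om_s <- spec$omega_per_hour / 3600                 # rad/s
      rx <- (x - spec$center_km[1]) * 1000               # m
      ry <- (y - spec$center_km[2]) * 1000
      list(u = -om_s * ry, v = om_s * rx)
    },
    shear = list(u = spec$shear_per_km * y, v = rep_len(0, n)),
    layered = {
      b <- bearing_to_uv(spec$layer_bearings_deg[layer], spec$layer_speeds_ms[layer])
      list(u = b$u, v = b$v)
    },
    time_shift = {
      b <- bearing_to_uv(spec$bearing_deg + spec$drift_deg_per_hour * t_hours,
                         spec$speed_ms)
      list(u = rep_len(b$u, n), v = rep_len(b$v, n))
    }
  )
  dens <- spec$density_base[layer] * pmax(0, 1 + spec$density_ns_gradient * y)
  tibble::tibble(u = uv$u, v = uv$v, density = dens)
}

#' Built-in synthetic radar layouts
#'
#' `eu5_sites()`: five stations over a ~300 x 300 km area spanning the Low
#' Countries, the footprint of a small European C-band network.
#' `us13_sites()`: thirteen stations over a ~1000 x 800 km area of the
#' northeastern United States, a WSR-88D-style layout. Coordinates are
#' synthetic (plausible positions, not real station locations).
#'
#' @return Site tibble (`radar_id`, `name`, `lon`, `lat`).
#' @export
eu5_sites <- function() {
  tibble::tibble(
    radar_id = c("EU01", "EU02", "EU03", "EU04", "EU05"),
    name = paste("Synthetic EU station", 1:5),
    lon = c(4.80, 5.18, 3.07, 4.46, 5.50),
    lat = c(52.95, 52.10, 51.19, 50.90, 49.92)
  )
}

#' @rdname eu5_sites
#' @export
us13_sites <- function() {
  tibble::tibble(
    radar_id = sprintf("US%02d", 1:13),
    name = paste("Synthetic US station", 1:13),
    lon = c(-78.0, -75.9, -73.8, -71.1, -69.8, -77.0, -74.4, -72.6, -70.3,
            -76.1, -73.9, -71.9, -75.0),
    lat = c(43.0, 43.4, 42.7, 42.2, 44.5, 41.2, 40.7, 41.4, 41.7,
            39.5, 39.9, 43.9, 42.2)
  )
}

#' Generate a synthetic case study on disk
#'
#' Samples a known ground-truth flow at each radar site, altitude bin and
#' 5-minute scan time, adds the configured noise, and writes a complete
#' case directory in the standard dialects: `radars.json`, a raw
#' `birds_raw.csv`, the filtered and aggregated `birds.csv` (produced by
#' running [preprocess()] on the raw table), a rectangle `basemap.geojson`
#' around the sites, and `config.yml`. Output is deterministic per seed.
#'
#' @param dir Output directory (created if needed).
#' @param layout `"eu5"`, `"us13"`, or a custom site tibble. The US layout
#'   defaults to 100-m bins up to 3000 m; the EU layout to 200-m bins up to
#'   4000 m.
#' @param flow A [flow_spec()].
#' @param start,end POSIXct UTC time range (`end` exclusive); scans every
#'   `scan_minutes`.
#' @param seed Integer seed.
#' @param config A [preprocess_config()]; defaults to the layout's
#'   conventions.
#' @param scan_minutes Scan spacing, minutes.
#' @param bin_m Altitude-bin width, m.
#' @return The generated case, as [read_case()] returns it (invisibly the
#'   directory path is attached as attribute `dir`).
#' @export
generate_case <- function(dir,
                          layout = "eu5",
                          flow = flow_spec("uniform"),
                          start = as.POSIXct("2013-04-05 18:00:00", tz = "UTC"),
                          end = start + 6 * 3600,
                          seed = 1,
                          config = NULL,
                          scan_minutes = 5,
                          bin_m = NULL) {
  sites <- if (is.character(layout)) {
    switch(layout, eu5 = eu5_sites(), us13 = us13_sites(),
           rlang::abort("unknown layout; use 'eu5', 'us13' or a site tibble",
                        class = "radarflow_config_error"))
  } else {
    layout
  }
  us_style <- is.character(layout) && layout == "us13"
  if (is.null(bin_m)) bin_m <- if (us_style) 100 else 200
  if (is.null(config)) {
    config <- preprocess_config(
      altitude_ceiling = if (us_style) 3000 else 4000,
      bands = altitude_bands(c(200, 1600), ceiling = if (us_style) 3000 else 4000)
    )
  }
  stopifnot(end > start)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  proj <- project_sites(sites)
  times <- seq(as.numeric(start), as.numeric(end) - 1, by = scan_minutes * 60)
  floors <- seq(0, config$altitude_ceiling - bin_m, by = bin_m)
  grid <- tidyr::expand_grid(
    site = seq_len(nrow(proj)),
    t = times,
    bin_floor_m = floors
  )
  tr <- truth_at(
    flow,
    x = proj$x[grid$site], y = proj$y[grid$site],
    t_hours = (grid$t - as.numeric(start)) / 3600,
    alt_m = grid$bin_floor_m + bin_m / 2
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  n <- nrow(grid)
  u <- tr$u + if (flow$sigma_v > 0) stats::rnorm(n, 0, flow$sigma_v) else 0
  v <- tr$v + if (flow$sigma_v > 0) stats::rnorm(n, 0, flow$sigma_v) else 0
  density <- pmax(0, tr$density +
                    if (flow$sigma_d > 0) stats::rnorm(n, 0, flow$sigma_d) else 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  raw <- tibble::tibble(
    radar_id = proj$radar_id[grid$site],
    timestamp = as.POSIXct(grid$t, origin = "1970-01-01", tz = "UTC"),
    bin_floor_m = grid$bin_floor_m,
    bin_width_m = bin_m,
    density = density,
    u = u,
    v = v
  ) |>
    dplyr::arrange(.data$radar_id, .data$timestamp, .data$bin_floor_m)

  write_radar_sites(sites, file.path(dir, "radars.json"))
  write_profile_table(raw, file.path(dir, "birds_raw.csv"), schema = "raw")
  agg <- preprocess(raw, config)
  write_profile_table(agg, file.path(dir, "birds.csv"), schema = "aggregated")
  write_preprocess_config(config, file.path(dir, "config.yml"))

  margin <- 0.5
  lon0 <- min(sites$lon) - margin; lon1 <- max(sites$lon) + margin
  lat0 <- min(sites$lat) - margin; lat1 <- max(sites$lat) + margin
  rect <- tibble::tibble(
    feature = 1L, part = 1L,
    lon = c(lon0, lon1, lon1, lon0, lon0),
    lat = c(lat0, lat0, lat1, lat1, lat0)
  )
  write_basemap(rect, file.path(dir, "basemap.geojson"))

  out <- read_case(dir)
  attr(out, "dir") <- dir
  invisible(out)
}
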