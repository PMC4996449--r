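# Independent oracles and small fixture builders shared across tests.
# These deliberately do NOT reuse package internals.

# Brute-force inverse-distance-weighted interpolation restricted to the k
# nearest samples (ties at the k-th distance included).
idw_oracle <- function(qx, qy, sx, sy, vals, k = 5, p = 2) {
  vals <- as.matrix(vals)
  t(vapply(seq_along(qx), function(i) {
    d <- sqrt((sx - qx[i])^2 + (sy - qy[i])^2)
    if (any(d == 0)) return(vals[which(d == 0)[1], ])
    kd <- sort(d)[min(k, length(d))]
    keep <- d <= kd
    w <- d[keep]^(-p)
    colSums(vals[keep, , drop = FALSE] * w) / sum(w)
  }, numeric(ncol(vals))))
}

# Catmull-Rom evaluation at parameter s in [0,1] on segment (p1 -> p2) with
# neighbours p0, p3 (classic 0.5 * [...] basis form).
catmull_rom_point <- function(p0, p1, p2, p3, s) {
  0.5 * ((2 * p1) +
    (-p0 + p3 * 0 + p2) * s +
    (2 * p0 - 5 * p1 + 4 * p2 - p3) * s^2 +
    (-p0 + 3 * p1 - 3 * p2 + p3) * s^3)
}

# An aggregated-record tibble for hand-built field fixtures: one interval,
# one band, one row per radar.
make_agg <- function(sites, u, v, density,
                     t0 = as.POSIXct("2013-04-06 00:00:00", tz = "UTC"),
                     band = c(200, 1600)) {
  tibble::tibble(
    radar_id = sites$radar_id,
    interval_start_time = t0,
    band_floor_m = band[1],
    band_ceiling_m = band[2],
    avg_u_speed = u,
    avg_v_speed = v,
    avg_bird_density = density,
    velocity_is_zero_convention = !is.na(u) & !is.na(v) & u == 0 & v == 0
  )
}

# n synthetic radar sites on a ring in lon/lat, unique ids
ring_sites <- function(n, lon0 = 5, lat0 = 51.5, r_deg = 1.2) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(
    radar_id = sprintf("R%02d", seq_len(n)),
    name = paste("ring", seq_len(n)),
    lon = lon0 + r_deg * cos(ang),
    lat = lat0 + r_deg * sin(ang) * 0.7
  )
}

# quick raw-profile row builder
raw_row <- function(radar_id = "EU01", timestamp = "2013-04-06T00:00:00Z",
                    bin_floor_m = 200, bin_width_m = 200,
                    density = 10, u = 5, v = 5) {
  tibble::tibble(
    radar_id = radar_id,
    timestamp = as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    bin_floor_m = bin_floor_m, bin_width_m = bin_width_m,
    density = density, u = u, v = v
  )
}
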