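#' Altitude bands
#'
#' Build the altitude-band table over which vertical profiles are averaged.
#' Bands are half-open `[floor, ceiling)` intervals in metres above the
#' surface; the last band may be open-ended (`Inf` ceiling). The default for
#' the flow visualization splits the column at 1.6 km: band 1 from 0.2 km up
#' to (but excluding) 1.6 km, band 2 at and above 1.6 km.
#'
#' @param floors Numeric vector of band floors, m, strictly increasing.
#' @param ceiling Ceiling of the last band, m (`Inf` for open-ended).
#' @return Tibble with `band_floor_m`, `band_ceiling_m` and a `label` column.
#' @examples
#' altitude_bands(c(200, 1600), ceiling = 4000)
#' altitude_bands(seq(0, 3200, by = 800), ceiling = 4000) # 5 even strata
#' @export
altitude_bands <- function(floors = c(200, 1600), ceiling = Inf) {
  stopifnot(length(floors) >= 1, !is.unsorted(floors, strictly = TRUE))
  ceilings <- c(floors[-1], ceiling)
  if (any(ceilings <= floors)) {
    rlang::abort("band ceiling must exceed its floor", class = "radarflow_config_error")
  }
  tibble::tibble(
    band_floor_m = as.numeric(floors),
    band_ceiling_m = as.numeric(ceilings),
    label = band_label(as.numeric(floors), as.numeric(ceilings))
  )
}

#' Even altitude strata for TIMAMP
#'
#' Partition `[0, altitude_ceiling]` into `n` equal bands, the altitude
#' layout the multi-strata pathline visualization uses.
#'
#' @param n Number of strata, 1 to 6.
#' @param altitude_ceiling Column top, m.
#' @return An [altitude_bands()] tibble.
#' @export
even_strata <- function(n, altitude_ceiling = 4000) {
  if (!n %in% 1:6) {
    rlang::abort("strata count must be between 1 and 6", class = "radarflow_config_error")
  }
  altitude_bands(seq(0, altitude_ceiling, length.out = n + 1)[-(n + 1)],
                 ceiling = altitude_ceiling)
}

#' Preprocessing configuration
#'
#' Collects the filtering and aggregation constants applied to raw vertical
#' profiles before visualization. Defaults embody the standard pipeline for
#' a European-style C-band network: a per-bird radar cross section of
#' 11 cm^2 converts reflectivity to density; the lowest bin (0-200 m) is
#' excluded to reduce ground-clutter contamination; bins at or above the
#' 4000 m sampling ceiling are dropped; velocities are retained only where
#' bird density reaches 1 bird/km^3 (low-density speed estimates are easily
#' contaminated by residual rain or insects); records aggregate into
#' 20-minute intervals. `scan_rounding_minutes` rounds scan timestamps to
#' the nearest multiple before windowing, for networks (such as a WSR-88D
#' style one, where `altitude_ceiling` is typically 3000 with 100-m bins)
#' whose scans fall off-grid.
#'
#' @param cross_section Per-bird radar cross section sigma, cm^2.
#' @param density_threshold Minimum bird density for velocity retention,
#'   birds/km^3.
#' @param bin_floor_min Lowest retained bin floor, m.
#' @param altitude_ceiling Sampling ceiling, m; bins at or above it drop.
#' @param interval_minutes Aggregation window length, minutes.
#' @param scan_rounding_minutes Timestamp rounding step, minutes.
#' @param bands [altitude_bands()] tibble.
#' @param density_weighted If TRUE, band velocity means are weighted by bin
#'   density rather than unweighted. Off by default: the standard pipeline
#'   takes plain means over altitude bins.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cross_section = 11,
                              density_threshold = 1,
                              bin_floor_min = 200,
                              altitude_ceiling = 4000,
                              interval_minutes = 20,
                              scan_rounding_minutes = 5,
                              bands = altitude_bands(c(200, 1600), ceiling = 4000),
                              density_weighted = FALSE) {
  for (nm in c("cross_section", "density_threshold", "altitude_ceiling",
               "interval_minutes", "scan_rounding_minutes")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0) {
      rlang::abort(paste0(nm, " must be a positive number"),
                   class = "radarflow_config_error")
    }
  }
  if (!is.numeric(bin_floor_min) || length(bin_floor_min) != 1 || bin_floor_min < 0) {
    rlang::abort("bin_floor_min must be non-negative", class = "radarflow_config_error")
  }
  if (is.unsorted(bands$band_floor_m, strictly = TRUE) ||
      any(bands$band_ceiling_m[-nrow(bands)] > bands$band_floor_m[-1])) {
    rlang::abort("bands must be sorted and non-overlapping",
                 class = "radarflow_config_error")
  }
  structure(
    list(
      cross_section = cross_section,
      density_threshold = density_threshold,
      bin_floor_min = bin_floor_min,
      altitude_ceiling = altitude_ceiling,
      interval_minutes = interval_minutes,
      scan_rounding_minutes = scan_rounding_minutes,
      bands = bands,
      density_weighted = density_weighted
    ),
    class = "preprocess_config"
  )
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("<preprocess_config>\n")
  cat("  cross section sigma:   ", x$cross_section, " cm^2\n", sep = "")
  cat("  density threshold:     ", x$density_threshold, " birds/km^3\n", sep = "")
  cat("  retained bin floors:   [", x$bin_floor_min, ", ", x$altitude_ceiling, ") m\n", sep = "")
  cat("  aggregation interval:  ", x$interval_minutes, " min (scan rounding ",
      x$scan_rounding_minutes, " min)\n", sep = "")
  cat("  bands:                 ", paste(x$bands$label, collapse = ", "), " m\n", sep = "")
  invisible(x)
}

#' @rdname preprocess_config
#' @param path Path of a flat key-value YAML file mirroring the config
#'   fields; `bands` is a comma-separated floor list plus `band_ceiling`.
#' @export
read_preprocess_config <- function(path) {
  y <- yaml::read_yaml(path)
  bands <- if (!is.null(y$band_floors)) {
    altitude_bands(as.numeric(strsplit(as.character(y$band_floors), ",")[[1]]),
                   ceiling = as.numeric(y$band_ceiling %||% Inf))
  } else {
    altitude_bands(c(200, 1600), ceiling = 4000)
  }
  preprocess_config(
    cross_section = y$cross_section %||% 11,
    density_threshold = y$density_threshold %||% 1,
    bin_floor_min = y$bin_floor_min %||% 200,
    altitude_ceiling = y$altitude_ceiling %||% 4000,
    interval_minutes = y$interval_minutes %||% 20,
    scan_rounding_minutes = y$scan_rounding_minutes %||% 5,
    bands = bands,
    density_weighted = isTRUE(y$density_weighted)
  )
}

#' @rdname preprocess_config
#' @param config A `preprocess_config`.
#' @export
write_preprocess_config <- function(config, path) {
  yaml::write_yaml(
    list(
      cross_section = config$cross_section,
      density_threshold = config$density_threshold,
      bin_floor_min = config$bin_floor_min,
      altitude_ceiling = config$altitude_ceiling,
      interval_minutes = config$interval_minutes,
      scan_rounding_minutes = config$scan_rounding_minutes,
      band_floors = paste(config$bands$band_floor_m, collapse = ","),
      band_ceiling = max(config$bands$band_ceiling_m),
      density_weighted = config$density_weighted
    ),
    path
  )
  invisible(path)
}

#' Convert radar reflectivity to bird density
#'
#' Divides linear reflectivity eta (cm^2/km^3) by the assumed per-bird
#' radar cross section sigma (cm^2, default 11, the cross-calibrated value
#' for nocturnal passerine migration) to give bird density in birds/km^3.
#'
#' @param eta Reflectivity, cm^2/km^3, non-negative. `NA` passes through.
#' @param config A [preprocess_config()] supplying `cross_section`.
#' @return Bird density, birds/km^3.
#' @examples
#' reflectivity_to_density(22) # 2 birds/km^3
#' @export
reflectivity_to_density <- function(eta, config = preprocess_config()) {
  if (any(eta < 0, na.rm = TRUE)) {
    rlang::abort("reflectivity must be non-negative", class = "radarflow_domain_error")
  }
  eta / config$cross_section
}

#' Filter raw vertical-profile records
#'
#' Applies the standard exclusions: altitude bins below `bin_floor_min`
#' (ground clutter) and at or above `altitude_ceiling` are dropped; where
#' bird density is below `density_threshold` the velocity pair is cleared to
#' missing (density itself is kept). The threshold is inclusive: a bin at
#' exactly the threshold keeps its velocity. A `velocity_measured` column
#' records whether a velocity existed before clearing, so aggregation can
#' distinguish "measured but filtered" (which becomes the zero-velocity
#' convention) from "never measured".
#'
#' @param records Raw profile tibble (see [read_profile_table()]).
#' @param config A [preprocess_config()].
#' @return Filtered tibble with `velocity_measured` appended.
#' @export
filter_records <- function(records, config = preprocess_config()) {
  records |>
    dplyr::filter(
      .data$bin_floor_m >= config$bin_floor_min,
      .data$bin_floor_m < config$altitude_ceiling
    ) |>
    dplyr::mutate(
      velocity_measured = !is.na(.data$u) & !is.na(.data$v),
      clear = !is.na(.data$density) & .data$density < config$density_threshold,
      u = ifelse(.data$clear, NA_real_, .data$u),
      v = ifelse(.data$clear, NA_real_, .data$v)
    ) |>
    dplyr::select(-"clear")
}

#' Aggregate filtered profiles into interval and band means
#'
#' Rounds scan timestamps to the nearest `scan_rounding_minutes`, assigns
#' each record to a half-open interval `[t, t + interval)` anchored at the
#' hour and to the altitude band containing its bin floor, then averages
#' per (radar, interval, band): density over all bins with a density
#' present, velocity over the bins whose velocity survived filtering. If no
#' bin in a group passed the velocity filter but at least one had a measured
#' velocity, the aggregate velocity is set to (0, 0) with
#' `velocity_is_zero_convention` -- "measured, no migration detected" -- and
#' participates in field interpolation downstream. If no velocity was
#' measured at all, the aggregate velocity is missing and the record does
#' not steer the field.
#'
#' @param records Output of [filter_records()] (a `velocity_measured`
#'   column is reconstructed from non-missing u/v if absent, which is only
#'   correct for unfiltered input).
#' @param config A [preprocess_config()]; `config$bands` defines the bands.
#' @return An aggregated tibble in the [read_profile_table()] aggregated
#'   layout, sorted by radar, interval, band.
#' @export
aggregate_profiles <- function(records, config = preprocess_config()) {
  if (!"velocity_measured" %in% names(records)) {
    records$velocity_measured <- !is.na(records$u) & !is.na(records$v)
  }
  bands <- config$bands
  round_s <- config$scan_rounding_minutes * 60
  int_s <- config$interval_minutes * 60
  t <- as.numeric(records$timestamp)
  t_rounded <- round(t / round_s) * round_s
  interval_start <- floor(t_rounded / int_s) * int_s
  band_idx <- findInterval(records$bin_floor_m, bands$band_floor_m)
  in_band <- band_idx >= 1 & records$bin_floor_m < bands$band_ceiling_m[pmax(band_idx, 1)]

  wmean <- function(x, w) {
    keep <- !is.na(x)
    if (!any(keep)) return(NA_real_)
    if (is.null(w)) return(mean(x[keep]))
    w <- w[keep]
    if (all(w == 0) || anyNA(w)) return(mean(x[keep]))
    sum(x[keep] * w) / sum(w)
  }

  out <- records[in_band, , drop = FALSE] |>
    dplyr::mutate(
      interval_start_time = as.POSIXct(interval_start[in_band],
                                       origin = "1970-01-01", tz = "UTC"),
      band_floor_m = bands$band_floor_m[band_idx[in_band]],
      band_ceiling_m = bands$band_ceiling_m[band_idx[in_band]]
    ) |>
    dplyr::group_by(
      .data$radar_id, .data$interval_start_time,
      .data$band_floor_m, .data$band_ceiling_m
    ) |>
    dplyr::summarise(
      avg_bird_density = wmean(.data$density, NULL),
      n_vel = sum(!is.na(.data$u)),
      avg_u_speed = wmean(.data$u, if (config$density_weighted) .data$density else NULL),
      avg_v_speed = wmean(.data$v, if (config$density_weighted) .data$density else NULL),
      any_measured = any(.data$velocity_measured),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      velocity_is_zero_convention = .data$n_vel == 0 & .data$any_measured,
      avg_u_speed = ifelse(.data$velocity_is_zero_convention, 0, .data$avg_u_speed),
      avg_v_speed = ifelse(.data$velocity_is_zero_convention, 0, .data$avg_v_speed)
    ) |>
    dplyr::select(
      "radar_id", "interval_start_time", "band_floor_m", "band_ceiling_m",
      "avg_u_speed", "avg_v_speed", "avg_bird_density",
      "velocity_is_zero_convention"
    ) |>
    dplyr::arrange(
      .data$radar_id, .data$interval_start_time, .data$band_floor_m
    )
  out
}

#' Run the whole preprocessing pipeline
#'
#' Convenience wrapper: [filter_records()] then [aggregate_profiles()].
#'
#' @inheritParams filter_records
#' @return Aggregated tibble.
#' @export
preprocess <- function(records, config = preprocess_config()) {
  aggregate_profiles(filter_records(records, config), config)
}
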