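#' Read and write radar-site metadata
#'
#' A case study names its radars in a JSON file (`radars.json`): an array of
#' objects `{id, name, longitude, latitude}`. Sites are validated on read:
#' ids must be unique within a case and coordinates must be geographic
#' degrees.
#'
#' @param path Path to the JSON site listing.
#' @return A tibble with columns `radar_id` (character), `name` (character),
#'   `lon`, `lat` (degrees), one row per site, input order preserved.
#' @seealso [read_profile_table()], [read_basemap()], [read_case()]
#' @export
read_radar_sites <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("radar site file not found: ", path), class = "radarflow_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sites <- tibble::tibble(
    radar_id = purrr::map_chr(raw, ~ as.character(.x$id)),
    name = purrr::map_chr(raw, ~ as.character(.x$name %||% "")),
    lon = purrr::map_dbl(raw, ~ as.numeric(.x$longitude)),
    lat = purrr::map_dbl(raw, ~ as.numeric(.x$latitude))
  )
  validate_sites(sites)
  sites
}

#' @rdname read_radar_sites
#' @param sites A site tibble as returned by `read_radar_sites()`.
#' @export
write_radar_sites <- function(sites, path) {
  validate_sites(sites)
  entries <- purrr::pmap(sites, function(radar_id, name, lon, lat, ...) {
    list(id = radar_id, name = name, longitude = lon, latitude = lat)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

validate_sites <- function(sites) {
  dup <- sites$radar_id[duplicated(sites$radar_id)]
  if (length(dup) > 0) {
    rlang::abort(
      paste0("duplicate radar_id: ", paste(unique(dup), collapse = ", ")),
      class = "radarflow_validation_error"
    )
  }
  bad <- !is.finite(sites$lon) | sites$lon < -180 | sites$lon > 180 |
    !is.finite(sites$lat) | sites$lat < -90 | sites$lat > 90
  if (any(bad)) {
    rlang::abort(
      paste0(
        "coordinates out of range for radar_id: ",
        paste(sites$radar_id[bad], collapse = ", ")
      ),
      class = "radarflow_validation_error"
    )
  }
  invisible(sites)
}

# ---------------------------------------------------------------------------
# Profile tables: the birds.csv dialects
# ---------------------------------------------------------------------------

.raw_cols <- c("radar_id", "timestamp", "bin_floor_m", "bin_width_m", "density", "u", "v")
.agg_cols <- c(
  "radar_id", "interval_start_time", "altitude_band",
  "avg_u_speed", "avg_v_speed", "avg_bird_density"
)

#' Read and write bird-profile tables
#'
#' Two delimited dialects are supported. The raw schema holds one vertical
#' profile measurement per row, columns `radar_id, timestamp, bin_floor_m,
#' bin_width_m, density, u, v`: bird density in birds per cubic km and
#' eastward/northward ground-speed components in m/s for one altitude bin at
#' one scan time. The aggregated schema holds per-band, per-interval means,
#' columns `radar_id, interval_start_time, altitude_band, avg_u_speed,
#' avg_v_speed, avg_bird_density`. Timestamps are ISO-8601 UTC with a
#' trailing Z. Altitude bands are written as `floor-ceiling` in metres
#' (`200-1600`) with an open ceiling written `1600+`.
#'
#' Empty fields are the missing-value marker and are read as `NA`, never as
#' zero: "no measurement" and "measured zero migration" carry different
#' meanings downstream. In the aggregated dialect, a record with u and v both
#' exactly 0 is marked `velocity_is_zero_convention`: measurements were
#' taken, but no migration was detected; such records still steer the
#' interpolated field, unlike missing ones.
#'
#' @param path Path to the delimited file.
#' @param schema `"raw"` or `"aggregated"`.
#' @return A tibble. Raw schema: columns `radar_id`, `timestamp` (POSIXct
#'   UTC), `bin_floor_m`, `bin_width_m`, `density`, `u`, `v`. Aggregated
#'   schema: `radar_id`, `interval_start_time` (POSIXct UTC), `band_floor_m`,
#'   `band_ceiling_m` (may be `Inf`), `avg_u_speed`, `avg_v_speed`,
#'   `avg_bird_density`, `velocity_is_zero_convention`.
#' @export
read_profile_table <- function(path, schema = c("aggregated", "raw")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    rlang::abort(paste0("profile table not found: ", path), class = "radarflow_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  want <- if (schema == "raw") .raw_cols else .agg_cols
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0(
        "profile table does not match the ", schema, " schema; missing columns: ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "radarflow_schema_error"
    )
  }
  num <- function(col, label) {
    x <- df[[col]]
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      rlang::abort(
        paste0("non-numeric ", label, " in row ", bad[1], ": '", x[bad[1]], "'"),
        class = "radarflow_validation_error"
      )
    }
    out
  }
  if (schema == "raw") {
    out <- tibble::tibble(
      radar_id = df$radar_id,
      timestamp = parse_utc(df$timestamp),
      bin_floor_m = num("bin_floor_m", "bin floor"),
      bin_width_m = num("bin_width_m", "bin width"),
      density = num("density", "density"),
      u = num("u", "u"),
      v = num("v", "v")
    )
    validate_profile_records(out)
  } else {
    band <- parse_band_label(df$altitude_band)
    out <- tibble::tibble(
      radar_id = df$radar_id,
      interval_start_time = parse_utc(df$interval_start_time),
      band_floor_m = band$floor,
      band_ceiling_m = band$ceiling,
      avg_u_speed = num("avg_u_speed", "avg_u_speed"),
      avg_v_speed = num("avg_v_speed", "avg_v_speed"),
      avg_bird_density = num("avg_bird_density", "avg_bird_density")
    )
    out$velocity_is_zero_convention <-
      !is.na(out$avg_u_speed) & !is.na(out$avg_v_speed) &
      out$avg_u_speed == 0 & out$avg_v_speed == 0
    if (any(out$avg_bird_density < 0, na.rm = TRUE)) {
      rlang::abort("negative avg_bird_density", class = "radarflow_validation_error")
    }
  }
  out
}

#' @rdname read_profile_table
#' @param records A tibble in the layout `read_profile_table()` returns for
#'   the chosen schema.
#' @export
write_profile_table <- function(records, path, schema = c("aggregated", "raw")) {
  schema <- match.arg(schema)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, scientific = FALSE, trim = TRUE))
  if (schema == "raw") {
    validate_profile_records(records)
    df <- data.frame(
      radar_id = records$radar_id,
      timestamp = format_utc(records$timestamp),
      bin_floor_m = fmt(records$bin_floor_m),
      bin_width_m = fmt(records$bin_width_m),
      density = fmt(records$density),
      u = fmt(records$u),
      v = fmt(records$v),
      check.names = FALSE
    )
  } else {
    df <- data.frame(
      radar_id = records$radar_id,
      interval_start_time = format_utc(records$interval_start_time),
      altitude_band = band_label(records$band_floor_m, records$band_ceiling_m),
      avg_u_speed = fmt(records$avg_u_speed),
      avg_v_speed = fmt(records$avg_v_speed),
      avg_bird_density = fmt(records$avg_bird_density),
      check.names = FALSE
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_profile_records <- function(records) {
  if (any(records$density < 0, na.rm = TRUE)) {
    rlang::abort("negative bird density", class = "radarflow_validation_error")
  }
  if (any(records$bin_width_m <= 0, na.rm = TRUE)) {
    rlang::abort("non-positive bin width", class = "radarflow_validation_error")
  }
  lone <- xor(is.na(records$u), is.na(records$v))
  if (any(lone)) {
    rlang::abort(
      paste0("u and v must be present as a pair (row ", which(lone)[1], ")"),
      class = "radarflow_validation_error"
    )
  }
  invisible(records)
}

parse_utc <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  retry <- is.na(out) & !is.na(x) & x != ""
  # tolerate second-less timestamps
  out[retry] <- as.POSIXct(x[retry], format = "%Y-%m-%dT%H:%MZ", tz = "UTC")
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    rlang::abort(
      paste0("unparseable UTC timestamp in row ", bad[1], ": '", x[bad[1]], "'"),
      class = "radarflow_validation_error"
    )
  }
  out
}

format_utc <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

band_label <- function(floor, ceiling) {
  ifelse(is.finite(ceiling),
    paste0(format(floor, trim = TRUE, scientific = FALSE), "-",
           format(ceiling, trim = TRUE, scientific = FALSE)),
    paste0(format(floor, trim = TRUE, scientific = FALSE), "+")
  )
}

parse_band_label <- function(label) {
  open <- grepl("\\+$", label)
  floor <- ceiling <- rep(NA_real_, length(label))
  floor[open] <- suppressWarnings(as.numeric(sub("\\+$", "", label[open])))
  floor[!open] <- suppressWarnings(as.numeric(sub("-.*$", "", label[!open])))
  ceiling[open] <- Inf
  ceiling[!open] <- suppressWarnings(as.numeric(sub("^[^-]*-", "", label[!open])))
  if (any(is.na(floor) | is.na(ceiling))) {
    bad <- which(is.na(floor) | is.na(ceiling))[1]
    rlang::abort(
      paste0("unparseable altitude band label in row ", bad, ": '", label[bad], "'"),
      class = "radarflow_validation_error"
    )
  }
  list(floor = floor, ceiling = ceiling)
}

# ---------------------------------------------------------------------------
# Basemaps: TopoJSON and GeoJSON
# ---------------------------------------------------------------------------

#' Read a basemap (TopoJSON or GeoJSON)
#'
#' Reads the geographic line/polygon features drawn under a visualization:
#' country or state borders, coastlines. Both standard TopoJSON (topology
#' with delta-encoded, optionally quantized arcs) and plain GeoJSON are
#' accepted; the format is detected from the `type` member.
#'
#' @param path Path to a `.topojson`/`.geojson`/`.json` file.
#' @return A tibble with one row per vertex: `feature` (integer feature
#'   index), `part` (ring/line index within the feature), `lon`, `lat`
#'   (degrees). An empty feature collection yields a zero-row tibble, which
#'   all renderers accept.
#' @export
read_basemap <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("basemap not found: ", path), class = "radarflow_io_error")
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  type <- obj$type %||% ""
  parts <- if (identical(type, "Topology")) {
    decode_topojson(obj)
  } else if (identical(type, "FeatureCollection")) {
    purrr::map(obj$features %||% list(), ~ geojson_geometry_parts(.x$geometry))
  } else if (type %in% .geojson_geom_types) {
    list(geojson_geometry_parts(obj))
  } else {
    rlang::abort(paste0("unrecognized basemap format: type '", type, "'"),
                 class = "radarflow_format_error")
  }
  parts_to_tibble(parts)
}

.geojson_geom_types <- c(
  "Point", "MultiPoint", "LineString", "MultiLineString",
  "Polygon", "MultiPolygon", "GeometryCollection"
)

# parts: list (per feature) of list (per ring/line) of n x 2 matrices [lon, lat]
parts_to_tibble <- function(parts) {
  rows <- purrr::imap(parts, function(rings, fi) {
    purrr::imap(rings, function(m, pi) {
      if (length(m) == 0) return(NULL)
      tibble::tibble(feature = fi, part = pi, lon = m[, 1], lat = m[, 2])
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      feature = integer(), part = integer(), lon = numeric(), lat = numeric()
    )
  }
  out
}

coord_matrix <- function(coords) {
  if (length(coords) == 0) return(matrix(numeric(), ncol = 2))
  do.call(rbind, purrr::map(coords, ~ c(as.numeric(.x[[1]]), as.numeric(.x[[2]]))))
}

geojson_geometry_parts <- function(geom) {
  if (is.null(geom)) return(list())
  switch(geom$type,
    Point = list(matrix(as.numeric(unlist(geom$coordinates)), ncol = 2)),
    MultiPoint = list(coord_matrix(geom$coordinates)),
    LineString = list(coord_matrix(geom$coordinates)),
    MultiLineString = purrr::map(geom$coordinates, coord_matrix),
    Polygon = purrr::map(geom$coordinates, coord_matrix),
    MultiPolygon = purrr::flatten(
      purrr::map(geom$coordinates, ~ purrr::map(.x, coord_matrix))
    ),
    GeometryCollection = purrr::flatten(
      purrr::map(geom$geometries, geojson_geometry_parts)
    ),
    rlang::abort(paste0("unsupported geometry type: ", geom$type),
                 class = "radarflow_format_error")
  )
}

# Decode a TopoJSON topology into per-feature coordinate parts.
# Arcs are stored delta-encoded; with a transform present, positions are
# quantized integers mapped back by scale/translate.
decode_topojson <- function(topo) {
  tf <- topo$transform
  arcs <- purrr::map(topo$arcs %||% list(), function(arc) {
    m <- do.call(rbind, purrr::map(arc, ~ as.numeric(unlist(.x))[1:2]))
    if (!is.null(tf)) {
      m <- apply(m, 2, cumsum)
      if (is.null(dim(m))) m <- matrix(m, ncol = 2)
      m[, 1] <- m[, 1] * tf$scale[[1]] + tf$translate[[1]]
      m[, 2] <- m[, 2] * tf$scale[[2]] + tf$translate[[2]]
    }
    m
  })
  pt <- function(coords) {
    p <- as.numeric(unlist(coords))[1:2]
    if (!is.null(tf)) {
      p[1] <- p[1] * tf$scale[[1]] + tf$translate[[1]]
      p[2] <- p[2] * tf$scale[[2]] + tf$translate[[2]]
    }
    p
  }
  stitch <- function(idx) {
    segs <- purrr::map(idx, function(i) {
      i <- as.numeric(i)
      if (i >= 0) arcs[[i + 1]] else arcs[[-i]][rev(seq_len(nrow(arcs[[-i]]))), , drop = FALSE]
    })
    out <- segs[[1]]
    for (s in segs[-1]) out <- rbind(out, s[-1, , drop = FALSE])
    out
  }
  geom_parts <- function(g) {
    switch(g$type,
      Point = list(matrix(pt(g$coordinates), ncol = 2)),
      MultiPoint = list(do.call(rbind, purrr::map(g$coordinates, pt))),
      LineString = list(stitch(g$arcs)),
      MultiLineString = purrr::map(g$arcs, stitch),
      Polygon = purrr::map(g$arcs, stitch),
      MultiPolygon = purrr::flatten(purrr::map(g$arcs, ~ purrr::map(.x, stitch))),
      GeometryCollection = purrr::flatten(purrr::map(g$geometries, geom_parts)),
      rlang::abort(paste0("unsupported TopoJSON geometry: ", g$type),
                   class = "radarflow_format_error")
    )
  }
  objs <- topo$objects %||% list()
  purrr::flatten(purrr::map(objs, function(o) {
    if (identical(o$type, "GeometryCollection")) {
      purrr::map(o$geometries, geom_parts)
    } else {
      list(geom_parts(o))
    }
  }))
}

#' Write a basemap tibble as GeoJSON
#'
#' Each `(feature, part)` polyline becomes a LineString feature; used by the
#' synthetic-case generator to emit simple rectangle basemaps.
#'
#' @param basemap Tibble as returned by [read_basemap()].
#' @param path Output path.
#' @export
write_basemap <- function(basemap, path) {
  feats <- basemap |>
    dplyr::group_by(.data$feature, .data$part) |>
    dplyr::group_map(function(df, key) {
      list(
        type = "Feature",
        properties = stats::setNames(list(), character()),
        geometry = list(
          type = "LineString",
          coordinates = purrr::map2(df$lon, df$lat, ~ c(.x, .y))
        )
      )
    })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Whole-case convenience
# ---------------------------------------------------------------------------

#' Read a case-study directory
#'
#' A case directory bundles the three files a visualization needs --
#' `radars.json`, an aggregated `birds.csv`, a basemap (`basemap.topojson`
#' or `basemap.geojson`) -- plus optionally the raw profile table
#' (`birds_raw.csv`) and a preprocessing config (`config.yml`).
#'
#' @param dir Case directory.
#' @return An object of class `radar_case`: a list with `sites`, `records`
#'   (aggregated tibble), `raw` (raw tibble or NULL), `basemap`, `config`
#'   (a [preprocess_config()]), and `center` (projection origin).
#' @export
read_case <- function(dir) {
  if (!dir.exists(dir)) {
    rlang::abort(paste0("case directory not found: ", dir), class = "radarflow_io_error")
  }
  sites <- read_radar_sites(file.path(dir, "radars.json"))
  records <- read_profile_table(file.path(dir, "birds.csv"), schema = "aggregated")
  unresolved <- setdiff(unique(records$radar_id), sites$radar_id)
  if (length(unresolved) > 0) {
    rlang::abort(
      paste0("records reference unknown radar_id: ", paste(unresolved, collapse = ", ")),
      class = "radarflow_validation_error"
    )
  }
  bm_path <- Filter(file.exists, file.path(dir, c("basemap.topojson", "basemap.geojson")))
  basemap <- if (length(bm_path) > 0) read_basemap(bm_path[1]) else parts_to_tibble(list())
  raw_path <- file.path(dir, "birds_raw.csv")
  raw <- if (file.exists(raw_path)) read_profile_table(raw_path, schema = "raw") else NULL
  cfg_path <- file.path(dir, "config.yml")
  config <- if (file.exists(cfg_path)) read_preprocess_config(cfg_path) else preprocess_config()
  structure(
    list(
      sites = sites, records = records, raw = raw, basemap = basemap,
      config = config, center = site_centroid(sites)
    ),
    class = "radar_case"
  )
}

#' @export
print.radar_case <- function(x, ...) {
  cat("<radar_case>\n")
  cat("  sites:   ", nrow(x$sites), " (", paste(x$sites$radar_id, collapse = ", "), ")\n", sep = "")
  cat("  records: ", nrow(x$records), " aggregated rows",
      if (!is.null(x$raw)) paste0(", ", nrow(x$raw), " raw rows"), "\n", sep = "")
  if (nrow(x$records) > 0) {
    cat("  window:  ", format_utc(min(x$records$interval_start_time)), " .. ",
        format_utc(max(x$records$interval_start_time)), "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
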