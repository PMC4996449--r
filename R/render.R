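#' Rendering style
#'
#' Canvas geometry and colours shared by the flow animation and the TIMAMP
#' map.
#'
#' @param width_px,height_px Canvas size, pixels.
#' @param band_colors Character vector of colours, recycled over altitude
#'   bands/strata (lowest first).
#' @param background Background colour.
#' @param basemap_color Basemap line colour.
#' @param radar_color Radar dot colour (radar locations are drawn as filled
#'   circles).
#' @param dot_radius Endpoint-dot radius for pathlines, plot units.
#' @return List of class `render_style`.
#' @export
render_style <- function(width_px = 640, height_px = 640,
                         band_colors = c("#1b9e77", "#d95f02", "#7570b3",
                                         "#e7298a", "#66a61e", "#e6ab02"),
                         background = "white",
                         basemap_color = "grey70",
                         radar_color = "black",
                         dot_radius = 1.6) {
  stopifnot(width_px > 0, height_px > 0)
  structure(
    list(
      width_px = width_px, height_px = height_px, band_colors = band_colors,
      background = background, basemap_color = basemap_color,
      radar_color = radar_color, dot_radius = dot_radius
    ),
    class = "render_style"
  )
}

project_basemap <- function(basemap, center) {
  if (is.null(basemap) || nrow(basemap) == 0) {
    return(tibble::tibble(feature = integer(), part = integer(),
                          x = numeric(), y = numeric()))
  }
  xy <- project_aeqd(basemap$lon, basemap$lat, center)
  dplyr::mutate(basemap, x = xy$x, y = xy$y)
}

map_canvas <- function(sites, basemap, center, style, limits = NULL) {
  bm <- project_basemap(basemap, center)
  ggplot2::ggplot() +
    (if (nrow(bm) > 0) {
      ggplot2::geom_path(
        data = bm,
        ggplot2::aes(.data$x, .data$y, group = interaction(.data$feature, .data$part)),
        color = style$basemap_color, linewidth = 0.3
      )
    }) +
    ggplot2::geom_point(
      data = sites, ggplot2::aes(.data$x, .data$y),
      color = style$radar_color, size = 1.8
    ) +
    (if (is.null(limits)) {
      ggplot2::coord_equal()
    } else {
      ggplot2::coord_equal(xlim = limits[1:2], ylim = limits[3:4], expand = FALSE)
    }) +
    ggplot2::labs(x = "km east", y = "km north") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      panel.background = ggplot2::element_rect(fill = style$background, color = NA),
      plot.background = ggplot2::element_rect(fill = style$background, color = NA)
    )
}

#' Plot one streamlet animation frame
#'
#' Draws the current frame of a flow state over the basemap: one polyline
#' per streamlet with per-segment opacity, radar sites as filled circles.
#'
#' @param state A `flow_state`.
#' @param field The [flow_field()] being advected through.
#' @param basemap Optional basemap tibble ([read_basemap()]).
#' @param style A [render_style()].
#' @param color Streamlet colour.
#' @return A ggplot object.
#' @export
plot_flow_frame <- function(state, field, basemap = NULL,
                            style = render_style(), color = NULL) {
  geom <- frame_geometry(state)
  band_i <- which(abs(field$bands$band_floor_m - state$band_floor) < 1e-9)
  if (is.null(color)) {
    color <- style$band_colors[((band_i - 1) %% length(style$band_colors)) + 1]
  }
  segs <- geom |>
    dplyr::group_by(.data$streamlet) |>
    dplyr::mutate(xend = dplyr::lead(.data$x), yend = dplyr::lead(.data$y),
                  seg_opacity = dplyr::lead(.data$opacity)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$xend))
  p <- map_canvas(field$sites, basemap, field$center, style, limits = state$domain)
  if (nrow(segs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend,
                   alpha = .data$seg_opacity),
      color = color, linewidth = 0.5, show.legend = FALSE
    ) +
      ggplot2::scale_alpha_identity()
  }
  p
}

#' Plot a TIMAMP result
#'
#' The static pathline map: one colour per altitude stratum, line thickness
#' proportional to interpolated bird density, a dot at each pathline's
#' temporal endpoint marking the direction of movement, radar sites as
#' filled circles, all over the basemap.
#'
#' @param object A `timamp` object.
#' @param style A [render_style()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.timamp <- function(object, style = render_style(), ...) {
  cfg <- object$config
  strata_floors <- cfg$strata$band_floor_m
  color_of <- function(band_floor) {
    i <- match(band_floor, strata_floors)
    style$band_colors[((i - 1) %% length(style$band_colors)) + 1]
  }
  curves <- list()
  dots <- list()
  for (pid in object$paths$path_id) {
    v <- object$vertices[object$vertices$path_id == pid, ]
    styled <- smooth_and_style(v, cfg)
    band <- object$paths$band_floor_m[object$paths$path_id == pid]
    if (nrow(styled) > 0) {
      curves[[length(curves) + 1]] <- dplyr::mutate(
        styled, path_id = pid, band_floor_m = band
      )
    }
    ep <- attr(styled, "endpoint")
    dots[[length(dots) + 1]] <- tibble::tibble(
      path_id = pid, band_floor_m = band, x = ep["x"], y = ep["y"]
    )
  }
  curves <- dplyr::bind_rows(curves)
  dots <- dplyr::bind_rows(dots)
  p <- map_canvas(object$sites, object$basemap, object$field$center, style)
  if (nrow(curves) > 0) {
    p <- p + ggplot2::geom_path(
      data = curves,
      ggplot2::aes(.data$x, .data$y, group = .data$path_id,
                   color = factor(.data$band_floor_m),
                   linewidth = .data$thickness),
      lineend = "round", alpha = 0.8
    ) +
      ggplot2::scale_linewidth_identity()
  }
  if (nrow(dots) > 0) {
    p <- p + ggplot2::geom_point(
      data = dots,
      ggplot2::aes(.data$x, .data$y, color = factor(.data$band_floor_m)),
      size = style$dot_radius, show.legend = FALSE
    )
  }
  p + ggplot2::scale_color_manual(
    values = stats::setNames(
      style$band_colors[((seq_along(strata_floors) - 1) %% length(style$band_colors)) + 1],
      strata_floors
    ),
    name = "stratum floor (m)"
  ) +
    ggplot2::labs(
      title = paste0("TIMAMP ", format_utc(cfg$window_start), " + ",
                     cfg$duration_hours, " h"),
      subtitle = paste0(format(cfg$migrants_per_path, big.mark = ","),
                       " migrants per pathline")
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

ggplot_to_array <- function(p, style) {
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp, width = style$width_px, height = style$height_px, res = 96)
  print(p)
  grDevices::dev.off()
  on.exit(unlink(tmp))
  png::readPNG(tmp)
}

#' Render the animated flow visualization to a file
#'
#' Runs the streamlet engine over the reconstructed field and writes the
#' animation: an animated GIF if `out` ends in `.gif`, otherwise a
#' directory of numbered PNG frames. Deterministic for a given seed, config
#' and style.
#'
#' @param case A `radar_case`.
#' @param band_floor Altitude-band floor (m) to animate.
#' @param start POSIXct start time (defaults to the first interval).
#' @param n_frames Number of frames.
#' @param out Output path (`.gif` file or a directory).
#' @param seed Integer seed for streamlet seeding.
#' @param style A [render_style()].
#' @param ... Passed to [seed_streamlets()] (population size, fading,
#'   speed exaggeration, ...).
#' @param delay_cs GIF frame delay, centiseconds.
#' @return Invisibly, the output path.
#' @export
render_flow <- function(case, band_floor = 200, start = NULL, n_frames = 24,
                        out, seed = 1, style = render_style(), delay_cs = 5,
                        ...) {
  field <- flow_field(case$records, case$sites, center = case$center)
  state <- seed_streamlets(field_domain(field), band_floor, seed, ...)
  if (!is.null(start)) {
    idx <- findInterval(as.numeric(start), field$intervals)
    if (idx < 1 || idx > length(field$intervals)) {
      rlang::abort("start time outside field coverage", class = "radarflow_range_error")
    }
    state$interval_index <- idx
  }
  gif <- grepl("\\.gif$", out, ignore.case = TRUE)
  if (!gif) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    step_streamlets(state, field)
    p <- plot_flow_frame(state, field, case$basemap, style)
    arr <- ggplot_to_array(p, style)
    if (gif) {
      frames[[f]] <- arr[, , 1:3, drop = FALSE]
    } else {
      png::writePNG(arr, file.path(out, sprintf("frame_%04d.png", f)))
    }
  }
  if (gif) write_gif(frames, out, delay_cs = delay_cs)
  invisible(out)
}

#' Render a TIMAMP map to a file
#'
#' Computes nothing: takes a finished [timamp()] result and writes the
#' static map as PNG (or SVG when `out` ends in `.svg` and cairo is
#' available).
#'
#' @param x A `timamp` object.
#' @param out Output path (`.png` or `.svg`).
#' @param style A [render_style()].
#' @return Invisibly, the output path.
#' @export
render_timamp <- function(x, out, style = render_style()) {
  p <- autoplot(x, style = style)
  if (grepl("\\.svg$", out, ignore.case = TRUE)) {
    grDevices::svg(out, width = style$width_px / 96, height = style$height_px / 96)
  } else {
    grDevices::png(out, width = style$width_px, height = style$height_px, res = 96)
  }
  print(p)
  grDevices::dev.off()
  invisible(out)
}
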