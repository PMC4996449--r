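t0 <- as.POSIXct("2013-04-06 00:00:00", tz = "UTC")

# a field with constant velocity/density over `hours`, one band 0-4000 m
const_field <- function(sites, u, v, density, hours = 4, start = t0,
                        bands = c(0, 4000)) {
  recs <- dplyr::bind_rows(purrr::map(seq(0, hours * 3600 - 1200, by = 1200),
    function(off) {
      make_agg(sites, u = rep(u, nrow(sites)), v = rep(v, nrow(sites)),
               density = rep(density, nrow(sites)), t0 = start + off,
               band = bands)
    }))
  flow_field(recs, sites)
}

test_that("configuration enforces the menu ranges", {
  expect_error(timamp_config(t0, duration_hours = 9), class = "radarflow_config_error")
  expect_error(timamp_config(t0, duration_hours = 0), class = "radarflow_config_error")
  expect_error(timamp_config(t0, duration_hours = 2.5), class = "radarflow_config_error")
  expect_error(timamp_config(t0, strata_count = 7), class = "radarflow_config_error")
  expect_error(timamp_config(t0, migrants_per_path = 0), class = "radarflow_config_error")
  expect_error(timamp_config(t0, spline_tension = 1.5), class = "radarflow_config_error")
  cfg <- timamp_config(t0, duration_hours = 6, strata_count = 5)
  expect_equal(nrow(cfg$strata), 5)
  expect_equal(cfg$strata$band_floor_m, seq(0, 3200, by = 800))
})

test_that("the lattice keeps cells whose centre is within reach of a radar", {
  one <- tibble::tibble(radar_id = "A", name = "a", lon = 5, lat = 51.5)
  cfg <- timamp_config(t0, strata_count = 1, cell_km = 10, radius_km = 75)
  vol <- build_lattice(one, cfg)
  d <- sqrt(vol$cx^2 + vol$cy^2)
  expect_true(all(d <= 75 + 1e-9))
  # cell count approximates the disk area / cell area
  expect_equal(nrow(vol), pi * 75^2 / 10^2, tolerance = 0.04)
  expect_equal(unique(vol$thickness_km), 4)

  # two radars 300 km apart give two disjoint disks of cells
  two <- tibble::tibble(radar_id = c("A", "B"), name = c("a", "b"),
                        lon = c(3, 7.35), lat = c(51.5, 51.5))
  ptwo <- project_sites(two)
  gap <- sqrt(diff(ptwo$x)^2 + diff(ptwo$y)^2)
  expect_gt(gap, 290)
  vol2 <- build_lattice(ptwo, cfg)
  dA <- sqrt((vol2$cx - ptwo$x[1])^2 + (vol2$cy - ptwo$y[1])^2)
  dB <- sqrt((vol2$cx - ptwo$x[2])^2 + (vol2$cy - ptwo$y[2])^2)
  expect_true(all(xor(dA <= 75, dB <= 75)))
})

test_that("expected migrants are density times volume, averaged over time", {
  sites <- ring_sites(5)
  cfg <- timamp_config(t0, duration_hours = 2, strata_count = 1,
                       altitude_ceiling = 800, cell_km = 10)
  f <- const_field(sites, u = 5, v = 5, density = 100, bands = c(0, 800))
  vol <- volume_migrants(build_lattice(sites, cfg), f, cfg)
  # 100 birds/km^3 x 10 x 10 km x 0.8 km = 8000 birds in every volume
  expect_equal(unique(round(vol$expected_migrants, 6)), 8000)

  fz <- const_field(sites, u = 5, v = 5, density = 0, bands = c(0, 800))
  volz <- volume_migrants(build_lattice(sites, cfg), fz, cfg)
  expect_equal(unique(volz$expected_migrants), 0)

  # time-varying density {50, 150} averages to 100
  recs <- dplyr::bind_rows(
    make_agg(sites, rep(5, 5), rep(5, 5), rep(50, 5), t0 = t0, band = c(0, 800)),
    make_agg(sites, rep(5, 5), rep(5, 5), rep(50, 5), t0 = t0 + 1200, band = c(0, 800)),
    make_agg(sites, rep(5, 5), rep(5, 5), rep(150, 5), t0 = t0 + 2400, band = c(0, 800)),
    make_agg(sites, rep(5, 5), rep(5, 5), rep(150, 5), t0 = t0 + 3600, band = c(0, 800))
  )
  cfg80 <- timamp_config(t0, duration_hours = 1, strata_count = 1,
                         altitude_ceiling = 800, cell_km = 10)
  # 1-h window covers the two 50s and one 150: mean (50+50+150)/3
  fv <- flow_field(recs, sites)
  volv <- volume_migrants(build_lattice(sites, cfg80), fv, cfg80)
  expect_equal(unique(round(volv$mean_density, 9)), round((50 + 50 + 150) / 3, 9))
})

test_that("anchor counts follow the floor-plus-Bernoulli rule", {
  vols <- tibble::tibble(
    i = 1, j = 1:2, cx = 5, cy = c(5, 15),
    band_floor_m = 0, band_ceiling_m = 4000, thickness_km = 4,
    mean_density = c(0, 0), expected_migrants = c(0, 0)
  )
  cfg <- timamp_config(t0, duration_hours = 1, strata_count = 1,
                       migrants_per_path = 1000)
  # lambda = 0 everywhere: no pathlines
  expect_equal(nrow(draw_anchors(vols, cfg)), 0)

  # integer lambda: exactly that many anchors, no randomness in the count
  vols$expected_migrants <- c(3000, 0) # lambda = 3 over 3 steps -> 1 per step
  for (s in 1:5) {
    set.seed(s)
    a <- draw_anchors(vols, cfg)
    expect_equal(nrow(a), 3)
    expect_equal(sort(unique(a$step)), 1:3)
    # anchors fall inside the cell footprint
    expect_true(all(abs(a$x - 5) <= 5 & abs(a$y - 5) <= 5))
  }
})

test_that("Monte-Carlo anchor counts are unbiased for fractional lambda", {
  vols <- tibble::tibble(
    i = 1:4, j = 1, cx = c(5, 15, 25, 35), cy = 5,
    band_floor_m = 0, band_ceiling_m = 4000, thickness_km = 4,
    mean_density = 1,
    expected_migrants = c(700, 1300, 2450, 160)
  )
  cfg <- timamp_config(t0, duration_hours = 1, strata_count = 1,
                       migrants_per_path = 1000)
  lambda_tot <- sum(vols$expected_migrants) / 1000
  set.seed(99)
  n_rep <- 10000
  counts <- vapply(seq_len(n_rep), function(i) nrow(draw_anchors(vols, cfg)),
                   numeric(1))
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - lambda_tot), 3 * se + 1e-9)
})

test_that("Heun steps are exact in constant fields and reversible", {
  sites <- ring_sites(5)
  f <- const_field(sites, u = 10, v = 0, density = 10)
  st <- heun_step(0, 0, t0, 1200, f, 0)
  expect_true(st$ok)
  expect_equal(st$x, 12)
  expect_equal(st$y, 0)
  back <- heun_step(st$x, st$y, as.numeric(t0) + 1200, -1200, f, 0)
  expect_equal(back$x, 0)
  expect_equal(back$y, 0)
})

test_that("Heun is second-order accurate on a rotating flow", {
  omega_s <- 2e-4
  rot <- function(x, y, t) list(u = -omega_s * y * 1000, v = omega_s * x * 1000)
  integrate_n <- function(h, total) {
    p <- c(30, 0); tt <- 0
    for (i in seq_len(total / h)) {
      s <- heun_step(p[1], p[2], tt, h, rot, 0)
      p <- c(s$x, s$y); tt <- tt + h
    }
    p
  }
  total <- 7200 # ~1.44 rad of arc
  exact <- 30 * c(cos(omega_s * total), sin(omega_s * total))
  err <- function(h) sqrt(sum((integrate_n(h, total) - exact)^2))
  e1 <- err(1200)
  e2 <- err(600)
  e3 <- err(300)
  expect_equal(e1 / e2, 4, tolerance = 0.2)
  expect_equal(e2 / e3, 4, tolerance = 0.2)
})

test_that("pathlines are centrally anchored and straight in constant flow", {
  sites <- ring_sites(5)
  f <- const_field(sites, u = 10, v = 0, density = 10, hours = 8,
                   start = t0 - 4 * 3600)
  cfg <- timamp_config(t0 - 3600, duration_hours = 2, strata_count = 1,
                       altitude_ceiling = 4000)
  anchor <- list(x = 0, y = 0, band_floor_m = 0, anchor_time = t0)
  pl <- integrate_pathline(anchor, f, cfg)
  # 6 x 20-min steps of 12 km: 72 km west-to-east, anchor at the midpoint
  expect_equal(nrow(pl), 7)
  expect_false(attr(pl, "truncated"))
  expect_equal(pl$x, seq(-36, 36, by = 12))
  expect_equal(unique(pl$y), 0)
  expect_equal(pl$x[pl$step == 0], 0)
  expect_true(!is.unsorted(pl$time))
  expect_equal(unname(diff(range(pl$x))), 72)

  # zero flow: all vertices coincide
  fz <- const_field(sites, u = 0, v = 0, density = 10, hours = 8,
                    start = t0 - 4 * 3600)
  plz <- integrate_pathline(anchor, fz, cfg)
  expect_equal(unique(plz$x), 0)
  expect_equal(unique(plz$y), 0)

  # truncation at the edge of coverage is flagged
  f_short <- const_field(sites, u = 10, v = 0, density = 10, hours = 1,
                         start = t0 - 1200)
  pls <- integrate_pathline(anchor, f_short, cfg)
  expect_true(attr(pls, "truncated"))
  expect_lt(nrow(pls), 7)
})

test_that("pathline vertices in a rotating flow stay near the circle", {
  omega_s <- 1e-4
  rot <- function(x, y, t) list(u = -omega_s * y * 1000, v = omega_s * x * 1000)
  cfg <- timamp_config(t0, duration_hours = 4, strata_count = 1)
  anchor <- list(x = 50, y = 0, band_floor_m = 0, anchor_time = t0 + 2 * 3600)
  pl <- integrate_pathline(anchor, rot, cfg)
  expect_equal(nrow(pl), 13)
  r <- sqrt(pl$x^2 + pl$y^2)
  # O(h^2) radial drift: (omega h)^2 ~ 1.4e-2 per step, a few km over 6 steps
  expect_lt(max(abs(r - 50)), 50 * 6 * (omega_s * 1200)^2)
})

test_that("cardinal splines interpolate their control vertices", {
  x <- c(0, 10, 15, 30, 42)
  y <- c(0, 8, -3, 5, 5)
  for (tension in c(0, 0.25, 0.5, 1)) {
    sp <- cardinal_spline(x, y, tension = tension)
    hits <- purrr::map_lgl(seq_along(x), function(i) {
      any(abs(sp$x - x[i]) < 1e-9 & abs(sp$y - y[i]) < 1e-9)
    })
    expect_true(all(hits))
  }
  # collinear control points stay collinear
  sp <- cardinal_spline(c(0, 1, 2, 5, 9), c(0, 2, 4, 10, 18), tension = 0.5)
  expect_equal(sp$y, 2 * sp$x, tolerance = 1e-12)
})

test_that("tension 1 reproduces the Catmull-Rom closed form", {
  set.seed(21)
  x <- cumsum(runif(5, 1, 10))
  y <- rnorm(5, sd = 5)
  sp <- cardinal_spline(x, y, tension = 1, n_per_seg = 8)
  # interior segment i: compare against the classic basis-matrix evaluation
  for (i in 2:3) {
    seg <- sp[sp$seg == i, ]
    px <- catmull_rom_point(x[i - 1], x[i], x[i + 1], x[i + 2], seg$s)
    py <- catmull_rom_point(y[i - 1], y[i], y[i + 1], y[i + 2], seg$s)
    expect_lt(max(abs(seg$x - px)), 1e-9)
    expect_lt(max(abs(seg$y - py)), 1e-9)
  }
})

test_that("styling maps density to clipped thickness and marks the endpoint", {
  cfg <- timamp_config(t0, duration_hours = 2, strata_count = 1,
                       thickness_range = c(1, 3), density_scale = 100)
  pl <- tibble::tibble(
    step = -1:1,
    time = t0 + (-1:1) * 1200,
    x = c(0, 10, 20), y = c(0, 0, 0),
    density = c(0, 50, 1e6)
  )
  styled <- smooth_and_style(pl, cfg)
  expect_equal(attr(styled, "endpoint"), c(x = 20, y = 0))
  expect_equal(min(styled$thickness), 1)
  expect_equal(max(styled$thickness), 3) # clipped at t_max
  th_mid <- styled$thickness[which.min(abs(styled$x - 10))]
  expect_equal(th_mid, 1 + (3 - 1) * 50 / 100)

  # single-vertex pathline: dot only
  deg <- tibble::tibble(step = 0, time = t0, x = 5, y = 5, density = 10)
  styled0 <- smooth_and_style(deg, cfg)
  expect_equal(nrow(styled0), 0)
  expect_equal(attr(styled0, "endpoint"), c(x = 5, y = 5))
})

test_that("the pathline set represents the observed migrant numbers", {
  d <- withr::local_tempdir()
  case <- generate_case(d, layout = "eu5",
                        flow = flow_spec("uniform", bearing_deg = 41, speed_ms = 10,
                                         density_base = 150),
                        start = t0, end = t0 + 4 * 3600, seed = 2)
  cfg <- timamp_config(t0 + 3600, duration_hours = 2, strata_count = 2,
                       migrants_per_path = 250000, seed = 5)
  tm <- timamp(case, cfg)
  g <- glance(tm)
  expect_gt(g$n_paths, 10)
  # paths x migrants/path within 15% of the summed expectation
  expect_lt(abs(g$migrants_represented - g$total_expected_migrants) /
              g$total_expected_migrants, 0.15)
  expect_equal(nrow(tm$anchors), nrow(tm$paths))
  expect_equal(tidy(tm)$path_id, tm$anchors$path_id)
})

test_that("anchor placement follows the density distribution", {
  # northern half 4x the density of the southern half
  d <- withr::local_tempdir()
  case <- generate_case(d, layout = "eu5",
                        flow = flow_spec("uniform", bearing_deg = 0, speed_ms = 8,
                                         density_base = 100,
                                         density_ns_gradient = 0.006),
                        start = t0, end = t0 + 2 * 3600, seed = 3)
  cfg <- timamp_config(t0, duration_hours = 2, strata_count = 1,
                       migrants_per_path = 100000, seed = 9)
  tm <- timamp(case, cfg)
  north <- tm$volumes[tm$volumes$cy > 0, ]
  south <- tm$volumes[tm$volumes$cy <= 0, ]
  ratio_expected <- sum(north$expected_migrants) / sum(south$expected_migrants)
  anchors_north <- sum(tm$anchors$y > 0)
  anchors_south <- sum(tm$anchors$y <= 0)
  expect_gt(anchors_north, anchors_south)
  expect_equal(anchors_north / anchors_south, ratio_expected, tolerance = 0.25)
})
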