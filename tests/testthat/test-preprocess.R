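test_that("reflectivity converts to density by the assumed cross section", {
  expect_equal(reflectivity_to_density(0), 0)
  expect_equal(reflectivity_to_density(22), 2)
  expect_equal(reflectivity_to_density(5.5), 0.5)
  cfg <- preprocess_config(cross_section = 5)
  expect_equal(reflectivity_to_density(10, cfg), 2)
  expect_error(reflectivity_to_density(-1), class = "radarflow_domain_error")
})

test_that("filtering drops clutter bins and clears sub-threshold velocities", {
  recs <- dplyr::bind_rows(
    raw_row(bin_floor_m = 0, density = 50),          # ground-clutter bin
    raw_row(bin_floor_m = 4000, density = 50),       # at the ceiling
    raw_row(bin_floor_m = 200, density = 0.5, u = 3, v = 4),
    raw_row(bin_floor_m = 400, density = 1.0, u = 3, v = 4),
    raw_row(bin_floor_m = 600, density = 2.0, u = NA, v = NA)
  )
  out <- filter_records(recs)
  expect_equal(out$bin_floor_m, c(200, 400, 600))
  # below threshold: density kept, velocity cleared, measurement remembered
  expect_equal(out$density[1], 0.5)
  expect_true(is.na(out$u[1]) && is.na(out$v[1]))
  expect_true(out$velocity_measured[1])
  # at the threshold (inclusive): unchanged
  expect_equal(out$u[2], 3)
  expect_equal(out$v[2], 4)
  # never measured
  expect_false(out$velocity_measured[3])
})

test_that("aggregation takes unweighted means per radar, interval and band", {
  one <- filter_records(raw_row(bin_floor_m = 400, density = 7, u = 2, v = -1))
  agg <- aggregate_profiles(one)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$avg_bird_density, 7)
  expect_equal(agg$avg_u_speed, 2)
  expect_equal(agg$avg_v_speed, -1)
  expect_false(agg$velocity_is_zero_convention)

  two <- filter_records(dplyr::bind_rows(
    raw_row(bin_floor_m = 200, density = 5, u = 2, v = 1),
    raw_row(bin_floor_m = 400, density = 15, u = 4, v = 3)
  ))
  agg <- aggregate_profiles(two)
  expect_equal(agg$avg_u_speed, 3)
  expect_equal(agg$avg_v_speed, 2)
  expect_equal(agg$avg_bird_density, 10)
})

test_that("zero-velocity convention marks measured-but-filtered intervals", {
  # all bins below the density threshold, but velocities were measured
  recs <- filter_records(dplyr::bind_rows(
    raw_row(bin_floor_m = 200, density = 0.2, u = 3, v = 4),
    raw_row(bin_floor_m = 400, density = 0.8, u = 5, v = 6)
  ))
  agg <- aggregate_profiles(recs)
  expect_equal(agg$avg_u_speed, 0)
  expect_equal(agg$avg_v_speed, 0)
  expect_true(agg$velocity_is_zero_convention)
  # densities are still averaged
  expect_equal(agg$avg_bird_density, 0.5)

  # nothing measured at all: velocity stays missing, no flag
  none <- filter_records(raw_row(density = 0.2, u = NA, v = NA))
  agg2 <- aggregate_profiles(none)
  expect_true(is.na(agg2$avg_u_speed))
  expect_false(agg2$velocity_is_zero_convention)
})

test_that("timestamps are rounded to the scan grid before windowing", {
  # 17:58 rounds to 18:00 and lands in the [18:00, 18:20) window
  recs <- filter_records(dplyr::bind_rows(
    raw_row(timestamp = "2013-04-05T17:58:00Z", density = 10, u = 2, v = 2),
    raw_row(timestamp = "2013-04-05T18:07:00Z", density = 10, u = 4, v = 4),
    raw_row(timestamp = "2013-04-05T18:12:00Z", density = 10, u = 6, v = 6)
  ))
  agg <- aggregate_profiles(recs)
  expect_equal(nrow(agg), 1)
  expect_equal(format(agg$interval_start_time, "%H:%M", tz = "UTC"), "18:00")
  expect_equal(agg$avg_u_speed, 4)
})

test_that("altitude bins are assigned to bands by their floor", {
  cfg <- preprocess_config(bands = altitude_bands(c(200, 1600), ceiling = 4000))
  recs <- filter_records(dplyr::bind_rows(
    raw_row(bin_floor_m = 1400, density = 10, u = 1, v = 1),
    raw_row(bin_floor_m = 1600, density = 10, u = 9, v = 9)
  ), cfg)
  agg <- aggregate_profiles(recs, cfg)
  expect_equal(agg$band_floor_m, c(200, 1600))
  expect_equal(agg$avg_u_speed, c(1, 9))
})

test_that("records below the minimum bin floor never change aggregates", {
  set.seed(7)
  base <- dplyr::bind_rows(purrr::map(1:20, function(i) {
    raw_row(
      bin_floor_m = 200 * sample(1:19, 1),
      timestamp = sprintf("2013-04-05T%02d:%02d:00Z", 18 + (i %% 3), 5 * (i %% 12)),
      density = stats::rexp(1, 1 / 10), u = stats::rnorm(1), v = stats::rnorm(1)
    )
  }))
  with_clutter <- dplyr::bind_rows(base, raw_row(bin_floor_m = 0, density = 999, u = 99, v = 99))
  cfg <- preprocess_config()
  expect_equal(preprocess(with_clutter, cfg), preprocess(base, cfg))
})

test_that("aggregating already-aggregated records is the identity", {
  set.seed(11)
  raw <- dplyr::bind_rows(purrr::map(1:30, function(i) {
    raw_row(
      radar_id = sample(c("A", "B"), 1),
      bin_floor_m = 200 * sample(1:19, 1),
      timestamp = sprintf("2013-04-05T18:%02d:00Z", 5 * (i %% 4)),
      density = stats::rexp(1, 1 / 10), u = stats::rnorm(1, 5), v = stats::rnorm(1, 5)
    )
  }))
  cfg <- preprocess_config()
  agg <- preprocess(raw, cfg)
  # re-present the aggregates as bins at their band floors
  as_raw <- tibble::tibble(
    radar_id = agg$radar_id,
    timestamp = agg$interval_start_time,
    bin_floor_m = agg$band_floor_m,
    bin_width_m = 200,
    density = agg$avg_bird_density,
    u = agg$avg_u_speed,
    v = agg$avg_v_speed
  )
  again <- preprocess(as_raw, cfg)
  expect_equal(again$avg_bird_density, agg$avg_bird_density)
  expect_equal(again$avg_u_speed, agg$avg_u_speed)
  expect_equal(again$avg_v_speed, agg$avg_v_speed)
})

test_that("band mean density equals a brute-force mean over retained bins", {
  set.seed(13)
  for (rep in 1:5) {
    raw <- tibble::tibble(
      radar_id = "A",
      timestamp = as.POSIXct("2013-04-05 18:00:00", tz = "UTC"),
      bin_floor_m = seq(200, 3800, by = 200),
      bin_width_m = 200,
      density = stats::rexp(19, 1 / 5),
      u = stats::rnorm(19), v = stats::rnorm(19)
    )
    agg <- preprocess(raw, preprocess_config())
    lo <- raw$density[raw$bin_floor_m < 1600]
    hi <- raw$density[raw$bin_floor_m >= 1600]
    expect_equal(agg$avg_bird_density[agg$band_floor_m == 200], mean(lo))
    expect_equal(agg$avg_bird_density[agg$band_floor_m == 1600], mean(hi))
  }
})

test_that("config validation rejects bad parameters", {
  expect_error(preprocess_config(cross_section = -1), class = "radarflow_config_error")
  expect_error(preprocess_config(interval_minutes = 0), class = "radarflow_config_error")
  expect_error(altitude_bands(c(200, 100)), "sorted|floor", ignore.case = TRUE)
  expect_error(even_strata(7), class = "radarflow_config_error")
  # config files round-trip
  cfg <- preprocess_config(altitude_ceiling = 3000,
                           bands = altitude_bands(c(200, 1600), ceiling = 3000))
  p <- withr::local_tempfile(fileext = ".yml")
  write_preprocess_config(cfg, p)
  expect_equal(read_preprocess_config(p), cfg)
})
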