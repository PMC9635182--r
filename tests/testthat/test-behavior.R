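test_that("dive rule: maximal runs at or below 5 m, duration from sample count", {
  rec <- make_records(depth = c(0, 0, 6, 10, 6, 0),
                      temp = rep(3, 6), wet = rep(TRUE, 6))
  dv <- detect_dives(rec)
  expect_equal(nrow(dv), 1L)
  expect_equal(dv$duration_min, 0.5)
  expect_equal(dv$max_depth_m, 10)

  # exactly 5 m counts; 4.99 does not
  rec2 <- make_records(depth = c(0, 5, 4.99, 5, 0), temp = rep(3, 5),
                       wet = rep(TRUE, 5))
  expect_equal(nrow(detect_dives(rec2)), 2L)

  # all shallow -> no dives; empty input -> empty output
  rec3 <- make_records(depth = rep(4.9, 10), temp = rep(3, 10), wet = rep(TRUE, 10))
  expect_equal(nrow(detect_dives(rec3)), 0L)
  expect_equal(nrow(detect_dives(rec3[0, ])), 0L)

  # raising the threshold never increases the dive count
  depths <- c(0, 6, 8, 0, 5.5, 0, 12, 12, 0, 7)
  rec4 <- make_records(depth = depths, temp = rep(3, 10), wet = rep(TRUE, 10))
  counts <- sapply(c(5, 6, 7, 9, 13), function(th) nrow(detect_dives(rec4, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("daily water range uses 5th/95th linear-interpolation quantiles", {
  expect_equal(unname(water_temp_range(rep(3, 7))), c(3, 3))
  expect_equal(unname(water_temp_range(0:10)), c(0.5, 9.5))
  expect_equal(unname(water_temp_range(4.2)), c(4.2, 4.2))
  expect_true(all(is.na(water_temp_range(numeric(0)))))
})

test_that("surface detection applies all four conditions", {
  # one dive supplies the water range (temps ~ 3), then a quiet wet period
  n <- 60
  depth <- c(rep(0, 10), rep(8, 6), rep(0, n - 16))
  temp <- rep(3, n)
  wet <- rep(TRUE, n)
  rec <- make_records(depth, temp, wet)
  dives <- detect_dives(rec)
  mask <- detect_surface_points(rec, dives)
  expect_true(all(mask[depth < 5])) # stable, wet, in range, not diving
  expect_true(!any(mask[depth >= 5])) # dives excluded

  # condition (d): temperature far from the water range
  temp2 <- temp; temp2[30:40] <- 10
  rec2 <- make_records(depth, temp2, wet)
  mask2 <- detect_surface_points(rec2, detect_dives(rec2))
  expect_true(!any(mask2[30:40]))

  # condition (a): a 0.6 degC jump poisons every window containing it
  temp3 <- temp; temp3[40] <- 3.6
  rec3 <- make_records(depth, temp3, wet)
  mask3 <- detect_surface_points(rec3, detect_dives(rec3))
  expect_true(!any(mask3[31:49])) # centred 180-s windows reaching sample 40

  # condition (c): dry samples never at surface
  wet4 <- wet; wet4[25] <- FALSE
  mask4 <- detect_surface_points(make_records(depth, temp, wet4),
                                 detect_dives(rec))
  expect_false(mask4[25])
})

test_that("daily SST is the mean of at-surface temperatures, missing if none", {
  rec <- make_records(depth = rep(0, 20), temp = rep(3, 20), wet = rep(TRUE, 20))
  mask <- rep(c(TRUE, FALSE), 10)
  sst <- estimate_daily_sst(rec, mask)
  expect_equal(sst$sst_c, 3)
  sst2 <- estimate_daily_sst(rec, rep(FALSE, 20))
  expect_true(is.na(sst2$sst_c))
  expect_equal(sst2$n_surface, 0L)
})

test_that("flight and rest rules: 60-s dry and the 7 degC threshold", {
  # 120 s dry and cold -> flight
  rec <- make_records(depth = rep(0, 20), temp = c(rep(3, 4), rep(5, 12), rep(3, 4)),
                      wet = c(rep(TRUE, 4), rep(FALSE, 12), rep(TRUE, 4)))
  iv <- detect_flight_and_rest(rec)
  expect_equal(iv$class, "flight")
  expect_equal(iv$duration_s, 120)

  # 50 s dry and cold -> nothing (swim residual)
  rec2 <- make_records(depth = rep(0, 12), temp = rep(5, 12),
                       wet = c(rep(TRUE, 4), rep(FALSE, 5), rep(TRUE, 3)))
  expect_equal(nrow(detect_flight_and_rest(rec2)), 0L)

  # warm dry run of any length -> rest (leg-tuck), even short ones
  rec3 <- make_records(depth = rep(0, 40), temp = c(rep(3, 5), rep(15, 30), rep(3, 5)),
                       wet = c(rep(TRUE, 5), rep(FALSE, 30), rep(TRUE, 5)))
  iv3 <- detect_flight_and_rest(rec3)
  expect_equal(iv3$class, "rest")
  expect_equal(iv3$duration_s, 300)

  # max temperature exactly 7 stays unclassified
  rec4 <- make_records(depth = rep(0, 20), temp = rep(7, 20),
                       wet = c(rep(TRUE, 2), rep(FALSE, 16), rep(TRUE, 2)))
  expect_equal(nrow(detect_flight_and_rest(rec4)), 0L)
})

test_that("daily budget components always sum to recorded coverage", {
  # a gap-free synthetic day that is one long rest bout
  n <- 8640
  rec <- make_records(depth = rep(0, n), temp = rep(15, n), wet = rep(FALSE, n),
                      start = as.POSIXct("2019-01-15 00:00:00", tz = "UTC"))
  b <- daily_activity_budget(rec)
  expect_equal(c(b$t_fly_h, b$t_dive_h, b$t_rest_h, b$t_swim_h), c(0, 0, 24, 0))

  # no classifiable intervals -> all swim
  rec2 <- make_records(depth = rep(0, 360), temp = rep(3, 360), wet = rep(TRUE, 360))
  b2 <- daily_activity_budget(rec2)
  expect_equal(b2$t_swim_h, 1)
  expect_equal(b2$t_fly_h + b2$t_dive_h + b2$t_rest_h + b2$t_swim_h, b2$coverage_h)
})

test_that("dive light assignment and per-class dive time", {
  # local solar noon at 55N, 50W in January is about 15:20 UTC -> day
  dives <- data.frame(bird_id = "b1", date = as.Date("2019-01-15"),
                      start = as.POSIXct("2019-01-15 15:20:00", tz = "UTC"),
                      end = as.POSIXct("2019-01-15 15:22:00", tz = "UTC"),
                      duration_min = 2, max_depth_m = 40, n_samples = 12L)
  pos <- data.frame(bird_id = "b1", date = as.Date("2019-01-15"),
                    lat = 55, lon = -50, source = "provided")
  dv <- assign_dive_light(dives, pos)
  expect_equal(as.character(dv$light_class), "day")
  agg <- dive_time_by_light(dv)
  expect_equal(agg$dive_day_h, 2 / 60)
  expect_equal(agg$prop_day, 1)
  expect_equal(agg$dive_night_h, 0)

  # deep night at the same place -> night
  dives$start <- as.POSIXct("2019-01-15 03:00:00", tz = "UTC")
  dv2 <- assign_dive_light(dives, pos)
  expect_equal(as.character(dv2$light_class), "night")

  # missing position -> missing light class
  dv3 <- assign_dive_light(dives, pos[0, ])
  expect_true(is.na(dv3$light_class))
})

test_that("depth histogram normalises to 100 within each group", {
  dives <- data.frame(
    bird_id = "b1", date = as.Date("2019-01-15"),
    max_depth_m = c(55, 8, 12, 73, 15),
    light_class = factor(c("day", "night", "night", "day", "nautical_twilight"),
                         levels = light_levels()),
    habitat = c("cold", "cold", "warm", "warm", "warm")
  )
  h <- dive_depth_histogram(dives, group = "habitat")
  sums <- tapply(h$pct, h$group, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  one <- dive_depth_histogram(dives[1, ])
  expect_equal(one$depth_bin_lo, 50)
  expect_equal(one$pct, 100)
  expect_equal(as.character(one$light_class), "day")
})
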