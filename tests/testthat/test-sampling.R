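test_that("scan times follow the end-of-interval convention", {
  expect_length(scan_times(7200, 600), 12)
  expect_length(scan_times(7200, 300), 24)
  expect_length(scan_times(7200, 900), 8)
  expect_length(scan_times(7200, 1800), 4)
  expect_equal(scan_times(7200, 7200), 7200)
  expect_equal(scan_times(1200, 600), c(600, 1200))
  expect_warning(out <- scan_times(500, 600), "no scans")
  expect_length(out, 0)
})

test_that("scan grids at multiple intervals nest when intervals divide", {
  t10 <- scan_times(7200, 600)
  t15 <- scan_times(7200, 900)
  t30 <- scan_times(7200, 1800)
  expect_true(all(t30 %in% t15))
  expect_true(all(t30 %in% t10))
  # an offset shifts the whole grid
  expect_equal(scan_times(7200, 1800, offset_s = 900),
               c(2700, 4500, 6300) + 0)
})

test_that("instantaneous scanning reads off state and visibility", {
  tl <- walk_rest_timeline(split = 60, duration = 120)
  st <- scan_sample(tl, sampling_scheme(30))
  expect_equal(st$scans$time_s, c(30, 60, 90, 120))
  expect_equal(st$scans$visible_count, rep(1L, 4))
  # half-open bouts: at t=60 the animal has switched to rest
  expect_equal(st$scans$walk, c(1L, 0L, 0L, 0L))
  expect_equal(st$scans$rest, c(0L, 1L, 1L, 1L))

  # invisible at exactly one scan time decrements that scan only
  tl2 <- session_timeline(
    "s1", 120,
    bouts = tibble::tibble(animal_id = "a1", behavior = "walk",
                           start_s = 0, end_s = 120),
    visibility = tibble::tibble(animal_id = "a1", start_s = c(0, 55, 65),
                                end_s = c(55, 65, 120),
                                visible = c(TRUE, FALSE, TRUE)))
  st2 <- scan_sample(tl2, sampling_scheme(30))
  expect_equal(st2$scans$visible_count, c(1L, 0L, 1L, 1L))
})

test_that("window-majority scoring uses the dominant behavior and half-window visibility", {
  # within the 10-s window ending at t=60: walk 6 s then rest 4 s
  tl <- session_timeline(
    "s1", 120,
    bouts = tibble::tibble(animal_id = "a1",
                           behavior = c("walk", "rest", "walk"),
                           start_s = c(0, 56, 70), end_s = c(56, 70, 120)))
  st <- scan_sample(tl, sampling_scheme(60, window_s = 10,
                                        mode = "window_majority"))
  expect_equal(st$scans$walk[1], 1L)
  expect_equal(st$scans$rest[1], 0L)

  # visible for under half the window: not counted
  tl3 <- session_timeline(
    "s1", 120,
    bouts = tibble::tibble(animal_id = "a1", behavior = "walk",
                           start_s = 0, end_s = 120),
    visibility = tibble::tibble(animal_id = "a1", start_s = c(0, 57),
                                end_s = c(57, 120), visible = c(FALSE, TRUE)))
  st3 <- scan_sample(tl3, sampling_scheme(60, window_s = 10,
                                          mode = "window_majority"))
  expect_equal(st3$scans$visible_count[1], 0L)
  # ...but at the second scan (window fully visible) it is
  expect_equal(st3$scans$visible_count[2], 1L)
})

test_that("occurrence from scans averages percent of visible animals", {
  scans <- tibble::tibble(time_s = c(600, 1200),
                          visible_count = c(10L, 10L),
                          walk = c(1L, 2L), rest = c(9L, 8L))
  st <- scan_table("s1", 600, scans)
  occ <- occurrence_from_scans(st)
  expect_equal(occ$value[occ$behavior == "walk"], 15)
  expect_equal(occ$value[occ$behavior == "rest"], 85)
  expect_equal(occ$method[1], "10min")

  # zero-visible scans are dropped from the mean, not treated as zero
  scans3 <- tibble::tibble(time_s = c(600, 1200, 1800),
                           visible_count = c(50L, 50L, 0L),
                           walk = c(5L, 10L, 0L), rest = c(45L, 40L, 0L))
  st3 <- scan_table("s1", 600, scans3)
  expect_message(occ3 <- occurrence_from_scans(st3), "dropped")
  expect_equal(occ3$value[occ3$behavior == "walk"], 15)

  # all-zero-visible is an error
  scans0 <- tibble::tibble(time_s = 600, visible_count = 0L,
                           walk = 0L, rest = 0L)
  expect_error(occurrence_from_scans(scan_table("s1", 600, scans0)),
               "visible")
})

test_that("a behavior never observed scores exactly zero", {
  tl <- walk_rest_timeline()
  eth3 <- ethogram(c("walk", "rest", "fly"))
  occ <- occurrence_from_scans(scan_sample(tl, sampling_scheme(30), eth3))
  expect_equal(occ$value[occ$behavior == "fly"], 0)
  occ_c <- occurrence_continuous(tl, eth3)
  expect_equal(occ_c$value[occ_c$behavior == "fly"], 0)
})

test_that("continuous occurrence weights by visible animal-time", {
  tl <- walk_rest_timeline(split = 60, duration = 120)
  occ <- occurrence_continuous(tl)
  expect_equal(occ$value[occ$behavior == "walk"], 50)

  # visibility off during all resting time -> walking is 100% of visible time
  tl2 <- session_timeline(
    "s1", 120,
    bouts = tibble::tibble(animal_id = "a1", behavior = c("walk", "rest"),
                           start_s = c(0, 60), end_s = c(60, 120)),
    visibility = tibble::tibble(animal_id = "a1", start_s = c(0, 60),
                                end_s = c(60, 120), visible = c(TRUE, FALSE)))
  occ2 <- occurrence_continuous(tl2)
  expect_equal(occ2$value[occ2$behavior == "walk"], 100)
  expect_equal(occ2$value[occ2$behavior == "rest"], 0)
})

test_that("occurrence values sum to 100 under both methods", {
  cfg <- fast_sim_config(n_animals = 6, duration_s = 3600,
                         visible_fraction = 0.8)
  tl <- simulate_flock(cfg, seed = 31)
  expect_equal(sum(occurrence_continuous(tl)$value), 100, tolerance = 1e-9)
  for (iv in c(300, 900)) {
    occ <- occurrence_from_scans(scan_sample(tl, sampling_scheme(iv)))
    expect_equal(sum(occ$value), 100, tolerance = 1e-9)
  }
})

test_that("short-interval scanning converges to the continuous record", {
  cfg <- fast_sim_config(n_animals = 15, duration_s = 7200)
  tl <- simulate_flock(cfg, seed = 41)
  occ_c <- occurrence_continuous(tl)
  occ_s <- occurrence_from_scans(scan_sample(tl, sampling_scheme(60)))
  j <- dplyr::inner_join(occ_c, occ_s, by = "behavior")
  expect_lt(max(abs(j$value.x - j$value.y)), 3)
})
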