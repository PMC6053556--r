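test_that("simulate_population respects size, arc and seed", {
  expect_equal(nrow(simulate_population(0)), 0)

  pop <- simulate_population(6, spatial_extent = 180, seed = 3)
  expect_equal(nrow(pop), 6)
  expect_true(all(pop$bearing_deg >= 0 & pop$bearing_deg < 180))
  expect_true(all(pop$distance_m > 0))
  expect_true(all(pop$call_rate >= 0))
  expect_true(all(pop$boom_mean >= 1))

  expect_identical(simulate_population(12, seed = 1),
                   simulate_population(12, seed = 1))

  expect_error(simulate_population(-1), "integer")
  expect_error(simulate_population(3, spatial_extent = 0), "spatial_extent")
  expect_error(simulate_population(3, spatial_extent = 400), "spatial_extent")
})

test_that("stereo channel follows the half-plane convention with right-side tie-break", {
  expect_identical(stereo_channel_of(90, 0), "right")
  expect_identical(stereo_channel_of(270, 0), "left")
  expect_identical(stereo_channel_of(0, 0), "right")    # on-axis ahead
  expect_identical(stereo_channel_of(180, 0), "right")  # on-axis astern
  # rotating the recorder rotates the split
  expect_identical(stereo_channel_of(10, 100), "left")
  expect_identical(stereo_channel_of(190, 100), "right")
  expect_error(stereo_channel_of(NaN, 0), "finite")
})

test_that("empty populations and empty channel sets are handled", {
  ses <- simulate_session(simulate_population(0), seed = 1)
  expect_equal(ses$truth_n_calling, 0)
  expect_true(all(vapply(ses$calls, nrow, integer(1)) == 0))
  # empty channels still typed correctly
  expect_type(ses$calls$STEREO$stereo_channel, "character")
  expect_error(simulate_session(simulate_population(1), channels = character(0)),
               "non-empty")
  expect_error(simulate_session(simulate_population(1), channels = "SONO"),
               "subset")
})

test_that("perfect detection with zero noise gives identical call lists on all channels", {
  det <- detection_spec(p_detect = c(OBS = 1, MONO = 1, STEREO = 1),
                        bearing_noise_sd = 0, volume_misclass_p = 0)
  pop <- simulate_population(5, seed = 11, call_rate_mean = 4)
  ses <- simulate_session(pop, det, seed = 12)
  core <- function(ch) ses$calls[[ch]][c("time_s", "bearing_deg",
                                         "volume_class", "boom_count",
                                         "truth_id")]
  expect_identical(core("OBS"), core("MONO"))
  expect_identical(core("OBS"), core("STEREO"))
  expect_gt(nrow(ses$calls$OBS), 0)
})

test_that("a channel with zero detection probability records nothing", {
  det <- detection_spec(p_detect = c(OBS = 1, MONO = 0, STEREO = 1))
  pop <- simulate_population(4, seed = 21, call_rate_mean = 6)
  ses <- simulate_session(pop, det, seed = 22)
  expect_equal(nrow(ses$calls$MONO), 0)
  expect_gt(nrow(ses$calls$OBS), 0)
})

test_that("volume classes come from inverse-square received level and misclassify only to adjacent classes", {
  # cuts far above any received level force every true class to low ...
  det_low <- detection_spec(bearing_noise_sd = 0, volume_cuts = c(1e6, 2e6))
  pop <- simulate_population(4, seed = 31, call_rate_mean = 5)
  ses <- simulate_session(pop, det_low, seed = 32)
  expect_true(all(ses$calls$OBS$volume_class == "low"))
  # ... and certain misclassification moves low exactly one class up to med
  det_flip <- detection_spec(bearing_noise_sd = 0, volume_misclass_p = 1,
                             volume_cuts = c(1e6, 2e6))
  ses2 <- simulate_session(pop, det_flip, seed = 32)
  expect_true(all(ses2$calls$OBS$volume_class == "med"))
})

test_that("distance-dependent detection functions are honoured", {
  det <- detection_spec(p_detect = list(OBS = 1,
                                        MONO = function(d) as.numeric(d < 500)))
  pop <- simulate_population(8, seed = 41, call_rate_mean = 5,
                             distance_range = c(100, 1000))
  ses <- simulate_session(pop, det, channels = c("OBS", "MONO"), seed = 42)
  near <- pop$id[pop$distance_m < 500]
  expect_true(all(ses$calls$MONO$truth_id %in% near))
})

test_that("campaign composition matches the spec fields exactly", {
  spec <- campaign_spec(n_three_way = 5, n_obs_mono = 4, n_obs_stereo = 3,
                        station_count = 6, seed = 9)
  camp <- simulate_campaign(spec)
  comp <- table(camp$sessions$channels_present)
  expect_equal(nrow(camp$sessions), 12)
  expect_equal(unname(comp[["OBS+MONO+STEREO"]]), 5)
  expect_equal(unname(comp[["OBS+MONO"]]), 4)
  expect_equal(unname(comp[["OBS+STEREO"]]), 3)
  # stations cycle, occasions advance
  expect_equal(camp$sessions$station_id[1:7],
               c("S01", "S02", "S03", "S04", "S05", "S06", "S01"))
  expect_equal(camp$sessions$occasion[7], 2)

  empty <- simulate_campaign(campaign_spec(0, 0, 0, seed = 1))
  expect_equal(nrow(empty$sessions), 0)
})

test_that("campaigns are bit-reproducible under a fixed seed, including CSV export", {
  spec <- campaign_spec(n_three_way = 4, n_obs_mono = 3, n_obs_stereo = 2,
                        seed = 77)
  c1 <- simulate_campaign(spec)
  c2 <- simulate_campaign(spec)
  expect_identical(c1$sessions, c2$sessions)
  expect_identical(c1$calls, c2$calls)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_campaign(c1, d1)
  write_campaign(c2, d2)
  for (f in c("sessions.csv", "calls.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("raising a channel's detection probability raises its expected call count", {
  pop <- simulate_population(5, seed = 51, call_rate_mean = 3)
  mean_count <- function(p) {
    det <- detection_spec(p_detect = c(OBS = 1, MONO = p))
    counts <- vapply(seq_len(200), function(i) {
      nrow(simulate_session(pop, det, channels = c("OBS", "MONO"),
                            seed = 1000 + i)$calls$MONO)
    }, numeric(1))
    mean(counts)
  }
  m <- vapply(c(0.2, 0.5, 0.9), mean_count, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("simulate_session_counts matches the session total-count law of the full simulator", {
  pop <- simulate_population(3, seed = 61, call_rate_mean = 2)
  rate <- sum(pop$call_rate)
  p <- 0.6
  det <- detection_spec(p_detect = c(MONO = p))
  full <- vapply(seq_len(400), function(i) {
    nrow(simulate_session(pop, det, channels = "MONO", seed = 2000 + i)$calls$MONO)
  }, numeric(1))
  quick <- simulate_session_counts(400, rate, p_detect = p, seed = 3)
  # both are Poisson(rate * p): compare means within 4 MC standard errors
  se <- sqrt(2 * rate * p / 400)
  expect_lt(abs(mean(full) - mean(quick)), 4 * se)
  expect_lt(abs(mean(quick) - rate * p), 4 * se)
})
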