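test_that("spearman_cor recovers perfect monotone association and rejects bad input", {
  expect_equal(spearman_cor(1:4, 1:4)$rho, 1)
  expect_equal(spearman_cor(1:4, 4:1)$rho, -1)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(c(2, 2, 2), 1:3), "zero variance")
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("spearman_cor matches the hand-rank oracle on tied count data", {
  set.seed(31)
  for (i in 1:25) {
    x <- rpois(20, 3)
    y <- rpois(20, 2) + rbinom(20, 1, 0.5) * x
    if (sd(x) == 0 || sd(y) == 0) next
    res <- spearman_cor(x, y)
    expect_equal(res$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    # p from the t approximation with df = n - 2
    tt <- res$rho * sqrt(res$df / (1 - res$rho^2))
    expect_equal(res$p, 2 * pt(-abs(tt), res$df), tolerance = 1e-12)
  }
})

test_that("rho is invariant under strictly monotone transforms of either margin", {
  set.seed(32)
  x <- rpois(30, 4)
  y <- rpois(30, 3) + x
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(x, 2^y)$rho, base)
  expect_equal(spearman_cor(x^3 + x, y)$rho, base)
})

test_that("fisher_z is atanh with a guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "within")
  expect_error(fisher_z(-1.2), "within")
})

test_that("through-origin fit handles exact and noisy data", {
  x <- c(1, 2, 3, 4, 5)
  exact <- through_origin_fit(x, x)
  expect_equal(exact$slope, 1)
  expect_equal(exact$slope_se, 0)
  expect_equal(through_origin_fit(x, 2 * x)$slope, 2)
  expect_error(through_origin_fit(rep(0, 4), 1:4), "degenerate")
  expect_error(through_origin_fit(1, 2), "at least 2")
})

test_that("through-origin fit matches a direct RSS-minimisation oracle", {
  set.seed(33)
  for (i in 1:20) {
    x <- rpois(30, 5)
    y <- rbinom(30, x, 0.7) + rpois(30, 1)
    if (all(x == 0)) next
    fit <- through_origin_fit(x, y)
    ora <- oracle_through_origin(x, y)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-8)
    expect_equal(fit$slope_se, ora$se, tolerance = 1e-8)
    # CI uses the t quantile on n - 1 df
    expect_equal(fit$ci_high - fit$slope, qt(0.975, 29) * fit$slope_se)
  }
})

test_that("through-origin slope is equivariant under scaling of the response", {
  set.seed(34)
  x <- rpois(25, 4) + 1
  y <- rpois(25, 3)
  base <- through_origin_fit(x, y)$slope
  expect_equal(through_origin_fit(x, 3.5 * y)$slope, 3.5 * base)
})

test_that("noiseless campaigns calibrate to rho = 1 and slope = 1 for every option", {
  det <- detection_spec(bearing_noise_sd = 0, volume_misclass_p = 0)
  camp <- simulate_campaign(campaign_spec(20, 15, 10, seed = 35), det)
  tab <- suppressWarnings(calibration_table(camp))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$rho, rep(1, 4))
  expect_equal(tab$slope, rep(1, 4))
  expect_equal(tab$df, tab$n - 2L)
})

test_that("duplicating every session leaves rho and slope unchanged while n doubles", {
  det <- detection_spec(p_detect = c(OBS = 1, MONO = 0.7, STEREO = 0.85))
  camp <- simulate_campaign(campaign_spec(15, 10, 5, seed = 36), det)
  dup_sessions <- camp$sessions
  dup_sessions$session_id <- paste0(dup_sessions$session_id, "b")
  dup_calls <- camp$calls
  dup_calls$session_id <- paste0(dup_calls$session_id, "b")
  camp2 <- as_campaign(rbind(camp$sessions, dup_sessions),
                       rbind(camp$calls, dup_calls))
  t1 <- calibration_table(camp)
  t2 <- calibration_table(camp2)
  expect_equal(t2$rho, t1$rho)
  expect_equal(t2$slope, t1$slope)
  expect_equal(t2$n, 2L * t1$n)
})

test_that("options without paired sessions are dropped with a warning", {
  camp <- simulate_campaign(campaign_spec(0, 10, 0, seed = 37))
  expect_warning(expect_warning(tab <- calibration_table(camp),
                                "STEREO-VISUAL"),
                 "STEREO-AUDIBLE")
  expect_equal(sort(tab$option), c("MONO-AUDIBLE", "MONO-VISUAL"))
})

test_that("individuals calibration pairs stereo estimates with observer estimates", {
  det <- detection_spec(bearing_noise_sd = 0, volume_misclass_p = 0)
  camp <- simulate_campaign(campaign_spec(25, 0, 15, seed = 38), det,
                            birds_lambda = 3)
  res <- individuals_calibration(camp)
  expect_s3_class(res, "calibration_result")
  expect_equal(res$n, 40)
  expect_true(all(res$pairs$device_count <= 6))
  expect_true(all(res$pairs$device_count >= 0))
  # against truth instead of the observer estimate
  res_truth <- individuals_calibration(camp, use_truth = TRUE)
  expect_equal(res_truth$n, 40)
  expect_error(individuals_calibration(
    simulate_campaign(campaign_spec(0, 5, 0, seed = 39))), "STEREO")
})

test_that("the stereo capacity binds: crowded sessions cap device counts at six", {
  # one session with ten well-separated loud birds spread over both channels
  set.seed(40)
  bearings <- seq(5, 355, length.out = 10)
  calls <- tibble::tibble(
    session_id = "C001", station_id = "S01", occasion = 1L, channel = "STEREO",
    time_s = seq(10, 100, length.out = 10),
    bearing_deg = bearings,
    volume_class = rep(c("low", "med", "high"), length.out = 10),
    boom_count = 3L,
    stereo_channel = stereo_channel_of(bearings),
    truth_id = 1:10
  )
  sessions <- tibble::tibble(session_id = "C001", station_id = "S01",
                             occasion = 1L, channels_present = "STEREO",
                             truth_n_calling = 10L)
  camp <- as_campaign(sessions, calls)
  dev <- assign_stereo_audible(calls)
  expect_lte(dev$n_individuals, 6)
  expect_gt(sessions$truth_n_calling[1], dev$n_individuals)
})

test_that("zero-variance pairings yield a flagged undefined rho, not an error", {
  sessions <- tibble::tibble(session_id = paste0("C", 1:4), station_id = "S01",
                             occasion = 1L, channels_present = "OBS+STEREO",
                             truth_n_calling = 1L)
  calls <- dplyr::bind_rows(lapply(1:4, function(i) tibble::tibble(
    session_id = paste0("C", i), station_id = "S01", occasion = 1L,
    channel = c("OBS", "STEREO"), time_s = 10, bearing_deg = 45,
    volume_class = "med", boom_count = 3L,
    stereo_channel = c(NA, "right"), truth_id = 1L
  )))
  camp <- as_campaign(sessions, calls)
  res <- individuals_calibration(camp, use_truth = TRUE)
  expect_true(is.na(res$rho))
  expect_match(res$note, "zero-variance")
  expect_equal(res$slope, 1)
})
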