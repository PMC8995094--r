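protocol_events <- c(Tg = 60, Ca_readd = 660, Ca_removal = 780, Mn_add = 840)

test_that("noiseless recordings are exact piecewise constructions", {
  rec <- simulate_fura2_recording(noise_sd = 0, quench_rate_per_s = 0.01,
                                  events = protocol_events, seed = 1)
  tr <- ratio_trace(rec)
  # baseline segment is exactly 1 in R/R0
  expect_equal(tr$R_over_R0[tr$time_s < 60], rep(1, sum(tr$time_s < 60)))
  # max first derivative of the rise equals the entry slope exactly
  rise <- tr[tr$time_s >= 660 & tr$time_s <= 780, ]
  d <- diff(rise$R_over_R0) / diff(rise$time_s)
  expect_equal(max(d), 0.02, tolerance = 1e-12)
  # 360 nm channel decays as exp(-rate * (t - t_Mn)) after the Mn event
  f360 <- rec$data[rec$data$roi_id == "roi01" & rec$data$channel == "F360", ]
  post <- f360$time_s >= 840
  norm <- (f360$value[post] - 50) / (f360$value[f360$time_s == 0] - 50)
  expect_equal(norm, exp(-0.01 * (f360$time_s[post] - 840)), tolerance = 1e-12)
})

test_that("a null entry protocol produces a flat post-readmission segment", {
  rec <- simulate_fura2_recording(entry_slope_per_s = 0, noise_sd = 0,
                                  release_decay_s = 10, seed = 1)
  tr <- ratio_trace(rec)
  seg <- tr$R_over_R0[tr$time_s >= 660 & tr$time_s < 780]
  expect_lt(diff(range(seg)), 1e-9)
})

test_that("recordings are seed-deterministic and validate their events", {
  a <- simulate_fura2_recording(n_rois = 2, seed = 5)
  b <- simulate_fura2_recording(n_rois = 2, seed = 5)
  expect_identical(a$data, b$data)
  expect_error(simulate_fura2_recording(frame_interval_s = 0), "frame_interval")
  expect_error(simulate_fura2_recording(events = c(Tg = 500, Ca_readd = 100)),
               "increasing")
  expect_error(simulate_fura2_recording(events = c(Tg = 60, Ca_readd = 2000)),
               "inside the recording")
})

test_that("R/R0 traces are ratio- and scale-invariant with unit baseline", {
  rec <- simulate_fura2_recording(noise_sd = 0, seed = 1)
  tr <- ratio_trace(rec)
  base <- tr$R_over_R0[tr$time_s < 60]
  expect_equal(mean(base), 1, tolerance = 1e-12)
  # constant F340 = 2 * F380 after subtraction: R identically 2, R/R0 = 1
  t <- seq(0, 100, 1)
  d <- tibble::tibble(
    time_s = rep(t, 3),
    roi_id = rep(c("roi01", "roi01", "background"), each = length(t)),
    channel = rep(c("F340", "F380", "F380"), each = length(t)),
    value = rep(c(210, 105, 5), each = length(t))
  )
  d <- rbind(d, tibble::tibble(time_s = t, roi_id = "background",
                               channel = "F340", value = 10))
  rec2 <- fura2_recording(d, events = c(Tg = 50))
  tr2 <- ratio_trace(rec2)
  expect_equal(unique(tr2$R), 2)
  expect_equal(unique(tr2$R_over_R0), 1)
  # doubling both channels and their backgrounds leaves R unchanged
  d3 <- d; d3$value <- d3$value * 2
  tr3 <- ratio_trace(fura2_recording(d3, events = c(Tg = 50)))
  expect_equal(tr3$R, tr2$R)
})

test_that("frames with non-positive denominator are dropped and counted", {
  t <- seq(0, 20, 1)
  f380 <- rep(100, length(t)); f380[5] <- 2   # below the background of 5
  d <- dplyr::bind_rows(
    tibble::tibble(time_s = t, roi_id = "roi01", channel = "F340", value = 200),
    tibble::tibble(time_s = t, roi_id = "roi01", channel = "F380", value = f380),
    tibble::tibble(time_s = t, roi_id = "background", channel = "F340", value = 0),
    tibble::tibble(time_s = t, roi_id = "background", channel = "F380", value = 5)
  )
  tr <- ratio_trace(fura2_recording(d, events = c(Tg = 10)))
  expect_equal(unname(attr(tr, "n_dropped")["roi01"]), 1L)
  expect_equal(nrow(tr), length(t) - 1)
})

test_that("slope engine is exact on a noiseless clamped ramp", {
  t <- seq(0, 200, 0.5)
  tr <- tibble::tibble(time_s = t,
                       R_over_R0 = pmin(1 + 0.02 * pmax(t - 50, 0), 1.5))
  est <- slope_from_derivative(tr, direction = "rising")
  expect_equal(est$slope_per_s, 0.02, tolerance = 1e-12)
  # regression window spans the ramp (50 s to 75 s)
  expect_lt(est$t_start, 52)
  expect_gt(est$t_end, 73)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
})

test_that("slope engine approaches the logistic maximum slope A*k/4", {
  # high derivative fraction shrinks the window onto the inflection point,
  # where the instantaneous slope of A/(1+exp(-k(t-t0))) is A*k/4
  t <- seq(-50, 50, 0.05)
  A <- 1; k <- 0.3
  tr <- tibble::tibble(time_s = t, R_over_R0 = A / (1 + exp(-k * t)))
  est <- slope_from_derivative(tr, direction = "rising", alpha = 0.95)
  expect_equal(est$slope_per_s, A * k / 4, tolerance = 0.02)
  # detected window is centred on the inflection time t0 = 0
  expect_lt(abs((est$t_start + est$t_end) / 2), 1)
})

test_that("slope engine handles flat traces and short segments", {
  t <- seq(0, 50, 1)
  flat <- tibble::tibble(time_s = t, R_over_R0 = rep(2, length(t)))
  est <- slope_from_derivative(flat, direction = "rising")
  expect_equal(est$slope_per_s, 0)
  expect_true(est$flat)
  expect_true(is.na(est$r_squared))
  expect_error(slope_from_derivative(flat[1:4, ], direction = "rising"),
               "at least 5 frames")
})

test_that("entry rate is exact noiseless and unbiased under noise", {
  rec0 <- simulate_fura2_recording(noise_sd = 0, seed = 1)
  est0 <- entry_rate(ratio_trace(rec0))
  expect_equal(est0$slope_per_s, 0.02, tolerance = 1e-9)
  rec <- simulate_fura2_recording(noise_sd = 0.005, seed = 2)
  est <- entry_rate(ratio_trace(rec))
  expect_equal(est$slope_per_s, 0.02, tolerance = 0.1)
})

test_that("a zero-slope protocol yields an entry estimate consistent with zero", {
  rec <- simulate_fura2_recording(entry_slope_per_s = 0, release_decay_s = 10,
                                  noise_sd = 0.005, seed = 3)
  tr <- ratio_trace(rec)
  est <- entry_rate(tr)
  # refit over the reported window to get the OLS standard error
  seg <- tr[tr$time_s >= est$t_start & tr$time_s <= est$t_end, ]
  se <- summary(lm(R_over_R0 ~ time_s, data = seg))$coefficients[2, 2]
  expect_lt(abs(est$slope_per_s), 3 * se + 1e-6)
})

test_that("extrusion rate recovers the decay constant; short segments error", {
  rec <- simulate_fura2_recording(noise_sd = 0, extrusion_rate_per_s = 0.05,
                                  seed = 1)
  tr <- ratio_trace(rec)
  est <- extrusion_rate(tr)
  expect_equal(est$rate_per_s, 0.05, tolerance = 1e-9)
  expect_lte(est$slope_per_s, 0)
  expect_equal(est$kind, "extrusion")
  # no decay: rate 0, flagged flat
  rec0 <- simulate_fura2_recording(noise_sd = 0, extrusion_rate_per_s = 0, seed = 1)
  est0 <- extrusion_rate(ratio_trace(rec0))
  expect_equal(est0$rate_per_s, 0)
  expect_true(est0$flat)
  # 4-frame decay segment is a precondition violation
  tr4 <- tibble::tibble(time_s = c(780, 781, 782, 783), roi_id = "roi01",
                        R_over_R0 = c(1.5, 1.4, 1.3, 1.2))
  expect_error(extrusion_rate(tr4, events = c(Ca_removal = 780)),
               "at least 5 frames")
})

test_that("Mn2+ quench analysis recovers rates and enforces its inputs", {
  rec <- simulate_fura2_recording(noise_sd = 0, quench_rate_per_s = 0.01,
                                  events = protocol_events, seed = 1)
  est <- quench_rate(rec)
  expect_equal(est$rate_per_s, 0.01, tolerance = 1e-9)
  expect_lte(est$slope_per_s, 0)
  # flat F360 (no quench modeled): rate 0
  rec0 <- simulate_fura2_recording(noise_sd = 0, quench_rate_per_s = 0,
                                   events = protocol_events, seed = 1)
  expect_equal(quench_rate(rec0)$rate_per_s, 0)
  # missing F360 channel is an explicit unsupported-recording error
  rec2 <- simulate_fura2_recording(seed = 1)
  rec2$data <- rec2$data[rec2$data$channel != "F360", ]
  expect_error(quench_rate(rec2), "F360")
})

test_that("peak amplitude uses the global maximum over baseline", {
  rec <- simulate_fura2_recording(noise_sd = 0, release_amplitude = 0.8, seed = 1)
  pk <- peak_amplitude(ratio_trace(rec), "Tg")
  expect_equal(pk$peak_amplitude, 0.8, tolerance = 1e-9)
  expect_false(pk$nonpositive)
  # monotone decreasing post-event trace: amplitude <= 0, flagged
  t <- 0:60
  tr <- tibble::tibble(time_s = t, roi_id = "roi01",
                       R_over_R0 = c(rep(1, 10), 1 - 0.01 * (0:50)))
  pk2 <- peak_amplitude(tr, "Tg", events = c(Tg = 10))
  expect_true(pk2$nonpositive)
  # two transients in the segment: global max wins
  tr3 <- tibble::tibble(time_s = 0:100, roi_id = "roi01",
                        R_over_R0 = 1 + 0.5 * exp(-(0:100 - 20)^2 / 8) +
                          0.9 * exp(-(0:100 - 70)^2 / 8))
  pk3 <- peak_amplitude(tr3, "Tg", events = c(Tg = 10))
  expect_equal(pk3$peak_amplitude, max(tr3$R_over_R0) - 1, tolerance = 1e-6)
  expect_equal(pk3$t_peak, 70)
})

test_that("entry slopes are non-negative and quench slopes non-positive", {
  for (s in 1:10) {
    rec <- simulate_fura2_recording(noise_sd = 0.005, quench_rate_per_s = 0.024,
                                    events = protocol_events, seed = s)
    tr <- ratio_trace(rec)
    expect_gte(entry_rate(tr)$slope_per_s, 0)
    expect_lte(quench_rate(rec)$slope_per_s, 0)
  }
})
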