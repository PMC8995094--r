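test_that("gap distance is exact for parallel and coincident traces", {
  tp <- simulate_trace_pair(gap_nm = 17, length_nm = 66, seed = 1)
  expect_equal(gap_distance(tp)$gap_nm, 17, tolerance = 1e-12)
  # coincident traces
  er <- cbind(seq(0, 50, 5), 0)
  expect_equal(gap_distance(list(pm = er, er = er))$gap_nm, 0)
})

test_that("gap distance uses point-to-segment distances, not vertices", {
  # PM with widely spaced vertices: a point above the middle of a segment is
  # 5 nm from the segment but ~50 nm from the nearest vertex
  pm <- cbind(c(0, 100), c(0, 0))
  er <- cbind(c(45, 55), c(5, 5))
  expect_equal(gap_distance(list(pm = pm, er = er), spacing_nm = 1)$gap_nm, 5,
               tolerance = 1e-12)
})

test_that("cer length sums segment lengths and prefers a long-axis trace", {
  expect_equal(cer_length(cbind(c(0, 66), c(0, 0))), 66)
  expect_equal(cer_length(cbind(c(0, 30, 30), c(0, 40, 100))), 110)
  # random polyline equals the independent hypotenuse-sum oracle
  set.seed(42)
  xy <- cbind(cumsum(rnorm(20)), cumsum(rnorm(20)))
  expect_equal(cer_length(xy), oracle_polyline_length(xy), tolerance = 1e-9)
  # AXIS rows, when present, define the measured polyline
  tp <- simulate_trace_pair(10, 50, seed = 1)
  axis <- tibble::tibble(structure_id = "S1", membrane = "AXIS",
                         x_nm = c(0, 80), y_nm = c(0, 0),
                         condition = "NT", tether = "none")
  expect_equal(cer_length(rbind(tp, axis)), 80)
})

test_that("morphometry is invariant under rigid transforms", {
  fx <- make_curved_fixture(gap = 12, length_er = 80, curvature = 0.002)
  g0 <- gap_distance(list(pm = fx$pm, er = fx$er), spacing_nm = 0.5)$gap_nm
  l0 <- cer_length(fx$er)
  for (i in 1:5) {
    th <- i * 1.1
    shift <- c(100 * i, -50 * i)
    g1 <- gap_distance(list(pm = rigid_transform(fx$pm, th, shift),
                            er = rigid_transform(fx$er, th, shift)),
                       spacing_nm = 0.5)$gap_nm
    l1 <- cer_length(rigid_transform(fx$er, th, shift))
    expect_equal(g1, g0, tolerance = 1e-9)
    expect_equal(l1, l0, tolerance = 1e-9)
  }
})

test_that("degenerate traces are rejected", {
  expect_error(gap_distance(list(pm = cbind(0, 0), er = cbind(c(0, 1), c(0, 0)))),
               "at least 2 points")
  same <- cbind(c(5, 5, 5), c(2, 2, 2))
  expect_error(gap_distance(list(pm = same, er = cbind(c(0, 1), c(0, 0)))),
               "zero-length")
  expect_error(cer_length(cbind(1, 1)), "at least 2 points")
  expect_error(gap_distance(list(pm = cbind(c(0, NaN), c(0, 1)),
                                 er = cbind(c(0, 1), c(0, 0)))), "finite")
})

test_that("cleft volume follows the cylindric model and its limits", {
  expect_equal(cleft_volume(1, 2), pi)
  expect_equal(cleft_volume(17, 66), pi * 33^2 * 17)
  # linear in gap near zero
  expect_equal(cleft_volume(1e-9, 100) / 1e-9, pi * 50^2, tolerance = 1e-9)
  expect_error(cleft_volume(0, 10), "positive")
  expect_error(cleft_volume(10, -1), "positive")
})

test_that("cortical filter keeps gaps strictly below 30 nm and reports discards", {
  d <- tibble::tibble(gap_nm = c(5, 17, 29.9, 30, 45),
                      length_nm = 1, cleft_volume_nm3 = 1)
  expect_message(out <- cortical_filter(d), "discarded 2")
  expect_equal(out$gap_nm, c(5, 17, 29.9))
  expect_equal(attr(out, "n_discarded"), 2)
  # identity when everything is cortical
  all_in <- d[d$gap_nm < 30, ]
  expect_silent(out2 <- cortical_filter(all_in))
  expect_equal(out2$gap_nm, all_in$gap_nm)
  # retained fraction matches the analytic CDF for a known gap law
  gaps <- tibble::tibble(gap_nm = seq(0.02, 40, by = 0.02) - 0.01)
  frac <- nrow(suppressMessages(cortical_filter(gaps))) / nrow(gaps)
  expect_equal(frac, 30 / 40, tolerance = 0.001)
})

test_that("condition summaries use per-structure volumes and sample sd", {
  d <- tibble::tibble(condition = "NT", tether = "none",
                      gap_nm = c(10, 10), length_nm = c(100, 200),
                      cleft_volume_nm3 = cleft_volume(c(10, 10), c(100, 200)))
  s <- condition_summary(d)
  expect_equal(s$n, 2)
  expect_equal(s$mean_length_nm, 150)
  # mean of per-structure volumes, not volume of the mean structure
  expect_equal(s$mean_volume_nm3, mean(c(pi * 2500 * 10, pi * 10000 * 10)))
  expect_false(isTRUE(all.equal(s$mean_volume_nm3, pi * 75^2 * 10)))
  expect_equal(s$sd_gap_nm, sd(c(10, 10)))
  # single-record group flagged, sd undefined
  expect_warning(s1 <- condition_summary(d[1, ]), "single record")
  expect_false(s1$sd_defined)
  expect_true(is.na(s1$sd_gap_nm))
})

test_that("group means recover generator parameters within sampling error", {
  pop <- simulate_cer_population(1500, short_gap_mean_nm = 17,
                                 short_gap_sd_nm = 2, plateau_gap_nm = 5.2,
                                 seed = 11)
  s <- condition_summary(pop, group_keys = character(0))
  short <- pop[!pop$long, ]
  se <- sd(short$gap_nm) / sqrt(nrow(short))
  expect_lt(abs(mean(short$gap_nm) - 17), 3 * se)
  expect_equal(s$n, nrow(pop))
})

test_that("fold changes report full precision plus a 2-significant-figure label", {
  fc <- fold_change(66, 156)
  expect_equal(fc$ratio, 156 / 66)
  expect_equal(fc$label, "2.4-fold")
  fc2 <- fold_change(117, 521)
  expect_equal(fc2$ratio, 521 / 117)
  expect_equal(fc2$label, "4.5-fold")
  expect_equal(fold_change(12, 12)$ratio, 1)
  expect_error(fold_change(0, 5), "denominator")
  # summary-level interface
  d <- tibble::tibble(condition = c("NT", "CF"),
                      gap_nm = c(17, 17), length_nm = c(66, 156),
                      cleft_volume_nm3 = 1)
  s <- condition_summary(rbind(d, d), group_keys = "condition")
  expect_equal(fold_change(s[s$condition == "NT", ], s[s$condition == "CF", ],
                           "length")$ratio, 156 / 66)
})

test_that("cer_morphometry maps traces to one record per structure", {
  tps <- dplyr::bind_rows(
    simulate_trace_pair(17, 66, structure_id = "A", seed = 1),
    simulate_trace_pair(12, 150, structure_id = "B", seed = 2)
  )
  m <- cer_morphometry(tps, spacing_nm = 0.5)
  expect_equal(nrow(m), 2)
  expect_equal(m$gap_nm[m$structure_id == "A"], 17, tolerance = 1e-9)
  expect_equal(m$length_nm[m$structure_id == "B"], 150, tolerance = 1e-9)
  expect_equal(m$cleft_volume_nm3, pi * (m$length_nm / 2)^2 * m$gap_nm)
})
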