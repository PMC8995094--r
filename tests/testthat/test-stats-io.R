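test_that("ANOVA F statistic matches a hand computation on a textbook fixture", {
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 4),
    y = c(6, 8, 4, 5, 8, 12, 9, 11, 13, 9, 11, 8)
  )
  # between/within mean squares by hand
  gm <- mean(d$y)
  means <- tapply(d$y, d$g, mean)
  ssb <- 4 * sum((means - gm)^2)
  ssw <- sum((d$y - means[d$g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  res <- group_compare(d, "y", "g")
  expect_equal(res$f_statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$df, c(2, 9))
  expect_equal(nrow(res$pairs), 3)        # all Tukey pairs
  expect_true(all(res$pairs$p_adj >= 0 & res$pairs$p_adj <= 1))
})

test_that("Dunnett comparisons are against the named control only", {
  set.seed(1)
  d <- data.frame(g = rep(c("ctrl", "t1", "t2"), each = 8),
                  y = c(rnorm(8), rnorm(8, 2), rnorm(8, 0)))
  res <- group_compare(d, "y", "g", scheme = "dunnett", control = "ctrl")
  expect_equal(nrow(res$pairs), 2)
  expect_true(all(grepl("ctrl", res$pairs$contrast)))
  expect_error(group_compare(d, "y", "g", scheme = "dunnett"), "control")
  expect_error(group_compare(d, "y", "g", scheme = "dunnett", control = "zz"),
               "not a group level")
})

test_that("degenerate zero-variance groups are flagged", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2), each = 3))
  expect_warning(res <- group_compare(d, "y", "g"), "degenerate")
  expect_true(res$degenerate)
})

test_that("significance stars follow the four-level convention", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***", "****"))
  expect_error(significance_stars(1.5))
})

test_that("tidiers expose pairwise tables and model summaries", {
  set.seed(2)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 6), y = rnorm(18))
  res <- group_compare(d, "y", "g")
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1)
  expect_equal(glance(res)$df_between, 2)
  im <- simulate_tirf_image(n_puncta = 5, seed = 1)
  ps <- segment_puncta(im)
  expect_equal(nrow(tidy(ps)), 5)
  expect_equal(glance(ps)$n_puncta, 5)
})

test_that("trace and recording files round-trip losslessly", {
  dir <- withr::local_tempdir()
  tp <- simulate_trace_pair(17, 66, noise_sd_nm = 1, seed = 3)
  f <- file.path(dir, "traces.csv")
  write_trace_csv(tp, f)
  back <- read_trace_csv(f)
  expect_equal(back$x_nm, tp$x_nm)
  expect_equal(back$membrane, tp$membrane)
  expect_equal(attr(back, "pixel_size_nm"), attr(tp, "pixel_size_nm"))

  rec <- simulate_fura2_recording(n_rois = 2, seed = 4)
  g <- file.path(dir, "rec.csv")
  write_recording_csv(rec, g)
  rec2 <- read_recording_csv(g)
  expect_equal(rec2$data$value, rec$data$value)
  expect_equal(rec2$events, rec$events)
  expect_equal(rec2$frame_interval_s, rec$frame_interval_s)

  pop <- simulate_cer_population(20, seed = 1)
  h <- file.path(dir, "structures.csv")
  write_structures_csv(pop, h)
  expect_equal(as.data.frame(read_structures_csv(h)), as.data.frame(pop),
               ignore_attr = TRUE)
})

test_that("TIFF images round-trip through the tiff wrappers", {
  dir <- withr::local_tempdir()
  im <- simulate_tirf_image(n_puncta = 3, seed = 2)
  f <- file.path(dir, "im.tif")
  write_tirf_tiff(im$image, f, scale = 2000)
  back <- read_tirf_tiff(f, scale = 2000)
  expect_equal(dim(back), dim(im$image))
  expect_equal(back, im$image, tolerance = 1e-4)   # 32-bit float storage
})

test_that("the pipeline is deterministic and validates its configuration", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- pipeline_config(sim_n_structures = 80, sim_n_rois = 2, n_boot = 200)
  suppressMessages(run_pipeline(cfg, dir1, seed = 11))
  suppressMessages(run_pipeline(cfg, dir2, seed = 11))
  for (f in c("structures.csv", "condition_summary.csv", "plateau.csv",
              "scatter.csv", "kinetics_rates.csv", "puncta_summary.csv")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  prov <- jsonlite::read_json(file.path(dir1, "provenance.json"))
  expect_equal(prov$seed, 11)
  expect_true(nzchar(prov$config_hash))
  expect_error(pipeline_config(not_a_key = 1), "not_a_key")
  expect_error(run_pipeline(pipeline_config(trace_csv = "/nope.csv"),
                            dir1, seed = 1), "not found")
})

test_that("pipeline outputs match the generators' ground truth", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(sim_n_structures = 400, sim_n_rois = 3, n_boot = 200)
  out <- suppressMessages(run_pipeline(cfg, dir, seed = 7))
  # plateau near the generator's 5.2 nm
  p <- out$plateau
  expect_lt(abs(p$plateau_gap_nm - 5.2), 3 * p$sd_nm / sqrt(p$n_long))
  # entry slope near the generator's 0.02 /s, quench near 0.024 /s
  rates <- out$rates
  entry <- rates$slope_per_s[rates$kind == "entry"]
  expect_equal(mean(entry), 0.02, tolerance = 0.05)
  quench <- rates$rate_per_s[rates$kind == "quench"]
  expect_equal(mean(quench), 0.024, tolerance = 0.05)
  # puncta summary consistent with the simulated image
  expect_equal(nrow(out$puncta$puncta), 10)
})
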