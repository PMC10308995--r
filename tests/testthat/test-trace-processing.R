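test_that("ROI extraction returns per-label means in label order", {
  stack <- array(7, dim = c(8, 8, 5))
  mask <- matrix(0L, 8, 8)
  mask[2:4, 2:4] <- 2L
  mask[6:8, 6:8] <- 1L
  traces <- extract_traces(stack, mask, laser_index = 2L)
  expect_length(traces, 2)
  expect_identical(vapply(traces, `[[`, 0L, "cell_id"), c(1L, 2L))
  expect_true(all(traces[[1]]$intensities == 7))
  expect_error(extract_traces(stack, mask, labels = c(1, 3), laser_index = 2L),
               "label 3")
  expect_error(extract_traces(stack, matrix(0L, 8, 8), laser_index = 2L),
               "no labeled")
})

test_that("linear bleach correction divides out an exact linear baseline", {
  frames <- 0:479
  y <- 100 - 0.05 * frames
  tr <- fluor_trace(times = frames, intensities = y, laser_index = 101L)
  ct <- bleach_correct(tr)
  expect_equal(ct$rel_intensity, rep(1, 480), tolerance = 1e-12)
  expect_equal(ct$resting_intensity, 100, tolerance = 1e-9)
  expect_equal(ct$bleach_slope, -0.05, tolerance = 1e-9)

  # flat trace: fitted slope 0, corrected = intensities / background mean
  yf <- rep(42, 480)
  ctf <- bleach_correct(fluor_trace(frames, yf, 101L))
  expect_equal(ctf$bleach_slope, 0, tolerance = 1e-12)
  expect_equal(ctf$rel_intensity, yf / mean(yf[1:100]), tolerance = 1e-12)
})

test_that("corrected perforated traces preserve the dip depth", {
  spec <- trace_spec(resting_intensity = 800, bleach_slope = -0.4,
                     dip_fraction = 0.55, true_resealing_time = 35,
                     noise_sd = 0)
  ct <- bleach_correct(make_trace(spec)$trace)
  post_min <- min(ct$rel_intensity[ct$laser_index:length(ct$rel_intensity)])
  expect_equal(post_min, 0.55, tolerance = 1e-9)
  # background of the corrected trace is flat at 1
  expect_equal(mean(ct$rel_intensity[1:100]), 1, tolerance = 1e-12)
})

test_that("bleach correction is idempotent and rejects invalid baselines", {
  spec <- trace_spec(resting_intensity = 600, bleach_slope = -0.3,
                     dip_fraction = 0.6, true_resealing_time = 40, noise_sd = 0)
  ct <- bleach_correct(make_trace(spec)$trace)
  ct2 <- optopore:::recorrect(ct)
  expect_lt(max(abs(ct2$rel_intensity - ct$rel_intensity)), 1e-9)

  # a slope that extrapolates through zero within the trace is an error
  bad <- fluor_trace(0:479, 50 - 0.3 * (0:479), 101L)
  expect_error(bleach_correct(bad), "non-positive")
})

test_that("perforation classification applies the strict k-sigma rule", {
  # noiseless flat trace: unperforated, zero dip depth
  ct <- bleach_correct(fluor_trace(0:479, rep(10, 480), 101L))
  cls <- classify_perforated(ct)
  expect_false(cls$perforated)
  expect_equal(cls$dip_depth, 0, tolerance = 1e-12)

  # clear dip: 0.6 < 1 - 5 * 0.01
  spec <- trace_spec(dip_fraction = 0.6, true_resealing_time = 40, noise_sd = 0)
  ct2 <- bleach_correct(make_trace(spec)$trace)
  expect_true(classify_perforated(ct2, k_sigma = 5)$perforated)

  # boundary: a post-laser minimum exactly at 1 - k*sigma is NOT perforated
  rel <- rep(c(1.01, 0.99), 50)           # background with known sd
  sigma <- sd(rel)
  k <- 5
  ct3 <- structure(list(rel_intensity = c(rel, rep(1, 9), 1 - k * sigma),
                        laser_index = 101L, frame_interval = 1,
                        times = 0:109, cell_id = "b"),
                   class = "corrected_trace")
  expect_false(classify_perforated(ct3, k_sigma = k)$perforated)
  ct3$rel_intensity[110] <- 1 - k * sigma - 1e-6
  expect_true(classify_perforated(ct3, k_sigma = k)$perforated)

  # degenerate noiseless case: sigma = 0, any real post-laser dip below 1
  ct4 <- structure(list(rel_intensity = c(rep(1, 100), 0.999),
                        laser_index = 101L, frame_interval = 1,
                        times = 0:100, cell_id = "d"),
                   class = "corrected_trace")
  expect_true(classify_perforated(ct4)$perforated)
})

test_that("false-positive rate on noisy unperforated traces is at most 1%", {
  n_fp <- 0L
  for (i in 1:1000) {
    spec <- trace_spec(resting_intensity = 1000, bleach_slope = -0.5,
                       perforated = FALSE, noise_sd = 10, seed = 10000 + i)
    ct <- bleach_correct(make_trace(spec)$trace)
    if (classify_perforated(ct, k_sigma = 5)$perforated) n_fp <- n_fp + 1L
  }
  expect_lte(n_fp, 10L)
})

test_that("resealing time recovers the constructed 90% crossing", {
  spec <- trace_spec(dip_fraction = 0.6, true_resealing_time = 41.59,
                     noise_sd = 0)
  ct <- bleach_correct(make_trace(spec)$trace)
  rt <- resealing_time(ct)
  expect_lt(abs(rt - 41.59), 0.01)
})

test_that("crossings are interpolated between the bracketing frames", {
  # monotone recovery crossing 0.9 between frames 149 and 150 (laser at 101,
  # 1 s frames): time from onset must fall in (49, 50)
  rel <- c(rep(1, 100), seq(0.5, 0.9 - 1e-6, length.out = 49),
           seq(0.905, 1, length.out = 331))
  ct <- structure(list(rel_intensity = rel, laser_index = 101L,
                       frame_interval = 1, times = 0:479, cell_id = "x"),
                  class = "corrected_trace")
  rt <- resealing_time(ct)
  expect_gt(rt, 48)
  expect_lt(rt, 50)

  # a trace that never recovers is flagged unresealed
  low <- c(rep(1, 100), rep(0.5, 380))
  ctl <- structure(list(rel_intensity = low, laser_index = 101L,
                        frame_interval = 1, times = 0:479, cell_id = "y"),
                   class = "corrected_trace")
  rtl <- resealing_time(ctl)
  expect_true(is.na(rtl))
  expect_match(attr(rtl, "reason"), "unresealed")

  # a 1-frame blip above threshold does not count as a confirmed crossing
  blip <- c(rep(1, 100), rep(0.5, 50), 0.95, rep(0.5, 100),
            rep(0.95, 229))
  ctb <- structure(list(rel_intensity = blip, laser_index = 101L,
                        frame_interval = 1, times = 0:479, cell_id = "z"),
                   class = "corrected_trace")
  rtb <- resealing_time(ctb, confirm_frames = 3)
  expect_gt(rtb, 150)   # the confirmed crossing, not the blip at 50 s
})

test_that("extracted resealing times track the truth curve across fluences", {
  des <- noiseless_design(cells = 10, seed = 3)
  ex <- make_experiment(des)
  res <- analyze_traces(ex$traces)
  res$fluence <- ex$truth$fluence_J_cm2
  res$truth_time <- ex$truth$true_resealing_time_s
  expect_true(all(res$perforated))
  agg <- aggregate(resealing_time_s ~ fluence, data = res, FUN = mean)
  tru <- aggregate(truth_time ~ fluence, data = res, FUN = mean)
  expect_lt(max(abs(agg$resealing_time_s - tru$truth_time)), 1)
  # median extracted time strictly increases with fluence
  med <- aggregate(resealing_time_s ~ fluence, data = res, FUN = median)
  expect_true(all(diff(med$resealing_time_s) > 0))
})
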