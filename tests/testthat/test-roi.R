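# ROI extraction: background estimation, object detection, the
# area-adjusted join, and full-stack trace extraction.

test_that("background of a constant frame is (c, 0)", {
  bg <- estimate_background(matrix(7.5, 20, 20))
  expect_equal(bg$mean, 7.5)
  expect_equal(bg$sd, 0)
})

test_that("two-pass background ignores a bright blob", {
  withr::local_seed(1)
  frame <- matrix(rnorm(100 * 100, 100, 5), 100, 100)
  blob_free <- estimate_background(frame)
  # truncating at mean + 2 SD barely moves the mean; the SD shrinks a bit
  expect_equal(blob_free$mean, mean(frame), tolerance = 0.02)
  expect_equal(blob_free$sd, sd(frame), tolerance = 0.10)
  frame[1:10, 1:10] <- 1000  # 1% of pixels
  bg <- estimate_background(frame)
  expect_lt(abs(bg$mean - 100), 1)
})

test_that("object detection finds blobs with exact pixel counts", {
  fr <- patch_frame(patches = list(
    list(rows = 3:8, cols = 3:7, mcherry = 300, ratio = 2),     # 30 px
    list(rows = 20:24, cols = 20:21, mcherry = 300, ratio = 1)))# 10 px
  obj <- detect_objects(fr$gcamp, fr$mcherry,
                        background = list(mean = 0, sd = 1))
  expect_equal(nrow(obj), 2)
  expect_setequal(obj$pixel_count, c(30, 10))
  expect_equal(sort(obj$mean_ratio), c(1, 2), tolerance = 1e-12)
})

test_that("diagonally touching pixels join into one 8-connected object", {
  m <- matrix(0, 10, 10)
  m[3, 3] <- 100; m[4, 4] <- 100; m[5, 5] <- 100
  obj <- detect_objects(m, m, background = list(mean = 0, sd = 1),
                        min_object_px = 1)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$pixel_count, 3)
})

test_that("an all-background frame yields an empty object list", {
  fr <- patch_frame(bg = 100)
  obj <- detect_objects(fr$gcamp, fr$mcherry,
                        background = list(mean = 100, sd = 0.01))
  expect_equal(nrow(obj), 0)
  expect_equal(join_objects(obj)$ratio, NA_real_)
})

test_that("area-adjusted join is the pixel-weighted mean and split-invariant", {
  one <- tibble::tibble(object = 1L, pixel_count = 40L, mean_gcamp = 2,
                        mean_mcherry = 1, mean_ratio = 1.75)
  expect_equal(join_objects(one)$ratio, 1.75)

  two <- tibble::tibble(object = 1:2, pixel_count = c(30L, 10L),
                        mean_gcamp = c(4, 1), mean_mcherry = c(2, 1),
                        mean_ratio = c(2, 1))
  j <- join_objects(two)
  expect_equal(j$ratio, (30 * 2 + 10 * 1) / 40)
  expect_equal(j$ratio, 1.75)
  expect_equal(j$total_area, 40L)

  equal_areas <- tibble::tibble(object = 1:2, pixel_count = c(10L, 10L),
                                mean_gcamp = 0, mean_mcherry = 1,
                                mean_ratio = c(1.2, 2.6))
  expect_equal(join_objects(equal_areas)$ratio, 1.9)

  # splitting one object into components over the same pixels changes nothing
  withr::local_seed(2)
  px_ratios <- runif(40, 0.5, 3)
  split_at <- 17
  whole <- tibble::tibble(object = 1L, pixel_count = 40L, mean_gcamp = 1,
                          mean_mcherry = 1, mean_ratio = mean(px_ratios))
  parts <- tibble::tibble(
    object = 1:2, pixel_count = c(split_at, 40L - split_at),
    mean_gcamp = 1, mean_mcherry = 1,
    mean_ratio = c(mean(px_ratios[1:split_at]),
                   mean(px_ratios[(split_at + 1):40])))
  expect_equal(join_objects(parts)$ratio, join_objects(whole)$ratio)
})

test_that("join equals a brute-force pixelwise mean on a rendered two-blob frame", {
  fr <- patch_frame(patches = list(
    list(rows = 3:8, cols = 3:7, mcherry = 300, ratio = 2),
    list(rows = 20:24, cols = 20:21, mcherry = 300, ratio = 1)))
  obj <- detect_objects(fr$gcamp, fr$mcherry,
                        background = list(mean = 0, sd = 1))
  mask <- fr$mcherry > 2  # brute force: all object pixels at once
  brute <- mean(fr$gcamp[mask] / fr$mcherry[mask])
  expect_equal(join_objects(obj)$ratio, brute)
})

test_that("noise-free stack extraction recovers ground truth exactly", {
  cfg <- sim_config(duration = 5, seed = 5,
                    noise = list(gcamp_sd = 0, mcherry_sd = 0,
                                 artifact_amplitude = 0),
                    image = list(background_sd = 0))
  truth <- suppressWarnings(simulate_behavior(cfg))
  fs <- render_frames(truth, cfg, cell = "vm", n_frames = 60,
                      profile = "disk")
  tr <- extract_trace(fs$gcamp, fs$mcherry, frame_rate = 20)
  expect_equal(tr$ratio, fs$ratio_true, tolerance = 1e-12)
})

test_that("extraction is exactly invariant to a shared per-frame gain", {
  cfg <- sim_config(duration = 5, seed = 5,
                    noise = list(gcamp_sd = 0, mcherry_sd = 0,
                                 artifact_amplitude = 0),
                    image = list(background_sd = 0))
  truth <- suppressWarnings(simulate_behavior(cfg))
  plain <- render_frames(truth, cfg, cell = "vm", n_frames = 60)
  gain <- function(t) 1 + 0.5 * sin(3 * t) * cos(t)
  warped <- render_frames(truth, cfg, cell = "vm", n_frames = 60,
                          artifact = gain)
  tr_plain <- extract_trace(plain$gcamp, plain$mcherry, frame_rate = 20)
  tr_warp <- extract_trace(warped$gcamp, warped$mcherry, frame_rate = 20)
  expect_identical(tr_warp$total_area_px, tr_plain$total_area_px)
  expect_equal(tr_warp$ratio, tr_plain$ratio, tolerance = 1e-12)
})

test_that("noisy default stack extraction stays under the noise-propagation bound", {
  cfg <- sim_config(duration = 10, seed = 5)
  truth <- suppressWarnings(simulate_behavior(cfg))
  fs <- render_frames(truth, cfg, cell = "vm", n_frames = 200)
  tr <- extract_trace(fs$gcamp, fs$mcherry, frame_rate = 20)
  rmse <- sqrt(mean((tr$ratio - fs$ratio_true)^2))
  expect_lt(rmse, 3 * cfg$image$background_sd / cfg$image$blob_peak)
})

test_that("object size shrinks monotonically with the rendered blob", {
  sizes <- vapply(c(8, 6, 4, 2), function(half) {
    fr <- patch_frame(patches = list(
      list(rows = (15 - half):(15 + half), cols = (15 - half):(15 + half),
           mcherry = 300, ratio = 1)))
    obj <- detect_objects(fr$gcamp, fr$mcherry,
                          background = list(mean = 0, sd = 1))
    join_objects(obj)$total_area
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("short object gaps are interpolated and long ones abort extraction", {
  h <- 20; w <- 20; n <- 30
  g <- array(0, c(h, w, n)); r <- array(0, c(h, w, n))
  for (i in seq_len(n)) {
    if (i %in% 10:12) next  # blob absent: missing frames
    g[5:10, 5:10, i] <- 200 * (1 + 0.5 * (i / n))
    r[5:10, 5:10, i] <- 200
  }
  tr <- extract_trace(g, r, frame_rate = 20)
  expect_true(all(tr$interpolated[10:12]))
  expect_false(anyNA(tr$ratio))
  # a run longer than max_gap_frames stays missing
  tr2 <- extract_trace(g, r, frame_rate = 20, max_gap_frames = 2)
  expect_true(all(is.na(tr2$ratio[10:12])))
  # overwhelming missingness aborts
  for (i in 5:30) { g[, , i] <- 0; r[, , i] <- 0 }
  expect_error(extract_trace(g, r, frame_rate = 20), "aborting")
})
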