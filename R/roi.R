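# ROI extraction: two-channel image stacks -> per-frame area-adjusted
# GCaMP/mCherry ratio and object-size traces.

#' Estimate image background from the mCherry channel
#'
#' Two-pass robust estimate: pass 1 takes the mean and SD over all pixels;
#' pass 2 recomputes them over pixels below pass-1 mean + 2 SD, so bright
#' cell pixels do not inflate the background. A constant frame returns
#' `sd = 0` (any brighter pixel then exceeds the object threshold).
#'
#' @param frame Numeric matrix (one mCherry frame).
#' @return List: `mean`, `sd`.
#' @export
estimate_background <- function(frame) {
  if (length(frame) == 0L) abort("empty frame")
  m1 <- mean(frame)
  s1 <- sd(as.vector(frame))
  if (!is.finite(s1)) s1 <- 0
  keep <- frame < m1 + 2 * s1
  if (!any(keep)) keep <- rep(TRUE, length(frame))
  m2 <- mean(frame[keep])
  s2 <- if (sum(keep) > 1L) sd(frame[keep]) else 0
  list(mean = m2, sd = s2)
}

#' Detect fluorescent objects in a two-channel frame
#'
#' Thresholds the mCherry channel at `background mean + 2 SD`, labels
#' 8-connected components, discards components smaller than
#' `min_object_px`, and summarizes each object on both channels and on the
#' pixelwise GCaMP/mCherry ratio. By default each channel's estimated
#' background mean is subtracted before the pixelwise ratio is formed, so
#' the object ratio reflects cell fluorescence rather than a mixture of
#' cell and background (and is exactly invariant to any gain shared by both
#' channels).
#'
#' @param gcamp,mcherry Aligned equal-shape numeric matrices.
#' @param background Optional list with `mean` and `sd`; defaults to
#'   [estimate_background()] of the mCherry frame.
#' @param min_object_px Minimum object size, pixels.
#' @param background_gcamp Optional GCaMP-channel background (list with
#'   `mean`); estimated from the frame when `NULL`.
#' @param subtract_background Subtract per-channel background means before
#'   computing pixel ratios.
#' @return Tibble with one row per object: `object`, `pixel_count`,
#'   `mean_gcamp`, `mean_mcherry` (raw channel means), `mean_ratio`
#'   (background-subtracted pixelwise ratio). Empty (zero rows) when no
#'   pixels exceed the threshold.
#' @export
detect_objects <- function(gcamp, mcherry, background = NULL,
                           min_object_px = 5, background_gcamp = NULL,
                           subtract_background = TRUE) {
  if (!identical(dim(gcamp), dim(mcherry))) {
    abort("gcamp and mcherry frames must have identical shape")
  }
  bg <- background %||% estimate_background(mcherry)
  off_r <- if (subtract_background) bg$mean else 0
  off_g <- if (subtract_background) {
    (background_gcamp %||% estimate_background(gcamp))$mean
  } else {
    0
  }
  mask <- mcherry > bg$mean + 2 * bg$sd
  if (!any(mask)) {
    return(tibble::tibble(object = integer(), pixel_count = integer(),
                          mean_gcamp = numeric(), mean_mcherry = numeric(),
                          mean_ratio = numeric()))
  }
  lab <- label_components_cpp(mask)
  labs <- lab[lab > 0L]
  sizes <- tabulate(labs)
  keep <- which(sizes >= min_object_px)
  if (!length(keep)) {
    return(tibble::tibble(object = integer(), pixel_count = integer(),
                          mean_gcamp = numeric(), mean_mcherry = numeric(),
                          mean_ratio = numeric()))
  }
  g <- gcamp[lab > 0L]
  r <- mcherry[lab > 0L]
  tibble::tibble(
    object = seq_along(keep),
    pixel_count = sizes[keep],
    mean_gcamp = vapply(keep, function(k) mean(g[labs == k]), numeric(1)),
    mean_mcherry = vapply(keep, function(k) mean(r[labs == k]), numeric(1)),
    mean_ratio = vapply(keep, function(k) {
      mean((g[labs == k] - off_g) / (r[labs == k] - off_r))
    }, numeric(1))
  )
}

#' Join detected objects into one area-adjusted ratio
#'
#' The joined ratio is the pixel-area-weighted mean of per-object mean
#' ratios: `sum(pixel_count * mean_ratio) / sum(pixel_count)`. Splitting an
#' object into components covering the same pixels leaves the result
#' unchanged.
#'
#' @param objects Tibble from [detect_objects()].
#' @return List: `ratio` (NA when no objects), `total_area` (pixels).
#' @export
join_objects <- function(objects) {
  if (nrow(objects) == 0L) {
    return(list(ratio = NA_real_, total_area = 0L))
  }
  list(ratio = sum(objects$pixel_count * objects$mean_ratio) /
         sum(objects$pixel_count),
       total_area = sum(objects$pixel_count))
}

#' Extract an area-adjusted ratio trace from a two-channel image stack
#'
#' Per frame: estimate background (per frame or once per recording), detect
#' objects, and join them into an area-adjusted ratio and a total object
#' size (the muscle-contraction proxy). Frames without objects become
#' missing values; gaps up to `max_gap_frames` are linearly interpolated.
#'
#' @param gcamp,mcherry Height x width x frames arrays (or a `frame_stack`
#'   passed as `gcamp`).
#' @param frame_rate Frames/s.
#' @param min_object_px Minimum object size, pixels.
#' @param max_gap_frames Longest missing run to interpolate.
#' @param max_missing_fraction Abort if more frames than this are missing.
#' @param background `"per_frame"` or `"per_recording"`.
#' @param subtract_background Subtract per-channel background means before
#'   computing pixel ratios (see [detect_objects()]).
#' @return Tibble: `time_s`, `ratio`, `total_area_px`, `n_objects`,
#'   `interpolated`; QC attributes `qc` (list: missing frames, background
#'   stats).
#' @export
extract_trace <- function(gcamp, mcherry = NULL, frame_rate = 20,
                          min_object_px = 5, max_gap_frames = 10,
                          max_missing_fraction = 0.5,
                          background = c("per_frame", "per_recording"),
                          subtract_background = TRUE) {
  background <- match.arg(background)
  if (inherits(gcamp, "frame_stack")) {
    stack <- gcamp
    gcamp <- stack$gcamp
    mcherry <- stack$mcherry
    frame_rate <- stack$config$frame_rate
  }
  if (!identical(dim(gcamp), dim(mcherry))) {
    abort("channel stacks must have identical shape")
  }
  n <- dim(gcamp)[3]
  bg_rec <- if (background == "per_recording") {
    estimate_background(as.vector(mcherry))
  }
  bg_rec_g <- if (background == "per_recording") {
    estimate_background(as.vector(gcamp))
  }
  ratio <- rep(NA_real_, n)
  area <- rep(0L, n)
  nobj <- integer(n)
  bg_mean <- numeric(n); bg_sd <- numeric(n)
  for (i in seq_len(n)) {
    bg <- bg_rec %||% estimate_background(mcherry[, , i])
    bg_mean[i] <- bg$mean; bg_sd[i] <- bg$sd
    obj <- detect_objects(gcamp[, , i], mcherry[, , i], bg, min_object_px,
                          background_gcamp = bg_rec_g,
                          subtract_background = subtract_background)
    j <- join_objects(obj)
    ratio[i] <- j$ratio
    area[i] <- j$total_area
    nobj[i] <- nrow(obj)
  }
  missing <- which(is.na(ratio))
  if (length(missing) / n > max_missing_fraction) {
    abort(paste0(length(missing), "/", n,
                 " frames have no detectable object; aborting extraction"))
  }
  interpolated <- rep(FALSE, n)
  if (length(missing) && length(missing) < n) {
    runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
    ok <- which(!is.na(ratio))
    for (run in runs) {
      if (length(run) <= max_gap_frames &&
          min(run) > 1L && max(run) < n) {
        ratio[run] <- approx(ok, ratio[ok], xout = run)$y
        interpolated[run] <- TRUE
      }
    }
  }
  out <- tibble::tibble(time_s = (seq_len(n) - 1L) / frame_rate,
                        ratio = ratio, total_area_px = area,
                        n_objects = nobj, interpolated = interpolated)
  attr(out, "qc") <- list(
    n_frames = n, n_missing = length(missing),
    missing_frames = missing,
    background_mean = mean(bg_mean), background_sd = mean(bg_sd),
    background_mode = background)
  out
}
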