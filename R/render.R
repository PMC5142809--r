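# Fluorescence forward model: event-level ground truth -> two-channel
# recordings (traces and, optionally, image stacks).

# Clean delta-R/R series for one cell type on a uniform time grid:
# sum of amplitude-scaled kernels at the true peak times. Overlapping
# transients sum linearly.
clean_droverr <- function(truth, cell, t, kernel = truth$config$kernel) {
  tr <- dplyr::filter(truth$transients, .data$cell_type == cell)
  dr <- numeric(length(t))
  if (nrow(tr) == 0L || length(t) == 0L) return(dr)
  dt <- if (length(t) > 1L) t[2] - t[1] else 1
  for (i in seq_len(nrow(tr))) {
    if (kernel == "gaussian") {
      sigma <- tr$fwhm_s[i] / (2 * sqrt(2 * log(2)))
      lo <- max(1L, floor((tr$peak_time_s[i] - 5 * sigma - t[1]) / dt) + 1L)
      hi <- min(length(t), ceiling((tr$peak_time_s[i] + 5 * sigma - t[1]) / dt) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      dr[idx] <- dr[idx] +
        tr$amplitude[i] * exp(-(t[idx] - tr$peak_time_s[i])^2 / (2 * sigma^2))
    } else {
      # double exponential with rise = decay/4, rescaled so the peak equals
      # the amplitude and the width at half-maximum matches fwhm_s
      # (for tau_r = tau_d/4 the half-max width is 1.3281 tau_d and the
      # peak sits at tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r))
      tau_d <- tr$fwhm_s[i] / 1.3281
      tau_r <- tau_d / 4
      t_pk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
      lo <- max(1L, floor((tr$peak_time_s[i] - 2 * tr$fwhm_s[i] - t[1]) / dt) + 1L)
      hi <- min(length(t), ceiling((tr$peak_time_s[i] + 6 * tau_d - t[1]) / dt) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      s <- t[idx] - (tr$peak_time_s[i] - t_pk)
      k <- ifelse(s > 0, exp(-s / tau_d) - exp(-s / tau_r), 0)
      pk <- exp(-t_pk / tau_d) - exp(-t_pk / tau_r)
      dr[idx] <- dr[idx] + tr$amplitude[i] * k / pk
    }
  }
  dr
}

# Smooth multiplicative motion artifact shared by both channels: a sum of
# two low-frequency sinusoids with random frequencies and phases.
artifact_factor <- function(t, amplitude) {
  if (amplitude <= 0) return(rep(1, length(t)))
  f <- runif(2, 0.005, 0.05)
  ph <- runif(2, 0, 2 * pi)
  1 + amplitude * (0.6 * sin(2 * pi * f[1] * t + ph[1]) +
                   0.4 * sin(2 * pi * f[2] * t + ph[2]))
}

#' Render two-channel fluorescence traces from simulated ground truth
#'
#' The GCaMP channel is `baseline * (1 + delta-R/R)` with transients as
#' amplitude-scaled kernels of the configured FWHM; the mCherry channel is a
#' constant baseline. Both channels are multiplied by the same smooth
#' motion-artifact factor (which therefore cancels exactly in their ratio)
#' and receive independent additive Gaussian noise.
#'
#' @param truth An `egg_sim_truth` from [simulate_behavior()].
#' @param config A [sim_config()]; defaults to the one stored in `truth`.
#' @param cells Cell types to render.
#' @param artifact Optional function of time (s) returning the shared
#'   multiplicative factor, overriding the configured random artifact.
#' @return Tibble: `cell_type`, `time_s`, `gcamp`, `mcherry`, `ratio_true`
#'   (the noise- and artifact-free ratio, kept for ground-truth comparison).
#' @export
#' @examples
#' truth <- simulate_behavior(sim_config(duration = 120, seed = 3))
#' traces <- render_traces(truth, cells = "hsn")
render_traces <- function(truth, config = truth$config,
                          cells = c("hsn", "vc", "vm", "uv1"),
                          artifact = NULL) {
  n <- round(config$frame_rate * truth$duration)
  t <- (seq_len(n) - 1L) / config$frame_rate
  base_ratio <- config$baselines$gcamp / config$baselines$mcherry
  out <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cell <- cells[k]
    dr <- clean_droverr(truth, cell, t)
    out[[k]] <- withr::with_seed(derive_seed(config$seed, 20L + k), {
      m <- if (is.null(artifact)) {
        artifact_factor(t, config$noise$artifact_amplitude)
      } else {
        artifact(t)
      }
      if (any(m <= 0)) abort("artifact factor must stay positive")
      g <- config$baselines$gcamp * (1 + dr) * m +
        rnorm(n, 0, config$noise$gcamp_sd)
      r <- config$baselines$mcherry * m +
        rnorm(n, 0, config$noise$mcherry_sd)
      tibble::tibble(cell_type = cell, time_s = t, gcamp = g, mcherry = r,
                     ratio_true = base_ratio * (1 + dr))
    })
  }
  dplyr::bind_rows(out)
}

#' Render a two-channel image stack from simulated ground truth
#'
#' Draws the recorded cell as a 2-D Gaussian blob: mCherry blob intensity is
#' constant, GCaMP blob intensity follows the clean ratio trace, background
#' pixels are Gaussian noise, and an optional shared multiplicative artifact
#' scales whole frames of both channels. Intended as the test input for the
#' object-detection stage; frames are small by default.
#'
#' @param truth An `egg_sim_truth`.
#' @param config A [sim_config()]; the `image` element controls geometry.
#' @param cell Cell type whose activity drives the GCaMP blob.
#' @param n_frames Number of frames (default: full recording).
#' @param artifact Optional function of time (s) giving the shared per-frame
#'   multiplicative factor.
#' @param profile Blob radial profile: `"gaussian"` (realistic, default) or
#'   `"disk"` (flat-top; with zero background noise the extraction stage
#'   recovers the blob ratio exactly, so disk blobs serve as exactness
#'   fixtures).
#' @return List of class `frame_stack`: `gcamp`, `mcherry` (height x width x
#'   frames arrays), `time_s`, `ratio_true` (per-frame ground-truth blob
#'   ratio), `config`.
#' @export
render_frames <- function(truth, config = truth$config, cell = "vm",
                          n_frames = NULL, artifact = NULL,
                          profile = c("gaussian", "disk")) {
  profile <- match.arg(profile)
  im <- config$image
  n_total <- round(config$frame_rate * truth$duration)
  n <- min(n_frames %||% n_total, n_total)
  t <- (seq_len(n) - 1L) / config$frame_rate
  dr <- clean_droverr(truth, cell, t)
  base_ratio <- config$baselines$gcamp / config$baselines$mcherry
  ratio_true <- base_ratio * (1 + dr)

  rows <- matrix(seq_len(im$height), im$height, im$width)
  cols <- matrix(seq_len(im$width), im$height, im$width, byrow = TRUE)
  d2 <- (rows - im$centroid[1])^2 + (cols - im$centroid[2])^2
  blob <- if (profile == "gaussian") {
    exp(-d2 / (2 * im$cell_radius_px^2))
  } else {
    (d2 <= im$cell_radius_px^2) * 1
  }
  edge_mass <- max(blob[1, ], blob[im$height, ], blob[, 1], blob[, im$width])
  if (edge_mass > 0.01) {
    warn("cell blob is clipped by the frame edge; truncated mass > 1%")
  }

  withr::with_seed(derive_seed(config$seed, 30L), {
    m <- if (is.null(artifact)) {
      artifact_factor(t, config$noise$artifact_amplitude)
    } else {
      artifact(t)
    }
    g <- array(0, c(im$height, im$width, n))
    r <- array(0, c(im$height, im$width, n))
    for (i in seq_len(n)) {
      bg_g <- matrix(rnorm(im$height * im$width, im$background_mean,
                           im$background_sd), im$height, im$width)
      bg_r <- matrix(rnorm(im$height * im$width, im$background_mean,
                           im$background_sd), im$height, im$width)
      g[, , i] <- (bg_g + im$blob_peak * ratio_true[i] * blob) * m[i]
      r[, , i] <- (bg_r + im$blob_peak * blob) * m[i]
    }
    structure(list(gcamp = g, mcherry = r, time_s = t,
                   ratio_true = ratio_true, config = config),
              class = "frame_stack")
  })
}

#' Write a simulated recording to disk
#'
#' Writes `traces.csv` (time_s, gcamp, mcherry, cell_type), `annotations.csv`
#' (time_s, event_type in egg / ventral_contraction / ventral_relaxation),
#' `truth.json` (full ground truth), `manifest.json` (config, seed, config
#' hash), and optionally 16-bit two-channel TIFF stacks with a JSON sidecar
#' describing channel order.
#'
#' @param truth An `egg_sim_truth`.
#' @param traces Output of [render_traces()].
#' @param dir Output directory (created if missing).
#' @param frames Optional `frame_stack` from [render_frames()].
#' @return `dir`, invisibly.
#' @export
write_recording <- function(truth, traces, dir, frames = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::select(traces, "time_s", "gcamp", "mcherry",
                                 "cell_type"),
                   file.path(dir, "traces.csv"))
  ann <- dplyr::bind_rows(
    tibble::tibble(time_s = truth$eggs$time_s, event_type = "egg"),
    tibble::tibble(time_s = truth$landmarks$time_s,
                   event_type = paste0("ventral_",
                                       truth$landmarks$kind))) %>%
    dplyr::arrange(.data$time_s)
  readr::write_csv(ann, file.path(dir, "annotations.csv"))
  jsonlite::write_json(
    list(states = truth$states, landmarks = truth$landmarks,
         eggs = truth$eggs, transients = truth$transients,
         duration = truth$duration),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(seed = truth$config$seed,
         config_hash = rlang::hash(truth$config),
         frame_rate = truth$config$frame_rate,
         duration = truth$duration),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(frames)) {
    write_stack(frames$gcamp, file.path(dir, "gcamp.tif"))
    write_stack(frames$mcherry, file.path(dir, "mcherry.tif"))
    jsonlite::write_json(
      list(channels = c("gcamp.tif", "mcherry.tif"),
           frame_order = "time-major, one frame per TIFF directory",
           bits = 16, time_s = frames$time_s,
           ratio_true = frames$ratio_true),
      file.path(dir, "frames.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read or write a single-channel TIFF stack as a numeric array
#'
#' Thin wrappers over the tiff package: `write_stack()` scales intensities
#' into 16-bit range using a fixed `scale` (intensity units per full scale),
#' `read_stack()` inverts it.
#'
#' @param x Height x width x frames array.
#' @param path TIFF file path.
#' @param scale Full-scale intensity; stored values are `x / scale`.
#' @return `read_stack()`: height x width x frames array.
#' @export
write_stack <- function(x, path, scale = 2^16 - 1) {
  rlang::check_installed("tiff")
  frames <- lapply(seq_len(dim(x)[3]), function(i) {
    pmin(pmax(x[, , i] / scale, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, scale = 2^16 - 1) {
  rlang::check_installed("tiff")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- array(0, c(dim(frames[[1]])[1], dim(frames[[1]])[2], length(frames)))
  for (i in seq_along(frames)) out[, , i] <- frames[[i]] * scale
  out
}
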