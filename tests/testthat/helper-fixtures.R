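# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Wild-type simulation at the scale used for parameter-recovery checks:
# enough state cycles for >= 20 analyzable active states and >= 300
# active-state HSN transients.
wildtype_fixture <- function() {
  if (!is.null(.fixture_env$wt)) return(.fixture_env$wt)
  cfg <- sim_config(duration = 79200, seed = 1)
  truth <- simulate_behavior(cfg)
  traces <- render_traces(truth)
  ann <- annotations_from_truth(truth)
  res <- suppressWarnings(run_analyze(traces, ann))
  .fixture_env$wt <- list(config = cfg, truth = truth, traces = traces,
                          annotations = ann, res = res)
  .fixture_env$wt
}

annotations_from_truth <- function(truth) {
  dplyr::bind_rows(
    tibble::tibble(time_s = truth$eggs$time_s, event_type = "egg"),
    tibble::tibble(time_s = truth$landmarks$time_s,
                   event_type = paste0("ventral_", truth$landmarks$kind))) %>%
    dplyr::arrange(time_s)
}

# A clean single-transient ratio trace (Gaussian kernel) for detector checks.
gaussian_trace <- function(amp = 0.8, fwhm = 4, peak_t = 60,
                           duration = 120, frame_rate = 20, noise_sd = 0) {
  t <- seq(0, duration - 1 / frame_rate, by = 1 / frame_rate)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  dr <- amp * exp(-(t - peak_t)^2 / (2 * sigma^2))
  ratio <- 1 + dr + rnorm(length(t), 0, noise_sd)
  ratio_trace(tibble::tibble(time_s = t, ratio = ratio),
              frame_rate = frame_rate)
}

# Two-channel frames with uniform rectangular "cells" on a flat background;
# exact pixel counts make object bookkeeping checkable.
patch_frame <- function(h = 30, w = 30, bg = 0, patches = list()) {
  g <- matrix(bg, h, w)
  r <- matrix(bg, h, w)
  for (p in patches) {
    g[p$rows, p$cols] <- p$mcherry * p$ratio
    r[p$rows, p$cols] <- p$mcherry
  }
  list(gcamp = g, mcherry = r)
}
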