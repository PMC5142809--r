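#' Simulation configuration for synthetic egg-laying circuit recordings
#'
#' Builds the parameter set that drives [simulate_behavior()],
#' [render_traces()] and [render_frames()]. Defaults describe a wild-type
#' adult: ~20 min inactive states alternating with ~2 min active states, a
#' ~10 s locomotor body-bend cycle, HSN bursting at a ~20 s rhythm with
#' occasional doublet events, VC and vulval-muscle (vm) activity locked to
#' the body-bend cycle, egg-laying vm contractions about four-fold larger
#' than twitches, and uv1 transients triggered by egg release.
#'
#' HSN bursting extends `burst_lead` seconds before and `burst_tail` seconds
#' after each behavioral active state: bursts of HSN activity drive the
#' active state, so they begin before the first egg of a cluster. VC and vm
#' excitability follows the same window.
#'
#' @param frame_rate Sampling rate of rendered recordings, frames/s.
#' @param duration Recording length, s. `frame_rate * duration` must be a
#'   whole number of samples.
#' @param seed Integer seed; all randomness flows from per-component
#'   sub-streams derived from it.
#' @param inactive_mean,active_mean Mean exponential durations of the
#'   inactive and active behavior states, s.
#' @param bend_period_mean,bend_period_cv Mean and coefficient of variation
#'   of the locomotor body-bend period, s.
#' @param burst_lead,burst_tail Extension of the HSN/VC/vm excitable epoch
#'   beyond each active state, s.
#' @param egg_rate_active Rate of candidate egg-release proposals during
#'   active states, 1/s. Candidates are thinned to HSN transient spans and
#'   body-bend phase windows, so the realized egg rate is lower (defaults
#'   yield roughly 5 eggs per 2 min active state).
#' @param egg_phase_mu,egg_phase_kappa Preferred body-bend phase (degrees)
#'   and von Mises concentration of the phase window used to thin egg
#'   candidates.
#' @param egg_lag_mean,egg_lag_sd,egg_lag_range Truncated-normal lag, s, of
#'   egg release after the triggering HSN transient peak. The upper bound
#'   must stay below half the HSN FWHM so every egg lies inside the HSN
#'   half-max span.
#' @param cells Named list of per-cell-type parameter lists (`hsn`, `vc`,
#'   `vm`, `uv1`); partial lists are merged over the defaults. See Details.
#' @param noise List: `gcamp_sd`, `mcherry_sd` (additive intensity noise per
#'   channel) and `artifact_amplitude` (shared multiplicative motion
#'   artifact; 0 disables).
#' @param baselines List: `gcamp`, `mcherry` baseline fluorescence
#'   intensities (their ratio is the resting ratio).
#' @param kernel Transient kernel shape, `"gaussian"` (parameterized by
#'   FWHM) or `"dblexp"` (double exponential with matched FWHM).
#' @param image List of frame-rendering parameters: `height`, `width`,
#'   `cell_radius_px`, `background_mean`, `background_sd`, `blob_peak`,
#'   `centroid` (c(row, col)).
#' @param speed List of centroid-track parameters: `mean` (locomotion speed,
#'   arbitrary length units/s), `dip_frac` (fractional slow-down at egg
#'   release), `dip_sd` (width of the slow-down, s).
#'
#' @details
#' Per-cell parameters:
#' * `hsn`: `fwhm` (s), `rhythm_period` (s), `rhythm_cv`, `doublet_prob`,
#'   `doublet_offset` (s), `inactive_interval_mean` (s), `amplitude_mean`
#'   (delta-R/R), `amplitude_cv`. The expected active-state inter-transient
#'   interval is `rhythm_period / (1 + doublet_prob)`.
#' * `vc`, `vm`: `fwhm`, `phase_mu` (deg), `phase_kappa`,
#'   `inactive_interval_mean`, `amplitude_mean`, `amplitude_cv`; `vc` adds
#'   `egg_peak_lead` (s before egg release of the forced VC transient), `vm`
#'   adds `egg_amplitude_factor` (egg-laying transient amplitude relative to
#'   twitches).
#' * `uv1`: `fwhm`, `onset_lag_mean`, `onset_lag_sd` (s after egg release at
#'   which the rise begins), `amplitude_mean`, `amplitude_cv`.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_behavior()], [expected_active_interval()]
#' @export
#' @examples
#' cfg <- sim_config(duration = 600, seed = 7)
#' expected_active_interval(cfg, "hsn")
sim_config <- function(frame_rate = 20,
                       duration = 1800,
                       seed = 1,
                       inactive_mean = 1200,
                       active_mean = 120,
                       bend_period_mean = 10,
                       bend_period_cv = 0.1,
                       burst_lead = 60,
                       burst_tail = 60,
                       egg_rate_active = 1,
                       egg_phase_mu = 225,
                       egg_phase_kappa = 2,
                       egg_lag_mean = 1.5,
                       egg_lag_sd = 0.4,
                       egg_lag_range = c(0.2, 1.9),
                       cells = list(),
                       noise = list(),
                       baselines = list(),
                       kernel = c("gaussian", "dblexp"),
                       image = list(),
                       speed = list()) {
  kernel <- match.arg(kernel)

  default_cells <- list(
    hsn = list(fwhm = 4, rhythm_period = 20, rhythm_cv = 0.05,
               doublet_prob = 0.15, doublet_offset = 5,
               inactive_interval_mean = 41,
               amplitude_mean = 0.8, amplitude_cv = 0.2),
    vc  = list(fwhm = 2, phase_mu = 270, phase_kappa = 2,
               inactive_interval_mean = 300,
               amplitude_mean = 0.5, amplitude_cv = 0.4,
               egg_peak_lead = 0.3),
    vm  = list(fwhm = 2, phase_mu = 270, phase_kappa = 4,
               inactive_interval_mean = 30,
               amplitude_mean = 0.5, amplitude_cv = 0.3,
               egg_amplitude_factor = 4),
    uv1 = list(fwhm = 3, onset_lag_mean = 0.5, onset_lag_sd = 0.25,
               amplitude_mean = 1.0, amplitude_cv = 0.3)
  )
  for (ct in names(cells)) {
    if (!ct %in% names(default_cells)) {
      abort(paste0("unknown cell type in `cells`: ", ct))
    }
    bad <- setdiff(names(cells[[ct]]), names(default_cells[[ct]]))
    if (length(bad)) {
      abort(paste0("unknown ", ct, " parameter(s): ", paste(bad, collapse = ", ")))
    }
    default_cells[[ct]][names(cells[[ct]])] <- cells[[ct]]
  }

  merge_over <- function(defaults, user, what) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      abort(paste0("unknown ", what, " parameter(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(user)] <- user
    defaults
  }
  noise <- merge_over(list(gcamp_sd = 2, mcherry_sd = 2,
                           artifact_amplitude = 0.1), noise, "noise")
  baselines <- merge_over(list(gcamp = 100, mcherry = 100), baselines,
                          "baselines")
  image <- merge_over(list(height = 40, width = 40, cell_radius_px = 4,
                           background_mean = 100, background_sd = 5,
                           blob_peak = 500, centroid = c(20, 20)),
                      image, "image")
  speed <- merge_over(list(mean = 0.15, dip_frac = 0.5, dip_sd = 0.5),
                      speed, "speed")

  cfg <- structure(list(
    frame_rate = frame_rate, duration = duration, seed = as.integer(seed),
    inactive_mean = inactive_mean, active_mean = active_mean,
    bend_period_mean = bend_period_mean, bend_period_cv = bend_period_cv,
    burst_lead = burst_lead, burst_tail = burst_tail,
    egg_rate_active = egg_rate_active,
    egg_phase_mu = egg_phase_mu, egg_phase_kappa = egg_phase_kappa,
    egg_lag_mean = egg_lag_mean, egg_lag_sd = egg_lag_sd,
    egg_lag_range = egg_lag_range,
    cells = default_cells, noise = noise, baselines = baselines,
    kernel = kernel, image = image, speed = speed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$frame_rate > 0, cfg$duration >= 0)
  n <- cfg$frame_rate * cfg$duration
  if (abs(n - round(n)) > 1e-8) {
    abort("frame_rate * duration must be an integer number of samples")
  }
  pos <- c(inactive_mean = cfg$inactive_mean, active_mean = cfg$active_mean,
           bend_period_mean = cfg$bend_period_mean)
  if (any(pos <= 0)) abort("state and bend-period means must be > 0")
  if (cfg$bend_period_cv < 0) abort("bend_period_cv must be >= 0")
  if (cfg$egg_rate_active < 0) abort("egg_rate_active must be >= 0")
  if (cfg$egg_phase_mu < 0 || cfg$egg_phase_mu >= 360) {
    abort("egg_phase_mu must lie in [0, 360)")
  }
  for (ct in names(cfg$cells)) {
    p <- cfg$cells[[ct]]
    if (p$fwhm <= 0 || p$amplitude_mean <= 0) {
      abort(paste0(ct, ": fwhm and amplitude_mean must be > 0"))
    }
  }
  if (!is.null(cfg$cells$hsn$doublet_prob) &&
      (cfg$cells$hsn$doublet_prob < 0 || cfg$cells$hsn$doublet_prob > 1)) {
    abort("hsn doublet_prob must lie in [0, 1]")
  }
  if (cfg$egg_lag_range[2] >= cfg$cells$hsn$fwhm / 2) {
    abort("egg_lag_range upper bound must be < hsn fwhm / 2")
  }
  if (cfg$noise$artifact_amplitude < 0 || cfg$noise$artifact_amplitude > 0.5) {
    abort("artifact_amplitude must lie in [0, 0.5]")
  }
  invisible(cfg)
}

#' Expected active-state inter-transient interval implied by a configuration
#'
#' For rhythm-locked cells the active-state interval distribution is implied
#' by the rhythm parameters rather than set directly: HSN emits one base
#' transient per rhythm period plus doublets, so its expected interval is
#' `rhythm_period / (1 + doublet_prob)`; VC and vm fire once per body bend,
#' so their expected interval is the bend period; uv1 has no intrinsic
#' rhythm (egg-triggered) and returns `NA`.
#'
#' @param config A [sim_config()].
#' @param cell_type One of `"hsn"`, `"vc"`, `"vm"`, `"uv1"`.
#' @return Expected interval in seconds.
#' @export
expected_active_interval <- function(config, cell_type = c("hsn", "vc", "vm", "uv1")) {
  cell_type <- match.arg(cell_type)
  switch(cell_type,
    hsn = config$cells$hsn$rhythm_period / (1 + config$cells$hsn$doublet_prob),
    vc = config$bend_period_mean,
    vm = config$bend_period_mean,
    uv1 = NA_real_
  )
}
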