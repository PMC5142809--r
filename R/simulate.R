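#' Simulate ground-truth behavior and cell activity for the egg-laying circuit
#'
#' Draws one realization of the circuit's event-level ground truth: an
#' alternating inactive/active behavior-state timeline, a jittered
#' body-bend landmark oscillator, per-cell-type transient trains (HSN
#' rhythmic bursting with doublets; VC and vm locked to the body-bend
#' cycle during the excitable epoch; renewal trains during quiet epochs),
#' egg-release events thinned to HSN transient spans and body-bend phase
#' windows, and uv1 transients triggered by egg passage.
#'
#' @param config A [sim_config()].
#' @return A list of class `egg_sim_truth` with elements
#'   `states` (tibble: start_s, end_s, label), `landmarks` (tibble: time_s,
#'   kind), `eggs` (tibble: time_s, hsn_peak_s, phase_deg), `transients`
#'   (tibble: cell_type, peak_time_s, amplitude, fwhm_s, egg_coupled,
#'   state, phase_deg), `duration`, and `config`.
#' @export
#' @examples
#' truth <- simulate_behavior(sim_config(duration = 1800, seed = 2))
#' dplyr::count(truth$transients, cell_type)
simulate_behavior <- function(config = sim_config()) {
  validate_sim_config(config)
  dur <- config$duration
  empty <- egg_sim_truth(
    states = tibble::tibble(start_s = numeric(), end_s = numeric(),
                            label = character()),
    landmarks = tibble::tibble(time_s = numeric(), kind = character()),
    eggs = tibble::tibble(time_s = numeric(), hsn_peak_s = numeric(),
                          phase_deg = numeric()),
    transients = tibble::tibble(cell_type = character(),
                                peak_time_s = numeric(), amplitude = numeric(),
                                fwhm_s = numeric(), egg_coupled = logical(),
                                state = character(), phase_deg = numeric()),
    duration = dur, config = config)
  if (dur <= 0) return(empty)

  states <- withr::with_seed(derive_seed(config$seed, 1L),
                             sim_state_timeline(dur, config$inactive_mean,
                                                config$active_mean))
  landmarks <- withr::with_seed(derive_seed(config$seed, 2L),
                                sim_bend_landmarks(dur, config$bend_period_mean,
                                                   config$bend_period_cv))

  active <- dplyr::filter(states, .data$label == "active")
  burst <- merge_intervals(pmax(active$start_s - config$burst_lead, 0),
                           pmin(active$end_s + config$burst_tail, dur))
  quiet <- complement_intervals(burst$start, burst$end, 0, dur)

  hsn <- withr::with_seed(derive_seed(config$seed, 3L),
                          sim_hsn_train(burst, quiet, config))
  vc <- withr::with_seed(derive_seed(config$seed, 4L),
                         sim_bend_locked_train("vc", burst, quiet, landmarks, config))
  vm <- withr::with_seed(derive_seed(config$seed, 5L),
                         sim_bend_locked_train("vm", burst, quiet, landmarks, config))

  eggs <- withr::with_seed(derive_seed(config$seed, 7L),
                           sim_eggs(active, hsn, landmarks, config))

  # Couple the trains to egg release.
  hsn$egg_coupled <- vapply(seq_len(nrow(hsn)), function(i) {
    any(abs(eggs$time_s - hsn$peak_time_s[i]) <= hsn$fwhm_s[i] / 2)
  }, logical(1))

  withr::with_seed(derive_seed(config$seed, 8L), {
    vm <- insert_vm_egg_transients(vm, eggs, config)
    vc <- insert_vc_egg_transients(vc, eggs, config)
  })
  uv1 <- withr::with_seed(derive_seed(config$seed, 6L),
                          sim_uv1_train(eggs, config))

  transients <- dplyr::bind_rows(hsn = hsn, vc = vc, vm = vm, uv1 = uv1,
                                 .id = "cell_type") %>%
    dplyr::arrange(.data$cell_type, .data$peak_time_s)
  transients$state <- ifelse(
    is.na(interval_index(transients$peak_time_s,
                         active$start_s, active$end_s)),
    "inactive", "active")
  transients$phase_deg <- assign_phase(transients$peak_time_s, landmarks)

  egg_sim_truth(states = states, landmarks = landmarks, eggs = eggs,
                transients = dplyr::select(
                  transients, "cell_type", "peak_time_s", "amplitude",
                  "fwhm_s", "egg_coupled", "state", "phase_deg"),
                duration = dur, config = config)
}

egg_sim_truth <- function(states, landmarks, eggs, transients, duration, config) {
  structure(list(states = states, landmarks = landmarks, eggs = eggs,
                 transients = transients, duration = duration,
                 config = config),
            class = "egg_sim_truth")
}

#' @export
print.egg_sim_truth <- function(x, ...) {
  cat("<egg_sim_truth> ", x$duration, " s, ",
      sum(x$states$label == "active"), " active state(s), ",
      nrow(x$eggs), " egg(s), ", nrow(x$transients), " transient(s)\n",
      sep = "")
  invisible(x)
}

# Alternating-state timeline with exponential durations, starting inactive.
sim_state_timeline <- function(duration, inactive_mean, active_mean) {
  t <- 0
  label <- "inactive"
  start <- numeric(); end <- numeric(); lab <- character()
  while (t < duration) {
    len <- rexp(1, 1 / if (label == "inactive") inactive_mean else active_mean)
    start <- c(start, t); end <- c(end, min(t + len, duration))
    lab <- c(lab, label)
    t <- t + len
    label <- if (label == "inactive") "active" else "inactive"
  }
  if (length(start) == 1L) {
    warn("recording is shorter than a single behavior state; timeline has one state")
  }
  tibble::tibble(start_s = start, end_s = end, label = lab)
}

# Jittered two-landmark oscillator: contraction and relaxation alternate,
# half a (jittered) period apart; first contraction at t = 0.
sim_bend_landmarks <- function(duration, period_mean, period_cv,
                               start_kind = "contraction") {
  half_mean <- period_mean / 2
  times <- 0
  while (tail(times, 1) < duration) {
    # draw in blocks for speed
    halves <- rgamma_cv(256L, half_mean, period_cv)
    times <- c(times, tail(times, 1) + cumsum(halves))
  }
  times <- times[times < duration]
  kinds <- rep(c(start_kind,
                 if (start_kind == "contraction") "relaxation" else "contraction"),
               length.out = length(times))
  tibble::tibble(time_s = times, kind = kinds)
}

amp_draw <- function(n, mean, cv) {
  rtrunc_norm(n, mean, mean * cv, lower = 0.05 * mean)
}

# Renewal-train interval draw with a refractory floor: distinct calcium
# events closer than ~2 FWHM are not separable as local maxima, so quiet
# trains keep that floor while preserving the configured mean.
renewal_interval <- function(mean, fwhm) {
  ref <- min(2 * fwhm, 0.5 * mean)
  ref + rexp(1, 1 / (mean - ref))
}

# HSN: rhythmic base train with doublets inside burst epochs, renewal train
# in quiet epochs.
sim_hsn_train <- function(burst, quiet, config) {
  p <- config$cells$hsn
  peaks <- numeric()
  for (i in seq_len(nrow(burst))) {
    t <- burst$start[i] + runif(1, 0, p$rhythm_period)
    while (t < burst$end[i]) {
      peaks <- c(peaks, t)
      if (runif(1) < p$doublet_prob) {
        d <- t + rtrunc_norm(1, p$doublet_offset, 0.5,
                             lower = p$fwhm + 0.5,
                             upper = p$rhythm_period - p$fwhm / 2)
        if (d < burst$end[i]) peaks <- c(peaks, d)
      }
      t <- t + rgamma_cv(1, p$rhythm_period, p$rhythm_cv)
    }
  }
  for (i in seq_len(nrow(quiet))) {
    t <- quiet$start[i] + renewal_interval(p$inactive_interval_mean, p$fwhm)
    while (t < quiet$end[i]) {
      peaks <- c(peaks, t)
      t <- t + renewal_interval(p$inactive_interval_mean, p$fwhm)
    }
  }
  peaks <- sort(peaks)
  tibble::tibble(peak_time_s = peaks,
                 amplitude = amp_draw(length(peaks), p$amplitude_mean,
                                      p$amplitude_cv),
                 fwhm_s = rep(p$fwhm, length(peaks)),
                 egg_coupled = rep(FALSE, length(peaks)))
}

# VC / vm: one transient per body-bend cycle at a von Mises phase inside
# burst epochs; renewal train in quiet epochs.
sim_bend_locked_train <- function(cell, burst, quiet, landmarks, config) {
  p <- config$cells[[cell]]
  peaks <- numeric()
  contr <- landmarks$time_s[landmarks$kind == "contraction"]
  relax <- landmarks$time_s[landmarks$kind == "relaxation"]
  # cycles are contraction -> relaxation -> next contraction
  n_cyc <- length(contr) - 1L
  if (n_cyc > 0) {
    phases <- rvonmises_deg(n_cyc, p$phase_mu, p$phase_kappa)
    for (i in seq_len(n_cyc)) {
      c1 <- contr[i]; c2 <- contr[i + 1L]
      r <- relax[relax > c1 & relax < c2]
      if (length(r) != 1L) next
      t <- time_at_phase(phases[i], c1, r, c2)
      if (!is.na(interval_index(t, burst$start, burst$end))) {
        peaks <- c(peaks, t)
      }
    }
  }
  for (i in seq_len(nrow(quiet))) {
    t <- quiet$start[i] + renewal_interval(p$inactive_interval_mean, p$fwhm)
    while (t < quiet$end[i]) {
      peaks <- c(peaks, t)
      t <- t + renewal_interval(p$inactive_interval_mean, p$fwhm)
    }
  }
  peaks <- sort(peaks)
  tibble::tibble(peak_time_s = peaks,
                 amplitude = amp_draw(length(peaks), p$amplitude_mean,
                                      p$amplitude_cv),
                 fwhm_s = rep(p$fwhm, length(peaks)),
                 egg_coupled = rep(FALSE, length(peaks)))
}

# Convert a phase (deg) within one cycle (contraction c1, relaxation r,
# contraction c2) to a time, inverting the landmark-interpolation rule.
time_at_phase <- function(phase_deg, c1, r, c2) {
  phase_deg <- phase_deg %% 360
  if (phase_deg < 180) c1 + phase_deg / 180 * (r - c1)
  else r + (phase_deg - 180) / 180 * (c2 - r)
}

# Egg release: homogeneous candidates in active states, thinned to HSN
# half-max spans and body-bend phase windows; each egg sits at its
# triggering HSN peak + a truncated-normal lag.
sim_eggs <- function(active, hsn, landmarks, config) {
  out <- tibble::tibble(time_s = numeric(), hsn_peak_s = numeric(),
                        phase_deg = numeric())
  if (config$egg_rate_active <= 0 || nrow(active) == 0L || nrow(hsn) == 0L) {
    return(out)
  }
  half <- config$cells$hsn$fwhm / 2
  used <- rep(FALSE, nrow(hsn))
  for (i in seq_len(nrow(active))) {
    len <- active$end_s[i] - active$start_s[i]
    n_cand <- stats::rpois(1, config$egg_rate_active * len)
    if (n_cand == 0) next
    cand <- sort(runif(n_cand, active$start_s[i], active$end_s[i]))
    for (tc in cand) {
      j <- which(abs(hsn$peak_time_s - tc) <= half & !used)
      if (!length(j)) next
      j <- j[which.min(abs(hsn$peak_time_s[j] - tc))]
      lag <- rtrunc_norm(1, config$egg_lag_mean, config$egg_lag_sd,
                         config$egg_lag_range[1], config$egg_lag_range[2])
      te <- hsn$peak_time_s[j] + lag
      if (te < active$start_s[i] || te >= active$end_s[i]) next
      ph <- assign_phase(te, landmarks)
      w <- if (is.na(ph)) 1 else
        vonmises_weight(ph, config$egg_phase_mu, config$egg_phase_kappa)
      if (runif(1) < w) {
        used[j] <- TRUE
        out <- dplyr::bind_rows(out, tibble::tibble(
          time_s = te, hsn_peak_s = hsn$peak_time_s[j], phase_deg = ph))
      }
    }
  }
  dplyr::arrange(out, .data$time_s)
}

# The vm twitch of the cycle containing an egg becomes the (larger)
# egg-laying contraction, re-timed to the moment of egg release.
insert_vm_egg_transients <- function(vm, eggs, config) {
  p <- config$cells$vm
  half_period <- config$bend_period_mean / 2
  for (i in seq_len(nrow(eggs))) {
    te <- eggs$time_s[i]
    d <- abs(vm$peak_time_s - te)
    d[vm$egg_coupled] <- Inf  # one vm contraction per egg
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= half_period) {
      vm$peak_time_s[j] <- te
      vm$amplitude[j] <- vm$amplitude[j] * p$egg_amplitude_factor
      vm$egg_coupled[j] <- TRUE
    } else {
      vm <- dplyr::bind_rows(vm, tibble::tibble(
        peak_time_s = te,
        amplitude = amp_draw(1, p$amplitude_mean, p$amplitude_cv) *
          p$egg_amplitude_factor,
        fwhm_s = p$fwhm, egg_coupled = TRUE))
    }
  }
  dplyr::arrange(vm, .data$peak_time_s)
}

# Every egg release is accompanied by a VC transient: if no VC peak lies
# within the VC half-max span of the egg, one is inserted just before it.
insert_vc_egg_transients <- function(vc, eggs, config) {
  p <- config$cells$vc
  for (i in seq_len(nrow(eggs))) {
    te <- eggs$time_s[i]
    d <- abs(vc$peak_time_s - te)
    if (any(d <= p$fwhm / 2)) {
      vc$egg_coupled[which(d <= p$fwhm / 2)] <- TRUE
    } else {
      vc <- dplyr::bind_rows(vc, tibble::tibble(
        peak_time_s = te - p$egg_peak_lead,
        amplitude = amp_draw(1, p$amplitude_mean, p$amplitude_cv),
        fwhm_s = p$fwhm, egg_coupled = TRUE))
    }
  }
  dplyr::arrange(vc, .data$peak_time_s)
}

# uv1: rise starts at egg release (+ small lag), so the peak falls about
# half a FWHM later.
sim_uv1_train <- function(eggs, config) {
  p <- config$cells$uv1
  n <- nrow(eggs)
  if (n == 0L) {
    return(tibble::tibble(peak_time_s = numeric(), amplitude = numeric(),
                          fwhm_s = numeric(), egg_coupled = logical()))
  }
  lag <- rtrunc_norm(n, p$onset_lag_mean, p$onset_lag_sd, lower = 0)
  tibble::tibble(peak_time_s = eggs$time_s + lag + p$fwhm / 2,
                 amplitude = amp_draw(n, p$amplitude_mean, p$amplitude_cv),
                 fwhm_s = rep(p$fwhm, n),
                 egg_coupled = rep(TRUE, n)) %>%
    dplyr::arrange(.data$peak_time_s)
}

#' Simulate a worm centroid track with egg-release slow-downs
#'
#' A constant-speed sinuous path whose instantaneous speed dips by
#' `config$speed$dip_frac` in a Gaussian window of width `config$speed$dip_sd`
#' centered on each egg-release event, emulating the brief locomotor pause
#' at egg laying.
#'
#' @param truth An `egg_sim_truth`.
#' @param config A [sim_config()]; defaults to the one stored in `truth`.
#' @return Tibble: `time_s`, `x`, `y`.
#' @export
simulate_centroid_track <- function(truth, config = truth$config) {
  n <- round(config$frame_rate * truth$duration)
  t <- seq_len(n - 1L) / config$frame_rate
  t <- c(0, t)
  v <- rep(config$speed$mean, n)
  for (te in truth$eggs$time_s) {
    v <- v * (1 - config$speed$dip_frac *
                exp(-(t - te)^2 / (2 * config$speed$dip_sd^2)))
  }
  # heading wanders slowly; speed profile is what matters downstream
  heading <- cumsum(rep(2 * pi / (30 * config$frame_rate), n))
  dt <- 1 / config$frame_rate
  x <- cumsum(c(0, v[-n] * cos(heading[-n]) * dt))
  y <- cumsum(c(0, v[-n] * sin(heading[-n]) * dt))
  tibble::tibble(time_s = t, x = x, y = y)
}
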