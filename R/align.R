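# Egg-release-triggered alignment: trace ensembles, muscle-size ensembles,
# and peri-event locomotion speed.

new_aligned_ensemble <- function(time_rel_s, mat, offsets, normalize,
                                 n_excluded, value = "droverr") {
  med <- if (nrow(mat)) apply(mat, 2, median, na.rm = TRUE) else
    rep(NA_real_, length(time_rel_s))
  structure(list(time_rel_s = time_rel_s, snippets = mat,
                 median = med, offsets = offsets,
                 n_events = nrow(mat), n_excluded = n_excluded,
                 normalize = normalize, value = value),
            class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat("<aligned_ensemble> ", x$n_events, " event(s) (", x$n_excluded,
      " excluded), window [", min(x$time_rel_s), ", ", max(x$time_rel_s),
      "] s, value = ", x$value, "\n", sep = "")
  invisible(x)
}

align_core <- function(time_s, values, frame_rate, egg_times, window,
                       normalize, value_name) {
  k <- round(window * frame_rate)
  rel <- (-k:k) / frame_rate
  n <- length(values)
  rows <- list()
  offsets <- numeric()
  excluded <- 0L
  for (te in egg_times) {
    ci <- round((te - time_s[1]) * frame_rate) + 1L
    if (ci - k < 1L || ci + k > n) {
      excluded <- excluded + 1L
      next
    }
    snip <- values[(ci - k):(ci + k)]
    if (anyNA(snip)) {
      excluded <- excluded + 1L
      next
    }
    snip <- switch(normalize,
      peak = 100 * snip / max(snip),
      pre_event_mean = 100 * snip / mean(snip[rel < 0]),
      none = snip)
    rows[[length(rows) + 1L]] <- snip
    offsets <- c(offsets, rel[which.max(snip)])
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0L, length(rel))
  new_aligned_ensemble(rel, mat,
                       tibble::tibble(event = seq_along(offsets),
                                      peak_offset_s = offsets),
                       normalize, excluded, value_name)
}

#' Align delta-R/R snippets to egg-release events
#'
#' Cuts a `window`-second snippet around each egg-release time with the
#' full window inside the recording (others are excluded and counted),
#' normalizes each snippet so its peak is 100%, and computes the pointwise
#' median trace. Each event's peak offset is the time of the snippet
#' maximum relative to egg release (negative = before); when a transient
#' table is supplied the offset of the nearest detected peak is used
#' instead.
#'
#' @param trace A baselined [ratio_trace()] (needs `droverr`).
#' @param egg_times Egg-release times, s.
#' @param window Half-window, s.
#' @param transients Optional [detect_transients()] table for peak offsets.
#' @return An `aligned_ensemble`; see [tidy.aligned_ensemble()].
#' @export
align_to_eggs <- function(trace, egg_times, window = 10, transients = NULL) {
  if (!"droverr" %in% names(trace)) {
    abort("trace has no droverr column; run compute_baseline() first")
  }
  fr <- trace_frame_rate(trace)
  ens <- align_core(trace$time_s, trace$droverr, fr, egg_times, window,
                    "peak", "droverr")
  if (!is.null(transients) && nrow(transients) && ens$n_events) {
    kept <- egg_times[vapply(egg_times, function(te) {
      ci <- round((te - trace$time_s[1]) * fr) + 1L
      k <- round(window * fr)
      ci - k >= 1L && ci + k <= nrow(trace)
    }, logical(1))]
    ens$offsets$peak_offset_s <- vapply(kept, function(te) {
      transients$peak_time_s[which.min(abs(transients$peak_time_s - te))] - te
    }, numeric(1))
  }
  ens
}

#' Align object-size (muscle contraction) snippets to egg-release events
#'
#' As [align_to_eggs()] but on the total-object-area trace, with each
#' snippet normalized to its pre-event mean (= 100%).
#'
#' @param size_trace Tibble with `time_s` and `total_area_px` (e.g. from
#'   [extract_trace()]).
#' @param egg_times Egg-release times, s.
#' @param window Half-window, s.
#' @param frame_rate Frames/s; inferred from the time grid when `NULL`.
#' @return An `aligned_ensemble`.
#' @export
align_size_to_eggs <- function(size_trace, egg_times, window = 10,
                               frame_rate = NULL) {
  fr <- frame_rate %||% (1 / mean(diff(size_trace$time_s)))
  align_core(size_trace$time_s, size_trace$total_area_px, fr, egg_times,
             window, "pre_event_mean", "total_area_px")
}

#' Peri-event locomotion speed around egg release
#'
#' Speed is the centroid displacement per frame divided by the frame
#' interval (central difference), smoothed with the pipeline's 3-point
#' rolling average. Snippets are aligned at egg release; the mean trace and
#' pointwise 95% t-interval are returned together with paired comparisons
#' of speed at 0 s against -1 s and +1 s.
#'
#' @param track Tibble: `time_s`, `x`, `y`, uniformly sampled.
#' @param egg_times Egg-release times, s.
#' @param window Half-window, s.
#' @return List of class `peri_event_speed`: `time_rel_s`, `mean`,
#'   `ci_lower`, `ci_upper`, `n_events`, `comparisons` (tibble with paired
#'   t-tests at -1 s and +1 s).
#' @export
peri_event_speed <- function(track, egg_times, window = 10) {
  dt <- mean(diff(track$time_s))
  fr <- 1 / dt
  n <- nrow(track)
  if (n < 3L) abort("track too short")
  dx <- track$x[c(-1L, -2L)] - track$x[c(-(n - 1L), -n)]
  dy <- track$y[c(-1L, -2L)] - track$y[c(-(n - 1L), -n)]
  speed <- c(NA, sqrt(dx^2 + dy^2) / (2 * dt), NA)
  speed[1] <- speed[2]; speed[n] <- speed[n - 1L]
  speed <- rolling_mean(speed, 3L)
  ens <- align_core(track$time_s, speed, fr, egg_times, window, "none",
                    "speed")
  m <- ens$snippets
  if (nrow(m) == 0L) abort("no egg event with a full window inside the track")
  mean_tr <- colMeans(m)
  if (nrow(m) >= 2L) {
    se <- apply(m, 2, sd) / sqrt(nrow(m))
    tq <- qt(0.975, nrow(m) - 1L)
    lo <- mean_tr - tq * se; hi <- mean_tr + tq * se
  } else {
    warn("single event: confidence interval undefined")
    lo <- hi <- rep(NA_real_, ncol(m))
  }
  at <- function(t_rel) m[, which.min(abs(ens$time_rel_s - t_rel))]
  comparisons <- if (nrow(m) >= 2L) {
    purrr::map_dfr(c(-1, 1), function(tr) {
      d <- at(0) - at(tr)
      if (sd(d) < .Machine$double.eps^0.5 * (1 + mean(abs(d)))) {
        # degenerate paired differences (e.g. constant-velocity track)
        return(tibble::tibble(reference_s = tr, mean_diff = mean(d),
                              statistic = 0, p_value = 1))
      }
      tt <- t.test(at(0), at(tr), paired = TRUE)
      tibble::tibble(reference_s = tr, mean_diff = unname(tt$estimate),
                     statistic = unname(tt$statistic), p_value = tt$p.value)
    })
  } else {
    tibble::tibble(reference_s = numeric(), mean_diff = numeric(),
                   statistic = numeric(), p_value = numeric())
  }
  structure(list(time_rel_s = ens$time_rel_s, mean = mean_tr,
                 ci_lower = lo, ci_upper = hi, n_events = nrow(m),
                 n_excluded = ens$n_excluded, comparisons = comparisons),
            class = "peri_event_speed")
}

#' @export
print.peri_event_speed <- function(x, ...) {
  cat("<peri_event_speed> ", x$n_events, " event(s); speed at 0 s = ",
      signif(x$mean[which.min(abs(x$time_rel_s))], 4), "\n", sep = "")
  if (nrow(x$comparisons)) print(x$comparisons)
  invisible(x)
}
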