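# Trace processing: raw ratio traces -> delta-R/R and detected transients.

#' Construct a ratio trace
#'
#' Wraps a uniformly sampled two-channel (or precomputed-ratio) trace table
#' as a `ratio_trace` tibble. If `gcamp` and `mcherry` columns are present
#' the `ratio` column is computed as their quotient.
#'
#' @param x Data frame with `time_s` and either `ratio` or `gcamp` +
#'   `mcherry` columns.
#' @param frame_rate Frames/s; inferred from the time grid when `NULL`.
#' @param cell_type Optional label (`"hsn"`, `"vc"`, `"vm"`, `"uv1"`, ...).
#' @return A `ratio_trace` tibble with columns `time_s`, `ratio` (plus any
#'   input columns), and attributes `frame_rate`, `cell_type`.
#' @export
#' @examples
#' tr <- ratio_trace(tibble::tibble(time_s = 0:99 / 20, ratio = 1 + 0 * (0:99)))
ratio_trace <- function(x, frame_rate = NULL, cell_type = NULL) {
  x <- tibble::as_tibble(x)
  if (!"time_s" %in% names(x)) abort("`x` must have a time_s column")
  if (!"ratio" %in% names(x)) {
    if (!all(c("gcamp", "mcherry") %in% names(x))) {
      abort("`x` needs a ratio column or gcamp + mcherry columns")
    }
    x$ratio <- x$gcamp / x$mcherry
  }
  n <- nrow(x)
  if (n >= 2L) {
    dt <- diff(x$time_s)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
      abort("time_s must be a strictly increasing uniform grid")
    }
    frame_rate <- frame_rate %||% (1 / mean(dt))
  }
  structure(x, class = c("ratio_trace", class(tibble::tibble()))) %>%
    set_trace_attrs(frame_rate = frame_rate, cell_type = cell_type)
}

set_trace_attrs <- function(x, ...) {
  dots <- list(...)
  for (nm in names(dots)) attr(x, nm) <- dots[[nm]]
  x
}

trace_frame_rate <- function(trace) {
  fr <- attr(trace, "frame_rate")
  if (is.null(fr)) abort("trace has no frame_rate; build it with ratio_trace()")
  fr
}

#' Smooth a ratio trace with a short rolling average
#'
#' Centered moving average over `round(window_s * frame_rate)` samples
#' (three timepoints at 20 frames/s for the default 150 ms window); edges
#' use shrunken windows. Adds/overwrites a `ratio_smooth` column.
#'
#' @param trace A [ratio_trace()].
#' @param window_s Window length, s.
#' @return The trace with a `ratio_smooth` column.
#' @export
smooth_trace <- function(trace, window_s = 0.15) {
  fr <- trace_frame_rate(trace)
  k <- round(window_s * fr)
  if (k < 1) {
    warn("smoothing window shorter than one sample; trace left unchanged")
    k <- 1L
  }
  if (nrow(trace) < 3L) abort("need at least 3 samples to smooth")
  trace$ratio_smooth <- rolling_mean(trace$ratio, k)
  trace
}

#' Baseline a ratio trace from its lowest decile
#'
#' The baseline is the mean of the `floor(fraction * n)` smallest ratio
#' values over the entire recording (at least one value); delta-R/R is then
#' `(ratio - baseline) / baseline`, computed on the smoothed ratio when
#' available.
#'
#' @param trace A [ratio_trace()]; run [smooth_trace()] first for the
#'   standard pipeline.
#' @param fraction Fraction of lowest values averaged.
#' @param use_smoothed Compute the baseline (and delta-R/R) on
#'   `ratio_smooth` when present.
#' @return The trace with a `droverr` column and a `baseline` attribute.
#' @export
compute_baseline <- function(trace, fraction = 0.10, use_smoothed = TRUE) {
  if (nrow(trace) < 10L) abort("need at least 10 samples to baseline")
  src <- if (use_smoothed && "ratio_smooth" %in% names(trace)) {
    trace$ratio_smooth
  } else {
    trace$ratio
  }
  k <- max(1L, floor(fraction * length(src)))
  baseline <- mean(sort(src)[seq_len(k)])
  if (!is.finite(baseline) || baseline <= 0) {
    abort("baseline is not positive; ratio traces must be positive")
  }
  trace$droverr <- (src - baseline) / baseline
  set_trace_attrs(trace, baseline = baseline)
}

#' Detect calcium transients in a delta-R/R trace
#'
#' Finds local maxima with topographic prominence at least
#' `min_prominence_sigmas` times a robust noise scale (1.4826 x the median
#' absolute deviation of the first difference, divided by sqrt(2)) and at
#' least `min_separation_s` apart (the larger peak wins). The noise scale is
#' estimated from the raw (pre-smoothing) ratio when available: the rolling
#' average correlates adjacent samples, which would deflate a
#' difference-based noise estimate roughly three-fold. Each peak's extent
#' is the half-maximum span, found by walking outward to the half-amplitude
#' crossings with linear interpolation between samples; overlapping spans
#' are truncated at the inter-peak minimum.
#'
#' @param trace A smoothed, baselined [ratio_trace()] (needs `droverr`).
#' @param min_prominence_sigmas Prominence threshold in robust noise SDs.
#' @param min_separation_s Minimum peak separation, s.
#' @return Tibble with one transient per row: `peak_time_s`, `amplitude`
#'   (delta-R/R at peak), `prominence`, `onset_s`, `offset_s`, `fwhm_s`;
#'   attributes `noise_sigma`, `frame_rate`, `params`.
#' @export
detect_transients <- function(trace, min_prominence_sigmas = 4.5,
                              min_separation_s = 0.5) {
  if (!"droverr" %in% names(trace)) {
    abort("trace has no droverr column; run compute_baseline() first")
  }
  fr <- trace_frame_rate(trace)
  x <- trace$droverr
  t <- trace$time_s
  empty <- tibble::tibble(peak_time_s = numeric(), amplitude = numeric(),
                          prominence = numeric(), onset_s = numeric(),
                          offset_s = numeric(), fwhm_s = numeric())
  baseline <- attr(trace, "baseline")
  noise_src <- if ("ratio" %in% names(trace) && !is.null(baseline)) {
    (trace$ratio - baseline) / baseline
  } else {
    x
  }
  d <- diff(x)
  sigma <- mad(diff(noise_src)) / sqrt(2)
  attr(empty, "noise_sigma") <- sigma
  if (all(d == 0)) return(empty)
  cand <- local_maxima_cpp(x)
  if (!length(cand)) return(empty)
  prom <- peak_prominence_cpp(x, cand)
  # numerical floor: on (near-)noise-free traces sigma collapses to ~0 and
  # floating-point ripple would otherwise register as peaks
  thr <- max(min_prominence_sigmas * sigma, 0.01 * diff(range(x)))
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  # enforce minimum separation, higher peak wins
  o <- order(x[cand], decreasing = TRUE)
  sel <- logical(length(cand))
  taken_t <- numeric(0)
  for (i in o) {
    if (!length(taken_t) || all(abs(t[cand[i]] - taken_t) >= min_separation_s)) {
      sel[i] <- TRUE
      taken_t <- c(taken_t, t[cand[i]])
    }
  }
  cand <- cand[sel]; prom <- prom[sel]
  o <- order(cand)
  cand <- cand[o]; prom <- prom[o]

  spans <- half_max_spans(x, t, cand)
  out <- tibble::tibble(peak_time_s = t[cand], amplitude = x[cand],
                        prominence = prom,
                        onset_s = spans$onset, offset_s = spans$offset,
                        fwhm_s = spans$offset - spans$onset)
  attr(out, "noise_sigma") <- sigma
  attr(out, "frame_rate") <- fr
  attr(out, "params") <- list(min_prominence_sigmas = min_prominence_sigmas,
                              min_separation_s = min_separation_s)
  out
}

# Half-maximum spans for detected peaks: walk outward to the half-amplitude
# crossing (linear interpolation), stopping at the minimum between adjacent
# kept peaks when the signal never drops below half there.
half_max_spans <- function(x, t, peaks) {
  n <- length(x)
  m <- length(peaks)
  onset <- numeric(m); offset <- numeric(m)
  for (k in seq_len(m)) {
    p <- peaks[k]
    half <- x[p] / 2
    lo_lim <- if (k > 1L) {
      seg <- peaks[k - 1L]:p
      seg[which.min(x[seg])]
    } else 1L
    hi_lim <- if (k < m) {
      seg <- p:peaks[k + 1L]
      seg[which.min(x[seg])]
    } else n
    j <- p
    while (j > lo_lim && x[j - 1L] >= half) j <- j - 1L
    onset[k] <- if (j > lo_lim) {
      # crossing between samples j-1 and j
      t[j - 1L] + (half - x[j - 1L]) / (x[j] - x[j - 1L]) * (t[j] - t[j - 1L])
    } else {
      t[lo_lim]  # truncated at inter-peak minimum / trace start
    }
    j <- p
    while (j < hi_lim && x[j + 1L] >= half) j <- j + 1L
    offset[k] <- if (j < hi_lim) {
      t[j] + (x[j] - half) / (x[j] - x[j + 1L]) * (t[j + 1L] - t[j])
    } else {
      t[hi_lim]
    }
  }
  list(onset = onset, offset = offset)
}

#' Normalize transient amplitudes to the recording maximum
#'
#' Adds `normalized_amplitude = amplitude / max(amplitude)`, so the largest
#' transient of the recording is 1 and amplitudes are comparable across
#' reporters and recording conditions.
#'
#' @param transients Tibble from [detect_transients()].
#' @param mode Normalization mode (only `"per_recording_max"`).
#' @return The transients with a `normalized_amplitude` column.
#' @export
normalize_amplitudes <- function(transients, mode = "per_recording_max") {
  mode <- match.arg(mode, "per_recording_max")
  if (nrow(transients) == 0L) {
    transients$normalized_amplitude <- numeric(0)
    return(transients)
  }
  transients$normalized_amplitude <-
    transients$amplitude / max(transients$amplitude)
  transients
}
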