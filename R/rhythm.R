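# Rhythm analysis: periodograms of active-state delta-R/R segments and
# dominant-peak extraction in the 0-250 mHz band.

new_periodogram <- function(frequency_mhz, power, method, frame_rate = NA,
                            n = NA, segment = NULL, low_resolution = FALSE) {
  structure(tibble::tibble(frequency_mhz = frequency_mhz, power = power),
            class = c("periodogram", class(tibble::tibble())),
            method = method, frame_rate = frame_rate, n = n,
            segment = segment, low_resolution = low_resolution)
}

#' FFT periodogram of a uniformly sampled segment
#'
#' The segment is mean-subtracted, zero-padded to the next power of two at
#' least `pad_factor` times its length (about 1-2 mHz grid spacing for a
#' 2 min active-state segment at 20 frames/s), and its squared-magnitude
#' spectrum is returned over `[0, Nyquist]`. No taper is applied by
#' default; a Hann window is available for longer segments.
#'
#' @param x Numeric delta-R/R samples, or a data frame with a `droverr`
#'   column.
#' @param frame_rate Frames/s.
#' @param pad_factor Zero-padding factor.
#' @param window `"none"` or `"hann"`.
#' @param segment Optional `(start_s, end_s)` metadata.
#' @return A `periodogram` tibble: `frequency_mhz`, `power`; attribute
#'   `low_resolution` flags segments shorter than 30 s.
#' @export
#' @examples
#' p <- periodogram_fft(sin(2 * pi * 0.05 * (0:2399) / 20), frame_rate = 20)
#' dominant_peak(p)
periodogram_fft <- function(x, frame_rate, pad_factor = 4,
                            window = c("none", "hann"), segment = NULL) {
  window <- match.arg(window)
  if (is.data.frame(x)) {
    frame_rate <- attr(x, "frame_rate") %||% frame_rate
    x <- x$droverr
  }
  n <- length(x)
  if (n < 2L) abort("segment too short for spectral analysis")
  low_res <- n / frame_rate < 30
  if (low_res) {
    warn("segment shorter than 30 s; periodogram flagged low-resolution")
  }
  y <- x - mean(x)
  if (window == "hann") {
    y <- y * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  }
  nfft <- 2^ceiling(log2(pad_factor * n))
  ft <- fft(c(y, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  power <- Mod(ft[half])^2 / n
  freq <- (half - 1L) * frame_rate / nfft * 1000
  new_periodogram(freq, power, "fft", frame_rate, n, segment, low_res)
}

#' Lomb-Scargle periodogram of an unevenly sampled segment or event train
#'
#' Classic normalized Scargle periodogram (time-shift-invariant form) for
#' arbitrary sampling. An event train (times only) is first binarized onto
#' a uniform grid (`event_dt` bins, 1 where an event falls) and the
#' periodogram computed on that series.
#'
#' @param times Sample (or event) times, s.
#' @param values Sample values; `NULL` for an event train.
#' @param freq_mhz Frequency grid, mHz; default spans (0, 250] with spacing
#'   `1/(4 T)`.
#' @param event_dt Bin width for binarizing event trains, s.
#' @return A `periodogram` tibble.
#' @export
periodogram_lomb_scargle <- function(times, values = NULL, freq_mhz = NULL,
                                     event_dt = 0.25) {
  if (length(times) < 4L) abort("need at least 4 samples or events")
  if (is.null(values)) {
    # binarized event series on a uniform grid
    span <- range(times)
    grid <- seq(span[1], span[2] + event_dt, by = event_dt)
    values <- as.numeric(tabulate(findInterval(times, grid),
                                  nbins = length(grid)) > 0)
    times <- grid
  }
  T_span <- diff(range(times))
  if (is.null(freq_mhz)) {
    df <- 1000 / (4 * T_span)
    freq_mhz <- seq(df, 250, by = df)
  }
  y <- values - mean(values)
  var_y <- sum(y^2) / (length(y) - 1L)
  if (var_y == 0) {
    return(new_periodogram(freq_mhz, rep(0, length(freq_mhz)),
                           "lomb_scargle", NA, length(y)))
  }
  power <- vapply(freq_mhz, function(f) {
    w <- 2 * pi * f / 1000
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * var_y)
  }, numeric(1))
  new_periodogram(freq_mhz, power, "lomb_scargle", NA, length(y))
}

#' Autocorrelation estimate of the dominant rhythm
#'
#' The dominant frequency is `1 / lag` of the first positive
#' autocorrelation peak whose value exceeds the `2 / sqrt(n)` significance
#' bound. Returned as a `periodogram` over the corresponding frequency grid
#' so [dominant_peak()] applies unchanged.
#'
#' @param x Uniformly sampled values.
#' @param frame_rate Frames/s.
#' @param max_lag_s Longest lag examined, s.
#' @return A `periodogram` tibble (power = autocorrelation at `1/f` lag).
#' @export
periodogram_autocorr <- function(x, frame_rate, max_lag_s = NULL) {
  n <- length(x)
  max_lag <- min(n - 1L, round((max_lag_s %||% (n / frame_rate / 2)) * frame_rate))
  r <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1L]
  lag_s <- seq_along(r) / frame_rate
  bound <- 2 / sqrt(n)
  # skip the initial short-lag decay: rhythm peaks lie beyond the first dip
  # below the significance bound
  first_dip <- which(r < bound)[1]
  pk <- local_maxima_cpp(c(-Inf, r, -Inf)) - 1L
  pk <- pk[pk >= 1L & pk <= length(r)]
  pk <- pk[r[pk] > bound & (!is.na(first_dip) & pk > first_dip)]
  if (!length(pk)) {
    return(new_periodogram(numeric(), numeric(), "autocorrelation",
                           frame_rate, n))
  }
  first <- min(pk)
  new_periodogram(1000 / lag_s[first], r[first], "autocorrelation",
                  frame_rate, n)
}

#' Dominant periodogram peak within a frequency band
#'
#' Argmax of power restricted to the open-below band (the zero-frequency
#' bin is always excluded); ties break toward the lower frequency.
#'
#' @param p A `periodogram`.
#' @param band Length-2 band, mHz; the peak is sought in `(band[1], band[2]]`.
#' @return One-row tibble: `frequency_mhz`, `power`.
#' @export
dominant_peak <- function(p, band = c(0, 250)) {
  stopifnot(length(band) == 2L, band[2] > band[1])
  keep <- p$frequency_mhz > band[1] & p$frequency_mhz <= band[2] &
    p$frequency_mhz > 0
  if (!any(keep)) abort("no periodogram frequencies inside the band")
  f <- p$frequency_mhz[keep]; pw <- p$power[keep]
  o <- order(f)
  f <- f[o]; pw <- pw[o]
  i <- which.max(pw)  # first maximum = lowest frequency on ties
  tibble::tibble(frequency_mhz = f[i], power = pw[i])
}

#' Periodograms and dominant peaks of all active-state segments
#'
#' Cuts the delta-R/R trace at the active-state intervals, computes one FFT
#' periodogram per segment at least `min_segment_s` long, and extracts each
#' segment's dominant peak in `band`.
#'
#' @param trace A baselined [ratio_trace()].
#' @param states A [define_states()] result.
#' @param band Search band, mHz.
#' @param min_segment_s Shortest segment analyzed, s.
#' @param ... Passed to [periodogram_fft()].
#' @return List: `periodograms` (list of `periodogram`), `peaks` (tibble:
#'   segment, start_s, end_s, duration_s, frequency_mhz, power).
#' @export
active_state_rhythms <- function(trace, states, band = c(0, 250),
                                 min_segment_s = 30, ...) {
  act <- states[states$label == "active", , drop = FALSE]
  fr <- trace_frame_rate(trace)
  pgs <- list()
  rows <- list()
  for (i in seq_len(nrow(act))) {
    sel <- trace$time_s >= act$start_s[i] & trace$time_s < act$end_s[i]
    if (sum(sel) / fr < min_segment_s) next
    p <- periodogram_fft(trace$droverr[sel], fr,
                         segment = c(act$start_s[i], act$end_s[i]), ...)
    pk <- dominant_peak(p, band)
    pgs[[length(pgs) + 1L]] <- p
    rows[[length(rows) + 1L]] <- tibble::tibble(
      segment = length(pgs), start_s = act$start_s[i], end_s = act$end_s[i],
      duration_s = sum(sel) / fr,
      frequency_mhz = pk$frequency_mhz, power = pk$power)
  }
  list(periodograms = pgs, peaks = dplyr::bind_rows(rows))
}
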