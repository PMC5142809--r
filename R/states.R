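# Behavioral state segmentation from egg-release event times, state
# assignment of transients, state-resolved inter-transient intervals, and
# egg-coincidence statistics.

#' Define egg-laying active and inactive states from egg-release times
#'
#' Each egg contributes a window `[egg - pad, egg + pad]`; overlapping
#' windows (or windows separated by at most `merge_gap`) merge into one
#' active interval. The complement of the active intervals is labeled
#' inactive, and everything is clipped to the recording span. With no eggs
#' the whole recording is one inactive interval.
#'
#' @param egg_times Sorted egg-release times, s.
#' @param recording_span Length-2 numeric, recording start and end, s.
#' @param pad Window half-width around each egg, s (1 min by default).
#' @param merge_gap Merge active windows separated by at most this gap, s.
#' @return Tibble of class `state_intervals`: `start_s`, `end_s`, `label`;
#'   attributes `egg_times`, `pad`, `recording_span`.
#' @export
#' @examples
#' define_states(c(300, 360), c(0, 1800))
define_states <- function(egg_times, recording_span, pad = 60,
                          merge_gap = 0) {
  stopifnot(length(recording_span) == 2L, recording_span[2] >= recording_span[1])
  egg_times <- sort(egg_times)
  if (length(egg_times) &&
      (min(egg_times) < recording_span[1] || max(egg_times) > recording_span[2])) {
    abort("egg times must lie inside the recording span")
  }
  if (length(egg_times) == 0L) {
    out <- tibble::tibble(start_s = recording_span[1],
                          end_s = recording_span[2], label = "inactive")
  } else {
    act <- merge_intervals(pmax(egg_times - pad, recording_span[1]),
                           pmin(egg_times + pad, recording_span[2]),
                           merge_gap = merge_gap)
    inact <- complement_intervals(act$start, act$end,
                                  recording_span[1], recording_span[2])
    out <- dplyr::bind_rows(
      tibble::tibble(start_s = act$start, end_s = act$end, label = "active"),
      tibble::tibble(start_s = inact$start, end_s = inact$end,
                     label = "inactive")) %>%
      dplyr::arrange(.data$start_s)
  }
  structure(out, class = c("state_intervals", class(tibble::tibble())),
            egg_times = egg_times, pad = pad,
            recording_span = recording_span)
}

#' Assign behavior-state labels to transients
#'
#' Membership is by peak time under a half-open `[start, end)` convention,
#' so a peak exactly on a boundary belongs to the interval starting there.
#'
#' @param transients Tibble with a `peak_time_s` column.
#' @param states A [define_states()] result.
#' @return The transients with `state` and `state_interval` (row index into
#'   `states`) columns.
#' @export
assign_states <- function(transients, states) {
  idx <- interval_index(transients$peak_time_s, states$start_s, states$end_s)
  # peaks exactly at the recording end belong to the last interval
  at_end <- is.na(idx) &
    transients$peak_time_s == attr(states, "recording_span")[2]
  idx[at_end] <- nrow(states)
  transients$state <- ifelse(is.na(idx), "unassigned", states$label[idx])
  transients$state_interval <- idx
  transients
}

#' State-resolved inter-transient intervals
#'
#' Elapsed time between successive transient peaks within each behavior
#' state. Pairs whose members fall in different state intervals (i.e. that
#' span a state boundary) are excluded unless `include_cross_state = TRUE`
#' (in which case pairs sharing a label contribute). When the inactive
#' state contains no successive-peak pairs at all, the operational boundary
#' intervals are used instead: the time from the recording start to the
#' first transient and from the last transient to the recording end, tagged
#' `kind = "boundary"`.
#'
#' @param transients State-labeled transients (see [assign_states()]).
#' @param states The [define_states()] result used for labeling.
#' @param include_cross_state Keep successive pairs with equal labels but
#'   different state intervals.
#' @return Tibble: `state`, `interval_s`, `kind` (`"successive"` or
#'   `"boundary"`).
#' @export
inter_transient_intervals <- function(transients, states,
                                      include_cross_state = FALSE) {
  tr <- dplyr::arrange(transients, .data$peak_time_s)
  out <- tibble::tibble(state = character(), interval_s = numeric(),
                        kind = character())
  if (nrow(tr) >= 2L) {
    same_label <- tr$state[-nrow(tr)] == tr$state[-1L]
    same_interval <- tr$state_interval[-nrow(tr)] == tr$state_interval[-1L]
    keep <- same_label & (include_cross_state | same_interval)
    keep[is.na(keep)] <- FALSE
    out <- tibble::tibble(state = tr$state[-nrow(tr)][keep],
                          interval_s = diff(tr$peak_time_s)[keep],
                          kind = "successive")
  }
  span <- attr(states, "recording_span")
  n_inactive_pairs <- sum(out$state == "inactive")
  if (n_inactive_pairs == 0L && nrow(tr) >= 1L &&
      any(states$label == "inactive")) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      state = "inactive",
      interval_s = c(min(tr$peak_time_s) - span[1],
                     span[2] - max(tr$peak_time_s)),
      kind = "boundary"))
  }
  out
}

#' Egg-coincidence classification of transients
#'
#' A transient is egg-coupled when some egg-release time falls inside its
#' half-maximum span `[onset_s, offset_s]` (closed interval); an egg is
#' covered when some transient span contains it.
#'
#' @param transients Tibble with `onset_s` and `offset_s` columns.
#' @param egg_times Egg-release times, s.
#' @return The transients with an `egg_coupled` column; attribute
#'   `egg_summary` holds the summary tibble from
#'   [egg_coincidence_summary()].
#' @export
egg_coincidence <- function(transients, egg_times) {
  transients$egg_coupled <- vapply(seq_len(nrow(transients)), function(i) {
    any(egg_times >= transients$onset_s[i] & egg_times <= transients$offset_s[i])
  }, logical(1))
  attr(transients, "egg_summary") <-
    egg_coincidence_summary(transients, egg_times)
  transients
}

#' @rdname egg_coincidence
#' @return `egg_coincidence_summary()`: one-row tibble with `n_transients`,
#'   `n_eggs`, `frac_transients_coupled`, `frac_eggs_covered`.
#' @export
egg_coincidence_summary <- function(transients, egg_times) {
  coupled <- vapply(seq_len(nrow(transients)), function(i) {
    any(egg_times >= transients$onset_s[i] & egg_times <= transients$offset_s[i])
  }, logical(1))
  covered <- vapply(egg_times, function(te) {
    any(te >= transients$onset_s & te <= transients$offset_s)
  }, logical(1))
  tibble::tibble(
    n_transients = nrow(transients),
    n_eggs = length(egg_times),
    frac_transients_coupled = if (nrow(transients)) mean(coupled) else NA_real_,
    frac_eggs_covered = if (length(egg_times)) mean(covered) else NA_real_)
}
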