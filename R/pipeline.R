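# End-to-end orchestration: simulate, analyze, compare.

#' Analysis configuration
#'
#' Collects the tunable parameters of every analysis stage with the
#' pipeline defaults. Unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    smooth_window_s = 0.15,
    baseline_fraction = 0.10,
    baseline_on_smoothed = TRUE,
    min_prominence_sigmas = 4.5,
    min_separation_s = 0.5,
    state_pad_s = 60,
    state_merge_gap_s = 0,
    band_mhz = c(0, 250),
    min_segment_s = 30,
    pad_factor = 4,
    align_window_s = 10,
    phase_bin_width = 45,
    seed = 1L
  )
  user <- list(...)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown analysis parameter(s): ", paste(bad, collapse = ", ")))
  }
  defaults[names(user)] <- user
  structure(defaults, class = "analysis_config")
}

#' Simulate a recording and optionally write its artifacts
#'
#' Wraps [simulate_behavior()] and [render_traces()] (and
#' [render_frames()] when `frames = TRUE`), writing all artifacts plus a
#' manifest (seed, config hash) when `out_dir` is given.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param frames Also render an image stack for `frames_cell`.
#' @param frames_cell Cell type rendered to frames.
#' @param cells Cell types whose traces are rendered.
#' @return List: `truth`, `traces`, optionally `frames`, `dir`.
#' @export
run_simulate <- function(config = sim_config(), out_dir = NULL,
                         frames = FALSE, frames_cell = "vm",
                         cells = c("hsn", "vc", "vm", "uv1")) {
  truth <- simulate_behavior(config)
  traces <- render_traces(truth, cells = cells)
  fr <- if (frames) render_frames(truth, cell = frames_cell)
  if (!is.null(out_dir)) {
    write_recording(truth, traces, out_dir, frames = fr)
  }
  list(truth = truth, traces = traces, frames = fr, dir = out_dir)
}

#' Analyze two-channel traces with behavioral annotations
#'
#' Runs the full quantification pipeline per cell type: ratio formation,
#' 150 ms smoothing, lowest-decile baselining, transient detection and
#' amplitude normalization, egg-based active/inactive state segmentation,
#' state-resolved inter-transient intervals, egg-coincidence fractions,
#' active-state FFT periodograms with 0-250 mHz dominant peaks, body-bend
#' phase assignment and binning, and egg-release-triggered alignment.
#'
#' @param traces Tibble: `time_s`, `gcamp`, `mcherry` (or `ratio`),
#'   `cell_type`.
#' @param annotations Tibble: `time_s`, `event_type` with values `egg`,
#'   `ventral_contraction`, `ventral_relaxation`.
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for per-stage CSVs and a
#'   summary JSON.
#' @return List of class `egg_analysis` with one entry per cell type
#'   (`trace`, `transients`, `intervals`, `rhythms`, `phases`,
#'   `phase_histogram`, `aligned`, `egg_summary`) plus `states`, `eggs`,
#'   `landmarks`, `config`, and a `summary` list.
#' @export
run_analyze <- function(traces, annotations, config = analysis_config(),
                        out_dir = NULL) {
  stopifnot(is.data.frame(traces), is.data.frame(annotations))
  if (!"cell_type" %in% names(traces)) traces$cell_type <- "cell"
  if (nrow(annotations)) {
    rng_t <- range(traces$time_s)
    rng_a <- range(annotations$time_s)
    if (rng_a[1] > rng_t[2] || rng_a[2] < rng_t[1]) {
      abort("annotation and trace time ranges are disjoint")
    }
  }
  egg_times <- sort(annotations$time_s[annotations$event_type == "egg"])
  landmarks <- annotations %>%
    dplyr::filter(.data$event_type %in% c("ventral_contraction",
                                          "ventral_relaxation")) %>%
    dplyr::transmute(time_s = .data$time_s,
                     kind = sub("^ventral_", "", .data$event_type)) %>%
    dplyr::arrange(.data$time_s)

  span <- range(traces$time_s)
  states <- define_states(egg_times, span, pad = config$state_pad_s,
                          merge_gap = config$state_merge_gap_s)

  cells <- unique(traces$cell_type)
  per_cell <- purrr::map(setNames(cells, cells), function(ct) {
    tr <- traces %>%
      dplyr::filter(.data$cell_type == ct) %>%
      ratio_trace(cell_type = ct) %>%
      smooth_trace(window_s = config$smooth_window_s) %>%
      compute_baseline(fraction = config$baseline_fraction,
                       use_smoothed = config$baseline_on_smoothed)
    transients <- detect_transients(
      tr, min_prominence_sigmas = config$min_prominence_sigmas,
      min_separation_s = config$min_separation_s) %>%
      normalize_amplitudes() %>%
      assign_states(states) %>%
      egg_coincidence(egg_times)
    transients$phase_deg <- assign_phase(transients$peak_time_s, landmarks)
    intervals <- inter_transient_intervals(transients, states)
    rhythms <- active_state_rhythms(tr, states, band = config$band_mhz,
                                    min_segment_s = config$min_segment_s,
                                    pad_factor = config$pad_factor)
    aligned <- if (length(egg_times)) {
      align_to_eggs(tr, egg_times, window = config$align_window_s,
                    transients = transients)
    }
    list(trace = tr, transients = transients, intervals = intervals,
         rhythms = rhythms,
         phase_histogram = bin_phases(transients$phase_deg,
                                      config$phase_bin_width),
         aligned = aligned,
         egg_summary = attr(transients, "egg_summary"))
  })

  summary <- list(
    n_eggs = length(egg_times),
    n_active_states = sum(states$label == "active"),
    cells = purrr::map(per_cell, function(cc) {
      iv <- cc$intervals
      by_state <- function(st) {
        v <- iv$interval_s[iv$state == st]
        if (!length(v)) return(list(n = 0L))
        list(n = length(v), mean = mean(v), median = median(v),
             q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)))
      }
      list(
        n_transients = nrow(cc$transients),
        intervals = list(active = by_state("active"),
                         inactive = by_state("inactive")),
        egg_coupling = as.list(cc$egg_summary),
        dominant_frequency_mhz = if (nrow(cc$rhythms$peaks)) {
          median(cc$rhythms$peaks$frequency_mhz)
        } else {
          NA_real_
        },
        median_peak_offset_s = if (!is.null(cc$aligned) && cc$aligned$n_events) {
          median(cc$aligned$offsets$peak_offset_s)
        } else {
          NA_real_
        })
    }))

  res <- structure(list(cells = per_cell, states = states,
                        eggs = egg_times, landmarks = landmarks,
                        config = config, summary = summary),
                   class = "egg_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

write_analysis <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(res$states), file.path(dir, "states.csv"))
  for (ct in names(res$cells)) {
    cc <- res$cells[[ct]]
    readr::write_csv(
      dplyr::select(cc$transients, dplyr::any_of(c(
        "peak_time_s", "amplitude", "fwhm_s", "onset_s", "offset_s",
        "normalized_amplitude", "state", "egg_coupled", "phase_deg"))),
      file.path(dir, paste0("transients_", ct, ".csv")))
    readr::write_csv(cc$intervals, file.path(dir, paste0("intervals_", ct, ".csv")))
    if (nrow(cc$rhythms$peaks)) {
      readr::write_csv(cc$rhythms$peaks,
                       file.path(dir, paste0("dominant_peaks_", ct, ".csv")))
    }
    readr::write_csv(cc$phase_histogram,
                     file.path(dir, paste0("phase_histogram_", ct, ".csv")))
  }
  jsonlite::write_json(
    c(res$summary, list(parameters = unclass(res$config))),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.egg_analysis <- function(x, ...) {
  cat("<egg_analysis> ", length(x$cells), " cell type(s), ",
      x$summary$n_eggs, " egg(s), ", x$summary$n_active_states,
      " active state(s)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Compare transient statistics between groups
#'
#' Pools transient-level samples (state-resolved inter-transient intervals,
#' normalized amplitudes, half-max widths) per results bundle and compares
#' them across groups: Mann-Whitney for two groups, Kruskal-Wallis followed
#' by Dunn's pairwise z-tests (Bonferroni-adjusted) for more. Medians and
#' quartiles are reported alongside.
#'
#' @param bundles Named list (>= 2) of `egg_analysis` objects.
#' @param cell_type Cell type whose samples are compared.
#' @param metrics Which samples to compare.
#' @return Tibble: `metric`, `state`, `group1`, `group2`, group sizes,
#'   medians, quartiles, `statistic`, `p_value`, `p_adjusted`, `method`,
#'   and `note` for skipped comparisons.
#' @export
run_compare <- function(bundles, cell_type = "hsn",
                        metrics = c("interval", "amplitude", "fwhm")) {
  stopifnot(length(bundles) >= 2L)
  if (is.null(names(bundles)) || any(names(bundles) == "")) {
    names(bundles) <- paste0("group", seq_along(bundles))
  }
  pull_samples <- function(res, metric, state) {
    cc <- res$cells[[cell_type]]
    if (is.null(cc)) return(numeric())
    switch(metric,
      interval = cc$intervals$interval_s[cc$intervals$state == state],
      amplitude = cc$transients$normalized_amplitude[cc$transients$state == state],
      fwhm = cc$transients$fwhm_s[cc$transients$state == state])
  }
  grid <- tidyr::expand_grid(metric = metrics,
                             state = c("active", "inactive"))
  purrr::pmap_dfr(grid, function(metric, state) {
    samples <- purrr::map(bundles, pull_samples, metric = metric,
                          state = state)
    compare_samples(samples, metric = metric, state = state)
  })
}

#' @rdname run_compare
#' @param samples Named list of numeric vectors (one per group).
#' @param metric,state Labels carried into the output.
#' @export
compare_samples <- function(samples, metric = "value", state = NA_character_) {
  qfun <- function(v, p) if (length(v)) unname(quantile(v, p)) else NA_real_
  pairs <- utils::combn(names(samples), 2L, simplify = FALSE)
  empty_groups <- names(samples)[lengths(samples) == 0L]
  out <- purrr::map_dfr(pairs, function(pr) {
    v1 <- samples[[pr[1]]]; v2 <- samples[[pr[2]]]
    base <- tibble::tibble(
      metric = metric, state = state, group1 = pr[1], group2 = pr[2],
      n1 = length(v1), n2 = length(v2),
      median1 = qfun(v1, 0.5), median2 = qfun(v2, 0.5),
      q1_1 = qfun(v1, 0.25), q3_1 = qfun(v1, 0.75),
      q1_2 = qfun(v2, 0.25), q3_2 = qfun(v2, 0.75))
    if (!length(v1) || !length(v2)) {
      return(dplyr::mutate(base, statistic = NA_real_, p_value = NA_real_,
                           p_adjusted = NA_real_, method = NA_character_,
                           note = "skipped: empty sample in a group"))
    }
    if (length(samples) == 2L) {
      wt <- suppressWarnings(wilcox.test(v1, v2))
      dplyr::mutate(base, statistic = unname(wt$statistic),
                    p_value = wt$p.value, p_adjusted = wt$p.value,
                    method = "Mann-Whitney", note = NA_character_)
    } else {
      dplyr::mutate(base, statistic = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, method = "Dunn",
                    note = NA_character_)
    }
  })
  if (length(samples) > 2L && length(empty_groups) < length(samples) - 1L) {
    keep <- samples[lengths(samples) > 0L]
    if (length(keep) >= 2L) {
      kw <- kruskal.test(keep)
      dn <- dunn_test(keep)
      for (i in seq_len(nrow(dn))) {
        j <- which(out$group1 == dn$group1[i] & out$group2 == dn$group2[i])
        out$statistic[j] <- dn$z[i]
        out$p_value[j] <- dn$p_value[i]
        out$p_adjusted[j] <- dn$p_adjusted[i]
        out$method[j] <- "Kruskal-Wallis + Dunn (Bonferroni)"
      }
      attr(out, "kruskal_wallis") <- list(statistic = unname(kw$statistic),
                                          p_value = kw$p.value)
    }
  }
  out
}

#' Dunn's pairwise z-tests on mean ranks
#'
#' Post-hoc comparison after Kruskal-Wallis: for groups i and j,
#' `z = (Ri - Rj) / sqrt((N (N + 1) / 12 - T) (1/ni + 1/nj))` with the
#' standard tie correction `T = sum(t^3 - t) / (12 (N - 1))`, two-sided
#' p-values Bonferroni-adjusted over all pairs.
#'
#' @param samples Named list of numeric vectors.
#' @return Tibble: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(samples) {
  g <- rep(names(samples), lengths(samples))
  x <- unlist(samples, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(names(samples), 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- (mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]) / se
    tibble::tibble(group1 = pr[1], group2 = pr[2], z = z,
                   p_value = 2 * pnorm(-abs(z)))
  }) %>%
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "bonferroni"))
}
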