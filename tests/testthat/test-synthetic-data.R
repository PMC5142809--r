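# Synthetic-recording generator: determinism, timeline structure,
# renewal-process statistics, and egg/transient coupling guarantees.

test_that("identical configurations give bit-identical simulations", {
  cfg <- sim_config(duration = 1800, seed = 42)
  a <- simulate_behavior(cfg)
  b <- simulate_behavior(cfg)
  expect_identical(a$states, b$states)
  expect_identical(a$transients, b$transients)
  expect_identical(a$eggs, b$eggs)
  expect_identical(render_traces(a, cells = "hsn"),
                   render_traces(b, cells = "hsn"))
  c2 <- simulate_behavior(sim_config(duration = 1800, seed = 43))
  expect_false(identical(a$eggs$time_s, c2$eggs$time_s))
})

test_that("zero-duration config yields an empty ground truth", {
  truth <- simulate_behavior(sim_config(duration = 0, seed = 1))
  expect_equal(nrow(truth$states), 0)
  expect_equal(nrow(truth$landmarks), 0)
  expect_equal(nrow(truth$eggs), 0)
  expect_equal(nrow(truth$transients), 0)
})

test_that("jitter-free oscillator places alternating landmarks half a period apart", {
  truth <- suppressWarnings(simulate_behavior(sim_config(duration = 60, seed = 1,
                                        bend_period_cv = 0)))
  lm <- truth$landmarks
  expect_equal(sum(lm$kind == "contraction"), 6)
  expect_equal(sum(lm$kind == "relaxation"), 6)
  expect_true(all(lm$kind[-1] != lm$kind[-nrow(lm)]))
  expect_equal(diff(lm$time_s), rep(5, 11))
})

test_that("long-run fraction of time active matches the renewal-process value", {
  # alternating exponential states: long-run active fraction is
  # active_mean / (active_mean + inactive_mean)
  fracs <- vapply(1:200, function(i) {
    st <- withr::with_seed(1000 + i,
      eggcircuit:::sim_state_timeline(1e5, 1200, 120))
    sum((st$end_s - st$start_s)[st$label == "active"]) / 1e5
  }, numeric(1))
  expect_equal(mean(fracs), 120 / 1320, tolerance = 0.05)
})

test_that("landmarks stay monotone and alternating across random configs", {
  for (s in 1:10) {
    truth <- suppressWarnings(
      simulate_behavior(sim_config(duration = 600, seed = s,
                                   bend_period_cv = 0.3)))
    lm <- truth$landmarks
    expect_true(all(diff(lm$time_s) > 0))
    expect_true(all(lm$kind[-1] != lm$kind[-nrow(lm)]))
  }
})

test_that("state intervals tile the recording and eggs lie in active states", {
  for (s in 1:5) {
    truth <- simulate_behavior(sim_config(duration = 6600, seed = s,
                                          inactive_mean = 400))
    st <- truth$states
    expect_equal(st$start_s[1], 0)
    expect_equal(st$end_s[nrow(st)], truth$duration)
    expect_equal(st$start_s[-1], st$end_s[-nrow(st)])
    expect_equal(sum(st$end_s - st$start_s), truth$duration)
    act <- st[st$label == "active", ]
    for (te in truth$eggs$time_s) {
      expect_true(any(te >= act$start_s & te < act$end_s))
    }
  }
})

test_that("every egg lies inside an HSN transient span; uv1 and vm are coupled", {
  truth <- wildtype_fixture()$truth
  hsn <- dplyr::filter(truth$transients, cell_type == "hsn")
  covered <- vapply(truth$eggs$time_s, function(te) {
    any(abs(hsn$peak_time_s - te) <= hsn$fwhm_s / 2)
  }, logical(1))
  expect_true(all(covered))
  uv1 <- dplyr::filter(truth$transients, cell_type == "uv1")
  expect_equal(nrow(uv1), nrow(truth$eggs))
  expect_true(all(uv1$egg_coupled))
  vm <- dplyr::filter(truth$transients, cell_type == "vm")
  expect_equal(sum(vm$egg_coupled), nrow(truth$eggs))
  # egg-laying vm transients carry the configured amplitude factor
  expect_gt(median(vm$amplitude[vm$egg_coupled]) /
              median(vm$amplitude[!vm$egg_coupled]), 3)
})

test_that("zero egg rate produces no eggs and no uv1 transients", {
  truth <- simulate_behavior(sim_config(duration = 3600, seed = 2,
                                        egg_rate_active = 0))
  expect_equal(nrow(truth$eggs), 0)
  expect_equal(sum(truth$transients$cell_type == "uv1"), 0)
})

test_that("ground-truth inter-transient intervals converge to configured means", {
  truth <- wildtype_fixture()$truth
  cfg <- wildtype_fixture()$config
  act <- dplyr::filter(truth$states, label == "active")
  within_active <- function(cell) {
    tr <- dplyr::filter(truth$transients, cell_type == cell)
    unlist(lapply(seq_len(nrow(act)), function(i) {
      pk <- tr$peak_time_s[tr$peak_time_s >= act$start_s[i] &
                             tr$peak_time_s < act$end_s[i]]
      diff(pk)
    }))
  }
  iv_hsn <- within_active("hsn")
  expect_gte(length(iv_hsn), 300)
  expect_equal(mean(iv_hsn), expected_active_interval(cfg, "hsn"),
               tolerance = 0.05)
  iv_vm <- within_active("vm")
  expect_gte(length(iv_vm), 500)
  expect_equal(mean(iv_vm), expected_active_interval(cfg, "vm"),
               tolerance = 0.05)
  # quiet-epoch HSN train is a renewal process at the configured mean
  inact <- dplyr::filter(truth$states, label == "inactive")
  hsn <- dplyr::filter(truth$transients, cell_type == "hsn")
  iv_quiet <- unlist(lapply(seq_len(nrow(inact)), function(i) {
    lo <- inact$start_s[i] + cfg$burst_tail
    hi <- inact$end_s[i] - cfg$burst_lead
    if (hi <= lo) return(numeric())
    diff(hsn$peak_time_s[hsn$peak_time_s >= lo & hsn$peak_time_s < hi])
  }))
  expect_gte(length(iv_quiet), 300)
  expect_equal(mean(iv_quiet), cfg$cells$hsn$inactive_interval_mean,
               tolerance = 0.05)
})

test_that("short recordings fall back to a single state with a warning", {
  expect_warning(simulate_behavior(sim_config(duration = 5, seed = 7)),
                 "shorter than a single behavior state")
})
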