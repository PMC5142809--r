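# Body-bend phase assignment, landmark detection, circular histograms,
# and uniformity testing.

test_that("the landmark-interpolation rule reproduces both worked poses", {
  lm1 <- tibble::tibble(time_s = c(0, 4),
                        kind = c("relaxation", "contraction"))
  expect_equal(assign_phase(2, lm1), 270)

  lm2 <- tibble::tibble(time_s = c(0, 4),
                        kind = c("contraction", "relaxation"))
  expect_equal(assign_phase(2, lm2), 90)

  # endpoint poses
  lm3 <- tibble::tibble(time_s = c(0, 4, 8),
                        kind = c("contraction", "relaxation", "contraction"))
  expect_equal(assign_phase(4, lm3), 180)
  expect_equal(assign_phase(0, lm3), 0)
  expect_equal(assign_phase(8, lm3), 0)    # 360 represented as 0
  expect_true(is.na(assign_phase(9, lm3)))
  expect_true(is.na(assign_phase(-1, lm3)))
})

test_that("phase is invariant to translation and uniform rescaling", {
  withr::local_seed(6)
  for (i in 1:10) {
    times <- cumsum(runif(8, 2, 8))
    lm <- tibble::tibble(time_s = times,
                         kind = rep(c("contraction", "relaxation"), 4))
    peaks <- runif(5, min(times), max(times))
    base <- assign_phase(peaks, lm)
    shift <- runif(1, -50, 50)
    scale <- runif(1, 0.2, 5)
    lm2 <- dplyr::mutate(lm, time_s = (time_s + shift) * scale)
    expect_equal(assign_phase((peaks + shift) * scale, lm2), base,
                 tolerance = 1e-9)
  }
})

test_that("phase is monotone in peak time between two fixed landmarks", {
  lm <- tibble::tibble(time_s = c(0, 7), kind = c("relaxation", "contraction"))
  ph <- assign_phase(seq(0.1, 6.9, by = 0.2), lm)
  expect_true(all(diff(ph) > 0))
})

test_that("landmarks recovered from a sinusoidal bend signal sit at the extrema", {
  t <- seq(0, 60 - 0.05, by = 0.05)
  lm <- find_bend_landmarks(sin(2 * pi * t / 10), frame_rate = 20)
  contr <- lm$time_s[lm$kind == "contraction"]
  relax <- lm$time_s[lm$kind == "relaxation"]
  expect_equal(contr, seq(2.5, 52.5, by = 10), tolerance = 0.03)
  expect_equal(relax, seq(7.5, 57.5, by = 10), tolerance = 0.03)
  expect_true(all(lm$kind[-1] != lm$kind[-nrow(lm)]))

  expect_equal(nrow(find_bend_landmarks(rep(1, 100))), 0)
})

test_that("landmark recovery from a rendered bend signal matches ground truth", {
  fx <- wildtype_fixture()
  lm_true <- fx$truth$landmarks
  t <- seq(0, 600 - 0.05, by = 0.05)
  # render a bend signal from the jittered ground-truth landmarks:
  # cosine interpolation peaking at contractions
  ph <- assign_phase(t, lm_true)
  sig <- cos(ph * pi / 180)
  ok <- !is.na(ph)
  lm_rec <- find_bend_landmarks(tibble::tibble(time_s = t[ok],
                                               value = sig[ok]))
  matched <- vapply(lm_rec$time_s, function(x) {
    min(abs(lm_true$time_s - x))
  }, numeric(1))
  expect_lt(median(matched), 0.05 + 1e-9)  # one sample at 20 fps
})

test_that("phase histogram uses half-open 45-degree bins summing to 100%", {
  h <- bin_phases(c(0, 44.99, 45, 225, 359.9))
  expect_equal(nrow(h), 8)
  expect_equal(sum(h$percent), 100)
  expect_equal(h$n[h$bin_start == 0], 2)
  expect_equal(h$n[h$bin_start == 45], 1)
  expect_equal(h$n[h$bin_start == 225], 1)
  expect_equal(h$n[h$bin_start == 315], 1)

  all225 <- bin_phases(rep(225, 40))
  expect_equal(all225$percent[all225$bin_start == 225], 100)

  empty <- bin_phases(numeric())
  expect_equal(empty$percent, rep(0, 8))
})

test_that("uniform phases approach 12.5% per bin", {
  withr::local_seed(10)
  h <- bin_phases(runif(1e5, 0, 360))
  expect_true(all(abs(h$percent - 12.5) < 0.5))
})

test_that("simulated vm twitches concentrate at their configured phase", {
  fx <- wildtype_fixture()
  det <- fx$res$cells$vm$transients
  ph <- det$phase_deg[!det$egg_coupled & !is.na(det$phase_deg) &
                        det$state == "active"]
  h <- bin_phases(ph)
  modal <- h$bin_start[which.max(h$n)]
  mu <- fx$config$cells$vm$phase_mu
  # modal bin contains or borders the configured preferred phase
  expect_lte(min(abs(c(modal - mu, modal + 45 - mu))), 45)
  # the two bins flanking the preferred phase dominate
  near <- h$percent[h$bin_start %in% c(225, 270)]
  expect_gt(sum(near), 60)
})

test_that("round trip from drawn phases through event times returns the phases", {
  withr::local_seed(12)
  lm <- tibble::tibble(time_s = cumsum(runif(40, 3, 7)),
                       kind = rep(c("contraction", "relaxation"), 20))
  contr <- lm$time_s[lm$kind == "contraction"]
  phases <- as.numeric(eggcircuit:::rvonmises_deg(30, 270, 4))
  cyc <- sample(length(contr) - 1, 30, replace = TRUE)
  times <- vapply(seq_len(30), function(i) {
    c1 <- contr[cyc[i]]; c2 <- contr[cyc[i] + 1]
    r <- lm$time_s[lm$kind == "relaxation" & lm$time_s > c1 & lm$time_s < c2]
    eggcircuit:::time_at_phase(phases[i], c1, r, c2)
  }, numeric(1))
  back <- assign_phase(times, lm)
  expect_equal(back, phases %% 360, tolerance = 1e-6)
})

test_that("the binned uniformity construction is valid though conservative", {
  # size: the rank test's discreteness makes it conservative, never
  # anti-conservative
  withr::local_seed(14)
  p_null <- vapply(1:200, function(i) {
    suppressWarnings(phase_uniformity_test(runif(60, 0, 360)))$p_value
  }, numeric(1))
  expect_lte(mean(p_null <= 0.05), 0.05)
  # a fully concentrated sample is always flagged at the 5% level
  p_delta <- vapply(1:100, function(i) {
    suppressWarnings(phase_uniformity_test(rep(225, 50)))$p_value
  }, numeric(1))
  expect_true(all(p_delta < 0.05))
  expect_error(phase_uniformity_test(numeric()), "at least 8")
})

test_that("the Rayleigh addition is calibrated and powerful", {
  withr::local_seed(15)
  p_null <- vapply(1:500, function(i) {
    suppressWarnings(phase_uniformity_test(runif(50, 0, 360)))$rayleigh_p
  }, numeric(1))
  size <- mean(p_null <= 0.05)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_lt(abs(size - 0.05), ci + 0.01)
  conc <- suppressWarnings(
    phase_uniformity_test(eggcircuit:::rvonmises_deg(50, 100, 3)))
  expect_lt(conc$rayleigh_p, 1e-4)
})
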