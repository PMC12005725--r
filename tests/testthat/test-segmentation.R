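# Trajectory segmentation: each operation against an independent oracle,
# then pipeline-level properties on simulated data.

test_that("rolling 2D s.d. matches a brute-force window loop", {
  ## constant trajectory: identically zero on defined frames
  tr0 <- traj2d(rep(3, 100), rep(-2, 100), 1000)
  s0 <- compute_rolling_sd(tr0, 20)
  expect_true(all(is.na(s0[c(1:20, 81:100)])))
  expect_true(all(s0[21:80] == 0))

  ## random data: independent brute-force variance per window
  traj <- withr::with_seed(11, traj2d(rnorm(500, 0, 6), rnorm(500, 1, 3), 1000))
  hw <- 20
  got <- compute_rolling_sd(traj, hw)
  brute <- rep(NA_real_, 500)
  for (i in (hw + 1):(500 - hw)) {
    w <- (i - hw):(i + hw)
    brute[i] <- sqrt(var(traj$on_axis[w]) + var(traj$off_axis[w]))
  }
  expect_equal(got, brute, tolerance = 1e-10)

  ## alternating +/- a on-axis, zero off-axis: brute force again (the
  ## sample-variance convention makes the n = 41 window testable)
  a <- 5
  tra <- traj2d(rep(c(a, -a), 250), rep(0, 500), 1000)
  ga <- compute_rolling_sd(tra, hw)
  w <- 1:(2 * hw + 1)
  expect_equal(ga[hw + 1], sqrt(var(tra$on_axis[w])), tolerance = 1e-12)

  ## bound-state stretches of a simulation: modal s.d. ~ noise_bound * sqrt(2)
  sim <- simulate_two_state_trajectory(
    traj_sim_params(n_frames = 100000, seed = 12))
  sds <- compute_rolling_sd(sim$traj, 20)
  bound_sd <- sds[!is.na(sds) & sim$truth$labels == "bound"]
  expect_equal(median(bound_sd), 4 * sqrt(2), tolerance = 0.05)

  expect_error(compute_rolling_sd(traj2d(1:10, 1:10, 100), 20), "too short")
})

test_that("noise-floor fit recovers the generating Gaussian and its mode", {
  ## N(5, 1) samples: mu ~ 5, sigma ~ 1, threshold ~ 9 within 5%
  v <- withr::with_seed(13, rnorm(20000, 5, 1))
  nf <- fit_noise_floor(v, seg_params())
  expect_equal(nf$mu, 5, tolerance = 0.05)
  expect_equal(nf$sigma, 1, tolerance = 0.05)
  expect_equal(nf$threshold, 9, tolerance = 0.05)
  expect_false(nf$degenerate)

  ## degenerate histogram
  expect_warning(nfd <- fit_noise_floor(rep(5, 2000), seg_params()),
                 "degenerate")
  expect_identical(nfd[c("mu", "sigma", "threshold")],
                   list(mu = 5, sigma = 0, threshold = 5))
  expect_true(nfd$degenerate)

  ## bimodal s.d. from a mostly-bound simulation: mu tracks the bound mode
  ## (known simulator noise), not the global mean
  sim <- simulate_two_state_trajectory(
    traj_sim_params(n_frames = 200000, seed = 14))
  sds <- compute_rolling_sd(sim$traj, 20)
  nfb <- fit_noise_floor(sds, seg_params())
  expect_equal(nfb$mu, 4 * sqrt(2), tolerance = 0.05)
  expect_lt(nfb$mu, mean(sds, na.rm = TRUE))

  expect_error(fit_noise_floor(rnorm(100), seg_params()), ">= 1000")
})

test_that("hysteresis transition detection follows the persistence rule", {
  floor <- list(threshold = 5)
  ## always below threshold: no transitions, machine starts bound
  t1 <- detect_transitions(rep(1, 200), floor, 10)
  expect_identical(nrow(t1), 0L)
  expect_identical(attr(t1, "initial_state"), "bound")

  ## square excursion of 15 frames: exactly one unbound dwell at the
  ## designed frames (hand-traced state machine)
  sd2 <- rep(1, 200); sd2[101:115] <- 9
  t2 <- detect_transitions(sd2, floor, 10)
  expect_identical(t2$frame, c(100L, 115L))
  expect_identical(t2$direction, c("bound_to_unbound", "unbound_to_bound"))

  ## 9-frame excursion with persistence 10: nothing
  sd3 <- rep(1, 200); sd3[101:109] <- 9
  expect_identical(nrow(detect_transitions(sd3, floor, 10)), 0L)

  ## NA edges are skipped; frames still absolute
  sd4 <- c(rep(NA, 20), rep(1, 80), rep(9, 20), rep(1, 80), rep(NA, 20))
  t4 <- detect_transitions(sd4, floor, 10)
  expect_identical(t4$frame, c(100L, 120L))
})

test_that("step-fit refinement locates steps and honors the tie-break", {
  ## noiseless step: exact localization from a displaced initial guess
  tr <- make_step_traj(100, 100, mu_right = -8)
  expect_identical(refine_transition_stepfit(tr, 105, 40), 100L)
  expect_identical(refine_transition_stepfit(tr, 95, 40), 100L)

  ## flat signal: tie broken toward the provisional frame
  flat <- traj2d(rep(2, 200), rep(0, 200), 1000)
  expect_identical(refine_transition_stepfit(flat, 90, 40), 90L)

  ## out-of-bounds window is clipped with a warning
  expect_warning(refine_transition_stepfit(tr, 15, 40), "clipped")

  ## Monte Carlo: noisy step recovered within +/-2 frames in >= 95% of 500
  ## seeded replicates
  hits <- withr::with_seed(15, {
    sum(replicate(500, {
      trn <- make_step_traj(100, 100, mu_right = -8, sd_left = 4,
                            sd_right = 4)
      abs(refine_transition_stepfit(trn, 100 + sample(-5:5, 1), 40) - 100) <= 2
    }))
  })
  expect_gte(hits / 500, 0.95)
})

test_that("dwell extraction tiles the labels and flags boundary censoring", {
  ## labels BBBUUB at 1 kHz: hand-counted dwells
  dw <- extract_dwells(c("bound", "bound", "bound", "unbound", "unbound",
                         "bound"), frame_rate = 1000)
  expect_identical(dw$state, c("bound", "unbound", "bound"))
  expect_identical(dw$start_frame, c(0L, 3L, 5L))
  expect_identical(dw$end_frame, c(3L, 5L, 6L))
  expect_equal(dw$duration_s, c(0.003, 0.002, 0.001))
  expect_identical(dw$censored, c(TRUE, FALSE, TRUE))
  ## the dwells tile the labelled region without overlap
  expect_identical(dw$start_frame[-1], dw$end_frame[-nrow(dw)])

  ## single-state trace: one censored dwell
  dw1 <- extract_dwells(rep("bound", 50), frame_rate = 1000)
  expect_identical(nrow(dw1), 1L)
  expect_true(dw1$censored)

  ## edge_undefined frames are excluded from the tiling
  dw2 <- extract_dwells(c("edge_undefined", "bound", "bound", "unbound",
                          "edge_undefined"), frame_rate = 1000)
  expect_identical(dw2$start_frame, c(1L, 3L))
  expect_identical(dw2$end_frame, c(3L, 4L))
})

test_that("composite-unbound merge rule: gap and separation criteria", {
  runs_merge <- data.frame(
    state = c("bound", "unbound", "bound", "unbound", "bound"),
    n = c(100, 20, 30, 20, 100),
    on_mean = c(0, -8, -8, -8, 0))
  mk <- function(runs) {
    rt <- make_runs_traj(runs)
    make_seg(rt$labels, rt$traj, mu = 0.7)
  }
  rt <- make_runs_traj(runs_merge)
  seg <- make_seg(rt$labels, rt$traj, mu = 0.7)
  ## 30 ms gap, displaced intervening bound: merged into one unbound event
  m <- apply_g0_merge_rule(seg, rt$traj, merge_gap = 0.05)
  expect_length(m$merged_groups, 1)
  expect_identical(m$merged_groups[[1]], c(2L, 3L, 4L))
  expect_identical(sum(m$dwells$state == "unbound"), 1L)
  expect_identical(m$dwells$start_frame[m$dwells$state == "unbound"], 100L)
  expect_identical(m$dwells$end_frame[m$dwells$state == "unbound"], 170L)

  ## 80 ms gap: not merged
  runs_gap <- runs_merge; runs_gap$n[3] <- 80
  rtg <- make_runs_traj(runs_gap)
  mg <- apply_g0_merge_rule(make_seg(rtg$labels, rtg$traj, mu = 0.7),
                            rtg$traj, merge_gap = 0.05)
  expect_length(mg$merged_groups, 0)
  expect_identical(sum(mg$dwells$state == "unbound"), 2L)

  ## intervening bound at the flank position: not merged
  runs_same <- runs_merge; runs_same$on_mean[3] <- 0
  rts <- make_runs_traj(runs_same)
  ms <- apply_g0_merge_rule(make_seg(rts$labels, rts$traj, mu = 0.7),
                            rts$traj, merge_gap = 0.05)
  expect_length(ms$merged_groups, 0)
})

test_that("detachment-origin classification uses the on-axis displacement", {
  mkseg <- function(u_mean) {
    runs <- data.frame(state = c("bound", "unbound", "bound"),
                       n = c(100, 50, 100), on_mean = c(0, u_mean, 0))
    rt <- make_runs_traj(runs)
    list(seg = make_seg(rt$labels, rt$traj), traj = rt$traj)
  }
  b <- mkseg(-8)
  expect_identical(classify_detachment_origin(b$traj, b$seg), "leading")
  f <- mkseg(8)
  expect_identical(classify_detachment_origin(f$traj, f$seg), "trailing")
  a <- mkseg(0)
  expect_identical(classify_detachment_origin(a$traj, a$seg), "ambiguous")

  ## unbound dwell without a preceding bound dwell: undefined
  runs <- data.frame(state = c("unbound", "bound"), n = c(50, 100),
                     on_mean = c(-8, 0))
  rt <- make_runs_traj(runs)
  expect_true(is.na(classify_detachment_origin(rt$traj,
                                               make_seg(rt$labels, rt$traj))))
})

test_that("median filter: robustness, ramps, and per-dwell application", {
  cst <- traj2d(rep(4, 200), rep(-1, 200), 1000)
  expect_equal(median_filter_trace(cst, 51)$on_axis, rep(4, 200))

  ## single-frame outlier removed
  sp <- traj2d(c(rep(0, 100), 100, rep(0, 99)), rep(0, 200), 1000)
  expect_equal(median_filter_trace(sp, 51)$on_axis, rep(0, 200))

  ## ramp preserved: brute-force median per window oracle
  rmp <- traj2d(seq_len(200), rep(0, 200), 1000)
  sm <- median_filter_trace(rmp, 11)$on_axis
  brute <- vapply(6:195, function(i) median(rmp$on_axis[(i - 5):(i + 5)]),
                  numeric(1))
  expect_equal(sm[6:195], brute)

  expect_error(median_filter_trace(cst, 50), "odd")
})

test_that("pipeline properties: label agreement, idempotence, monotonicity", {
  sim <- simulate_two_state_trajectory(
    traj_sim_params(n_frames = 300000L, seed = 16))
  seg <- segment_trajectory(sim$traj)

  ## frame-level agreement with ground truth >= 97% where defined
  est <- as.character(seg$labels)
  tru <- as.character(sim$truth$labels)
  def <- est != "edge_undefined"
  expect_gte(mean(est[def] == tru[def]), 0.97)

  ## >= 90% of detected unbound dwells labelled leading (offset -8 nm)
  org <- seg$dwells$origin[seg$dwells$state == "unbound"]
  expect_gte(mean(org == "leading", na.rm = TRUE), 0.90)

  ## determinism / idempotence: segmenting the same trajectory twice gives
  ## identical labels (also via a write/read round trip)
  seg2 <- segment_trajectory(sim$traj)
  expect_identical(seg$labels, seg2$labels)
  tf <- tempfile(fileext = ".csv")
  write_trajectory_csv(sim$traj, tf)
  seg3 <- segment_trajectory(read_trajectory_csv(tf))
  expect_identical(seg$labels, seg3$labels)
  unlink(tf)

  ## threshold monotonicity: raising the multiplier never increases the
  ## number of detected unbound dwells
  counts <- vapply(c(3, 4, 5, 6), function(k)
    sum(segment_trajectory(sim$traj,
                           seg_params(threshold_multiplier = k)
                           )$dwells$state == "unbound"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})
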