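# Simulators: determinism, limiting cases, and distributional ground truth.

test_that("all simulators are bit-identical under a fixed seed", {
  sc <- scheme_params(5, 0.5, 0.5, ligand_conc = 1)
  runs <- list(
    function() simulate_two_state_trajectory(
      traj_sim_params(n_frames = 2000, seed = 42)),
    function() simulate_fret_trace(
      fret_sim_params(sc, frame_interval = 0.05, duration = 20, seed = 42)),
    function() simulate_stopped_flow_transient(
      sc, list(baseline = 0, amplitude = 1), seq(0, 1, by = 0.01),
      noise_sd = 0.01, seed = 42),
    function() simulate_bound_dwells_mm(
      mm_dwell_sim_params(6.3, 43, c(10, 100), 50, seed = 42)),
    function() simulate_gfp_dwells(2.3, 0.01, 50, seed = 42))
  for (f in runs) expect_identical(f(), f())
  ## seeding does not disturb the caller's RNG stream
  set.seed(7); before <- .Random.seed
  simulate_gfp_dwells(1, 0.01, 10, seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("two-state trajectory: absorbing, zero-noise and dwell statistics", {
  ## absorbing bound state (rate 0): every frame bound, no transitions
  sim <- simulate_two_state_trajectory(
    traj_sim_params(mean_bound_dwell = Inf, n_frames = 1000, seed = 1))
  expect_true(all(sim$truth$labels == "bound"))
  expect_identical(nrow(sim$truth$dwells), 1L)

  ## zero noise: on-axis trace is a two-level square wave of the state means
  p0 <- traj_sim_params(frame_rate = 1000, mean_bound_dwell = 0.05,
                        mean_unbound_dwell = 0.05, noise_bound = 0,
                        noise_unbound = 1e-12, n_frames = 5000, seed = 2)
  sim0 <- simulate_two_state_trajectory(p0)
  expect_equal(unname(sim0$traj$on_axis),
               ifelse(sim0$truth$labels == "unbound", -8, 0),
               tolerance = 1e-6)
  expect_gt(sum(sim0$truth$labels == "unbound"), 0)

  ## law of large numbers on the exponential draws (oracle: sample mean of
  ## the drawn dwells before discretization)
  sim <- simulate_two_state_trajectory(
    traj_sim_params(n_frames = 400000L, seed = 3))
  dw <- sim$truth$dwells
  bd <- dw$duration_draw_s[dw$state == "bound" & !dw$censored]
  expect_gt(length(bd), 80)
  expect_lt(abs(mean(bd) - 0.160), 2 * sd(bd) / sqrt(length(bd)))

  ## invalid parameters
  expect_error(traj_sim_params(mean_bound_dwell = 0), "must be >")
  expect_error(traj_sim_params(frame_rate = -1), "must be >")
  expect_error(traj_sim_params(noise_bound = 5, noise_unbound = 4),
               "noise_unbound")
})

test_that("stopped-flow transient: closed forms and ODE agreement", {
  tg <- seq(0, 0.5, by = 0.001)
  ## irreversible binding: B(t) = 1 - exp(-10 t)
  tr <- simulate_stopped_flow_transient(
    scheme_params(1, 0, 0, ligand_conc = 10),
    list(baseline = 0, amplitude = 1, binding_only = TRUE), tg)
  expect_equal(tr$y, 1 - exp(-10 * tg), tolerance = 1e-12)

  ## t_grid = 0: the initial condition is the baseline
  tr0 <- simulate_stopped_flow_transient(
    scheme_params(5.3, 92, 0, 10),
    list(baseline = 0.7, amplitude = 2, binding_only = TRUE), 0)
  expect_equal(tr0$y, 0.7)

  ## relaxation rate of a generated binding trace equals k+1 [S] + k-1 = 145;
  ## oracle: log-linear regression of the approach to equilibrium
  tg2 <- seq(0, 0.04, by = 1e-4)
  tr2 <- simulate_stopped_flow_transient(
    scheme_params(5.3, 92, 0, ligand_conc = 10),
    list(baseline = 0, amplitude = 1, binding_only = TRUE), tg2)
  Binf <- 10 / (10 + 92 / 5.3)
  slope <- coef(lm(log(Binf - tr2$y[-length(tg2)]) ~ tg2[-length(tg2)]))[[2]]
  expect_equal(-slope, 145, tolerance = 1e-6)

  ## numeric ODE path with k2 = 0 matches the analytic binding_only closed
  ## form to < 1e-6 relative on a 1 ms grid
  tg3 <- seq(0, 0.05, by = 0.001)
  sc <- scheme_params(5.3, 92, 0, 10)
  an <- simulate_stopped_flow_transient(
    sc, list(baseline = 0, amplitude = 1, binding_only = TRUE), tg3)
  od <- simulate_stopped_flow_transient(
    sc, list(baseline = 0, amplitude = 1, binding_only = FALSE), tg3)
  expect_lt(max(abs(an$y - od$y)) / max(abs(an$y)), 1e-6)

  ## full three-state solver against an independent RK4 oracle
  sc3 <- scheme_params(2, 30, 50, ligand_conc = 40)
  od3 <- simulate_stopped_flow_transient(
    sc3, list(baseline = 0, amplitude = 1, binding_only = FALSE), tg3)
  rk4 <- local({
    a <- 2 * 40; b <- 30; cc <- 50
    f <- function(s) c(-a * s[1] + b * s[2], a * s[1] - (b + cc) * s[2])
    s <- c(1, 0); dt <- 1e-5; out <- numeric(length(tg3)); out[1] <- 0
    tcur <- 0
    for (i in 2:length(tg3)) {
      while (tcur < tg3[i] - dt / 2) {
        k1 <- f(s); k2 <- f(s + dt / 2 * k1); k3 <- f(s + dt / 2 * k2)
        k4 <- f(s + dt * k3)
        s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4); tcur <- tcur + dt
      }
      out[i] <- s[2]
    }
    out
  })
  expect_lt(max(abs(od3$y - rk4)) / max(abs(rk4)), 1e-6)

  expect_error(scheme_params(-1, 0), ">= 0")
})

test_that("FRET simulator: exit statistics, competing risks and censoring", {
  ## k2 = 0, no bleaching: binding dwells are exponential with mean 1/k-1
  sc <- scheme_params(5, 5, 0, ligand_conc = 20)   # kon = 100/s, koff = 5/s
  sim <- simulate_fret_trace(
    fret_sim_params(sc, frame_interval = 0.05, duration = 2200, seed = 4))
  d <- sim$events$duration_s[sim$events$end_type == "atp_dissociation"]
  expect_gt(length(d), 9000)
  expect_lt(abs(mean(d) - 1 / 5), 2 * sd(d) / sqrt(length(d)))
  ## Kolmogorov-Smirnov against the intended exponential at alpha = 0.01
  ks <- suppressWarnings(stats::ks.test(d[1:10000], stats::pexp, rate = 5))
  expect_gt(ks$p.value, 0.01)

  ## competing exponentials: P(detachment) = k2/(k2 + k-1) within 3
  ## binomial SE of the ground-truth event types
  sc2 <- scheme_params(5, 0.5, 0.5, ligand_conc = 2)
  types <- character(0)
  for (s in 1:700) {
    ev <- simulate_fret_trace(
      fret_sim_params(sc2, frame_interval = 0.05, duration = 50,
                      seed = s))$events
    types <- c(types, ev$end_type)
  }
  types <- types[types %in% c("atp_dissociation", "detachment")]
  n <- length(types)
  expect_gt(n, 1000)
  phat <- mean(types == "detachment")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))

  ## duration shorter than the first event: one censored event
  sc3 <- scheme_params(5, 1e-4, 0, ligand_conc = 100)
  sim3 <- simulate_fret_trace(
    fret_sim_params(sc3, frame_interval = 0.05, duration = 5, seed = 5))
  expect_identical(nrow(sim3$events), 1L)
  expect_identical(sim3$events$end_type, "censored")

  expect_error(fret_sim_params(sc, frame_interval = 0), "must be >")
  expect_error(fret_sim_params(sc, fret_bound = 0.4, fret_unbound = 0.5),
               "fret_unbound")
})

test_that("MM dwell simulator: hypo-exponential structure and means", {
  ## population mean dwell = Km/(kcat [ATP]) + 1/kcat = 0.165 s at the
  ## stated parameters
  p <- mm_dwell_sim_params(6.3, 43, atp_concs = 1000, n_per_conc = 10000,
                           seed = 6)
  d <- simulate_bound_dwells_mm(p)$dwell_s
  expect_lt(abs(mean(d) - 0.165), 2 * sd(d) / sqrt(length(d)))

  ## KS against the hypo-exponential sum (rates r1 = kcat [S]/Km, r2 = kcat)
  r1 <- 6.3 * 1000 / 43; r2 <- 6.3
  phypo <- function(q) 1 - (r2 * exp(-r1 * q) - r1 * exp(-r2 * q)) / (r2 - r1)
  ks <- suppressWarnings(stats::ks.test(d, phypo))
  expect_gt(ks$p.value, 0.01)

  ## saturating [ATP]: mean dwell -> 1/kcat
  dsat <- simulate_bound_dwells_mm(
    mm_dwell_sim_params(6.3, 43, 1e6, 5000, seed = 7))$dwell_s
  expect_equal(mean(dsat), 1 / 6.3, tolerance = 0.05)

  expect_error(mm_dwell_sim_params(6.3, 43, numeric(0), 10), "atp_concs")
  expect_error(mm_dwell_sim_params(6.3, 43, 100, 0), "n_per_conc")
})

test_that("GFP dwell simulator: discretization and sample mean", {
  ## rate 100/s at 10 ms frames: nearly all dwells are 1-2 frames, excluded
  ## by the more-than-two-frames rule
  g <- simulate_gfp_dwells(100, 0.01, 2000, seed = 8)
  expect_gt(mean(g$n_frames <= 2), 0.8)
  expect_true(all(g$duration_s == g$n_frames * 0.01))

  ## sample mean of the discretized dwells ~ 1/rate (+ ~h/2) within 2 SEM
  g2 <- simulate_gfp_dwells(2.3, 0.01, 2000, seed = 9)
  expect_lt(abs(mean(g2$duration_s) - 1 / 2.3),
            2 * sd(g2$duration_s) / sqrt(2000))

  ## single value reproducible under a fixed seed
  expect_identical(simulate_gfp_dwells(2.3, 0.01, 1, seed = 10),
                   simulate_gfp_dwells(2.3, 0.01, 1, seed = 10))
  expect_error(simulate_gfp_dwells(0, 0.01, 10), "must be >")
})
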