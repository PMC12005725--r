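rel_err <- function(x, ref) abs(x - ref) / abs(ref)

## noiseless or noisy step trajectory: n_left frames at (0, 0), n_right at
## (mu_right, 0), per-side on/off-axis noise
make_step_traj <- function(n_left, n_right, mu_right = -8,
                           sd_left = 0, sd_right = 0,
                           frame_rate = 20000, seed = NULL) {
  gen <- function() {
    on <- c(rnorm(n_left, 0, sd_left), rnorm(n_right, mu_right, sd_right))
    off <- c(rnorm(n_left, 0, sd_left), rnorm(n_right, 0, sd_right))
    traj2d(on, off, frame_rate)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## hand-built state_segmentation from a label vector and trajectory, for
## tests of operations that consume segmentations
make_seg <- function(labels, traj, mu = 5) {
  seg <- structure(list(
    labels = factor(labels, levels = c("bound", "unbound", "edge_undefined")),
    transitions = NULL,
    dwells = NULL,
    noise_floor = structure(list(mu = mu, sigma = mu / 10,
                                 threshold = mu * 1.4, degenerate = FALSE),
                            class = "noise_floor"),
    params = seg_params(),
    merged_groups = list(),
    frame_rate = attr(traj, "frame_rate"),
    frame0 = traj$frame[1L]), class = "state_segmentation")
  seg$dwells <- extract_dwells(seg, traj = traj)
  seg
}

## piecewise-constant trajectory from a run-length spec:
## runs = data.frame(state, n, on_mean); noise per state
make_runs_traj <- function(runs, sd_bound = 0.5, sd_unbound = 1.5,
                           frame_rate = 1000, seed = 1) {
  withr::with_seed(seed, {
    on <- unlist(mapply(function(s, n, m)
      rnorm(n, m, if (s == "bound") sd_bound else sd_unbound),
      runs$state, runs$n, runs$on_mean, SIMPLIFY = FALSE))
    off <- unlist(mapply(function(s, n)
      rnorm(n, 0, if (s == "bound") sd_bound else sd_unbound),
      runs$state, runs$n, SIMPLIFY = FALSE))
    list(traj = traj2d(on, off, frame_rate),
         labels = rep(runs$state, runs$n))
  })
}
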