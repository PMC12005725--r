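## Generative models for all three data modalities.  Each simulator draws its
## randomness through with_seed(), so identical parameters + seed give
## bit-identical output and the caller's RNG stream is untouched.

#' Simulate a two-state gold-probe trajectory
#'
#' Generates alternating microtubule-bound / unbound dwells with exponential
#' durations, discretizes them to the camera frame grid, and emits per-frame
#' 2D positions: state mean plus independent per-axis Gaussian noise.  The
#' trace starts in the bound state.  A frame is assigned the state occupying
#' the scheme at the frame start time, so continuous event times are in
#' effect floored to frame boundaries.
#'
#' @param params a [traj_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{traj}{a [traj2d()] trajectory of `n_frames` frames,}
#'     \item{truth}{ground truth: `labels` (factor `bound`/`unbound` per
#'       frame), `dwells` (one row per dwell: `state`, continuous
#'       `start_s`/`end_s`, `start_frame`/`end_frame` half-open,
#'       `duration_draw_s` = the un-discretized exponential draw, and
#'       `censored` for the boundary dwells), and the parameters.}
#'   }
#' @examples
#' sim <- simulate_two_state_trajectory(
#'   traj_sim_params(n_frames = 5000, seed = 1))
#' table(sim$truth$labels)
#' @export
simulate_two_state_trajectory <- function(params) {
  if (!inherits(params, "traj_sim_params"))
    stop_user("'params' must be a traj_sim_params object")
  p <- params
  n <- p$n_frames
  fps <- p$frame_rate
  duration <- n / fps
  rate_b <- if (is.finite(p$mean_bound_dwell)) 1 / p$mean_bound_dwell else 0
  rate_u <- if (is.finite(p$mean_unbound_dwell)) 1 / p$mean_unbound_dwell else 0

  with_seed(p$seed, {
    ## alternating dwell draws, bound first, until the trace is covered
    states <- character(0)
    draws <- numeric(0)
    tot <- 0
    s <- "bound"
    while (tot < duration) {
      r <- if (s == "bound") rate_b else rate_u
      d <- if (r > 0) rexp(1L, r) else Inf
      states <- c(states, s)
      draws <- c(draws, d)
      tot <- tot + d
      s <- if (s == "bound") "unbound" else "bound"
    }
    start_s <- cumsum(c(0, head(draws, -1L)))
    end_s <- pmin(start_s + draws, duration)

    frame_t <- seq.int(0L, n - 1L) / fps
    idx <- findInterval(frame_t, start_s)   # dwell index per frame
    labels <- factor(states[idx], levels = c("bound", "unbound"))

    cnt <- tabulate(idx, nbins = length(states))
    end_cum <- cumsum(cnt)
    start_frame <- ifelse(cnt > 0L, end_cum - cnt, NA_integer_)
    end_frame <- ifelse(cnt > 0L, end_cum, NA_integer_)

    mu_on <- ifelse(labels == "unbound", p$unbound_on_axis_offset, 0)
    sd_ax <- ifelse(labels == "unbound", p$noise_unbound, p$noise_bound)
    on <- mu_on + rnorm(n) * sd_ax
    off <- rnorm(n) * sd_ax

    dwells <- data.frame(
      state = states,
      start_s = start_s, end_s = end_s,
      start_frame = start_frame, end_frame = end_frame,
      duration_draw_s = draws,
      censored = c(rep(FALSE, length(states) - 1L), TRUE))
    ## the first dwell starts exactly at t = 0, so its draw is fully
    ## observed; only the final dwell is truncated by the trace end
    list(traj = traj2d(on, off, fps),
         truth = list(labels = labels, dwells = dwells, params = p))
  })
}

#' Simulate a stopped-flow transient of the three-step scheme
#'
#' Deterministic occupancy-proportional signal for the scheme
#' `E <-> B -> detached` under pseudo-first-order ligand excess.  In
#' `binding_only` mode (`k2` ignored) the bound fraction follows the closed
#' form `B(t) = S/(S+Kd) * (1 - exp(-(k+1*S + k-1) t))` with
#' `Kd = k-1/k+1`; otherwise the full linear two-compartment system is solved
#' by eigen-decomposition.
#'
#' @param scheme a [scheme_params()] object; `ligand_conc` is the
#'   post-mixing nucleotide concentration (uM).
#' @param signal_model list with elements `baseline`, `amplitude` and logical
#'   `binding_only`; optional `observable` chooses what the signal reports:
#'   `"bound"` (nucleotide occupancy, the mant-ATP fluorescence model) or
#'   `"attached"` (microtubule-attached fraction `E + B`, the turbidity
#'   model).
#' @param t_grid time points (s), strictly increasing from 0.
#' @param noise_sd optional additive Gaussian noise s.d. (a.u.).
#' @param kind trace kind label for the output.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return An [sf_trace()].
#' @examples
#' tr <- simulate_stopped_flow_transient(
#'   scheme_params(5.3, 92, ligand_conc = 10),
#'   list(baseline = 0.1, amplitude = 1, binding_only = TRUE),
#'   t_grid = seq(0, 0.1, by = 1e-4))
#' @export
simulate_stopped_flow_transient <- function(scheme,
                                            signal_model = list(baseline = 0,
                                                                amplitude = 1,
                                                                binding_only = FALSE),
                                            t_grid,
                                            noise_sd = 0,
                                            kind = c("fluorescence", "turbidity"),
                                            seed = NULL) {
  if (!inherits(scheme, "scheme_params"))
    stop_user("'scheme' must be a scheme_params object")
  kind <- match.arg(kind)
  if (!is.numeric(t_grid) || length(t_grid) < 1L || t_grid[1] < 0 ||
      (length(t_grid) > 1 && any(diff(t_grid) <= 0)))
    stop_user("'t_grid' must be non-negative and strictly increasing")
  baseline <- signal_model$baseline %||% 0
  amplitude <- signal_model$amplitude %||% 1
  binding_only <- isTRUE(signal_model$binding_only)
  observable <- signal_model$observable %||% "bound"
  if (!observable %in% c("bound", "attached"))
    stop_user("'observable' must be \"bound\" or \"attached\"")

  S <- scheme$ligand_conc
  a <- scheme$k_plus1 * S      # pseudo-first-order on rate
  b <- scheme$k_minus1
  cc <- if (binding_only) 0 else scheme$k2

  if (binding_only) {
    kobs <- a + b
    Beq <- if (kobs > 0) a / kobs else 0
    B <- Beq * (1 - exp(-kobs * t_grid))
    occ <- if (observable == "bound") B else rep(1, length(t_grid))
  } else {
    ## d/dt (E, B) = M (E, B), E(0)=1, B(0)=0.  Eigenvalues are real for
    ## this rate structure; nudge k2 by 1e-9 relative in the (measure-zero)
    ## defective case of a repeated eigenvalue.
    M <- matrix(c(-a, a, b, -(b + cc)), nrow = 2L)
    eig <- eigen(M)
    if (abs(diff(Re(eig$values))) <
        1e-9 * max(abs(eig$values), .Machine$double.eps)) {
      M <- matrix(c(-a, a, b, -(b + cc * (1 + 1e-9))), nrow = 2L)
      eig <- eigen(M)
    }
    c0 <- solve(eig$vectors, c(1, 0))
    Et <- exp(outer(Re(eig$values), t_grid))
    X <- Re(eig$vectors %*% (c0 * Et))
    occ <- if (observable == "bound") X[2L, ] else X[1L, ] + X[2L, ]
  }
  y <- baseline + amplitude * occ
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(y), sd = noise_sd))
  sf_trace(t_grid, y, kind = kind, ligand_conc = S)
}

## piecewise-constant level -> per-frame time-weighted means over frames of
## width h covering [0, nf*h]
frame_average_piecewise <- function(breaks, levels, h, nf) {
  edges <- seq.int(0L, nf) * h
  cum <- c(0, cumsum(levels * diff(breaks)))
  j <- findInterval(edges, breaks, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(levels))
  I <- cum[j] + levels[j] * (edges - breaks[j])
  diff(I) / h
}

#' Simulate an smFRET nucleotide-binding trace
#'
#' Continuous-time Markov jumps between the empty and ATP-bound states of one
#' head (rates `k_plus1 * ligand_conc` and `k_minus1`) with a competing `k2`
#' detachment exit that terminates the trace by dropping both channels to
#' background.  Donor and acceptor photobleach independently; donor bleaching
#' silences both channels (the acceptor is FRET-sensitized), acceptor
#' bleaching returns the donor to full intensity.  Channel levels are
#' `donor_mean * (1 - E)` and `acceptor_mean * E` for the state efficiency
#' `E`, integrated over each camera frame (time-weighted mean, modelling
#' camera integration) and read out with additive Gaussian noise.
#'
#' @param params a [fret_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{trace}{a [fret_trace()] covering `floor(duration /
#'       frame_interval)` frames,}
#'     \item{events}{ground-truth binding events: continuous `start_s`,
#'       `end_s`, `duration_s` and `end_type` in `atp_dissociation`,
#'       `detachment`, `donor_bleach`, `censored`,}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_fret_trace <- function(params) {
  if (!inherits(params, "fret_sim_params"))
    stop_user("'params' must be a fret_sim_params object")
  p <- params
  sc <- p$scheme
  kon <- sc$k_plus1 * sc$ligand_conc
  koff <- sc$k_minus1
  k2 <- sc$k2
  dur <- p$duration
  h <- p$frame_interval
  nf <- floor(dur / h + 1e-9)
  if (nf < 1L) stop_user("'duration' shorter than one frame")

  with_seed(p$seed, {
    t_db <- if (p$donor_bleach_rate > 0) rexp(1L, p$donor_bleach_rate) else Inf
    t_ab <- if (p$acceptor_bleach_rate > 0) rexp(1L, p$acceptor_bleach_rate) else Inf

    ## state path: start empty; record bound intervals and termination
    sw_t <- numeric(0)   # times entering 'bound' / leaving 'bound'
    ev_start <- numeric(0); ev_end <- numeric(0); ev_type <- character(0)
    t_now <- 0; t_detach <- Inf
    state <- "empty"
    while (t_now < dur && is.finite(t_now)) {
      if (state == "empty") {
        w <- if (kon > 0) rexp(1L, kon) else Inf
        t_now <- t_now + w
        if (t_now >= dur) break
        state <- "bound"
        ev_start <- c(ev_start, t_now)
      } else {
        tot <- koff + k2
        w <- if (tot > 0) rexp(1L, tot) else Inf
        detach <- tot > 0 && runif(1L) < k2 / tot
        t_end <- t_now + w
        if (t_end >= dur) {
          ev_end <- c(ev_end, dur); ev_type <- c(ev_type, "censored")
          t_now <- dur
          break
        }
        ev_end <- c(ev_end, t_end)
        ev_type <- c(ev_type, if (detach) "detachment" else "atp_dissociation")
        t_now <- t_end
        if (detach) { t_detach <- t_end; break }
        state <- "empty"
      }
    }

    ## censor ground-truth events at donor bleach
    if (length(ev_start) > 0 && is.finite(t_db)) {
      keep <- ev_start < t_db
      ev_start <- ev_start[keep]; ev_end <- ev_end[keep]
      ev_type <- ev_type[keep]
      if (length(ev_end) > 0 && ev_end[length(ev_end)] > t_db) {
        ev_end[length(ev_end)] <- t_db
        ev_type[length(ev_type)] <- "donor_bleach"
      }
    }

    ## piecewise-constant channel levels over [0, dur]
    brk <- sort(unique(c(0, ev_start, ev_end, t_db, t_ab, t_detach, dur)))
    brk <- brk[brk >= 0 & brk <= dur]
    if (brk[length(brk)] < dur) brk <- c(brk, dur)
    mid <- (head(brk, -1L) + tail(brk, -1L)) / 2
    ## events are disjoint and sorted, so membership is parity of the
    ## insertion point into the interleaved start/end edges
    isb <- if (length(ev_start) == 0) rep(FALSE, length(mid))
    else findInterval(mid, as.numeric(rbind(ev_start, ev_end))) %% 2L == 1L
    dark <- mid >= t_detach | mid >= t_db
    acc_off <- mid >= t_ab
    E <- ifelse(isb, p$fret_bound, p$fret_unbound)
    E[acc_off] <- 0
    Dlev <- ifelse(dark, 0, p$donor_mean * (1 - E))
    Alev <- ifelse(dark | acc_off, 0, p$acceptor_mean * E)

    D <- frame_average_piecewise(brk, Dlev, h, nf)
    A <- frame_average_piecewise(brk, Alev, h, nf)
    if (p$intensity_sd > 0) {
      D <- D + rnorm(nf, sd = p$intensity_sd)
      A <- A + rnorm(nf, sd = p$intensity_sd)
    }

    events <- data.frame(start_s = ev_start, end_s = ev_end,
                         duration_s = ev_end - ev_start,
                         end_type = ev_type)
    list(trace = fret_trace(t = (seq_len(nf) - 1L) * h, donor = D,
                            acceptor = A, frame_interval = h),
         events = events, params = p)
  })
}

#' Simulate microtubule-bound dwells under the Michaelis--Menten scheme
#'
#' Each dwell is the sum of an exponential ATP-waiting time at rate
#' `(kcat/Km) * [ATP]` and an exponential catalysis/detachment time at rate
#' `kcat`, so the population mean dwell is `Km/(kcat*[ATP]) + 1/kcat` and the
#' inverse mean follows the Michaelis--Menten equation exactly.
#'
#' @param params an [mm_dwell_sim_params()] object.
#' @return A data frame with columns `atp_conc_uM` and `dwell_s`
#'   (`n_per_conc` rows per concentration), with the parameters attached as
#'   attribute `params`.
#' @export
simulate_bound_dwells_mm <- function(params) {
  if (!inherits(params, "mm_dwell_sim_params"))
    stop_user("'params' must be a mm_dwell_sim_params object")
  p <- params
  with_seed(p$seed, {
    out <- do.call(rbind, lapply(p$atp_concs, function(S) {
      k_bind <- (p$kcat / p$Km) * S
      d <- rexp(p$n_per_conc, k_bind) + rexp(p$n_per_conc, p$kcat)
      data.frame(atp_conc_uM = S, dwell_s = d)
    }))
    attr(out, "params") <- p
    out
  })
}

#' Simulate frame-discretized single-fluorophore dwells
#'
#' Exponential dwells snapped up to the camera frame grid (duration = number
#' of frames the spot is visible times the frame interval, i.e. the ceiling
#' of the continuous dwell).  The standard inclusion rule for such data --
#' keep spots that dwell more than two frames -- is applied downstream by the
#' fitting routines via their `min_dwell` argument, not here.
#'
#' @param rate detachment rate (s^-1), > 0.
#' @param frame_interval camera frame interval (s).
#' @param n number of dwells.
#' @param seed RNG seed.
#' @return A data frame with columns `duration_s` (multiple of
#'   `frame_interval`) and `n_frames`.
#' @export
simulate_gfp_dwells <- function(rate, frame_interval = 0.010, n = 1000L,
                                seed = NULL) {
  check_scalar(rate, "rate", min = 0, strict = TRUE)
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  check_scalar(n, "n", min = 1)
  with_seed(seed, {
    d <- rexp(as.integer(n), rate)
    nfr <- pmax(1L, as.integer(ceiling(d / frame_interval - 1e-12)))
    data.frame(duration_s = nfr * frame_interval, n_frames = nfr)
  })
}
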