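#' Kinetic scheme parameters
#'
#' Parameters of the three-step scheme for ATP-promoted detachment of a
#' microtubule-bound kinesin head: reversible ATP binding (`k_plus1`,
#' `k_minus1`) followed by ATP-induced microtubule detachment (`k2`).
#'
#' @param k_plus1 second-order ATP on-rate (uM^-1 s^-1).
#' @param k_minus1 ATP off-rate (s^-1).
#' @param k2 ATP-induced microtubule-detachment rate (s^-1).
#' @param ligand_conc nucleotide concentration (uM).
#' @return An object of class `scheme_params`.
#' @examples
#' scheme_params(k_plus1 = 5.3, k_minus1 = 92, k2 = 0, ligand_conc = 10)
#' @export
scheme_params <- function(k_plus1, k_minus1, k2 = 0, ligand_conc = 0) {
  check_scalar(k_plus1, "k_plus1", min = 0)
  check_scalar(k_minus1, "k_minus1", min = 0)
  check_scalar(k2, "k2", min = 0)
  check_scalar(ligand_conc, "ligand_conc", min = 0)
  structure(list(k_plus1 = k_plus1, k_minus1 = k_minus1, k2 = k2,
                 ligand_conc = ligand_conc),
            class = "scheme_params")
}

#' Parameters for the two-state gold-probe trajectory simulator
#'
#' The stated world of the simulator mirrors the high-speed dark-field
#' acquisition: 20,000 frames/s, a microtubule-bound state with small
#' positional noise and a transiently detached (unbound) state with larger
#' noise whose mean on-axis position sits backward of the bound position.
#' Dwells in each state are exponential.
#'
#' The defaults for the noise amplitudes and the unbound offset are package
#' choices (4 nm bound, 12 nm unbound per axis, -8 nm offset): the ratio
#' `noise_unbound > noise_bound` is the contrast that the rolling-s.d.
#' segmenter relies on, and 3x noise with a near-step-size backward offset
#' makes the mu+4*sigma threshold comfortably detectable at the default
#' +/-20-frame window.
#'
#' @param frame_rate frames per second (Hz).
#' @param mean_bound_dwell mean bound dwell (s); `Inf` gives an absorbing
#'   bound state (rate 0).
#' @param mean_unbound_dwell mean unbound dwell (s); `Inf` allowed as above.
#' @param noise_bound per-axis positional s.d. in the bound state (nm).
#' @param noise_unbound per-axis positional s.d. in the unbound state (nm);
#'   must exceed `noise_bound`.
#' @param unbound_on_axis_offset mean on-axis displacement of the unbound
#'   state relative to bound (nm; negative = toward the minus end).
#' @param n_frames number of frames to simulate.
#' @param seed RNG seed.
#' @return An object of class `traj_sim_params`.
#' @export
traj_sim_params <- function(frame_rate = 20000,
                            mean_bound_dwell = 0.160,
                            mean_unbound_dwell = 0.011,
                            noise_bound = 4,
                            noise_unbound = 12,
                            unbound_on_axis_offset = -8,
                            n_frames = 200000L,
                            seed = NULL) {
  check_scalar(frame_rate, "frame_rate", min = 0, strict = TRUE)
  check_scalar(mean_bound_dwell, "mean_bound_dwell", min = 0, strict = TRUE,
               allow_inf = TRUE)
  check_scalar(mean_unbound_dwell, "mean_unbound_dwell", min = 0,
               strict = TRUE, allow_inf = TRUE)
  check_scalar(noise_bound, "noise_bound", min = 0)
  check_scalar(noise_unbound, "noise_unbound", min = 0)
  check_scalar(unbound_on_axis_offset, "unbound_on_axis_offset")
  check_scalar(n_frames, "n_frames", min = 2)
  if (noise_unbound <= noise_bound)
    stop_user("'noise_unbound' must exceed 'noise_bound' (detection contrast)")
  structure(list(frame_rate = frame_rate,
                 mean_bound_dwell = mean_bound_dwell,
                 mean_unbound_dwell = mean_unbound_dwell,
                 noise_bound = noise_bound,
                 noise_unbound = noise_unbound,
                 unbound_on_axis_offset = unbound_on_axis_offset,
                 n_frames = as.integer(n_frames),
                 seed = seed),
            class = "traj_sim_params")
}

#' Parameters for the smFRET trace simulator
#'
#' @param scheme a [scheme_params()] object; `ligand_conc` sets the
#'   pseudo-first-order binding rate `k_plus1 * ligand_conc`.
#' @param frame_interval camera exposure (s).
#' @param donor_mean,acceptor_mean full-scale channel intensities (a.u.): the
#'   donor emits `donor_mean * (1 - E)` and the acceptor `acceptor_mean * E`
#'   at FRET efficiency `E`.
#' @param intensity_sd per-frame Gaussian intensity noise (a.u.).
#' @param fret_bound true efficiency of the nucleotide-bound state.
#' @param fret_unbound efficiency of the empty (apo) state;
#'   `0 <= fret_unbound < fret_bound <= 1`.
#' @param donor_bleach_rate,acceptor_bleach_rate photobleaching rates (s^-1).
#' @param duration trace length (s).
#' @param seed RNG seed.
#' @return An object of class `fret_sim_params`.
#' @export
fret_sim_params <- function(scheme,
                            frame_interval = 0.2,
                            donor_mean = 1000,
                            acceptor_mean = 1000,
                            intensity_sd = 60,
                            fret_bound = 0.9,
                            fret_unbound = 0.05,
                            donor_bleach_rate = 0,
                            acceptor_bleach_rate = 0,
                            duration = 100,
                            seed = NULL) {
  if (!inherits(scheme, "scheme_params"))
    stop_user("'scheme' must be a scheme_params object")
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  check_scalar(donor_mean, "donor_mean", min = 0)
  check_scalar(acceptor_mean, "acceptor_mean", min = 0)
  check_scalar(intensity_sd, "intensity_sd", min = 0)
  check_scalar(fret_bound, "fret_bound", min = 0)
  check_scalar(fret_unbound, "fret_unbound", min = 0)
  check_scalar(donor_bleach_rate, "donor_bleach_rate", min = 0)
  check_scalar(acceptor_bleach_rate, "acceptor_bleach_rate", min = 0)
  check_scalar(duration, "duration", min = 0, strict = TRUE)
  if (!(fret_unbound < fret_bound && fret_bound <= 1))
    stop_user("need 0 <= fret_unbound < fret_bound <= 1")
  structure(list(scheme = scheme, frame_interval = frame_interval,
                 donor_mean = donor_mean, acceptor_mean = acceptor_mean,
                 intensity_sd = intensity_sd, fret_bound = fret_bound,
                 fret_unbound = fret_unbound,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 duration = duration, seed = seed),
            class = "fret_sim_params")
}

#' Parameters for the Michaelis--Menten bound-dwell simulator
#'
#' @param kcat maximal detachment rate (s^-1).
#' @param Km Michaelis constant for ATP (uM).
#' @param atp_concs ATP concentrations (uM), one dwell set per value.
#' @param n_per_conc dwells per concentration.
#' @param seed RNG seed.
#' @return An object of class `mm_dwell_sim_params`.
#' @export
mm_dwell_sim_params <- function(kcat, Km, atp_concs, n_per_conc = 1000L,
                                seed = NULL) {
  check_scalar(kcat, "kcat", min = 0, strict = TRUE)
  check_scalar(Km, "Km", min = 0, strict = TRUE)
  if (!is.numeric(atp_concs) || length(atp_concs) < 1L ||
      any(!is.finite(atp_concs)) || any(atp_concs <= 0))
    stop_user("'atp_concs' must be a non-empty vector of positive ",
              "concentrations (uM)")
  check_scalar(n_per_conc, "n_per_conc", min = 1)
  structure(list(kcat = kcat, Km = Km, atp_concs = as.numeric(atp_concs),
                 n_per_conc = as.integer(n_per_conc), seed = seed),
            class = "mm_dwell_sim_params")
}

#' Construct a 2D gold-probe trajectory
#'
#' A `traj2d` is a data frame with columns `frame` (0-based integer), `t`
#' (s), `on_axis` (nm, positive toward the microtubule plus end) and
#' `off_axis` (nm), with the acquisition rate stored in the `frame_rate`
#' attribute.  Frames must be consecutive and `t` must equal
#' `frame / frame_rate`.
#'
#' @param on_axis,off_axis position series (nm).
#' @param frame_rate frames per second (Hz).
#' @param frame0 index of the first frame (default 0).
#' @return A data frame of class `traj2d`.
#' @export
traj2d <- function(on_axis, off_axis, frame_rate, frame0 = 0L) {
  check_scalar(frame_rate, "frame_rate", min = 0, strict = TRUE)
  n <- length(on_axis)
  if (length(off_axis) != n)
    stop_user("'on_axis' and 'off_axis' must have equal length")
  if (any(!is.finite(on_axis)) || any(!is.finite(off_axis)))
    stop_user("trajectory coordinates must be finite")
  frame <- seq.int(frame0, length.out = n)
  out <- data.frame(frame = frame, t = frame / frame_rate,
                    on_axis = as.numeric(on_axis),
                    off_axis = as.numeric(off_axis))
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("traj2d", "data.frame")
  out
}

#' Frame rate of a trajectory
#' @param traj a [traj2d()] object.
#' @return Frames per second (Hz).
#' @export
frame_rate <- function(traj) {
  fr <- attr(traj, "frame_rate")
  if (is.null(fr)) stop_user("object has no 'frame_rate' attribute")
  fr
}

#' Construct a stopped-flow trace
#'
#' @param t time from mixing (s), non-negative and increasing.
#' @param y signal (a.u.).
#' @param kind `"fluorescence"` or `"turbidity"`.
#' @param ligand_conc nucleotide concentration after mixing (uM).
#' @return A data frame of class `sf_trace` with attributes `kind` and
#'   `ligand_conc`.
#' @export
sf_trace <- function(t, y, kind = c("fluorescence", "turbidity"),
                     ligand_conc = NA_real_) {
  kind <- match.arg(kind)
  if (length(t) != length(y)) stop_user("'t' and 'y' lengths differ")
  if (length(t) > 1 && any(diff(t) <= 0))
    stop_user("'t' must be strictly increasing")
  if (any(t < 0)) stop_user("'t' must be non-negative")
  out <- data.frame(t = as.numeric(t), y = as.numeric(y))
  attr(out, "kind") <- kind
  attr(out, "ligand_conc") <- ligand_conc
  class(out) <- c("sf_trace", "data.frame")
  out
}

#' Construct an smFRET two-channel trace
#'
#' @param t frame times (s).
#' @param donor,acceptor channel intensities (a.u.).
#' @param frame_interval exposure time (s); inferred from `t` when omitted.
#' @param background_donor,background_acceptor channel backgrounds (a.u.).
#' @return A data frame of class `fret_trace`.
#' @export
fret_trace <- function(t, donor, acceptor, frame_interval = NULL,
                       background_donor = 0, background_acceptor = 0) {
  n <- length(t)
  if (length(donor) != n || length(acceptor) != n)
    stop_user("channel lengths must match 't'")
  if (is.null(frame_interval)) {
    if (n < 2) stop_user("cannot infer 'frame_interval' from one frame")
    frame_interval <- median(diff(t))
  }
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  out <- data.frame(t = as.numeric(t), donor = as.numeric(donor),
                    acceptor = as.numeric(acceptor))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "background_donor") <- background_donor
  attr(out, "background_acceptor") <- background_acceptor
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' @export
print.scheme_params <- function(x, ...) {
  cat(sprintf(
    "kinetic scheme: k+1 = %g uM^-1 s^-1, k-1 = %g s^-1, k2 = %g s^-1, [S] = %g uM\n",
    x$k_plus1, x$k_minus1, x$k2, x$ligand_conc))
  invisible(x)
}
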