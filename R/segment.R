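## Two-state segmentation of gold-probe trajectories.
##
## The bound/unbound call is made on the rolling two-dimensional standard
## deviation of the centroid: the bound state sets a narrow noise floor whose
## centre mu and spread sigma are read off a Gaussian fit to the s.d.
## histogram, and excursions above mu + k*sigma sustained for `persistence`
## frames are scored as unbound.  Transition frames are then refined by a
## two-level step fit to the raw positions.

#' Segmentation parameters
#'
#' Defaults follow the analysis settings used for 20 kHz dark-field data:
#' rolling window `[t - 20, t + 20]`, mu + 4 sigma threshold sustained for 10
#' consecutive frames, 51-frame median filter for display traces, and a 50 ms
#' gap for the composite-unbound (G0) merge rule.
#'
#' @param half_window half-width of the rolling s.d. window (frames).
#' @param persistence consecutive frames required above/below threshold to
#'   call a transition.
#' @param threshold_multiplier `k` in the `mu + k * sigma` threshold.
#' @param median_window window of the display median filter (odd, frames).
#' @param merge_gap maximum separation of two unbound dwells for the
#'   composite-unbound merge rule (s).
#' @param sd_hist_bin histogram bin width for the noise-floor fit (nm);
#'   `NULL` selects a Freedman--Diaconis width.
#' @param step_search_halfwidth half-width of the step-fit refinement window
#'   (frames).
#' @param g0_min_sep_nm floor of the on-axis separation criterion in the
#'   merge rule (nm).
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(half_window = 20L, persistence = 10L,
                       threshold_multiplier = 4, median_window = 51L,
                       merge_gap = 0.050, sd_hist_bin = NULL,
                       step_search_halfwidth = 40L, g0_min_sep_nm = 4) {
  check_scalar(half_window, "half_window", min = 1)
  check_scalar(persistence, "persistence", min = 1)
  check_scalar(threshold_multiplier, "threshold_multiplier", min = 0,
               strict = TRUE)
  check_scalar(median_window, "median_window", min = 1)
  if (median_window %% 2 == 0) stop_user("'median_window' must be odd")
  check_scalar(merge_gap, "merge_gap", min = 0)
  if (!is.null(sd_hist_bin))
    check_scalar(sd_hist_bin, "sd_hist_bin", min = 0, strict = TRUE)
  check_scalar(step_search_halfwidth, "step_search_halfwidth", min = 1)
  check_scalar(g0_min_sep_nm, "g0_min_sep_nm", min = 0)
  structure(list(half_window = as.integer(half_window),
                 persistence = as.integer(persistence),
                 threshold_multiplier = threshold_multiplier,
                 median_window = as.integer(median_window),
                 merge_gap = merge_gap,
                 sd_hist_bin = sd_hist_bin,
                 step_search_halfwidth = as.integer(step_search_halfwidth),
                 g0_min_sep_nm = g0_min_sep_nm),
            class = "seg_params")
}

#' Rolling two-dimensional standard deviation
#'
#' For each frame `t` the 2D s.d. over the window `[t - half_window,
#' t + half_window]` is `sqrt(var(on_axis) + var(off_axis))` with the sample
#' (n-1) variance convention; the per-axis variances add, which makes the
#' statistic rotation invariant.  The first and last `half_window` frames
#' have no complete window and are returned as `NA`.
#'
#' @param traj a [traj2d()] trajectory.
#' @param half_window window half-width (frames).
#' @return Numeric vector of per-frame s.d. values (nm), `NA` at the edges.
#' @export
compute_rolling_sd <- function(traj, half_window = 20L) {
  if (!inherits(traj, "traj2d")) stop_user("'traj' must be a traj2d object")
  check_scalar(half_window, "half_window", min = 1)
  w <- 2L * as.integer(half_window) + 1L
  n <- nrow(traj)
  if (n < w)
    stop_user("trajectory too short: need at least 2*half_window+1 = ", w,
              " frames, got ", n)
  roll_var <- function(x) {
    s1 <- data.table::frollsum(x, w, align = "center")
    s2 <- data.table::frollsum(x * x, w, align = "center")
    pmax((s2 - s1 * s1 / w) / (w - 1), 0)
  }
  sqrt(roll_var(traj$on_axis) + roll_var(traj$off_axis))
}

#' Fit the bound-state noise floor of an s.d. series
#'
#' Builds a histogram of the defined rolling-s.d. values and fits a Gaussian
#' to its dominant (lowest) mode; the fit is restricted to bins up to the
#' first local minimum after the primary mode so that the unbound-state tail
#' does not drag the centre.  Returns the centre `mu`, width `sigma` and the
#' detection threshold `mu + threshold_multiplier * sigma`.
#'
#' @param sd_series per-frame s.d. values from [compute_rolling_sd()]; `NA`s
#'   are ignored.  At least 1000 defined values are required.
#' @param params a [seg_params()] object (bin width and multiplier).
#' @return An object of class `noise_floor`: list with `mu`, `sigma`,
#'   `threshold`, logical `degenerate`, and the histogram range used.
#' @export
fit_noise_floor <- function(sd_series, params = seg_params()) {
  v <- sd_series[is.finite(sd_series)]
  if (length(v) < 1000L)
    stop_user("need >= 1000 defined s.d. values to fit the noise floor, got ",
              length(v))
  k <- params$threshold_multiplier
  if (diff(range(v)) == 0) {
    warning("degenerate s.d. histogram: all values identical")
    return(structure(list(mu = v[1L], sigma = 0, threshold = v[1L],
                          degenerate = TRUE, hist_range = range(v)),
                     class = "noise_floor"))
  }
  binw <- params$sd_hist_bin
  if (is.null(binw)) {
    binw <- 2 * stats::IQR(v) * length(v)^(-1 / 3)
    if (!is.finite(binw) || binw <= 0) binw <- diff(range(v)) / 100
  }
  brks <- seq(min(v), max(v) + binw, by = binw)
  h <- graphics::hist(v, breaks = brks, plot = FALSE)
  cnt <- h$counts
  mids <- h$mids

  ## smooth for mode / local-minimum detection only
  sm <- stats::filter(cnt, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  mode_i <- which.max(sm)
  cut_i <- length(cnt)
  if (mode_i < length(cnt) - 1L) {
    below_half <- FALSE
    for (i in seq(mode_i + 1L, length(cnt) - 1L)) {
      if (sm[i] < sm[mode_i] / 2) below_half <- TRUE
      if (below_half && sm[i] <= sm[i + 1L]) { cut_i <- i; break }
    }
  }
  fit_idx <- seq_len(cut_i)
  df <- data.frame(x = mids[fit_idx], y = cnt[fit_idx])

  fwhm_guess <- {
    above <- which(cnt >= cnt[mode_i] / 2)
    span <- range(mids[above])
    max(diff(span) / 2.355, binw)
  }
  starts <- list(
    list(a = max(cnt), mu = mids[mode_i], sig = fwhm_guess),
    list(a = max(cnt), mu = mids[mode_i], sig = sd(v)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      nls(y ~ a * exp(-(x - mu)^2 / (2 * sig^2)), data = df, start = st,
          algorithm = "port",
          lower = c(a = 0, mu = min(v), sig = binw / 100),
          control = list(warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("noise-floor Gaussian fit did not converge on histogram range [",
         signif(min(v), 4), ", ", signif(max(v), 4), "] nm")
  co <- coef(fit)
  structure(list(mu = unname(co["mu"]), sigma = unname(co["sig"]),
                 threshold = unname(co["mu"] + k * co["sig"]),
                 degenerate = FALSE, hist_range = range(v)),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("noise floor: mu = %.3g nm, sigma = %.3g nm, threshold = %.3g nm%s\n",
              x$mu, x$sigma, x$threshold,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Detect provisional bound/unbound transitions by hysteresis thresholding
#'
#' Scans the s.d. series with a two-state machine: a bound-to-unbound
#' transition is called at the first frame of a run of at least `persistence`
#' frames above the threshold, and an unbound-to-bound transition at the
#' first frame of a run of at least `persistence` frames below it.  Runs
#' shorter than `persistence` do not flip the state.  The machine starts in
#' the bound state if the first defined frame is below threshold, otherwise
#' in the unbound state.
#'
#' @param sd_series per-frame s.d. values (`NA` at undefined edges).
#' @param floor a [fit_noise_floor()] result (or any list with a `threshold`
#'   element).
#' @param persistence run length required to call a transition (frames).
#' @return A data frame with columns `frame` (0-based, first frame of the new
#'   state) and `direction` (`"bound_to_unbound"` / `"unbound_to_bound"`),
#'   with the starting state in attribute `initial_state` and the defined
#'   frame range in attribute `defined_range`.
#' @export
detect_transitions <- function(sd_series, floor, persistence = 10L) {
  thr <- floor$threshold
  if (is.null(thr) || !is.finite(thr)) stop_user("floor$threshold undefined")
  check_scalar(persistence, "persistence", min = 1)
  persistence <- as.integer(persistence)
  def <- which(is.finite(sd_series))
  if (length(def) == 0L)
    stop_user("s.d. series has no defined values")
  ind <- sd_series[def] > thr
  r <- rle(ind)
  state <- if (ind[1L]) "unbound" else "bound"
  init_state <- state
  pos <- cumsum(c(1L, head(r$lengths, -1L)))  # run start offsets in def
  frames <- integer(0)
  dirs <- character(0)
  for (i in seq_along(r$lengths)) {
    if (state == "bound" && r$values[i] && r$lengths[i] >= persistence) {
      frames <- c(frames, def[pos[i]] - 1L)
      dirs <- c(dirs, "bound_to_unbound")
      state <- "unbound"
    } else if (state == "unbound" && !r$values[i] &&
               r$lengths[i] >= persistence) {
      frames <- c(frames, def[pos[i]] - 1L)
      dirs <- c(dirs, "unbound_to_bound")
      state <- "bound"
    }
  }
  out <- data.frame(frame = frames, direction = dirs)
  attr(out, "initial_state") <- init_state
  attr(out, "defined_range") <- c(def[1L] - 1L, def[length(def)] - 1L)
  out
}

#' Refine a transition frame by a two-level step fit
#'
#' Fits a two-level step model jointly to the on- and off-axis positions over
#' `[approx_frame - search_halfwidth, approx_frame + search_halfwidth]`: for
#' every candidate split the model is the segment mean on each side, and the
#' split minimizing the total residual sum of squares over both axes is
#' returned (ties broken toward `approx_frame`).  The returned frame is the
#' first frame of the right-hand (new-state) segment.
#'
#' @param traj a [traj2d()] trajectory.
#' @param approx_frame provisional transition frame (0-based).
#' @param search_halfwidth search window half-width (frames).
#' @return Refined transition frame (0-based integer).
#' @export
refine_transition_stepfit <- function(traj, approx_frame,
                                      search_halfwidth = 40L) {
  if (!inherits(traj, "traj2d")) stop_user("'traj' must be a traj2d object")
  check_scalar(approx_frame, "approx_frame")
  check_scalar(search_halfwidth, "search_halfwidth", min = 1)
  n <- nrow(traj)
  f0 <- traj$frame[1L]
  i_approx <- as.integer(approx_frame) - f0 + 1L   # 1-based row
  lo <- i_approx - as.integer(search_halfwidth)
  hi <- i_approx + as.integer(search_halfwidth)
  if (lo < 1L || hi > n) {
    warning("step-fit window clipped to the trajectory bounds")
    lo <- max(lo, 1L); hi <- min(hi, n)
  }
  if (hi - lo < 1L) return(as.integer(approx_frame))
  rss_split <- function(x) {
    m <- length(x)
    cs <- cumsum(x); cs2 <- cumsum(x * x)
    s <- seq_len(m - 1L)
    left <- cs2[s] - cs[s]^2 / s
    nr <- m - s
    sr <- cs[m] - cs[s]; sr2 <- cs2[m] - cs2[s]
    right <- sr2 - sr^2 / nr
    left + right
  }
  rss <- rss_split(traj$on_axis[lo:hi]) + rss_split(traj$off_axis[lo:hi])
  best <- which(rss <= min(rss) + 1e-9 * max(abs(rss), 1))
  ## candidate split s: right segment starts at row lo + s (1-based)
  cand_frames <- (lo + best) - 1L + f0
  cand_frames[which.min(abs(cand_frames - approx_frame))]
}

#' Extract dwells from per-frame state labels
#'
#' Runs of identical labels become dwells with half-open frame intervals
#' `[start_frame, end_frame)` and durations `(end - start) / frame_rate`.
#' The first and last dwells are flagged censored (truncated by the trace or
#' by the undefined edge region).  Frames labelled `edge_undefined` (or `NA`)
#' are excluded.
#'
#' @param x a `state_segmentation` object or a vector of per-frame labels
#'   (`"bound"`/`"unbound"`, anything else treated as undefined).
#' @param frame_rate frames per second; taken from the segmentation when `x`
#'   is a `state_segmentation`.
#' @param traj optional [traj2d()]; when supplied, per-dwell mean on/off-axis
#'   positions are included.
#' @return A data frame with columns `state`, `start_frame`, `end_frame`,
#'   `duration_s`, `censored` (and `mean_on_nm`, `mean_off_nm` when `traj`
#'   is given).
#' @export
extract_dwells <- function(x, frame_rate = NULL, traj = NULL) {
  if (inherits(x, "state_segmentation")) {
    labels <- as.character(x$labels)
    frame_rate <- frame_rate %||% x$frame_rate
    f0 <- x$frame0 %||% 0L
  } else {
    labels <- as.character(x)
    f0 <- 0L
  }
  if (is.null(frame_rate)) stop_user("'frame_rate' required")
  check_scalar(frame_rate, "frame_rate", min = 0, strict = TRUE)
  known <- labels %in% c("bound", "unbound")
  if (!any(known))
    return(data.frame(state = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0),
                      censored = logical(0)))
  idx <- range(which(known))
  lab <- labels[idx[1L]:idx[2L]]
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    state = r$values,
    start_frame = starts + idx[1L] - 2L + f0,
    end_frame = ends + idx[1L] - 1L + f0,
    duration_s = r$lengths / frame_rate,
    censored = FALSE)
  out$censored[c(1L, nrow(out))] <- TRUE
  if (!is.null(traj)) {
    row0 <- traj$frame[1L]
    out$mean_on_nm <- mapply(function(s, e)
      mean(traj$on_axis[(s - row0 + 1L):(e - row0)]),
      out$start_frame, out$end_frame)
    out$mean_off_nm <- mapply(function(s, e)
      mean(traj$off_axis[(s - row0 + 1L):(e - row0)]),
      out$start_frame, out$end_frame)
  }
  out
}

#' Composite-unbound (G0) merge rule
#'
#' When two unbound dwells are separated by less than `merge_gap` and the
#' intervening bound dwell's mean on-axis position is separated from both
#' flanking bound dwells by more than the separation criterion, the
#' unbound--bound--unbound triplet is re-labelled as one composite unbound
#' event.  The criterion is `max(g0_min_sep_nm, 2 * noise_se)` where
#' `noise_se` is the standard error of the intervening dwell's mean position
#' implied by the bound-state noise floor (`mu / sqrt(2)` per axis).
#'
#' @param seg a `state_segmentation` from [segment_trajectory()].
#' @param traj the [traj2d()] the segmentation came from.
#' @param merge_gap maximum intervening bound duration (s).
#' @param params a [seg_params()] (for `g0_min_sep_nm`).
#' @return The updated `state_segmentation`; merged triplets are recorded in
#'   `merged_groups` (list of dwell-index triplets of the input dwell table).
#' @export
apply_g0_merge_rule <- function(seg, traj, merge_gap = 0.050,
                                params = seg_params()) {
  if (!inherits(seg, "state_segmentation"))
    stop_user("'seg' must be a state_segmentation object")
  dw <- seg$dwells
  if (is.null(dw$mean_on_nm))
    dw <- extract_dwells(seg, traj = traj)
  labels <- as.character(seg$labels)
  noise_se <- function(nfr) (seg$noise_floor$mu / sqrt(2)) / sqrt(nfr)
  merged <- list()
  i <- 1L
  while (i <= nrow(dw) - 2L) {
    u1 <- dw[i, ]; b <- dw[i + 1L, ]; u2 <- dw[i + 2L, ]
    if (u1$state == "unbound" && b$state == "bound" &&
        u2$state == "unbound" && !b$censored &&
        b$duration_s < merge_gap) {
      flanks <- c(if (i > 1L && dw$state[i - 1L] == "bound")
        dw$mean_on_nm[i - 1L],
        if (i + 3L <= nrow(dw) && dw$state[i + 3L] == "bound")
          dw$mean_on_nm[i + 3L])
      nfr <- b$end_frame - b$start_frame
      crit <- max(params$g0_min_sep_nm, 2 * noise_se(nfr))
      if (length(flanks) > 0 &&
          all(abs(b$mean_on_nm - flanks) > crit)) {
        merged <- c(merged, list(c(i, i + 1L, i + 2L)))
        rows <- (b$start_frame:(b$end_frame - 1L)) - (seg$frame0 %||% 0L) + 1L
        labels[rows] <- "unbound"
        i <- i + 3L
        next
      }
    }
    i <- i + 1L
  }
  if (length(merged) > 0) {
    seg$labels <- factor(labels,
                         levels = c("bound", "unbound", "edge_undefined"))
    seg$dwells <- extract_dwells(seg, traj = traj)
    seg$transitions <- transitions_from_dwells(seg$dwells)
  }
  seg$merged_groups <- merged
  seg
}

transitions_from_dwells <- function(dwells) {
  if (nrow(dwells) < 2L)
    return(data.frame(frame = integer(0), direction = character(0)))
  data.frame(
    frame = dwells$start_frame[-1L],
    direction = ifelse(dwells$state[-1L] == "unbound",
                       "bound_to_unbound", "unbound_to_bound"))
}

#' Classify whether a detached head left from the leading or trailing position
#'
#' An unbound dwell whose mean on-axis position lies backward (more negative)
#' of the preceding bound dwell's mean by more than
#' `displacement_criterion` is labelled `leading` (the head stepped back
#' toward its partner on detaching, so it had occupied the front position);
#' forward displacement gives `trailing`; smaller displacements are
#' `ambiguous`.  Unbound dwells without a preceding bound dwell get `NA`.
#'
#' @param traj a [traj2d()] trajectory.
#' @param seg a `state_segmentation`.
#' @param displacement_criterion minimum |on-axis displacement| (nm).
#' @return Character vector, one label per unbound dwell in `seg$dwells`.
#' @export
classify_detachment_origin <- function(traj, seg, displacement_criterion = 4) {
  if (!inherits(seg, "state_segmentation"))
    stop_user("'seg' must be a state_segmentation object")
  dw <- seg$dwells
  if (is.null(dw$mean_on_nm)) dw <- extract_dwells(seg, traj = traj)
  ui <- which(dw$state == "unbound")
  vapply(ui, function(i) {
    if (i == 1L || dw$state[i - 1L] != "bound") return(NA_character_)
    delta <- dw$mean_on_nm[i] - dw$mean_on_nm[i - 1L]
    if (delta < -displacement_criterion) "leading"
    else if (delta > displacement_criterion) "trailing"
    else "ambiguous"
  }, character(1))
}

#' Median-filter a trajectory for display
#'
#' Per-axis running median with an odd window.  When a segmentation is
#' supplied the filter is applied within each dwell separately, so bound and
#' unbound stretches are smoothed independently and transitions are not
#' blurred across.  Edges use shrinking windows (`runmed` end rule
#' `"median"`).
#'
#' @param traj a [traj2d()] trajectory.
#' @param window odd filter window (frames).
#' @param seg optional `state_segmentation`.
#' @return A [traj2d()] with smoothed coordinates.
#' @export
median_filter_trace <- function(traj, window = 51L, seg = NULL) {
  if (!inherits(traj, "traj2d")) stop_user("'traj' must be a traj2d object")
  check_scalar(window, "window", min = 1)
  if (window %% 2 == 0) stop_user("'window' must be odd")
  smooth_seg <- function(x) {
    if (length(x) == 1L) return(x)
    k <- min(window, if (length(x) %% 2 == 1L) length(x) else length(x) - 1L)
    as.numeric(runmed(x, k, endrule = "median"))
  }
  on <- traj$on_axis; off <- traj$off_axis
  if (is.null(seg)) {
    on <- smooth_seg(on); off <- smooth_seg(off)
  } else {
    dw <- seg$dwells
    row0 <- traj$frame[1L]
    for (i in seq_len(nrow(dw))) {
      rows <- (dw$start_frame[i] - row0 + 1L):(dw$end_frame[i] - row0)
      on[rows] <- smooth_seg(traj$on_axis[rows])
      off[rows] <- smooth_seg(traj$off_axis[rows])
    }
  }
  traj2d(on, off, frame_rate(traj), frame0 = traj$frame[1L])
}

#' Segment a gold-probe trajectory into bound and unbound states
#'
#' Runs the full pipeline: rolling 2D s.d., Gaussian noise-floor fit,
#' hysteresis transition detection, per-transition step-fit refinement,
#' dwell extraction and leading/trailing classification, optionally followed
#' by the composite-unbound merge rule.
#'
#' @param traj a [traj2d()] trajectory.
#' @param params a [seg_params()] object.
#' @param refine logical: refine transition frames by the step fit.
#' @param merge logical: apply [apply_g0_merge_rule()].
#' @param noise_floor optional precomputed [fit_noise_floor()] result.
#' @return An object of class `state_segmentation`: per-frame `labels`
#'   (`bound`/`unbound`/`edge_undefined`), `transitions`, `dwells` (with
#'   per-dwell positions and `origin` labels for unbound dwells),
#'   `noise_floor`, `params`, `merged_groups`, `frame_rate`, `frame0`.
#' @examples
#' sim <- simulate_two_state_trajectory(
#'   traj_sim_params(n_frames = 50000, seed = 7))
#' seg <- segment_trajectory(sim$traj)
#' seg$dwells[1:3, ]
#' @export
segment_trajectory <- function(traj, params = seg_params(), refine = TRUE,
                               merge = FALSE, noise_floor = NULL) {
  if (!inherits(traj, "traj2d")) stop_user("'traj' must be a traj2d object")
  sd_series <- compute_rolling_sd(traj, params$half_window)
  nf <- noise_floor %||% fit_noise_floor(sd_series, params)
  prov <- detect_transitions(sd_series, nf, params$persistence)
  ## detect_transitions indexes frames relative to the series start
  prov$frame <- prov$frame + traj$frame[1L]
  attr(prov, "defined_range") <-
    attr(prov, "defined_range") + traj$frame[1L]

  frames <- prov$frame
  if (refine && nrow(prov) > 0) {
    frames <- vapply(prov$frame, function(f)
      suppressWarnings(
        refine_transition_stepfit(traj, f, params$step_search_halfwidth)),
      numeric(1))
    ## refinement windows of neighbouring transitions can overlap; enforce a
    ## strictly increasing sequence
    for (i in seq_along(frames)[-1L])
      frames[i] <- max(frames[i], frames[i - 1L] + 1L)
  }

  n <- nrow(traj)
  f0 <- traj$frame[1L]
  def <- attr(prov, "defined_range")
  labels <- rep(NA_character_, n)
  state <- attr(prov, "initial_state")
  bounds <- c(def[1L], frames, def[2L] + 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[i] - f0 + 1L):(bounds[i + 1L] - f0)
    rows <- rows[rows >= 1L & rows <= n]
    if (length(rows)) labels[rows] <- state
    state <- if (state == "bound") "unbound" else "bound"
  }
  labels[is.na(labels)] <- "edge_undefined"
  labels <- factor(labels, levels = c("bound", "unbound", "edge_undefined"))

  seg <- structure(list(labels = labels,
                        transitions = data.frame(frame = as.integer(frames),
                                                 direction = prov$direction),
                        dwells = NULL,
                        noise_floor = nf,
                        params = params,
                        merged_groups = list(),
                        frame_rate = frame_rate(traj),
                        frame0 = f0),
                   class = "state_segmentation")
  seg$dwells <- extract_dwells(seg, traj = traj)
  if (merge) seg <- apply_g0_merge_rule(seg, traj, params$merge_gap, params)
  origin <- rep(NA_character_, nrow(seg$dwells))
  if (nrow(seg$dwells) > 0) {
    ui <- which(seg$dwells$state == "unbound")
    origin[ui] <- classify_detachment_origin(traj, seg)
  }
  seg$dwells$origin <- origin
  seg
}

#' @export
print.state_segmentation <- function(x, ...) {
  dw <- x$dwells
  nb <- sum(dw$state == "bound"); nu <- sum(dw$state == "unbound")
  cat(sprintf("state segmentation: %d frames, %d bound / %d unbound dwells\n",
              length(x$labels), nb, nu))
  print(x$noise_floor)
  ub <- dw$state == "bound" & !dw$censored
  uu <- dw$state == "unbound" & !dw$censored
  if (any(ub)) cat(sprintf("  mean bound dwell   : %.4g ms (n = %d)\n",
                           mean(dw$duration_s[ub]) * 1e3, sum(ub)))
  if (any(uu)) cat(sprintf("  mean unbound dwell : %.4g ms (n = %d)\n",
                           mean(dw$duration_s[uu]) * 1e3, sum(uu)))
  invisible(x)
}
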