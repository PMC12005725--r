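## File-format plumbing.  All tabular formats are comma-separated with a
## required header carrying units; all JSON sidecars go through jsonlite.
## Units repo-wide: s, nm, uM, s^-1.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop_user("file ", path, " is missing required columns: ",
              paste(missing, collapse = ", "))
  dt
}

check_monotonic_time <- function(t, path) {
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop_user("non-monotonic time in ", path, " at line ", bad[1L] + 2L,
                " (data row ", bad[1L] + 1L, ")")
  }
  invisible(TRUE)
}

#' Read / write gold-probe trajectory CSV
#'
#' Columns `frame, t_s, on_nm, off_nm`.  The reader validates a complete
#' header, consecutive frames, strictly increasing time and `t_s =
#' frame / frame_rate`; the frame rate is inferred from the time column when
#' not supplied.
#'
#' @param path file path.
#' @param frame_rate frames per second; inferred from `t_s` when `NULL`.
#' @return [read_trajectory_csv()]: a [traj2d()].
#' @export
read_trajectory_csv <- function(path, frame_rate = NULL) {
  dt <- read_csv_checked(path, c("frame", "t_s", "on_nm", "off_nm"))
  check_monotonic_time(dt$t_s, path)
  if (nrow(dt) > 1L && any(diff(dt$frame) != 1L))
    stop_user("frames not consecutive in ", path, " at line ",
              which(diff(dt$frame) != 1L)[1L] + 2L)
  if (is.null(frame_rate)) {
    if (nrow(dt) < 2L) stop_user("cannot infer frame rate from one row")
    frame_rate <- 1 / median(diff(dt$t_s))
  }
  if (any(abs(dt$t_s - dt$frame / frame_rate) > 1e-6))
    stop_user("time column inconsistent with frame/frame_rate in ", path)
  traj2d(dt$on_nm, dt$off_nm, frame_rate, frame0 = dt$frame[1L])
}

#' @rdname read_trajectory_csv
#' @param traj a [traj2d()] object.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "traj2d")) stop_user("'traj' must be a traj2d object")
  data.table::fwrite(data.frame(frame = traj$frame, t_s = traj$t,
                                on_nm = traj$on_axis,
                                off_nm = traj$off_axis),
                     path)
  invisible(path)
}

#' Read / write smFRET trace CSV
#'
#' Columns `t_s, donor, acceptor`.
#'
#' @param path file path.
#' @param frame_interval exposure (s); inferred from `t_s` when `NULL`.
#' @return [read_fret_csv()]: a [fret_trace()].
#' @export
read_fret_csv <- function(path, frame_interval = NULL) {
  dt <- read_csv_checked(path, c("t_s", "donor", "acceptor"))
  check_monotonic_time(dt$t_s, path)
  fret_trace(dt$t_s, dt$donor, dt$acceptor, frame_interval = frame_interval)
}

#' @rdname read_fret_csv
#' @param trace a [fret_trace()] object.
#' @export
write_fret_csv <- function(trace, path) {
  if (!inherits(trace, "fret_trace"))
    stop_user("'trace' must be a fret_trace object")
  data.table::fwrite(data.frame(t_s = trace$t, donor = trace$donor,
                                acceptor = trace$acceptor), path)
  invisible(path)
}

#' Read / write stopped-flow trace CSV
#'
#' Columns `t_s, signal`.
#'
#' @param path file path.
#' @param kind trace kind.
#' @param ligand_conc nucleotide concentration (uM).
#' @return [read_stopped_flow_csv()]: an [sf_trace()].
#' @export
read_stopped_flow_csv <- function(path, kind = "fluorescence",
                                  ligand_conc = NA_real_) {
  dt <- read_csv_checked(path, c("t_s", "signal"))
  check_monotonic_time(dt$t_s, path)
  sf_trace(dt$t_s, dt$signal, kind = kind, ligand_conc = ligand_conc)
}

#' @rdname read_stopped_flow_csv
#' @param trace an [sf_trace()] object.
#' @export
write_stopped_flow_csv <- function(trace, path) {
  if (!inherits(trace, "sf_trace"))
    stop_user("'trace' must be an sf_trace object")
  data.table::fwrite(data.frame(t_s = trace$t, signal = trace$y), path)
  invisible(path)
}

#' Read / write dwell-table CSV
#'
#' Columns `state, start_frame, end_frame, duration_s, censored,
#' origin_label`.
#'
#' @param path file path.
#' @return [read_dwell_csv()]: a data frame.
#' @export
read_dwell_csv <- function(path) {
  dt <- read_csv_checked(path, c("state", "start_frame", "end_frame",
                                 "duration_s", "censored", "origin_label"))
  dt$censored <- as.logical(dt$censored)
  dt$origin_label[dt$origin_label == ""] <- NA_character_
  dt
}

#' @rdname read_dwell_csv
#' @param dwells a dwell table (e.g. `seg$dwells` from
#'   [segment_trajectory()]).
#' @export
write_dwell_csv <- function(dwells, path) {
  out <- data.frame(state = dwells$state,
                    start_frame = dwells$start_frame,
                    end_frame = dwells$end_frame,
                    duration_s = dwells$duration_s,
                    censored = dwells$censored,
                    origin_label = dwells$origin %||% dwells$origin_label %||%
                      rep(NA_character_, nrow(dwells)))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read / write segmentation JSON
#'
#' Serializes a `state_segmentation`: run-length-encoded labels,
#' transitions, dwells, noise floor and parameters.
#'
#' @param path file path.
#' @return [read_segmentation_json()]: a `state_segmentation`.
#' @export
read_segmentation_json <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- factor(rep(x$labels_rle$values, x$labels_rle$lengths),
                   levels = c("bound", "unbound", "edge_undefined"))
  seg <- structure(list(
    labels = labels,
    transitions = as.data.frame(x$transitions),
    dwells = as.data.frame(x$dwells),
    noise_floor = structure(x$noise_floor, class = "noise_floor"),
    params = structure(x$params, class = "seg_params"),
    merged_groups = x$merged_groups %||% list(),
    frame_rate = x$frame_rate,
    frame0 = x$frame0 %||% 0L), class = "state_segmentation")
  seg
}

#' @rdname read_segmentation_json
#' @param seg a `state_segmentation` object.
#' @export
write_segmentation_json <- function(seg, path) {
  if (!inherits(seg, "state_segmentation"))
    stop_user("'seg' must be a state_segmentation object")
  r <- rle(as.character(seg$labels))
  payload <- list(
    labels_rle = list(lengths = r$lengths, values = r$values),
    transitions = seg$transitions,
    dwells = seg$dwells,
    noise_floor = seg$noise_floor[c("mu", "sigma", "threshold", "degenerate")],
    params = unclass(seg$params),
    merged_groups = seg$merged_groups,
    frame_rate = seg$frame_rate,
    frame0 = seg$frame0)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a simulation ground-truth sidecar
#'
#' JSON sidecar carrying the generating parameters, seed and ground-truth
#' events/dwells of a simulator run.
#'
#' @param truth the `truth` element of a simulator result (or any list).
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  payload <- truth
  if (!is.null(payload$labels)) {
    r <- rle(as.character(payload$labels))
    payload$labels <- list(lengths = r$lengths, values = r$values)
  }
  if (!is.null(payload$params)) payload$params <- unclass(payload$params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a rate table as JSON
#'
#' @param table a [build_rate_table()] result.
#' @param path file path.
#' @export
write_rate_table_json <- function(table, path) {
  jsonlite::write_json(as.data.frame(table), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
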