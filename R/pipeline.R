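## Pipeline orchestration: validated config, deterministic seeding, manifest.

pipeline_schema <- list(
  top = c("out_dir", "seed", "stages", "simulate", "segment",
          "input_trajectory"),
  simulate = c("frame_rate", "mean_bound_dwell", "mean_unbound_dwell",
               "noise_bound", "noise_unbound", "unbound_on_axis_offset",
               "n_frames"),
  segment = c("half_window", "persistence", "threshold_multiplier",
              "median_window", "merge_gap", "sd_hist_bin",
              "step_search_halfwidth", "g0_min_sep_nm", "merge", "refine"))

validate_config <- function(config) {
  bad <- setdiff(names(config), pipeline_schema$top)
  if (!is.null(config$simulate))
    bad <- c(bad, paste0("simulate.", setdiff(names(config$simulate),
                                              pipeline_schema$simulate)))
  if (!is.null(config$segment))
    bad <- c(bad, paste0("segment.", setdiff(names(config$segment),
                                             pipeline_schema$segment)))
  bad <- bad[!endsWith(bad, ".")]
  if (length(bad))
    stop_user("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop_user("config needs 'out_dir'")
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop_user("config needs a non-empty 'stages' list")
  unknown <- setdiff(unlist(config$stages), c("simulate", "segment", "report"))
  if (length(unknown))
    stop_user("unknown stages: ", paste(unknown, collapse = ", "))
  invisible(config)
}

#' Run the simulate / segment / report pipeline
#'
#' Executes the requested stages in order and writes all artifacts plus a
#' `manifest.json` recording package version, parameters, seeds and md5
#' digests of every file written, so identical config + seed reproduce
#' identical digests.
#'
#' Config keys: `out_dir`; `seed`; `stages` (subset of `"simulate"`,
#' `"segment"`, `"report"` in order); `simulate` ([traj_sim_params()]
#' fields); `segment` ([seg_params()] fields plus logicals `merge`,
#' `refine`); `input_trajectory` (CSV path, when segmenting without
#' simulating).
#'
#' @param config a named list, or path to a JSON file holding one.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_user("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- unlist(config$stages)
  paths <- list()
  truth <- NULL
  traj <- NULL

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- child_seed(seed, 1L)
    sim <- simulate_two_state_trajectory(do.call(traj_sim_params, sim_args))
    traj <- sim$traj
    truth <- sim$truth
    paths$trajectory <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(traj, paths$trajectory)
    paths$ground_truth <- file.path(out_dir, "ground_truth.json")
    write_ground_truth_json(truth, paths$ground_truth)
  }

  seg <- NULL
  if ("segment" %in% stages) {
    if (is.null(traj)) {
      if (is.null(config$input_trajectory))
        stop_user("segment stage needs 'input_trajectory' when not simulating")
      traj <- read_trajectory_csv(config$input_trajectory)
      paths$trajectory <- config$input_trajectory
    }
    sp_args <- config$segment %||% list()
    merge <- isTRUE(sp_args$merge)
    refine <- !isFALSE(sp_args$refine)
    sp_args$merge <- NULL; sp_args$refine <- NULL
    seg <- segment_trajectory(traj, do.call(seg_params, sp_args),
                              refine = refine, merge = merge)
    paths$segmentation <- file.path(out_dir, "segmentation.json")
    write_segmentation_json(seg, paths$segmentation)
    paths$dwells <- file.path(out_dir, "dwells.csv")
    write_dwell_csv(seg$dwells, paths$dwells)
  }

  if ("report" %in% stages) {
    rep <- list()
    if (!is.null(seg)) {
      dw <- seg$dwells
      for (st in c("bound", "unbound")) {
        sel <- dw$state == st & !dw$censored
        rep[[paste0("recovered_mean_", st, "_dwell_s")]] <-
          if (any(sel)) mean(dw$duration_s[sel]) else NA_real_
        rep[[paste0("n_", st, "_dwells")]] <- sum(sel)
      }
    }
    if (!is.null(truth)) {
      tdw <- truth$dwells
      for (st in c("bound", "unbound")) {
        sel <- tdw$state == st & !tdw$censored
        rep[[paste0("true_mean_", st, "_dwell_s")]] <-
          mean(tdw$duration_draw_s[sel])
      }
      rep$generating_mean_bound_dwell_s <- truth$params$mean_bound_dwell
      rep$generating_mean_unbound_dwell_s <- truth$params$mean_unbound_dwell
    }
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(rep, paths$report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  manifest <- list(
    package = "kinegate",
    version = as.character(packageVersion("kinegate")),
    seed = seed,
    stages = as.list(stages),
    config = config[setdiff(names(config), c("out_dir"))],
    digests = as.list(tools::md5sum(unlist(paths))))
  names(manifest$digests) <- basename(names(manifest$digests))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

cli_spec <- function(sub) {
  make <- optparse::make_option
  switch(sub,
    simulate = list(
      make("--out", type = "character", help = "output directory"),
      make("--seed", type = "integer", default = 1L),
      make("--n-frames", type = "integer", default = 200000L,
           dest = "n_frames"),
      make("--frame-rate", type = "double", default = 20000,
           dest = "frame_rate"),
      make("--mean-bound", type = "double", default = 0.160,
           dest = "mean_bound_dwell"),
      make("--mean-unbound", type = "double", default = 0.011,
           dest = "mean_unbound_dwell")),
    segment = list(
      make("--traj", type = "character", help = "trajectory CSV"),
      make("--frame-rate", type = "double", default = NULL,
           dest = "frame_rate"),
      make("--half-window", type = "integer", default = 20L,
           dest = "half_window"),
      make("--persistence", type = "integer", default = 10L),
      make("--k", type = "double", default = 4, dest = "threshold_multiplier"),
      make("--merge-gap", type = "double", default = 0.05,
           dest = "merge_gap"),
      make("--merge", action = "store_true", default = FALSE),
      make("--out", type = "character", help = "output prefix")),
    fret = list(
      make("--trace", type = "character", help = "FRET CSV"),
      make("--threshold", type = "double", default = 0.5),
      make("--min-frames", type = "integer", default = 2L,
           dest = "min_frames"),
      make("--out", type = "character", help = "output prefix")),
    stoppedflow = list(
      make("--mode", type = "character", default = "fit-exp",
           help = "fit-exp | fit-burst"),
      make("--trace", type = "character", help = "stopped-flow CSV"),
      make("--out", type = "character", help = "output JSON")),
    recover = list(
      make("--out", type = "character", help = "output directory"),
      make("--seed", type = "integer", default = 1L),
      make("--n-frames", type = "integer", default = 500000L,
           dest = "n_frames")),
    stop_user("unknown subcommand: ", sub))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `segment`, `fret`, `stoppedflow`
#' and `recover` (end-to-end simulate-segment-report benchmark).  Invoked by
#' the `inst/cli/kinegate.R` script:
#' `Rscript kinegate.R segment --traj run.csv --out out/`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Invisibly, the result of the dispatched stage.
#' @export
kinegate_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the 'optparse' package is required for the command line interface")
  if (length(args) == 0L)
    stop_user("usage: kinegate <simulate|segment|fret|stoppedflow|recover> ",
              "[options]")
  sub <- args[1L]
  spec <- cli_spec(sub)
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = spec), args[-1L])
  opts$help <- NULL

  if (sub == "simulate") {
    if (is.null(opts$out)) stop_user("--out required")
    cfg <- list(out_dir = opts$out, seed = opts$seed,
                stages = list("simulate"),
                simulate = opts[intersect(names(opts),
                                          pipeline_schema$simulate)])
    return(invisible(run_pipeline(cfg)))
  }
  if (sub == "segment") {
    if (is.null(opts$traj) || is.null(opts$out))
      stop_user("--traj and --out required")
    traj <- read_trajectory_csv(opts$traj, frame_rate = opts$frame_rate)
    sp <- seg_params(half_window = opts$half_window,
                     persistence = opts$persistence,
                     threshold_multiplier = opts$threshold_multiplier,
                     merge_gap = opts$merge_gap)
    seg <- segment_trajectory(traj, sp, merge = isTRUE(opts$merge))
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    write_segmentation_json(seg, file.path(opts$out, "segmentation.json"))
    write_dwell_csv(seg$dwells, file.path(opts$out, "dwells.csv"))
    message("wrote ", file.path(opts$out, "dwells.csv"))
    return(invisible(seg))
  }
  if (sub == "fret") {
    if (is.null(opts$trace) || is.null(opts$out))
      stop_user("--trace and --out required")
    trace <- read_fret_csv(opts$trace)
    res <- analyze_fret_trace(trace, threshold = opts$threshold,
                              min_frames = opts$min_frames)
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    ev <- res$events
    ev$start_s <- ev$start_frame * attr(trace, "frame_interval")
    data.table::fwrite(ev[, c("start_s", "duration_s", "end_type",
                              "censored")],
                       file.path(opts$out, "events.csv"))
    summary <- list(n_events = nrow(ev),
                    n_by_end_type = as.list(table(ev$end_type)),
                    mean_dwell_s = res$rate$mean_dwell %||% NA,
                    rate_s = res$rate$rate %||% NA,
                    rate_se = res$rate$se %||% NA,
                    rate_is_lower_bound = res$rate_is_lower_bound)
    jsonlite::write_json(summary, file.path(opts$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  if (sub == "stoppedflow") {
    if (is.null(opts$trace) || is.null(opts$out))
      stop_user("--trace and --out required")
    trace <- read_stopped_flow_csv(opts$trace)
    fit <- if (opts$mode == "fit-burst") fit_burst(trace)
    else fit_single_exponential(trace)
    out <- fit[setdiff(names(fit), "fit")]
    jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(fit))
  }
  if (sub == "recover") {
    if (is.null(opts$out)) stop_user("--out required")
    cfg <- list(out_dir = opts$out, seed = opts$seed,
                stages = list("simulate", "segment", "report"),
                simulate = list(n_frames = opts$n_frames))
    return(invisible(run_pipeline(cfg)))
  }
  stop_user("unknown subcommand: ", sub)
}
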