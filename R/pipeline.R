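#' Assemble a full pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: argument lists for each
#' stage constructor plus rate-window and model settings. Every stochastic
#' stage consumes an explicit seed.
#'
#' @param sim list of [sim_config()] arguments.
#' @param optics list of [optics_config()] arguments.
#' @param segmentation list of [segmentation_params()] arguments.
#' @param link list of [link_config()] arguments.
#' @param classifier list of [classifier_params()] arguments.
#' @param rates list with `window` (length-2, min; `NULL` means from 80
#'   min to the end) and optional `truncation_time` beyond which frames
#'   are excluded from the fits.
#' @param model list with `tau_bar_d` (min) used for the fraction /
#'   growth-rate consistency check; `NULL` uses the simulation's
#'   `model_division_time`.
#' @param render_seed seed for rendering noise and flicker.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), optics = list(),
                            segmentation = list(), link = list(),
                            classifier = list(),
                            rates = list(window = NULL,
                                         truncation_time = NULL),
                            model = list(tau_bar_d = NULL),
                            render_seed = 1L) {
  structure(list(sim = sim, optics = optics, segmentation = segmentation,
                 link = link, classifier = classifier, rates = rates,
                 model = model, render_seed = as.integer(render_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of the [pipeline_config()] blocks.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic colony
#'
#' Executes simulate -> render -> segment -> track -> classify -> rates ->
#' model and returns a results bundle including the event-log oracle for
#' comparison. Deterministic given the seeds in the configuration.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `pipeline_result`: list with `history`,
#'   `oracle` (event-log [oracle_rates()]), `stack`, `detections`,
#'   `trajectories`, `division_events`, `calls`, `divider_fraction`
#'   (series and its time average), `series`, `rates`
#'   ([rate_decomposition()] of the tracked data), `division_stats`,
#'   `model` (fraction/growth consistency and [fit_mean_division_time()]),
#'   and `config`. For an empty simulation all elements are present but
#'   empty and `empty = TRUE`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- run_stage("simulate", do.call(sim_config, config$sim))
  history <- run_stage("simulate", simulate_colony(sim))
  if (nrow(history$agents) == 0) {
    return(structure(list(empty = TRUE, history = history, oracle = NULL,
                          stack = NULL, detections = empty_detections(),
                          trajectories = trajectory_set(
                            empty_trajectory_points(),
                            empty_trajectory_meta()),
                          division_events = NULL, calls = NULL,
                          divider_fraction = NULL, series = NULL,
                          rates = NULL, division_stats = NULL, model = NULL,
                          config = config), class = "pipeline_result"))
  }
  optics <- run_stage("render", do.call(optics_config, config$optics))
  stack <- run_stage("render",
                     render_frames(history, optics, seed = config$render_seed))
  seg <- run_stage("segment", do.call(segmentation_params, config$segmentation))
  detections <- run_stage("segment", segment_stack(stack, seg))
  link <- run_stage("track", do.call(link_config, config$link))
  traj <- run_stage("track", link_trajectories(detections, link))
  div <- run_stage("track", detect_division_events(traj, link))
  traj <- div$trajectories
  cls <- run_stage("classify", do.call(classifier_params, config$classifier))
  calls <- run_stage("classify", classify_trajectories(traj, cls))
  dfs <- run_stage("classify", divider_fraction_series(traj, cls))

  series <- run_stage("rates", population_series(traj))
  t_end <- max(series$time)
  if (!is.null(config$rates$truncation_time))
    t_end <- min(t_end, config$rates$truncation_time)
  window <- if (is.null(config$rates$window)) c(80, t_end)
  else config$rates$window
  eta <- run_stage("rates", observed_growth_rate(series, window))
  rates <- run_stage("rates", rate_decomposition(eta, series, window))
  tau_div <- traj$meta$duration[traj$meta$end_reason == "division"]
  birth_div <- traj$meta$start_time[traj$meta$end_reason == "division"]
  division_stats <- if (length(tau_div) >= 10)
    run_stage("rates", division_time_statistics(tau_div, birth_div))
  else NULL

  tau_model <- config$model$tau_bar_d
  if (is.null(tau_model)) tau_model <- sim$model_division_time
  in_w <- dfs$time >= window[1] & dfs$time <= window[2]
  f_measured <- mean(dfs$fraction[in_w], na.rm = TRUE)
  model <- run_stage("model", list(
    tau_bar_d = tau_model,
    f_measured = f_measured,
    f_from_growth = tryCatch(fraction_from_growth(rates$eta_eff, tau_model),
                             error = function(e) NA_real_),
    eta_from_fraction = effective_growth_from_fraction(
      max(f_measured, 0.51), tau_model),
    fit = fit_mean_division_time(
      data.frame(f = f_measured, eta_eff = rates$eta_eff))))

  oracle <- run_stage("oracle", oracle_rates(history, window))
  structure(list(empty = FALSE, history = history, oracle = oracle,
                 stack = stack, detections = detections,
                 trajectories = traj, division_events = div$events,
                 calls = calls,
                 divider_fraction = list(series = dfs, mean = f_measured),
                 series = series, rates = rates,
                 division_stats = division_stats, model = model,
                 config = config), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (isTRUE(x$empty)) { cat("  (empty simulation)\n"); return(invisible(x)) }
  cat("  trajectories:", nrow(x$trajectories$meta),
      " divisions:", nrow(x$division_events), "\n")
  cat(sprintf("  eta = %.3f 1/h, eta_eff = %.3f 1/h (oracle %.3f)\n",
              x$rates$eta, x$rates$eta_eff, x$oracle$eta_eff))
  cat(sprintf("  divider fraction (time-averaged) = %.3f\n",
              x$divider_fraction$mean))
  invisible(x)
}

#' Scalar results of a pipeline run as JSON
#'
#' @param result a [run_pipeline()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_results_json <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  out <- if (isTRUE(result$empty)) list(empty = TRUE)
  else list(
    empty = FALSE,
    eta = result$rates$eta, eta_d = result$rates$eta_d,
    eta_a = result$rates$eta_a, eta_eff = result$rates$eta_eff,
    R_d = result$rates$R_d, R_a = result$rates$R_a,
    divider_fraction = result$divider_fraction$mean,
    f_from_growth = result$model$f_from_growth,
    tau_bar_d_fit = result$model$fit$tau_bar_d,
    mean_division_time =
      if (is.null(result$division_stats)) NA_real_
      else result$division_stats$mean_division_time,
    oracle_eta = result$oracle$eta, oracle_eta_eff = result$oracle$eta_eff)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

## ---- tabular and image I/O ----

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing required columns: ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Write / read a colony history as plain-text tables
#'
#' The history is stored as three CSV tables (`agents.csv`, `states.csv`,
#' `events.csv`) plus a JSON echo of the configuration.
#'
#' @param history a [simulate_colony()] result.
#' @param dir output directory (created if missing).
#' @return `write_history()` the directory, invisibly; `read_history()` a
#'   `colony_history`.
#' @export
write_history <- function(history, dir) {
  stopifnot(inherits(history, "colony_history"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(history$agents, file.path(dir, "agents.csv"),
                   row.names = FALSE)
  utils::write.csv(history$states, file.path(dir, "states.csv"),
                   row.names = FALSE)
  utils::write.csv(history$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  cfg <- history$config; class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(times = history$times)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_history
#' @export
read_history <- function(dir) {
  agents <- utils::read.csv(file.path(dir, "agents.csv"))
  states <- utils::read.csv(file.path(dir, "states.csv"))
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  check_columns(agents, c("id", "mother_id", "phenotype", "birth_time"),
                "agents table")
  check_columns(states, c("time", "agent_id", "x1", "y1", "x2", "y2",
                          "xc", "yc", "length"), "states table")
  check_columns(events, c("time", "event", "agent_id"), "events table")
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  times <- cfg$times; cfg$times <- NULL
  cfg <- structure(cfg, class = "sim_config")
  structure(list(agents = agents, states = states, events = events,
                 times = times, truncated_at = NA_real_, config = cfg),
            class = "colony_history")
}

#' Write / read a trajectory set as CSV
#'
#' Tidy storage: one CSV of trajectory points (one row per
#' trajectory-timepoint) and one of per-trajectory metadata.
#'
#' @param trajectories a [trajectory_set()].
#' @param points_path,meta_path file paths.
#' @return `write_trajectories()` invisibly `NULL`; `read_trajectories()`
#'   a `trajectory_set`.
#' @export
write_trajectories <- function(trajectories, points_path, meta_path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  utils::write.csv(trajectories$points, points_path, row.names = FALSE)
  utils::write.csv(trajectories$meta, meta_path, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(points_path, meta_path) {
  pts <- utils::read.csv(points_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  check_columns(pts, c("traj_id", "time", "x", "y", "x1", "y1", "x2", "y2",
                       "length"), "trajectory points table")
  check_columns(meta, c("traj_id", "start_time", "end_time", "duration",
                        "end_reason"), "trajectory meta table")
  trajectory_set(pts, meta)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Intensities (0-1) are quantized to 16 bits on write; a written stack
#' re-reads bit-exactly.
#'
#' @param stack a [render_frames()] result (or plain ny x nx x nt array).
#' @param path TIFF path.
#' @param pixel_size,frame_interval metadata for re-reading a plain TIFF.
#' @return `write_stack_tiff()` the path invisibly; `read_stack_tiff()` a
#'   `frame_stack` (without ground truth).
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  pages <- lapply(seq_len(dim(frames)[3]), function(k)
    round(frames[, , k] * 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, pixel_size = 0.1, frame_interval = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  structure(list(frames = frames,
                 times = (seq_along(pages) - 1) * frame_interval,
                 optics = optics_config(pixel_size = pixel_size,
                                        image_shape = dim(pages[[1]]),
                                        frame_interval = frame_interval),
                 ground_truth = NULL),
            class = "frame_stack")
}
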