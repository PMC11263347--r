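#' Trajectory set container
#'
#' A tidy container for linked single-cell trajectories: a long `points`
#' table (one row per trajectory-timepoint) and a `meta` table (one row
#' per trajectory).
#'
#' @param points data.frame with columns `traj_id, time, x, y, x1, y1,
#'   x2, y2, length, eccentricity`.
#' @param meta data.frame with columns `traj_id, agent_id, start_time,
#'   end_time, duration, end_reason`; `end_reason` is one of `division`,
#'   `detachment`, `censored_end_of_movie`, `lost` (or `NA` before event
#'   detection has run).
#' @return Object of class `trajectory_set`.
#' @export
trajectory_set <- function(points, meta) {
  need_p <- c("traj_id", "time", "x", "y", "x1", "y1", "x2", "y2", "length")
  miss <- setdiff(need_p, names(points))
  if (length(miss))
    stop("trajectory points table lacks columns: ", paste(miss, collapse = ", "))
  if (!"eccentricity" %in% names(points)) points$eccentricity <- NA_real_
  need_m <- c("traj_id", "start_time", "end_time", "duration", "end_reason")
  miss <- setdiff(need_m, names(meta))
  if (length(miss))
    stop("trajectory meta table lacks columns: ", paste(miss, collapse = ", "))
  if (!"agent_id" %in% names(meta)) meta$agent_id <- NA_integer_
  structure(list(points = points, meta = meta), class = "trajectory_set")
}

empty_trajectory_points <- function() {
  data.frame(traj_id = integer(), time = numeric(), x = numeric(),
             y = numeric(), x1 = numeric(), y1 = numeric(), x2 = numeric(),
             y2 = numeric(), length = numeric(), eccentricity = numeric())
}

empty_trajectory_meta <- function() {
  data.frame(traj_id = integer(), agent_id = integer(),
              start_time = numeric(), end_time = numeric(),
              duration = numeric(), end_reason = character(),
              stringsAsFactors = FALSE)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", nrow(x$meta), " trajectories, ",
      nrow(x$points), " points\n", sep = "")
  if (nrow(x$meta))
    print(table(x$meta$end_reason, useNA = "ifany"))
  invisible(x)
}

#' Linking configuration
#'
#' @param search_radius maximum link distance (um) between a predicted
#'   position and a detection.
#' @param memory_frames number of consecutive frames a trajectory may go
#'   undetected (flicker) and still be resumed.
#' @param use_motion_prediction constant-velocity extrapolation of the next
#'   position (otherwise the last position is used).
#' @param division_pair_radius radius (um) within which two new
#'   trajectories after a trajectory end are interpreted as daughters;
#'   default one cell length.
#' @param detach_displacement_threshold displacement (um) between
#'   successive positions above which a move is a detachment hop
#'   (high-frame-rate mode).
#' @return Object of class `link_config`.
#' @export
link_config <- function(search_radius = 1.5, memory_frames = 3L,
                        use_motion_prediction = TRUE,
                        division_pair_radius = 2,
                        detach_displacement_threshold = 5) {
  if (search_radius <= 0) stop("invalid config: search_radius must be > 0")
  if (memory_frames < 0) stop("invalid config: memory_frames must be >= 0")
  structure(list(search_radius = search_radius,
                 memory_frames = as.integer(memory_frames),
                 use_motion_prediction = isTRUE(use_motion_prediction),
                 division_pair_radius = division_pair_radius,
                 detach_displacement_threshold = detach_displacement_threshold),
            class = "link_config")
}

#' Link per-frame detections into trajectories
#'
#' Greedy frame-to-frame assignment: candidate (track, detection) pairs
#' within `search_radius` of the predicted position are linked in order of
#' increasing distance, each detection joining at most one trajectory.
#' Tracks missing from up to `memory_frames` consecutive frames are kept
#' open (gap closing); a link is withheld when a track meets two
#' half-length detections inside `division_pair_radius` (a completed
#' division: the mother trajectory ends, both daughters start fresh).
#' Pole labels are made consistent along each trajectory by
#' minimal-displacement matching against the previous frame.
#'
#' @param detections data.frame from [segment_stack()] (needs `frame`,
#'   `time`, `x`, `y`, `x1..y2`, `length`; `eccentricity` optional).
#' @param config a [link_config()].
#' @return A [trajectory_set()]. End reasons are `censored_end_of_movie`
#'   for trajectories reaching the final frame and `NA` otherwise until
#'   [detect_division_events()] / [detect_attach_detach_events()] assign
#'   them.
#' @export
link_trajectories <- function(detections, config) {
  stopifnot(inherits(config, "link_config"))
  if (!nrow(detections))
    return(trajectory_set(empty_trajectory_points(), empty_trajectory_meta()))
  if (!"eccentricity" %in% names(detections))
    detections$eccentricity <- NA_real_
  frames <- sort(unique(detections$frame))
  det_by_frame <- split(seq_len(nrow(detections)), detections$frame)

  n_alloc <- nrow(detections)
  pt_traj <- integer(n_alloc); pt_row <- integer(n_alloc); n_pt <- 0L
  # active track state
  tr_id <- integer(); tr_x <- tr_y <- tr_vx <- tr_vy <- numeric()
  tr_len <- numeric(); tr_last_frame <- integer()
  tr_p1x <- tr_p1y <- tr_p2x <- tr_p2y <- numeric()
  next_traj <- 1L
  add_point <- function(traj, row) {
    n_pt <<- n_pt + 1L
    pt_traj[n_pt] <<- traj; pt_row[n_pt] <<- row
  }

  for (f in frames) {
    # retire tracks whose gap exceeds the memory window before matching
    # (covers frames skipped entirely, e.g. when every cell flickered)
    if (length(tr_id)) {
      keep <- (f - tr_last_frame) <= (config$memory_frames + 1L)
      tr_id <- tr_id[keep]; tr_x <- tr_x[keep]; tr_y <- tr_y[keep]
      tr_vx <- tr_vx[keep]; tr_vy <- tr_vy[keep]; tr_len <- tr_len[keep]
      tr_last_frame <- tr_last_frame[keep]
      tr_p1x <- tr_p1x[keep]; tr_p1y <- tr_p1y[keep]
      tr_p2x <- tr_p2x[keep]; tr_p2y <- tr_p2y[keep]
    }
    rows <- det_by_frame[[as.character(f)]]
    dx <- detections$x[rows]; dy <- detections$y[rows]
    dlen <- detections$length[rows]
    matched_det <- rep(FALSE, length(rows))
    matched_tr <- rep(FALSE, length(tr_id))

    if (length(tr_id)) {
      gap <- f - tr_last_frame
      px <- tr_x + if (config$use_motion_prediction) tr_vx * gap else 0
      py <- tr_y + if (config$use_motion_prediction) tr_vy * gap else 0

      # division guard: a track facing >= 2 fresh half-length detections
      # within division_pair_radius has divided; close it, leave daughters
      divided <- rep(FALSE, length(tr_id))
      for (i in seq_along(tr_id)) {
        dd <- sqrt((dx - px[i])^2 + (dy - py[i])^2)
        half <- dd <= config$division_pair_radius & dlen < 0.7 * tr_len[i]
        if (sum(half) >= 2) divided[i] <- TRUE
      }

      cand_t <- integer(); cand_d <- integer(); cand_dist <- numeric()
      for (i in which(!divided)) {
        dd <- sqrt((dx - px[i])^2 + (dy - py[i])^2)
        ok <- which(dd <= config$search_radius)
        cand_t <- c(cand_t, rep(i, length(ok)))
        cand_d <- c(cand_d, ok)
        cand_dist <- c(cand_dist, dd[ok])
      }
      for (j in order(cand_dist)) {
        i <- cand_t[j]; d <- cand_d[j]
        if (matched_tr[i] || matched_det[d]) next
        matched_tr[i] <- TRUE; matched_det[d] <- TRUE
        row <- rows[d]
        gap_i <- f - tr_last_frame[i]
        tr_vx[i] <- (detections$x[row] - tr_x[i]) / gap_i
        tr_vy[i] <- (detections$y[row] - tr_y[i]) / gap_i
        tr_x[i] <- detections$x[row]; tr_y[i] <- detections$y[row]
        tr_len[i] <- detections$length[row]; tr_last_frame[i] <- f
        add_point(tr_id[i], row)
      }
    }

    # unmatched detections open new trajectories
    for (d in which(!matched_det)) {
      row <- rows[d]
      tr_id <- c(tr_id, next_traj)
      tr_x <- c(tr_x, detections$x[row]); tr_y <- c(tr_y, detections$y[row])
      tr_vx <- c(tr_vx, 0); tr_vy <- c(tr_vy, 0)
      tr_len <- c(tr_len, detections$length[row])
      tr_last_frame <- c(tr_last_frame, f)
      tr_p1x <- c(tr_p1x, 0); tr_p1y <- c(tr_p1y, 0)
      tr_p2x <- c(tr_p2x, 0); tr_p2y <- c(tr_p2y, 0)
      add_point(next_traj, row)
      next_traj <- next_traj + 1L
    }

  }

  pt_traj <- pt_traj[seq_len(n_pt)]; pt_row <- pt_row[seq_len(n_pt)]
  o <- order(pt_traj, detections$frame[pt_row])
  pts <- data.frame(traj_id = pt_traj[o],
                    time = detections$time[pt_row[o]],
                    x = detections$x[pt_row[o]], y = detections$y[pt_row[o]],
                    x1 = detections$x1[pt_row[o]], y1 = detections$y1[pt_row[o]],
                    x2 = detections$x2[pt_row[o]], y2 = detections$y2[pt_row[o]],
                    length = detections$length[pt_row[o]],
                    eccentricity = detections$eccentricity[pt_row[o]])
  pts <- match_poles(pts)
  tid <- unique(pts$traj_id)
  first_t <- tapply(pts$time, pts$traj_id, min)
  last_t <- tapply(pts$time, pts$traj_id, max)
  t_end <- max(detections$time)
  meta <- data.frame(traj_id = as.integer(names(first_t)),
                     agent_id = NA_integer_,
                     start_time = as.numeric(first_t),
                     end_time = as.numeric(last_t),
                     duration = as.numeric(last_t - first_t),
                     end_reason = ifelse(as.numeric(last_t) >= t_end,
                                         "censored_end_of_movie",
                                         NA_character_),
                     stringsAsFactors = FALSE)
  meta <- meta[order(meta$traj_id), ]
  rownames(meta) <- NULL
  trajectory_set(pts, meta)
}

# resolve the pole-labelling ambiguity (the ellipse axis is orientation-free)
# by minimal-displacement matching frame to frame within each trajectory
match_poles <- function(pts) {
  for (tid in unique(pts$traj_id)) {
    i <- which(pts$traj_id == tid)
    if (length(i) < 2) next
    for (k in i[-1]) {
      prev <- k - 1L
      straight <- (pts$x1[k] - pts$x1[prev])^2 + (pts$y1[k] - pts$y1[prev])^2 +
        (pts$x2[k] - pts$x2[prev])^2 + (pts$y2[k] - pts$y2[prev])^2
      crossed <- (pts$x1[k] - pts$x2[prev])^2 + (pts$y1[k] - pts$y2[prev])^2 +
        (pts$x2[k] - pts$x1[prev])^2 + (pts$y2[k] - pts$y1[prev])^2
      if (crossed < straight) {
        tmp <- pts[k, c("x1", "y1")]
        pts[k, c("x1", "y1")] <- pts[k, c("x2", "y2")]
        pts[k, c("x2", "y2")] <- tmp
      }
    }
  }
  pts
}

#' Detect division events among trajectory ends
#'
#' A trajectory end is a division when at least two new trajectories begin
#' within `division_pair_radius` of its endpoint in the next occupied
#' frame(s). Ambiguous multi-way matches are resolved by distance; the two
#' nearest starters become the daughters. Matched mothers get
#' `end_reason = "division"`.
#'
#' @param trajectories a [trajectory_set()].
#' @param config a [link_config()].
#' @param frame_interval frame spacing (min) used to bound "next occupied
#'   frame"; inferred from the data when `NULL`.
#' @return list with `events` (data.frame `mother_traj, daughter_a,
#'   daughter_b, time`) and the updated `trajectories`.
#' @export
detect_division_events <- function(trajectories, config,
                                   frame_interval = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  meta <- trajectories$meta; pts <- trajectories$points
  if (!nrow(meta))
    return(list(events = data.frame(mother_traj = integer(),
                                    daughter_a = integer(),
                                    daughter_b = integer(), time = numeric()),
                trajectories = trajectories))
  if (is.null(frame_interval)) {
    dts <- diff(sort(unique(pts$time)))
    frame_interval <- if (length(dts)) min(dts) else 1
  }
  horizon <- (config$memory_frames + 1.5) * frame_interval
  end_xy <- pts[!duplicated(pts$traj_id, fromLast = TRUE), ]
  start_xy <- pts[!duplicated(pts$traj_id), ]
  events <- list()
  taken <- integer()
  enders <- meta$traj_id[is.na(meta$end_reason) |
                           meta$end_reason != "censored_end_of_movie"]
  for (m in enders) {
    e <- end_xy[end_xy$traj_id == m, ]
    cand <- start_xy[start_xy$time > e$time &
                       start_xy$time <= e$time + horizon &
                       !(start_xy$traj_id %in% c(m, taken)), ]
    if (!nrow(cand)) next
    dd <- sqrt((cand$x - e$x)^2 + (cand$y - e$y)^2)
    near <- which(dd <= config$division_pair_radius)
    if (length(near) < 2) next
    near <- near[order(dd[near])][1:2]
    d_ids <- cand$traj_id[near]
    taken <- c(taken, d_ids)
    events[[length(events) + 1L]] <-
      data.frame(mother_traj = m, daughter_a = d_ids[1],
                 daughter_b = d_ids[2], time = min(cand$time[near]))
    meta$end_reason[meta$traj_id == m] <- "division"
  }
  ev <- if (length(events)) do.call(rbind, events)
  else data.frame(mother_traj = integer(), daughter_a = integer(),
                  daughter_b = integer(), time = numeric())
  trajectories$meta <- meta
  list(events = ev, trajectories = trajectories)
}

#' Detect detachment and attachment events (high-frame-rate mode)
#'
#' After division matching, a trajectory end that is not a division and
#' does not reach the end of the movie is a detachment; a trajectory start
#' that is not a daughter of a division and does not coincide with the
#' first frame is an attachment. A within-trajectory displacement larger
#' than `detach_displacement_threshold` between successive positions also
#' counts as a detach-reattach pair (the cell hopped downstream within one
#' frame).
#'
#' @param trajectories a [trajectory_set()].
#' @param config a [link_config()].
#' @param division_events the `events` table from
#'   [detect_division_events()], or `NULL` to detect divisions first.
#' @return list with `events` (data.frame `time, type, traj_id`), `series`
#'   (data.frame `time, N_d, N_a` of cumulative counts on the frame grid)
#'   and the updated `trajectories`.
#' @export
detect_attach_detach_events <- function(trajectories, config,
                                        division_events = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (is.null(division_events)) {
    dd <- detect_division_events(trajectories, config)
    division_events <- dd$events
    trajectories <- dd$trajectories
  }
  meta <- trajectories$meta; pts <- trajectories$points
  times <- sort(unique(pts$time))
  if (!nrow(meta))
    return(list(events = data.frame(time = numeric(), type = character(),
                                    traj_id = integer()),
                series = data.frame(time = times, N_d = numeric(0),
                                    N_a = numeric(0)),
                trajectories = trajectories))
  t_start <- min(times); t_end <- max(times)
  daughters <- c(division_events$daughter_a, division_events$daughter_b)
  ev <- list()
  for (j in seq_len(nrow(meta))) {
    m <- meta[j, ]
    if (is.na(m$end_reason)) {
      meta$end_reason[j] <- "detachment"
      ev[[length(ev) + 1L]] <- data.frame(time = m$end_time,
                                          type = "detach",
                                          traj_id = m$traj_id)
    }
    if (m$start_time > t_start && !(m$traj_id %in% daughters))
      ev[[length(ev) + 1L]] <- data.frame(time = m$start_time,
                                          type = "attach",
                                          traj_id = m$traj_id)
  }
  # intra-trajectory hops larger than the displacement threshold
  step_ok <- which(diff(pts$traj_id) == 0)
  if (length(step_ok)) {
    step <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)[step_ok]
    hop <- step_ok[step > config$detach_displacement_threshold]
    for (k in hop) {
      ev[[length(ev) + 1L]] <- data.frame(time = pts$time[k + 1],
                                          type = "detach",
                                          traj_id = pts$traj_id[k])
      ev[[length(ev) + 1L]] <- data.frame(time = pts$time[k + 1],
                                          type = "attach",
                                          traj_id = pts$traj_id[k])
    }
  }
  ev <- if (length(ev)) do.call(rbind, ev)
  else data.frame(time = numeric(), type = character(), traj_id = integer())
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  N_d <- vapply(times, function(t) sum(ev$type == "detach" & ev$time <= t),
                numeric(1))
  N_a <- vapply(times, function(t) sum(ev$type == "attach" & ev$time <= t),
                numeric(1))
  trajectories$meta <- meta
  list(events = ev, series = data.frame(time = times, N_d = N_d, N_a = N_a),
       trajectories = trajectories)
}
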