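#' Mean square displacement of a trajectory at one lag
#'
#' The time-averaged squared displacement over a lag `tau = k * dt`:
#' `sum_{i=1}^{N-k} (x_{i+k} - x_i)^2 / norm`. Two normalizations are
#' provided: `"printed"` divides by the number of trajectory points `N`
#' (a convention sometimes printed in the field), `"pairs"` divides by
#' the number of summed pairs `N - k` (the standard time-average, and the
#' one the trajectory classifier evaluates at the maximal lag, where the
#' sum has a single term).
#'
#' @param x,y coordinate vectors of the trajectory (um), equally spaced in
#'   time.
#' @param k integer lag in frames, `1 <= k <= N - 1`.
#' @param normalization `"printed"` (1/N) or `"pairs"` (1/(N-k)).
#' @return MSD (um^2).
#' @export
msd_at_lag <- function(x, y, k, normalization = c("printed", "pairs")) {
  normalization <- match.arg(normalization)
  n <- length(x)
  if (k < 1 || k > n - 1)
    stop("undefined lag: k must satisfy 1 <= k <= N - 1 (got k = ", k,
         ", N = ", n, ")")
  i <- seq_len(n - k)
  s <- sum((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  s / if (normalization == "printed") n else (n - k)
}

#' MSD curve of one trajectory
#'
#' Evaluates [msd_at_lag()] at every available lag. By construction
#' `msd(0) = 0` and lags are bounded by the trajectory duration.
#'
#' @param x,y coordinate vectors (um).
#' @param dt frame interval (min).
#' @param normalization see [msd_at_lag()].
#' @return data.frame `tau` (min), `msd` (um^2), `n_pairs`.
#' @export
msd_curve <- function(x, y, dt = 1, normalization = c("printed", "pairs")) {
  normalization <- match.arg(normalization)
  n <- length(x)
  if (n < 2)
    return(data.frame(tau = 0, msd = 0, n_pairs = 0L))
  ks <- seq_len(n - 1)
  data.frame(tau = c(0, ks * dt),
             msd = c(0, vapply(ks, function(k)
               msd_at_lag(x, y, k, normalization), numeric(1))),
             n_pairs = c(n, n - ks))
}

#' Classifier parameters for the MSD phenotype call
#'
#' @param msd_threshold end-of-trajectory MSD above which a trajectory is
#'   a divider (um^2); default `(0.5 um)^2`.
#' @param min_duration minimal duration (min) for a low-MSD trajectory to
#'   be called a non-divider rather than censored; default the mean
#'   division time, 40 min (shorter low-MSD trajectories may be
#'   pre-division detachments).
#' @param lag_divider_cutoff division time (min) above which a divider is
#'   a lagged divider; default 160 min.
#' @return Object of class `classifier_params`.
#' @export
classifier_params <- function(msd_threshold = 0.25, min_duration = 40,
                              lag_divider_cutoff = 160) {
  if (msd_threshold <= 0) stop("invalid params: msd_threshold must be > 0")
  if (min_duration <= 0) stop("invalid params: min_duration must be > 0")
  if (lag_divider_cutoff <= min_duration)
    stop("invalid params: lag_divider_cutoff must exceed min_duration")
  structure(list(msd_threshold = msd_threshold, min_duration = min_duration,
                 lag_divider_cutoff = lag_divider_cutoff),
            class = "classifier_params")
}

#' Classify one trajectory as divider / non-divider / censored
#'
#' The end-of-trajectory MSD (evaluated at the maximal lag `tau = T`,
#' i.e. the squared displacement between the first and last positions)
#' is compared to `msd_threshold`: above it the cell was elongating and
#' dividing; below it the trajectory is a non-divider when longer than
#' `min_duration`, and censored otherwise (too short to tell a
#' non-divider from a pre-division detachment).
#'
#' @param x,y coordinate vectors (um).
#' @param dt frame interval (min).
#' @param params a [classifier_params()].
#' @return One-row data.frame: `call`, `end_msd` (um^2), `duration_T` (min).
#' @export
classify_phenotype <- function(x, y, dt = 1, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  n <- length(x)
  if (n < 2)
    return(data.frame(call = "censored", end_msd = NA_real_, duration_T = 0))
  end_msd <- msd_at_lag(x, y, n - 1L, normalization = "pairs")
  duration <- (n - 1) * dt
  call <- if (end_msd > params$msd_threshold) "divider"
  else if (duration > params$min_duration) "non_divider"
  else "censored"
  data.frame(call = call, end_msd = end_msd, duration_T = duration,
             stringsAsFactors = FALSE)
}

#' Classify every trajectory of a set
#'
#' @param trajectories a [trajectory_set()].
#' @param params a [classifier_params()].
#' @return data.frame with one row per trajectory: `traj_id`, `call`,
#'   `end_msd`, `duration_T`, `end_reason`.
#' @export
classify_trajectories <- function(trajectories, params = classifier_params()) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  pts <- trajectories$points
  out <- lapply(split(seq_len(nrow(pts)), pts$traj_id), function(i) {
    dt <- if (length(i) > 1) min(diff(pts$time[i])) else 1
    cbind(traj_id = pts$traj_id[i[1]],
          classify_phenotype(pts$x[i], pts$y[i], dt, params))
  })
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  merge(calls, trajectories$meta[, c("traj_id", "end_reason")],
        by = "traj_id", all.x = TRUE, sort = TRUE)
}

#' Partition division times into continuous and lagged dividers
#'
#' Division times above `lag_divider_cutoff` depart from the exponential
#' bulk and define the lagged-divider subgroup.
#'
#' @param division_times vector of division times (min).
#' @param cutoff lagged cutoff (min).
#' @return list `continuous`, `lagged` (the partitioned values) and
#'   `lagged_fraction`.
#' @export
identify_lagged_dividers <- function(division_times, cutoff = 160) {
  division_times <- division_times[is.finite(division_times)]
  if (!length(division_times))
    return(list(continuous = numeric(), lagged = numeric(),
                lagged_fraction = NA_real_))
  lagged <- division_times > cutoff
  list(continuous = division_times[!lagged], lagged = division_times[lagged],
       lagged_fraction = mean(lagged))
}

#' Pole and centroid displacement statistics of a trajectory
#'
#' Total travelled path (sum of per-frame step lengths) of each pole and
#' of the centroid, after correcting pole-label flips by
#' minimal-displacement matching. The pole with the larger total
#' displacement is `max`, the other `min` — assigned per bacterium, not
#' per frame.
#'
#' @param pts data.frame with columns `x, y, x1, y1, x2, y2` ordered in
#'   time (one trajectory).
#' @return list `max_pole_disp`, `min_pole_disp`, `centroid_disp`,
#'   `ratio_max`, `ratio_min` (pole over centroid displacement),
#'   `ratio_min_max` (min over max pole).
#' @export
pole_displacement_stats <- function(pts) {
  need <- c("x", "y", "x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(pts))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(pts) < 2)
    return(list(max_pole_disp = 0, min_pole_disp = 0, centroid_disp = 0,
                ratio_max = NA_real_, ratio_min = NA_real_,
                ratio_min_max = NA_real_))
  pts$traj_id <- 1L
  pts <- match_poles(pts)
  path <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))
  p1 <- path(pts$x1, pts$y1); p2 <- path(pts$x2, pts$y2)
  pc <- path(pts$x, pts$y)
  mx <- max(p1, p2); mn <- min(p1, p2)
  list(max_pole_disp = mx, min_pole_disp = mn, centroid_disp = pc,
       ratio_max = if (pc > 0) mx / pc else NA_real_,
       ratio_min = if (pc > 0) mn / pc else NA_real_,
       ratio_min_max = if (mx > 0) mn / mx else NA_real_)
}

#' Time-resolved divider fraction from trajectory displacement crossings
#'
#' Cumulative divider / non-divider counting over observation time:
#' a trajectory joins the divider count at the first time its
#' displacement from the starting position exceeds `sqrt(msd_threshold)`
#' (dividing cells elongate about one cell length with one pole anchored,
#' so their centroid crosses this level before separation); a trajectory
#' that has not crossed counts as a non-divider once it is older than
#' `min_duration`. The fraction is the ratio of cumulative divider count
#' to classified cells at each frame.
#'
#' @param trajectories a [trajectory_set()].
#' @param params a [classifier_params()].
#' @param times evaluation time grid (min); default every frame time.
#' @return data.frame `time, n_divider, n_non_divider, fraction`.
#' @export
divider_fraction_series <- function(trajectories,
                                    params = classifier_params(),
                                    times = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  pts <- trajectories$points
  if (is.null(times)) times <- sort(unique(pts$time))
  r_thresh <- sqrt(params$msd_threshold)
  i0 <- which(!duplicated(pts$traj_id))
  x0 <- pts$x[i0][match(pts$traj_id, pts$traj_id[i0])]
  y0 <- pts$y[i0][match(pts$traj_id, pts$traj_id[i0])]
  crossed <- sqrt((pts$x - x0)^2 + (pts$y - y0)^2) > r_thresh
  cross_time <- suppressWarnings(
    tapply(ifelse(crossed, pts$time, Inf), pts$traj_id, min))
  start_time <- tapply(pts$time, pts$traj_id, min)
  end_time <- tapply(pts$time, pts$traj_id, max)
  n_div <- vapply(times, function(t) sum(cross_time <= t), numeric(1))
  n_non <- vapply(times, function(t)
    sum(cross_time > t & (pmin(t, end_time) - start_time) > params$min_duration),
    numeric(1))
  frac <- ifelse(n_div + n_non > 0, n_div / (n_div + n_non), NA_real_)
  data.frame(time = times, n_divider = n_div, n_non_divider = n_non,
             fraction = frac)
}
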