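#' Per-frame population series from a trajectory set
#'
#' Attached-cell count per frame (number of trajectory points), optionally
#' merged with cumulative detachment / attachment counts from
#' [detect_attach_detach_events()].
#'
#' @param trajectories a [trajectory_set()].
#' @param events_series optional data.frame `time, N_d, N_a`.
#' @param times frame grid (min); default the observed point times.
#' @return data.frame `time, N, N_d, N_a`.
#' @export
population_series <- function(trajectories, events_series = NULL,
                              times = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  pts <- trajectories$points
  if (is.null(times)) times <- sort(unique(pts$time))
  N <- as.numeric(table(factor(pts$time, levels = times)))
  out <- data.frame(time = times, N = N, N_d = 0, N_a = 0)
  if (!is.null(events_series)) {
    k <- findInterval(times, events_series$time)
    out$N_d <- c(0, events_series$N_d)[k + 1]
    out$N_a <- c(0, events_series$N_a)[k + 1]
  }
  out
}

#' Birth-class partition of the attached population
#'
#' Tags every trajectory by the interval of its birth (trajectory start)
#' in successive windows of `interval` minutes and counts, per frame, the
#' attached cells of each class. Cells already attached at the start of
#' the movie carry class 1 (the first interval). Birth times beyond the
#' class range are clipped into the last class with a warning.
#'
#' @param trajectories a [trajectory_set()].
#' @param interval class width (min); the mean division time.
#' @param n_classes number of classes.
#' @param times frame grid (min).
#' @return matrix of counts, `length(times)` rows x `n_classes` columns;
#'   row sums equal the attached count per frame.
#' @export
birth_class_partition <- function(trajectories, interval = 40,
                                  n_classes = 9L, times = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  pts <- trajectories$points
  meta <- trajectories$meta
  if (is.null(times)) times <- sort(unique(pts$time))
  birth <- meta$start_time[match(pts$traj_id, meta$traj_id)]
  cls <- pmax(1L, ceiling(birth / interval + 1e-9))
  cls[birth == 0] <- 1L
  if (any(cls > n_classes)) {
    warning("birth times beyond the class range; clipped to class ",
            n_classes)
    cls <- pmin(cls, n_classes)
  }
  counts <- table(factor(pts$time, levels = times),
                  factor(cls, levels = seq_len(n_classes)))
  m <- matrix(as.numeric(counts), nrow = length(times),
              dimnames = list(NULL, paste0("class_", seq_len(n_classes))))
  m
}

#' Observed population growth rate
#'
#' The time-averaged per-capita growth rate of the attached count,
#' estimated as the least-squares slope of `ln N` versus time over the
#' fit window (equivalent to fitting `N = N0 exp(eta t)`). An
#' instantaneous-average variant, `mean((1/N) dN/dt)` over finite
#' differences, is available for comparison.
#'
#' @param series data.frame with `time` (min) and `N`.
#' @param window numeric length-2 fit window (min).
#' @param method `"logfit"` (default) or `"instantaneous"`.
#' @return list `eta` (1/h), `se` (1/h), `window`, `method`.
#' @export
observed_growth_rate <- function(series, window = c(80, max(series$time)),
                                 method = c("logfit", "instantaneous")) {
  method <- match.arg(method)
  sel <- series$time >= window[1] & series$time <= window[2]
  s <- series[sel, , drop = FALSE]
  if (nrow(s) < 3) stop("fit window shorter than 3 frames")
  if (any(s$N <= 0)) stop("N must be positive over the fit window")
  if (method == "logfit") {
    fit <- stats::lm(log(N) ~ time, data = s)
    eta <- unname(stats::coef(fit)[2]) * 60
    # exact exponential input produces a perfect fit; the summary warning
    # about it is not informative here
    se <- suppressWarnings(summary(fit)$coefficients[2, 2]) * 60
  } else {
    dN <- diff(s$N); dtv <- diff(s$time)
    inst <- (dN / dtv) / s$N[-nrow(s)]
    eta <- mean(inst) * 60
    se <- stats::sd(inst) / sqrt(length(inst)) * 60
  }
  list(eta = eta, se = se, window = window, method = method)
}

#' Detachment and attachment ratios
#'
#' Pointwise `R_d(t) = N_d(t) / N(t)` (cumulative detachments over the
#' current attached count) and `R_a(t) = N_a(t) / N_d(t)` (fraction of
#' detached cells that reattached; undefined where no detachment has
#' occurred yet), plus experiment-level summaries.
#'
#' @param series data.frame `time, N, N_d, N_a`.
#' @return list `series` (with `R_d`, `R_a` columns), `R_d_mean`,
#'   `R_a_mean` (time averages over defined values), `R_d_end`, `R_a_end`.
#' @export
detachment_attachment_ratios <- function(series) {
  stopifnot(all(c("time", "N", "N_d", "N_a") %in% names(series)))
  if (any(diff(series$N_d) < 0) || any(diff(series$N_a) < 0))
    stop("cumulative counts N_d, N_a must be non-decreasing")
  R_d <- ifelse(series$N > 0, series$N_d / series$N, NA_real_)
  R_a <- ifelse(series$N_d > 0, series$N_a / series$N_d, NA_real_)
  s <- cbind(series, R_d = R_d, R_a = R_a)
  last <- nrow(s)
  list(series = s,
       R_d_mean = mean(R_d, na.rm = TRUE),
       R_a_mean = if (all(is.na(R_a))) NA_real_ else mean(R_a, na.rm = TRUE),
       R_d_end = R_d[last], R_a_end = R_a[last])
}

#' Decompose the effective growth rate
#'
#' Assembles the effective per-capita division rate
#' `eta_eff = eta + eta_d - eta_a`, where the detachment and attachment
#' rates are time-averaged per-capita event rates over the same window:
#' left-aligned finite differences of the cumulative counts divided by the
#' current attached count.
#'
#' @param eta result of [observed_growth_rate()] (or a plain rate in 1/h).
#' @param series data.frame `time, N, N_d, N_a`.
#' @param window numeric length-2 window (min); defaults to `eta$window`
#'   when available.
#' @return Object of class `rate_estimates`: list `eta, eta_se, eta_d,
#'   eta_a, eta_eff` (1/h), `R_d, R_a` (end-of-window ratios), `window`.
#' @export
rate_decomposition <- function(eta, series, window = NULL) {
  if (is.list(eta)) {
    if (is.null(window)) window <- eta$window
    eta_se <- eta$se; eta <- eta$eta
  } else eta_se <- NA_real_
  if (is.null(window)) window <- range(series$time)
  sel <- which(series$time >= window[1] & series$time <= window[2])
  if (length(sel) < 2) stop("window must contain at least 2 frames")
  s <- series[sel, , drop = FALSE]
  dtv <- diff(s$time)
  head_i <- seq_len(nrow(s) - 1)
  per_capita <- function(cum) mean((diff(cum) / dtv) / s$N[head_i]) * 60
  eta_d <- per_capita(s$N_d)
  eta_a <- per_capita(s$N_a)
  last <- nrow(s)
  structure(list(eta = eta, eta_se = eta_se, eta_d = eta_d, eta_a = eta_a,
                 eta_eff = eta + eta_d - eta_a,
                 R_d = if (s$N[last] > 0) s$N_d[last] / s$N[last] else NA_real_,
                 R_a = if (s$N_d[last] > 0) s$N_a[last] / s$N_d[last] else NA_real_,
                 window = window), class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf(paste0("<rate_estimates> eta = %.3f, eta_d = %.3f, ",
                     "eta_a = %.3f, eta_eff = %.3f (1/h); R_d = %.3f, ",
                     "R_a = %s\n"),
              x$eta, x$eta_d, x$eta_a, x$eta_eff, x$R_d,
              ifelse(is.na(x$R_a), "undefined", sprintf("%.3f", x$R_a))))
  invisible(x)
}

# truncated-exponential maximum likelihood: rate of an exponential law
# observed only on [floor, floor + span]; solves the score equation
# 1/lambda = mean(tau - floor) + span * exp(-l*span) / (1 - exp(-l*span))
fit_truncated_exponential <- function(tau, floor_ = 0, span = Inf) {
  tau <- tau - floor_
  m <- mean(tau)
  if (!is.finite(span)) return(1 / m)
  score <- function(l) 1 / l - m - span * exp(-l * span) / (1 - exp(-l * span))
  stats::uniroot(score, interval = c(1e-8, 1e3), tol = 1e-12)$root
}

#' Division-time statistics
#'
#' Fits the exponential (Poisson-process) division-time law to the bulk of
#' the distribution (division times at or below the lagged cutoff) by
#' truncated-exponential maximum likelihood, reports the lagged fraction,
#' and — when birth times are supplied — the mean division time per birth
#' observation bin (which relaxes to the continuous-divider mean as the
#' initial lagged cohort divides out).
#'
#' @param division_times vector of division times (min).
#' @param birth_times optional vector (same length) of the times the
#'   dividing cells appeared.
#' @param observation_bin width (min) of the birth-time bins.
#' @param lag_cutoff lagged-divider cutoff (min).
#' @param floor_ left end of the fitted support (min); 0 fits the plain
#'   exponential bulk.
#' @return list `lambda_hat` (1/min), `mean_division_time` (= 1 /
#'   lambda_hat + floor, min), `lagged_fraction_hat`, `n`, `degenerate`
#'   (zero-variance flag), and `mean_vs_observation_time` (data.frame
#'   `bin_start, bin_mid, mean_tau, n` or `NULL`).
#' @export
division_time_statistics <- function(division_times, birth_times = NULL,
                                     observation_bin = 40, lag_cutoff = 160,
                                     floor_ = 0) {
  tau <- division_times[is.finite(division_times)]
  if (length(tau) < 10)
    stop("need at least 10 division-time samples for fitting")
  bulk <- tau[tau <= lag_cutoff & tau > floor_]
  if (!length(bulk))
    stop("fit refused: all division times exceed the lagged cutoff of ",
         lag_cutoff, " min")
  degenerate <- stats::sd(bulk) == 0
  lambda_hat <- if (degenerate) 1 / (mean(bulk) - floor_)
  else fit_truncated_exponential(bulk, floor_, lag_cutoff - floor_)
  if (degenerate)
    warning("degenerate division-time sample (zero variance); ",
            "rate set to 1/mean")
  mvt <- NULL
  if (!is.null(birth_times)) {
    stopifnot(length(birth_times) == length(division_times))
    bt <- birth_times[is.finite(division_times)]
    bin <- floor(bt / observation_bin)
    agg <- tapply(tau, bin, mean)
    cnt <- tapply(tau, bin, length)
    b0 <- as.numeric(names(agg)) * observation_bin
    mvt <- data.frame(bin_start = b0, bin_mid = b0 + observation_bin / 2,
                      mean_tau = as.numeric(agg), n = as.numeric(cnt))
  }
  list(lambda_hat = lambda_hat,
       mean_division_time = 1 / lambda_hat + floor_,
       lagged_fraction_hat = mean(tau > lag_cutoff),
       n = length(tau), degenerate = degenerate,
       mean_vs_observation_time = mvt)
}
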