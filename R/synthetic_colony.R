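#' Simulation configuration for the synthetic colony generator
#'
#' Parameters of the agent-based surface-colonization model. Three
#' phenotypes coexist: continuous dividers (exponential division clock),
#' lagged dividers (a fixed delay followed by the same clock) and
#' non-dividers (never divide, strongly anchored by both poles). At each
#' division both daughters independently become dividers with probability
#' `divider_fraction_f`, otherwise non-dividers.
#'
#' The division clock is `division_time_floor + Exp(mean_division_time -
#' division_time_floor)`, i.e. an exponential left-truncated at the floor
#' and parameterised so that its realized mean equals
#' `mean_division_time`. `clock = "fixed"` replaces the draw by the mean
#' (zero-variance mode, under which the population grows in synchronous
#' generations).
#'
#' @param divider_fraction_f probability that a daughter is a divider.
#' @param mean_division_time mean division time of continuous dividers (min).
#' @param model_division_time generation time used when emulating the
#'   divider-fraction growth model fit (min); kept distinct from
#'   `mean_division_time` on purpose.
#' @param lagged_fraction fraction of *initial* dividers that are lagged.
#' @param daughter_lagged_fraction fraction of newborn dividers that are
#'   lagged (0 by default: the lag is an initial-attachment phenotype, which
#'   is what makes the population mean division time relax to the
#'   continuous-divider mean as the initial lagged cohort divides out).
#' @param lagged_delay fixed lag before a lagged divider's clock starts
#'   (min). The default places the initial-population mean division time,
#'   `(1 - lagged_fraction) * 40 + lagged_fraction * (lagged_delay + 40)`,
#'   inside the observed 65-105 min band.
#' @param division_time_floor minimal division time (min).
#' @param clock `"exponential"` (default) or `"fixed"` (zero variance).
#' @param initial_phase `"newborn"` starts every initial cell at the top of
#'   its cycle (synchronous); `"uniform"` draws a uniform random cell-cycle
#'   phase for initial cells (asynchronous attachment, the realistic
#'   condition for rate estimation).
#' @param detachment_rate per-cell Poisson detachment rate (1/h).
#' @param reattachment_prob probability that a detached cell reattaches.
#' @param reattachment_offset range (um) of the downstream displacement at
#'   reattachment.
#' @param anchored_pole_jitter,free_pole_jitter per-coordinate random-walk
#'   step (um/frame) of a divider's anchored and free pole.
#' @param nondivider_jitter per-coordinate random-walk step (um/frame) of
#'   both poles of a non-divider.
#' @param initial_density initial surface density (cells/um^2).
#' @param domain_size domain width and height (um).
#' @param cell_length,cell_width newborn cell length and width (um).
#' @param frame_interval time between recorded frames (min).
#' @param duration simulated time (min).
#' @param resolve_overlaps resolve capsule overlaps by axial push (dividers
#'   yield, doubly anchored non-dividers resist). Required for rendered
#'   stacks where touching cells would merge; can be disabled for
#'   event-level studies where geometry is irrelevant.
#' @param seed RNG seed (single stream for all draws).
#' @param record_states keep the per-frame state table (set `FALSE` for
#'   event-level studies at large population sizes).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(divider_fraction_f = 0.8,
                       mean_division_time = 40,
                       model_division_time = 52,
                       lagged_fraction = 0.125,
                       daughter_lagged_fraction = 0,
                       lagged_delay = 260,
                       division_time_floor = 20,
                       clock = c("exponential", "fixed"),
                       initial_phase = c("newborn", "uniform"),
                       detachment_rate = 0,
                       reattachment_prob = 0.5,
                       reattachment_offset = c(5, 10),
                       anchored_pole_jitter = 0.04,
                       free_pole_jitter = 0.08,
                       nondivider_jitter = 0.004,
                       initial_density = 1e-2,
                       domain_size = c(100, 100),
                       cell_length = 2,
                       cell_width = 1,
                       frame_interval = 1,
                       duration = 360,
                       resolve_overlaps = TRUE,
                       seed = 1L,
                       record_states = TRUE) {
  clock <- match.arg(clock)
  initial_phase <- match.arg(initial_phase)
  probs <- c(divider_fraction_f, lagged_fraction, daughter_lagged_fraction,
             reattachment_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("invalid config: probabilities must lie in [0, 1]")
  durs <- c(mean_division_time, model_division_time, lagged_delay,
            division_time_floor, frame_interval, duration)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("invalid config: durations must be strictly positive")
  if (division_time_floor >= mean_division_time)
    stop("invalid config: division_time_floor must be < mean_division_time")
  jit <- c(anchored_pole_jitter, free_pole_jitter, nondivider_jitter)
  if (any(!is.finite(jit)) || any(jit < 0))
    stop("invalid config: jitters must be >= 0")
  if (initial_density > 0 && initial_density * prod(domain_size) < 1)
    stop("invalid config: domain too small for at least one initial agent")
  structure(list(
    divider_fraction_f = divider_fraction_f,
    mean_division_time = mean_division_time,
    model_division_time = model_division_time,
    lagged_fraction = lagged_fraction,
    daughter_lagged_fraction = daughter_lagged_fraction,
    lagged_delay = lagged_delay,
    division_time_floor = division_time_floor,
    clock = clock,
    initial_phase = initial_phase,
    detachment_rate = detachment_rate,
    reattachment_prob = reattachment_prob,
    reattachment_offset = reattachment_offset,
    anchored_pole_jitter = anchored_pole_jitter,
    free_pole_jitter = free_pole_jitter,
    nondivider_jitter = nondivider_jitter,
    initial_density = initial_density,
    domain_size = domain_size,
    cell_length = cell_length,
    cell_width = cell_width,
    frame_interval = frame_interval,
    duration = duration,
    resolve_overlaps = isTRUE(resolve_overlaps),
    seed = as.integer(seed),
    record_states = isTRUE(record_states)), class = "sim_config")
}

# point-to-segment distances, vectorised over (px, py) with segment arrays
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  tt <- ifelse(l2 > 0, pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2)), 0)
  sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
}

# hard-overlap resolution by axial push: capsules whose spines come closer
# than ~the cell width are translated apart along their centroid line; one
# relaxation pass per frame (residual overlaps decay over successive frames)
push_apart <- function(ax, ay, fx, fy, idx, width, movable, bin = 6) {
  n <- length(idx)
  if (n < 2) return(list(ax = ax, ay = ay, fx = fx, fy = fy))
  cx <- (ax[idx] + fx[idx]) / 2; cy <- (ay[idx] + fy[idx]) / 2
  bx <- floor(cx / bin); by <- floor(cy / bin)
  key <- paste(bx, by)
  cand_i <- integer(); cand_j <- integer()
  members <- split(seq_len(n), key)
  # pairs within a bin and across the 4 forward-neighbour bins
  keymap <- new.env(hash = TRUE)
  for (k in names(members)) assign(k, members[[k]], envir = keymap)
  for (k in names(members)) {
    v <- members[[k]]
    if (length(v) > 1) {
      pr <- utils::combn(v, 2)
      cand_i <- c(cand_i, pr[1, ]); cand_j <- c(cand_j, pr[2, ])
    }
    b <- strsplit(k, " ")[[1]]
    bxk <- as.numeric(b[1]); byk <- as.numeric(b[2])
    for (nb in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      kk <- paste(bxk + nb[1], byk + nb[2])
      w <- if (exists(kk, envir = keymap, inherits = FALSE))
        get(kk, envir = keymap) else NULL
      if (length(w)) {
        cand_i <- c(cand_i, rep(v, each = length(w)))
        cand_j <- c(cand_j, rep(w, length(v)))
      }
    }
  }
  if (!length(cand_i)) return(list(ax = ax, ay = ay, fx = fx, fy = fy))
  gi <- idx[cand_i]; gj <- idx[cand_j]
  # spine-spine distance as the min over the four endpoint projections
  d <- pmin(
    point_seg_dist(ax[gi], ay[gi], ax[gj], ay[gj], fx[gj], fy[gj]),
    point_seg_dist(fx[gi], fy[gi], ax[gj], ay[gj], fx[gj], fy[gj]),
    point_seg_dist(ax[gj], ay[gj], ax[gi], ay[gi], fx[gi], fy[gi]),
    point_seg_dist(fx[gj], fy[gj], ax[gi], ay[gi], fx[gi], fy[gi]))
  # spine-to-spine clearance: one cell width plus a quarter-width gap so
  # that rendered capsule surfaces stay resolvable
  clearance <- 1.25 * width
  ov <- which(d < clearance)
  for (p in ov) {
    i <- gi[p]; j <- gj[p]
    # doubly anchored non-dividers resist pushing; dividers yield
    mi <- movable[i]; mj <- movable[j]
    if (!mi && !mj) next
    vx <- (ax[j] + fx[j] - ax[i] - fx[i]) / 2
    vy <- (ay[j] + fy[j] - ay[i] - fy[i]) / 2
    nv <- sqrt(vx^2 + vy^2)
    if (nv == 0) { vx <- 1; vy <- 0; nv <- 1 }
    sh <- clearance - d[p]
    shi <- if (mi && mj) sh / 2 else if (mi) sh else 0
    shj <- if (mi && mj) sh / 2 else if (mj) sh else 0
    ax[i] <- ax[i] - shi * vx / nv; fx[i] <- fx[i] - shi * vx / nv
    ay[i] <- ay[i] - shi * vy / nv; fy[i] <- fy[i] - shi * vy / nv
    ax[j] <- ax[j] + shj * vx / nv; fx[j] <- fx[j] + shj * vx / nv
    ay[j] <- ay[j] + shj * vy / nv; fy[j] <- fy[j] + shj * vy / nv
  }
  list(ax = ax, ay = ay, fx = fx, fy = fy)
}

# division clock draw: floor + exponential with realized mean = mean;
# "fixed" mode returns the mean itself
draw_division_time <- function(n, config, mean = config$mean_division_time) {
  if (config$clock == "fixed") return(rep(mean, n))
  config$division_time_floor +
    stats::rexp(n, rate = 1 / (mean - config$division_time_floor))
}

#' Simulate a surface-attached colony under flow
#'
#' Agent-based generator of a colonization history: rod-shaped cells on a
#' flat domain elongate linearly from one to two cell lengths with their
#' anchored pole fixed, divide into two end-to-end daughters, stochastically
#' produce non-dividing daughters, detach as Poisson events and reattach
#' downstream with a configurable probability. The returned history is
#' ground truth for every downstream analysis stage.
#'
#' @param config a [sim_config()].
#' @param division_time_mean override the continuous-divider clock mean
#'   (min); defaults to `config$mean_division_time`.
#' @return An object of class `colony_history`: a list with
#'   \describe{
#'     \item{agents}{one row per agent: `id`, `mother_id`, `phenotype`,
#'       `birth_time`, `anchored_pole_id`, `division_due`.}
#'     \item{states}{per-frame table `time, agent_id, x1, y1, x2, y2, xc,
#'       yc, length` (um), empty if `record_states = FALSE`.}
#'     \item{events}{ordered log `time, event, agent_id` with events
#'       `birth`, `division_complete`, `detach`, `reattach`.}
#'     \item{times}{the frame time grid (min).}
#'     \item{config}{the configuration echo.}
#'   }
#' @export
simulate_colony <- function(config, division_time_mean = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dt <- config$frame_interval
  times <- seq(0, config$duration, by = dt)
  W <- config$domain_size[1]; H <- config$domain_size[2]
  L0 <- config$cell_length
  mean_tau <- if (is.null(division_time_mean)) config$mean_division_time else division_time_mean
  cl_draw <- function(n) {
    if (config$clock == "fixed") rep(mean_tau, n)
    else config$division_time_floor +
      stats::rexp(n, 1 / (mean_tau - config$division_time_floor))
  }

  ## ---- initial population ----
  n0 <- round(config$initial_density * W * H)
  margin <- L0 * 1.5
  # sequential minimum-distance sampling: freshly attached cells do not
  # overlap (centres at least 1.75 cell lengths apart when space allows)
  min_d2 <- (1.75 * L0)^2
  xc <- yc <- numeric(n0)
  for (i in seq_len(n0)) {
    for (try in 1:200) {
      px_ <- stats::runif(1, margin, W - margin)
      py_ <- stats::runif(1, margin, H - margin)
      if (i == 1) break
      j <- seq_len(i - 1)
      if (min((xc[j] - px_)^2 + (yc[j] - py_)^2) >= min_d2) break
    }
    xc[i] <- px_; yc[i] <- py_
  }
  th <- stats::runif(n0, 0, pi)
  is_div <- stats::runif(n0) < config$divider_fraction_f
  is_lag <- is_div & (stats::runif(n0) < config$lagged_fraction)
  phen <- ifelse(!is_div, "non_divider",
                 ifelse(is_lag, "lagged_divider", "continuous_divider"))
  # agent state (active set)
  ax <- xc - (L0 / 2) * cos(th); ay <- yc - (L0 / 2) * sin(th)  # anchored pole
  fx <- xc + (L0 / 2) * cos(th); fy <- yc + (L0 / 2) * sin(th)  # free pole
  id <- seq_len(n0)
  birth <- rep(0, n0)
  birth_len <- rep(L0, n0)
  due <- rep(NA_real_, n0)
  due[is_div] <- cl_draw(sum(is_div)) + ifelse(is_lag[is_div], config$lagged_delay, 0)
  if (config$initial_phase == "uniform" && any(is_div)) {
    # initial cells attached mid-cycle: only the residual fraction remains
    due[is_div] <- due[is_div] * stats::runif(sum(is_div))
  }
  len <- rep(L0, n0)
  # agent registry (all agents ever)
  reg <- list(id = id, mother_id = rep(NA_integer_, n0), phenotype = phen,
              birth_time = birth,
              anchored_pole_id = sample(1:2, n0, replace = TRUE),
              division_due = due)
  next_id <- n0 + 1L
  active <- rep(TRUE, n0)
  ev_time <- rep(0, n0); ev_type <- rep("birth", n0); ev_id <- id

  states <- if (config$record_states) vector("list", length(times)) else NULL
  rec <- function(k, t) {
    if (!config$record_states) return(invisible(NULL))
    i <- which(active)
    if (!length(i)) return(invisible(NULL))
    # pole labels: anchored pole printed first or second per anchored_pole_id
    ap <- reg$anchored_pole_id[id[i]]
    p1x <- ifelse(ap == 1L, ax[i], fx[i]); p1y <- ifelse(ap == 1L, ay[i], fy[i])
    p2x <- ifelse(ap == 1L, fx[i], ax[i]); p2y <- ifelse(ap == 1L, fy[i], ay[i])
    states[[k]] <<- cbind(time = t, agent_id = id[i], x1 = p1x, y1 = p1y,
                          x2 = p2x, y2 = p2y, xc = (ax[i] + fx[i]) / 2,
                          yc = (ay[i] + fy[i]) / 2, length = len[i])
    invisible(NULL)
  }

  p_det <- 1 - exp(-config$detachment_rate * dt / 60)
  rec(1L, 0)
  truncated_at <- NA_real_

  for (k in seq_along(times)[-1]) {
    t_new <- times[k]
    n_act <- sum(active)
    if (n_act == 0L) { rec(k, t_new); next }
    ii <- which(active)
    ph <- reg$phenotype[id[ii]]
    div_like <- ph != "non_divider"

    ## pole jitter (random walk), phenotype-dependent anchoring
    sa <- ifelse(ph == "continuous_divider", config$anchored_pole_jitter,
          ifelse(ph == "lagged_divider", config$anchored_pole_jitter,
                 config$nondivider_jitter))
    sf <- ifelse(ph == "continuous_divider", config$free_pole_jitter,
          ifelse(ph == "lagged_divider", config$anchored_pole_jitter,
                 config$nondivider_jitter))
    ax[ii] <- ax[ii] + stats::rnorm(n_act, 0, sa)
    ay[ii] <- ay[ii] + stats::rnorm(n_act, 0, sa)
    fx[ii] <- fx[ii] + stats::rnorm(n_act, 0, sf)
    fy[ii] <- fy[ii] + stats::rnorm(n_act, 0, sf)

    ## linear elongation toward twice the newborn length, anchored pole fixed
    el <- ii[div_like]
    if (length(el)) {
      b <- reg$birth_time[id[el]]; d <- due[el]
      frac <- pmin(1, pmax(0, (t_new - b) / (d - b)))
      len[el] <- birth_len[el] + (2 * L0 - birth_len[el]) * frac
    }
    ## re-impose length along the (jittered) axis
    ux <- fx[ii] - ax[ii]; uy <- fy[ii] - ay[ii]
    nn <- sqrt(ux^2 + uy^2); nn[nn == 0] <- 1
    grow <- div_like
    # dividers: anchored pole fixed, free pole set at distance len
    fx[ii[grow]] <- ax[ii[grow]] + len[ii[grow]] * (ux / nn)[grow]
    fy[ii[grow]] <- ay[ii[grow]] + len[ii[grow]] * (uy / nn)[grow]
    # non-dividers: keep length about the centroid
    nd <- !div_like
    if (any(nd)) {
      cx <- (ax[ii[nd]] + fx[ii[nd]]) / 2; cy <- (ay[ii[nd]] + fy[ii[nd]]) / 2
      hx <- (len[ii[nd]] / 2) * (ux / nn)[nd]; hy <- (len[ii[nd]] / 2) * (uy / nn)[nd]
      ax[ii[nd]] <- cx - hx; ay[ii[nd]] <- cy - hy
      fx[ii[nd]] <- cx + hx; fy[ii[nd]] <- cy + hy
    }

    ## overlap resolution (axial push, dividers yield); two relaxation
    ## passes per frame keep fast-elongating neighbours resolvable
    if (config$resolve_overlaps && n_act > 1) {
      movable <- logical(length(ax))
      movable[ii] <- div_like
      for (pass in 1:2) {
        res <- push_apart(ax, ay, fx, fy, ii, config$cell_width, movable)
        ax <- res$ax; ay <- res$ay; fx <- res$fx; fy <- res$fy
      }
    }

    ## keep whole cells inside the domain (the imaged field of view):
    ## translate back any cell whose pole would exit
    bw <- config$cell_width / 2
    shx <- pmax(0, bw - pmin(ax[ii], fx[ii])) -
      pmax(0, pmax(ax[ii], fx[ii]) - (W - bw))
    shy <- pmax(0, bw - pmin(ay[ii], fy[ii])) -
      pmax(0, pmax(ay[ii], fy[ii]) - (H - bw))
    ax[ii] <- ax[ii] + shx; fx[ii] <- fx[ii] + shx
    ay[ii] <- ay[ii] + shy; fy[ii] <- fy[ii] + shy

    ## detachment (Poisson per frame), optional downstream reattachment
    if (p_det > 0) {
      det <- ii[stats::runif(n_act) < p_det]
      if (length(det)) {
        ev_time <- c(ev_time, rep(t_new, length(det)))
        ev_type <- c(ev_type, rep("detach", length(det)))
        ev_id <- c(ev_id, id[det])
        re <- det[stats::runif(length(det)) < config$reattachment_prob]
        lost <- setdiff(det, re)
        active[lost] <- FALSE
        if (length(re)) {
          off <- stats::runif(length(re), config$reattachment_offset[1],
                              config$reattachment_offset[2])
          lat <- stats::rnorm(length(re), 0, 1)
          ax[re] <- ax[re] + off; fx[re] <- fx[re] + off
          ay[re] <- ay[re] + lat; fy[re] <- fy[re] + lat
          # wrap by whole-cell shifts to stay on the domain
          shx <- floor(((ax[re] + fx[re]) / 2) / W) * W
          shy <- floor(((ay[re] + fy[re]) / 2) / H) * H
          ax[re] <- ax[re] - shx; fx[re] <- fx[re] - shx
          ay[re] <- ay[re] - shy; fy[re] <- fy[re] - shy
          ev_time <- c(ev_time, rep(t_new, length(re)))
          ev_type <- c(ev_type, rep("reattach", length(re)))
          ev_id <- c(ev_id, id[re])
        }
      }
    }

    ## divisions due by t_new
    dv <- which(active & !is.na(due) & due <= t_new)
    if (length(dv)) {
      nd2 <- 2L * length(dv)
      mid_x <- (ax[dv] + fx[dv]) / 2; mid_y <- (ay[dv] + fy[dv]) / 2
      uxd <- (fx[dv] - ax[dv]); uyd <- (fy[dv] - ay[dv])
      nnd <- sqrt(uxd^2 + uyd^2); nnd[nnd == 0] <- 1
      uxd <- uxd / nnd; uyd <- uyd / nnd
      ang <- stats::rnorm(nd2, 0, 0.05)  # small angular noise per daughter
      ca <- cos(ang); sa2 <- sin(ang)
      # daughters contract to 85% of a newborn length at separation, which
      # opens a visible septum gap between the sister cells
      Lb <- 0.85 * L0
      # daughter A inherits the mother's anchored (old) pole, B the free pole
      dA_ax <- ax[dv]; dA_ay <- ay[dv]
      dB_ax <- fx[dv]; dB_ay <- fy[dv]
      uxA <- uxd * ca[seq_along(dv)] - uyd * sa2[seq_along(dv)]
      uyA <- uxd * sa2[seq_along(dv)] + uyd * ca[seq_along(dv)]
      jB <- seq_along(dv) + length(dv)
      uxB <- -(uxd * ca[jB] - uyd * sa2[jB])
      uyB <- -(uxd * sa2[jB] + uyd * ca[jB])
      new_ax <- c(dA_ax, dB_ax); new_ay <- c(dA_ay, dB_ay)
      new_fx <- c(dA_ax + Lb * uxA, dB_ax + Lb * uxB)
      new_fy <- c(dA_ay + Lb * uyA, dB_ay + Lb * uyB)

      is_div_d <- stats::runif(nd2) < config$divider_fraction_f
      is_lag_d <- is_div_d & (stats::runif(nd2) < config$daughter_lagged_fraction)
      phen_d <- ifelse(!is_div_d, "non_divider",
                       ifelse(is_lag_d, "lagged_divider", "continuous_divider"))
      due_d <- rep(NA_real_, nd2)
      if (any(is_div_d))
        due_d[is_div_d] <- t_new + cl_draw(sum(is_div_d)) +
          ifelse(is_lag_d[is_div_d], config$lagged_delay, 0)
      ids_d <- seq.int(next_id, length.out = nd2)
      next_id <- next_id + nd2

      reg$id <- c(reg$id, ids_d)
      reg$mother_id <- c(reg$mother_id, rep(id[dv], 2L))
      reg$phenotype <- c(reg$phenotype, phen_d)
      reg$birth_time <- c(reg$birth_time, rep(t_new, nd2))
      reg$anchored_pole_id <- c(reg$anchored_pole_id,
                                sample(1:2, nd2, replace = TRUE))
      reg$division_due <- c(reg$division_due, due_d)

      ev_time <- c(ev_time, rep(t_new, length(dv) + nd2))
      ev_type <- c(ev_type, rep("division_complete", length(dv)),
                   rep("birth", nd2))
      ev_id <- c(ev_id, id[dv], ids_d)

      active[dv] <- FALSE
      id <- c(id, ids_d); birth <- c(birth, rep(t_new, nd2))
      birth_len <- c(birth_len, rep(Lb, nd2))
      due <- c(due, due_d); len <- c(len, rep(Lb, nd2))
      ax <- c(ax, new_ax); ay <- c(ay, new_ay)
      fx <- c(fx, new_fx); fy <- c(fy, new_fy)
      active <- c(active, rep(TRUE, nd2))
    }

    ## single-layer guard: projected area must stay below 90% of the surface
    if (sum(len[active] * config$cell_width) > 0.9 * W * H) {
      truncated_at <- t_new
      rec(k, t_new)
      warning(sprintf(paste0("single-layer violation: projected cell area ",
                             "exceeded 90%% of the domain at t = %g min; ",
                             "history truncated"), t_new),
              call. = FALSE)
      times <- times[seq_len(k)]
      if (config$record_states) states <- states[seq_len(k)]
      break
    }
    rec(k, t_new)
  }

  ord <- order(ev_time, match(ev_type, c("birth", "division_complete",
                                         "detach", "reattach")), ev_id)
  events <- data.frame(time = ev_time[ord], event = ev_type[ord],
                       agent_id = ev_id[ord], stringsAsFactors = FALSE)
  st <- if (config$record_states)
    as.data.frame(do.call(rbind, states))
  else data.frame(time = numeric(), agent_id = integer(), x1 = numeric(),
                  y1 = numeric(), x2 = numeric(), y2 = numeric(),
                  xc = numeric(), yc = numeric(), length = numeric())
  agents <- data.frame(id = reg$id, mother_id = reg$mother_id,
                       phenotype = reg$phenotype, birth_time = reg$birth_time,
                       anchored_pole_id = reg$anchored_pole_id,
                       division_due = reg$division_due,
                       stringsAsFactors = FALSE)
  structure(list(agents = agents, states = st, events = events,
                 times = times, truncated_at = truncated_at,
                 config = config), class = "colony_history")
}

#' @export
print.colony_history <- function(x, ...) {
  cat("<colony_history>\n")
  cat("  agents:", nrow(x$agents), " frames:", length(x$times),
      " events:", nrow(x$events), "\n")
  cat("  divisions:", sum(x$events$event == "division_complete"),
      " detach:", sum(x$events$event == "detach"),
      " reattach:", sum(x$events$event == "reattach"), "\n")
  invisible(x)
}

#' Qualitative detachment/reattachment defaults for the four shear regimes
#'
#' Simulator presets emulating how detachment pressure rises and
#' reattachment success falls as shear increases: near-zero detachment with
#' almost certain immediate reattachment at ultra-low shear, frequent
#' detachment with rare reattachment at high shear. The divider fractions
#' span the observed 80-63% range. These presets reproduce orderings
#' (detachment ratio increasing, reattachment ratio decreasing with
#' shear), not any particular measured magnitude.
#'
#' @return data.frame `name, shear_rate, divider_fraction_f,
#'   detachment_rate (1/h), reattachment_prob`.
#' @export
shear_regime_defaults <- function() {
  data.frame(name = c("ulow", "low", "med", "high"),
             shear_rate = c(7, 29, 72, 116),
             divider_fraction_f = c(0.80, 0.72, 0.70, 0.63),
             detachment_rate = c(0.02, 0.3, 0.9, 1.6),
             reattachment_prob = c(0.95, 0.75, 0.40, 0.08),
             stringsAsFactors = FALSE)
}

#' Per-frame population series from the event log
#'
#' Attached-cell count `N`, cumulative detachments `N_d` and cumulative
#' reattachments `N_a` at every frame time, reconstructed from the event
#' log alone (no imaging or tracking involved).
#'
#' @param history a [simulate_colony()] result.
#' @return data.frame `time, N, N_d, N_a`.
#' @export
population_series_from_events <- function(history) {
  stopifnot(inherits(history, "colony_history"))
  ev <- history$events
  delta <- c(birth = 1, division_complete = -1, detach = -1, reattach = 1)
  times <- history$times
  N <- N_d <- N_a <- numeric(length(times))
  for (k in seq_along(times)) {
    upto <- ev$time <= times[k]
    N[k] <- sum(delta[ev$event[upto]])
    N_d[k] <- sum(ev$event[upto] == "detach")
    N_a[k] <- sum(ev$event[upto] == "reattach")
  }
  data.frame(time = times, N = N, N_d = N_d, N_a = N_a)
}

#' Event-log oracle for population rates
#'
#' Computes the observed growth rate, detachment/attachment rates and
#' ratios directly from the simulator's event log, with the same estimators
#' as [rate_decomposition()] but bypassing rendering, segmentation and
#' tracking entirely. Used as the ground-truth twin of the imaging
#' pipeline.
#'
#' @param history a [simulate_colony()] result.
#' @param window numeric length-2 time window (min) for the rate fits;
#'   defaults to the full simulated span.
#' @return A `rate_estimates` object (see [rate_decomposition()]).
#' @export
oracle_rates <- function(history, window = range(history$times)) {
  stopifnot(inherits(history, "colony_history"))
  if (window[2] <= window[1])
    stop("empty window: oracle_rates needs a window of positive length")
  series <- population_series_from_events(history)
  in_w <- series$time >= window[1] & series$time <= window[2]
  if (!any(in_w)) stop("empty window: no frames inside the requested window")
  eta <- observed_growth_rate(series, window)
  rate_decomposition(eta, series, window)
}

#' Growth rate of cumulative division production
#'
#' Log-linear slope of the cumulative count of completed divisions over a
#' time window. Unlike the attached-count growth rate, this per-capita
#' production measure is unaffected by transients in the divider /
#' non-divider composition of the attached population, and is the
#' quantity the generational divider-fraction model describes directly.
#'
#' @param history a [simulate_colony()] result.
#' @param window numeric length-2 time window (min).
#' @return Growth rate (1/h).
#' @export
division_growth_rate <- function(history, window = range(history$times)) {
  stopifnot(inherits(history, "colony_history"))
  dt_times <- history$times
  div_t <- history$events$time[history$events$event == "division_complete"]
  cum <- vapply(dt_times, function(t) sum(div_t <= t), numeric(1))
  sel <- dt_times >= window[1] & dt_times <= window[2] & cum > 0
  if (sum(sel) < 3) stop("too few frames with divisions in the window")
  fit <- stats::lm(log(cum[sel]) ~ dt_times[sel])
  unname(stats::coef(fit)[2]) * 60
}

#' Ground-truth trajectories from a colony history
#'
#' Converts the simulator's per-frame states into a trajectory set: one
#' trajectory per agent per continuous attachment interval (a reattachment
#' after a downstream hop starts a new trajectory, as it would for a
#' tracking algorithm with a bounded search radius). End reasons are taken
#' from the event log: `division`, `detachment` or
#' `censored_end_of_movie`.
#'
#' @param history a [simulate_colony()] result with recorded states.
#' @return A `trajectory_set` (see [trajectory_set()]).
#' @export
trajectories_from_history <- function(history) {
  stopifnot(inherits(history, "colony_history"))
  st <- history$states
  if (!nrow(st)) return(trajectory_set(empty_trajectory_points(),
                                       empty_trajectory_meta()))
  ev <- history$events
  dt <- history$config$frame_interval
  t_end <- max(history$times)
  # break agent state series at reattachment times
  re <- ev[ev$event == "reattach", c("time", "agent_id")]
  seg_key <- rep(0L, nrow(st))
  if (nrow(re)) {
    for (j in seq_len(nrow(re))) {
      hit <- st$agent_id == re$agent_id[j] & st$time >= re$time[j]
      seg_key[hit] <- seg_key[hit] + 1L
    }
  }
  grp <- interaction(st$agent_id, seg_key, drop = TRUE)
  traj_id <- as.integer(grp)
  o <- order(traj_id, st$time)
  pts <- data.frame(traj_id = traj_id[o], time = st$time[o],
                    x = st$xc[o], y = st$yc[o],
                    x1 = st$x1[o], y1 = st$y1[o],
                    x2 = st$x2[o], y2 = st$y2[o],
                    length = st$length[o],
                    eccentricity = NA_real_)
  agent_of <- st$agent_id[o][!duplicated(traj_id[o])]
  last_t <- tapply(pts$time, pts$traj_id, max)
  first_t <- tapply(pts$time, pts$traj_id, min)
  tid <- sort(unique(pts$traj_id))
  divided <- ev$agent_id[ev$event == "division_complete"]
  detached <- ev[ev$event == "detach", ]
  reason <- character(length(tid))
  for (j in seq_along(tid)) {
    a <- agent_of[j]; te <- last_t[j]
    if (a %in% divided &&
        any(abs(ev$time[ev$event == "division_complete" & ev$agent_id == a] -
                (te + dt)) < dt / 2)) {
      reason[j] <- "division"
    } else if (any(detached$agent_id == a &
                   abs(detached$time - (te + dt)) < dt / 2)) {
      reason[j] <- "detachment"
    } else if (te >= t_end - dt / 2) {
      reason[j] <- "censored_end_of_movie"
    } else reason[j] <- "lost"
  }
  meta <- data.frame(traj_id = tid, agent_id = agent_of,
                     start_time = as.numeric(first_t),
                     end_time = as.numeric(last_t),
                     duration = as.numeric(last_t - first_t),
                     end_reason = reason, stringsAsFactors = FALSE)
  trajectory_set(pts, meta)
}
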