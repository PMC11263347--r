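#' Optics configuration for the synthetic frame renderer
#'
#' Describes the emulated acquisition: magnification (pixel size), image
#' size, intensity convention, blur, additive noise, and detection flicker
#' (a cell randomly missing from single frames, as happens near the
#' detection threshold in real movies).
#'
#' @param pixel_size physical pixel pitch (um/px).
#' @param image_shape image size `c(ny, nx)` in pixels; `NULL` sizes the
#'   frame to the simulation domain at render time.
#' @param background_level background intensity (0-1 scale).
#' @param cell_contrast intensity offset of a cell relative to background.
#' @param cells_dark if `TRUE` cells are darker than the background
#'   (phase-contrast-like after preprocessing); otherwise brighter.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param blur_sigma Gaussian blur (px); 0 disables blurring.
#' @param flicker_prob probability that an attached cell is omitted from a
#'   given frame (it persists in the ground truth).
#' @param frame_interval frame interval carried as metadata (min).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size = 0.1, image_shape = NULL,
                          background_level = 0.7, cell_contrast = 0.4,
                          cells_dark = TRUE, noise_sd = 0.01,
                          blur_sigma = 1, flicker_prob = 0,
                          frame_interval = 1) {
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("invalid optics: pixel_size must be > 0")
  if (flicker_prob < 0 || flicker_prob >= 1)
    stop("invalid optics: flicker_prob must be in [0, 1)")
  if (!is.null(image_shape) && (length(image_shape) != 2 || any(image_shape < 1)))
    stop("invalid optics: image_shape must be two positive integers")
  structure(list(pixel_size = pixel_size, image_shape = image_shape,
                 background_level = background_level,
                 cell_contrast = cell_contrast, cells_dark = cells_dark,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 flicker_prob = flicker_prob,
                 frame_interval = frame_interval),
            class = "optics_config")
}

# add one anti-aliased capsule (segment with round caps) to an intensity
# matrix; coordinates in um, pixel (r, c) centred at ((c-1)*ps, (r-1)*ps)
draw_capsule <- function(img, x1, y1, x2, y2, width, contrast, ps) {
  r <- width / 2
  ny <- nrow(img); nx <- ncol(img)
  c0 <- max(1L, floor((min(x1, x2) - r) / ps))
  c1 <- min(nx, ceiling((max(x1, x2) + r) / ps) + 2L)
  r0 <- max(1L, floor((min(y1, y2) - r) / ps))
  r1 <- min(ny, ceiling((max(y1, y2) + r) / ps) + 2L)
  cols <- seq.int(c0, c1); rows <- seq.int(r0, r1)
  px <- (cols - 1) * ps; py <- (rows - 1) * ps
  X <- matrix(px, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(py, length(rows), length(cols))
  # the poles delimit the full cell extent: inset the capsule spine by the
  # cap radius so the rounded ends finish exactly at the poles
  dx <- x2 - x1; dy <- y2 - y1
  ll <- sqrt(dx^2 + dy^2)
  if (ll > 2 * r) {
    ux <- dx / ll; uy <- dy / ll
    x1 <- x1 + r * ux; y1 <- y1 + r * uy
    x2 <- x2 - r * ux; y2 <- y2 - r * uy
  } else {
    x1 <- x2 <- (x1 + x2) / 2; y1 <- y2 <- (y1 + y2) / 2
  }
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  if (l2 == 0) {
    d <- sqrt((X - x1)^2 + (Y - y1)^2)
  } else {
    tt <- pmin(1, pmax(0, ((X - x1) * dx + (Y - y1) * dy) / l2))
    d <- sqrt((X - (x1 + tt * dx))^2 + (Y - (y1 + tt * dy))^2)
  }
  cov <- pmin(1, pmax(0, 0.5 + (r - d) / ps))
  img[rows, cols] <- img[rows, cols] + contrast * cov
  img
}

#' Render a colony history into a synthetic image stack
#'
#' Draws every attached cell as an anti-aliased capsule between its poles,
#' applies Gaussian blur, adds Gaussian noise, and (optionally) omits
#' cells from single frames with probability `flicker_prob`. An exact
#' ground-truth detection table accompanies the stack for oracle tests.
#'
#' @param history a [simulate_colony()] result with recorded states.
#' @param optics an [optics_config()].
#' @param seed RNG seed for noise and flicker.
#' @return An object of class `frame_stack`: list with `frames` (numeric
#'   array ny x nx x n_frames, intensities clipped to `[0, 1]`), `times`
#'   (min), `optics`, and `ground_truth` (per frame and agent: poles,
#'   centroid, length, and an `omitted` flicker flag).
#' @export
render_frames <- function(history, optics, seed = 1L) {
  stopifnot(inherits(history, "colony_history"),
            inherits(optics, "optics_config"))
  set.seed(seed)
  ps <- optics$pixel_size
  st <- history$states
  shape <- optics$image_shape
  if (is.null(shape)) {
    dom <- history$config$domain_size
    shape <- c(ceiling(dom[2] / ps) + 1L, ceiling(dom[1] / ps) + 1L)
  }
  ny <- shape[1]; nx <- shape[2]
  xmax <- (nx - 1) * ps; ymax <- (ny - 1) * ps
  if (nrow(st)) {
    bad <- st$x1 < 0 | st$x2 < 0 | st$y1 < 0 | st$y2 < 0 |
      st$x1 > xmax | st$x2 > xmax | st$y1 > ymax | st$y2 > ymax
    if (any(bad))
      stop("cells out of field of view: agent ids ",
           paste(sort(unique(st$agent_id[bad])), collapse = ", "))
  }
  times <- history$times
  w <- history$config$cell_width
  sgn <- if (optics$cells_dark) -1 else 1
  frames <- array(0, dim = c(ny, nx, length(times)))
  omitted <- logical(nrow(st))
  if (nrow(st) && optics$flicker_prob > 0)
    omitted <- stats::runif(nrow(st)) < optics$flicker_prob
  frame_of <- if (nrow(st)) match(st$time, times) else integer()
  for (k in seq_along(times)) {
    img <- matrix(optics$background_level, ny, nx)
    rows <- which(frame_of == k & !omitted)
    for (j in rows)
      img <- draw_capsule(img, st$x1[j], st$y1[j], st$x2[j], st$y2[j],
                          w, sgn * optics$cell_contrast, ps)
    if (optics$blur_sigma > 0)
      img <- EBImage::gblur(img, sigma = optics$blur_sigma)
    if (optics$noise_sd > 0)
      img <- img + matrix(stats::rnorm(ny * nx, 0, optics$noise_sd), ny, nx)
    frames[, , k] <- pmin(1, pmax(0, img))
  }
  gt <- if (nrow(st))
    data.frame(frame = frame_of, time = st$time, agent_id = st$agent_id,
               x = st$xc, y = st$yc, x1 = st$x1, y1 = st$y1,
               x2 = st$x2, y2 = st$y2, length = st$length,
               omitted = omitted)
  else data.frame(frame = integer(), time = numeric(), agent_id = integer(),
                  x = numeric(), y = numeric(), x1 = numeric(),
                  y1 = numeric(), x2 = numeric(), y2 = numeric(),
                  length = numeric(), omitted = logical())
  structure(list(frames = frames, times = times, optics = optics,
                 ground_truth = gt), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<frame_stack> ", d[3], " frames of ", d[1], "x", d[2], " px, ",
      "pixel size ", x$optics$pixel_size, " um\n", sep = "")
  invisible(x)
}
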