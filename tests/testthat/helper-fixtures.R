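# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small rendered colony: ~25 initial cells on 50x50 um, 81 frames; used by
# segmentation, tracking and acceptance tests
rendered_fixture <- function() {
  cached("rendered", function() {
    cfg <- sim_config(divider_fraction_f = 0.8, lagged_fraction = 0,
                      domain_size = c(50, 50), duration = 80, seed = 21)
    history <- simulate_colony(cfg)
    optics <- optics_config(noise_sd = 0, blur_sigma = 1)
    stack <- render_frames(history, optics, seed = 2)
    params <- segmentation_params(intensity_threshold = 0.15,
                                  min_area_px = 40)
    detections <- segment_stack(stack, params)
    list(config = cfg, history = history, stack = stack, params = params,
         detections = detections)
  })
}

# event-level mixture colony (no states): source of >= 1500 division times
mixture_fixture <- function() {
  cached("mixture", function() {
    cfg <- sim_config(divider_fraction_f = 0.7, lagged_fraction = 0.125,
                      lagged_delay = 260, domain_size = c(200, 200),
                      duration = 360, record_states = FALSE,
                      resolve_overlaps = FALSE, seed = 5)
    history <- simulate_colony(cfg)
    ag <- history$agents
    divided <- ag$id %in%
      history$events$agent_id[history$events$event == "division_complete"]
    list(history = history,
         tau = (ag$division_due - ag$birth_time)[divided],
         birth = ag$birth_time[divided],
         agents = ag, divided = divided)
  })
}

# detections table straight from simulator states (noise-free tracking input)
detections_from_states <- function(history) {
  st <- history$states
  det <- data.frame(frame = match(st$time, history$times), time = st$time,
                    x = st$xc, y = st$yc, x1 = st$x1, y1 = st$y1,
                    x2 = st$x2, y2 = st$y2, length = st$length,
                    eccentricity = NA_real_)
  det[order(det$frame), ]
}

# hand-built static detection table: cells at fixed positions over n frames
static_detections <- function(centres, n_frames, dt = 1, length = 2) {
  do.call(rbind, lapply(seq_len(n_frames), function(f) {
    data.frame(frame = f, time = (f - 1) * dt,
               x = centres[, 1], y = centres[, 2],
               x1 = centres[, 1] - length / 2, y1 = centres[, 2],
               x2 = centres[, 1] + length / 2, y2 = centres[, 2],
               length = length, eccentricity = 0.87)
  }))
}

# shared end-to-end pipeline configuration (same colony as rendered_fixture)
small_pipeline_config <- function(seed = 21) {
  pipeline_config(
    sim = list(divider_fraction_f = 0.8, lagged_fraction = 0,
               domain_size = c(50, 50), duration = 80, seed = seed),
    optics = list(noise_sd = 0, blur_sigma = 1),
    segmentation = list(intensity_threshold = 0.15, min_area_px = 40),
    rates = list(window = c(30, 80)),
    model = list(tau_bar_d = 52),
    render_seed = 2)
}

# brute-force MSD oracle: literal double loop over the printed estimator
msd_brute <- function(x, y, k, normalization = "printed") {
  n <- length(x); s <- 0
  for (i in seq_len(n - k)) {
    s <- s + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
  }
  s / if (normalization == "printed") n else (n - k)
}
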