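make_one_division_set <- function() {
  # one initial cell dividing at t = 50 into two daughters tracked to 100
  pts_m <- data.frame(traj_id = 1L, time = 0:49, x = 10, y = 10,
                      x1 = 9, y1 = 10, x2 = 11, y2 = 10,
                      length = 2, eccentricity = 0.87)
  mk_d <- function(id, x0) data.frame(traj_id = id, time = 50:100, x = x0,
                                      y = 10, x1 = x0 - 1, y1 = 10,
                                      x2 = x0 + 1, y2 = 10, length = 2,
                                      eccentricity = 0.87)
  pts <- rbind(pts_m, mk_d(2L, 9), mk_d(3L, 11))
  meta <- data.frame(traj_id = 1:3, agent_id = 1:3,
                     start_time = c(0, 50, 50), end_time = c(49, 100, 100),
                     duration = c(49, 50, 50),
                     end_reason = c("division", rep("censored_end_of_movie", 2)))
  trajectory_set(pts, meta)
}

test_that("birth classes partition the attached population exactly", {
  tr <- make_one_division_set()
  bc <- birth_class_partition(tr, interval = 40, n_classes = 9)
  times <- sort(unique(tr$points$time))
  # before the division: one class-1 cell; after: two class-2 cells
  expect_equal(unname(bc[times == 30, "class_1"]), 1)
  expect_equal(sum(bc[times == 30, ]), 1)
  expect_equal(unname(bc[times == 60, "class_1"]), 0)
  expect_equal(unname(bc[times == 60, "class_2"]), 2)
  # row sums equal the attached count at every frame
  N <- as.numeric(table(factor(tr$points$time, levels = times)))
  expect_equal(unname(rowSums(bc)), N)

  # without divisions, all mass stays in class 1
  det <- static_detections(cbind(5, 5), 30)
  tr0 <- link_trajectories(det, link_config())
  bc0 <- birth_class_partition(tr0, 40, 9)
  expect_true(all(bc0[, "class_1"] == 1))
  expect_true(all(bc0[, -1] == 0))

  # birth times beyond the class range are clipped with a warning
  late <- tr
  late$meta$start_time[2] <- 500
  expect_warning(birth_class_partition(late, 40, 9), "clipped")
})

test_that("observed growth rate recovers exact exponential input", {
  t <- 0:360
  series <- data.frame(time = t, N = 100 * exp(0.54 * t / 60))
  est <- observed_growth_rate(series, c(80, 360))
  expect_equal(est$eta, 0.54, tolerance = 1e-9)
  expect_lt(est$se, 1e-9)
  # constant population: zero rate
  flat <- data.frame(time = t, N = rep(50, length(t)))
  expect_equal(observed_growth_rate(flat, c(80, 360))$eta, 0)
  # the instantaneous-average variant agrees on smooth input
  est2 <- observed_growth_rate(series, c(80, 360), method = "instantaneous")
  expect_equal(est2$eta, 0.54, tolerance = 0.01)
  expect_error(observed_growth_rate(series[1:2, ], c(0, 1)), "3 frames")
  bad <- data.frame(time = 0:10, N = c(rep(5, 10), 0))
  expect_error(observed_growth_rate(bad, c(0, 10)), "positive")
})

test_that("detachment and attachment ratios follow their definitions", {
  series <- data.frame(time = 0:10, N = rep(100, 11),
                       N_d = 0:10 * 5, N_a = 0:10 * 2)
  r <- detachment_attachment_ratios(series)
  expect_equal(r$R_d_end, 0.5)
  expect_equal(r$R_a_end, 0.4)
  # undefined (not zero) attachment ratio before any detachment
  expect_true(is.na(r$series$R_a[1]))
  none <- data.frame(time = 0:10, N = rep(100, 11), N_d = 0, N_a = 0)
  r0 <- detachment_attachment_ratios(none)
  expect_true(all(r0$series$R_d == 0))
  expect_true(all(is.na(r0$series$R_a)))
  expect_true(is.na(r0$R_a_mean))
  dec <- series; dec$N_d[5] <- 100
  expect_error(detachment_attachment_ratios(dec), "non-decreasing")
})

test_that("rate decomposition assembles eta_eff = eta + eta_d - eta_a", {
  # constant N = 100 with N_d growing at 0.15/min: eta_d = 0.09 1/h
  t <- 0:120
  series <- data.frame(time = t, N = 100, N_d = 0.15 * t, N_a = 0)
  rd <- rate_decomposition(0.21, series, c(0, 120))
  expect_equal(rd$eta_d, 0.09, tolerance = 1e-9)
  expect_equal(rd$eta_a, 0)
  expect_equal(rd$eta_eff, 0.30, tolerance = 1e-9)
  # identity holds by construction for any inputs
  series2 <- data.frame(time = t, N = 100 + t, N_d = 0.3 * t, N_a = 0.1 * t)
  rd2 <- rate_decomposition(0.5, series2, c(0, 120))
  expect_equal(rd2$eta_eff, rd2$eta + rd2$eta_d - rd2$eta_a, tolerance = 1e-12)
  # no events: eta_eff equals eta
  s0 <- data.frame(time = t, N = 100, N_d = 0, N_a = 0)
  expect_equal(rate_decomposition(0.4, s0, c(0, 120))$eta_eff, 0.4)
  expect_error(rate_decomposition(0.4, s0, c(0, 0.5)), "2 frames")
})

test_that("exponential division-time fit recovers the 40-min mean", {
  set.seed(77)
  tau <- rexp(1500, 1 / 40)
  st <- division_time_statistics(tau)
  expect_equal(st$mean_division_time, 40, tolerance = 2 / 40)
  expect_equal(st$lagged_fraction_hat, mean(tau > 160), tolerance = 1e-12)
  # degenerate sample flagged
  expect_warning(st_d <- division_time_statistics(rep(40, 100)), "degenerate")
  expect_true(st_d$degenerate)
  expect_equal(st_d$mean_division_time, 40)
  # refusals
  expect_error(division_time_statistics(rexp(5, 1 / 40)), "at least 10")
  expect_error(division_time_statistics(rep(500, 50)), "fit refused")
})

test_that("lagged mixture shifts the pooled mean division time to 55 min", {
  set.seed(101)
  n <- 4000
  lagged <- runif(n) < 0.125
  tau <- ifelse(lagged, 120 + rexp(n, 1 / 40), rexp(n, 1 / 40))
  # analytic mixture mean: 0.875*40 + 0.125*160 = 55
  expect_equal(mean(tau), 55, tolerance = 0.05)
  st <- division_time_statistics(tau, lag_cutoff = Inf)
  expect_equal(st$mean_division_time, 55, tolerance = 0.05)
})

test_that("time-resolved mean division time relaxes to the continuous mean", {
  fx <- mixture_fixture()
  st <- division_time_statistics(fx$tau, fx$birth)
  mvt <- st$mean_vs_observation_time
  # the first bin carries the lagged cohort; later bins sit at 40 min
  expect_gt(mvt$mean_tau[1], 45)
  late <- mvt$mean_tau[mvt$bin_start %in% c(120, 160)]
  expect_true(all(abs(late - 40) < 2))
  expect_gt(mvt$mean_tau[1], max(late))
  # bulk exponential fit recovers the 40-min scale
  expect_equal(1 / st$lambda_hat, 40, tolerance = 2 / 40)
})

test_that("population series from trajectories matches the event-log series", {
  cfg <- sim_config(divider_fraction_f = 0.8, lagged_fraction = 0,
                    domain_size = c(60, 60), duration = 100, seed = 23)
  h <- simulate_colony(cfg)
  tr <- trajectories_from_history(h)
  s_tr <- population_series(tr, times = h$times)
  s_ev <- population_series_from_events(h)
  expect_identical(s_tr$N, s_ev$N)
})
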