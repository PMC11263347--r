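test_that("MSD estimator equals the brute-force double loop on random fixtures", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    for (k in unique(c(1, sample(n - 1, min(4, n - 1)), n - 1))) {
      expect_equal(msd_at_lag(x, y, k, "printed"), msd_brute(x, y, k, "printed"),
                   tolerance = 1e-12)
      expect_equal(msd_at_lag(x, y, k, "pairs"), msd_brute(x, y, k, "pairs"),
                   tolerance = 1e-12)
    }
  }
  expect_error(msd_at_lag(1:5, 1:5, 5), "undefined lag")
  expect_error(msd_at_lag(1:5, 1:5, 0), "undefined lag")
})

test_that("MSD closed forms: static and uniformly moving trajectories", {
  n <- 60
  expect_true(all(msd_curve(rep(2, n), rep(3, n))$msd == 0))
  # uniform motion at speed v: printed form gives (N-k)/N (v tau)^2
  v <- 0.25; x <- v * (0:(n - 1)); y <- rep(0, n)
  for (k in c(1, 7, 30, n - 1)) {
    expect_equal(msd_at_lag(x, y, k, "printed"), (n - k) / n * (v * k)^2,
                 tolerance = 1e-12)
    expect_equal(msd_at_lag(x, y, k, "pairs"), (v * k)^2, tolerance = 1e-12)
  }
  cur <- msd_curve(x, y, dt = 2)
  expect_equal(cur$msd[1], 0)
  expect_equal(cur$n_pairs, c(n, n - seq_len(n - 1)))
  expect_true(all(cur$tau <= (n - 1) * 2))
})

test_that("phenotype calls follow the MSD threshold and duration rules", {
  p <- classifier_params()
  # net 1 um displacement over 45 min: divider
  x <- seq(0, 1, length.out = 46)
  call <- classify_phenotype(x, rep(0, 46), dt = 1, p)
  expect_equal(call$call, "divider")
  expect_equal(call$end_msd, 1, tolerance = 1e-9)
  expect_equal(call$duration_T, 45)
  # tiny displacement, long duration: non-divider
  x2 <- c(rep(0, 60), 0.1)
  expect_equal(classify_phenotype(x2, rep(0, 61), 1, p)$call, "non_divider")
  # tiny displacement, short duration: censored (possible pre-division loss)
  x3 <- c(rep(0, 30), 0.1)
  expect_equal(classify_phenotype(x3, rep(0, 31), 1, p)$call, "censored")
  # single point: censored
  expect_equal(classify_phenotype(1, 1, 1, p)$call, "censored")
  # classification is invariant under rigid translation
  set.seed(3)
  xr <- cumsum(rnorm(50, 0, 0.1)); yr <- cumsum(rnorm(50, 0, 0.1))
  c1 <- classify_phenotype(xr, yr, 1, p)
  c2 <- classify_phenotype(xr + 100, yr - 55, 1, p)
  expect_identical(c1$call, c2$call)
  expect_equal(c1$end_msd, c2$end_msd, tolerance = 1e-9)
})

test_that("lagged dividers are split at the division-time cutoff", {
  part <- identify_lagged_dividers(c(40, 200, 35, 161, 159))
  expect_equal(sort(part$lagged), c(161, 200))
  expect_equal(part$lagged_fraction, 0.4)
  empty <- identify_lagged_dividers(numeric(0))
  expect_length(empty$continuous, 0)
  expect_true(is.na(empty$lagged_fraction))
  expect_equal(identify_lagged_dividers(40)$lagged_fraction, 0)
})

test_that("pole displacement statistics capture anchoring asymmetry", {
  set.seed(11)
  n <- 2000
  mk <- function(s1, s2) {
    data.frame(x = rep(0, n), y = rep(0, n),
               x1 = cumsum(rnorm(n, 0, s1)), y1 = cumsum(rnorm(n, 0, s1)),
               x2 = 2 + cumsum(rnorm(n, 0, s2)), y2 = cumsum(rnorm(n, 0, s2)))
  }
  # symmetric jitter: ratio of pole displacements near 1
  sym <- pole_displacement_stats(mk(0.05, 0.05))
  expect_equal(sym$ratio_min_max, 1, tolerance = 0.05)
  # free pole twice as jittery as the anchored pole: min ~ half of max
  asym <- pole_displacement_stats(mk(0.05, 0.10))
  expect_equal(asym$ratio_min_max, 0.5, tolerance = 0.06)
  # perfectly fixed anchored pole
  fixed <- pole_displacement_stats(mk(0, 0.1))
  expect_equal(fixed$min_pole_disp, 0)
  # pole-label flips are corrected before summing paths
  tr <- mk(0.05, 0.10)
  flipped <- tr
  swap <- seq(2, n, by = 3)
  flipped[swap, c("x1", "y1", "x2", "y2")] <- tr[swap, c("x2", "y2", "x1", "y1")]
  s1 <- pole_displacement_stats(tr)
  s2 <- pole_displacement_stats(flipped)
  expect_equal(s2$max_pole_disp, s1$max_pole_disp, tolerance = 1e-9)
  expect_equal(s2$min_pole_disp, s1$min_pole_disp, tolerance = 1e-9)
  expect_error(pole_displacement_stats(data.frame(x = 1, y = 1)),
               "missing columns")
})

test_that("simulated dividers separate from non-dividers by over 10x in end-MSD", {
  cfg <- sim_config(divider_fraction_f = 0.6, lagged_fraction = 0,
                    domain_size = c(80, 80), duration = 150, seed = 51)
  h <- simulate_colony(cfg)
  gt <- trajectories_from_history(h)
  cls <- classify_trajectories(gt)
  m_div <- mean(cls$end_msd[cls$call == "divider"])
  m_non <- mean(cls$end_msd[cls$call == "non_divider"])
  expect_gt(m_div / m_non, 10)
  # dividers carry end-MSD on the order of 1 um^2
  expect_gt(m_div, 0.5)
  expect_lt(m_non, 0.05)
  # trajectories that end in division are overwhelmingly called dividers
  div_tr <- cls$call[cls$end_reason == "division" & cls$duration_T > 10]
  expect_gt(mean(div_tr == "divider"), 0.9)
})

test_that("measured divider fraction recovers the generative f", {
  cfg <- sim_config(divider_fraction_f = 0.7, lagged_fraction = 0,
                    initial_phase = "uniform", resolve_overlaps = FALSE,
                    domain_size = c(140, 140), duration = 240, seed = 61)
  h <- simulate_colony(cfg, division_time_mean = 52)
  gt <- trajectories_from_history(h)
  dfs <- divider_fraction_series(gt)
  f_meas <- mean(dfs$fraction[dfs$time >= 80], na.rm = TRUE)
  # realized daughter divider share
  daughters <- h$agents[!is.na(h$agents$mother_id), ]
  f_real <- mean(daughters$phenotype != "non_divider")
  expect_lt(abs(f_meas - f_real), 0.05)
  expect_lt(abs(f_meas - 0.7), 0.05)
})
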