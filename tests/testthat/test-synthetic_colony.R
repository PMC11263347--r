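test_that("zero-variance pure-divider colony doubles every 40 minutes", {
  cfg <- sim_config(divider_fraction_f = 1, clock = "fixed",
                    mean_division_time = 40, lagged_fraction = 0,
                    initial_density = 10 / 1e4, domain_size = c(100, 100),
                    duration = 120, seed = 7)
  h <- simulate_colony(cfg)
  s <- population_series_from_events(h)
  expect_equal(s$N[s$time == 0], 10)
  expect_equal(s$N[s$time == 39], 10)
  expect_equal(s$N[s$time == 41], 20)
  expect_equal(s$N[s$time == 120], 80)
  expect_equal(sum(h$events$event == "division_complete"), 70)

  # identical seeds give identical histories
  h2 <- simulate_colony(cfg)
  expect_identical(h$events, h2$events)
  expect_identical(h$states, h2$states)
})

test_that("event log conserves the attached count at every frame", {
  delta <- c(birth = 1, division_complete = -1, detach = -1, reattach = 1)
  for (seed in c(2, 9)) {
    cfg <- sim_config(divider_fraction_f = 0.7, detachment_rate = 1,
                      reattachment_prob = 0.5, domain_size = c(80, 80),
                      duration = 100, seed = seed)
    h <- simulate_colony(cfg)
    n_ev <- vapply(h$times, function(t)
      sum(delta[h$events$event[h$events$time <= t]]), numeric(1))
    n_st <- as.numeric(table(factor(h$states$time, levels = h$times)))
    expect_identical(n_ev, n_st)
    # a division removes the mother and adds exactly two daughters
    mothers <- h$events$agent_id[h$events$event == "division_complete"]
    for (m in mothers) {
      expect_equal(sum(h$agents$mother_id == m, na.rm = TRUE), 2)
    }
  }
})

test_that("division clock matches its truncated-exponential law (KS test)", {
  fx <- mixture_fixture()
  # cells born early enough for near-complete follow-up (residual
  # censoring < 1%), excluding the lagged initial cohort (delay >> cutoff)
  keep <- fx$birth <= 240 & fx$tau < 260
  tau <- fx$tau[keep]
  expect_gt(length(tau), 5000)
  ks <- stats::ks.test(tau - 20, "pexp", rate = 1 / 20)
  expect_gt(ks$p.value, 0.01)
  # realized mean equals the configured mean division time
  expect_equal(mean(tau), 40, tolerance = 0.03)
})

test_that("daughter phenotypes follow the divider fraction f", {
  fx <- mixture_fixture()
  daughters <- fx$agents[!is.na(fx$agents$mother_id), ]
  expect_gt(nrow(daughters), 2000)
  p_hat <- mean(daughters$phenotype != "non_divider")
  se <- sqrt(0.7 * 0.3 / nrow(daughters))
  expect_lt(abs(p_hat - 0.7), 4 * se)
  # non-divider is absorbing: no divisions by non-dividers
  nd_ids <- fx$agents$id[fx$agents$phenotype == "non_divider"]
  div_ids <- fx$history$events$agent_id[
    fx$history$events$event == "division_complete"]
  expect_length(intersect(nd_ids, div_ids), 0)
})

test_that("detachment ratio increases with the detachment rate", {
  rd <- vapply(c(0, 0.5, 1.5, 4), function(rate) {
    cfg <- sim_config(divider_fraction_f = 0.6, detachment_rate = rate,
                      reattachment_prob = 0.3, domain_size = c(70, 70),
                      duration = 90, record_states = FALSE,
                      resolve_overlaps = FALSE, seed = 13)
    oracle_rates(simulate_colony(cfg))$R_d
  }, numeric(1))
  expect_equal(rd[1], 0)
  expect_true(all(diff(rd) > 0))
})

test_that("reattachment ratio recovers the generative probability", {
  cfg <- sim_config(divider_fraction_f = 0.5, detachment_rate = 2,
                    reattachment_prob = 0.4, domain_size = c(120, 120),
                    duration = 120, record_states = FALSE,
                    resolve_overlaps = FALSE, seed = 17)
  h <- simulate_colony(cfg)
  nd <- sum(h$events$event == "detach")
  na <- sum(h$events$event == "reattach")
  expect_gt(nd, 100)
  se <- sqrt(0.4 * 0.6 / nd)
  expect_lt(abs(na / nd - 0.4), 4 * se)
  orc <- oracle_rates(h)
  expect_equal(orc$R_a, na / nd, tolerance = 1e-12)
})

test_that("oracle rates equal rates computed from ground-truth trajectories", {
  cfg <- sim_config(divider_fraction_f = 0.8, lagged_fraction = 0,
                    domain_size = c(60, 60), duration = 100, seed = 23)
  h <- simulate_colony(cfg)
  tr <- trajectories_from_history(h)
  series_tr <- population_series(tr, times = h$times)
  series_ev <- population_series_from_events(h)
  # identical attached counts frame by frame, hence identical growth rates
  expect_identical(series_tr$N, series_ev$N)
  w <- c(20, 100)
  eta_tr <- observed_growth_rate(series_tr, w)$eta
  expect_equal(oracle_rates(h, w)$eta, eta_tr, tolerance = 1e-12)
})

test_that("zero-event histories give eta_eff = eta and R_d = 0", {
  cfg <- sim_config(divider_fraction_f = 0.9, lagged_fraction = 0,
                    domain_size = c(60, 60), duration = 100,
                    record_states = FALSE, seed = 3)
  orc <- oracle_rates(simulate_colony(cfg), c(20, 100))
  expect_identical(orc$eta_eff, orc$eta)
  expect_identical(orc$R_d, 0)
  expect_true(is.na(orc$R_a))
})

test_that("deterministic pure-divider oracle growth rate is ln 2 per 40 min", {
  cfg <- sim_config(divider_fraction_f = 1, clock = "fixed",
                    initial_phase = "uniform", lagged_fraction = 0,
                    initial_density = 200 / 2.25e4, domain_size = c(150, 150),
                    duration = 200, record_states = FALSE,
                    resolve_overlaps = FALSE, seed = 19)
  h <- simulate_colony(cfg)
  orc <- oracle_rates(h, c(40, 200))
  expect_equal(orc$eta, log(2) / (40 / 60), tolerance = 0.08)
  # cumulative division production grows at the same rate (the early
  # burst leaves a decaying positive bias, hence the looser band)
  expect_equal(division_growth_rate(h, c(80, 200)), log(2) / (40 / 60),
               tolerance = 0.15)
  expect_error(division_growth_rate(h, c(0, 2)), "too few frames")
})

test_that("config validation and degenerate inputs fail loudly", {
  expect_error(sim_config(divider_fraction_f = 1.2), "probabilities")
  expect_error(sim_config(division_time_floor = 50), "floor")
  expect_error(sim_config(anchored_pole_jitter = -1), "jitters")
  expect_error(sim_config(initial_density = 1e-5,
                          domain_size = c(10, 10)), "domain too small")
  expect_error(oracle_rates(simulate_colony(sim_config(
    domain_size = c(40, 40), duration = 50, seed = 1)), c(30, 30)),
    "empty window")
})

test_that("over-dense growth stops with a single-layer violation", {
  cfg <- sim_config(divider_fraction_f = 1, lagged_fraction = 0,
                    initial_density = 0.05, domain_size = c(30, 30),
                    duration = 300, record_states = FALSE,
                    resolve_overlaps = FALSE, seed = 29)
  expect_warning(h <- simulate_colony(cfg), "single-layer violation")
  expect_false(is.na(h$truncated_at))
  expect_lt(max(h$times), 300)
})
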