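test_that("well-separated static cells give one full trajectory each", {
  det <- static_detections(rbind(c(10, 10), c(30, 30)), n_frames = 50)
  tr <- link_trajectories(det, link_config())
  expect_equal(nrow(tr$meta), 2)
  expect_true(all(table(tr$points$traj_id) == 50))
  expect_true(all(tr$meta$end_reason == "censored_end_of_movie"))
  # every detection belongs to exactly one trajectory
  expect_equal(nrow(tr$points), nrow(det))
})

test_that("gap closing bridges flicker within the memory window", {
  det <- static_detections(cbind(10, 10), n_frames = 30)
  det <- det[!(det$frame %in% c(12, 13)), ]  # 2-frame flicker gap
  tr <- link_trajectories(det, link_config(memory_frames = 3))
  expect_equal(nrow(tr$meta), 1)
  expect_equal(nrow(tr$points), 28)
  expect_equal(tr$meta$duration, 29)
  # without memory the trajectory breaks at the gap
  tr0 <- link_trajectories(det, link_config(memory_frames = 0))
  expect_equal(nrow(tr0$meta), 2)
})

test_that("division endings are recognized from paired daughter starts", {
  # mother at (10,10), length 4, until frame 10; daughters at +/-1 um after
  mother <- static_detections(cbind(10, 10), n_frames = 10, length = 4)
  d1 <- static_detections(cbind(9, 10), n_frames = 10, length = 1.9)
  d2 <- static_detections(cbind(11, 10), n_frames = 10, length = 1.9)
  for (d in c("d1", "d2")) {
    dd <- get(d); dd$frame <- dd$frame + 10; dd$time <- dd$time + 10
    assign(d, dd)
  }
  det <- rbind(mother, d1, d2)
  det <- det[order(det$frame), ]
  tr <- link_trajectories(det, link_config())
  dv <- detect_division_events(tr, link_config())
  expect_equal(nrow(dv$events), 1)
  expect_equal(sum(dv$trajectories$meta$end_reason == "division",
                   na.rm = TRUE), 1)
  mother_id <- dv$events$mother_traj
  expect_equal(dv$trajectories$meta$duration[
    dv$trajectories$meta$traj_id == mother_id], 9)

  # a movie without divisions yields an empty event list
  tr2 <- link_trajectories(static_detections(cbind(5, 5), 20), link_config())
  dv2 <- detect_division_events(tr2, link_config())
  expect_equal(nrow(dv2$events), 0)
})

test_that("rendered divisions are recovered with high recall and timing", {
  fx <- rendered_fixture()
  lk <- link_config()
  tr <- link_trajectories(fx$detections, lk)
  dv <- detect_division_events(tr, lk)
  true_div <- sum(fx$history$events$event == "division_complete")
  expect_gte(nrow(dv$events), 0.95 * true_div)
  expect_lte(nrow(dv$events), 1.05 * true_div)
  # recovered division times match the ground-truth clocks within 2 frames
  true_t <- sort(fx$history$events$time[
    fx$history$events$event == "division_complete"])
  est_t <- sort(dv$events$time)
  matched <- vapply(est_t, function(t) min(abs(true_t - t)), numeric(1))
  expect_gte(mean(matched <= 2), 0.95)
})

test_that("tracked points correspond to ground-truth agents at standard density", {
  fx <- rendered_fixture()
  tr <- link_trajectories(fx$detections, link_config())
  gt <- fx$stack$ground_truth
  pts <- tr$points
  # map every tracked point to the nearest ground-truth cell in its frame
  agent <- integer(nrow(pts))
  frames <- match(pts$time, fx$stack$times)
  for (k in unique(frames)) {
    gk <- gt[gt$frame == k, ]
    sel <- which(frames == k)
    for (i in sel) {
      d <- sqrt((gk$x - pts$x[i])^2 + (gk$y - pts$y[i])^2)
      agent[i] <- if (min(d) < 0.5) gk$agent_id[which.min(d)] else NA_integer_
    }
  }
  expect_gt(mean(!is.na(agent)), 0.99)
  # trajectory purity: each trajectory follows a single agent
  purity <- vapply(split(agent, pts$traj_id), function(a) {
    a <- a[!is.na(a)]
    if (!length(a)) return(1)
    max(table(a)) / length(a)
  }, numeric(1))
  expect_gt(mean(purity == 1), 0.95)
})

test_that("detachment and attachment events are counted from trajectory ends", {
  # static colony plus: one cell leaving at frame 11, one arriving at 16,
  # one hopping 7 um at frame 21 (detach + immediate reattach)
  base <- static_detections(rbind(c(10, 10), c(35, 35)), n_frames = 40)
  leaver <- static_detections(cbind(20, 10), n_frames = 10)
  arriver <- static_detections(cbind(10, 30), n_frames = 25)
  arriver$frame <- arriver$frame + 15; arriver$time <- arriver$time + 15
  hopper <- static_detections(cbind(30, 20), n_frames = 40)
  hop <- hopper$frame > 20
  hopper$x[hop] <- hopper$x[hop] + 7
  hopper$x1[hop] <- hopper$x1[hop] + 7
  hopper$x2[hop] <- hopper$x2[hop] + 7
  det <- rbind(base, leaver, arriver, hopper)
  det <- det[order(det$frame), ]
  lk <- link_config(detach_displacement_threshold = 5)
  tr <- link_trajectories(det, lk)
  ad <- detect_attach_detach_events(tr, lk)
  expect_equal(sum(ad$events$type == "detach"), 2)
  expect_equal(sum(ad$events$type == "attach"), 2)
  expect_equal(max(ad$series$N_d), 2)
  expect_equal(max(ad$series$N_a), 2)

  # fully static movie: no events at all
  tr0 <- link_trajectories(base, lk)
  ad0 <- detect_attach_detach_events(tr0, lk)
  expect_equal(nrow(ad0$events), 0)
  expect_true(all(ad0$series$N_d == 0) && all(ad0$series$N_a == 0))
})

test_that("simulated detach/reattach dynamics are recovered through tracking", {
  cfg <- sim_config(divider_fraction_f = 0.5, lagged_fraction = 0,
                    detachment_rate = 1.5, reattachment_prob = 0.4,
                    domain_size = c(100, 100), duration = 120, seed = 31)
  h <- simulate_colony(cfg)
  det <- detections_from_states(h)
  lk <- link_config()
  tr <- link_trajectories(det, lk)
  ad <- detect_attach_detach_events(tr, lk)
  true_d <- sum(h$events$event == "detach")
  true_a <- sum(h$events$event == "reattach")
  nd <- sum(ad$events$type == "detach")
  na <- sum(ad$events$type == "attach")
  expect_lt(abs(nd - true_d) / true_d, 0.05)
  expect_lt(abs(na - true_a) / max(true_a, 1), 0.05)
  # recovered reattachment fraction within binomial CI of the probability
  se <- sqrt(0.4 * 0.6 / nd)
  expect_lt(abs(na / nd - 0.4), 4 * se)
})

test_that("linking is conservative: every detection used exactly once", {
  fx <- rendered_fixture()
  tr <- link_trajectories(fx$detections, link_config())
  expect_equal(nrow(tr$points), nrow(fx$detections))
  # per frame: open trajectories = previously open + starts - ends
  frames <- sort(unique(tr$points$time))
  open_at <- vapply(frames, function(t)
    sum(tr$meta$start_time <= t & tr$meta$end_time >= t), numeric(1))
  starts <- vapply(frames, function(t) sum(tr$meta$start_time == t), numeric(1))
  ends <- vapply(frames, function(t) sum(tr$meta$end_time == t), numeric(1))
  running <- cumsum(starts) - cumsum(c(0, head(ends, -1)))
  expect_equal(open_at, running)
})
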