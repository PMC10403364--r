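still_pair <- function(rx = 0, ry = 0, rori = 0, sx = 3, sy = 0, sori = 0,
                       n = 60, fs = 30) {
  tracked_pair(data.frame(frame = seq_len(n), rx = rx, ry = ry, rori = rori,
                          sx = sx, sy = sy, sori = sori), fs = fs)
}

test_that("tracked pairs validate their frame table", {
  expect_error(tracked_pair(data.frame(frame = 1, rx = 0), fs = 30))
  p <- still_pair()
  expect_s3_class(p, "tracked_pair")
  expect_true(all(p$frames$valid))
})

test_that("track cleaning flags teleports and orientation glitches", {
  p <- still_pair(n = 100)
  p$frames$rx[50] <- 10 # 10 mm in one frame at 30 Hz = 300 mm/s
  cleaned <- clean_tracks(p)
  expect_false(cleaned$frames$valid[50])
  expect_true(cleaned$frames$valid[10])
  p2 <- still_pair(n = 100)
  p2$frames$rori[30] <- 90 # 90 deg in 1/30 s = 2700 deg/s
  expect_false(clean_tracks(p2)$frames$valid[30])
  # wrap-around of orientation is not a glitch
  p3 <- still_pair(n = 100)
  p3$frames$rori <- seq(170, 170 + 99 * 2, by = 2) # smooth 60 deg/s
  expect_true(all(clean_tracks(p3)$frames$valid))
})

test_that("relative orientation is 0 ahead and positive to the right", {
  # receiver at origin facing +x; stimulus ahead
  expect_equal(relative_orientation(still_pair(sx = 3, sy = 0), 1), 0)
  # stimulus at +y (world left of heading) -> negative (receiver's left)
  expect_equal(relative_orientation(still_pair(sx = 0, sy = 3), 1), -90)
  # stimulus at -y -> receiver's right -> +90
  expect_equal(relative_orientation(still_pair(sx = 0, sy = -3), 1), 90)
  # rotate the receiver 90 deg CCW; stimulus at +y is now ahead
  expect_equal(relative_orientation(still_pair(rori = 90, sx = 0, sy = 3), 1),
               0)
  expect_error(relative_orientation(still_pair(sx = 0, sy = 0), 1),
               "coincident")
})

test_that("OSP scores a constructed preference exactly", {
  fs <- 30
  n <- 300
  # opposite-sex assay: receiver within 5 mm of the stimulus 60% of frames
  near <- c(rep(2, 180), rep(7.9, 120)) # distances from stimulus at (0,0)
  opp <- tracked_pair(data.frame(frame = 1:n, rx = -near, ry = 0, rori = 0,
                                 sx = 0, sy = 0, sori = 0),
                      fs = fs, arena_radius = 12)
  # same-sex control: within 5 mm 20% of frames
  d_same <- c(rep(2, 60), rep(7.9, 240))
  same <- tracked_pair(data.frame(frame = 1:n, rx = -d_same, ry = 0,
                                  rori = 0, sx = 0, sy = 0, sori = 0),
                       fs = fs, arena_radius = 12)
  res <- osp_score(opp, same, radius = 5, rim_margin = 2, max_radius = 12)
  expect_equal(res$osp, (180 - 60) / n * 100)
  # cumulative profile is the cumulative sum of the discrete profile
  expect_equal(cumsum(res$discrete$osp), res$cumulative$osp,
               tolerance = 1e-9)
  expect_equal(res$cumulative$osp[res$cumulative$radius == 5], res$osp)
})

test_that("OSP rim exclusion removes wall-hugging frames", {
  fs <- 30
  n <- 100
  # receiver always within 1 mm of the stimulus but parked at the rim
  opp <- tracked_pair(data.frame(frame = 1:n, rx = 7.5, ry = 0, rori = 0,
                                 sx = 7, sy = 0, sori = 0),
                      fs = fs, arena_radius = 8)
  same <- tracked_pair(data.frame(frame = 1:n, rx = -4, ry = 0, rori = 0,
                                  sx = 4, sy = 0, sori = 0),
                       fs = fs, arena_radius = 8)
  res <- osp_score(opp, same)
  expect_equal(res$osp, 0) # all near frames are rim-excluded
})

test_that("scripted turns are recovered exactly by the detector", {
  turns <- data.frame(time = c(5, 12), rel_orientation = c(45, -90),
                      ang_speed = c(90, -120))
  pair <- generate_turn_scenario(turns, total_duration = 20)
  ev <- detect_turns(pair)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$time, c(5, 12), tolerance = 0.1)
  expect_equal(ev$rel_orientation, c(45, -90), tolerance = 5)
  expect_equal(sign(ev$angular_velocity), c(1, -1))
})

test_that("sub-threshold turns are not detected", {
  slow <- data.frame(time = 5, rel_orientation = 45, ang_speed = 40)
  expect_equal(nrow(detect_turns(generate_turn_scenario(slow,
                                                        total_duration = 12))),
               0)
})

test_that("turns closer than the merge gap collapse into one event", {
  close_turns <- data.frame(time = c(5, 5.5),
                            rel_orientation = c(45, 45),
                            ang_speed = c(200, 200), duration = c(0.3, 0.3))
  pair <- generate_turn_scenario(close_turns, total_duration = 12)
  expect_equal(nrow(detect_turns(pair)), 1)
  expect_error(generate_turn_scenario(
    data.frame(time = c(5, 5.1), rel_orientation = c(0, 0),
               ang_speed = c(90, 90))), "overlap")
})

test_that("turns outside the detection range are rejected", {
  far <- data.frame(time = 5, rel_orientation = 0, ang_speed = 120,
                    centroid_dist = 8) # antennae-abdomen > 5 mm gate
  expect_equal(nrow(detect_turns(generate_turn_scenario(far,
                                                        total_duration = 12))),
               0)
  near <- data.frame(time = 5, rel_orientation = 0, ang_speed = 120,
                     centroid_dist = 1.5) # inside the 2 mm contact gate
  expect_equal(nrow(detect_turns(generate_turn_scenario(near,
                                                        total_duration = 12))),
               0)
})

test_that("random-walk trajectories stay in the arena and are seeded", {
  p1 <- generate_osp_trajectories(duration = 30, seed = 1)
  p2 <- generate_osp_trajectories(duration = 30, seed = 1)
  expect_identical(p1$frames, p2$frames)
  r <- sqrt(p1$frames$rx^2 + p1$frames$ry^2)
  expect_true(all(r <= 8 + 1e-9))
  # a fully attracted receiver converges to the stimulus
  pa <- generate_osp_trajectories(duration = 30, attraction_bias = 1,
                                  seed = 2)
  last <- tail(pa$frames, 100)
  d <- sqrt((last$rx - last$sx)^2 + (last$ry - last$sy)^2)
  expect_true(all(d < 1.5))
})
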