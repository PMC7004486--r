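test_that("wall classification follows the IR sector rule", {
  arena <- arena_spec()
  p <- navigator_params()
  expect_equal(check_wall(agent_state(50, 50, 1.3), arena, p), "none")
  # facing the inlet wall head on
  expect_equal(check_wall(agent_state(5, 50, pi), arena, p), "center")
  # wall y = 100 sits at bearing +pi/2: left sector
  expect_equal(check_wall(agent_state(50, 95, 0), arena, p), "left")
  # mirror case: wall y = 0 at bearing -pi/2 when heading 0
  expect_equal(check_wall(agent_state(50, 5, 0), arena, p), "right")
  # behind the agent: ignored
  expect_equal(check_wall(agent_state(95, 50, pi), arena, p), "none")
  # two walls within threshold (corner) is conservatively head-on
  expect_equal(check_wall(agent_state(5, 5, 0.7), arena, p), "center")
})

test_that("wall avoidance executes the quoted schedules", {
  g <- agent_geometry()
  p <- navigator_params()
  arena <- arena_spec()
  s0 <- agent_state(50, 95, 0, clock_s = 5)
  # left-side wall: turn right (heading -pi/6), then forward, 0.6 s total
  out <- avoid_wall(s0, "left", g, p, arena)
  expect_equal(out$action, "TURN_RIGHT_FWD")
  expect_equal(out$state$heading_rad, wrap_2pi(s0$heading_rad - pi / 6))
  expect_equal(out$state$clock_s, 5.6)
  # forward 200 ms at 4 cm/s along the post-turn heading
  d <- c(out$state$x_cm - 50, out$state$y_cm - 95)
  expect_equal(sqrt(sum(d^2)), 0.8)
  expect_equal(atan2(d[2], d[1]), -pi / 6)
  # right-side wall turns left
  out <- avoid_wall(agent_state(50, 5, 0), "right", g, p, arena)
  expect_equal(out$action, "TURN_LEFT_FWD")
  expect_equal(out$state$heading_rad, pi / 6)
  # head-on: turn right then back up 0.8 cm opposite the post-turn heading
  s0 <- agent_state(5, 50, pi)
  out <- avoid_wall(s0, "center", g, p, arena)
  expect_equal(out$action, "TURN_RIGHT_BACKUP")
  th <- wrap_2pi(pi - pi / 6)
  d <- c(out$state$x_cm - 5, out$state$y_cm - 50)
  expect_equal(sqrt(sum(d^2)), 0.8)
  expect_equal(wrap_pi(atan2(d[2], d[1]) - (th + pi)), 0)
  expect_equal(out$state$clock_s - s0$clock_s, 0.6)
})

test_that("Code A turns toward the stronger sensor above threshold", {
  p <- navigator_params("A")
  expect_equal(decide_code_a(0.15, 0.10, 0, p), "TURN_LEFT_FWD")   # d = 0.05
  expect_equal(decide_code_a(0.10, 0.15, 0, p), "TURN_RIGHT_FWD")
  expect_equal(decide_code_a(0.12, 0.10, 0, p), "FWD")             # d = 0.02
  expect_equal(decide_code_a(0.2, 0.2, 0, p), "FWD")
  # strict inequality: exactly at threshold falls through
  expect_equal(decide_code_a(0.13, 0.10, 0, p), "FWD")
  # baseline correction cancels
  expect_equal(decide_code_a(0.15, 0.10, 5, p), "TURN_LEFT_FWD")
})

test_that("Code B goes straight on a rising pair sum, else binaral rules", {
  p <- navigator_params("B")
  # pair sum rose 0.4 -> 0.5: dC = 0.05 > 0.0075, straight wins precedence
  d <- decide_code_b(0.3, 0.2, prev_pair_sum = 0.4, 0, p)
  expect_equal(d$action, "FWD")
  expect_equal(d$pair_sum, 0.5)
  # flat pair sum, left-right difference 0.02 > thr/2 = 0.015
  d <- decide_code_b(0.26, 0.24, prev_pair_sum = 0.5, 0, p)
  expect_equal(d$action, "TURN_LEFT_FWD")
  d <- decide_code_b(0.24, 0.26, prev_pair_sum = 0.5, 0, p)
  expect_equal(d$action, "TURN_RIGHT_FWD")
  # flat and balanced: default straight
  d <- decide_code_b(0.25, 0.25, prev_pair_sum = 0.5, 0, p)
  expect_equal(d$action, "FWD")
  # falling pair sum does not fire rule 1
  d <- decide_code_b(0.2, 0.2, prev_pair_sum = 0.5, 0, p)
  expect_equal(d$action, "FWD")
})

test_that("zero plume yields straight-line failure with only FWD decisions", {
  # corner source: the blind straight walk down the midline stays >= 25 cm
  # from it, so no odor and no luck can produce a capture
  tr <- run_trial(zero_plume(), navigator_params("A"), start_angle_deg = 180,
                  source = "corner")
  expect_false(tr$success)
  expect_true(is.na(tr$time_to_target_s))
  nav <- tr$trajectory[tr$trajectory$provenance != "baseline", ]
  pre_wall <- nav[seq_len(max(which(cumsum(nav$provenance == "wall") == 0))), ]
  expect_true(all(pre_wall$action == "FWD"))
  expect_equal(unique(pre_wall$heading_rad), pi)
  expect_equal(unique(pre_wall$y_cm), 50)
  # with no odor everything from the odor controller is a straight move
  expect_true(all(nav$action[nav$provenance == "odor"] == "FWD"))
})

test_that("Code B in a uniform constant field acts as always-forward", {
  tr <- run_trial(uniform_static(0.4), navigator_params("B",
                                                        time_budget_s = 6),
                  start_pose = agent_state(50, 50, deg2rad(45)))
  nav <- tr$trajectory[tr$trajectory$provenance != "baseline", ]
  expect_true(all(nav$provenance == "odor"))
  expect_true(all(nav$action == "FWD"))
})

test_that("a straight static gradient is climbed to success", {
  tr <- run_trial(acc_static(), navigator_params("A"), start_angle_deg = 180)
  expect_true(tr$success)
  expect_lte(tr$time_to_target_s, 75)
  # distance to the source shrinks over the navigation phase
  nav <- tr$trajectory[tr$trajectory$provenance != "baseline", ]
  d <- sqrt((nav$x_cm - tr$source[1])^2 + (nav$y_cm - tr$source[2])^2)
  idx <- seq(1, length(d), by = 50)   # every 5 s
  expect_true(all(diff(d[idx]) < 1))
  expect_lt(d[length(d)], tr$params$success_radius_cm)
})

test_that("trials are deterministic given the plume state", {
  a <- run_trial(acc_static(), navigator_params("B"), start_angle_deg = 126)
  b <- run_trial(acc_static(), navigator_params("B"), start_angle_deg = 126)
  expect_identical(a$trajectory, b$trajectory)
  a <- run_trial(acc_movie(), navigator_params("A"), start_angle_deg = 216,
                 seed = 77)
  b <- run_trial(acc_movie(), navigator_params("A"), start_angle_deg = 216,
                 seed = 77)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$start_frame, b$start_frame)
  # an explicit start frame pins the dynamic trajectory too
  c1 <- run_trial(acc_movie(), navigator_params("A"), start_angle_deg = 216,
                  start_frame = a$start_frame)
  expect_identical(a$trajectory, c1$trajectory)
})

test_that("navigation clock and containment respect their bounds", {
  tr <- run_trial(zero_plume(), navigator_params("A"), start_angle_deg = 96)
  nav_t <- max(tr$trajectory$t_s) - 12
  expect_lte(nav_t, 75 + 0.6 + 1e-9)
  expect_gt(nav_t, 74)
  expect_true(all(tr$trajectory$x_cm >= 0 & tr$trajectory$x_cm <= 100))
  expect_true(all(tr$trajectory$y_cm >= 0 & tr$trajectory$y_cm <= 100))
})

test_that("trial validates its configuration before simulating", {
  expect_error(run_trial(acc_static(),
                         start_pose = agent_state(120, 50, 0)),
               "inside the arena")
  expect_error(run_trial(acc_static(), source = "nope"), "unknown port")
  expect_error(run_trial("not a plume"), "static_plume or dynamic_plume")
  expect_error(run_trial(acc_static(),
                         navigator_params(pause_s = 0.35, turn_s = 0.1)),
               "integer multiples")
})

test_that("trajectory CSV and JSON sidecar round-trip", {
  tr <- run_trial(acc_static(), navigator_params("A",
                                                 time_budget_s = 10),
                  start_angle_deg = 180)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(tr$trajectory))
  expect_equal(back$x_cm, tr$trajectory$x_cm)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$success, tr$success)
  expect_equal(side$start_frame, tr$start_frame)
  expect_equal(side$params$code, "A")
})
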