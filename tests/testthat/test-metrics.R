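test_that("linearity matches closed forms and a segment-sum oracle", {
  straight <- tracked_path(0:4, seq(0, 8, 2), rep(1, 5))
  expect_equal(path_linearity(straight), 1.0)
  l_path <- tracked_path(0:2, c(0, 3, 3), c(0, 0, 4))
  expect_equal(path_linearity(l_path), 5 / 7)
  rw <- random_walk_path(200, seed = 5)
  # independent brute-force oracle
  seg <- 0
  for (i in 2:200) {
    seg <- seg + sqrt((rw$body_x[i] - rw$body_x[i - 1])^2 +
                      (rw$body_y[i] - rw$body_y[i - 1])^2)
  }
  eu <- sqrt((rw$body_x[200] - rw$body_x[1])^2 +
             (rw$body_y[200] - rw$body_y[1])^2)
  expect_equal(path_linearity(rw), eu / seg, tolerance = 1e-12)
  expect_lte(path_linearity(rw), 1)
  expect_error(path_linearity(tracked_path(0:1, c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("total angle sum matches geometric cases and a pairwise oracle", {
  expect_equal(total_angle_sum(tracked_path(0:3, 0:3, rep(0, 4))), 0)
  # three sides of a square: two 90-degree turns
  square3 <- tracked_path(0:3, c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(total_angle_sum(square3), 180)
  rw <- random_walk_path(120, seed = 9)
  # independently coded pairwise-angle loop
  oracle <- 0
  prev <- NULL
  for (i in 2:120) {
    dx <- rw$body_x[i] - rw$body_x[i - 1]
    dy <- rw$body_y[i] - rw$body_y[i - 1]
    h <- atan2(dy, dx)
    if (!is.null(prev)) {
      dh <- h - prev
      while (dh > pi) dh <- dh - 2 * pi
      while (dh <= -pi) dh <- dh + 2 * pi
      oracle <- oracle + abs(dh) * 180 / pi
    }
    prev <- h
  }
  expect_equal(total_angle_sum(rw), oracle, tolerance = 1e-9)
  # zero-displacement frames are skipped, not counted as turns
  dup <- tracked_path(0:4, c(0, 1, 1, 1, 0), c(0, 0, 0, 1, 1))
  expect_equal(total_angle_sum(dup), 180)
})

test_that("angle sum is invariant under rotation and translation", {
  rw <- random_walk_path(80, seed = 13)
  base <- total_angle_sum(rw)
  for (ang in c(0.3, 1.7, 4)) {
    xs <- rw$body_x * cos(ang) - rw$body_y * sin(ang) + 12
    ys <- rw$body_x * sin(ang) + rw$body_y * cos(ang) - 7
    expect_equal(total_angle_sum(tracked_path(rw$t_s, xs, ys)), base,
                 tolerance = 1e-9)
  }
})

test_that("wall hugging counts frames inside the band", {
  arena <- arena_spec()
  theta <- seq(0, 2 * pi, length.out = 100)
  center_circle <- tracked_path(seq_along(theta), 50 + 10 * cos(theta),
                                50 + 10 * sin(theta))
  expect_equal(wall_hugging_fraction(center_circle, arena), 0)
  wall_trace <- tracked_path(1:50, seq(2, 98, length.out = 50), rep(2, 50))
  expect_equal(wall_hugging_fraction(wall_trace, arena), 1)
  # constructed fixture: exactly 30% of frames within 5 cm of a wall
  xs <- c(rep(3, 30), rep(50, 70))
  mixed <- tracked_path(1:100, xs, rep(50, 100))
  expect_equal(wall_hugging_fraction(mixed, arena), 0.3)
  # monotone in the band width
  rw <- tracked_path(1:60, runif(60, 1, 99), runif(60, 1, 99))
  fr <- vapply(c(1, 5, 10, 25), function(b)
    wall_hugging_fraction(rw, arena, b), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("nose metrics: ratio and per-frame bearing change", {
  t <- 0:100
  same <- tracked_path(t, t, rep(0, 101), nose_x = t, nose_y = rep(0, 101))
  expect_equal(nose_body_ratio(same), 1.0)
  # zig-zagging nose over a straight body: ratio > 1
  zig <- tracked_path(t, t, rep(0, 101), nose_x = t,
                      nose_y = rep(c(2, -2), length.out = 101))
  expect_gt(nose_body_ratio(zig), 1)
  # sinusoidal nose against a numerical arc-length oracle
  h <- 0.00025
  tt <- seq(0, 10, by = h)
  nose_y <- 0.5 * sin(2 * pi * tt)
  fine <- tracked_path(tt, tt, rep(0, length(tt)), nose_x = tt,
                       nose_y = nose_y)
  oracle <- stats::integrate(function(u)
    sqrt(1 + (0.5 * 2 * pi * cos(2 * pi * u))^2), 0, 10,
    rel.tol = 1e-10)$value / 10
  expect_equal(nose_body_ratio(fine), oracle, tolerance = 1e-6)
  expect_error(nose_body_ratio(tracked_path(0:1, c(0, 1), c(0, 0))),
               "no nose track")
})

test_that("delta nose angle: rigid motion is 0, orbiting is the step angle", {
  t <- 0:50
  rigid <- tracked_path(t, t, t, nose_x = t + 3, nose_y = t + 1)
  expect_equal(delta_nose_angle(rigid)$mean_deg, 0)
  ang <- deg2rad(10 * (0:35))
  orbit <- tracked_path(0:35, rep(5, 36), rep(5, 36),
                        nose_x = 5 + 2 * cos(ang), nose_y = 5 + 2 * sin(ang))
  expect_equal(delta_nose_angle(orbit)$mean_deg, 10, tolerance = 1e-9)
  # random fixture vs independent bearing-difference oracle
  set.seed(21)
  n <- 40
  bx <- cumsum(rnorm(n)); by <- cumsum(rnorm(n))
  nx <- bx + runif(n, 0.5, 2); ny <- by + runif(n, 0.5, 2)
  p <- tracked_path(1:n, bx, by, nose_x = nx, nose_y = ny)
  bearings <- atan2(ny - by, nx - bx)
  dd <- abs(((diff(bearings) + pi) %% (2 * pi)) - pi) * 180 / pi
  expect_equal(delta_nose_angle(p)$per_frame_deg, dd, tolerance = 1e-9)
  # coincident points are skipped with a message
  co <- tracked_path(0:3, c(0, 1, 2, 3), rep(0, 4),
                     nose_x = c(1, 1, 3, 4), nose_y = rep(0, 4))
  expect_message(delta_nose_angle(co), "skipped 1")
})

test_that("resampling hits the frame count and preserves endpoints", {
  tr <- run_trial(acc_static(), navigator_params("A", time_budget_s = 20),
                  start_angle_deg = 160)
  p <- as_tracked_path(tr)
  r <- resample_path(p, 755)
  expect_equal(nrow(r), 755)
  expect_equal(c(r$body_x[1], r$body_y[1]), c(p$body_x[1], p$body_y[1]))
  expect_equal(c(r$body_x[755], r$body_y[755]),
               c(p$body_x[nrow(p)], p$body_y[nrow(p)]))
  const <- tracked_path(0:9, rep(2, 10), rep(3, 10))
  rc <- resample_path(const, 20)
  expect_true(all(rc$body_x == 2) && all(rc$body_y == 3))
  # linearity is stable under 10x upsampling
  expect_equal(path_linearity(resample_path(p, 10 * nrow(p))),
               path_linearity(p), tolerance = 0.01)
})

test_that("condition summaries report mean, SEM and Bonferroni pairs", {
  set.seed(6)
  df <- data.frame(
    cond = rep(c("a", "b"), each = 30),
    success = rep(c(TRUE, FALSE), c(40, 20)),
    linearity = c(rnorm(30, 0.8, 0.05), rnorm(30, 0.5, 0.05)))
  out <- summarize_conditions(df, "cond", metrics = "linearity")
  s <- out$summary
  expect_equal(s$n, c(30, 30))
  expect_equal(s$pct_success[s$group == "a"], 100)
  a_vals <- df$linearity[df$cond == "a"]
  expect_equal(s$linearity_mean[s$group == "a"], mean(a_vals))
  # SEM equals sd/sqrt(n) computed independently
  expect_equal(s$linearity_sem[s$group == "a"],
               sqrt(sum((a_vals - mean(a_vals))^2) / 29) / sqrt(30))
  cmp <- out$comparisons
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$diff, mean(a_vals) - mean(df$linearity[df$cond == "b"]))
  expect_lt(cmp$p_bonferroni, 0.001)
  # empty factor levels are dropped with a warning
  df$cond <- factor(df$cond, levels = c("a", "b", "ghost"))
  expect_warning(summarize_conditions(df, "cond", metrics = "linearity"),
                 "ghost")
})

test_that("simulated trials convert to tracked paths with a nose point", {
  tr <- run_trial(acc_static(), navigator_params("A", time_budget_s = 5),
                  start_angle_deg = 180)
  p <- as_tracked_path(tr)
  expect_s3_class(p, "tracked_path")
  expect_true(has_nose <- all(c("nose_x", "nose_y") %in% names(p)))
  # nose leads the body by one chassis radius
  d <- sqrt((p$nose_x - p$body_x)^2 + (p$nose_y - p$body_y)^2)
  expect_equal(unique(round(d, 9)), 8)
  expect_false(any(p$t_s < 12))   # baseline phase dropped
})
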