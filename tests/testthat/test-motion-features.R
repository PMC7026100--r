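make_visible_traj <- function(x, y, fps = 25) {
  trajectory(seq_along(x) - 1L, x, y, rep(TRUE, length(x)), fps = fps)
}

test_that("window selection maximizes visibility with earliest-start ties", {
  n <- 180 * 25
  full <- trajectory(0:(n - 1), runif(n), runif(n), rep(TRUE, n))
  w <- select_window(full, 60)
  expect_equal(nrow(w), 1500)
  expect_equal(w$x, full$x[1:1500]) # tie broken by earliest start

  vis <- rep(FALSE, n); vis[(60 * 25 + 1):(120 * 25)] <- TRUE
  part <- trajectory(0:(n - 1), runif(n), runif(n), vis)
  w2 <- select_window(part, 60)
  expect_equal(mean(w2$visible), 1)
  expect_equal(w2$x, part$x[(60 * 25 + 1):(120 * 25)])

  short <- make_visible_traj(runif(10), runif(10))
  expect_warning(select_window(short, 60), "shorter")
})

test_that("window selection matches the exhaustive visibility scan", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 500
    vis <- runif(n) < 0.6
    tr <- trajectory(0:(n - 1), runif(n), runif(n), vis)
    win <- 100
    w <- select_window(tr, win / 25)
    brute <- max(vapply(1:(n - win + 1),
                        function(s) sum(vis[s:(s + win - 1)]), 0L))
    expect_equal(sum(w$visible), brute)
  }
})

test_that("spatial descriptors follow unit-square geometry", {
  sq <- make_visible_traj(c(0, 1, 0, 1), c(0, 0, 1, 1))
  d <- spatial_descriptors(sq)
  expect_equal(unname(d["xRange"]), 1)
  expect_equal(unname(d["yRange"]), 1)
  expect_equal(unname(d["maxPairDist"]), sqrt(2))

  same <- make_visible_traj(rep(0.3, 5), rep(0.3, 5))
  d0 <- spatial_descriptors(same)
  expect_equal(unname(d0[c("xRange", "yRange", "xSd", "ySd",
                           "maxPairDist")]), rep(0, 5))

  one <- trajectory(0:2, c(0.1, NA, NA), c(0.1, NA, NA),
                    c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(spatial_descriptors(one))))
})

test_that("farthest pair equals the quadratic scan on random point sets", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(farthest_pair_distance(x, y), oracle_farthest_pair(x, y),
                 tolerance = 1e-12)
  }
})

test_that("kinematics recover closed-form speeds", {
  cfg <- run_config(smooth_frames = 1)
  # uniform linear motion: speed d*fps everywhere, acceleration ~ 0
  d <- 0.004
  lin <- make_visible_traj(cumsum(rep(d, 100)), rep(0.5, 100))
  kin <- kinematics(lin, cfg)
  expect_equal(kin$speed[!is.na(kin$speed)],
               rep(d * 25, 100), tolerance = 1e-9)
  expect_lt(max(kin$acc, na.rm = TRUE), 1e-9)

  still <- make_visible_traj(rep(0.2, 50), rep(0.2, 50))
  expect_true(all(kinematics(still, cfg)$speed == 0))

  # sinusoid x(t) = sin(2 pi t): analytic velMax = 2 pi
  t <- seq(0, 2, by = 1 / 25)
  sine <- make_visible_traj(sin(2 * pi * t), rep(0, length(t)))
  expect_lt(abs(kinematics(sine, cfg)$velMax - 2 * pi) / (2 * pi), 0.02)
})

test_that("derivatives never cross invisibility gaps", {
  x <- c(seq(0, 0.1, length.out = 10), seq(0.9, 1, length.out = 10))
  vis <- rep(TRUE, 20)
  tr <- trajectory(0:19, x, rep(0.5, 20), vis)
  tr$visible[10] <- FALSE; tr$x[10] <- NA
  kin <- kinematics(tr, run_config(smooth_frames = 1))
  # the jump between the runs (0.1 -> 0.9) must not appear as a speed
  expect_lt(max(kin$speed, na.rm = TRUE), 0.9 * 25)
  expect_true(is.na(kin$speed[10]))
})

test_that("pause detection obeys the 4-s minimum and matches the run scan", {
  fps <- 25
  all_zero <- rep(0, 60 * fps)
  p <- detect_pauses(all_zero, fps, threshold = 1e-6, min_dur_s = 4,
                     visible_duration_s = 60)
  expect_equal(p$pauseCount, 1)
  expect_equal(p$pauseRelTime, 1)

  spd <- rep(1, 60 * fps)
  spd[100:174] <- 0 # 3-s run: below the minimum
  expect_equal(detect_pauses(spd, fps, 0.5, 4)$pauseCount, 0)
  spd[100:199] <- 0 # exactly 4 s
  expect_equal(detect_pauses(spd, fps, 0.5, 4)$pauseCount, 1)

  set.seed(31)
  for (rep in 1:10) {
    s <- runif(600)
    s[sample(600, 60)] <- NA
    got <- detect_pauses(s, fps, 0.5, 1.2)
    want <- oracle_pause_runs(s, fps, 0.5, 1.2)
    expect_equal(as_num_mat(got$intervals), as_num_mat(want))
  }
})

test_that("curvature matches closed forms on circle, line and parabola", {
  t <- seq(0, 2 * pi, by = 1 / 25)
  circ <- make_visible_traj(2 * cos(t), 2 * sin(t))
  crv <- curvature(circ, run_config(), eps_speed = 1e-6)
  kk <- crv$kappa[!is.na(crv$kappa)]
  expect_true(all(abs(kk - 0.5) / 0.5 < 0.02))

  line <- make_visible_traj(seq(0, 1, length.out = 100),
                            seq(0, 0.5, length.out = 100))
  expect_lt(curvature(line, run_config(), eps_speed = 1e-9)$curvMax, 1e-6)

  x <- seq(-1, 1, by = 1 / 25)
  para <- make_visible_traj(x, x^2)
  kap <- curvature(para, run_config(smooth_frames = 1),
                   eps_speed = 1e-9)$kappa
  at0 <- kap[which.min(abs(x))]
  expect_lt(abs(at0 - 2) / 2, 0.02) # kappa(0) = 2 for y = x^2
})

test_that("the full descriptor vector has 21 fields with coherent pauses", {
  still <- make_visible_traj(rep(0.5, 1500), rep(0.5, 1500))
  mf <- suppressMessages(motion_features(still))
  expect_length(mf, 21)
  expect_equal(unname(mf["pauseCount"]), 1)
  expect_equal(unname(mf["velMax"]), 0)
  expect_equal(unname(mf["visibleFraction"]), 1)

  tr <- make_trajectory(motion_params(pause_rate = 3, pause_dur_mean_s = 5,
                                      occlusion_rate = 0),
                        duration_s = 60, seed = 17)
  mf2 <- suppressMessages(motion_features(tr))
  expect_equal(unname(mf2["pauseCount"]),
               nrow(attr(tr, "pause_truth")))
})

test_that("descriptors are scale-equivariant and time-reversal invariant", {
  tr <- make_trajectory(motion_params(pause_rate = 2, occlusion_rate = 2),
                        duration_s = 30, seed = 23)
  mf <- suppressMessages(motion_features(tr))
  c_scale <- 3.7
  scaled <- trajectory(tr$frame, tr$x * c_scale, tr$y * c_scale, tr$visible)
  mfs <- suppressMessages(motion_features(scaled))
  for (nm in c("xRange", "yRange", "xSd", "ySd", "maxPairDist",
               "pathLength", "velMax")) {
    expect_equal(unname(mfs[nm]), unname(mf[nm]) * c_scale,
                 tolerance = 1e-9)
  }
  for (nm in c("pauseRelTime", "visibleFraction", "pauseCount")) {
    expect_equal(unname(mfs[nm]), unname(mf[nm]), tolerance = 1e-9)
  }

  rev_tr <- trajectory(tr$frame, rev(tr$x), rev(tr$y), rev(tr$visible))
  mfr <- suppressMessages(motion_features(rev_tr))
  for (nm in c("xRange", "yRange", "xSd", "ySd", "maxPairDist",
               "pauseTotalDur_s", "pauseCount")) {
    expect_equal(unname(mfr[nm]), unname(mf[nm]), tolerance = 1e-9)
  }
})
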