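# build a trajectory tibble from per-frame displacement vectors (normalized)
traj_from_steps <- function(steps_x, steps_y, id = 1L, start = c(0.5, 0.5)) {
  cx <- start[1] + cumsum(c(0, steps_x))
  cy <- start[2] + cumsum(c(0, steps_y))
  tibble::tibble(
    frame = seq_along(cx) - 1L, id = id, cx = cx, cy = cy, w = 0.1, h = 0.04
  )
}

# normalized step length corresponding to v m/s at the default calibration
step_for <- function(v, k = 0.01, fps = 30, W = 1000) v / (k * fps * W)

test_that("kinematics recovers displacement, speed and heading", {
  still <- traj_from_steps(rep(0, 59), rep(0, 59))
  kin <- kinematics(still)
  expect_true(all(kin$delta_d == 0))
  expect_true(all(kin$v == 0))
  # constant-velocity track: v = k * fps * pixel step
  s <- step_for(0.05)
  lin <- traj_from_steps(rep(s, 59), rep(0, 59))
  kin2 <- kinematics(lin)
  expect_equal(unique(round(kin2$v, 12)), 0.05)
  expect_equal(unique(kin2$heading), 0)
  # median smoothing leaves a constant series unchanged
  expect_equal(kin2$v, rep(0.05, 59), tolerance = 1e-12)
  # single-frame track yields no kinematics
  expect_equal(nrow(kinematics(still[1, ])), 0L)
})

test_that("the three behavior rules fire on their construction segments", {
  fps <- 30
  # stationary: tiny displacement for 5 s
  still <- traj_from_steps(rep(1e-5, 5 * fps), rep(0, 5 * fps))
  lab1 <- classify_behavior(kinematics(still), fps = fps)
  expect_true(all(lab1$label == "stationary"))
  # swim-breathing: fast dash (0.12 m/s, step 4e-3 > 0.01? delta_d uses the
  # normalized step; use a diagonal step large enough)
  s_fast <- step_for(0.12)
  dash <- traj_from_steps(rep(0.011, 4 * fps), rep(0, 4 * fps), start = c(0.1, 0.5))
  kin_dash <- kinematics(dash)
  expect_true(all(kin_dash$delta_d > 0.01))
  expect_true(all(kin_dash$v > 0.08))
  lab2 <- classify_behavior(kin_dash, fps = fps)
  expect_true(all(lab2$label == "swim_breathing"))
  # foraging: 0.05 m/s with a 90 degree turn inside 10 s
  s_mid <- step_for(0.05)
  n_half <- 5 * fps
  forage <- traj_from_steps(
    c(rep(s_mid, n_half), rep(0, n_half)),
    c(rep(0, n_half), rep(s_mid, n_half)),
    start = c(0.2, 0.2)
  )
  lab3 <- classify_behavior(kinematics(forage), fps = fps)
  expect_true(mean(lab3$label == "foraging") > 0.9)
  # same speed without turning: not foraging
  straight <- traj_from_steps(rep(s_mid, 10 * fps), rep(0, 10 * fps), start = c(0.05, 0.5))
  lab4 <- classify_behavior(kinematics(straight), fps = fps)
  expect_true(all(lab4$label == "unclassified"))
})

test_that("classification is threshold-monotone in the stationary ceiling", {
  set.seed(5)
  steps <- step_for(runif(300, 0.005, 0.04))
  tr <- traj_from_steps(steps * 0.3, steps * 0.2, start = c(0.3, 0.3))
  kin <- kinematics(tr)
  n_still <- function(vc) {
    lab <- classify_behavior(kin, behavior_rules(still_v = vc, min_run_s = 0), fps = 30)
    sum(lab$label == "stationary")
  }
  counts <- vapply(c(0.01, 0.02, 0.04, 0.08), n_still, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("behavior intervals partition each track without overlap", {
  fps <- 30
  s_mid <- step_for(0.05)
  tr <- traj_from_steps(
    c(rep(1e-5, 4 * fps), rep(0.011, 2 * fps), rep(s_mid, 2 * fps)),
    rep(0, 8 * fps), start = c(0.1, 0.5)
  )
  lab <- classify_behavior(kinematics(tr), fps = fps)
  iv <- behavior_intervals(lab)
  expect_true(all(iv$end >= iv$start))
  expect_equal(sum(iv$n_frames), nrow(lab))
  expect_true(all(diff(iv$start) > 0))
})

test_that("rhythm summary computes time-weighted day/night proportions", {
  fps <- 30
  # 95.5% stationary / 4.1% swim / 0.4% forage by construction, all daytime
  n <- 1000L
  lab <- tibble::tibble(
    id = 1L, frame = seq_len(n) - 1L,
    label = factor(
      rep(c("stationary", "swim_breathing", "foraging"), c(955, 41, 4)),
      levels = c("stationary", "swim_breathing", "foraging", "unclassified")
    )
  )
  rs <- rhythm_summary(lab, start_time = "08:00:00", fps = fps)
  expect_equal(rs$period, rep("day", 3))
  expect_equal(rs$proportion[rs$label == "stationary"], 0.955, tolerance = 1e-9)
  expect_equal(rs$proportion[rs$label == "swim_breathing"], 0.041, tolerance = 1e-9)
  expect_equal(sum(rs$proportion), 1, tolerance = 1e-9)
  expect_equal(sum(rs$seconds), n / fps)
  # unclassified time is excluded from the denominator
  lab2 <- lab
  lab2$label[1:100] <- "unclassified"
  rs2 <- rhythm_summary(lab2, start_time = "08:00:00", fps = fps)
  expect_equal(sum(rs2$proportion, na.rm = TRUE), 1, tolerance = 1e-9)
  # id permutation invariance
  lab3 <- lab
  lab3$id <- rep(c(2L, 9L), length.out = n)
  rs3 <- rhythm_summary(lab3, start_time = "08:00:00", fps = fps)
  expect_equal(rs3$proportion, rs$proportion)
  # splitting at midnight conserves durations
  rs_night <- rhythm_summary(lab, start_time = "17:59:50", fps = fps)
  expect_equal(sum(rs_night$seconds), n / fps)
  expect_setequal(unique(rs_night$period), c("day", "night"))
})
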