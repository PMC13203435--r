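test_that("scene classification follows the image-statistic rules", {
  th <- list(b_night = 0.25, v_turbid = 0.01, e_turbid = 0.05)
  expect_equal(
    classify_scene(list(mean_brightness = 0.7, pixel_variance = 0.1, edge_density = 0.2), th),
    "daytime"
  )
  expect_equal(
    classify_scene(list(mean_brightness = 0, pixel_variance = 0.1, edge_density = 0.2), th),
    "nighttime"
  )
  expect_equal(
    classify_scene(list(mean_brightness = 0.6, pixel_variance = 0.005, edge_density = 0.01), th),
    "turbid"
  )
  expect_equal(classify_scene(NULL, th, override = "turbid"), "turbid")
})

test_that("detection filtering applies the scene confidence floor", {
  dets <- tibble::tibble(cx = 0.5, cy = 0.5, w = 0.1, h = 0.1, conf = 0.4)
  expect_equal(nrow(filter_detections(dets, scene_context("daytime"))), 0L)
  expect_equal(nrow(filter_detections(dets, scene_context("nighttime"))), 1L)
  expect_equal(nrow(filter_detections(dets[0, ], scene_context("daytime"))), 0L)
})

test_that("a clean single target yields one confirmed stable track", {
  sc <- simulate_scenario(
    scenario_config(
      n_targets = 1L, n_frames = 20L, miss_prob = 0, sigma_center = 0,
      sigma_size = 0, fp_rate = 0, seed = 1L
    )
  )
  trk <- track_sequence(sc$detections, tracker_config())
  expect_equal(length(unique(trk$id)), 1L)
  expect_equal(nrow(trk), 20L) # confirmation back-fills the first frames
  m <- mot_metrics(sc$truth, trk)
  expect_equal(m$MOTA, 100)
  expect_equal(m$IDs, 0L)
})

test_that("noise-free linear motion reproduces ground truth exactly", {
  sc <- simulate_scenario(
    preset("crossing", n_frames = 60L, miss_prob = 0, sigma_center = 0,
           sigma_size = 0, fp_rate = 0),
    seed = 3L
  )
  trk <- track_sequence(sc$detections, tracker_config())
  m <- mot_metrics(sc$truth, trk)
  expect_equal(m$MOTA, 100)
  expect_equal(m$IDs, 0L)
  expect_equal(m$Frag, 0L)
  gt <- dplyr::arrange(sc$truth, frame, cx)
  hy <- dplyr::arrange(tibble::as_tibble(trk), frame, cx)
  expect_equal(hy$cx, gt$cx, tolerance = 1e-12)
  expect_equal(hy$cy, gt$cy, tolerance = 1e-12)
  expect_equal(hy$w, gt$w, tolerance = 1e-12)
  expect_equal(hy$h, gt$h, tolerance = 1e-12)
})

test_that("short detector gaps keep the identity alive", {
  sc <- simulate_scenario(
    scenario_config(
      n_targets = 1L, n_frames = 40L, miss_prob = 0, sigma_center = 0,
      sigma_size = 0, fp_rate = 0, seed = 2L
    )
  )
  dets <- sc$detections[!(sc$detections$frame %in% c(15L, 16L)), ]
  trk <- track_sequence(dets, tracker_config())
  expect_equal(length(unique(trk$id)), 1L)
  expect_false(any(trk$frame %in% c(15L, 16L))) # no hallucinated boxes
  m <- mot_metrics(sc$truth, trk)
  expect_equal(m$IDs, 0L)
  expect_equal(m$Frag, 1L)
})

test_that("ids are strictly increasing and never reused", {
  sc <- simulate_scenario(preset("nighttime", n_frames = 200L), seed = 4L)
  trk <- track_sequence(sc$detections, tracker_config(scene = "nighttime"))
  log <- attr(trk, "log")
  expect_s3_class(log, "tbl_df")
  first_seen <- tapply(trk$frame, trk$id, min)
  expect_true(all(diff(as.integer(names(sort(first_seen)))) > 0))
})

test_that("crossing targets with distinct appearance keep their ids", {
  sc <- simulate_scenario(preset("crossing", n_frames = 150L), seed = 6L)
  trk <- track_sequence(sc$detections, tracker_config())
  m <- mot_metrics(sc$truth, trk)
  expect_equal(m$IDs, 0L)
  expect_gte(m$MOTA, 90)
})

test_that("out-of-order frames are rejected", {
  st <- tracker_init(tracker_config())
  dets <- tibble::tibble(cx = 0.5, cy = 0.5, w = 0.1, h = 0.1, conf = 0.9)
  tracker_step(st, 0L, dets)
  tracker_step(st, 1L, dets)
  expect_error(tracker_step(st, 1L, dets), "increasing")
})

test_that("empty detection tables yield a valid empty run", {
  trk <- track_sequence(
    tibble::tibble(frame = integer(), cx = numeric(), cy = numeric(),
                   w = numeric(), h = numeric(), conf = numeric()),
    tracker_config()
  )
  expect_equal(nrow(trk), 0L)
})

test_that("identical inputs give byte-identical outputs", {
  sc <- simulate_scenario(preset("occlusion"), seed = 5L)
  t1 <- track_sequence(sc$detections, tracker_config(scene = "occlusion"))
  t2 <- track_sequence(sc$detections, tracker_config(scene = "occlusion"))
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("a stage-3 reactivation preserves the id across a long occlusion", {
  # single target, full occlusion longer than max_age but within the TTL
  cfg <- scenario_config(
    n_targets = 1L, n_frames = 200L, miss_prob = 0, sigma_center = 1e-3,
    sigma_size = 0.01, fp_rate = 0,
    occlusions = tibble::tibble(id = 1L, start = 80L, end = 139L), seed = 8L
  )
  sc <- simulate_scenario(cfg)
  with3 <- track_sequence(sc$detections, tracker_config(scene = "occlusion"))
  no3 <- track_sequence(sc$detections, tracker_config(scene = "occlusion", use_stage3 = FALSE))
  expect_equal(length(unique(with3$id)), 1L)
  expect_gt(length(unique(no3$id)), 1L)
  m3 <- mot_metrics(sc$truth, with3)
  m0 <- mot_metrics(sc$truth, no3)
  expect_lte(m3$IDs, m0$IDs)
})
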