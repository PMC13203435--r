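test_that("similarity kernels match their definitions", {
  f <- c(1, 2, 3)
  expect_equal(cosine_similarity(f, 3 * f), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(f, -f), -1)
  expect_error(cosine_similarity(f, c(0, 0, 0)), "zero vector")

  h <- c(0.2, 0.3, 0.5)
  expect_equal(bhattacharyya(h, h), 1)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  expect_equal(
    bhattacharyya(c(0.5, 0.5, 0, 0), c(0.25, 0.75, 0, 0)),
    sqrt(0.125) + sqrt(0.375)
  )
  expect_error(bhattacharyya(c(1, 0), c(1, 0, 0)), "length")
})

test_that("fused similarity is the omega-weighted mean with its bounds", {
  expect_equal(fused_similarity(1, 0, 0.7), 0.7)
  expect_equal(fused_similarity(0, 1, 0.7), 0.3)
  expect_equal(fused_similarity(0.4, 0.9, 1), 0.4)
  # monotone in both arguments, bounded by the two scores
  set.seed(3)
  for (i in 1:50) {
    sa <- runif(1); sm <- runif(1); w <- runif(1)
    s <- fused_similarity(sa, sm, w)
    expect_gte(s, min(sa, sm) - 1e-12)
    expect_lte(s, max(sa, sm) + 1e-12)
    expect_gte(fused_similarity(sa + 0.05, sm, w), s)
    expect_gte(fused_similarity(sa, sm + 0.05, w), s)
  }
})

test_that("flow direction histograms bin by angle with magnitude weights", {
  h <- flow_direction_histogram(rep(1, 10), rep(0, 10), n_bins = 8)
  expect_equal(h, c(1, rep(0, 7)))
  # equal magnitudes at all bin centers -> uniform
  centers <- (seq_len(8) - 0.5) * 2 * pi / 8
  h2 <- flow_direction_histogram(cos(centers), sin(centers), n_bins = 8)
  expect_equal(h2, rep(1 / 8, 8))
  # half +x, half +y
  h3 <- flow_direction_histogram(c(1, 1, 0, 0), c(0, 0, 1, 1), n_bins = 8)
  expect_equal(h3[1], 0.5)
  expect_equal(h3[3], 0.5) # pi/2 falls in the third bin
  # zero field -> uniform
  expect_equal(flow_direction_histogram(0, 0), rep(1 / 8, 8))
  expect_error(flow_direction_histogram(numeric(), numeric()), "non-empty")
})

test_that("scene context carries the scene-adaptive defaults", {
  expect_equal(scene_context("daytime")$tau_biou, 0.30)
  expect_equal(scene_context("occlusion")$tau_biou, 0.30)
  expect_equal(scene_context("nighttime")$tau_biou, 0.20)
  expect_equal(scene_context("turbid")$tau_biou, 0.20)
  expect_equal(scene_context("daytime")$det_conf_min, 0.5)
  expect_equal(scene_context("nighttime")$det_conf_min, 0.3)
  expect_error(scene_context("daytime", tau_biou = 1.2), "tau_biou")
})

test_that("stage 1 matches by gated BIOU assignment", {
  b <- c(0.5, 0.5, 0.2, 0.1)
  m <- stage1_match(rbind(b), rbind(b))
  expect_equal(nrow(m), 1L)
  expect_equal(m$stage, 1L)
  expect_equal(m$score, 1)
  far <- c(0.9, 0.9, 0.05, 0.05)
  expect_equal(nrow(stage1_match(rbind(b), rbind(far))), 0L)
})

test_that("stage 2 fuses features and falls back gracefully", {
  f1 <- c(1, 0, 0); f2 <- c(0, 1, 0)
  h1 <- c(1, 0, 0, 0); h2 <- c(0, 0, 1, 0)
  # identical features -> matched with S = 1
  m <- stage2_match(list(f1), list(f1), list(h1), list(h1))
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 1)
  # orthogonal appearance + disjoint histograms -> S = 0, below the gate
  expect_equal(nrow(stage2_match(list(f1), list(f2), list(h1), list(h2))), 0L)
  # missing histogram: appearance alone decides
  m2 <- stage2_match(list(f1), list(f1), list(NULL), list(NULL))
  expect_equal(m2$score, 1)
  # no features at all -> infeasible
  expect_equal(nrow(stage2_match(list(NULL), list(NULL))), 0L)
})

test_that("stage 3 reactivates only within all gates", {
  app <- c(1, 1, 0)
  dormant <- tibble::tibble(
    track = 5L, cx = 0.5, cy = 0.5, elapsed = 5, speed = 0.004, app = list(app)
  )
  prm <- matcher_params()
  det_at_pred <- rbind(c(0.5, 0.5, 0.1, 0.05))
  m <- stage3_reactivate(dormant, det_at_pred, list(app), prm)
  expect_equal(m$track, 5L)
  expect_equal(m$stage, 3L)
  # beyond the time-to-live: no reactivation
  old <- dormant; old$elapsed <- prm$dormant_ttl + 1
  expect_equal(nrow(stage3_reactivate(old, det_at_pred, list(app), prm)), 0L)
  # outside the spatial gate
  det_far <- rbind(c(0.9, 0.9, 0.1, 0.05))
  expect_equal(nrow(stage3_reactivate(dormant, det_far, list(app), prm)), 0L)
  # dissimilar appearance
  expect_equal(nrow(stage3_reactivate(dormant, det_at_pred, list(c(0, 0, 1)), prm)), 0L)
})

test_that("the cascade composes stages on unmatched residues", {
  b1 <- c(0.2, 0.2, 0.1, 0.05) # easy stage-1 pair
  b2 <- c(0.6, 0.6, 0.1, 0.05) # displaced beyond overlap, feature-matched
  f_a <- c(1, 0); f_b <- c(0, 1)
  tracks <- tibble::tibble(
    cx = c(b1[1], b2[1]), cy = c(b1[2], b2[2]), w = c(b1[3], b2[3]), h = c(b1[4], b2[4]),
    app = list(f_a, f_b), fhist = list(NULL, NULL)
  )
  dets <- tibble::tibble(
    cx = c(b1[1], 0.8), cy = c(b1[2], 0.8), w = c(b1[3], 0.1), h = c(b1[4], 0.05),
    app = list(f_a, f_b), fhist = list(NULL, NULL)
  )
  dormant <- tibble::tibble(
    track = 9L, cx = 0.82, cy = 0.82, elapsed = 4, speed = 0.01, app = list(c(0, 1))
  )
  res <- associate(tracks, dets, dormant)
  expect_equal(sum(res$matches$stage == 1L), 1L)
  # detection 2 is far from track 2's prediction; stage 2 should pick it up
  # only if the gate admits it; here appearance matches exactly
  s2 <- res$matches[res$matches$stage == 2L, ]
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$track, 2L)
  # one-to-one across stages
  expect_equal(anyDuplicated(res$matches$det), 0L)
  expect_equal(anyDuplicated(res$matches$track), 0L)
  # empty detections: everything unmatched
  res2 <- associate(tracks, dets[0, ], NULL)
  expect_equal(res2$unmatched_tracks, c(1L, 2L))
})
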