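# tibble of one box per (frame, id) along simple paths
path_tbl <- function(id, frames, x0, step = 0.004, y = 0.5) {
  tibble::tibble(
    frame = frames, id = id, cx = x0 + step * (frames - frames[1]),
    cy = y, w = 0.1, h = 0.05
  )
}

test_that("frame_match keeps surviving pairs and maximizes IoU", {
  gt <- tibble::tibble(id = 1:2, cx = c(0.3, 0.7), cy = 0.5, w = 0.1, h = 0.1)
  hyp <- gt; hyp$id <- c(10L, 20L)
  m <- frame_match(gt, hyp, 0.5)
  expect_equal(nrow(m), 2L)
  expect_equal(m$hyp_id[match(1:2, m$gt_id)], c(10L, 20L))
  # empty hypotheses -> no matches
  expect_equal(nrow(frame_match(gt, hyp[0, ], 0.5)), 0L)
  # carryover keeps a still-overlapping previous pair even when a slightly
  # better partner appears
  hyp2 <- tibble::tibble(
    id = c(10L, 20L), cx = c(0.305, 0.3), cy = 0.5, w = 0.1, h = 0.1
  )
  m2 <- frame_match(gt[1, ], hyp2, 0.3, prev = c("1" = 10L))
  expect_equal(m2$hyp_id[1], 10L)
})

test_that("mot metrics match hand counts on an id-swap fixture", {
  frames <- 0:19
  gt <- dplyr::bind_rows(path_tbl(1L, frames, 0.2), path_tbl(2L, frames, 0.7))
  # hypotheses follow gt but swap ids from frame 10 on
  hyp <- gt
  hyp$id <- ifelse(gt$frame < 10, gt$id, c(2L, 1L)[gt$id])
  m <- mot_metrics(gt, hyp)
  # one switch per gt track at the swap instant, no FP/FN, no gaps
  expect_equal(m$IDs, 2L)
  expect_equal(m$FP, 0L)
  expect_equal(m$FN, 0L)
  expect_equal(m$Frag, 0L)
  expect_equal(m$MOTA, 100 * (1 - 2 / 40))
  # perfect tracking scores 100 with zero counts
  p <- mot_metrics(gt, gt)
  expect_equal(p$MOTA, 100)
  expect_equal(p$IDs + p$Frag + p$FP + p$FN, 0L)
})

test_that("mot metrics match hand counts on a fragmentation fixture", {
  frames <- 0:19
  gt <- path_tbl(1L, frames, 0.2)
  # coverage missing on frames 5-6 and 12: two resumed gaps
  hyp <- gt[!(gt$frame %in% c(5L, 6L, 12L)), ]
  m <- mot_metrics(gt, hyp)
  expect_equal(m$Frag, 2L)
  expect_equal(m$FN, 3L)
  expect_equal(m$IDs, 0L)
  expect_equal(m$MOTA, 100 * (1 - 3 / 20))
})

test_that("idf1 matches the closed-form half-coverage case", {
  frames <- 0:19
  gt <- path_tbl(1L, frames, 0.2)
  hyp <- dplyr::bind_rows(
    path_tbl(101L, 0:9, 0.2),
    path_tbl(102L, 10:19, 0.2 + 0.004 * 10)
  )
  expect_equal(idf1(gt, hyp), 50)
  expect_equal(idf1(gt, gt), 100)
  expect_equal(idf1(gt, hyp[0, ]), 0)
  # invariant to relabeling hypothesis ids
  hyp2 <- hyp; hyp2$id <- hyp2$id + 1000L
  expect_equal(idf1(gt, hyp2), idf1(gt, hyp))
})

test_that("mot metrics agree with the brute-force CLEAR oracle", {
  set.seed(14)
  for (trial in 1:20) {
    sc <- simulate_scenario(
      scenario_config(
        n_targets = sample(2:3, 1), n_frames = 40L,
        miss_prob = 0.1, fp_rate = 0.1, sigma_center = 3e-3, seed = trial
      )
    )
    # corrupting the truth's ids makes an imperfect hypothesis set
    hyp <- sc$detections[!is.na(sc$detections$true_id), ]
    hyp$id <- hyp$true_id
    swap <- hyp$frame > 20 & hyp$id <= 2
    hyp$id[swap] <- 3L - hyp$id[swap]
    fp <- sc$detections[is.na(sc$detections$true_id), ]
    if (nrow(fp)) {
      fp$id <- 90L + seq_len(nrow(fp))
      hyp <- dplyr::bind_rows(hyp, fp)
    }
    hyp <- hyp[, c("frame", "id", "cx", "cy", "w", "h")]
    m <- mot_metrics(sc$truth, hyp)
    o <- oracle_clear(sc$truth, hyp)
    expect_equal(m$FP, o$FP)
    expect_equal(m$FN, o$FN)
    expect_equal(m$IDs, o$IDs)
    expect_equal(m$Frag, o$Frag)
    expect_equal(m$MOTA, o$MOTA, tolerance = 1e-9)
  }
})

test_that("MOTA decreases monotonically with injected false positives", {
  sc <- simulate_scenario(
    scenario_config(n_targets = 2L, n_frames = 60L, miss_prob = 0, fp_rate = 0, seed = 2L)
  )
  hyp <- sc$truth[, c("frame", "id", "cx", "cy", "w", "h")]
  motas <- vapply(c(0L, 10L, 30L), function(nfp) {
    set.seed(1)
    fp <- tibble::tibble(
      frame = sample(unique(hyp$frame), nfp, replace = TRUE),
      id = 500L + seq_len(nfp),
      cx = runif(nfp, 0.05, 0.15), cy = runif(nfp, 0.05, 0.15), w = 0.05, h = 0.05
    )
    mot_metrics(sc$truth, dplyr::bind_rows(hyp, fp))$MOTA
  }, numeric(1))
  expect_true(all(diff(motas) < 0))
})

test_that("predictor AED scores perfect and persistence predictions exactly", {
  traj <- generate_truth(
    scenario_config(n_targets = 1L, n_frames = 60L, regimes = "linear", seed = 3L)
  )
  ex <- make_history_examples(traj, L = 5L)
  # persistence on constant-velocity tracks errs by one step per frame
  persistence_aed <- mean(vapply(seq_len(nrow(ex)), function(i) {
    h <- ex$hist[[i]]
    sqrt(sum((h[nrow(h), 1:2] - ex$target[[i]][1:2])^2))
  }, numeric(1)))
  steps <- sqrt(rowSums(do.call(rbind, ex$target_off)[, 1:2, drop = FALSE]^2))
  expect_equal(persistence_aed, mean(steps))
  # the constant-velocity baseline is exact on linear motion
  expect_equal(predictor_aed(ex), 0, tolerance = 1e-12)
  expect_error(predictor_aed(ex[0, ]), "no held-out")
})
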