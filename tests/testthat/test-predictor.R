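tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(
      L = 4L, n_layers = 2L, n_heads = 2L, ffn_dim = 16L, model_dim = 8L,
      epochs = 3L, batch_size = 4L, seed = 7L
    ),
    list(...)
  )
  do.call(predictor_config, args)
}

test_that("state histories and branch splitting follow the 6-D encoding", {
  boxes <- cbind(seq(0.3, 0.4, length.out = 6), 0.5, 0.05, 0.02)
  h <- state_history(boxes)
  expect_equal(dim(h), c(6L, 6L))
  expect_equal(h[1, 5:6], c(dx = 0, dy = 0))
  expect_equal(h[-1, 5], diff(boxes[, 1]), ignore_attr = TRUE)
  sp <- split_branch_inputs(h, L = 6L)
  expect_equal(cbind(sp$geom, sp$motion), h, ignore_attr = TRUE)
  # left-padding repeats the earliest state with zero displacement
  one <- state_history(c(0.5, 0.5, 0.1, 0.1))
  sp1 <- split_branch_inputs(one, L = 10L)
  expect_equal(nrow(sp1$geom), 10L)
  expect_true(all(sp1$geom[, 1] == 0.5))
  expect_true(all(sp1$motion == 0))
  expect_error(split_branch_inputs(matrix(numeric(), 0, 6)), "empty")
})

test_that("predicted_speed implements the calibrated de-normalization", {
  cfg <- predictor_config(k = 0.01, fps = 30, image_size = c(1000, 1000))
  expect_equal(predicted_speed(c(0, 0, 0.1, 0.1), cfg), 0)
  expect_equal(predicted_speed(c(0.003, 0.004, 0, 0), cfg), 1.5)
  cfg2 <- predictor_config(k = 0.02, fps = 30, image_size = c(1000, 1000))
  expect_equal(
    predicted_speed(c(0.003, 0.004, 0, 0), cfg2),
    2 * predicted_speed(c(0.003, 0.004, 0, 0), cfg)
  )
})

test_that("velocity loss is zero below the cap and quadratic beyond", {
  cfg <- predictor_config(k = 0.01, fps = 30, image_size = 1000, lambda_vel = 1, v_max = 2)
  expect_equal(velocity_loss(c(0.003, 0.004, 0, 0), cfg), 0) # 1.5 m/s
  off3 <- c(0.006, 0.008, 0, 0) # 3.0 m/s
  expect_equal(velocity_loss(off3, cfg), 1)
  cfg$lambda_vel <- 0
  expect_equal(velocity_loss(off3, cfg), 0)
  # strictly increasing beyond the cap
  cfg$lambda_vel <- 1
  v <- seq(2.1, 4, by = 0.1)
  losses <- vapply(v, function(s) {
    velocity_loss(c(s / (0.01 * 30 * 1000), 0, 0, 0), cfg)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("total loss is additive in regression and velocity terms", {
  cfg <- predictor_config(k = 0.01, fps = 30, image_size = 1000)
  b <- c(0.5, 0.5, 0.2, 0.1)
  expect_equal(total_loss(b, b, c(0.001, 0, 0, 0), cfg), 0)
  # perfect box, infeasible speed: equals the velocity loss alone
  off_fast <- c(0.006, 0.008, 0, 0)
  expect_equal(total_loss(b, b, off_fast, cfg), velocity_loss(off_fast, cfg))
  # feasible speed: equals the regression term alone
  b2 <- b + c(0.01, 0, 0, 0)
  slow <- c(0.001, 0, 0, 0)
  expect_equal(
    total_loss(b, b2, slow, cfg),
    total_loss(b, b2, c(0, 0, 0, 0), cfg)
  )
})

test_that("constant-velocity baseline extrapolates the last displacement", {
  still <- state_history(matrix(rep(c(0.5, 0.5, 0.1, 0.1), 5), 5, 4, byrow = TRUE))
  expect_equal(constant_velocity_baseline(still), c(0.5, 0.5, 0.1, 0.1), ignore_attr = TRUE)
  lin <- state_history(cbind(seq(0.3, 0.42, by = 0.03), 0.5, 0.05, 0.02))
  expect_equal(unname(constant_velocity_baseline(lin)[1]), 0.45)
  # 90 degree turn: extrapolating the pre-turn heading overshoots by the
  # full step in both axes
  straight <- state_history(rbind(
    c(0.50, 0.50, 0.1, 0.05), c(0.52, 0.50, 0.1, 0.05), c(0.54, 0.50, 0.1, 0.05)
  ))
  pred <- constant_velocity_baseline(straight) # continues along +x
  true_next <- c(0.54, 0.52) # target actually turned downward
  err <- sqrt((pred[1] - true_next[1])^2 + (pred[2] - true_next[2])^2)
  expect_equal(unname(err), sqrt(2) * 0.02)
})

test_that("inference is deterministic and composes with the offset head", {
  cfg <- tiny_cfg()
  mod <- init_predictor(cfg)
  h <- state_history(cbind(seq(0.3, 0.4, length.out = 5), 0.5, 0.05, 0.02))
  o1 <- predict_offsets(h, mod)
  o2 <- predict_offsets(h, mod)
  expect_identical(o1, o2)
  expect_true(all(is.finite(o1)))
  b <- predict_bbox(h, mod)
  last <- h[nrow(h), 1:4]
  expect_equal(as.numeric(b - last), as.numeric(o1), tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_cfg()
  cfg$v_max <- 0.5 # activate the velocity branch for some samples
  set.seed(7)
  params <- aquatrack:::nn_model_init(cfg)
  B <- 3L
  Xg <- matrix(abs(rnorm(B * cfg$L * 4, 0.5, 0.2)), B * cfg$L, 4)
  Xm <- matrix(rnorm(B * cfg$L * 2, 0, 0.01), B * cfg$L, 2)
  Y <- matrix(rnorm(B * 4, 0, 0.01), B, 4)
  core <- params[c("geom", "motion", "dec")]
  flat <- aquatrack:::nn_flatten(core)
  lossfun <- function(fl) {
    m <- aquatrack:::nn_apply_flat(core, fl)
    m$pe <- params$pe
    fw <- aquatrack:::nn_model_fwd(m, Xg, Xm, cfg, B)
    aquatrack:::loss_and_grad(fw$off, Y, cfg)$loss
  }
  m <- aquatrack:::nn_apply_flat(core, flat)
  m$pe <- params$pe
  fw <- aquatrack:::nn_model_fwd(m, Xg, Xm, cfg, B)
  res <- aquatrack:::loss_and_grad(fw$off, Y, cfg)
  grads <- aquatrack:::nn_flatten(
    aquatrack:::nn_model_bwd(m, fw, res$doff, cfg, B)[c("geom", "motion", "dec")]
  )
  eps <- 1e-4
  for (k in names(flat)) {
    i <- which.max(abs(grads[[k]]))
    fp <- flat; fp[[k]][i] <- fp[[k]][i] + eps
    fm <- flat; fm[[k]][i] <- fm[[k]][i] - eps
    num <- (lossfun(fp) - lossfun(fm)) / (2 * eps)
    expect_equal(grads[[k]][i], num,
      tolerance = 1e-4,
      label = sprintf("gradient of %s", k)
    )
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  traj <- generate_truth(preset("maneuver", n_targets = 2L, n_frames = 80L, seed = 31))
  ex <- make_history_examples(traj, L = 4L)
  cfg <- tiny_cfg(epochs = 8L, batch_size = 16L)
  m1 <- train_predictor(ex, cfg)
  expect_lt(m1$log$loss[nrow(m1$log)], m1$log$loss[1])
  m2 <- train_predictor(ex, cfg)
  expect_identical(
    predict_offsets(ex$hist[[1]], m1),
    predict_offsets(ex$hist[[1]], m2)
  )
  expect_error(train_predictor(ex[0, ], cfg), "empty")
  # broom methods
  expect_equal(nrow(tidy(m1)), 8L)
  g <- glance(m1)
  expect_equal(g$epochs_trained, 8L)
  expect_gt(g$n_parameters, 1000L)
})

test_that("jittered linear motion is recovered to within twice the noise", {
  set.seed(77)
  sigma <- 0.002
  mk <- function(id, n = 80) {
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.001, 0.003)
    tibble::tibble(
      frame = 1:n, id = id,
      cx = runif(1, 0.25, 0.75) + s * cos(th) * (1:n) + rnorm(n, 0, sigma),
      cy = runif(1, 0.25, 0.75) + s * sin(th) * (1:n) + rnorm(n, 0, sigma),
      w = 0.1, h = 0.04
    )
  }
  ex <- make_history_examples(dplyr::bind_rows(lapply(1:20, mk)), L = 10)
  set.seed(2)
  te_i <- sample(nrow(ex), 400)
  cfg <- predictor_config(
    L = 10, model_dim = 16, epochs = 40, batch_size = 256,
    learning_rate = 3e-3, seed = 3
  )
  mod <- train_predictor(ex[-te_i, ], cfg)
  expect_lte(predictor_aed(ex[te_i, ], mod), 2 * sigma)
})

test_that("a large velocity weight suppresses over-cap predictions", {
  set.seed(88)
  # linear tracks whose speeds straddle the 2 m/s cap
  mk <- function(id, n = 60) {
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.0055, 0.0075) # 1.65-2.25 m/s at default calibration
    tibble::tibble(
      frame = 1:n, id = id,
      cx = runif(1, 0.25, 0.75) + s * cos(th) * (1:n) + rnorm(n, 0, 0.002),
      cy = runif(1, 0.25, 0.75) + s * sin(th) * (1:n) + rnorm(n, 0, 0.002),
      w = 0.1, h = 0.04
    )
  }
  ex <- make_history_examples(dplyr::bind_rows(lapply(1:12, mk)), L = 6)
  set.seed(3)
  te_i <- sample(nrow(ex), 200)
  frac_over <- function(lam) {
    cfg <- predictor_config(
      L = 6, model_dim = 16, epochs = 15, batch_size = 128,
      learning_rate = 3e-3, seed = 4, lambda_vel = lam
    )
    m <- train_predictor(ex[-te_i, ], cfg)
    off <- predict_offsets(ex$hist[te_i], m)
    mean(predicted_speed(off, cfg) > cfg$v_max)
  }
  expect_lt(frac_over(1000), frac_over(0))
})
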