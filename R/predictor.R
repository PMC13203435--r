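#' Configuration for the trajectory predictor
#'
#' Collects the architecture, training and calibration parameters of the
#' dual-branch Transformer trajectory predictor. Architecture defaults (2
#' encoder layers per branch, 4 attention heads, feed-forward width 128,
#' history length `L = 10`) and training defaults (Adam, 500 epochs, batch 8,
#' learning rate 0.001) follow the tracker's reference configuration; the
#' physiological speed cap `v_max = 2` m/s bounds the burst swimming speed of
#' an adult giant salamander.
#'
#' @param L History length in frames (`>= 2`).
#' @param n_layers Encoder layers per branch.
#' @param n_heads Attention heads (must divide `model_dim`).
#' @param ffn_dim Feed-forward width inside each encoder layer.
#' @param model_dim Embedding width of each branch.
#' @param epochs,batch_size,learning_rate Training schedule (Adam).
#' @param lambda_vel Weight of the velocity-constraint loss (`>= 0`).
#' @param v_max Maximum biologically plausible speed, m/s.
#' @param k Calibration coefficient, meters per pixel.
#' @param fps Frames per second of the source video.
#' @param image_size Pixel dimensions `c(width, height)` used to de-normalize
#'   coordinates; a scalar is taken as a square image.
#' @param smooth_l1_beta Transition point of the smooth-L1 regression loss.
#' @param seed Integer seed controlling initialization and batching.
#' @return A list of class `"predictor_config"`.
#' @export
predictor_config <- function(L = 10L, n_layers = 2L, n_heads = 4L, ffn_dim = 128L,
                             model_dim = 64L, epochs = 500L, batch_size = 8L,
                             learning_rate = 0.001, lambda_vel = 1, v_max = 2,
                             k = 0.01, fps = 30, image_size = c(1000, 1000),
                             smooth_l1_beta = 1, seed = 42L) {
  if (L < 2) stop("L must be >= 2", call. = FALSE)
  if (model_dim %% n_heads != 0) stop("model_dim must be divisible by n_heads", call. = FALSE)
  if (v_max <= 0) stop("v_max must be positive", call. = FALSE)
  if (lambda_vel < 0) stop("lambda_vel must be >= 0", call. = FALSE)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  structure(
    list(
      L = as.integer(L), n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
      ffn_dim = as.integer(ffn_dim), model_dim = as.integer(model_dim),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, lambda_vel = lambda_vel, v_max = v_max,
      k = k, fps = fps, image_size = as.numeric(image_size),
      smooth_l1_beta = smooth_l1_beta, seed = as.integer(seed)
    ),
    class = "predictor_config"
  )
}

#' Build a per-frame state history from a box sequence
#'
#' Converts an ordered sequence of normalized center-format boxes into the
#' 6-dimensional per-frame state representation `(x, y, w, h, dx, dy)` where
#' `(dx, dy)` is the center displacement since the previous frame (0 for the
#' first state).
#'
#' @param boxes Boxes ordered by frame (vector, 4-column matrix or data frame
#'   with `cx, cy, w, h`).
#' @return A numeric matrix with columns `x, y, w, h, dx, dy`.
#' @export
state_history <- function(boxes) {
  m <- as_box_matrix(boxes, "boxes")
  n <- nrow(m)
  dx <- c(0, diff(m[, 1]))
  dy <- c(0, diff(m[, 2]))
  out <- cbind(m, dx, dy)
  colnames(out) <- c("x", "y", "w", "h", "dx", "dy")
  out
}

as_history_matrix <- function(hist) {
  if (is.data.frame(hist)) hist <- as.matrix(hist[, c("x", "y", "w", "h", "dx", "dy")])
  hist <- as.matrix(hist)
  if (ncol(hist) != 6L) stop("a state history needs 6 columns (x, y, w, h, dx, dy)", call. = FALSE)
  if (nrow(hist) == 0L) stop("empty state history", call. = FALSE)
  if (!all(is.finite(hist))) stop("state history contains non-finite values", call. = FALSE)
  hist
}

#' Split a state history into the two encoder branch inputs
#'
#' The geometric branch receives only `(x, y, w, h)`; the motion branch only
#' `(dx, dy)`. Histories shorter than `L` are left-padded by repeating the
#' earliest state with zero displacement, so a single code path serves young
#' and mature tracks alike.
#'
#' @param hist State history (matrix from [state_history()] or data frame).
#' @param L Target sequence length.
#' @return A list with `geom` (`L x 4`) and `motion` (`L x 2`) matrices.
#' @export
split_branch_inputs <- function(hist, L = 10L) {
  hist <- as_history_matrix(hist)
  n <- nrow(hist)
  if (n > L) hist <- hist[(n - L + 1):n, , drop = FALSE]
  if (nrow(hist) < L) {
    pad <- hist[rep(1L, L - nrow(hist)), , drop = FALSE]
    pad[, 5:6] <- 0
    hist <- rbind(pad, hist)
    hist[L - n + 1L, 5:6] <- 0 # earliest real state carries no displacement
  }
  list(geom = hist[, 1:4, drop = FALSE], motion = hist[, 5:6, drop = FALSE])
}

#' Predicted instantaneous speed of an offset, in m/s
#'
#' De-normalizes the predicted center offsets to pixels via `image_size`,
#' converts to meters with the calibration coefficient `k` (m/px) and to a
#' per-second rate with `fps`:
#' `v = k * fps * sqrt((d_cx * W)^2 + (d_cy * H)^2)`.
#'
#' @param off Offset vector `c(d_cx, d_cy, d_w, d_h)` or matrix with one
#'   offset per row.
#' @param cfg A [predictor_config()].
#' @return Speed(s) in m/s.
#' @export
predicted_speed <- function(off, cfg) {
  if (is.null(dim(off))) off <- matrix(off, nrow = 1)
  if (is.null(cfg$k) || is.null(cfg$fps) || is.null(cfg$image_size)) {
    stop("predictor config lacks calibration (k, fps, image_size)", call. = FALSE)
  }
  px <- sqrt((off[, 1] * cfg$image_size[1])^2 + (off[, 2] * cfg$image_size[2])^2)
  as.numeric(cfg$k * cfg$fps * px)
}

#' Velocity-constraint loss
#'
#' Penalizes biologically implausible predictions:
#' `lambda * max(0, v_pred - v_max)^2`, zero whenever the predicted speed is
#' within the physiological cap and smoothly quadratic beyond it.
#'
#' @inheritParams predicted_speed
#' @return Loss value(s), `>= 0`.
#' @export
velocity_loss <- function(off, cfg) {
  v <- predicted_speed(off, cfg)
  cfg$lambda_vel * pmax(0, v - cfg$v_max)^2
}

smooth_l1 <- function(z, beta) {
  ifelse(abs(z) < beta, 0.5 * z^2 / beta, abs(z) - 0.5 * beta)
}

#' Total training loss: regression + velocity constraint
#'
#' `L_total = L_reg + L_velocity`, where `L_reg` is the smooth-L1 distance
#' between predicted and target box parameters (mean over the four box
#' components) and `L_velocity` is [velocity_loss()].
#'
#' @param pred,target Boxes (length-4 vectors or 4-column matrices).
#' @param off Predicted offsets corresponding to `pred`.
#' @param cfg A [predictor_config()].
#' @return Loss value(s).
#' @export
total_loss <- function(pred, target, off, cfg) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  reg <- rowMeans(smooth_l1(pred - target, cfg$smooth_l1_beta))
  as.numeric(reg + velocity_loss(off, cfg))
}

#' Constant-velocity baseline prediction
#'
#' Extrapolates the last observed displacement:
#' `b_t = b_(t-1) + (dx, dy, 0, 0)`. Degenerates to persistence for
#' single-state histories. This is the linear-motion assumption the
#' Transformer predictor replaces, kept as the comparison baseline.
#'
#' @param hist State history.
#' @return A length-4 box `c(cx, cy, w, h)`.
#' @export
constant_velocity_baseline <- function(hist) {
  hist <- as_history_matrix(hist)
  last <- hist[nrow(hist), ]
  out <- c(last[1] + last[5], last[2] + last[6], last[3], last[4])
  names(out) <- c("cx", "cy", "w", "h")
  out
}

# stack a list of histories into branch input arrays
histories_to_arrays <- function(hists, L) {
  B <- length(hists)
  Xg <- matrix(0, B * L, 4)
  Xm <- matrix(0, B * L, 2)
  for (b in seq_len(B)) {
    sp <- split_branch_inputs(hists[[b]], L)
    rows <- (b - 1) * L + seq_len(L)
    Xg[rows, ] <- sp$geom
    Xm[rows, ] <- sp$motion
  }
  list(Xg = Xg, Xm = Xm, B = B)
}

new_predictor <- function(params, cfg, log = NULL) {
  structure(list(params = params, config = cfg, log = log), class = "aquatrack_predictor")
}

#' @export
print.aquatrack_predictor <- function(x, ...) {
  cfg <- x$config
  cat("<aquatrack_predictor>\n")
  cat(sprintf(
    "  dual-branch Transformer: %d layers x %d heads, model_dim %d, ffn %d, L = %d\n",
    cfg$n_layers, cfg$n_heads, cfg$model_dim, cfg$ffn_dim, cfg$L
  ))
  if (!is.null(x$log)) {
    cat(sprintf(
      "  trained %d epochs, final loss %.6g\n",
      nrow(x$log), x$log$loss[nrow(x$log)]
    ))
  } else {
    cat("  untrained (freshly initialized)\n")
  }
  invisible(x)
}

#' Initialize an untrained trajectory predictor
#'
#' @param cfg A [predictor_config()]; its `seed` fixes the initialization.
#' @return An `aquatrack_predictor` object.
#' @export
init_predictor <- function(cfg = predictor_config()) {
  set.seed(cfg$seed)
  new_predictor(nn_model_init(cfg), cfg)
}

#' Predict next-frame box offsets for one or more histories
#'
#' Runs each branch's Transformer encoder over its input sequence, takes the
#' final-time-step features, concatenates them and decodes through the MLP
#' head to the 4-dimensional offset `(d_cx, d_cy, d_w, d_h)`.
#'
#' @param hist A state history (matrix/data frame) or a list of histories.
#' @param model An `aquatrack_predictor`.
#' @return A matrix of offsets, one row per history, columns
#'   `d_cx, d_cy, d_w, d_h`.
#' @export
predict_offsets <- function(hist, model) {
  stopifnot(inherits(model, "aquatrack_predictor"))
  hists <- if (is.list(hist) && !is.data.frame(hist)) hist else list(hist)
  arr <- histories_to_arrays(hists, model$config$L)
  out <- nn_model_fwd(model$params, arr$Xg, arr$Xm, model$config, arr$B)$off
  colnames(out) <- c("d_cx", "d_cy", "d_w", "d_h")
  out
}

#' Predict the next-frame bounding box
#'
#' Adds the predicted offset to the last observed box, clamping width and
#' height to a small positive floor.
#'
#' @inheritParams predict_offsets
#' @param size_floor Minimum admissible box side after the update.
#' @return A length-4 box `c(cx, cy, w, h)` (or matrix for a list input).
#' @export
predict_bbox <- function(hist, model, size_floor = 1e-4) {
  hists <- if (is.list(hist) && !is.data.frame(hist)) hist else list(hist)
  off <- predict_offsets(hists, model)
  out <- t(vapply(seq_along(hists), function(b) {
    h <- as_history_matrix(hists[[b]])
    last <- h[nrow(h), 1:4]
    box <- last + off[b, ]
    box[3] <- max(box[3], size_floor)
    box[4] <- max(box[4], size_floor)
    box
  }, numeric(4)))
  colnames(out) <- c("cx", "cy", "w", "h")
  if (length(hists) == 1L) out[1, ] else out
}

#' Build history/target training examples from trajectories
#'
#' Slices each trajectory into (history, next-frame target) pairs: for every
#' frame with at least one predecessor, the history is the run of preceding
#' states (up to `L`, left-padded downstream) and the target is the next
#' frame's box. Only consecutive-frame runs are used.
#'
#' @param traj A tibble of trajectories with columns `frame, id, cx, cy, w, h`.
#' @param L History length.
#' @param min_hist Minimum number of observed states in a history.
#' @return A tibble with columns `id`, `frame` (target frame), list-column
#'   `hist`, and matrix-backed columns for the target box and offset.
#' @export
make_history_examples <- function(traj, L = 10L, min_hist = 2L) {
  traj <- dplyr::arrange(traj, .data$id, .data$frame)
  out <- list()
  for (tid in unique(traj$id)) {
    tt <- traj[traj$id == tid, , drop = FALSE]
    # split into consecutive-frame runs
    run <- cumsum(c(1L, diff(tt$frame) != 1L))
    for (r in unique(run)) {
      seg <- tt[run == r, , drop = FALSE]
      if (nrow(seg) < min_hist + 1L) next
      hist_full <- state_history(seg[, c("cx", "cy", "w", "h")])
      for (t in (min_hist + 1L):nrow(seg)) {
        lo <- max(1L, t - L)
        h <- hist_full[lo:(t - 1L), , drop = FALSE]
        if (lo > 1L) { # recompute first displacement inside the window
          h[1, 5:6] <- hist_full[lo, 1:2] - hist_full[lo - 1L, 1:2]
        }
        tgt <- as.numeric(unlist(seg[t, c("cx", "cy", "w", "h")]))
        lst <- as.numeric(unlist(seg[t - 1L, c("cx", "cy", "w", "h")]))
        off <- tgt - lst
        out[[length(out) + 1L]] <- tibble::tibble(
          id = tid, frame = seg$frame[t],
          hist = list(h), target = list(tgt), target_off = list(off)
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      id = integer(), frame = integer(), hist = list(),
      target = list(), target_off = list()
    ))
  }
  dplyr::bind_rows(out)
}

#' Train the trajectory predictor
#'
#' Minimizes the total loss (smooth-L1 box regression plus the velocity
#' constraint) with Adam over mini-batches. Fully reproducible for a fixed
#' config seed under single-threaded execution.
#'
#' @param examples A tibble from [make_history_examples()] (columns `hist`
#'   and `target_off`), or a list with elements `hist` and `target_off`.
#' @param cfg A [predictor_config()].
#' @param verbose Print the per-epoch loss.
#' @return A trained `aquatrack_predictor`; the per-epoch loss curve is in
#'   `$log` and via [tidy()].
#' @export
train_predictor <- function(examples, cfg = predictor_config(), verbose = FALSE) {
  hists <- examples$hist
  targets <- examples$target_off
  if (is.null(hists) || length(hists) == 0L) stop("empty training dataset", call. = FALSE)
  n <- length(hists)
  arr <- histories_to_arrays(hists, cfg$L)
  Y <- do.call(rbind, targets)
  last_boxes <- t(vapply(hists, function(h) {
    h <- as_history_matrix(h); h[nrow(h), 1:4]
  }, numeric(4)))

  set.seed(cfg$seed)
  params <- nn_model_init(cfg)
  flat <- nn_flatten(params[c("geom", "motion", "dec")])
  opt <- adam_init(flat)
  pe <- params$pe
  epoch_loss <- numeric(cfg$epochs)

  # per-component loss standardization: residuals relative to the
  # persistence initialization (last displacement for centers, zero for
  # sizes), so all four offset components contribute comparable gradients
  last_disp <- t(vapply(hists, function(h) {
    h <- as_history_matrix(h); h[nrow(h), 5:6]
  }, numeric(2)))
  resid0 <- Y - cbind(last_disp, 0, 0)
  comp_scale <- 1 / pmax(apply(resid0, 2, stats::sd), 1e-5)

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    tot <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      B <- length(idx)
      rows <- as.vector(t(outer(idx - 1L, seq_len(cfg$L), function(a, b) a * cfg$L + b)))
      model <- nn_apply_flat(params[c("geom", "motion", "dec")], flat)
      model$pe <- pe
      fw <- nn_model_fwd(
        model, arr$Xg[rows, , drop = FALSE], arr$Xm[rows, , drop = FALSE], cfg, B
      )
      res <- loss_and_grad(fw$off, Y[idx, , drop = FALSE], cfg, comp_scale)
      tot <- tot + res$loss * B
      bw <- nn_model_bwd(model, fw, res$doff, cfg, B)
      grads <- nn_flatten(bw[c("geom", "motion", "dec")])
      upd <- adam_step(flat, grads, opt, cfg$learning_rate)
      flat <- upd$flat
      opt <- upd$state
    }
    epoch_loss[ep] <- tot / n
    if (verbose) message(sprintf("epoch %d  loss %.6g", ep, epoch_loss[ep]))
  }
  params_final <- nn_apply_flat(params[c("geom", "motion", "dec")], flat)
  params_final$pe <- pe
  new_predictor(
    params_final, cfg,
    log = tibble::tibble(epoch = seq_len(cfg$epochs), loss = epoch_loss)
  )
}

# mean total loss over a batch of offsets and its gradient wrt the offsets.
# The regression term is evaluated on component-standardized residuals
# (comp_scale, one factor per box parameter): raw normalized offsets are
# O(1e-3) and would put gradients below Adam's epsilon, and the center
# components (largely explained by the persistence skip) carry far smaller
# residuals than the size components — without per-component balancing
# their gradient signal drowns. Standardizing preserves each component's
# minimizer.
loss_and_grad <- function(off, target_off, cfg, comp_scale = rep(nn_scales()$off, 4L)) {
  B <- nrow(off)
  sc <- rep(comp_scale, each = B)
  z <- (off - target_off) * sc
  beta <- cfg$smooth_l1_beta
  reg <- mean(smooth_l1(z, beta)) # mean over all B*4 elements
  dreg <- ifelse(abs(z) < beta, z / beta, sign(z)) * sc / (B * 4)
  kap <- cfg$k * cfg$fps
  px <- sqrt((off[, 1] * cfg$image_size[1])^2 + (off[, 2] * cfg$image_size[2])^2)
  v <- kap * px
  over <- pmax(0, v - cfg$v_max)
  vel <- mean(cfg$lambda_vel * over^2)
  dvel <- matrix(0, B, 4)
  nz <- over > 0 & px > 0
  if (any(nz)) {
    coef <- cfg$lambda_vel * 2 * over[nz] * kap / (px[nz] * B)
    dvel[nz, 1] <- coef * off[nz, 1] * cfg$image_size[1]^2
    dvel[nz, 2] <- coef * off[nz, 2] * cfg$image_size[2]^2
  }
  list(loss = reg + vel, doff = dreg + dvel)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the training log of a trajectory predictor
#'
#' @param x An `aquatrack_predictor`.
#' @param ... Unused.
#' @return A tibble with one row per epoch (`epoch`, `loss`); empty for an
#'   untrained predictor.
#' @export
tidy.aquatrack_predictor <- function(x, ...) {
  if (is.null(x$log)) tibble::tibble(epoch = integer(), loss = numeric()) else x$log
}

#' One-row summary of a trajectory predictor
#'
#' @inheritParams tidy.aquatrack_predictor
#' @return A tibble with the parameter count, training length and final loss.
#' @export
glance.aquatrack_predictor <- function(x, ...) {
  flat <- nn_flatten(x$params[c("geom", "motion", "dec")])
  tibble::tibble(
    n_parameters = sum(vapply(flat, length, integer(1))),
    L = x$config$L,
    epochs_trained = if (is.null(x$log)) 0L else nrow(x$log),
    final_loss = if (is.null(x$log)) NA_real_ else x$log$loss[nrow(x$log)]
  )
}
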