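#' Scenario configuration for the synthetic benchmark generator
#'
#' Describes a seeded, fully reproducible tracking scenario: ground-truth
#' targets alternating among stationary / burst / turn / oscillation motion
#' regimes, and a detection-corruption model emulating field conditions —
#' scene-dependent missed detections and confidence levels, localization
#' jitter, false positives, transient full occlusions, elongated
#' heading-dependent boxes, appearance embeddings with controlled identity
#' separation, and heading-concentrated flow-direction histograms.
#'
#' @param n_targets Number of targets.
#' @param n_frames Number of frames.
#' @param fps Frames per second.
#' @param image_size Pixel dimensions `c(width, height)`.
#' @param k Calibration coefficient, meters per pixel.
#' @param scene Scene class of the recording: `"daytime"`, `"nighttime"`,
#'   `"turbid"` or `"occlusion"`.
#' @param regimes Motion regimes sampled per segment; subset of
#'   `c("stationary", "burst", "turn", "oscillation", "linear")`.
#' @param segment_len Frame-count range of a motion segment.
#' @param speed_cap Physiological speed cap in m/s; ground-truth speeds never
#'   exceed it.
#' @param stationary_sigma Positional jitter (normalized units) around the
#'   resting point.
#' @param burst_speed Peak-speed range of a burst, m/s.
#' @param turn_speed Speed range while turning, m/s.
#' @param turn_radius Turn radius range, meters.
#' @param osc_speed Forward speed range while oscillating, m/s.
#' @param osc_amplitude Transverse oscillation amplitude (normalized units).
#' @param osc_period Oscillation period range, seconds.
#' @param body_length Body length range (normalized units).
#' @param elongation Body elongation (length/width) range.
#' @param sigma_center Detection center jitter, normalized units.
#' @param sigma_size Relative detection size jitter.
#' @param miss_prob Per-detection miss probability in this scene.
#' @param conf_mean,conf_sd Detection confidence distribution.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param occlusions Tibble of forced full occlusions with columns `id`,
#'   `start`, `end` (0-based frames, inclusive), or `NULL`.
#' @param n_clutter Number of persistent clutter objects (static, square-ish
#'   rock-like structures that the detector repeatedly fires on).
#' @param clutter_rate Per-frame probability that a clutter object emits a
#'   false detection.
#' @param app_dim,app_sep,app_noise Appearance embedding dimension,
#'   per-identity mean separation and within-identity noise (the default
#'   separation-to-noise ratio 4 makes appearance informative, not perfect).
#' @param flow_kappa Concentration of the flow-direction histogram around the
#'   true heading.
#' @param n_bins Flow-histogram bins.
#' @param layout `"random"`, `"crossing"` (two targets on intersecting
#'   paths) or `"clustered"` (targets share a small central area, provoking
#'   mutual occlusion and ambiguous association).
#' @param seed Scenario seed.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_targets = 3L, n_frames = 600L, fps = 30, image_size = c(1000, 1000),
                            k = 0.01, scene = "daytime",
                            regimes = c("stationary", "burst", "turn", "oscillation"),
                            segment_len = c(40L, 120L), speed_cap = 2,
                            stationary_sigma = 3e-4,
                            burst_speed = c(0.5, 1.8), turn_speed = c(0.2, 0.6),
                            turn_radius = c(0.3, 1.2), osc_speed = c(0.1, 0.4),
                            osc_amplitude = 2e-3, osc_period = c(0.5, 1.5),
                            body_length = c(0.07, 0.12), elongation = c(3, 6),
                            sigma_center = 2e-3, sigma_size = 0.03,
                            miss_prob = 0.03, conf_mean = 0.8, conf_sd = 0.08,
                            fp_rate = 0.02, occlusions = NULL,
                            n_clutter = 0L, clutter_rate = 0.7,
                            app_dim = 16L, app_sep = 4, app_noise = 1,
                            flow_kappa = 4, n_bins = 8L,
                            layout = "random", seed = 0L) {
  stopifnot(
    n_frames >= 1, n_targets >= 1, miss_prob >= 0, miss_prob <= 1,
    fp_rate >= 0, speed_cap > 0
  )
  scene <- match.arg(scene, c("daytime", "nighttime", "turbid", "occlusion"))
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  cfg <- as.list(environment())
  cfg$n_targets <- as.integer(n_targets)
  cfg$n_frames <- as.integer(n_frames)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scenario_config")
}

# normalized units traveled per frame at v m/s
mps_to_step <- function(v, cfg) {
  v / (cfg$k * cfg$image_size[1] * cfg$fps)
}

# heading-dependent axis-aligned box sides from an elongated body:
# projection of the body ellipse's bounding box
body_box <- function(len, elong, heading) {
  wid <- len / elong
  c(
    w = len * abs(cos(heading)) + wid * abs(sin(heading)),
    h = len * abs(sin(heading)) + wid * abs(cos(heading))
  )
}

#' Generate ground-truth trajectories
#'
#' Piecewise kinematic simulation per target: stationary segments jitter
#' around a resting point; bursts ramp the speed smoothly up to a sampled
#' peak below the physiological cap; turns follow a constant-speed arc of
#' sampled radius; oscillation superimposes a sinusoidal transverse
#' displacement on slow forward motion. Boxes derive from an elongated body
#' reorienting with heading, and trajectories reflect off the image border.
#'
#' @param cfg A [scenario_config()].
#' @return A tibble with columns `frame` (0-based), `id`, `cx`, `cy`, `w`,
#'   `h`, `heading`, `speed_mps`, `regime`, `scene`.
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n <- cfg$n_frames
  out <- vector("list", cfg$n_targets)
  for (tid in seq_len(cfg$n_targets)) {
    len <- stats::runif(1, cfg$body_length[1], cfg$body_length[2])
    elong <- stats::runif(1, cfg$elongation[1], cfg$elongation[2])
    if (identical(cfg$layout, "crossing")) {
      side <- (tid %% 2L)
      x <- if (side == 1) 0.15 else 0.85
      y <- 0.5 + (tid - 1.5) * 0.06
      heading <- if (side == 1) 0 else pi
      schedule <- rep("linear", n)
    } else {
      lim <- if (identical(cfg$layout, "clustered")) c(0.38, 0.62) else c(0.25, 0.75)
      x <- stats::runif(1, lim[1], lim[2])
      y <- stats::runif(1, lim[1], lim[2])
      heading <- stats::runif(1, 0, 2 * pi)
      schedule <- character(0)
      while (length(schedule) < n) {
        seg <- sample(cfg$regimes, 1)
        sl <- sample(seq(cfg$segment_len[1], cfg$segment_len[2]), 1)
        schedule <- c(schedule, rep(seg, sl))
      }
      schedule <- schedule[seq_len(n)]
    }
    cx <- numeric(n); cy <- numeric(n); hd <- numeric(n); sp <- numeric(n)
    anchor <- c(x, y)
    seg_id <- cumsum(c(TRUE, schedule[-1] != schedule[-n]))
    seg_pos <- stats::ave(seq_len(n), seg_id, FUN = seq_along)
    seg_len <- stats::ave(seq_len(n), seg_id, FUN = length)
    # per-segment sampled parameters
    seg_par <- list()
    v <- 0
    phase <- stats::runif(1, 0, 2 * pi)
    for (t in seq_len(n)) {
      reg <- schedule[t]
      if (seg_pos[t] == 1L) {
        seg_par <- switch(reg,
          stationary = list(),
          burst = list(
            peak = stats::runif(1, cfg$burst_speed[1], min(cfg$burst_speed[2], cfg$speed_cap))
          ),
          turn = list(
            v = stats::runif(1, cfg$turn_speed[1], cfg$turn_speed[2]),
            r = stats::runif(1, cfg$turn_radius[1], cfg$turn_radius[2]),
            dir = sample(c(-1, 1), 1)
          ),
          oscillation = list(
            v = stats::runif(1, cfg$osc_speed[1], cfg$osc_speed[2]),
            A = cfg$osc_amplitude * stats::runif(1, 0.5, 1.5),
            Tp = stats::runif(1, cfg$osc_period[1], cfg$osc_period[2]) * cfg$fps
          ),
          linear = list(v = stats::runif(1, 0.3, 0.6))
        )
        if (reg == "stationary") anchor <- c(x, y)
        phase <- stats::runif(1, 0, 2 * pi)
      }
      if (reg == "stationary") {
        v <- 0
        x <- anchor[1] + stats::rnorm(1, 0, cfg$stationary_sigma)
        y <- anchor[2] + stats::rnorm(1, 0, cfg$stationary_sigma)
      } else {
        v <- switch(reg,
          burst = {
            # smooth rise and fall across the segment
            u <- seg_pos[t] / seg_len[t]
            seg_par$peak * sin(pi * min(max(u, 0), 1))^2
          },
          turn = seg_par$v,
          oscillation = seg_par$v,
          linear = seg_par$v
        )
        v <- min(v, cfg$speed_cap)
        if (reg == "turn") {
          heading <- heading + seg_par$dir * (v / seg_par$r) / cfg$fps
        } else if (reg != "linear") {
          heading <- heading + stats::rnorm(1, 0, 0.02)
        }
        step <- mps_to_step(v, cfg)
        x <- x + step * cos(heading)
        y <- y + step * sin(heading)
        if (reg == "oscillation") {
          osc <- seg_par$A * sin(2 * pi * seg_pos[t] / seg_par$Tp + phase)
          x <- x - osc * sin(heading)
          y <- y + osc * cos(heading)
        }
        # reflect at borders
        margin <- 0.08
        if (x < margin || x > 1 - margin) {
          heading <- pi - heading
          x <- min(max(x, margin), 1 - margin)
          anchor <- c(x, y)
        }
        if (y < margin || y > 1 - margin) {
          heading <- -heading
          y <- min(max(y, margin), 1 - margin)
          anchor <- c(x, y)
        }
      }
      cx[t] <- x; cy[t] <- y; hd[t] <- heading; sp[t] <- v
    }
    sides <- t(vapply(hd, function(a) body_box(len, elong, a), numeric(2)))
    tb <- tibble::tibble(
      frame = seq_len(n) - 1L, id = tid,
      cx = pmin(pmax(cx, 0), 1), cy = pmin(pmax(cy, 0), 1),
      w = sides[, 1], h = sides[, 2],
      heading = hd %% (2 * pi), speed_mps = sp,
      regime = schedule, scene = cfg$scene
    )
    out[[tid]] <- tb
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$id)
}

# deterministic direction histogram concentrated around a heading
heading_histogram <- function(heading, kappa, n_bins) {
  centers <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  h <- exp(kappa * cos(centers - heading))
  h / sum(h)
}

#' Corrupt ground truth into a detection stream
#'
#' Applies the scene's degradation model to each true box: misses (random
#' plus forced occlusion intervals), Gaussian center/size jitter, a
#' scene-dependent confidence draw, Poisson false positives with square-ish
#' boxes, per-identity appearance embeddings with isotropic noise, and
#' flow-direction histograms concentrated around the true heading (uniform
#' for near-stationary targets).
#'
#' @param truth Output of [generate_truth()].
#' @param cfg The same [scenario_config()].
#' @return A list with `detections` (tibble `frame, cx, cy, w, h, conf,
#'   true_id` plus list-columns `app`, `fhist`) and `app_means` (the
#'   per-identity embedding means, for reference).
#' @export
corrupt_to_detections <- function(truth, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed + 104729L) # decouple from the truth stream
  ids <- sort(unique(truth$id))
  app_means <- lapply(ids, function(i) {
    v <- stats::rnorm(cfg$app_dim)
    v / sqrt(sum(v^2)) * cfg$app_sep
  })
  names(app_means) <- as.character(ids)
  occ <- cfg$occlusions
  occluded <- function(id, frame) {
    if (is.null(occ) || nrow(occ) == 0L) return(FALSE)
    any(occ$id == id & frame >= occ$start & frame <= occ$end)
  }
  clutter <- NULL
  if (cfg$n_clutter > 0L) {
    clutter <- lapply(seq_len(cfg$n_clutter), function(i) {
      s <- stats::runif(1, 0.04, 0.07)
      v <- stats::rnorm(cfg$app_dim)
      list(
        cx = stats::runif(1, 0.2, 0.8), cy = stats::runif(1, 0.2, 0.8),
        w = s * stats::runif(1, 1, 1.4), h = s,
        app = v / sqrt(sum(v^2)) * cfg$app_sep
      )
    })
  }
  n_cap <- nrow(truth) + 256L
  v_frame <- integer(n_cap); v_cx <- numeric(n_cap); v_cy <- numeric(n_cap)
  v_w <- numeric(n_cap); v_h <- numeric(n_cap); v_conf <- numeric(n_cap)
  v_tid <- integer(n_cap); v_app <- vector("list", n_cap); v_fh <- vector("list", n_cap)
  grow <- function() { # extend all columns when clutter/FPs overflow the cap
    n_cap <<- n_cap * 2L
    length(v_frame) <<- n_cap; length(v_cx) <<- n_cap; length(v_cy) <<- n_cap
    length(v_w) <<- n_cap; length(v_h) <<- n_cap; length(v_conf) <<- n_cap
    length(v_tid) <<- n_cap; length(v_app) <<- n_cap; length(v_fh) <<- n_cap
  }
  miss_rows <- list()
  k <- 0L
  slow <- mps_to_step(0.02, cfg) # below this, motion direction is noise
  for (fr in sort(unique(truth$frame))) {
    ft <- truth[truth$frame == fr, , drop = FALSE]
    for (r in seq_len(nrow(ft))) {
      if (occluded(ft$id[r], fr) || stats::runif(1) < cfg$miss_prob) {
        miss_rows[[length(miss_rows) + 1L]] <- c(fr, ft$id[r])
        next
      }
      w <- max(ft$w[r] * (1 + stats::rnorm(1, 0, cfg$sigma_size)), 1e-3)
      h <- max(ft$h[r] * (1 + stats::rnorm(1, 0, cfg$sigma_size)), 1e-3)
      conf <- min(max(stats::rnorm(1, cfg$conf_mean, cfg$conf_sd), 0.05), 0.99)
      step <- mps_to_step(ft$speed_mps[r], cfg)
      fh <- if (step <= slow) {
        rep(1 / cfg$n_bins, cfg$n_bins)
      } else {
        heading_histogram(ft$heading[r], cfg$flow_kappa, cfg$n_bins)
      }
      k <- k + 1L
      if (k > n_cap) grow()
      v_frame[k] <- fr
      v_cx[k] <- min(max(ft$cx[r] + stats::rnorm(1, 0, cfg$sigma_center), 0), 1)
      v_cy[k] <- min(max(ft$cy[r] + stats::rnorm(1, 0, cfg$sigma_center), 0), 1)
      v_w[k] <- w; v_h[k] <- h; v_conf[k] <- conf; v_tid[k] <- ft$id[r]
      v_app[[k]] <- app_means[[as.character(ft$id[r])]] + stats::rnorm(cfg$app_dim, 0, cfg$app_noise)
      v_fh[[k]] <- fh
    }
    for (cl in clutter) {
      if (stats::runif(1) >= cfg$clutter_rate) next
      k <- k + 1L
      if (k > n_cap) grow()
      v_frame[k] <- fr
      v_cx[k] <- cl$cx + stats::rnorm(1, 0, cfg$sigma_center)
      v_cy[k] <- cl$cy + stats::rnorm(1, 0, cfg$sigma_center)
      v_w[k] <- cl$w * (1 + stats::rnorm(1, 0, cfg$sigma_size))
      v_h[k] <- cl$h * (1 + stats::rnorm(1, 0, cfg$sigma_size))
      v_conf[k] <- stats::runif(1, 0.45, 0.7); v_tid[k] <- NA_integer_
      v_app[[k]] <- cl$app + stats::rnorm(cfg$app_dim, 0, cfg$app_noise)
      v_fh[[k]] <- rep(1 / cfg$n_bins, cfg$n_bins)
    }
    n_fp <- stats::rpois(1, cfg$fp_rate)
    for (i in seq_len(n_fp)) {
      s <- stats::runif(1, 0.03, 0.08)
      e <- stats::runif(1, 1, 1.6)
      k <- k + 1L
      if (k > n_cap) grow()
      v_frame[k] <- fr
      v_cx[k] <- stats::runif(1, 0.05, 0.95); v_cy[k] <- stats::runif(1, 0.05, 0.95)
      v_w[k] <- s * e; v_h[k] <- s
      v_conf[k] <- stats::runif(1, 0.3, 0.65); v_tid[k] <- NA_integer_
      v_app[[k]] <- stats::rnorm(cfg$app_dim, 0, cfg$app_noise)
      v_fh[[k]] <- rep(1 / cfg$n_bins, cfg$n_bins)
    }
  }
  idx <- seq_len(k)
  dets <- tibble::new_tibble(
    list(
      frame = v_frame[idx], cx = v_cx[idx], cy = v_cy[idx], w = v_w[idx],
      h = v_h[idx], conf = v_conf[idx], true_id = v_tid[idx],
      app = v_app[idx], fhist = v_fh[idx]
    ),
    nrow = k
  )
  misses <- if (length(miss_rows)) {
    m <- do.call(rbind, miss_rows)
    tibble::tibble(frame = as.integer(m[, 1]), id = as.integer(m[, 2]))
  } else {
    tibble::tibble(frame = integer(), id = integer())
  }
  list(detections = dets, app_means = app_means, misses = misses)
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running [generate_truth()] and
#' [corrupt_to_detections()] under one seed.
#'
#' @param cfg A [scenario_config()] (or a preset name for [preset()]).
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A list of class `"aquatrack_scenario"` with elements `truth`,
#'   `detections`, `app_means` and `config`.
#' @export
simulate_scenario <- function(cfg = scenario_config(), seed = NULL) {
  if (is.character(cfg)) cfg <- preset(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  truth <- generate_truth(cfg)
  det <- corrupt_to_detections(truth, cfg)
  structure(
    list(
      truth = truth, detections = det$detections, app_means = det$app_means,
      misses = det$misses, config = cfg
    ),
    class = "aquatrack_scenario"
  )
}

#' @export
print.aquatrack_scenario <- function(x, ...) {
  cat(sprintf(
    "<aquatrack_scenario> %d targets, %d frames, scene %s, %d detections\n",
    x$config$n_targets, x$config$n_frames, x$config$scene, nrow(x$detections)
  ))
  invisible(x)
}

#' Curated scenario presets
#'
#' Named configurations emulating the study's challenge subsets: `daytime`
#' (low noise, high confidence), `nighttime` (frequent misses, low
#' confidence), `turbid` (heavy localization jitter, more false positives),
#' `occlusion` (scripted full occlusions), `crossing` (two targets on
#' intersecting paths), `benchmark` (4 targets, 1500 mixed frames) and
#' `maneuver` (turning + oscillation regimes, the predictor's training
#' diet).
#'
#' @param name Preset name.
#' @param ... Overrides passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
preset <- function(name, ...) {
  args <- switch(name,
    daytime = list(scene = "daytime"),
    nighttime = list(
      scene = "nighttime", miss_prob = 0.15, conf_mean = 0.55, conf_sd = 0.1,
      sigma_center = 4e-3, fp_rate = 0.05
    ),
    turbid = list(
      scene = "turbid", miss_prob = 0.12, conf_mean = 0.5, conf_sd = 0.1,
      sigma_center = 6e-3, sigma_size = 0.06, fp_rate = 0.08
    ),
    occlusion = list(
      scene = "occlusion", n_targets = 3L, n_frames = 600L,
      # moderate localization degradation plus 2 s full disappearances that
      # outlast the tracker's dormancy onset
      sigma_center = 4e-3,
      occlusions = tibble::tibble(
        id = c(1L, 2L, 3L), start = c(150L, 300L, 450L), end = c(209L, 359L, 509L)
      )
    ),
    crossing = list(
      layout = "crossing", n_targets = 2L, n_frames = 300L, miss_prob = 0.02
    ),
    benchmark = list(
      n_targets = 4L, n_frames = 1500L,
      regimes = c("stationary", "burst", "turn", "oscillation")
    ),
    maneuver = list(
      n_targets = 4L, n_frames = 600L,
      regimes = c("turn", "oscillation"), segment_len = c(60L, 150L)
    ),
    stop("unknown preset: ", name, call. = FALSE)
  )
  do.call(scenario_config, utils::modifyList(args, list(...)))
}
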