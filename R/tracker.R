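#' Tracker run configuration
#'
#' Bundles all parameter groups of the tracking pipeline: the BIOU
#' association prior, the cascade thresholds, track lifecycle constants,
#' scene handling and calibration. Defaults follow the reference
#' configuration: first-stage gate 0.30 (daytime/occlusion) or 0.20
#' (nighttime/turbid), fusion weight 0.7, history length 10, speed cap
#' 2 m/s.
#'
#' @param scene Scene class of the run (`"daytime"`, `"nighttime"`,
#'   `"turbid"`, `"occlusion"`), or `"auto"` to classify per frame from
#'   image statistics when those are supplied.
#' @param biou A [biou_params()].
#' @param matcher A [matcher_params()].
#' @param predictor A trained `aquatrack_predictor`, or `NULL` to fall back
#'   to the constant-velocity extrapolation.
#' @param L State-history length kept per track.
#' @param n_init Consecutive hits needed to confirm a tentative track.
#' @param max_age Missed frames before an active track turns dormant.
#' @param use_stage2,use_stage3 Toggles for the cascade's second and third
#'   stages (ablation switches).
#' @param stage1_metric Stage-1 association kernel: `"biou"` (default) or a
#'   plain variant (`"iou"`, `"giou"`, `"diou"`, `"ciou"`) for ablations.
#' @param k,fps,image_size Calibration: meters per pixel, frame rate, image
#'   pixel dimensions.
#' @param scene_thresholds Thresholds for [classify_scene()].
#' @param tau_biou,det_conf_min Optional overrides of the scene-derived
#'   stage-1 gate and confidence floor.
#' @param seed Run seed (recorded in logs; the tracker itself is
#'   deterministic).
#' @return A list of class `"tracker_config"`.
#' @export
tracker_config <- function(scene = "daytime", biou = biou_params(), matcher = matcher_params(),
                           predictor = NULL, L = 10L, n_init = 3L, max_age = 30L,
                           use_stage2 = TRUE, use_stage3 = TRUE, stage1_metric = "biou",
                           k = 0.01, fps = 30, image_size = c(1000, 1000),
                           scene_thresholds = list(b_night = 0.25, v_turbid = 0.01, e_turbid = 0.05),
                           tau_biou = NULL, det_conf_min = NULL, seed = 0L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  structure(
    list(
      scene = scene, biou = biou, matcher = matcher, predictor = predictor,
      L = as.integer(L), n_init = as.integer(n_init), max_age = as.integer(max_age),
      use_stage2 = isTRUE(use_stage2), use_stage3 = isTRUE(use_stage3),
      stage1_metric = stage1_metric,
      k = k, fps = fps, image_size = as.numeric(image_size),
      scene_thresholds = scene_thresholds,
      tau_biou = tau_biou, det_conf_min = det_conf_min, seed = as.integer(seed)
    ),
    class = "tracker_config"
  )
}

#' Classify the scene from frame image statistics
#'
#' A lightweight rule distinguishing the four monitoring conditions:
#' nighttime when mean brightness falls below `b_night`; turbid water when
#' both pixel variance and edge density are low (detail washed out without
#' darkness); the occlusion class only by explicit override; daytime
#' otherwise.
#'
#' @param stats A list or one-row data frame with `mean_brightness`,
#'   `pixel_variance`, `edge_density` (all `>= 0`).
#' @param thresholds List with `b_night`, `v_turbid`, `e_turbid`.
#' @param override Optional explicit scene class short-circuiting the rule.
#' @return One of `"daytime"`, `"nighttime"`, `"turbid"`, `"occlusion"`.
#' @export
classify_scene <- function(stats, thresholds = list(b_night = 0.25, v_turbid = 0.01, e_turbid = 0.05),
                           override = NULL) {
  if (!is.null(override)) {
    return(match.arg(override, c("daytime", "nighttime", "turbid", "occlusion")))
  }
  if (stats$mean_brightness < thresholds$b_night) return("nighttime")
  if (stats$pixel_variance < thresholds$v_turbid && stats$edge_density < thresholds$e_turbid) {
    return("turbid")
  }
  "daytime"
}

#' Scene-adaptive detection confidence filtering
#'
#' Keeps detections whose confidence clears the scene's floor: 0.5 in
#' daytime/occlusion scenes, relaxed to 0.3 at night and in turbid water so
#' that genuinely present but low-contrast animals are not discarded before
#' association can vouch for them.
#'
#' @param dets Detection tibble with a `conf` column.
#' @param ctx A [scene_context()].
#' @return The filtered tibble.
#' @export
filter_detections <- function(dets, ctx = scene_context()) {
  dets[dets$conf >= ctx$det_conf_min, , drop = FALSE]
}

new_track <- function(id, frame, box, conf, app = NULL, fhist = NULL) {
  st <- c(box, 0, 0)
  list(
    id = id, status = "tentative",
    hist = matrix(st, 1, 6, dimnames = list(NULL, c("x", "y", "w", "h", "dx", "dy"))),
    app = app, fhist = fhist,
    hits = 1L, frames_since_update = 0L,
    birth_frame = frame, dormancy_frame = NA_integer_, last_update = frame,
    speeds = numeric(0), last_pred = box,
    buffer = list(list(frame = frame, box = box, conf = conf))
  )
}

track_predict <- function(tr, cfg) {
  if (!is.null(cfg$predictor) && nrow(tr$hist) >= 2L) {
    as.numeric(predict_bbox(tr$hist, cfg$predictor))
  } else {
    as.numeric(constant_velocity_baseline(tr$hist))
  }
}

track_append_state <- function(tr, box, L) {
  last <- tr$hist[nrow(tr$hist), ]
  st <- c(box, box[1] - last[1], box[2] - last[2])
  tr$hist <- rbind(tr$hist, st)
  if (nrow(tr$hist) > L) tr$hist <- tr$hist[(nrow(tr$hist) - L + 1):nrow(tr$hist), , drop = FALSE]
  tr$speeds <- utils::tail(c(tr$speeds, sqrt(st[5]^2 + st[6]^2)), 30L)
  tr
}

#' Create a tracker state
#'
#' @param config A [tracker_config()].
#' @return An environment holding the mutable tracker state, to be advanced
#'   with [tracker_step()] and finalized with [tracker_output()].
#' @export
tracker_init <- function(config = tracker_config()) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$tracks <- list()
  st$next_id <- 1L
  st$frame <- -1L
  st$out <- list()
  st$log <- list()
  st
}

#' Advance the tracker by one frame
#'
#' Executes the per-frame cycle: predict boxes for live tracks, filter
#' detections by the scene confidence floor, run the three-stage cascade,
#' update matched tracks with their detections, spawn tentative tracks from
#' unmatched detections, and apply the lifecycle rules (confirmation after
#' `n_init` consecutive hits, dormancy after `max_age` misses, death of
#' tentative tracks on a miss and of dormant tracks past the buffer's
#' time-to-live). Unmatched live tracks coast on their own predictions
#' internally; only matched, confirmed tracks emit output boxes.
#'
#' @param state Tracker state from [tracker_init()].
#' @param frame 0-based frame index, strictly increasing across calls.
#' @param dets Detections of this frame (tibble with `cx, cy, w, h, conf`
#'   and optional list-columns `app`, `fhist`).
#' @param scene Optional scene-class override for this frame.
#' @return The state, invisibly; per-frame results accumulate inside it.
#' @export
tracker_step <- function(state, frame, dets, scene = NULL) {
  cfg <- state$config
  if (frame <= state$frame) {
    stop("frames must be presented in strictly increasing order", call. = FALSE)
  }
  state$frame <- frame
  scene_class <- scene %||% if (identical(cfg$scene, "auto")) "daytime" else cfg$scene
  ctx <- scene_context(scene_class, tau_biou = cfg$tau_biou, det_conf_min = cfg$det_conf_min)

  if (is.null(dets)) {
    dets <- tibble::tibble(cx = numeric(), cy = numeric(), w = numeric(), h = numeric(), conf = numeric())
  }
  dets <- filter_detections(dets, ctx)

  live_idx <- which(vapply(state$tracks, function(t) t$status %in% c("active", "tentative"), logical(1)))
  dormant_idx <- which(vapply(state$tracks, function(t) t$status == "dormant", logical(1)))

  # predictions for live tracks (fast-path tibble construction: this runs
  # once per frame and dominates the per-frame cost otherwise)
  preds <- NULL
  if (length(live_idx)) {
    pm <- t(vapply(state$tracks[live_idx], function(t) track_predict(t, cfg), numeric(4)))
    preds <- tibble::new_tibble(
      list(
        cx = pm[, 1], cy = pm[, 2], w = pmax(pm[, 3], 1e-4), h = pmax(pm[, 4], 1e-4),
        app = lapply(state$tracks[live_idx], `[[`, "app"),
        fhist = lapply(state$tracks[live_idx], `[[`, "fhist")
      ),
      nrow = length(live_idx)
    )
    for (ii in seq_along(live_idx)) {
      state$tracks[[live_idx[ii]]]$last_pred <- c(
        preds$cx[ii], preds$cy[ii], preds$w[ii], preds$h[ii]
      )
    }
  }
  dormant_tbl <- NULL
  if (cfg$use_stage3 && length(dormant_idx)) {
    dormant_tbl <- tibble::new_tibble(
      list(
        track = dormant_idx,
        cx = vapply(state$tracks[dormant_idx], function(t) t$last_pred[1], numeric(1)),
        cy = vapply(state$tracks[dormant_idx], function(t) t$last_pred[2], numeric(1)),
        elapsed = frame - vapply(state$tracks[dormant_idx], function(t) t$last_update, numeric(1)),
        speed = vapply(state$tracks[dormant_idx], function(t) {
          if (length(t$speeds)) stats::median(t$speeds) else 0
        }, numeric(1)),
        app = lapply(state$tracks[dormant_idx], `[[`, "app")
      ),
      nrow = length(dormant_idx)
    )
  }

  if (!cfg$use_stage2 && !is.null(preds)) {
    preds$app <- vector("list", nrow(preds))
    preds$fhist <- vector("list", nrow(preds))
  }
  res <- associate(preds, dets, dormant_tbl,
    ctx = ctx, biou = cfg$biou, params = cfg$matcher, metric = cfg$stage1_metric
  )

  matched_tracks <- integer(0)
  n_match <- nrow(res$matches)
  if (n_match) {
    m_track <- res$matches$track; m_det <- res$matches$det; m_stage <- res$matches$stage
    det_app <- if ("app" %in% names(dets)) dets$app else NULL
    det_fh <- if ("fhist" %in% names(dets)) dets$fhist else NULL
    mom <- cfg$matcher$ema_momentum
    for (mi in seq_len(n_match)) {
      ti <- if (m_stage[mi] == 3L) m_track[mi] else live_idx[m_track[mi]]
      di <- m_det[mi]
      box <- c(dets$cx[di], dets$cy[di], dets$w[di], dets$h[di])
      tr <- state$tracks[[ti]]
      tr <- track_append_state(tr, box, cfg$L)
      if (!is.null(det_app) && !is.null(det_app[[di]])) {
        tr$app <- if (is.null(tr$app)) det_app[[di]] else mom * tr$app + (1 - mom) * det_app[[di]]
      }
      if (!is.null(det_fh) && !is.null(det_fh[[di]])) {
        tr$fhist <- if (is.null(tr$fhist)) det_fh[[di]] else mom * tr$fhist + (1 - mom) * det_fh[[di]]
      }
      tr$frames_since_update <- 0L
      tr$last_update <- frame
      if (tr$status == "tentative") {
        tr$hits <- tr$hits + 1L
        tr$buffer <- c(tr$buffer, list(list(frame = frame, box = box, conf = dets$conf[di])))
        if (tr$hits >= cfg$n_init) {
          tr$status <- "active"
          for (b in tr$buffer) {
            state$out[[length(state$out) + 1L]] <- c(b$frame, tr$id, b$box, b$conf)
          }
          tr$buffer <- list()
        }
      } else { # active or dormant (reactivation)
        tr$status <- "active"
        tr$dormancy_frame <- NA_integer_
        state$out[[length(state$out) + 1L]] <- c(frame, tr$id, box, dets$conf[di])
      }
      state$tracks[[ti]] <- tr
      matched_tracks <- c(matched_tracks, ti)
    }
  }

  # lifecycle for unmatched tracks
  for (ti in setdiff(c(live_idx, if (!is.null(dormant_tbl)) dormant_tbl$track else integer(0)), matched_tracks)) {
    tr <- state$tracks[[ti]]
    if (tr$status == "tentative") {
      tr$status <- "dead"
    } else if (tr$status == "active") {
      tr$frames_since_update <- tr$frames_since_update + 1L
      # coast internally on the prediction to keep the state chain per-frame
      tr <- track_append_state(tr, tr$last_pred, cfg$L)
      if (tr$frames_since_update > cfg$max_age) {
        tr$status <- "dormant"
        tr$dormancy_frame <- frame
      }
    } else if (tr$status == "dormant") {
      if ((frame - tr$last_update) > cfg$matcher$dormant_ttl) tr$status <- "dead"
    }
    state$tracks[[ti]] <- tr
  }
  # dormant tracks not considered this frame (stage 3 off) still age out
  if (!cfg$use_stage3) {
    for (ti in dormant_idx) {
      tr <- state$tracks[[ti]]
      if ((frame - tr$last_update) > cfg$matcher$dormant_ttl) {
        tr$status <- "dead"
        state$tracks[[ti]] <- tr
      }
    }
  }

  # births
  for (di in res$unmatched_dets) {
    tr <- new_track(
      state$next_id, frame,
      c(dets$cx[di], dets$cy[di], dets$w[di], dets$h[di]), dets$conf[di],
      app = if ("app" %in% names(dets)) dets$app[[di]] else NULL,
      fhist = if ("fhist" %in% names(dets)) dets$fhist[[di]] else NULL
    )
    if (cfg$n_init <= 1L) {
      tr$status <- "active"
      for (b in tr$buffer) state$out[[length(state$out) + 1L]] <- c(b$frame, tr$id, b$box, b$conf)
      tr$buffer <- list()
    }
    state$tracks[[length(state$tracks) + 1L]] <- tr
    state$next_id <- state$next_id + 1L
  }

  state$log[[length(state$log) + 1L]] <- list(
    frame = frame, scene = scene_class, n_dets = nrow(dets),
    stage1 = sum(res$matches$stage == 1L), stage2 = sum(res$matches$stage == 2L),
    stage3 = sum(res$matches$stage == 3L),
    births = length(res$unmatched_dets)
  )
  invisible(state)
}

#' Collect the tracker's output trajectories
#'
#' @param state Tracker state after stepping through all frames.
#' @return A tibble of class `"aquatrack_tracks"` with columns `frame`,
#'   `id`, `cx`, `cy`, `w`, `h`, `conf`, sorted by frame then id; the
#'   per-frame association log is attached as attribute `"log"`.
#' @export
tracker_output <- function(state) {
  out <- if (length(state$out)) {
    m <- do.call(rbind, state$out)
    tibble::tibble(
      frame = as.integer(m[, 1]), id = as.integer(m[, 2]),
      cx = m[, 3], cy = m[, 4], w = m[, 5], h = m[, 6], conf = m[, 7]
    )
  } else {
    tibble::tibble(
      frame = integer(), id = integer(), cx = numeric(), cy = numeric(),
      w = numeric(), h = numeric(), conf = numeric()
    )
  }
  out <- dplyr::arrange(out, .data$frame, .data$id)
  class(out) <- c("aquatrack_tracks", class(out))
  attr(out, "log") <- if (length(state$log)) {
    dplyr::bind_rows(lapply(state$log, tibble::as_tibble))
  } else {
    tibble::tibble()
  }
  out
}

#' Track a full detection sequence
#'
#' Runs the complete pipeline over a detection table: per frame, predict -
#' associate (three-stage cascade) - update lifecycle. Frames between the
#' first and last detection with no detections still age the tracks.
#'
#' @param detections Tibble with `frame` (0-based), `cx, cy, w, h`, `conf`
#'   and optional list-columns `app`, `fhist` (appearance embeddings and
#'   flow-direction histograms from the feature sidecar).
#' @param config A [tracker_config()].
#' @param scenes Optional tibble mapping `frame` to `scene` for
#'   frame-varying conditions.
#' @return An `aquatrack_tracks` tibble (see [tracker_output()]).
#' @examples
#' sc <- simulate_scenario(preset("crossing", n_frames = 80), seed = 1)
#' trk <- track_sequence(sc$detections, tracker_config())
#' head(trk)
#' @export
track_sequence <- function(detections, config = tracker_config(), scenes = NULL) {
  state <- tracker_init(config)
  if (nrow(detections) == 0L) return(tracker_output(state))
  frames <- seq(min(detections$frame), max(detections$frame))
  det_split <- split(seq_len(nrow(detections)), factor(detections$frame, levels = frames))
  for (fr in frames) {
    rows <- det_split[[as.character(fr)]]
    dets <- if (length(rows)) detections[rows, , drop = FALSE] else NULL
    sc <- if (!is.null(scenes)) scenes$scene[match(fr, scenes$frame)] else NULL
    tracker_step(state, fr, dets, scene = sc)
  }
  tracker_output(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
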