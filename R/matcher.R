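#' Similarity kernels for feature-based re-matching
#'
#' `cosine_similarity()` compares appearance embeddings (scale-invariant,
#' in `[-1, 1]`); `bhattacharyya()` compares normalized histograms
#' (`sum(sqrt(h1 * h2))`, 1 for identical, 0 for disjoint support);
#' `fused_similarity()` combines the two with the appearance weight
#' `omega`: `S = omega * S_a + (1 - omega) * S_m` (default `omega = 0.7`).
#'
#' @param f1,f2 Non-zero numeric vectors (appearance embeddings).
#' @param h1,h2 Non-negative histograms of equal length summing to 1.
#' @param s_a,s_m Appearance and motion similarity scores.
#' @param omega Fusion weight in `[0, 1]` for the appearance term.
#' @name similarity_kernels
NULL

#' @rdname similarity_kernels
#' @export
cosine_similarity <- function(f1, f2) {
  n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for a zero vector", call. = FALSE)
  sum(f1 * f2) / (n1 * n2)
}

#' @rdname similarity_kernels
#' @export
bhattacharyya <- function(h1, h2) {
  if (length(h1) != length(h2)) stop("histogram lengths differ", call. = FALSE)
  sum(sqrt(pmax(h1, 0) * pmax(h2, 0)))
}

#' @rdname similarity_kernels
#' @export
fused_similarity <- function(s_a, s_m, omega = 0.7) {
  stopifnot(omega >= 0, omega <= 1)
  omega * s_a + (1 - omega) * s_m
}

#' Direction histogram of a motion vector field
#'
#' Quantizes flow-vector angles `atan2(vy, vx)` into `n_bins` equal intervals
#' over `[0, 2 * pi)`, weighting each vector by its magnitude, and normalizes
#' the histogram to sum 1. A field with no motion (all magnitudes 0) yields
#' the uninformative uniform histogram.
#'
#' @param vx,vy Numeric vectors of flow components over a box region.
#' @param n_bins Number of angular bins (`>= 2`).
#' @return A normalized histogram of length `n_bins`.
#' @export
flow_direction_histogram <- function(vx, vy, n_bins = 8L) {
  if (length(vx) == 0L || length(vx) != length(vy)) {
    stop("flow field must be non-empty with matching component lengths", call. = FALSE)
  }
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  keep <- is.finite(vx) & is.finite(vy)
  if (!any(keep)) stop("flow field has no finite vectors", call. = FALSE)
  vx <- vx[keep]; vy <- vy[keep]
  mag <- sqrt(vx^2 + vy^2)
  if (sum(mag) == 0) return(rep(1 / n_bins, n_bins))
  ang <- atan2(vy, vx) %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi / n_bins)) + 1L, n_bins)
  h <- vapply(seq_len(n_bins), function(b) sum(mag[bin == b]), numeric(1))
  h / sum(h)
}

#' Scene-dependent association context
#'
#' Holds the scene class and the scene-adaptive thresholds: the first-stage
#' BIOU gate `tau_biou` (0.30 in daytime and occlusion scenes, relaxed to
#' 0.20 at night and in turbid water, where detection quality degrades) and
#' the detection confidence floor (0.5 daytime, 0.3 nighttime/turbid).
#'
#' @param scene_class One of `"daytime"`, `"nighttime"`, `"turbid"`,
#'   `"occlusion"`.
#' @param tau_biou First-stage association gate; scene default if `NULL`.
#' @param det_conf_min Detection confidence floor; scene default if `NULL`.
#' @return A list of class `"scene_context"`.
#' @export
scene_context <- function(scene_class = c("daytime", "nighttime", "turbid", "occlusion"),
                          tau_biou = NULL, det_conf_min = NULL) {
  scene_class <- match.arg(scene_class)
  if (is.null(tau_biou)) {
    tau_biou <- if (scene_class %in% c("daytime", "occlusion")) 0.30 else 0.20
  }
  if (is.null(det_conf_min)) {
    det_conf_min <- if (scene_class %in% c("nighttime", "turbid")) 0.3 else 0.5
  }
  if (tau_biou <= 0 || tau_biou >= 1) stop("tau_biou must lie in (0, 1)", call. = FALSE)
  structure(
    list(scene_class = scene_class, tau_biou = tau_biou, det_conf_min = det_conf_min),
    class = "scene_context"
  )
}

#' Parameters of the cascaded matcher
#'
#' @param omega Stage-2 fusion weight for appearance vs motion similarity.
#' @param tau_s Stage-2 gate on the fused similarity.
#' @param react_threshold Stage-3 combined-confidence threshold for
#'   reactivating a dormant track (a deliberately high bar).
#' @param app_gate Minimum appearance cosine for reactivation.
#' @param dormant_ttl Maximum dormancy, in frames, before a track dies.
#' @param v_gate_scale Allowed drift per dormant frame, as a multiple of the
#'   track's median pre-dormancy speed.
#' @param v_gate_floor Lower bound of the per-frame drift gate, normalized
#'   units.
#' @param n_bins Number of bins of the flow-direction histogram.
#' @param ema_momentum Momentum of the exponential moving average updating a
#'   live track's appearance/motion memories (frozen while dormant).
#' @return A list of class `"matcher_params"`.
#' @export
matcher_params <- function(omega = 0.7, tau_s = 0.5, react_threshold = 0.8,
                           app_gate = 0.5, dormant_ttl = 300L, v_gate_scale = 3,
                           v_gate_floor = 0.01, n_bins = 8L, ema_momentum = 0.9) {
  stopifnot(omega >= 0, omega <= 1, tau_s >= 0, tau_s <= 1, dormant_ttl >= 1)
  structure(
    list(
      omega = omega, tau_s = tau_s, react_threshold = react_threshold,
      app_gate = app_gate, dormant_ttl = as.integer(dormant_ttl),
      v_gate_scale = v_gate_scale, v_gate_floor = v_gate_floor,
      n_bins = as.integer(n_bins), ema_momentum = ema_momentum
    ),
    class = "matcher_params"
  )
}

empty_assoc <- function() {
  tibble::new_tibble(
    list(track = integer(), det = integer(), stage = integer(), score = numeric()),
    nrow = 0L
  )
}

#' Stage 1: fast motion-consistency matching
#'
#' Hungarian assignment on `1 - BIOU` between predicted track boxes and
#' detection boxes, gated at the scene-adaptive threshold `tau_biou`.
#'
#' @param pred_boxes Predicted boxes for the candidate tracks (4-column
#'   matrix/data frame), one row per track.
#' @param det_boxes Detection boxes, one row per detection.
#' @param ctx A [scene_context()].
#' @param params A [biou_params()].
#' @param metric Association kernel (default `"biou"`; `"iou"`, `"giou"`,
#'   `"diou"`, `"ciou"` support ablation comparisons).
#' @return A tibble with columns `track`, `det` (row indices into the
#'   inputs), `stage = 1` and the BIOU `score`.
#' @export
stage1_match <- function(pred_boxes, det_boxes, ctx = scene_context(), params = biou_params(),
                         metric = "biou") {
  cm <- box_cost_matrix(pred_boxes, det_boxes, metric = metric, gate = ctx$tau_biou, params = params)
  a <- hungarian_assign(cm$cost, cm$feasible)
  tibble::new_tibble(
    list(track = a$row, det = a$col, stage = rep(1L, nrow(a)), score = 1 - a$cost),
    nrow = nrow(a)
  )
}

#' Stage 2: fused appearance/motion re-matching
#'
#' For each leftover track x detection pair, computes the fused similarity
#' `omega * S_a + (1 - omega) * S_m` from appearance cosine and
#' flow-histogram Bhattacharyya coefficients, then solves the gated
#' assignment at `tau_s`. A pair missing one feature falls back to the
#' available one; pairs with neither feature are infeasible.
#'
#' @param track_app,det_app Lists of appearance embeddings (or `NULL`
#'   entries).
#' @param track_hist,det_hist Lists of direction histograms (or `NULL`
#'   entries).
#' @param params A [matcher_params()].
#' @return A tibble like [stage1_match()] with `stage = 2`.
#' @export
stage2_match <- function(track_app, det_app, track_hist = NULL, det_hist = NULL,
                         params = matcher_params()) {
  nt <- length(track_app); nd <- length(det_app)
  if (nt == 0L || nd == 0L) return(empty_assoc())
  if (is.null(track_hist)) track_hist <- vector("list", nt)
  if (is.null(det_hist)) det_hist <- vector("list", nd)
  S <- matrix(-Inf, nt, nd)
  for (i in seq_len(nt)) {
    for (j in seq_len(nd)) {
      s_a <- if (!is.null(track_app[[i]]) && !is.null(det_app[[j]])) {
        cosine_similarity(track_app[[i]], det_app[[j]])
      } else {
        NA_real_
      }
      s_m <- if (!is.null(track_hist[[i]]) && !is.null(det_hist[[j]])) {
        bhattacharyya(track_hist[[i]], det_hist[[j]])
      } else {
        NA_real_
      }
      S[i, j] <- if (is.na(s_a) && is.na(s_m)) {
        -Inf
      } else if (is.na(s_m)) {
        s_a
      } else if (is.na(s_a)) {
        s_m
      } else {
        fused_similarity(s_a, s_m, params$omega)
      }
    }
  }
  a <- hungarian_assign(1 - S, S >= params$tau_s)
  tibble::new_tibble(
    list(track = a$row, det = a$col, stage = rep(2L, nrow(a)), score = 1 - a$cost),
    nrow = nrow(a)
  )
}

#' Stage 3: reactivation of dormant tracks
#'
#' A dormant track can claim a still-unmatched detection only when all gates
#' hold: (i) the dormancy is younger than `dormant_ttl` frames; (ii) the
#' detection center lies within the motion-consistency gate, a radius of
#' `v_gate * elapsed` around the track's last predicted position (with
#' `v_gate` scaled from the track's pre-dormancy speed); (iii) the
#' appearance cosine against the frozen memory is at least `app_gate`; and
#' the combined confidence `0.5 * S_a + 0.5 * (1 - dist / gate_radius)`
#' clears `react_threshold`. Competing candidates are resolved by Hungarian
#' assignment on the combined confidence.
#'
#' @param dormant A tibble of dormant-track records with columns `track`
#'   (index), `cx`, `cy` (last predicted center), `elapsed` (frames since
#'   dormancy), `speed` (median pre-dormancy per-frame displacement) and
#'   list-column `app` (frozen appearance memory).
#' @param det_boxes Detection boxes, one row per unmatched detection.
#' @param det_app List of detection appearance embeddings.
#' @param params A [matcher_params()].
#' @return A tibble like [stage1_match()] with `stage = 3` and the combined
#'   confidence as `score`; `track` holds the values of `dormant$track`.
#' @export
stage3_reactivate <- function(dormant, det_boxes, det_app, params = matcher_params()) {
  if (is.null(dormant) || nrow(dormant) == 0L) return(empty_assoc())
  det_boxes <- as_box_matrix(if (is.null(det_boxes)) matrix(numeric(), 0, 4) else det_boxes)
  nd <- nrow(det_boxes)
  if (nd == 0L) return(empty_assoc())
  nt <- nrow(dormant)
  S <- matrix(-Inf, nt, nd)
  for (i in seq_len(nt)) {
    if (dormant$elapsed[i] > params$dormant_ttl) next
    v_gate <- max(params$v_gate_scale * dormant$speed[i], params$v_gate_floor)
    radius <- v_gate * dormant$elapsed[i]
    for (j in seq_len(nd)) {
      dist <- sqrt((det_boxes[j, 1] - dormant$cx[i])^2 + (det_boxes[j, 2] - dormant$cy[i])^2)
      if (dist > radius) next
      s_a <- if (!is.null(dormant$app[[i]]) && !is.null(det_app[[j]])) {
        cosine_similarity(dormant$app[[i]], det_app[[j]])
      } else {
        next
      }
      if (s_a < params$app_gate) next
      spatial <- 1 - dist / radius
      S[i, j] <- 0.5 * s_a + 0.5 * spatial
    }
  }
  a <- hungarian_assign(1 - S, S >= params$react_threshold)
  if (nrow(a) == 0L) return(empty_assoc())
  tibble::new_tibble(
    list(
      track = dormant$track[a$row], det = a$col,
      stage = rep(3L, nrow(a)), score = 1 - a$cost
    ),
    nrow = nrow(a)
  )
}

#' Three-stage cascaded association
#'
#' Runs the cascade on successively unmatched residues: (1) gated BIOU +
#' Hungarian on predicted boxes, (2) fused appearance/motion re-matching of
#' the leftovers, (3) reactivation of dormant tracks against the remaining
#' detections. No track or detection is matched twice.
#'
#' @param tracks A tibble of live (active/tentative) candidate tracks with
#'   predicted box columns `cx, cy, w, h` and optional list-columns `app`
#'   and `fhist` (memories).
#' @param dets A tibble of detections with box columns and optional
#'   list-columns `app` and `fhist`.
#' @param dormant Dormant-track records for [stage3_reactivate()] (or `NULL`).
#' @param ctx A [scene_context()].
#' @param biou A [biou_params()].
#' @param params A [matcher_params()].
#' @param metric Stage-1 association kernel (see [stage1_match()]).
#' @return A list with `matches` (tibble `track`, `det`, `stage`, `score`;
#'   `track` indexes `tracks` rows for stages 1-2 and carries
#'   `dormant$track` values for stage 3), `unmatched_tracks` and
#'   `unmatched_dets` (row indices).
#' @export
associate <- function(tracks, dets, dormant = NULL, ctx = scene_context(),
                      biou = biou_params(), params = matcher_params(), metric = "biou") {
  nt <- if (is.null(tracks)) 0L else nrow(tracks)
  nd <- if (is.null(dets)) 0L else nrow(dets)
  matches <- empty_assoc()
  left_t <- seq_len(nt)
  left_d <- seq_len(nd)

  if (nt > 0L && nd > 0L) {
    m1 <- stage1_match(tracks[, c("cx", "cy", "w", "h")], dets[, c("cx", "cy", "w", "h")],
      ctx = ctx, params = biou, metric = metric
    )
    matches <- m1
    left_t <- setdiff(left_t, m1$track)
    left_d <- setdiff(left_d, m1$det)
  }

  if (length(left_t) > 0L && length(left_d) > 0L) {
    t_app <- if ("app" %in% names(tracks)) tracks$app[left_t] else vector("list", length(left_t))
    d_app <- if ("app" %in% names(dets)) dets$app[left_d] else vector("list", length(left_d))
    t_h <- if ("fhist" %in% names(tracks)) tracks$fhist[left_t] else vector("list", length(left_t))
    d_h <- if ("fhist" %in% names(dets)) dets$fhist[left_d] else vector("list", length(left_d))
    m2 <- stage2_match(t_app, d_app, t_h, d_h, params = params)
    if (nrow(m2) > 0L) {
      m2$track <- left_t[m2$track]
      m2$det <- left_d[m2$det]
      matches <- dplyr::bind_rows(matches, m2)
      left_t <- setdiff(left_t, m2$track)
      left_d <- setdiff(left_d, m2$det)
    }
  }

  if (!is.null(dormant) && nrow(dormant) > 0L && length(left_d) > 0L) {
    d_app <- if ("app" %in% names(dets)) dets$app[left_d] else vector("list", length(left_d))
    m3 <- stage3_reactivate(dormant, dets[left_d, c("cx", "cy", "w", "h")], d_app, params = params)
    if (nrow(m3) > 0L) {
      m3$det <- left_d[m3$det]
      matches <- dplyr::bind_rows(matches, m3)
      left_d <- setdiff(left_d, m3$det)
    }
  }

  list(matches = matches, unmatched_tracks = left_t, unmatched_dets = left_d)
}
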