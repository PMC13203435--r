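#' Match ground-truth and hypothesis boxes within one frame
#'
#' CLEAR-style per-frame correspondence: pairs matched in the previous frame
#' are kept whenever their IoU still clears the gate (the carryover rule
#' that stabilizes identities), then the remaining boxes are assigned by the
#' Hungarian algorithm maximizing total IoU among pairs above the gate.
#'
#' @param gt Tibble of this frame's ground-truth boxes (`id, cx, cy, w, h`).
#' @param hyp Tibble of this frame's hypothesis boxes (`id, cx, cy, w, h`).
#' @param iou_gate Minimum IoU for a valid correspondence.
#' @param prev Named vector mapping gt id to the hyp id matched in the
#'   previous frame (used for carryover), or `NULL`.
#' @return A tibble with columns `gt_id`, `hyp_id`, `iou`.
#' @export
frame_match <- function(gt, hyp, iou_gate = 0.5, prev = NULL) {
  out <- tibble::tibble(gt_id = integer(), hyp_id = integer(), iou = numeric())
  if (nrow(gt) == 0L || nrow(hyp) == 0L) return(out)
  # carryover
  kept_g <- integer(0); kept_h <- integer(0)
  if (!is.null(prev) && length(prev)) {
    for (gi in seq_len(nrow(gt))) {
      hid <- prev[as.character(gt$id[gi])]
      if (is.na(hid)) next
      hi <- match(hid, hyp$id)
      if (is.na(hi)) next
      s <- iou(gt[gi, c("cx", "cy", "w", "h")], hyp[hi, c("cx", "cy", "w", "h")])
      if (s >= iou_gate) {
        out <- dplyr::bind_rows(out, tibble::tibble(gt_id = gt$id[gi], hyp_id = hyp$id[hi], iou = s))
        kept_g <- c(kept_g, gi); kept_h <- c(kept_h, hi)
      }
    }
  }
  rg <- setdiff(seq_len(nrow(gt)), kept_g)
  rh <- setdiff(seq_len(nrow(hyp)), kept_h)
  if (length(rg) && length(rh)) {
    cm <- box_cost_matrix(gt[rg, c("cx", "cy", "w", "h")], hyp[rh, c("cx", "cy", "w", "h")],
      metric = "iou", gate = iou_gate
    )
    a <- hungarian_assign(cm$cost, cm$feasible)
    if (nrow(a)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        gt_id = gt$id[rg[a$row]], hyp_id = hyp$id[rh[a$col]], iou = 1 - a$cost
      ))
    }
  }
  out
}

#' CLEAR-MOT and identity metrics
#'
#' Accumulates FP, FN, identity switches (a ground-truth identity's matched
#' hypothesis id differing from its last known match) and fragmentations
#' (a ground-truth track's coverage interrupted and later resumed) over all
#' frames, and computes
#' `MOTA = 100 * (1 - (FP + FN + IDs) / total gt boxes)` together with the
#' global identity-F1 score (IDF1, from the optimal whole-sequence
#' track-to-track assignment).
#'
#' @param gt Ground-truth trajectories (`frame, id, cx, cy, w, h`).
#' @param hyp Tracker output in the same form.
#' @param iou_gate Gate for per-frame correspondences (default 0.5).
#' @return A one-row tibble: `MOTA`, `IDF1` (percent), `IDs`, `Frag`, `FP`,
#'   `FN`, `n_gt`, `n_matches`.
#' @export
mot_metrics <- function(gt, hyp, iou_gate = 0.5) {
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  fp <- 0L; fn <- 0L; ids <- 0L
  last_match <- integer(0) # gt id -> last matched hyp id
  prev <- NULL # matches of previous frame, for carryover
  gt_ids <- unique(gt$id)
  # per gt id: matched-status over its own frames, to count fragmentations
  frag_state <- stats::setNames(rep(NA, length(gt_ids)), as.character(gt_ids)) # last status
  frag_broken <- stats::setNames(rep(FALSE, length(gt_ids)), as.character(gt_ids))
  frag <- 0L
  for (fr in frames) {
    gtf <- gt[gt$frame == fr, , drop = FALSE]
    hyf <- hyp[hyp$frame == fr, , drop = FALSE]
    m <- frame_match(gtf, hyf, iou_gate, prev)
    fp <- fp + (nrow(hyf) - nrow(m))
    fn <- fn + (nrow(gtf) - nrow(m))
    if (nrow(m)) {
      for (r in seq_len(nrow(m))) {
        key <- as.character(m$gt_id[r])
        old <- last_match[key]
        if (!is.na(old) && old != m$hyp_id[r]) ids <- ids + 1L
        last_match[key] <- m$hyp_id[r]
      }
    }
    # fragmentation bookkeeping over frames where the gt exists
    for (gid in gtf$id) {
      key <- as.character(gid)
      matched <- gid %in% m$gt_id
      if (matched) {
        if (isTRUE(frag_broken[key])) {
          frag <- frag + 1L
          frag_broken[key] <- FALSE
        }
        frag_state[key] <- TRUE
      } else {
        if (isTRUE(frag_state[key])) frag_broken[key] <- TRUE
      }
    }
    prev <- stats::setNames(m$hyp_id, as.character(m$gt_id))
  }
  n_gt <- nrow(gt)
  tibble::tibble(
    MOTA = 100 * (1 - (fp + fn + ids) / n_gt),
    IDF1 = idf1(gt, hyp, iou_gate),
    IDs = ids, Frag = frag, FP = fp, FN = fn,
    n_gt = n_gt, n_matches = n_gt - fn
  )
}

#' Identity F1 score
#'
#' Computes IDF1 from the optimal bijective assignment between whole
#' ground-truth tracks and whole hypothesis tracks: a gt/hyp track pair
#' scores an identity true positive in every frame where both are present
#' and their boxes overlap above the gate;
#' `IDF1 = 100 * 2 * IDTP / (2 * IDTP + IDFP + IDFN)`.
#'
#' @inheritParams mot_metrics
#' @return IDF1 in percent.
#' @export
idf1 <- function(gt, hyp, iou_gate = 0.5) {
  if (nrow(gt) == 0L) return(NA_real_)
  if (nrow(hyp) == 0L) return(0)
  gids <- sort(unique(gt$id)); hids <- sort(unique(hyp$id))
  ng <- length(gids); nh <- length(hids)
  len_g <- vapply(gids, function(i) sum(gt$id == i), integer(1))
  len_h <- vapply(hids, function(j) sum(hyp$id == j), integer(1))
  idtp <- matrix(0, ng, nh)
  for (gi in seq_len(ng)) {
    g <- gt[gt$id == gids[gi], , drop = FALSE]
    for (hi in seq_len(nh)) {
      h <- hyp[hyp$id == hids[hi], , drop = FALSE]
      common <- intersect(g$frame, h$frame)
      if (!length(common)) next
      s <- iou(
        g[match(common, g$frame), c("cx", "cy", "w", "h")],
        h[match(common, h$frame), c("cx", "cy", "w", "h")]
      )
      idtp[gi, hi] <- sum(s >= iou_gate)
    }
  }
  n <- ng + nh
  C <- matrix(Inf, n, n)
  C[seq_len(ng), seq_len(nh)] <- outer(len_g, len_h, "+") - 2 * idtp
  for (gi in seq_len(ng)) C[gi, nh + gi] <- len_g[gi]
  for (hi in seq_len(nh)) C[ng + hi, hi] <- len_h[hi]
  C[(ng + 1):n, (nh + 1):n] <- 0
  a <- hungarian_assign(C)
  cost <- sum(a$cost)
  idtp_tot <- (sum(len_g) + sum(len_h) - cost) / 2
  100 * 2 * idtp_tot / (sum(len_g) + sum(len_h))
}

#' Average Euclidean distance of next-frame predictions
#'
#' Mean distance (normalized units) between predicted and true next-frame
#' box centers over a set of held-out history/target examples — the
#' predictor's accuracy measure.
#'
#' @param examples Tibble from [make_history_examples()].
#' @param model A trained `aquatrack_predictor`, or `NULL` to score the
#'   constant-velocity baseline.
#' @return Mean center distance.
#' @export
predictor_aed <- function(examples, model = NULL) {
  if (nrow(examples) == 0L) stop("no held-out examples", call. = FALSE)
  tgt <- do.call(rbind, examples$target)
  if (is.null(model)) {
    pred <- t(vapply(examples$hist, constant_velocity_baseline, numeric(4)))
  } else {
    pred <- predict_bbox(examples$hist, model)
    if (is.null(dim(pred))) pred <- matrix(pred, 1)
  }
  mean(sqrt((pred[, 1] - tgt[, 1])^2 + (pred[, 2] - tgt[, 2])^2))
}
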