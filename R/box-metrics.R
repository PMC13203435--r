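#' Bounding-box association kernels
#'
#' Overlap-based similarity measures between axis-aligned bounding boxes in
#' normalized center format: `iou()` (intersection over union), `giou()`
#' (generalized, with an enclosure penalty), `diou()` (distance, with a
#' center-offset penalty), `ciou()` (complete, adding an aspect-ratio term),
#' and `biou()`, the biologically constrained variant used for track-detection
#' association: the CIoU-style aspect penalty weight is escalated
#' exponentially when the predicted box's elongation (long side / short side)
#' leaves the prior interval expected for the tracked species.
#'
#' All kernels are vectorized: `a` and `b` may be length-4 numeric vectors
#' `c(cx, cy, w, h)`, 4-column matrices, or data frames with columns
#' `cx, cy, w, h`; rows are recycled to a common length. Coordinates are
#' normalized to the image (`cx, cy` in `[0, 1]`, origin top-left, y down).
#'
#' @param a,b,pred,det Boxes in normalized center format (see Details).
#' @param params A [biou_params()] list controlling the BIOU prior.
#' @return A numeric vector of scores, one per box pair. `iou` lies in
#'   `[0, 1]`; `giou` in `(-1, 1]`; `diou`, `ciou` and `biou` are at most 1
#'   and can be negative for distant boxes.
#' @examples
#' iou(c(0.25, 0.25, 0.2, 0.2), c(0.35, 0.35, 0.2, 0.2)) # 1/7
#' biou(c(0.5, 0.5, 0.3, 0.1), c(0.5, 0.5, 0.3, 0.1))    # identical -> 1
#' @name box_kernels
NULL

as_box_matrix <- function(x, arg = "box") {
  if (is.data.frame(x)) {
    stopifnot(all(c("cx", "cy", "w", "h") %in% names(x)))
    x <- cbind(x$cx, x$cy, x$w, x$h)
  } else if (is.null(dim(x))) {
    if (length(x) != 4L) stop(arg, " must have 4 elements (cx, cy, w, h)", call. = FALSE)
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 4L) stop(arg, " must have 4 columns (cx, cy, w, h)", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (nrow(x) > 0L && (!all(is.finite(x)) || any(x[, 3] <= 0) || any(x[, 4] <= 0))) {
    stop("invalid box geometry: dimensions must be finite and positive", call. = FALSE)
  }
  colnames(x) <- c("cx", "cy", "w", "h")
  x
}

recycle_boxes <- function(a, b) {
  a <- as_box_matrix(a, "a")
  b <- as_box_matrix(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  list(a = a, b = b)
}

# corner coordinates (x1, y1, x2, y2) from a center-format matrix
box_corners <- function(m) {
  cbind(
    m[, 1] - m[, 3] / 2, m[, 2] - m[, 4] / 2,
    m[, 1] + m[, 3] / 2, m[, 2] + m[, 4] / 2
  )
}

#' @rdname box_kernels
#' @export
iou <- function(a, b) {
  p <- recycle_boxes(a, b)
  ca <- box_corners(p$a); cb <- box_corners(p$b)
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  union <- p$a[, 3] * p$a[, 4] + p$b[, 3] * p$b[, 4] - inter
  as.numeric(inter / union)
}

#' Center-distance penalty between two boxes
#'
#' The squared center distance divided by the squared diagonal of the
#' smallest box enclosing both, the distance term shared by DIoU, CIoU and
#' BIOU. Zero for co-centered boxes; defined as 0 by continuity when the
#' enclosure is degenerate (identical point boxes).
#'
#' @inheritParams box_kernels
#' @return Numeric vector in `[0, 1]`.
#' @export
center_penalty <- function(a, b) {
  p <- recycle_boxes(a, b)
  ca <- box_corners(p$a); cb <- box_corners(p$b)
  rho2 <- (p$a[, 1] - p$b[, 1])^2 + (p$a[, 2] - p$b[, 2])^2
  cw <- pmax(ca[, 3], cb[, 3]) - pmin(ca[, 1], cb[, 1])
  ch <- pmax(ca[, 4], cb[, 4]) - pmin(ca[, 2], cb[, 2])
  c2 <- cw^2 + ch^2
  out <- ifelse(c2 > 0, rho2 / c2, 0)
  as.numeric(out)
}

#' Aspect-ratio consistency term
#'
#' `v = (4 / pi^2) * (atan(w_a / h_a) - atan(w_b / h_b))^2`, the CIoU-family
#' measure of aspect-ratio disagreement: 0 for equal width/height ratios,
#' approaching 1 as the ratios diverge to opposite extremes.
#'
#' @inheritParams box_kernels
#' @return Numeric vector in `[0, 1]`.
#' @export
aspect_consistency <- function(a, b) {
  p <- recycle_boxes(a, b)
  d <- atan(p$a[, 3] / p$a[, 4]) - atan(p$b[, 3] / p$b[, 4])
  as.numeric(4 / pi^2 * d^2)
}

#' @rdname box_kernels
#' @export
giou <- function(a, b) {
  p <- recycle_boxes(a, b)
  ca <- box_corners(p$a); cb <- box_corners(p$b)
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  union <- p$a[, 3] * p$a[, 4] + p$b[, 3] * p$b[, 4] - inter
  hull <- (pmax(ca[, 3], cb[, 3]) - pmin(ca[, 1], cb[, 1])) *
    (pmax(ca[, 4], cb[, 4]) - pmin(ca[, 2], cb[, 2]))
  as.numeric(inter / union - (hull - union) / hull)
}

#' @rdname box_kernels
#' @export
diou <- function(a, b) {
  iou(a, b) - center_penalty(a, b)
}

#' @rdname box_kernels
#' @export
ciou <- function(a, b) {
  i <- iou(a, b)
  v <- aspect_consistency(a, b)
  alpha <- ifelse(v > 0, v / ((1 - i) + v), 0)
  i - center_penalty(a, b) - alpha * v
}

#' Parameters for the biologically constrained BIOU kernel
#'
#' BIOU subtracts from IoU a center-distance penalty and an aspect-ratio
#' penalty `alpha * v`. The weight `alpha` is either the CIoU-adaptive weight
#' `v / ((1 - IoU) + v)` (`alpha_mode = "adaptive"`) or a fixed constant, and
#' it is multiplied by `exp(prior_beta * dist(e, [prior_low, prior_high]))`
#' where `e = max(w, h) / min(w, h)` is the predicted box's elongation and
#' `dist` its distance to the prior interval (0 inside). The default interval
#' `[1.5, 8]` is a box-frame relaxation of the body-frame length-to-width
#' range observed for swimming giant salamanders (1:4 to 1:8): axis-aligned
#' boxes of diagonally oriented or bent animals are less elongated than the
#' body itself, so the lower bound is relaxed.
#'
#' @param alpha_mode `"adaptive"` (CIoU convention) or `"fixed"`.
#' @param alpha_fixed Constant weight used when `alpha_mode = "fixed"`.
#' @param prior_low,prior_high Elongation-prior interval bounds
#'   (dimensionless, `prior_low >= 1`, `prior_high > prior_low`).
#' @param prior_beta Exponential escalation rate (per unit of elongation
#'   outside the prior); 0 disables the prior entirely.
#' @return A list of class `"biou_params"`.
#' @export
biou_params <- function(alpha_mode = c("adaptive", "fixed"), alpha_fixed = 1,
                        prior_low = 1.5, prior_high = 8, prior_beta = 2) {
  alpha_mode <- match.arg(alpha_mode)
  if (!is.finite(prior_low) || prior_low < 1) stop("prior_low must be >= 1", call. = FALSE)
  if (!is.finite(prior_high) || prior_high <= prior_low) {
    stop("prior_high must exceed prior_low", call. = FALSE)
  }
  if (!is.finite(prior_beta) || prior_beta < 0) stop("prior_beta must be >= 0", call. = FALSE)
  if (!is.finite(alpha_fixed) || alpha_fixed < 0) stop("alpha_fixed must be >= 0", call. = FALSE)
  structure(
    list(
      alpha_mode = alpha_mode, alpha_fixed = alpha_fixed,
      prior_low = prior_low, prior_high = prior_high, prior_beta = prior_beta
    ),
    class = "biou_params"
  )
}

# elongation of boxes in a center-format matrix: long side / short side
box_elongation <- function(m) {
  pmax(m[, 3], m[, 4]) / pmin(m[, 3], m[, 4])
}

#' @rdname box_kernels
#' @export
biou <- function(pred, det, params = biou_params()) {
  if (!inherits(params, "biou_params")) stop("params must come from biou_params()", call. = FALSE)
  p <- recycle_boxes(pred, det)
  i <- iou(p$a, p$b)
  v <- aspect_consistency(p$a, p$b)
  alpha <- switch(params$alpha_mode,
    adaptive = ifelse(v > 0, v / ((1 - i) + v), 0),
    fixed = rep_len(params$alpha_fixed, length(i))
  )
  e <- box_elongation(p$a)
  out_dist <- pmax(0, params$prior_low - e) + pmax(0, e - params$prior_high)
  alpha <- alpha * exp(params$prior_beta * out_dist)
  i - center_penalty(p$a, p$b) - alpha * v
}

#' Gated association cost matrix
#'
#' Builds the cost matrix `1 - metric(pred_i, det_j)` for all prediction x
#' detection pairs, together with a feasibility mask marking pairs whose
#' similarity clears the gate. This is the input contract of
#' [hungarian_assign()].
#'
#' @param preds,dets Boxes (vectors, 4-column matrices or data frames with
#'   `cx, cy, w, h`); rows of `preds` index the matrix rows.
#' @param metric One of `"iou"`, `"giou"`, `"diou"`, `"ciou"`, `"biou"`.
#' @param gate Minimum similarity for a pair to be feasible.
#' @param params [biou_params()] used when `metric = "biou"`.
#' @return A list with `cost` (numeric matrix), `feasible` (logical matrix)
#'   and `gate`. Empty inputs yield 0-row/0-column matrices.
#' @export
box_cost_matrix <- function(preds, dets, metric = c("biou", "iou", "giou", "diou", "ciou"),
                            gate = 0.3, params = biou_params()) {
  metric <- match.arg(metric)
  preds <- as_box_matrix(if (is.null(preds)) matrix(numeric(), 0, 4) else preds, "preds")
  dets <- as_box_matrix(if (is.null(dets)) matrix(numeric(), 0, 4) else dets, "dets")
  np <- nrow(preds); nd <- nrow(dets)
  if (np == 0L || nd == 0L) {
    return(list(
      cost = matrix(numeric(), np, nd),
      feasible = matrix(logical(), np, nd), gate = gate
    ))
  }
  ai <- rep(seq_len(np), times = nd)
  bi <- rep(seq_len(nd), each = np)
  s <- switch(metric,
    iou = iou(preds[ai, , drop = FALSE], dets[bi, , drop = FALSE]),
    giou = giou(preds[ai, , drop = FALSE], dets[bi, , drop = FALSE]),
    diou = diou(preds[ai, , drop = FALSE], dets[bi, , drop = FALSE]),
    ciou = ciou(preds[ai, , drop = FALSE], dets[bi, , drop = FALSE]),
    biou = biou(preds[ai, , drop = FALSE], dets[bi, , drop = FALSE], params)
  )
  s <- matrix(s, np, nd)
  list(cost = 1 - s, feasible = s >= gate, gate = gate)
}
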