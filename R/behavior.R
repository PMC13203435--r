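#' Per-frame trajectory kinematics
#'
#' Computes, for each track, the inter-frame center displacement `delta_d`
#' (normalized units), the instantaneous speed `v` in m/s (pixel
#' displacement converted by the `k` calibration and the frame rate, then
#' smoothed by a centered moving median) and the heading (atan2 of the
#' displacement, image convention: y down).
#'
#' @param tracks Trajectory tibble (`frame, id, cx, cy, ...`), e.g. tracker
#'   output or ground truth.
#' @param k Meters per pixel.
#' @param fps Frames per second.
#' @param image_size Pixel dimensions `c(width, height)`.
#' @param smooth_w Width (frames, odd) of the median smoother on `v`.
#' @return A tibble `id, frame, delta_d, v, heading`; the first frame of a
#'   track has no displacement and is omitted. Single-frame tracks yield no
#'   rows.
#' @export
kinematics <- function(tracks, k = 0.01, fps = 30, image_size = c(1000, 1000), smooth_w = 5L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  tracks <- dplyr::arrange(tracks, .data$id, .data$frame)
  out <- lapply(split(tracks, tracks$id), function(tt) {
    if (nrow(tt) < 2L) return(NULL)
    dxn <- diff(tt$cx); dyn <- diff(tt$cy)
    dfr <- diff(tt$frame) # spread displacement over gaps
    dpx <- sqrt((dxn * image_size[1])^2 + (dyn * image_size[2])^2)
    v <- k * fps * dpx / dfr
    if (smooth_w > 1L && length(v) >= 2L) {
      v <- stats::runmed(v, k = min(smooth_w - (smooth_w %% 2 == 0), max(1, 2 * (length(v) %/% 2) - 1)),
        endrule = "keep"
      )
    }
    tibble::tibble(
      id = tt$id[-1], frame = tt$frame[-1],
      delta_d = sqrt(dxn^2 + dyn^2) / dfr,
      v = as.numeric(v),
      heading = atan2(dyn, dxn)
    )
  })
  dplyr::bind_rows(out)
}

#' Behavior-rule thresholds
#'
#' The rule set converting kinematics to discrete behaviors:
#' * stationary — displacement `delta_d < 0.005` and speed `v < 0.02` m/s,
#'   sustained for at least `still_min_s` seconds;
#' * swim_breathing — `delta_d > 0.01` and `v > 0.08` m/s;
#' * foraging — `0.02 <= v <= 0.08` m/s with cumulative heading change above
#'   60 degrees within a sliding 10 s window.
#' Precedence on conflict: stationary, then swim_breathing, then foraging.
#'
#' @param still_dd,still_v Stationary thresholds (normalized displacement,
#'   m/s).
#' @param still_min_s Minimum sustained stillness, seconds.
#' @param swim_dd,swim_v Swim-breathing thresholds.
#' @param forage_v_lo,forage_v_hi Foraging speed band, m/s.
#' @param forage_turn_deg Heading-change threshold, degrees.
#' @param forage_window_s Sliding window, seconds.
#' @param turn_mode `"cumulative"` (sum of absolute heading changes in the
#'   window) or `"instantaneous"` (largest single change).
#' @param min_run_s Runs shorter than this are merged into the preceding
#'   label (debouncing); 0 disables.
#' @return A list of class `"behavior_rules"`.
#' @export
behavior_rules <- function(still_dd = 0.005, still_v = 0.02, still_min_s = 3,
                           swim_dd = 0.01, swim_v = 0.08,
                           forage_v_lo = 0.02, forage_v_hi = 0.08,
                           forage_turn_deg = 60, forage_window_s = 10,
                           turn_mode = c("cumulative", "instantaneous"),
                           min_run_s = 1) {
  turn_mode <- match.arg(turn_mode)
  structure(as.list(environment()), class = "behavior_rules")
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Classify per-frame behavior from kinematics
#'
#' Applies the behavior rules frame by frame with the stated precedence.
#' The stationary rule only fires over runs of qualifying frames at least
#' `still_min_s` long; the foraging turn criterion holds for a frame if any
#' sliding window containing it accumulates enough heading change. Runs
#' shorter than `min_run_s` are merged into their predecessor to suppress
#' frame-level flicker.
#'
#' @param kin Kinematics tibble from [kinematics()].
#' @param rules A [behavior_rules()].
#' @param fps Frames per second.
#' @return The kinematics tibble with an added `label` factor column
#'   (`stationary`, `swim_breathing`, `foraging`, `unclassified`).
#' @export
classify_behavior <- function(kin, rules = behavior_rules(), fps = 30) {
  labs <- c("stationary", "swim_breathing", "foraging", "unclassified")
  out <- lapply(split(kin, kin$id), function(tt) {
    n <- nrow(tt)
    if (n == 0L) return(NULL)
    still_ok <- tt$delta_d < rules$still_dd & tt$v < rules$still_v
    # sustain requirement: qualifying runs must span >= still_min_s
    min_run <- max(1L, as.integer(round(rules$still_min_s * fps)))
    r <- rle(still_ok)
    r$values <- r$values & r$lengths >= min_run
    still <- inverse.rle(r)
    swim <- tt$delta_d > rules$swim_dd & tt$v > rules$swim_v
    in_band <- tt$v >= rules$forage_v_lo & tt$v <= rules$forage_v_hi
    w <- max(2L, as.integer(round(rules$forage_window_s * fps)))
    dh <- abs(wrap_angle(c(0, diff(tt$heading))))
    turn_deg <- if (identical(rules$turn_mode, "cumulative")) {
      cs <- cumsum(dh)
      # total change within any window of width w containing the frame:
      # max over window start positions; windowed sums via cumsum
      ws <- vapply(seq_len(n), function(i) {
        lo <- max(1L, i - w + 1L)
        starts <- lo:i
        ends <- pmin(starts + w - 1L, n)
        max(cs[ends] - cs[starts] + dh[starts])
      }, numeric(1))
      ws * 180 / pi
    } else {
      vapply(seq_len(n), function(i) {
        lo <- max(1L, i - w + 1L); hi <- min(n, i + w - 1L)
        max(dh[lo:hi]) * 180 / pi
      }, numeric(1))
    }
    forage <- in_band & turn_deg > rules$forage_turn_deg
    lab <- rep("unclassified", n)
    lab[forage] <- "foraging"
    lab[swim & lab != "stationary"] <- "swim_breathing"
    lab[still] <- "stationary"
    # debounce: merge sub-second runs into the preceding label
    if (rules$min_run_s > 0) {
      min_keep <- as.integer(round(rules$min_run_s * fps))
      r <- rle(lab)
      if (length(r$lengths) > 1L) {
        for (i in seq_along(r$lengths)) {
          if (r$lengths[i] < min_keep) {
            r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[min(i + 1L, length(r$values))]
          }
        }
        lab <- inverse.rle(r)
      }
    }
    tt$label <- factor(lab, levels = labs)
    tt
  })
  dplyr::bind_rows(out)
}

#' Collapse per-frame labels into behavior intervals
#'
#' @param labeled Output of [classify_behavior()].
#' @return A tibble `id, label, start, end, n_frames` with non-overlapping,
#'   ordered windows per track.
#' @export
behavior_intervals <- function(labeled) {
  out <- lapply(split(labeled, labeled$id), function(tt) {
    r <- rle(as.character(tt$label))
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    tibble::tibble(
      id = tt$id[1], label = r$values,
      start = tt$frame[starts], end = tt$frame[ends],
      n_frames = r$lengths
    )
  })
  dplyr::bind_rows(out)
}

#' Day/night behavioral rhythm summary
#'
#' Maps frames to wall-clock time, splits them into the diurnal period
#' (06:00-18:00) and the nocturnal period (18:00-06:00), and reports the
#' time-weighted proportion of each behavior within each period
#' (unclassified time excluded from the denominator) together with absolute
#' durations.
#'
#' @param labeled Output of [classify_behavior()].
#' @param start_time Wall-clock time of frame 0, seconds since midnight (or
#'   a `"HH:MM:SS"` string).
#' @param fps Frames per second.
#' @return A tibble `period, label, seconds, proportion`.
#' @export
rhythm_summary <- function(labeled, start_time = "06:00:00", fps = 30) {
  if (is.character(start_time)) {
    p <- as.numeric(strsplit(start_time, ":", fixed = TRUE)[[1]])
    start_time <- sum(p * c(3600, 60, 1)[seq_along(p)])
  }
  tod <- (start_time + labeled$frame / fps) %% 86400
  period <- ifelse(tod >= 6 * 3600 & tod < 18 * 3600, "day", "night")
  df <- tibble::tibble(period = period, label = as.character(labeled$label))
  agg <- dplyr::count(df, .data$period, .data$label, name = "frames")
  agg$seconds <- agg$frames / fps
  agg <- dplyr::group_by(agg, .data$period)
  agg <- dplyr::mutate(agg,
    proportion = ifelse(.data$label == "unclassified", NA_real_,
      .data$seconds / sum(.data$seconds[.data$label != "unclassified"])
    )
  )
  dplyr::ungroup(agg)[, c("period", "label", "seconds", "proportion")]
}
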