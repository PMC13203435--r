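# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package
# internals: assignments are found by exhaustive permutation search and
# CLEAR metrics by a from-scratch re-implementation with per-frame
# exhaustive matching.

# all permutations of a vector (n <= 7)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (p in all_perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
  }
  out
}

# exhaustive assignment oracle: maximizes the number of feasible pairs,
# then minimizes total cost over feasible pairs
brute_assignment <- function(cost, feasible = NULL) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (is.null(feasible)) feasible <- matrix(TRUE, nr, nc)
  best_cost <- Inf; best_n <- -1L
  sels <- if (nr <= nc) {
    lapply(all_perms(seq_len(nc)), function(p) cbind(seq_len(nr), p[seq_len(nr)]))
  } else {
    lapply(all_perms(seq_len(nr)), function(p) cbind(p[seq_len(nc)], seq_len(nc)))
  }
  for (sel in sels) {
    ok <- feasible[sel]
    n <- sum(ok)
    tot <- sum(cost[sel[ok, , drop = FALSE]])
    if (n > best_n || (n == best_n && tot < best_cost)) {
      best_n <- n; best_cost <- tot
    }
  }
  list(cost = best_cost, n_feasible = best_n)
}

# plain IoU on normalized center boxes, written independently
oracle_iou <- function(a, b) {
  ax1 <- a[1] - a[3] / 2; ay1 <- a[2] - a[4] / 2
  ax2 <- a[1] + a[3] / 2; ay2 <- a[2] + a[4] / 2
  bx1 <- b[1] - b[3] / 2; by1 <- b[2] - b[4] / 2
  bx2 <- b[1] + b[3] / 2; by2 <- b[2] + b[4] / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# From-scratch CLEAR accumulator: per frame, carry over surviving pairs,
# then match the rest by exhaustive search maximizing total IoU above the
# gate. Counts FP, FN, id switches (vs last known match) and
# fragmentations (resumed coverage gaps).
oracle_clear <- function(gt, hyp, gate = 0.5) {
  frames <- sort(unique(c(gt$frame, hyp$frame)))
  fp <- 0L; fn <- 0L; ids <- 0L; frag <- 0L
  last_match <- list()
  prev_pairs <- list() # gt id -> hyp id matched in previous frame
  covered <- list() # gt id -> was ever matched
  broken <- list() # gt id -> currently in a coverage gap
  for (fr in frames) {
    g <- gt[gt$frame == fr, , drop = FALSE]
    h <- hyp[hyp$frame == fr, , drop = FALSE]
    pairs <- list()
    used_g <- integer(0); used_h <- integer(0)
    for (gi in seq_len(nrow(g))) {
      pid <- prev_pairs[[as.character(g$id[gi])]]
      if (!is.null(pid)) {
        hi <- match(pid, h$id)
        if (!is.na(hi) && !(hi %in% used_h)) {
          s <- oracle_iou(as.numeric(g[gi, c("cx", "cy", "w", "h")]),
                          as.numeric(h[hi, c("cx", "cy", "w", "h")]))
          if (s >= gate) {
            pairs[[length(pairs) + 1L]] <- c(gi, hi)
            used_g <- c(used_g, gi); used_h <- c(used_h, hi)
          }
        }
      }
    }
    rg <- setdiff(seq_len(nrow(g)), used_g)
    rh <- setdiff(seq_len(nrow(h)), used_h)
    if (length(rg) && length(rh)) {
      # exhaustive best matching on IoU sum (feasible above gate only)
      S <- matrix(0, length(rg), length(rh))
      for (i in seq_along(rg)) {
        for (j in seq_along(rh)) {
          s <- oracle_iou(as.numeric(g[rg[i], c("cx", "cy", "w", "h")]),
                          as.numeric(h[rh[j], c("cx", "cy", "w", "h")]))
          S[i, j] <- if (s >= gate) s else NA
        }
      }
      best <- NULL; best_sum <- -Inf
      nr <- nrow(S); nc <- ncol(S)
      idx_perms <- if (nr <= nc) all_perms(seq_len(nc)) else all_perms(seq_len(nr))
      for (p in idx_perms) {
        sel <- if (nr <= nc) cbind(seq_len(nr), p[seq_len(nr)]) else cbind(p[seq_len(nc)], seq_len(nc))
        vals <- S[sel]
        tot <- sum(vals, na.rm = TRUE)
        if (tot > best_sum) {
          best_sum <- tot
          best <- sel[!is.na(vals), , drop = FALSE]
        }
      }
      if (!is.null(best) && nrow(best)) {
        for (r in seq_len(nrow(best))) {
          pairs[[length(pairs) + 1L]] <- c(rg[best[r, 1]], rh[best[r, 2]])
        }
      }
    }
    n_m <- length(pairs)
    fp <- fp + nrow(h) - n_m
    fn <- fn + nrow(g) - n_m
    new_prev <- list()
    matched_gids <- character(0)
    for (pr in pairs) {
      gid <- as.character(g$id[pr[1]]); hid <- h$id[pr[2]]
      matched_gids <- c(matched_gids, gid)
      old <- last_match[[gid]]
      if (!is.null(old) && old != hid) ids <- ids + 1L
      last_match[[gid]] <- hid
      new_prev[[gid]] <- hid
      if (isTRUE(broken[[gid]])) {
        frag <- frag + 1L
        broken[[gid]] <- FALSE
      }
      covered[[gid]] <- TRUE
    }
    for (gid in as.character(g$id)) {
      if (!(gid %in% matched_gids) && isTRUE(covered[[gid]])) broken[[gid]] <- TRUE
    }
    prev_pairs <- new_prev
  }
  list(FP = fp, FN = fn, IDs = ids, Frag = frag,
       MOTA = 100 * (1 - (fp + fn + ids) / nrow(gt)))
}
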