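#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the
#' Jonker-Volgenant shortest-augmenting-path method with dual potentials
#' (O(n^3)). Pairs marked infeasible are never assigned; among feasible
#' pairs the assignment minimizes total cost while matching as many pairs
#' as possible. Ties between equal-cost optima are broken deterministically
#' in favour of lexicographically smaller (row, column) pairs via an
#' infinitesimal cost tilt.
#'
#' @param cost Numeric cost matrix (rows = tracks/predictions, columns =
#'   detections). May be rectangular or empty.
#' @param feasible Optional logical matrix of the same shape; `FALSE` entries
#'   are excluded from the assignment. Non-finite costs are treated as
#'   infeasible as well.
#' @return A tibble with columns `row`, `col` and `cost`, one line per
#'   assigned feasible pair, ordered by `row`.
#' @examples
#' hungarian_assign(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
hungarian_assign <- function(cost, feasible = NULL) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (is.null(feasible)) feasible <- matrix(TRUE, nr, nc)
  feasible <- feasible & is.finite(cost)
  if (nr == 0L || nc == 0L || !any(feasible)) {
    return(tibble::new_tibble(
      list(row = integer(), col = integer(), cost = numeric()), nrow = 0L
    ))
  }

  # deterministic lexicographic tie-break: tilt each cell by a rank-ordered
  # infinitesimal, small enough never to override a real cost difference
  scale <- max(abs(cost[feasible]), 1)
  rank_tilt <- matrix(seq_len(nr * nc) * (1e-12 * scale / (nr * nc)), nr, nc, byrow = TRUE)
  big <- (scale + 1) * (max(nr, nc) + 1) * 4
  work <- ifelse(feasible, cost, big) + rank_tilt

  transposed <- nr > nc
  if (transposed) work <- t(work)
  sol <- lsap_solve(work)
  if (transposed) {
    row_idx <- sol$col4row
    col_idx <- seq_along(sol$col4row)
  } else {
    row_idx <- seq_along(sol$col4row)
    col_idx <- sol$col4row
  }
  keep <- feasible[cbind(row_idx, col_idx)]
  rows <- as.integer(row_idx[keep])
  cols <- as.integer(col_idx[keep])
  ord <- order(rows)
  tibble::new_tibble(
    list(
      row = rows[ord], col = cols[ord],
      cost = cost[cbind(rows[ord], cols[ord])]
    ),
    nrow = length(rows)
  )
}

# shortest augmenting path LSAP core; expects finite costs, nrow <= ncol.
# Returns col4row: assigned column per row.
lsap_solve <- function(C) {
  nr <- nrow(C); nc <- ncol(C)
  stopifnot(nr <= nc)
  u <- numeric(nr); v <- numeric(nc)
  col4row <- rep(NA_integer_, nr)
  row4col <- rep(NA_integer_, nc)
  for (cur_row in seq_len(nr)) {
    shortest <- rep(Inf, nc)
    prev_row <- rep(NA_integer_, nc) # row from which each column was reached
    sr <- rep(FALSE, nr); sc <- rep(FALSE, nc)
    min_val <- 0
    i <- cur_row
    sink <- NA_integer_
    while (is.na(sink)) {
      sr[i] <- TRUE
      jf <- which(!sc)
      red <- min_val + C[i, jf] - u[i] - v[jf]
      upd <- red < shortest[jf]
      if (any(upd)) {
        shortest[jf[upd]] <- red[upd]
        prev_row[jf[upd]] <- i
      }
      jmin <- jf[which.min(shortest[jf])]
      min_val <- shortest[jmin]
      sc[jmin] <- TRUE
      if (is.na(row4col[jmin])) sink <- jmin else i <- row4col[jmin]
    }
    # dual updates
    u[cur_row] <- u[cur_row] + min_val
    other <- which(sr); other <- other[other != cur_row]
    if (length(other)) u[other] <- u[other] + min_val - shortest[col4row[other]]
    scanned <- which(sc)
    v[scanned] <- v[scanned] - (min_val - shortest[scanned])
    # augment along the alternating path back from the sink
    j <- sink
    repeat {
      i <- prev_row[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur_row) break
      j <- tmp
    }
  }
  list(col4row = col4row, row4col = row4col, u = u, v = v)
}
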