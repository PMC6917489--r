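# Optimal linear assignment (Jonker-Volgenant shortest augmenting path),
# used by the frame-to-frame linker. Pure R, O(n^3), vectorized over the
# unvisited columns; sizes here are at most a few hundred detections.

#' Solve the linear assignment problem
#'
#' Minimizes `sum(cost[i, assign[i]])` over one-to-one assignments of rows to
#' columns. Requires `nrow(cost) <= ncol(cost)`; every row is assigned.
#'
#' @param cost numeric matrix of finite costs.
#' @return integer vector: for each row the assigned column.
#' @keywords internal
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr <= nc, all(is.finite(cost)))
  if (nr == 0L) return(integer())
  u <- numeric(nr); v <- numeric(nc)
  col4row <- rep(NA_integer_, nr)
  row4col <- rep(NA_integer_, nc)
  for (cur in seq_len(nr)) {
    min_val <- 0
    i <- cur
    remaining <- seq_len(nc)
    sr <- logical(nr); sc <- logical(nc)
    spc <- rep(Inf, nc)       # shortest path cost to each column
    path <- rep(NA_integer_, nc)
    sink <- NA_integer_
    while (is.na(sink)) {
      sr[i] <- TRUE
      red <- min_val + cost[i, remaining] - u[i] - v[remaining]
      upd <- red < spc[remaining]
      if (any(upd)) {
        cols <- remaining[upd]
        path[cols] <- i
        spc[cols] <- red[upd]
      }
      jrel <- which.min(spc[remaining])
      lowest <- spc[remaining][jrel]
      if (!is.finite(lowest)) stop("assignment infeasible")
      j <- remaining[jrel]
      min_val <- lowest
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
      sc[j] <- TRUE
      remaining <- remaining[-jrel]
    }
    u[cur] <- u[cur] + min_val
    others <- which(sr); others <- others[others != cur]
    if (length(others)) {
      u[others] <- u[others] + min_val - spc[col4row[others]]
    }
    scc <- which(sc)
    v[scc] <- v[scc] - (min_val - spc[scc])
    # augment along the path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- tmp
    }
  }
  col4row
}

#' Gated one-to-one matching between two point sets
#'
#' Matches rows of `a` to rows of `b` (coordinates as `row`/`col` columns or
#' two-column matrices) one-to-one, allowing only pairs at Euclidean distance
#' `<= gate`. Among all such matchings the result has maximum cardinality
#' and, among those, minimum total distance.
#'
#' @param a,b numeric matrices with two columns (row, col).
#' @param gate maximum allowed pair distance (same units as coordinates).
#' @return integer vector of length `nrow(a)`: matched row of `b`, or `NA`.
#' @keywords internal
match_points_gated <- function(a, b, gate) {
  na_ <- nrow(a); nb <- nrow(b)
  if (na_ == 0L) return(integer())
  if (nb == 0L) return(rep(NA_integer_, na_))
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  big <- (min(na_, nb) + 1) * max(gate, max(d[d <= gate], 0)) + 1
  cost <- d
  cost[d > gate] <- big
  flip <- na_ > nb
  m <- if (flip) {
    asg <- solve_assignment(t(cost))
    out <- rep(NA_integer_, na_)
    out[asg] <- seq_len(nb)
    out
  } else {
    solve_assignment(cost)
  }
  keep <- !is.na(m) & d[cbind(seq_len(na_), ifelse(is.na(m), 1L, m))] <= gate
  m[!keep] <- NA_integer_
  m
}
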