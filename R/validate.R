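#' Match automated detections against reference annotations
#'
#' Greedy one-to-one matching of two detection series (e.g. manual
#' annotations vs automated foci) in ascending distance order: a pair is a
#' candidate iff its spatial distance is at most `tol_px` (Euclidean,
#' inclusive) and its frame difference at most `tol_frames` (inclusive).
#' Ties in distance are broken lexicographically by the reference then test
#' (frame, row, col), so the matching is deterministic. The true positive
#' rate is the percentage of reference detections matched; the false
#' positive rate is the percentage of test detections left unmatched.
#'
#' @param reference data frame of reference detections with `frame`, `row`,
#'   `col` columns (typically manual annotations).
#' @param test data frame of test detections, same columns (typically
#'   automated output).
#' @param tol_px spatial tolerance, pixels (default 5).
#' @param tol_frames temporal tolerance, frames (default 1).
#' @return one-row tibble of class `match_report`:
#'   `true_positive_rate_pct`, `false_positive_rate_pct`, `n_reference`,
#'   `n_test`, `n_matched`, `tol_px`, `tol_frames`. Rates are `NaN` when the
#'   respective set is empty.
#' @export
match_detections <- function(reference, test, tol_px = 5, tol_frames = 1L) {
  stopifnot(tol_px >= 0, tol_frames >= 0)
  ref <- as_tibble(reference)
  tst <- as_tibble(test)
  need <- c("frame", "row", "col")
  stopifnot(all(need %in% names(ref)), all(need %in% names(tst)))
  n_ref <- nrow(ref); n_tst <- nrow(tst)
  # deterministic ordering for tie-breaks
  ro <- order(ref$frame, ref$row, ref$col)
  to <- order(tst$frame, tst$row, tst$col)
  ref <- ref[ro, ]; tst <- tst[to, ]
  n_matched <- 0L
  if (n_ref && n_tst) {
    df <- abs(outer(ref$frame, tst$frame, "-"))
    d <- sqrt(outer(ref$row, tst$row, "-")^2 +
              outer(ref$col, tst$col, "-")^2)
    ok <- which(df <= tol_frames & d <= tol_px)
    if (length(ok)) {
      i <- (ok - 1L) %% n_ref + 1L
      j <- (ok - 1L) %/% n_ref + 1L
      ord <- order(d[ok], i, j)
      used_i <- logical(n_ref); used_j <- logical(n_tst)
      for (k in ord) {
        if (!used_i[i[k]] && !used_j[j[k]]) {
          used_i[i[k]] <- TRUE
          used_j[j[k]] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  out <- tibble(
    true_positive_rate_pct = if (n_ref) 100 * n_matched / n_ref else NaN,
    false_positive_rate_pct = if (n_tst) 100 * (n_tst - n_matched) / n_tst
      else NaN,
    n_reference = n_ref, n_test = n_tst, n_matched = n_matched,
    tol_px = tol_px, tol_frames = as.integer(tol_frames))
  class(out) <- c("match_report", class(out))
  out
}
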