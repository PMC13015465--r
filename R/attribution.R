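#' Integrated gradients for a black-box scorer
#'
#' Path-integral attribution along the straight line from `x_ref` to `x`:
#' `IG_i = (x_i - x_ref_i) * mean_k dF/dx_i` evaluated at the midpoint grid
#' `x_ref + (k - 0.5)/steps * (x - x_ref)`. Gradients are central finite
#' differences with a relative step, so any deterministic scorer works
#' without autodiff. For a linear scorer the result is exact; for smooth
#' scorers the completeness identity `sum(IG) = F(x) - F(x_ref)` holds up to
#' the quadrature error.
#'
#' @param scorer function mapping a numeric vector to one finite number.
#' @param x input vector.
#' @param x_ref reference vector, same length.
#' @param steps number of quadrature points (>= 1).
#' @param h relative finite-difference step (default 1e-4).
#' @return numeric vector of per-coordinate attributions.
#' @export
integrated_gradients <- function(scorer, x, x_ref, steps = 50L, h = 1e-4) {
  if (length(x) != length(x_ref)) stop("x and x_ref must have the same length")
  if (steps < 1L) stop("steps must be >= 1")
  n <- length(x)
  grad_sum <- numeric(n)
  for (k in seq_len(steps)) {
    xk <- x_ref + (k - 0.5) / steps * (x - x_ref)
    for (i in seq_len(n)) {
      hi <- h * max(1, abs(xk[i]))
      up <- xk; up[i] <- up[i] + hi
      dn <- xk; dn[i] <- dn[i] - hi
      fu <- scorer(up); fd <- scorer(dn)
      if (!is.finite(fu) || !is.finite(fd)) stop("scorer returned a non-finite value")
      grad_sum[i] <- grad_sum[i] + (fu - fd) / (2 * hi)
    }
  }
  (x - x_ref) * grad_sum / steps
}

#' Segment an attribution track into regions of interest
#'
#' Finds maximal runs of strictly positive scores, merges adjacent runs
#' separated by at most `max_gap` non-positive positions (merging happens
#' before length filtering), keeps merged segments longer than `min_len`
#' positions and reports them in ascending offset order. Zeros count as gap
#' material.
#'
#' @param track numeric vector of attribution scores.
#' @param min_len segments must be strictly longer than this (default 5).
#' @param max_gap largest bridgeable non-positive gap (default 3).
#' @param offsets site-relative offset of each track position; defaults to
#'   -100..100 for a 201-long track, otherwise 0-based indices.
#' @return data.frame `start_offset`, `end_offset` (inclusive), `length`,
#'   `mean_score` (mean over the positive positions of the segment).
#' @export
roi_segments <- function(track, min_len = 5L, max_gap = 3L, offsets = NULL) {
  if (any(!is.finite(track))) stop("track must be finite")
  if (is.null(offsets)) {
    offsets <- if (length(track) == 201L) -100:100 else seq_along(track) - 1L
  }
  pos <- track > 0
  if (!any(pos)) {
    return(data.frame(start_offset = integer(0), end_offset = integer(0),
                      length = integer(0), mean_score = numeric(0)))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge consecutive positive runs across small non-positive gaps
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1L]) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (gap <= max_gap) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  merged <- merged[(merged$end - merged$start + 1L) > min_len, , drop = FALSE]
  if (!nrow(merged)) {
    return(data.frame(start_offset = integer(0), end_offset = integer(0),
                      length = integer(0), mean_score = numeric(0)))
  }
  data.frame(
    start_offset = offsets[merged$start],
    end_offset = offsets[merged$end],
    length = merged$end - merged$start + 1L,
    mean_score = vapply(seq_len(nrow(merged)), function(i) {
      seg <- track[merged$start[i]:merged$end[i]]
      mean(seg[seg > 0])
    }, numeric(1L))
  )
}
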