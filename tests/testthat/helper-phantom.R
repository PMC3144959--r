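# Shared fixtures: phantoms are generated in code at reduced frame sizes so
# the suite stays fast; geometry scales with the frame.

small_params <- function(...) {
  phantom_params(frame_height = 194L, frame_width = 138L, ...)
}

tiny_params <- function(...) {
  phantom_params(frame_height = 97L, frame_width = 69L, ...)
}

jaccard <- function(a, b) {
  if (inherits(a, "stain_mask")) a <- a$mask
  if (inherits(b, "stain_mask")) b <- b$mask
  sum(a & b) / sum(a | b)
}

# Independent per-pixel side assignment: explicit loop, linear interpolation
# of the polyline x at each pixel's row (clamped beyond the endpoints),
# strict x < line means the low-x side; ties go to the other side.
oracle_split <- function(mask, line_points) {
  pts <- line_points[order(line_points[, 2]), , drop = FALSE]
  line_x <- function(y) {
    if (y <= pts[1, 2]) return(pts[1, 1])
    if (y >= pts[nrow(pts), 2]) return(pts[nrow(pts), 1])
    for (i in seq_len(nrow(pts) - 1)) {
      if (y >= pts[i, 2] && y <= pts[i + 1, 2]) {
        f <- (y - pts[i, 2]) / (pts[i + 1, 2] - pts[i, 2])
        return(pts[i, 1] + f * (pts[i + 1, 1] - pts[i, 1]))
      }
    }
    stop("unreachable")
  }
  low <- 0L; high <- 0L
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      if (mask[r, cc]) {
        if (cc < line_x(r)) low <- low + 1L else high <- high + 1L
      }
    }
  }
  c(low = low, high = high)
}

# Exhaustive minimum within-cluster sum of squares over all 2-partitions of
# the rows of X (both parts nonempty).
oracle_best_2partition <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    inA <- bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) > 0
    sse <- 0
    for (part in list(X[inA, , drop = FALSE], X[!inA, , drop = FALSE])) {
      ctr <- colMeans(part)
      sse <- sse + sum(sweep(part, 2, ctr, "-")^2)
    }
    if (sse < best) best <- sse
  }
  best
}

expected_pair_transform <- function(truth, k) {
  compose_rigid(truth$transforms[[k - 1]], invert_rigid(truth$transforms[[k]]))
}
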