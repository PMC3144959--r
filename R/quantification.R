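#' Standardize a section image to the analysis frame
#'
#' The 2D quantification operates on images adjusted to a fixed total pixel
#' count: 690 x 970 = 669300 pixels. Resampling is nearest-neighbor by
#' default (pixel centers mapped proportionally); aspect distortion is
#' permitted because it is the total pixel count that is normalized, not the
#' aspect ratio. An image already at the target size is returned unchanged.
#'
#' @param image a [color_slice()], `H x W x 3` array, or `H x W` matrix.
#' @param width,height target frame (defaults 690, 970).
#' @return the standardized image, same class as the input.
#' @export
standardize_frame <- function(image, width = 690L, height = 970L) {
  if (inherits(image, "color_slice")) {
    out <- image
    out$pixels <- standardize_frame(image$pixels, width, height)
    return(out)
  }
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (h == height && w == width) return(image)
  if (h < 1 || w < 1) stop("empty image", call. = FALSE)
  # nearest-neighbor: map output pixel centers into the source grid
  sr <- pmin(pmax(floor((seq_len(height) - 0.5) * h / height) + 1L, 1L), h)
  sc <- pmin(pmax(floor((seq_len(width) - 0.5) * w / width) + 1L, 1L), w)
  if (length(d) == 2) {
    image[sr, sc, drop = FALSE]
  } else {
    out <- array(image[1], dim = c(height, width, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- image[sr, sc, ch]
    out
  }
}

#' Apex-to-base separation line
#'
#' The polyline that partitions a standardized section into anatomical left
#' and right: it originates at the apex and runs toward the base of the
#' heart (and through the aorta). Points are (x, y) pixel coordinates in the
#' standardized frame; the y coordinates must be strictly monotone
#' (apex-to-base), and consecutive points distinct.
#'
#' @param points numeric matrix (>= 2 rows) of (x, y) coordinates.
#' @param side_convention `"image_left"` if the low-x side of the line is
#'   the anatomical left (the default, and the phantom's convention), or
#'   `"image_right"` if the image is mirrored.
#' @return an object of class `partition_line` with points ordered by
#'   increasing y.
#' @export
partition_line <- function(points, side_convention = c("image_left", "image_right")) {
  side_convention <- match.arg(side_convention)
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (ncol(points) != 2 || nrow(points) < 2) {
    stop("partition line needs >= 2 (x, y) points", call. = FALSE)
  }
  dy <- diff(points[, 2])
  if (any(rowSums(abs(diff(points))) == 0)) {
    stop("consecutive partition-line points must be distinct", call. = FALSE)
  }
  if (!(all(dy > 0) || all(dy < 0))) {
    stop("partition line must be y-monotone (apex to base)", call. = FALSE)
  }
  if (dy[1] < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  structure(list(points = points, side_convention = side_convention),
            class = "partition_line")
}

# x position of the polyline at each y (linear interpolation, clamped to the
# end segments' x beyond the polyline's vertical extent)
line_x_at <- function(line, y) {
  pts <- line$points
  stats::approx(pts[, 2], pts[, 1], xout = y, rule = 2, ties = "ordered")$y
}

#' Split stain-positive pixels by the separation line
#'
#' Each positive pixel (center at its integer (column, row) coordinate) is
#' assigned to exactly one side by comparing its x coordinate with the
#' polyline's x at the pixel's row. The rule is half-open: pixels exactly on
#' the line count as anatomical right. Counts are returned under the line's
#' side convention.
#'
#' @param mask a `stain_mask` or `H x W` logical matrix in the standardized
#'   frame.
#' @param line a [partition_line()].
#' @return named numeric vector `c(left =, right =)`; `left + right` equals
#'   the mask's positive count.
#' @export
split_by_partition <- function(mask, line) {
  if (inherits(mask, "stain_mask")) mask <- mask$mask
  stopifnot(inherits(line, "partition_line"))
  pos <- which(mask)
  if (length(pos) == 0) return(c(left = 0, right = 0))
  h <- nrow(mask)
  y <- ((pos - 1L) %% h) + 1L
  x <- ((pos - 1L) %/% h) + 1L
  lx <- line_x_at(line, y)
  low <- sum(x < lx)          # strictly on the low-x side
  high <- length(pos) - low   # on-line pixels fall here
  if (line$side_convention == "image_left") {
    c(left = low, right = high)
  } else {
    c(left = sum(x > lx), right = length(pos) - sum(x > lx))
  }
}

#' Quantify one section: left/right positive-pixel counts
#'
#' @param mask a `stain_mask` or logical matrix (standardized frame).
#' @param line a [partition_line()].
#' @param slice_id identifier for the section.
#' @return one-row data frame: `slice`, `left`, `right`, `total_frame_pixels`.
#' @export
quantify_slice <- function(mask, line, slice_id = 1L) {
  m <- if (inherits(mask, "stain_mask")) mask$mask else mask
  lr <- split_by_partition(m, line)
  data.frame(slice = slice_id, left = unname(lr["left"]),
             right = unname(lr["right"]),
             total_frame_pixels = nrow(m) * ncol(m))
}

#' Per-heart summary of left/right stain counts
#'
#' Aggregates per-slice left/right positive-pixel counts for one heart:
#' arithmetic means, standard errors of the mean (sample SD with n-1
#' denominator over sqrt(n)), and mean per-slice percentages. Percentages
#' are computed per slice as `left / (left + right) * 100` and then
#' averaged (mean of ratios); slices with zero total positives are excluded
#' from the percentage mean and counted in `n_pct_excluded`. The pooled
#' ratio-of-means percentage is also reported for transparency.
#'
#' @param quants data frame with columns `left` and `right`, one row per
#'   slice (see [quantify_slice()]).
#' @param heart_id identifier for the heart.
#' @return one-row data frame of class `heart_summary`: `heart`, `n_slices`,
#'   `mean_left`, `sem_left`, `mean_right`, `sem_right`, `pct_left`,
#'   `pct_right`, `pooled_pct_left`, `n_pct_excluded`. For a single slice
#'   the SEMs are `NA`; if every slice has zero positives the percentages
#'   are `NA` and the summary is flagged via `n_pct_excluded == n_slices`.
#' @export
summarize_heart <- function(quants, heart_id = "heart") {
  quants <- as.data.frame(quants)
  n <- nrow(quants)
  if (n < 1) stop("need at least one slice", call. = FALSE)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  tot <- quants$left + quants$right
  nz <- tot > 0
  pct_l <- if (any(nz)) mean(quants$left[nz] / tot[nz]) * 100 else NA_real_
  pct_r <- if (any(nz)) mean(quants$right[nz] / tot[nz]) * 100 else NA_real_
  pooled <- if (sum(tot) > 0) sum(quants$left) / sum(tot) * 100 else NA_real_
  out <- data.frame(heart = heart_id, n_slices = n,
                    mean_left = mean(quants$left), sem_left = sem(quants$left),
                    mean_right = mean(quants$right), sem_right = sem(quants$right),
                    pct_left = pct_l, pct_right = pct_r,
                    pooled_pct_left = pooled,
                    n_pct_excluded = sum(!nz))
  class(out) <- c("heart_summary", class(out))
  out
}

#' Group-level summary across hearts
#'
#' The bottom ("Mean, n = ...") row of a per-heart table: means of the
#' per-heart mean pixel counts with the SEM taken across hearts, and the
#' mean of the per-heart percentages.
#'
#' @param summaries data frame of per-heart rows (see [summarize_heart()]),
#'   with columns `mean_left`, `mean_right`, `pct_left`, `pct_right`.
#' @return one-row data frame: `n_hearts`, `mean_left`, `sem_left`,
#'   `mean_right`, `sem_right`, `pct_left`, `pct_right`.
#' @export
summarize_group <- function(summaries) {
  s <- as.data.frame(summaries)
  n <- nrow(s)
  if (n < 1) stop("need at least one heart", call. = FALSE)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  data.frame(n_hearts = n,
             mean_left = mean(s$mean_left), sem_left = sem(s$mean_left),
             mean_right = mean(s$mean_right), sem_right = sem(s$mean_right),
             pct_left = mean(s$pct_left), pct_right = mean(s$pct_right))
}

#' Compare left and right sides across hearts
#'
#' Two-sample Student's t-test on per-heart mean pixel counts, two-tailed,
#' alpha = 0.05. The pooled-variance test is the reported default; the
#' Welch and paired variants are computed alongside (the pairing of sides
#' within a heart makes the paired test a defensible alternative).
#'
#' @param left_means,right_means per-heart values, equal length >= 2.
#' @param variant which variant populates the headline `t`, `df`, `p`:
#'   `"pooled"` (default), `"welch"`, or `"paired"`.
#' @return an object of class `side_comparison`: group means/SEMs,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `alpha`, `variant`,
#'   and an `all_variants` data frame.
#' @export
compare_sides <- function(left_means, right_means,
                          variant = c("pooled", "welch", "paired")) {
  variant <- match.arg(variant)
  if (length(left_means) < 2 || length(right_means) < 2) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (variant == "paired" && length(left_means) != length(right_means)) {
    stop("paired comparison needs equal-length groups", call. = FALSE)
  }
  safe_t <- function(...) tryCatch(stats::t.test(...), error = function(e) NULL)
  tt <- list(
    pooled = safe_t(left_means, right_means, var.equal = TRUE),
    welch  = safe_t(left_means, right_means, var.equal = FALSE),
    paired = if (length(left_means) == length(right_means))
      safe_t(left_means, right_means, paired = TRUE) else NULL)
  if (is.null(tt[[variant]])) {
    stop("degenerate data for the ", variant, " t-test", call. = FALSE)
  }
  av <- do.call(rbind, lapply(names(tt), function(v) {
    if (is.null(tt[[v]])) return(NULL)
    data.frame(variant = v, t = unname(tt[[v]]$statistic),
               df = unname(tt[[v]]$parameter), p = tt[[v]]$p.value)
  }))
  sel <- tt[[variant]]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(mean_left = mean(left_means), sem_left = sem(left_means),
                 mean_right = mean(right_means), sem_right = sem(right_means),
                 t_statistic = unname(sel$statistic),
                 degrees_of_freedom = unname(sel$parameter),
                 p_value = sel$p.value, alpha = 0.05, variant = variant,
                 all_variants = av),
            class = "side_comparison")
}

#' @export
print.side_comparison <- function(x, ...) {
  cat(sprintf("side_comparison (%s t-test): left %.1f +/- %.1f vs right %.1f +/- %.1f\n",
              x$variant, x$mean_left, x$sem_left, x$mean_right, x$sem_right))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g (alpha = %.2f)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$alpha))
  invisible(x)
}

#' Published per-heart left/right pixel summaries (worked example)
#'
#' Per-heart summaries of beta-galactosidase-positive (blue) pixel counts
#' from a genetic fate-mapping study of adrenergic-derived cells in the
#' adult mouse heart: mean +/- SEM positive pixels per five random sections,
#' left and right of the apex-to-base separation line, plus the mean
#' per-slice percentage per side. Used as the worked example for
#' [summarize_group()]: its group row reproduces 22533 +/- 8873 (left),
#' 1771 +/- 450 (right), 89.2% / 10.8%.
#'
#' @return data frame with one row per reporter-positive heart: `heart`,
#'   `mean_left`, `sem_left`, `mean_right`, `sem_right`, `pct_left`,
#'   `pct_right`.
#' @export
example_heart_summaries <- function() {
  data.frame(
    heart = c("R26R-Cre-1", "R26R-Cre-2", "R26R-Cre-3"),
    mean_left = c(7031, 22806, 37763),
    sem_left = c(1306, 2568, 14618),
    mean_right = c(965, 1827, 2521),
    sem_right = c(412, 79, 304),
    pct_left = c(87.5, 92.2, 87.9),
    pct_right = c(12.5, 7.8, 12.1))
}
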