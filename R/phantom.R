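#' A single color histology section
#'
#' Lightweight container for one 2D RGB section image in a ventral-to-dorsal
#' series.
#'
#' @param pixels `H x W x 3` array of 8-bit RGB intensities (0-255).
#' @param order_index integer position in the ventral-to-dorsal series.
#' @param section_thickness nominal section thickness in micrometers
#'   (cryosections are typically cut at 14-20 um).
#' @return an object of class `color_slice`.
#' @export
color_slice <- function(pixels, order_index = 1L, section_thickness = 14) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) {
    stop("color_slice pixels must be an H x W x 3 array", call. = FALSE)
  }
  if (d[1] < 1 || d[2] < 1) stop("image dimensions must be positive", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, order_index = as.integer(order_index),
                 section_thickness = section_thickness),
            class = "color_slice")
}

#' Parameters for the synthetic serial-section phantom
#'
#' Describes a stack of synthetic frontal heart sections: a two-lobed
#' tissue silhouette counterstained pink, blue stain-positive patches whose
#' pooled pixel mass is split left/right in a controlled proportion, optional
#' per-slice rigid misalignment, and additive Gaussian pixel noise. Defaults
#' mirror the analysis frame used downstream (690 x 970 pixels) and a
#' strongly left-lateralized stain.
#'
#' @param n_slices number of sections in the stack (>= 1).
#' @param frame_height,frame_width image dimensions in pixels (defaults 970,
#'   690, the standardized analysis frame).
#' @param left_fraction proportion in `[0, 1]` of stain-positive pixel mass
#'   placed on the anatomical-left side of the separation line.
#' @param stain_color,tissue_color,background_color RGB triples in 0-255;
#'   defaults: deep blue chromogen, eosin-pink tissue, white background
#'   (chosen to be well separated in CIE L*a*b*).
#' @param noise_sd per-channel Gaussian pixel noise standard deviation
#'   (added, then clipped to `[0, 255]` and rounded).
#' @param jitter_translation_max maximum |translation| per axis, pixels,
#'   for the rigid misalignment of slices 2..n (slice 1 is the anchor).
#' @param jitter_rotation_max maximum |rotation|, degrees.
#' @param n_stain_patches number of circular stain patches per slice.
#' @param patch_radius_frac length-2 range of patch radii as a fraction of
#'   frame width.
#' @param section_thickness nominal thickness in micrometers.
#' @param seed integer RNG seed; identical parameters and seed reproduce the
#'   stack bit for bit.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(n_slices = 5L,
                           frame_height = 970L, frame_width = 690L,
                           left_fraction = 0.9,
                           stain_color = c(49, 59, 125),
                           tissue_color = c(244, 169, 186),
                           background_color = c(255, 255, 255),
                           noise_sd = 5,
                           jitter_translation_max = 0,
                           jitter_rotation_max = 0,
                           n_stain_patches = 10L,
                           patch_radius_frac = c(0.015, 0.04),
                           section_thickness = 14,
                           seed = 1L) {
  p <- list(n_slices = as.integer(n_slices),
            frame_height = as.integer(frame_height),
            frame_width = as.integer(frame_width),
            left_fraction = left_fraction,
            stain_color = stain_color, tissue_color = tissue_color,
            background_color = background_color,
            noise_sd = noise_sd,
            jitter_translation_max = jitter_translation_max,
            jitter_rotation_max = jitter_rotation_max,
            n_stain_patches = as.integer(n_stain_patches),
            patch_radius_frac = patch_radius_frac,
            section_thickness = section_thickness,
            seed = as.integer(seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (p$n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  if (p$frame_height <= 0 || p$frame_width <= 0) {
    stop("frame dimensions must be positive", call. = FALSE)
  }
  if (p$left_fraction < 0 || p$left_fraction > 1) {
    stop("left_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cols <- c(p$stain_color, p$tissue_color, p$background_color)
  if (length(p$stain_color) != 3 || length(p$tissue_color) != 3 ||
      length(p$background_color) != 3 || any(cols < 0) || any(cols > 255)) {
    stop("colors must be RGB triples in [0, 255]", call. = FALSE)
  }
  if (p$jitter_translation_max < 0 || p$jitter_rotation_max < 0) {
    stop("jitter bounds must be >= 0", call. = FALSE)
  }
  if (p$n_stain_patches < 0) stop("n_stain_patches must be >= 0", call. = FALSE)
  invisible(p)
}

# Two-lobed tissue silhouette with a basal notch between the lobes and the
# apex of the larger (left) lobe at the bottom. Returns the H x W logical
# tissue mask plus the apex and base landmark points used for the
# ground-truth separation line.
phantom_silhouette <- function(h, w) {
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  in_ellipse <- function(cx, cy, rx, ry) {
    ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
  }
  left_lobe  <- in_ellipse(0.42 * w, 0.52 * h, 0.27 * w, 0.34 * h)
  right_lobe <- in_ellipse(0.62 * w, 0.44 * h, 0.21 * w, 0.26 * h)
  notch <- ((x - 0.53 * w)^2 + (y - 0.175 * h)^2) <= (0.045 * w)^2
  tissue <- (left_lobe | right_lobe) & !notch
  apex <- c(x = 0.42 * w, y = 0.52 * h + 0.34 * h)   # bottom of left lobe
  base <- c(x = 0.53 * w, y = 0.52 * h - 0.34 * h)   # top, through the notch
  list(tissue = tissue, apex = apex, base = base)
}

# Choose which patches go left so the left share of total patch area is as
# close as possible to `fraction`: exhaustive subset search for <= 16
# patches, greedy (largest first) beyond. Returns a logical vector.
assign_sides <- function(areas, fraction) {
  n <- length(areas)
  if (n == 0) return(logical(0))
  if (fraction <= 0) return(rep(FALSE, n))
  if (fraction >= 1) return(rep(TRUE, n))
  target <- fraction * sum(areas)
  if (n <= 16) {
    subsets <- matrix(FALSE, 2^n, n)
    for (j in seq_len(n)) {
      subsets[, j] <- bitwAnd(seq_len(2^n) - 1L, bitwShiftL(1L, j - 1L)) > 0
    }
    sums <- as.vector(subsets %*% areas)
    subsets[which.min(abs(sums - target)), ]
  } else {
    left <- rep(FALSE, n)
    mass <- 0
    for (j in order(areas, decreasing = TRUE)) {
      if (abs(mass + areas[j] - target) < abs(mass - target)) {
        left[j] <- TRUE
        mass <- mass + areas[j]
      }
    }
    left
  }
}

# Signed distance of points (px, py) to the line through p1 -> p2; positive on
# the side where the reference point lies.
signed_line_dist <- function(px, py, p1, p2, ref) {
  v <- p2 - p1
  nrm <- sqrt(sum(v^2))
  d <- (v[1] * (py - p1[2]) - v[2] * (px - p1[1])) / nrm
  sref <- (v[1] * (ref[2] - p1[2]) - v[2] * (ref[1] - p1[1])) / nrm
  if (sref < 0) d <- -d
  d
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Builds `n_slices` color sections of a two-lobed tissue silhouette with
#' blue stain patches, records exact ground truth (per-slice binary stain
#' masks, the applied rigid misalignment of each slice, the apex-to-base
#' separation line, and per-slice left/right true pixel counts), then
#' applies the misalignment and pixel noise to the emitted images.
#'
#' One base patch configuration (centers, radii, sides) is drawn per stack
#' and shared by all sections, mimicking the spatial continuity of serial
#' sections through one specimen; each section scales the patch radii by a
#' random factor (0.85-1.15) so per-slice counts vary the way staining does
#' between nearby sections. Patches are disjoint disks placed fully inside
#' the tissue with a margin to the separation line, and sides are assigned
#' by choosing the left subset of patch areas whose share best matches
#' `left_fraction` (exhaustive subset search up to 20 patches, greedy
#' beyond), so the pooled left share tracks `left_fraction` to within the
#' granularity of the smallest patch. Truth masks are stored post-jitter
#' (matching the emitted images); left/right counts are recorded
#' pre-jitter, against the canonical separation line, so for zero jitter
#' `left + right = positive pixels` exactly.
#'
#' @param params a [phantom_params()] object.
#' @return a list with elements
#'   \describe{
#'     \item{slices}{list of [color_slice()] objects, ventral to dorsal}
#'     \item{truth}{list with `masks` (post-jitter logical matrices),
#'       `transforms` (list of [rigid_transform()] applied to each slice),
#'       `line` (a [partition_line()] in the canonical frame),
#'       `left_counts`, `right_counts` (pre-jitter per-slice counts),
#'       `true_left_fraction` (the requested proportion), and
#'       `realized_left_share` (pooled share actually placed)}
#'   }
#' @export
generate_stack <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  h <- p$frame_height; w <- p$frame_width
  set.seed(p$seed)
  sil <- phantom_silhouette(h, w)
  line <- partition_line(rbind(sil$apex, sil$base))
  tissue_idx <- which(sil$tissue)
  tis_y <- ((tissue_idx - 1L) %% h) + 1L
  tis_x <- ((tissue_idx - 1L) %/% h) + 1L
  dline <- signed_line_dist(tis_x, tis_y, sil$apex, sil$base, ref = c(1, h / 2))
  # dline > 0 on the low-x (anatomical left) side

  radii <- p$patch_radius_frac * w
  scale_range <- c(0.85, 1.15)   # per-slice radius scale (staining variation)
  slices <- vector("list", p$n_slices)
  masks <- vector("list", p$n_slices)
  transforms <- vector("list", p$n_slices)
  left_counts <- right_counts <- integer(p$n_slices)

  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)

  # base patch configuration, shared by all sections of this stack
  patch_x <- patch_y <- patch_r <- numeric(0)
  patch_left <- logical(0)
  if (p$n_stain_patches > 0) {
    r_all <- stats::runif(p$n_stain_patches, radii[1], radii[2])
    want_left <- assign_sides(pi * r_all^2, p$left_fraction)
    for (j in seq_len(p$n_stain_patches)) {
      rr <- r_all[j]
      center <- NULL
      while (rr >= 1 && is.null(center)) {
        margin <- rr * scale_range[2] + 1   # strict even at the largest scale
        ok <- if (want_left[j]) dline >= margin else dline <= -margin
        cand <- which(ok)
        tries <- 0
        while (length(cand) > 0 && tries < 60 && is.null(center)) {
          tries <- tries + 1
          pick <- cand[sample.int(length(cand), 1)]
          cx0 <- tis_x[pick]; cy0 <- tis_y[pick]
          rmax <- rr * scale_range[2]
          # fully inside tissue at the largest per-slice scale, and disjoint
          # from earlier patches, so realized areas track pi r^2
          sub <- sil$tissue[pmax(1, round(cy0 - rmax)):pmin(h, round(cy0 + rmax)),
                            pmax(1, round(cx0 - rmax)):pmin(w, round(cx0 + rmax)),
                            drop = FALSE]
          yy <- pmax(1, round(cy0 - rmax)):pmin(h, round(cy0 + rmax))
          xx <- pmax(1, round(cx0 - rmax)):pmin(w, round(cx0 + rmax))
          dd <- outer(yy - cy0, xx - cx0, function(a, b) a^2 + b^2) <= rmax^2
          inside <- all(sub[dd])
          clear <- all(sqrt((patch_x - cx0)^2 + (patch_y - cy0)^2) >
                         (patch_r + rr) * scale_range[2] + 1)
          if (inside && clear) center <- c(cx0, cy0)
        }
        if (is.null(center)) rr <- rr * 0.7   # no room at this radius: shrink
      }
      if (is.null(center)) next
      patch_x <- c(patch_x, center[1]); patch_y <- c(patch_y, center[2])
      patch_r <- c(patch_r, rr)
      patch_left <- c(patch_left, want_left[j])
    }
  }

  for (k in seq_len(p$n_slices)) {
    s_k <- stats::runif(1, scale_range[1], scale_range[2])
    mask <- matrix(FALSE, h, w)
    for (j in seq_along(patch_r)) {
      mask <- mask |
        (((xg - patch_x[j])^2 + (yg - patch_y[j])^2 <= (patch_r[j] * s_k)^2) &
           sil$tissue)
    }
    # truth counts against the canonical line, before misalignment
    lr <- split_by_partition(mask, line)
    left_counts[k] <- lr[["left"]]; right_counts[k] <- lr[["right"]]

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(p$background_color[ch], h, w)
      plane[sil$tissue] <- p$tissue_color[ch]
      plane[mask] <- p$stain_color[ch]
      img[, , ch] <- plane
    }
    # per-slice rigid misalignment; slice 1 anchors the stack
    tf <- rigid_transform(0, 0, 0)
    if (k > 1 && (p$jitter_translation_max > 0 || p$jitter_rotation_max > 0)) {
      tf <- rigid_transform(
        stats::runif(1, -p$jitter_translation_max, p$jitter_translation_max),
        stats::runif(1, -p$jitter_translation_max, p$jitter_translation_max),
        stats::runif(1, -p$jitter_rotation_max, p$jitter_rotation_max) * pi / 180)
      img <- apply_rigid(img, tf, fill = p$background_color)
      mask <- apply_rigid(mask, tf, fill = FALSE)
    }
    if (p$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, p$noise_sd)
      img <- pmin(pmax(round(img), 0), 255)
    }
    slices[[k]] <- color_slice(img, order_index = k,
                               section_thickness = p$section_thickness)
    masks[[k]] <- mask
    transforms[[k]] <- tf
  }
  tot <- sum(left_counts) + sum(right_counts)
  truth <- list(masks = masks, transforms = transforms, line = line,
                left_counts = left_counts, right_counts = right_counts,
                true_left_fraction = p$left_fraction,
                realized_left_share = if (tot > 0) sum(left_counts) / tot else NA_real_)
  list(slices = slices, truth = truth, params = p)
}

#' Write a phantom stack to disk
#'
#' Writes numbered slice PNGs (`slice_000.png`, ...), single-channel 0/255
#' truth-mask PNGs (`mask_000.png`, ...), a JSON sidecar with parameters,
#' per-slice transforms and the separation line, and a per-slice CSV of
#' ground-truth left/right counts.
#'
#' @param stack result of [generate_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_phantom <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (k in seq_along(stack$slices)) {
    f <- file.path(dir, sprintf("slice_%03d.png", k - 1))
    write_slice_png(stack$slices[[k]], f)
    m <- file.path(dir, sprintf("mask_%03d.png", k - 1))
    write_mask_png(stack$truth$masks[[k]], m)
    files <- c(files, f, m)
  }
  side <- file.path(dir, "phantom.json")
  tf <- lapply(stack$truth$transforms,
               function(t) list(tx = t$tx, ty = t$ty, theta = t$theta))
  jsonlite::write_json(
    list(params = unclass(stack$params),
         transforms = tf,
         line = list(points = unclass(stack$truth$line$points),
                     side_convention = stack$truth$line$side_convention),
         true_left_fraction = stack$truth$true_left_fraction,
         realized_left_share = stack$truth$realized_left_share),
    side, auto_unbox = TRUE, digits = NA)
  cnt <- file.path(dir, "truth_counts.csv")
  utils::write.csv(data.frame(slice = seq_along(stack$slices) - 1L,
                              left = stack$truth$left_counts,
                              right = stack$truth$right_counts),
                   cnt, row.names = FALSE)
  invisible(c(files, side, cnt))
}
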