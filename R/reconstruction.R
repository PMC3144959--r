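#' Select a subsequence of sections
#'
#' A subset of sections of interest can be chosen for reconstruction; the
#' subsequence keeps the ventral-to-dorsal order.
#'
#' @param series list of masks (or any per-section objects), in order.
#' @param subset 1-based indices, strictly increasing.
#' @return the subsequence of `series`.
#' @export
select_slices <- function(series, subset) {
  subset <- as.integer(subset)
  if (length(subset) < 1 || any(subset < 1) || any(subset > length(series))) {
    stop("subset indices out of range", call. = FALSE)
  }
  if (is.unsorted(subset, strictly = TRUE)) {
    stop("subset indices must be strictly increasing", call. = FALSE)
  }
  series[subset]
}

#' Rigid registration of one segmented section onto another
#'
#' Finds the in-plane rigid transform (translation + rotation about the
#' image center) maximizing binary overlap (equivalently the Dice
#' coefficient) between the transformed moving mask and the fixed mask.
#' Exhaustive, deterministic two-stage search: a coarse grid over
#' (tx, ty, theta), then local refinement around the coarse optimum. Ties
#' break toward the smallest `|tx| + |ty| + |theta|`. If either mask is
#' empty the identity transform is returned, flagged via attribute
#' `"empty_input"`.
#'
#' @param moving,fixed `stain_mask` objects or logical matrices of equal
#'   dimensions.
#' @param translation_max search bound for |tx|, |ty| in pixels (default 15).
#' @param rotation_max search bound for |theta| in degrees (default 10).
#' @param coarse_step coarse grid step (pixels and degrees; default 1).
#' @param fine_step refinement step (default 0.1).
#' @return a [rigid_transform()] (theta in radians) with attributes
#'   `"dice"` (achieved Dice coefficient) and `"overlap"`.
#' @export
register_pair <- function(moving, fixed, translation_max = 15,
                          rotation_max = 10, coarse_step = 1,
                          fine_step = 0.1) {
  if (inherits(moving, "stain_mask")) moving <- moving$mask
  if (inherits(fixed, "stain_mask")) fixed <- fixed$mask
  if (!all(dim(moving) == dim(fixed))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  n_mov <- sum(moving); n_fix <- sum(fixed)
  if (n_mov == 0 || n_fix == 0) {
    out <- rigid_transform(0, 0, 0)
    attr(out, "empty_input") <- TRUE
    attr(out, "dice") <- 0
    return(out)
  }
  h <- nrow(moving); w <- ncol(moving)
  pos <- which(moving)
  py <- ((pos - 1L) %% h) + 1
  px <- ((pos - 1L) %/% h) + 1
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  grid1 <- function(mx, step) {
    g <- seq(0, mx, by = step)
    sort(unique(c(-g, g)))
  }
  coarse <- best_rigid_cpp(px, py, fixed, cx, cy,
                           grid1(translation_max, coarse_step),
                           grid1(translation_max, coarse_step),
                           grid1(rotation_max, coarse_step))
  ref <- function(center, mx, step) {
    g <- seq(center - coarse_step, center + coarse_step, by = step)
    g[abs(g) <= mx + 1e-9]
  }
  fine <- best_rigid_cpp(px, py, fixed, cx, cy,
                         ref(coarse[1], translation_max, fine_step),
                         ref(coarse[2], translation_max, fine_step),
                         ref(coarse[3], rotation_max, fine_step))
  out <- rigid_transform(fine[1], fine[2], fine[3] * pi / 180)
  attr(out, "overlap") <- fine[4]
  attr(out, "dice") <- 2 * fine[4] / (n_mov + n_fix)
  out
}

#' Align a series of segmented sections to the first section's frame
#'
#' Registers each section to its predecessor and composes the pairwise
#' transforms so every section is resampled into the first section's frame
#' (nearest-neighbor, so masks stay binary).
#'
#' @param masks list of `stain_mask` objects or logical matrices, in order.
#' @param ... passed to [register_pair()].
#' @return list with `aligned` (logical matrices), `pair_transforms`
#'   (transform aligning slice k onto slice k-1), and `to_first`
#'   (composed transform aligning slice k onto slice 1).
#' @export
align_series <- function(masks, ...) {
  masks <- lapply(masks, function(m) if (inherits(m, "stain_mask")) m$mask else m)
  n <- length(masks)
  pair <- vector("list", n)
  to_first <- vector("list", n)
  pair[[1]] <- to_first[[1]] <- rigid_transform(0, 0, 0)
  aligned <- masks
  for (k in seq_len(n)[-1]) {
    pair[[k]] <- register_pair(masks[[k]], masks[[k - 1]], ...)
    to_first[[k]] <- compose_rigid(to_first[[k - 1]], pair[[k]])
    aligned[[k]] <- apply_rigid(masks[[k]], to_first[[k]], fill = FALSE)
  }
  list(aligned = aligned, pair_transforms = pair, to_first = to_first)
}

#' Stack aligned sections into a 3D binary stain volume
#'
#' Each section mask contributes `replication_factor` consecutive identical
#' z-layers (default 7, simulating the thickness of one physical section),
#' in series order. Voxels are stored x-fastest (dimensions `c(W, H, Z)`);
#' z spacing is the section thickness divided by the replication factor so
#' the replicated layers of one section span one physical section.
#'
#' @param masks list of `stain_mask` objects or logical matrices of equal
#'   dimensions.
#' @param replication_factor z-layers per section (>= 1, default 7).
#' @param section_thickness physical section thickness (micrometers,
#'   default 14).
#' @param pixel_spacing in-plane spacing (arbitrary units, default 1).
#' @param slice_ids provenance identifiers (default sequence).
#' @return an object of class `stain_volume`: `voxels` (logical `W x H x Z`
#'   array), `replication_factor`, `slice_ids`, `spacing` (x, y, z),
#'   `n_slices`. Invariants: `Z = replication_factor * n_slices` and
#'   `sum(voxels) = replication_factor * sum(per-slice positives)`.
#' @export
stack_volume <- function(masks, replication_factor = 7L,
                         section_thickness = 14, pixel_spacing = 1,
                         slice_ids = seq_along(masks)) {
  masks <- lapply(masks, function(m) if (inherits(m, "stain_mask")) m$mask else m)
  stopifnot(length(masks) >= 1, replication_factor >= 1)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1)))) {
    stop("all masks must share the same dimensions", call. = FALSE)
  }
  rf <- as.integer(replication_factor)
  nz <- rf * length(masks)
  vox <- array(FALSE, dim = c(d[2], d[1], nz))   # (x, y, z)
  z <- 0L
  for (m in masks) {
    tm <- t(m)
    for (r in seq_len(rf)) {
      z <- z + 1L
      vox[, , z] <- tm
    }
  }
  structure(list(voxels = vox, replication_factor = rf,
                 slice_ids = slice_ids,
                 spacing = c(x = pixel_spacing, y = pixel_spacing,
                             z = section_thickness / rf),
                 n_slices = length(masks)),
            class = "stain_volume")
}

#' @export
print.stain_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("stain_volume: %d x %d x %d voxels (x,y,z), %d true, %d slices x %d layers\n",
              d[1], d[2], d[3], sum(x$voxels), x$n_slices, x$replication_factor))
  cat(sprintf("  spacing: %.3f x %.3f x %.3f\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Write a stain volume as MetaImage (.mhd + .raw)
#'
#' Writes a conformant MetaImage text header and the raw voxel data
#' (8-bit unsigned, 255 for stain-positive, 0 otherwise, x-fastest order),
#' loadable by standard medical-image viewers. The round trip through
#' [read_metaimage()] is bit-exact.
#'
#' @param volume a `stain_volume`.
#' @param path output path; a `.mhd` extension is added if absent, and the
#'   raw file takes the same stem with `.raw`.
#' @return invisibly, c(mhd_path, raw_path).
#' @export
write_metaimage <- function(volume, path) {
  stopifnot(inherits(volume, "stain_volume"))
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(volume$voxels)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           "Offset = 0 0 0",
           "CenterOfRotation = 0 0 0",
           sprintf("ElementSpacing = %g %g %g",
                   volume$spacing[1], volume$spacing[2], volume$spacing[3]),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_UCHAR",
           sprintf("ElementDataFile = %s", basename(raw_path)))
  con <- file(path, "wb")   # binary mode: fixed newlines across platforms
  writeLines(hdr, con)
  close(con)
  writeBin(as.raw(ifelse(as.vector(volume$voxels), 255L, 0L)), raw_path)
  invisible(c(path, raw_path))
}

#' Read a MetaImage volume written by [write_metaimage()]
#'
#' Minimal MetaImage reader: parses the `.mhd` key-value header (NDims = 3,
#' MET_UCHAR, uncompressed) and loads the raw voxel data; voxels > 0 are
#' true.
#'
#' @param path path to the `.mhd` header.
#' @return a `stain_volume` (with `replication_factor` and `slice_ids`
#'   unknown, set to `NA`).
#' @export
read_metaimage <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), character(1))
  get <- function(k) vals[match(k, keys)]
  if (!identical(get("NDims"), "3")) stop("expected NDims = 3", call. = FALSE)
  if (!identical(get("ElementType"), "MET_UCHAR")) {
    stop("only MET_UCHAR volumes supported", call. = FALSE)
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  v <- readBin(raw_path, "raw", n = prod(dims))
  if (length(v) != prod(dims)) stop("raw data shorter than DimSize", call. = FALSE)
  structure(list(voxels = array(as.integer(v) > 0, dim = dims),
                 replication_factor = NA_integer_, slice_ids = NA,
                 spacing = c(x = sp[1], y = sp[2], z = sp[3]),
                 n_slices = NA_integer_),
            class = "stain_volume")
}

#' Orthogonal maximum-intensity projections of a stain volume
#'
#' Projects the binary volume along each axis — axial (down z), coronal
#' (down y), sagittal (down x) — and optionally writes the three
#' projections as PNG images.
#'
#' @param volume a `stain_volume`.
#' @param dir output directory for `axial.png`, `coronal.png`,
#'   `sagittal.png`; if `NULL` (default) nothing is written.
#' @return invisibly, a list of the three logical projection matrices
#'   (`axial` is `H x W`, matching the section masks).
#' @export
export_orthogonal_views <- function(volume, dir = NULL) {
  v <- volume$voxels            # (x, y, z)
  axial <- t(apply(v, c(1, 2), any))       # H x W, image orientation
  coronal <- t(apply(v, c(1, 3), any))     # Z x W
  sagittal <- t(apply(v, c(2, 3), any))    # Z x H
  views <- list(axial = axial, coronal = coronal, sagittal = sagittal)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(views)) {
      write_mask_png(views[[nm]], file.path(dir, paste0(nm, ".png")))
    }
  }
  invisible(views)
}
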