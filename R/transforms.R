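#' In-plane rigid transform
#'
#' A rigid (translation + rotation) transform acting on image pixel
#' coordinates. Rotation is by `theta` radians about the image center;
#' translation `(tx, ty)` is applied after the rotation, in pixel units
#' (x = column, y = row). A point `p` maps forward to
#' `R(theta) (p - c) + c + (tx, ty)` where `c` is the image center.
#'
#' @param tx,ty translation in pixels (x = columns, y = rows).
#' @param theta rotation angle in radians.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0) {
  stopifnot(length(tx) == 1, length(ty) == 1, length(theta) == 1)
  tx <- as.numeric(tx); ty <- as.numeric(ty); theta <- as.numeric(theta)
  if (!all(is.finite(c(tx, ty, theta)))) {
    stop("rigid_transform parameters must be finite", call. = FALSE)
  }
  structure(list(tx = tx, ty = ty, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: tx=%.3f px, ty=%.3f px, theta=%.4f rad (%.2f deg)\n",
              x$tx, x$ty, x$theta, x$theta * 180 / pi))
  invisible(x)
}

is_identity_transform <- function(tf, tol = 1e-12) {
  abs(tf$tx) < tol && abs(tf$ty) < tol && abs(tf$theta) < tol
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `a` first, then `b`
#' (`compose_rigid(b, a)` maps `p` to `b(a(p))`), for transforms about the
#' same image center.
#'
#' @param b,a `rigid_transform` objects; `a` is applied first.
#' @return a `rigid_transform`.
#' @export
compose_rigid <- function(b, a) {
  R2 <- rot_mat(b$theta)
  t2 <- c(b$tx, b$ty) + as.vector(R2 %*% c(a$tx, a$ty))
  rigid_transform(t2[1], t2[2], a$theta + b$theta)
}

#' Invert a rigid transform
#'
#' @param tf a `rigid_transform`.
#' @return the inverse `rigid_transform` about the same center.
#' @export
invert_rigid <- function(tf) {
  Ri <- rot_mat(-tf$theta)
  t <- -as.vector(Ri %*% c(tf$tx, tf$ty))
  rigid_transform(t[1], t[2], -tf$theta)
}

#' Apply a rigid transform to an image or mask
#'
#' Resamples the image under the forward transform: output pixel `q` takes
#' the value of input pixel `R^{-1}(q - c - t) + c`, rounded to the nearest
#' pixel (nearest-neighbor interpolation, the default) so that binary masks
#' stay binary. Pixels mapping outside the input get `fill`. Output
#' dimensions equal input dimensions.
#'
#' @param image an `H x W` matrix (numeric or logical) or `H x W x 3` array,
#'   or a [color_slice()].
#' @param transform a [rigid_transform()].
#' @param fill fill value for out-of-range pixels; default 0 (`FALSE` for
#'   logical input). For 3-channel arrays a length-3 vector is accepted.
#' @param interp interpolation rule; only `"nearest"` is implemented.
#' @return object of the same shape/class as `image`.
#' @export
apply_rigid <- function(image, transform, fill = 0, interp = "nearest") {
  interp <- match.arg(interp, "nearest")
  if (inherits(image, "color_slice")) {
    out <- image
    out$pixels <- apply_rigid(image$pixels, transform, fill = fill)
    return(out)
  }
  stopifnot(inherits(transform, "rigid_transform"))
  if (is_identity_transform(transform)) return(image)
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  # output pixel centers
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  Ri <- rot_mat(-transform$theta)
  dx <- X - cx - transform$tx
  dy <- Y - cy - transform$ty
  sx <- round(Ri[1, 1] * dx + Ri[1, 2] * dy + cx)
  sy <- round(Ri[2, 1] * dx + Ri[2, 2] * dy + cy)
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  sx[!inside] <- 1L; sy[!inside] <- 1L
  idx <- (as.vector(sx) - 1L) * h + as.vector(sy)
  if (length(dims) == 2) {
    vals <- image[idx]
    if (is.logical(image) && identical(fill, 0)) fill <- FALSE
    vals[!inside] <- fill
    out <- matrix(vals, h, w)
  } else {
    fill <- rep_len(fill, dims[3])
    out <- image
    for (ch in seq_len(dims[3])) {
      plane <- image[, , ch]
      vals <- plane[idx]
      vals[!inside] <- fill[ch]
      out[, , ch] <- matrix(vals, h, w)
    }
  }
  out
}
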