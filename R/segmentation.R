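#' Convert 8-bit sRGB to CIE L*a*b*
#'
#' Standard colorimetric pipeline: sRGB gamma expansion, linear RGB to CIE
#' XYZ (sRGB primaries), XYZ to L*a*b* under the D65 reference white.
#' L* lies in `[0, 100]`; a* and b* in roughly `[-128, 127]`. Negative b*
#' indicates blue — the property used downstream to recognize the
#' chromogenic (X-gal) stain cluster.
#'
#' @param x a [color_slice()], an `H x W x 3` array, or an `N x 3` matrix of
#'   RGB values in 0-255.
#' @return an object of the same shape with (L*, a*, b*) in the channel
#'   (column) dimension; for a `color_slice`, an `H x W x 3` array.
#' @export
rgb_to_lab <- function(x) {
  if (inherits(x, "color_slice")) x <- x$pixels
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2, 3)) || d[length(d)] != 3) {
    stop("input must have 3 color channels", call. = FALSE)
  }
  m <- matrix(as.numeric(x), ncol = 3)   # column-major: channels end up in columns
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  wp <- c(0.95047, 1.00000, 1.08883)   # D65
  t3 <- sweep(xyz, 2, wp, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t3 > eps, t3^(1 / 3), t3 / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  if (length(d) == 3) array(lab, dim = d) else lab
}

#' Reference L*a*b* color of the blue chromogen
#'
#' The L*a*b* coordinates of the default deep-blue stain color, used as the
#' target when selecting the stain cluster.
#'
#' @param rgb RGB triple of the stain color (default the phantom's stain
#'   blue).
#' @return length-3 numeric (L*, a*, b*).
#' @export
stain_reference_lab <- function(rgb = c(49, 59, 125)) {
  as.vector(rgb_to_lab(matrix(rgb, 1, 3)))
}

#' k-means color clustering of a section in L*a*b* space
#'
#' Lloyd's algorithm with squared Euclidean distance on the per-pixel
#' (L*, a*, b*) feature vectors, run `n_restarts` times from seeded random
#' initializations (K distinct pixel colors each) and keeping the solution
#' with the lowest inertia (total within-cluster sum of squares). Fully
#' deterministic for a given seed. An empty cluster is re-seeded at the
#' pixel farthest from its assigned centroid.
#'
#' @param lab `H x W x 3` L*a*b* array (see [rgb_to_lab()]).
#' @param K number of clusters (>= 2; each section is initialized at 6 and
#'   may be tuned, see [tune_k()]).
#' @param seed integer RNG seed.
#' @param n_restarts number of random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return an object of class `cluster_model`: `K`, `centroids` (`K x 3`),
#'   `labels` (`H x W` integer matrix, values in 1..K), `inertia`, `seed`.
#' @export
cluster_colors <- function(lab, K = 6L, seed = 1L, n_restarts = 10L,
                           max_iter = 100L) {
  d <- dim(lab)
  stopifnot(length(d) == 3, d[3] == 3)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  X <- matrix(as.numeric(lab), ncol = 3)
  uniq <- X[!duplicated(X), , drop = FALSE]
  if (nrow(uniq) < K) {
    stop(sprintf("degenerate input: %d distinct colors < K = %d",
                 nrow(uniq), K), call. = FALSE)
  }
  set.seed(seed)
  inits <- replicate(n_restarts,
                     uniq[sample.int(nrow(uniq), K), , drop = FALSE],
                     simplify = FALSE)
  best <- NULL
  for (C0 in inits) {
    fit <- lloyd_kmeans_cpp(X, C0, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(K = as.integer(K), centroids = best$centroids,
                 labels = matrix(best$labels, d[1], d[2]),
                 inertia = best$inertia, seed = as.integer(seed),
                 dims = d[1:2]),
            class = "cluster_model")
}


#' Extract the stain-positive mask from a fitted cluster model
#'
#' Selects the cluster whose centroid is nearest (squared Euclidean in
#' L*a*b*) to the stain reference color, restricted to blue-shifted
#' centroids (centroid b* below `blue_guard`). If no centroid passes the
#' blue guard the section is treated as stain-free: an all-false mask
#' flagged `no_stain`, not an error.
#'
#' The guard defaults to b* < -10 rather than bare negativity: pixel noise
#' can split the near-achromatic background into a marginally blue-shifted
#' subcluster (b* of a few units below zero), while a true blue chromogen
#' sits far below (the default stain reference has b* of about -39).
#'
#' @param model a `cluster_model` from [cluster_colors()].
#' @param stain_reference length-3 (L*, a*, b*) target color; default
#'   [stain_reference_lab()].
#' @param blue_guard maximum admissible centroid b* (default -10).
#' @return an object of class `stain_mask`: `mask` (`H x W` logical),
#'   `selected_cluster`, `positive_count`, `no_stain` flag, and `model`
#'   provenance (K, centroids, inertia, seed).
#' @export
select_stain_cluster <- function(model, stain_reference = stain_reference_lab(),
                                 blue_guard = -10) {
  stopifnot(inherits(model, "cluster_model"))
  cen <- model$centroids
  blue <- cen[, 3] < blue_guard
  if (!any(blue)) {
    mask <- matrix(FALSE, model$dims[1], model$dims[2])
    return(new_stain_mask(mask, NA_integer_, model, no_stain = TRUE))
  }
  d2 <- rowSums(sweep(cen, 2, stain_reference, "-")^2)
  d2[!blue] <- Inf
  sel <- which.min(d2)
  new_stain_mask(model$labels == sel, sel, model, no_stain = FALSE)
}

new_stain_mask <- function(mask, selected, model = NULL, no_stain = FALSE) {
  structure(list(mask = mask,
                 selected_cluster = selected,
                 positive_count = sum(mask),
                 no_stain = no_stain,
                 model = if (!is.null(model))
                   list(K = model$K, centroids = model$centroids,
                        inertia = model$inertia, seed = model$seed)),
            class = "stain_mask")
}

#' Coerce a logical matrix to a stain mask
#'
#' Convenience wrapper so ground-truth or externally loaded masks flow
#' through the quantification and reconstruction stages.
#'
#' @param mask `H x W` logical matrix.
#' @return a `stain_mask`.
#' @export
as_stain_mask <- function(mask) {
  if (inherits(mask, "stain_mask")) return(mask)
  stopifnot(is.matrix(mask))
  new_stain_mask(mask != 0, NA_integer_, NULL, no_stain = !any(mask != 0))
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("stain_mask: %d x %d, %d positive pixels%s%s\n",
              nrow(x$mask), ncol(x$mask), x$positive_count,
              if (isTRUE(x$no_stain)) " [no stain detected]" else "",
              if (!is.null(x$model)) sprintf(" (K = %d)", x$model$K) else ""))
  invisible(x)
}

#' Deterministic replacement for interactive K tuning
#'
#' The number of clusters is nominally 6 per section but benefits from
#' adjustment when staining intensity varies. This tuner fits models for
#' `K = k_min..k_max`, extracts the candidate stain mask for each, and
#' scores each candidate by the mean L*a*b* distance of its pixels to the
#' stain reference plus a stability penalty (the symmetric-difference rate
#' between the masks at K and its neighbor K+1, or K-1 at the top of the
#' range). The lowest score wins; ties break toward K = 6, then toward
#' smaller K. Flagged stain-free candidates score infinity; if every K is
#' stain-free the K = 6 flagged mask is returned.
#'
#' @param lab `H x W x 3` L*a*b* array.
#' @param stain_reference length-3 (L*, a*, b*) target color.
#' @param k_min,k_max search range; must bracket 6 (`2 <= k_min <= 6 <=
#'   k_max`).
#' @param seed,n_restarts passed to [cluster_colors()].
#' @param stability_weight weight (L*a*b* units) of the mask-instability
#'   penalty.
#' @return the winning `stain_mask`, with the selection trace (a data frame
#'   of K, score, distance and stability terms, counts) in attribute
#'   `"trace"` and the chosen K in attribute `"K"`.
#' @export
tune_k <- function(lab, stain_reference = stain_reference_lab(),
                   k_min = 2L, k_max = 8L, seed = 1L, n_restarts = 10L,
                   stability_weight = 10) {
  if (!(2 <= k_min && k_min <= 6 && 6 <= k_max)) {
    stop("need 2 <= k_min <= 6 <= k_max", call. = FALSE)
  }
  ks <- k_min:k_max
  labmat <- matrix(as.numeric(lab), ncol = 3)
  cands <- lapply(ks, function(K) {
    select_stain_cluster(cluster_colors(lab, K = K, seed = seed,
                                        n_restarts = n_restarts),
                         stain_reference)
  })
  names(cands) <- as.character(ks)
  mean_dist <- vapply(cands, function(sm) {
    if (sm$positive_count == 0) return(Inf)
    px <- labmat[as.vector(sm$mask), , drop = FALSE]
    mean(sqrt(rowSums(sweep(px, 2, stain_reference, "-")^2)))
  }, numeric(1))
  symdiff_rate <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) return(0)
    sum(xor(a, b)) / u
  }
  stability <- vapply(seq_along(ks), function(i) {
    j <- if (i < length(ks)) i + 1L else i - 1L
    symdiff_rate(cands[[i]]$mask, cands[[j]]$mask)
  }, numeric(1))
  score <- mean_dist + stability_weight * stability
  # evaluate from K = 6 outward so ties stick to 6
  ord <- order(abs(ks - 6L), ks)
  best_i <- ord[1]
  for (i in ord) if (score[i] < score[best_i] - 1e-9) best_i <- i
  if (!is.finite(score[best_i])) {
    best_i <- which(ks == 6L)   # all stain-free: report the K = 6 flagged mask
  }
  out <- cands[[best_i]]
  attr(out, "K") <- ks[best_i]
  attr(out, "trace") <- data.frame(
    K = ks, score = score, mean_dist = mean_dist, stability = stability,
    positive_count = vapply(cands, function(s) s$positive_count, numeric(1)),
    no_stain = vapply(cands, function(s) isTRUE(s$no_stain), logical(1)),
    row.names = NULL)
  out
}

#' Segment one color section end to end
#'
#' Convenience wrapper: L*a*b* conversion, clustering (fixed K or tuned),
#' stain-cluster extraction.
#'
#' @param slice a [color_slice()] or `H x W x 3` RGB array.
#' @param K number of clusters; default 6.
#' @param tune if `TRUE`, use [tune_k()] over `k_range` instead of fixed K.
#' @param k_range length-2 range for tuning.
#' @param stain_reference,seed,n_restarts see [cluster_colors()] and
#'   [select_stain_cluster()].
#' @return a `stain_mask`.
#' @export
segment_slice <- function(slice, K = 6L, tune = FALSE, k_range = c(2L, 8L),
                          stain_reference = stain_reference_lab(),
                          seed = 1L, n_restarts = 10L) {
  lab <- rgb_to_lab(slice)
  if (tune) {
    tune_k(lab, stain_reference, k_min = k_range[1], k_max = k_range[2],
           seed = seed, n_restarts = n_restarts)
  } else {
    select_stain_cluster(cluster_colors(lab, K = K, seed = seed,
                                        n_restarts = n_restarts),
                         stain_reference)
  }
}
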