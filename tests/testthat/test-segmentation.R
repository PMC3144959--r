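test_that("rgb_to_lab hits the colorimetric anchors", {
  white <- rgb_to_lab(matrix(c(255, 255, 255), 1, 3))
  expect_equal(white[1, 1], 100, tolerance = 1e-3)
  expect_lt(abs(white[1, 2]), 0.01)
  expect_lt(abs(white[1, 3]), 0.01)
  black <- rgb_to_lab(matrix(c(0, 0, 0), 1, 3))
  expect_equal(unname(black[1, ]), c(0, 0, 0), tolerance = 1e-6)
  gray <- rgb_to_lab(matrix(c(119, 119, 119), 1, 3))
  expect_lt(abs(gray[1, 2]), 0.5)
  expect_lt(abs(gray[1, 3]), 0.5)
})

test_that("rgb_to_lab agrees with grDevices::convertColor on random colors", {
  set.seed(1)
  rgb <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  mine <- rgb_to_lab(rgb)
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab",
                                 to.ref.white = "D65")
  expect_equal(unname(mine), unname(ref), tolerance = 0.01)
})

test_that("rgb_to_lab rejects non-3-channel input", {
  expect_error(rgb_to_lab(matrix(1:4, 2, 2)), "3 color channels")
  expect_error(rgb_to_lab(array(0, c(2, 2, 4))), "3 color channels")
})

test_that("two-color image with K = 2 separates perfectly with zero inertia", {
  lab <- array(0, c(2, 3, 3))
  lab[, 2:3, 1] <- 100   # 2 colors: (0,0,0) and (100,0,0)
  cm <- cluster_colors(lab, K = 2, seed = 1, n_restarts = 5)
  expect_equal(cm$inertia, 0, tolerance = 1e-9)
  expect_length(unique(as.vector(cm$labels[, 1])), 1)
  expect_length(unique(as.vector(cm$labels[, 2:3])), 1)
  expect_false(cm$labels[1, 1] == cm$labels[1, 2])
  expect_setequal(round(cm$centroids[, 1]), c(0, 100))
})

test_that("k-means matches the brute-force 2-partition oracle on tiny instances", {
  # canonical 6-point instance: three at the origin, three at (100, 0, 0)
  lab <- array(0, c(1, 6, 3))
  lab[1, 4:6, 1] <- 100
  cm <- cluster_colors(lab, K = 2, seed = 1, n_restarts = 8)
  X <- matrix(as.numeric(lab), ncol = 3)
  expect_equal(cm$inertia, oracle_best_2partition(X), tolerance = 1e-9)
  expect_setequal(round(cm$centroids[, 1], 6), c(0, 100))
  # random <= 8 pixel instances
  set.seed(99)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    X <- matrix(runif(n * 3, 0, 50), n, 3)
    lab <- array(X, c(1, n, 3))
    cm <- cluster_colors(lab, K = 2, seed = i, n_restarts = 20)
    expect_equal(cm$inertia, oracle_best_2partition(X), tolerance = 1e-6)
  }
})

test_that("noise-free 3-color phantom clusters like nearest-palette assignment", {
  p <- small_params(n_slices = 1, noise_sd = 0, seed = 6)
  st <- generate_stack(p)
  lab <- rgb_to_lab(st$slices[[1]])
  cm <- cluster_colors(lab, K = 3, seed = 1, n_restarts = 5)
  palette <- rgb_to_lab(rbind(p$stain_color, p$tissue_color, p$background_color))
  X <- matrix(as.numeric(lab), ncol = 3)
  d2 <- sapply(1:3, function(j) rowSums(sweep(X, 2, palette[j, ], "-")^2))
  oracle_labels <- max.col(-d2)
  # same partition up to cluster relabeling
  expect_equal(length(unique(paste(as.vector(cm$labels), oracle_labels))), 3)
  expect_equal(cm$inertia, 0, tolerance = 1e-6)
})

test_that("clustering errors when distinct colors are fewer than K", {
  lab <- array(0, c(2, 2, 3))   # a single color
  expect_error(cluster_colors(lab, K = 2), "degenerate")
})

test_that("clustering is deterministic for a fixed seed", {
  st <- generate_stack(tiny_params(n_slices = 1, noise_sd = 6, seed = 2))
  lab <- rgb_to_lab(st$slices[[1]])
  a <- cluster_colors(lab, K = 4, seed = 7, n_restarts = 3)
  b <- cluster_colors(lab, K = 4, seed = 7, n_restarts = 3)
  expect_identical(a, b)
})

test_that("best-of-restarts inertia is non-increasing in K", {
  st <- generate_stack(tiny_params(n_slices = 1, noise_sd = 6, seed = 3))
  lab <- rgb_to_lab(st$slices[[1]])
  inertias <- vapply(2:7, function(K) {
    cluster_colors(lab, K = K, seed = 1, n_restarts = 10)$inertia
  }, numeric(1))
  expect_true(all(diff(inertias) <= abs(inertias[-length(inertias)]) * 1e-8))
})

test_that("stain cluster selection follows the reference color and blue guard", {
  st <- generate_stack(small_params(n_slices = 1, noise_sd = 0, seed = 8))
  lab <- rgb_to_lab(st$slices[[1]])
  cm <- cluster_colors(lab, K = 3, seed = 1, n_restarts = 5)
  # one centroid sits at the stain color exactly (noise-free): exact match
  sm <- select_stain_cluster(cm, stain_reference_lab())
  expect_false(sm$no_stain)
  expect_identical(sm$mask, cm$labels == sm$selected_cluster)
  expect_identical(sm$positive_count, sum(sm$mask))
})

test_that("a stain-free slide yields a flagged empty mask, not an error", {
  st <- generate_stack(small_params(n_slices = 1, n_stain_patches = 0,
                                    noise_sd = 0, seed = 8))
  lab <- rgb_to_lab(st$slices[[1]])
  cm <- cluster_colors(lab, K = 2, seed = 1, n_restarts = 5)
  expect_true(all(cm$centroids[, 3] > 0))   # pink + white: no negative b*
  sm <- select_stain_cluster(cm)
  expect_true(sm$no_stain)
  expect_identical(sm$positive_count, 0L)
  expect_false(any(sm$mask))
})

test_that("segmentation recovers phantom truth with Jaccard >= 0.95 at noise_sd = 8", {
  for (seed in c(21, 22)) {
    st <- generate_stack(small_params(n_slices = 1, noise_sd = 8, seed = seed))
    sm <- segment_slice(st$slices[[1]], K = 6, seed = 1, n_restarts = 10)
    expect_gte(jaccard(sm, st$truth$masks[[1]]), 0.95)
  }
})

test_that("positive_count is conserved under a joint pixel permutation", {
  st <- generate_stack(tiny_params(n_slices = 1, noise_sd = 5, seed = 13))
  sm <- segment_slice(st$slices[[1]], K = 6, seed = 2, n_restarts = 3)
  set.seed(1)
  perm_r <- sample(nrow(sm$mask))
  perm_c <- sample(ncol(sm$mask))
  sm_perm <- as_stain_mask(sm$mask[perm_r, perm_c])
  expect_identical(sm_perm$positive_count, sm$positive_count)
})

test_that("tune_k keeps K = 6 when the mask is K-insensitive", {
  st <- generate_stack(small_params(n_slices = 1, noise_sd = 2, seed = 14))
  lab <- rgb_to_lab(st$slices[[1]])
  sm6 <- select_stain_cluster(cluster_colors(lab, K = 6, seed = 1, n_restarts = 5))
  tuned <- tune_k(lab, seed = 1, n_restarts = 5)
  expect_identical(attr(tuned, "K"), 6L)
  expect_identical(tuned$mask, sm6$mask)
  expect_s3_class(attr(tuned, "trace"), "data.frame")
  expect_identical(nrow(attr(tuned, "trace")), 7L)
})

test_that("tune_k on a stain-free slide returns the flagged empty mask", {
  st <- generate_stack(small_params(n_slices = 1, n_stain_patches = 0,
                                    noise_sd = 3, seed = 15))
  tuned <- tune_k(rgb_to_lab(st$slices[[1]]), seed = 1, n_restarts = 3)
  expect_true(tuned$no_stain)
  expect_identical(tuned$positive_count, 0L)
})

test_that("tuned masks are at least as accurate as fixed K = 6 across seeds", {
  wins <- vapply(1:10, function(s) {
    st <- generate_stack(tiny_params(n_slices = 1, noise_sd = 8, seed = 30 + s))
    lab <- rgb_to_lab(st$slices[[1]])
    truth <- st$truth$masks[[1]]
    j6 <- jaccard(select_stain_cluster(
      cluster_colors(lab, K = 6, seed = s, n_restarts = 3)), truth)
    jt <- jaccard(tune_k(lab, seed = s, n_restarts = 3), truth)
    jt >= j6 - 1e-12
  }, logical(1))
  expect_true(all(wins))
})

test_that("tune_k enforces that the range brackets 6", {
  lab <- array(runif(60), c(2, 10, 3))
  expect_error(tune_k(lab, k_min = 3, k_max = 5), "k_min")
})
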