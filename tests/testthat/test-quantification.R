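test_that("standardize_frame returns a 690 x 970 = 669300 pixel image", {
  set.seed(5)
  for (d in list(c(100, 80), c(1380, 1940), c(971, 691))) {
    img <- array(sample(0:255, prod(d) * 3, replace = TRUE), c(d[1], d[2], 3))
    out <- standardize_frame(img)
    expect_identical(dim(out), c(970L, 690L, 3L))
    expect_identical(as.integer(prod(dim(out)[1:2])), 669300L)
  }
})

test_that("an image already in the analysis frame is returned unchanged", {
  img <- array(7, c(970, 690, 3))
  expect_identical(standardize_frame(img), img)
})

test_that("a constant image standardizes to the same constant", {
  img <- array(123, c(1940, 1380, 3))
  out <- standardize_frame(img)
  expect_true(all(out == 123))
  expect_identical(dim(out), c(970L, 690L, 3L))
})

test_that("partition lines are validated", {
  expect_error(partition_line(rbind(c(1, 1))), ">= 2")
  expect_error(partition_line(rbind(c(1, 1), c(1, 1))), "distinct")
  expect_error(partition_line(rbind(c(1, 1), c(2, 5), c(3, 2))), "monotone")
  # apex-first or base-first are both accepted and normalized
  a <- partition_line(rbind(c(5, 10), c(7, 1)))
  expect_equal(a$points[, 2], c(1, 10))
})

test_that("a vertical line strictly separates all-left positives", {
  mask <- matrix(FALSE, 20, 20)
  mask[cbind(c(3, 7, 15), c(2, 10, 14))] <- TRUE
  line <- partition_line(rbind(c(15, 1), c(15, 20)))
  expect_equal(split_by_partition(mask, line), c(left = 3, right = 0))
  expect_equal(split_by_partition(matrix(FALSE, 20, 20), line),
               c(left = 0, right = 0))
})

test_that("pixels exactly on the line count as right", {
  mask <- matrix(FALSE, 5, 5)
  mask[3, 3] <- TRUE
  line <- partition_line(rbind(c(3, 1), c(3, 5)))
  expect_equal(split_by_partition(mask, line), c(left = 0, right = 1))
})

test_that("side convention flips the counts", {
  mask <- matrix(FALSE, 10, 10)
  mask[5, 2] <- TRUE
  pts <- rbind(c(6, 1), c(6, 10))
  expect_equal(split_by_partition(mask, partition_line(pts)),
               c(left = 1, right = 0))
  expect_equal(split_by_partition(mask, partition_line(pts, "image_right")),
               c(left = 0, right = 1))
})

test_that("two-segment polyline split matches the brute-force oracle", {
  mask <- matrix(FALSE, 20, 20)
  set.seed(8)
  mask[cbind(sample(20, 7), sample(20, 7))] <- TRUE
  pts <- rbind(c(8, 1), c(12, 9), c(6, 20))
  line <- partition_line(pts)
  got <- split_by_partition(mask, line)
  want <- oracle_split(mask, pts)
  expect_equal(unname(got), unname(want))
  expect_equal(sum(got), sum(mask))
})

test_that("split counts always sum to the mask's positive count", {
  set.seed(9)
  for (i in 1:10) {
    mask <- matrix(runif(30 * 25) < 0.2, 30, 25)
    pts <- cbind(runif(3, 1, 25), sort(runif(3, 1, 30)))
    got <- split_by_partition(mask, partition_line(pts))
    expect_identical(as.integer(sum(got)), sum(mask))
  }
})

test_that("non-monotone polylines are rejected by the splitter path", {
  expect_error(partition_line(cbind(c(1, 2, 3), c(1, 5, 2))), "monotone")
})

test_that("summarize_heart on a symmetric heart gives mean 20 and 50 percent", {
  q <- data.frame(slice = 1:3, left = c(10, 20, 30), right = c(10, 20, 30))
  s <- summarize_heart(q, "sym")
  expect_equal(s$mean_left, 20)
  expect_equal(s$pct_left, 50)
  expect_equal(s$pct_right, 50)
  expect_equal(s$pct_left + s$pct_right, 100, tolerance = 0.1)
})

test_that("SEM uses the n-1 standard deviation over sqrt(n)", {
  q <- data.frame(left = c(7031, 22806, 37763), right = c(965, 1827, 2521))
  s <- summarize_heart(q, "printed-means")
  expect_identical(round(s$sem_left), 8873)
  expect_identical(round(s$sem_right), 450)
  expect_identical(round(s$mean_left), 22533)
  expect_identical(round(s$mean_right), 1771)
})

test_that("zero-positive slices are excluded from the percentage mean", {
  q <- data.frame(left = c(10, 0, 30), right = c(10, 0, 10))
  s <- summarize_heart(q, "h")
  expect_equal(s$pct_left, mean(c(50, 75)))
  expect_identical(s$n_pct_excluded, 1L)
  s0 <- summarize_heart(data.frame(left = c(0, 0), right = c(0, 0)), "z")
  expect_true(is.na(s0$pct_left))
  expect_identical(s0$n_pct_excluded, 2L)
})

test_that("single-slice summaries have NA SEM and empty input errors", {
  s <- summarize_heart(data.frame(left = 5, right = 5), "one")
  expect_true(is.na(s$sem_left))
  expect_error(summarize_heart(data.frame(left = numeric(0), right = numeric(0))),
               "at least one")
})

test_that("group summary reproduces the published bottom row", {
  g <- summarize_group(example_heart_summaries())
  expect_identical(round(g$mean_left), 22533)
  expect_identical(round(g$sem_left), 8873)
  expect_identical(round(g$mean_right), 1771)
  expect_identical(round(g$sem_right), 450)
  expect_equal(round(g$pct_left, 1), 89.2)
  expect_equal(round(g$pct_right, 1), 10.8)
})

test_that("identical groups give t = 0 and p = 1", {
  cmp <- compare_sides(c(5, 6, 7), c(5, 6, 7))
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("pooled t matches the closed-form value for a pure shift", {
  x <- c(1, 2, 3) + 10
  y <- c(1, 2, 3)
  cmp <- compare_sides(x, y)
  # hand formula: t = (mx - my) / (sp * sqrt(1/n + 1/m)), sp^2 pooled
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$degrees_of_freedom, 4)
  welch <- cmp$all_variants[cmp$all_variants$variant == "welch", ]
  expect_equal(welch$t, t_hand, tolerance = 1e-12)   # equal variances
})

test_that("compare_sides validates group sizes and supports the paired variant", {
  expect_error(compare_sides(1, c(1, 2)), "at least 2")
  cmp <- compare_sides(c(10, 20, 30), c(1, 2, 3), variant = "paired")
  expect_identical(cmp$variant, "paired")
  expect_equal(cmp$degrees_of_freedom, 2)
})

test_that("phantom quantification recovers the true left fraction (jitter 0)", {
  st <- generate_stack(small_params(n_slices = 5, left_fraction = 0.9,
                                    noise_sd = 5, seed = 17))
  q <- do.call(rbind, lapply(1:5, function(k) {
    sm <- segment_slice(st$slices[[k]], K = 6, seed = k, n_restarts = 4)
    quantify_slice(sm, st$truth$line, k)
  }))
  pooled <- sum(q$left) / sum(q$left + q$right)
  expect_lt(abs(pooled - 0.9), 0.03)
  s <- summarize_heart(q, "ph")
  expect_equal(s$pct_left + s$pct_right, 100, tolerance = 0.1)
})
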