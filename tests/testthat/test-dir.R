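test_that("DRCP is zero for identical profiles and matches direct arithmetic", {
  pos <- seq(1e4, 1e6, by = 2e4)
  a <- fake_smoothed(pos, exp(-pos / 1e5) * 1e-3)
  expect_true(all(compute_drcp(a, a)$drcp == 0))

  # p_ref = 0.01, p_test = 0.02: DRCP = log(2)/|log(0.01)| ~ +0.1505
  b1 <- fake_smoothed(1:3, rep(0.02, 3))
  b0 <- fake_smoothed(1:3, rep(0.01, 3))
  dr <- compute_drcp(b1, b0, rescale = FALSE)
  expect_equal(dr$drcp, rep(log(2) / abs(log(0.01)), 3), tolerance = 1e-12)

  # masked where the reference is pseudo-count-floor only or missing
  c1 <- fake_smoothed(1:3, c(0.02, 0.02, NA))
  c0 <- fake_smoothed(1:3, c(0.01, 0.01, 0.01), informative = c(TRUE, FALSE, TRUE))
  drm <- compute_drcp(c1, c0, rescale = FALSE)
  expect_true(is.na(drm$drcp[2]) && is.na(drm$drcp[3]))

  expect_error(compute_drcp(b1, fake_smoothed(1:2, c(1, 1))), "grids")
})

test_that("window rank test matches exact enumeration and handles edge cases", {
  # fully separated samples: two-sided exact p = 2/choose(10,5)
  p <- test_window(c(10, 20, 30, 40, 50), c(1, 2, 3, 4, 5))
  expect_equal(p, 2 / choose(10, 5), tolerance = 1e-12)
  # identical samples: p = 1 under the midrank convention
  expect_equal(test_window(c(1, 2, 3), c(1, 2, 3)), 1)
  # untestable windows return NA, no exception
  expect_true(is.na(test_window(c(1, 2), c(1, 2, 3))))
  expect_true(is.na(test_window(numeric(0), numeric(0))))
})

test_that("DIR calling requires two replicates and recovers an injected spike", {
  expect_error(call_dirs(list(), list(), list()), "two biological replicates")

  res <- run_pipeline(list(simulate = list(
    seed = 301, deletion_beads = NULL, spike = "standard")))
  vp <- res$viewpoints[nrow(res$viewpoints), ]
  target <- c(vp$mid - 9.5e5, vp$mid - 6.5e5)
  d <- res$dirs[[vp$id]]
  expect_gt(nrow(d), 0)
  hit <- d$direction == "increase" & d$start < target[2] & d$end > target[1]
  expect_true(any(hit))
  # every call spans at least one test window
  all_calls <- do.call(rbind, res$dirs)
  expect_true(all(all_calls$end - all_calls$start >= 8e4))
})

test_that("no-difference replicate pairs yield no DIR calls", {
  res <- run_pipeline(list(simulate = list(seed = 3, deletion_beads = NULL)))
  expect_equal(sum(vapply(res$dirs, nrow, integer(1))), 0L)
})

test_that("swapping test and reference flips DRCP signs and DIR directions", {
  pos <- seq(1e4, 1e6, by = 2e4)
  set.seed(21)
  a <- fake_smoothed(pos, exp(rnorm(length(pos), -8, 0.5)))
  b <- fake_smoothed(pos, exp(rnorm(length(pos), -8, 0.5)))
  d_ab <- compute_drcp(a, b, rescale = FALSE)
  d_ba <- compute_drcp(b, a, rescale = FALSE)
  # sign flip holds where the p_ref-floor masking is symmetric; with both
  # profiles informative everywhere the magnitudes differ only through the
  # |log p_ref| denominator
  expect_true(all(sign(d_ab$drcp) == -sign(d_ba$drcp)))
})

test_that("DIR calls round-trip through BED and stay sorted", {
  calls <- data.frame(start = c(400000, 100000), end = c(500000, 180000),
                      direction = c("decrease", "increase"),
                      max_drcp = c(-0.21, 1.4), p_rep1 = c(0.01, 0.002),
                      p_rep2 = c(0.03, 0.004))
  class(calls) <- c("dir_calls", "data.frame")
  path <- withr::local_tempfile(fileext = ".bed")
  write_dirs(calls, path, chrom = "chr4")
  back <- read_dirs(path)
  expect_equal(back$start, c(100000, 400000))     # sorted by start
  expect_equal(back$direction, c("increase", "decrease"))
  expect_equal(back$max_drcp, c(1.4, -0.21))
  raw <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(raw$score, c(1000, 210))           # 1000 * min(1, |DRCP|)

  # empty call list: header-only file
  empty <- calls[0, ]
  write_dirs(empty, path)
  expect_equal(nrow(read_dirs(path)), 0L)

  # overlapping same-direction calls must have been merged upstream
  bad <- data.frame(start = c(0, 50), end = c(100, 150),
                    direction = "increase", max_drcp = 0.1,
                    p_rep1 = 0.01, p_rep2 = 0.01)
  expect_error(write_dirs(bad, path), "merge")
})
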