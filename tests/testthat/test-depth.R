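test_that("window tiling matches the closed-form count", {
  # 10 kb region, 1000/100 windows: floor((10000-1000)/100)+1 = 91
  bg <- data.frame(contig = "c", start = seq(0L, 9900L, 100L),
                   end = seq(100L, 10000L, 100L), depth = 30)
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 10000L))
  expect_equal(nrow(tr$windows), 91L)
  expect_true(all(tr$windows$raw == 30))
  expect_equal(tr$windows$start[91], 9000L)
})

test_that("window means average per-base depth", {
  # first half of the first window at 10, second half at 30 -> mean 20
  bg <- data.frame(contig = "c",
                   start = c(0L, 500L), end = c(500L, 1000L),
                   depth = c(10, 30))
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 1000L))
  expect_equal(tr$windows$raw[1], 20)
})

test_that("coverage gaps mark windows missing", {
  starts <- seq(0L, 9900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  bg <- bg[bg$start != 5000L, ]  # drop one tile
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 10000L))
  overlapping <- tr$windows$start > 4000L & tr$windows$start <= 5000L
  expect_true(all(is.na(tr$windows$raw[overlapping])))
  expect_true(all(!is.na(tr$windows$raw[!overlapping])))
})

test_that("normalization divides by the control statistic", {
  starts <- seq(0L, 49900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  bg$depth[bg$start >= 40000L] <- 45  # 1.5x region outside control
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 50000L))
  tr <- normalize_depth(tr, list(start = 0L, end = 30000L))
  expect_equal(tr$control_stat, 30)
  expect_equal(tr$windows$norm[1], 1.0)
  expect_equal(tr$windows$norm[tr$windows$start == 42000L], 1.5)
  # scaling invariance: doubling raw depth changes nothing after normalizing
  bg2 <- bg; bg2$depth <- bg2$depth * 2
  tr2 <- window_depth(bg2, depth_config(), list(contig = "c", start = 0L,
                                                end = 50000L))
  tr2 <- normalize_depth(tr2, list(start = 0L, end = 30000L))
  expect_equal(tr2$windows$norm, tr$windows$norm)
})

test_that("normalization demands enough usable control windows", {
  starts <- seq(0L, 9900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 10000L))
  expect_error(normalize_depth(tr, list(start = 0L, end = 5000L)),
               "control windows")
})

test_that("sector CN doubles the mean normalized depth and rounds away from zero", {
  starts <- seq(0L, 49900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  bg$depth[bg$start >= 40000L & bg$start < 45000L] <- 45
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 50000L))
  tr <- normalize_depth(tr, list(start = 0L, end = 30000L))
  base <- sector_cn(tr, list(name = "beta", start = 20000L, end = 25000L))
  expect_equal(base$cn_continuous, 2.0)
  expect_equal(base$cn_call, 2L)
  dup <- sector_cn(tr, list(name = "beta", start = 41000L, end = 44000L))
  expect_equal(dup$cn_continuous, 3.0)
  expect_equal(dup$cn_call, 3L)
  expect_identical(dup$qc, "pass")
  # half-away-from-zero rounding at the .5 boundary
  expect_equal(structhap:::round_half_away(2.5), 3)
  expect_equal(structhap:::round_half_away(3.5), 4)
  expect_equal(structhap:::round_half_away(2.4), 2)
})

test_that("QC caps exclude implausible copy numbers, monotonically", {
  starts <- seq(0L, 49900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  bg$depth[bg$start >= 40000L & bg$start < 45000L] <- 30 * 30.5  # CN 61
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 50000L))
  tr <- normalize_depth(tr, list(start = 0L, end = 30000L))
  sec <- list(name = "kansl1", start = 41000L, end = 44000L)
  est <- sector_cn(tr, sec)  # default cap 20
  expect_identical(est$qc, "fail")
  nsf <- nsf_cn(tr, list(name = "nsf_1", start = 41000L, end = 42400L),
                list(name = "nsf_2", start = 42600L, end = 44000L))
  expect_identical(nsf$qc, "fail")  # ~61+ exceeds the NSF cap of 50
  # raising the cap never turns a passing sample into a failing one
  relaxed <- sector_cn(tr, sec, cap = 100)
  expect_identical(relaxed$qc, "pass")
  expect_equal(relaxed$cn_continuous, est$cn_continuous)
})

test_that("NSF baseline is diploid CN 4 at uniform depth", {
  starts <- seq(0L, 49900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 50000L))
  tr <- normalize_depth(tr, list(start = 0L, end = 30000L))
  nsf <- nsf_cn(tr, list(name = "nsf_1", start = 40000L, end = 44000L),
                list(name = "nsf_2", start = 45000L, end = 49000L))
  expect_equal(nsf$cn_continuous, 4.0)
  expect_equal(nsf$cn_call, 4L)
})

test_that("too few overlapping windows yields a no-call", {
  starts <- seq(0L, 49900L, 100L)
  bg <- data.frame(contig = "c", start = starts, end = starts + 100L,
                   depth = 30)
  tr <- window_depth(bg, depth_config(), list(contig = "c", start = 0L,
                                              end = 50000L))
  tr <- normalize_depth(tr, list(start = 0L, end = 30000L))
  tiny <- sector_cn(tr, list(name = "beta", start = 49800L, end = 49900L))
  expect_identical(tiny$qc, "no-call")
})
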