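test_that("a constant series zeroes every dispersion statistic", {
  td <- time_domain_metrics(make_nn(rep(1000, 1200)))
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
  expect_identical(td$nnx, 0L)
  expect_equal(td$mean_hr, 60)
  expect_equal(td$sd_hr, 0)
})

test_that("successive-difference statistics match hand computation", {
  td <- time_domain_metrics(make_nn(c(800, 810, 790)))
  expect_equal(td$rmssd, sqrt((100 + 400) / 2))  # 15.811 ms
  expect_identical(td$nnx, 0L)                   # default x = 50 ms
  td15 <- time_domain_metrics(make_nn(c(800, 810, 790)), x_ms = 15)
  expect_identical(td15$nnx, 1L)
  expect_equal(td15$pnnx, 0.5)
})

test_that("an alternating series has closed-form RMSSD and SDNN", {
  rr <- rep(c(790, 810), 750)  # ~20 min
  td <- time_domain_metrics(make_nn(rr))
  expect_equal(td$rmssd, 20)
  expect_equal(td$sdnn, 10)
})

test_that("every statistic equals its brute-force oracle on random series", {
  set.seed(101)
  for (i in 1:15) {
    rr <- runif(sample(5:20, 1), 600, 1200)
    td <- time_domain_metrics(make_nn(rr), segment_s = 2)
    or <- oracle_time_domain(rr)
    for (k in c("sdnn", "rmssd", "mean_hr", "sd_hr", "pnnx")) {
      expect_equal(td[[k]], or[[k]], tolerance = 1e-12)
    }
    expect_identical(as.integer(td$nnx), as.integer(or$nnx))
  }
})

test_that("gaps exclude successive differences but not the interval pool", {
  rr <- c(1000, 1000, 900, 900)
  nn <- nn_series(rr, end_times = c(1000, 2000, 5000, 5900),
                  contiguous = c(FALSE, TRUE, FALSE, TRUE))
  td <- time_domain_metrics(nn)
  # diffs: only within-run pairs (0 and 0); the 1000 -> 900 jump is a gap
  expect_equal(td$rmssd, 0)
  expect_equal(td$sdnn, oracle_pop_sd(rr))
})

test_that("SDANN and SDNNi follow the 5-min segmentation rules", {
  # ~20 min of 1000 ms beats with the 2nd segment uniformly shifted
  rr <- rep(1000, 1200)
  rr[301:600] <- 900
  nn <- make_nn(rr)
  td <- time_domain_metrics(nn)
  segs <- ceiling(cumsum(rr) / 3e5) - 1
  means <- tapply(rr, segs, mean)
  expect_equal(td$n_segments, 4L)
  expect_equal(td$sdann, oracle_pop_sd(as.numeric(means)))
  expect_equal(td$sdnni, mean(tapply(rr, segs, oracle_pop_sd)))
  # a trailing partial segment under 60 s is dropped, not pooled
  trail <- time_domain_metrics(make_nn(c(rep(1000, 1200), rep(1000, 30))))
  expect_equal(trail$n_segments, 4L)
  # fewer than two segments: SDANN is missing, not zero
  short <- time_domain_metrics(make_nn(rep(1000, 120)))
  expect_true(is.na(short$sdann))
})

test_that("SDNN is permutation invariant but RMSSD is not", {
  set.seed(5)
  rr <- runif(100, 700, 1200)
  perm <- sample(rr)
  expect_equal(time_domain_metrics(make_nn(rr))$sdnn,
               time_domain_metrics(make_nn(perm))$sdnn)
  expect_false(isTRUE(all.equal(time_domain_metrics(make_nn(rr))$rmssd,
                                time_domain_metrics(make_nn(sort(rr)))$rmssd)))
})

test_that("pNNx is non-increasing in x", {
  set.seed(6)
  rr <- runif(300, 700, 1200)
  xs <- seq(0, 200, by = 10)
  p <- vapply(xs, function(x) time_domain_metrics(make_nn(rr), x_ms = x)$pnnx, 0)
  expect_true(all(diff(p) <= 0))
})

test_that("degenerate histograms give the stated geometric values", {
  g <- geometric_metrics(make_nn(rep(1000, 100)))
  expect_equal(g$hrv_ti, 1)
  expect_equal(g$tinn, 7.8125)
})

test_that("TINN recovers the width of a triangular histogram", {
  # triangular distribution of half-width W = 100 ms around 1000 ms
  bw <- 7.8125
  W <- 100
  centers <- seq(1000 - W, 1000 + W, by = bw / 2)
  counts <- round(200 * (1 - abs(centers - 1000) / W))
  rr <- rep(centers, counts)
  g <- geometric_metrics(make_nn(rr[sample(length(rr))]), bin_width = bw)
  expect_lt(abs(g$tinn - 2 * W), 2 * bw)
  expect_gt(g$hrv_ti, 5)
})

test_that("hrv_ti equals count over modal bin height", {
  set.seed(9)
  rr <- rnorm(2000, 1000, 40)
  g <- geometric_metrics(make_nn(rr))
  expect_equal(g$hrv_ti, length(rr) / max(g$counts))
  expect_gte(g$hrv_ti, 1)
})
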