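test_that("DDAF hits its analytic endpoints", {
  # canonical division of labor: one strand all epsilon -> 0
  expect_equal(compute_ddaf(flat_fractions(1, 0))$ddaf, rep(0, 20))
  # both strands by Pols delta and alpha -> 1
  expect_equal(compute_ddaf(flat_fractions(0, 0))$ddaf, rep(1, 20))
  # both strands by Pol epsilon -> -1
  expect_equal(compute_ddaf(flat_fractions(1, 1))$ddaf, rep(-1, 20))
})

test_that("DDAF is linear in the f_epsilon rescale and propagates missingness", {
  fr <- flat_fractions(0.6, 0.3, n = 30)
  fr$f_epsilon$top[4] <- NA
  d1 <- compute_ddaf(fr)
  expect_true(is.na(d1$ddaf[4]))
  fr2 <- fr
  cc <- 0.8
  fr2$f_epsilon$top <- fr$f_epsilon$top * cc
  fr2$f_epsilon$bottom <- fr$f_epsilon$bottom * cc
  d2 <- compute_ddaf(fr2)
  expect_equal(1 - d2$ddaf, cc * (1 - d1$ddaf))
})

test_that("anchor aggregation orients, truncates and pads correctly", {
  grid <- strand_track(c(chr1 = 5000), 50)
  tr <- tibble::tibble(chrom = grid$chrom, start = grid$start,
                       end = grid$end, ddaf = seq_len(100))
  attr(tr, "bin_width") <- 50
  # single plus anchor reproduces the local track
  a <- aggregate_at_anchors(tr, data.frame(chrom = "chr1", pos = 2500,
                                           strand = "+"), flank = 500)
  expect_equal(unname(a$matrix[1, ]), 41:60)
  # minus orientation equals manual reversal
  b <- aggregate_at_anchors(tr, data.frame(chrom = "chr1", pos = 2500,
                                           strand = "-"), flank = 500)
  expect_equal(unname(b$matrix[1, ]), rev(41:60))
  # an anchor near the chromosome start pads out-of-range cells with NA
  d <- aggregate_at_anchors(tr, data.frame(chrom = "chr1", pos = 100,
                                           strand = "+"), flank = 500)
  expect_true(all(is.na(d$matrix[1, 1:8])))
  expect_equal(unname(d$matrix[1, 9:20]), 1:12)
  # truncation masks cells beyond the member-origin positions
  e <- aggregate_at_anchors(tr, data.frame(chrom = "chr1", pos = 2500,
                                           strand = "+", trunc_left = 2200,
                                           trunc_right = 2800), flank = 500)
  expect_true(all(is.na(e$matrix[1, c(1:4, 17:20)])))
  expect_equal(unname(e$matrix[1, 5:16]), 45:56)
})

test_that("peak areas are baseline-subtracted sums, invariant to offsets", {
  flat <- rep(0.3, 40)
  expect_equal(peak_area(flat, 50)$area, 0)
  # unit-height top-hat of 10 bins on a zero baseline: 10 * 50 = 500 bp
  hat <- rep(0, 40); hat[16:25] <- 1
  pa <- peak_area(hat, 50, baseline_flank = 0.15)
  expect_equal(pa$baseline, 0)
  expect_equal(pa$area, 500)
  # adding a constant shifts the baseline but not the area
  pa2 <- peak_area(hat + 2.5, 50, baseline_flank = 0.15)
  expect_equal(pa2$area, 500)
  expect_equal(pa2$baseline, 2.5)
  # brute-force check on a random curve
  set.seed(3)
  x <- stats::rnorm(60)
  k <- floor(0.15 * 60)
  base <- mean(c(x[1:k], x[(60 - k + 1):60]))
  expect_equal(peak_area(x, 50)$area,
               sum(x[(k + 1):(60 - k)] - base) * 50)
  expect_error(peak_area(x[1:5], 50), "too short")
})

test_that("the area-vs-efficiency fit recovers exact lines and rejects null shuffles", {
  eff <- seq(0.1, 1, by = 0.1)
  area <- 180 * eff - 12
  fit <- tract_length_fit(area, eff)
  expect_equal(fit$slope, 180)
  expect_equal(fit$intercept, -12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$area_at_full_efficiency, 168)
  set.seed(99)
  r2s <- replicate(20, tract_length_fit(sample(area), eff)$r_squared)
  expect_lt(stats::median(r2s), 0.3)
  expect_error(tract_length_fit(area, rep(0.5, 10)), "variance")
  expect_error(tract_length_fit(area[1:2], eff[1:2]), "3 origins")
})

test_that("smoothing respects missing bins without leaking zeros", {
  fr <- flat_fractions(0.5, 0.5, n = 30)
  fr$f_epsilon$top[10:12] <- NA
  sm <- smooth_track(fr$f_epsilon, 250)
  # neighbours of the gap renormalize over observed bins only
  expect_equal(sm$top[9], 0.5)
  expect_equal(sm$top[11], 0.5)   # window fully inside the gap edge still sees 0.5s
})
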