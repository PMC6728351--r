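test_that("solving the three-strain system inverts the measurement model exactly", {
  set.seed(42)
  n <- 400
  f <- random_simplex(n)
  w <- stats::runif(n, 0.5, 3)
  y <- noiseless_tracks(f, w_top = w)
  sol <- solve_fractions(y[c("epsilon-variant", "delta-variant",
                             "alpha-variant")], test_rates())
  expect_lt(max(abs(sol$f_alpha$top - f[, 1])), 1e-9)
  expect_lt(max(abs(sol$f_delta$top - f[, 2])), 1e-9)
  expect_lt(max(abs(sol$f_epsilon$top - f[, 3])), 1e-9)
  expect_lt(max(abs(sol$w$top - w)), 1e-9)
  # conservation holds by construction at every solvable bin
  expect_equal(sol$f_alpha$top + sol$f_delta$top + sol$f_epsilon$top,
               rep(1, n))
})

test_that("the worked single-bin example solves to the constructed f and w", {
  # y built from f = (0.1, 0.2, 0.7), w = 2 under the reference rates:
  # y = (0.07, 0.0556, 0.1096) for the epsilon/delta/alpha variants
  f <- matrix(c(0.1, 0.2, 0.7), 1, 3)
  y <- noiseless_tracks(f, w_top = 2)
  sol <- solve_fractions(y, test_rates())
  expect_equal(sol$f_alpha$top, 0.1)
  expect_equal(sol$f_delta$top, 0.2)
  expect_equal(sol$f_epsilon$top, 0.7)
  expect_equal(sol$w$top, 2)
  # pure-epsilon bin: y = (s_epsilon_var, s_epsilon, s_epsilon), f = (0,0,1)
  y2 <- noiseless_tracks(matrix(c(0, 0, 1), 1, 3))
  sol2 <- solve_fractions(y2, test_rates())
  expect_equal(sol2$f_epsilon$top, 1)
  expect_equal(sol2$w$top, 1)
})

test_that("degenerate and low-coverage bins are flagged, not zeroed", {
  r <- test_rates()
  grid <- strand_track(c(chr1 = 100), 50)
  zero <- grid
  y <- list("epsilon-variant" = zero, "delta-variant" = zero,
            "alpha-variant" = zero)
  sol <- solve_fractions(y, r)
  expect_true(all(sol$solvable$top == 0))
  expect_true(all(is.na(sol$f_delta$top)))
  # coverage floor turns thin bins into missing values
  y2 <- noiseless_tracks(matrix(c(0.1, 0.2, 0.7), 1, 3))
  sol2 <- solve_fractions(y2, r, coverage_floor = 10)
  expect_true(is.na(sol2$f_epsilon$top))
  expect_equal(sol2$solvable$top, 0)
})

test_that("strandedness and calibration windows recover the provenance map", {
  pr <- single_origin_program()
  st <- leading_strandedness(pr, n_iterations = 2, seed = 1)
  win <- select_calibration_windows(st, threshold = 0.9, min_len = 1000)
  # one deterministic origin: left region top strand is pure lagging,
  # right region top strand is pure leading
  lead <- win[win$role == "pure-leading", ]
  expect_setequal(lead$strand, c("top", "bottom"))
  right <- lead[lead$strand == "top", ]
  expect_true(all(right$start >= 50000))
  left <- lead[lead$strand == "bottom", ]
  expect_true(all(left$end <= 50000))
  # masking removes windows; an impossible threshold errors
  expect_error(select_calibration_windows(st, threshold = 0.3), "threshold")
  masked <- select_calibration_windows(
    st, exclude = data.frame(chrom = "chr1", start = 0, end = 49000))
  expect_true(all(masked$start >= 49000 | masked$end <= 49000))
})

test_that("rates are recovered exactly from noiseless single-origin data", {
  pr <- single_origin_program()
  ts <- simulate_replication(pr, n_iterations = 2, seed = 1)
  quiet <- noise_config(depth = 1, w_sd = 0, count_noise = FALSE,
                        background = 0, depth_jitter_sd = 0, replicates = 1)
  r_true <- test_rates()
  samples <- forward_model(ts, r_true, quiet, seed = 1)
  corrected <- list()
  for (s in samples) {
    if (s$treatment == "treated") corrected[[s$strain]] <- s$track
  }
  mask <- program_exclusion_mask(pr, pad = 1000)
  win <- select_calibration_windows(ts$strandedness, exclude = mask)
  est <- estimate_rates(corrected, win, head_fraction = 25 / 165,
                        alpha_delta_ratio = r_true$s_alpha / r_true$s_delta)
  for (k in names(unclass(r_true))) {
    expect_equal(est$rates[[k]], r_true[[k]], tolerance = 1e-9)
  }
  expect_equal(unname(est$rescale_factors), rep(1, 4), tolerance = 1e-9)
  # doubling one strain's depth before normalization cancels in the rescale
  c2 <- corrected
  c2[["epsilon-variant"]]$top <- 2 * c2[["epsilon-variant"]]$top
  c2[["epsilon-variant"]]$bottom <- 2 * c2[["epsilon-variant"]]$bottom
  est2 <- estimate_rates(c2, win, head_fraction = 25 / 165,
                         alpha_delta_ratio = r_true$s_alpha / r_true$s_delta)
  expect_equal(est2$rates$s_epsilon_var, r_true$s_epsilon_var,
               tolerance = 1e-9)
})

test_that("f_epsilon deviates from leading-strandedness only at origins and collisions", {
  pr <- two_origin_program()
  ts <- simulate_replication(pr, n_iterations = 2, seed = 1)
  dev <- abs(ts$fractions$f_epsilon$top - ts$strandedness$top)
  pos <- ts$strandedness$start
  near <- rep(FALSE, length(pos))
  for (p in c(50000, 150000)) near <- near | abs(pos - p) <= pr$l_init
  near <- near | abs(pos - 100000) <= pr$l_coll + 50
  expect_true(all(dev[!near] < 1e-9))
  expect_gt(max(dev[near]), 0.5)
})

test_that("rescaling f_epsilon divides by the smoothed maximum only", {
  fr <- flat_fractions(0.5, 0.25, n = 40)
  out <- rescale_epsilon(fr, window = 200)
  expect_equal(out$epsilon_scale, 0.5)
  expect_equal(out$f_epsilon$top, rep(1, 40))
  expect_equal(out$f_epsilon$bottom, rep(0.5, 40))
  # a track already at maximum 1 is untouched
  out2 <- rescale_epsilon(flat_fractions(1, 0), window = 200)
  expect_equal(out2$f_epsilon$top, rep(1, 20))
  # two tracks differing by a constant factor rescale identically
  a <- rescale_epsilon(flat_fractions(0.6, 0.3), window = 200)
  b <- rescale_epsilon(flat_fractions(0.3, 0.15), window = 200)
  expect_equal(a$f_epsilon$top, b$f_epsilon$top)
})

test_that("two-variant mode reproduces f_epsilon when alpha usage is zero", {
  set.seed(8)
  n <- 200
  f <- random_simplex(n)
  f <- cbind(0, f[, 1] + f[, 2], f[, 3])   # alpha lumped into delta
  w <- stats::runif(n, 0.5, 2)
  y <- noiseless_tracks(f, w_top = w)
  full <- solve_fractions(y, test_rates())
  two <- solve_fractions(y[c("epsilon-variant", "delta-variant")],
                         test_rates(), mode = "two-variant")
  expect_lt(max(abs(two$f_epsilon$top - full$f_epsilon$top)), 1e-9)
  expect_lt(max(abs(two$f_delta$top - f[, 2])), 1e-9)
  expect_true(all(two$f_alpha$top == 0))
})
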