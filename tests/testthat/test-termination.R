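test_that("deterministic equidistant origins give a top-hat collision density", {
  pr <- two_origin_program()   # 50k/150k, equal times, sigma 0, l_coll 2000
  sim <- simulate_collisions(pr, n_iter = 4, seed = 1)
  expect_equal(sim$efficiency$efficiency, c(1, 1))
  d <- sim$density
  inside <- d$start >= 98000 & d$end <= 102000
  expect_true(all(d$density[inside] == 1))
  expect_true(all(d$density[!inside & (d$end <= 98000 | d$start >= 102000)]
                  == 0))
  # the density integrates to 2 * l_coll per collision per iteration
  expect_equal(sum(d$density) * 50, 2 * pr$l_coll)
})

test_that("overrun origins lose their efficiency and ends terminate silently", {
  pr <- two_origin_program(t_fire = c(0, 60), v_f = 5000, sigma_t = 0)
  sim <- simulate_collisions(pr, n_iter = 3, seed = 1)
  expect_equal(sim$efficiency$efficiency, c(1, 0))
  # a lone fired origin has no collision partner: empty tract density
  expect_equal(nrow(sim$collisions), 0)
  expect_true(all(sim$density$density == 0))
  # sum of efficiencies approximates mean origins fired per iteration
  pr2 <- two_origin_program(t_fire = c(5, 18), v_f = 4000, sigma_t = 4)
  sim2 <- simulate_collisions(pr2, n_iter = 400, seed = 2)
  fired_per_iter <- 1 + nrow(sim2$collisions) / 400
  expect_equal(sum(sim2$efficiency$efficiency), fired_per_iter,
               tolerance = 1e-9)
})

test_that("efficiencies are invariant under the time rescale", {
  pr_fast <- termination_study_program()
  pr_slow <- termination_study_program(v_f = 6000 / 3.75,
                                       sigma_t = 2.6 * 3.75, s_t = 3.75)
  e1 <- simulate_collisions(pr_fast, n_iter = 400, seed = 31)$efficiency
  e2 <- simulate_collisions(pr_slow, n_iter = 400, seed = 59)$efficiency
  expect_lt(max(abs(e1$efficiency - e2$efficiency)), 0.05)
})

test_that("cubic extremum location is exact for exactly cubic objectives", {
  x <- seq(2, 10, by = 2)
  y <- 0.5 * (x - 5.5)^2 + 0.01 * (x - 5.5)^3 + 3
  ext <- polusage:::cubic_extremum(x, y, "min")
  expect_false(ext$flagged)
  # derivative (x-5.5)(1 + 0.03(x-5.5)) has its interior root at exactly 5.5
  expect_equal(ext$x_star, 5.5, tolerance = 1e-6)
  # monotone data has no interior extremum and is flagged to the best grid value
  ext2 <- polusage:::cubic_extremum(x, x^2, "max")
  expect_true(ext2$flagged)
  expect_equal(ext2$x_star, 10)
})

test_that("fork velocity is recovered from self-generated collision peaks", {
  pr <- two_origin_program(t_fire = c(5, 17), v_f = 5000, sigma_t = 2,
                           len = 400000, pos = c(100000, 300000))
  truth <- simulate_collisions(pr, n_iter = 600, seed = 8)
  obs_peaks <- predicted_collision_peaks(truth)
  fit <- fit_velocity(obs_peaks, pr, v_grid = seq(3000, 7000, by = 1000),
                      n_iter = 400, seed = 12)
  expect_false(fit$flagged)
  expect_lt(abs(fit$optimum - 5000), 1000)
})

test_that("peak pairing penalizes unmatched predictions instead of failing", {
  ori <- data.frame(chrom = "chr1", pos = c(1e5, 3e5))
  pred <- tibble::tibble(chrom = "chr1", pos = 2e5)
  # no observed peak in the tract: capped penalty of half the tract length
  expect_equal(polusage:::peak_rmsd(pred,
                                    tibble::tibble(chrom = "chr1",
                                                   pos = numeric(0)), ori),
               1e5)
  near <- tibble::tibble(chrom = "chr1", pos = 2.1e5)
  expect_equal(polusage:::peak_rmsd(pred, near, ori), 1e4)
})
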