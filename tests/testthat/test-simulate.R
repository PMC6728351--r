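test_that("a lone deterministic origin replicates the whole chromosome", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 2,
                             seed = 1)
  expect_equal(ts$efficiency$efficiency, 1)
  st <- ts$strandedness
  # top strand is nascent leading right of the origin, lagging left
  expect_true(all(st$top[st$start >= 50000] == 1))
  expect_true(all(st$top[st$end <= 50000] == 0))
  expect_equal(st$top + st$bottom, rep(1, nrow(st)))
})

test_that("fractions sum to one at every bin and strand", {
  pr <- two_origin_program(t_fire = c(4, 9), sigma_t = 2)
  ts <- simulate_replication(pr, n_iterations = 20, seed = 3)
  fr <- ts$fractions
  for (s in c("top", "bottom")) {
    expect_equal(fr$f_alpha[[s]] + fr$f_delta[[s]] + fr$f_epsilon[[s]],
                 rep(1, nrow(fr$f_alpha)), tolerance = 1e-12)
    expect_true(all(fr$f_alpha[[s]] >= -1e-12 & fr$f_alpha[[s]] <= 1 + 1e-12))
  }
})

test_that("simultaneous equidistant origins collide at the midpoint with a delta tract", {
  pr <- two_origin_program()    # origins 50k/150k, equal times, sigma 0
  ts <- simulate_replication(pr, n_iterations = 2, seed = 1)
  expect_equal(unique(ts$collisions$position), 100000)
  fr <- ts$fractions
  # both strands carry elevated Pol delta across the 2*l_coll window
  in_tract <- fr$f_delta$start >= 98000 & fr$f_delta$end <= 102000
  top_tract <- fr$f_delta$top[in_tract & fr$f_delta$end <= 100000]
  bot_tract <- fr$f_delta$bottom[in_tract & fr$f_delta$start >= 100000]
  expect_true(all(top_tract == 1))
  expect_true(all(bot_tract == 1))
  # outside, leading strands are epsilon
  expect_equal(fr$f_epsilon$top[fr$f_delta$start == 90000], 1)
})

test_that("an origin overrun before its firing time is passivated", {
  # fork from A reaches B (100 kb away) after 20 min; B would fire at 60
  pr <- two_origin_program(t_fire = c(0, 60), v_f = 5000, sigma_t = 0)
  ts <- simulate_replication(pr, n_iterations = 5, seed = 2)
  expect_equal(ts$efficiency$efficiency, c(1, 0))
  # everything is replicated by A: top strand leading right of A only
  st <- ts$strandedness
  expect_true(all(st$top[st$start >= 50000] == 1))
})

test_that("initiation units place alpha then delta at each leading strand start", {
  pr <- single_origin_program()   # l_init 180, primer 25 -> 90 bp per fork
  ts <- simulate_replication(pr, n_iterations = 1, seed = 1)
  fr <- ts$fractions
  i <- which(fr$f_alpha$start == 50000)
  expect_equal(fr$f_alpha$top[i], 0.5)    # 25 bp alpha of the first 50 bp bin
  expect_equal(fr$f_delta$top[i], 0.5)    # 25 bp delta
  i2 <- which(fr$f_alpha$start == 50050)
  expect_equal(fr$f_delta$top[i2], 0.8)   # 40 bp delta, 10 bp epsilon
  # mirrored on the bottom strand left of the origin
  j <- which(fr$f_alpha$start == 49950)
  expect_equal(fr$f_alpha$bottom[j], 0.5)
})

test_that("lagging strands carry the expected Okazaki head/body mixture", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  fr <- ts$fractions
  h <- 25 / 165
  j <- which(fr$f_alpha$start == 20000)   # top strand lagging left of origin
  expect_equal(fr$f_alpha$top[j], h, tolerance = 1e-9)
  expect_equal(fr$f_delta$top[j], 1 - h, tolerance = 1e-9)
  expect_equal(fr$f_epsilon$top[j], 0, tolerance = 1e-9)
})

test_that("collision-center spread follows v_f * sigma_t / sqrt(2)", {
  pr <- two_origin_program(t_fire = c(10, 10), sigma_t = 3, v_f = 2000,
                           len = 1000000, pos = c(200000, 800000))
  sim <- simulate_collisions(pr, n_iter = 1000, seed = 4)
  expect_equal(stats::sd(sim$collisions$position),
               2000 * 3 / sqrt(2), tolerance = 0.1)
  # and the mean collision sits at the midpoint for equal firing times
  expect_equal(mean(sim$collisions$position), 500000, tolerance = 0.01)
})

test_that("delaying one origin never increases its realized efficiency", {
  base_t <- 12
  effs <- vapply(c(0, 6, 12, 18), function(delay) {
    pr <- two_origin_program(t_fire = c(0, base_t + delay), v_f = 4000,
                             sigma_t = 4)
    # same seed -> identical normal deviates, only the mean shifts
    ts <- simulate_replication(pr, n_iterations = 60, seed = 9)
    ts$efficiency$efficiency[2]
  }, numeric(1))
  expect_true(all(diff(effs) <= 0))
  expect_lt(effs[4], effs[1])
})

test_that("time rescaling leaves firing outcomes unchanged under a shared seed", {
  s_t <- 3.75
  pr1 <- two_origin_program(t_fire = c(4, 16), sigma_t = 2, v_f = 6000)
  pr2 <- replication_program(c(chr1 = 200000),
                             data.frame(chrom = "chr1",
                                        pos = c(50000, 150000),
                                        t_fire = c(4, 16)),
                             v_f = 6000 / s_t, sigma_t = 2 * s_t, s_t = s_t,
                             l_coll = 2000)
  s1 <- simulate_collisions(pr1, n_iter = 300, seed = 5)
  s2 <- simulate_collisions(pr2, n_iter = 300, seed = 5)
  # with one shared stream the rescaling is an exact symmetry
  expect_equal(s1$efficiency$efficiency, s2$efficiency$efficiency)
  expect_equal(s1$collisions$position, s2$collisions$position,
               tolerance = 1e-9)
})

test_that("ground-truth exports are plain text with the documented columns", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_fractions_tsv(ts, f1)
  tab <- utils::read.table(f1, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("chrom", "start", "end", "strand", "polymerase",
                             "fraction"))
  expect_equal(nrow(tab), 2000 * 6)
  write_efficiency_bed(ts, f2)
  bed <- utils::read.table(f2, sep = "\t")
  expect_equal(bed[[5]], 1000)   # score = 1000 x efficiency
})
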