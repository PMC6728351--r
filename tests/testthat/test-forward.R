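test_that("the measurement model reproduces hand-computed end densities", {
  # f = (0.1, 0.2, 0.7), w = 2: y_epsilon-variant = 2 * (0.05*0.1 + 0.01*0.2
  # + 0.04*0.7) = 0.07, and analogously 0.0556 / 0.1096 for the others
  f <- matrix(c(0.1, 0.2, 0.7), 1, 3)
  r <- test_rates()
  y <- noiseless_tracks(f, w_top = 2, rates = r)
  expect_equal(y[["epsilon-variant"]]$top, 0.07)
  expect_equal(y[["delta-variant"]]$top, 0.0556)
  expect_equal(y[["alpha-variant"]]$top, 0.1096)
  # a pure-epsilon bin in the epsilon-variant strain reads s_epsilon_var
  y1 <- noiseless_tracks(matrix(c(0, 0, 1), 1, 3), rates = r)
  expect_equal(y1[["epsilon-variant"]]$top, r$s_epsilon_var)
})

test_that("forward_model emits one sample per strain/treatment/replicate with shared w", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  noise <- noise_config(replicates = 2)
  samples <- forward_model(ts, polymerase_rates(), noise, seed = 5)
  expect_length(samples, 4 * 2 * 2)
  labels <- vapply(samples, function(s)
    paste(s$strain, s$treatment, s$replicate), character(1))
  expect_equal(anyDuplicated(labels), 0L)
  w <- attr(samples, "w")
  expect_s3_class(w, "strand_track")
  expect_true(all(w$top > 0))
  # unknown strain has no rate entry
  expect_error(forward_model(ts, polymerase_rates(), noise, seed = 5,
                             strains = "zeta-variant"), "strain")
})

test_that("noise off yields exact expectations and depth acts linearly", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  quiet <- noise_config(depth = 100, w_sd = 0, count_noise = FALSE,
                        background = 0, depth_jitter_sd = 0, replicates = 1)
  s1 <- forward_model(ts, test_rates(), quiet, seed = 1,
                      strains = "epsilon-variant")
  quiet2 <- quiet; quiet2$depth <- 200
  s2 <- forward_model(ts, test_rates(), quiet2, seed = 1,
                      strains = "epsilon-variant")
  tr1 <- s1[[1]]$track; tr2 <- s2[[1]]$track
  expect_equal(tr2$top, 2 * tr1$top)
  expect_equal(tr2$bottom, 2 * tr1$bottom)
  expect_equal(2 * s1[[1]]$site_counts, s2[[1]]$site_counts)
  # treated leading-strand bin away from origin reads depth * s_epsilon_var
  i <- which(tr1$start == 90000)
  expect_equal(tr1$top[i], 100 * test_rates()$s_epsilon_var)
  # untreated control carries no polymerase signal without background
  ctrl <- forward_model(ts, test_rates(), quiet, seed = 1,
                        strains = "epsilon-variant")
  expect_true(all(Filter(function(s) s$treatment == "control",
                         ctrl)[[1]]$track$top == 0))
})

test_that("identical seeds give byte-identical samples", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  a <- forward_model(ts, polymerase_rates(), noise_config(replicates = 1),
                     seed = 42)
  b <- forward_model(ts, polymerase_rates(), noise_config(replicates = 1),
                     seed = 42)
  expect_identical(a, b)
})
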