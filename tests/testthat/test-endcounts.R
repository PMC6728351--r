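test_that("normalization factors are medians of site ratios to geometric means", {
  # sites (8, 2, 4) vs (2, 8, 16): geometric means (4, 4, 8);
  # factor_A = median(2, 0.5, 0.5) = 0.5, factor_B = median(0.5, 2, 2) = 2
  a <- tiny_sample(c(8, 2, 4))
  b <- tiny_sample(c(2, 8, 16), strain = "delta-variant")
  out <- normalize_by_sites(list(a, b))
  expect_equal(out[[1]]$norm_factor, 0.5)
  expect_equal(out[[2]]$norm_factor, 2)
  expect_equal(out[[1]]$track$top, rep(20, 10))
  expect_equal(out[[2]]$track$top, rep(5, 10))
})

test_that("a single sample normalizes to factor 1 and sites with zeros are excluded", {
  solo <- normalize_by_sites(list(tiny_sample(c(5, 9))))
  expect_equal(solo[[1]]$norm_factor, 1)
  expect_equal(solo[[1]]$track$top, rep(10, 10))
  # zero at one site in one sample drops that site everywhere
  a <- tiny_sample(c(10, 0))
  b <- tiny_sample(c(5, 7), strain = "delta-variant")
  out <- normalize_by_sites(list(a, b))
  expect_equal(attr(out, "excluded_sites"), "s2")
  gm <- sqrt(10 * 5)
  expect_equal(out[[1]]$norm_factor, 10 / gm)
  expect_equal(out[[2]]$norm_factor, 5 / gm)
  expect_error(normalize_by_sites(list(tiny_sample(0))), "nonzero")
})

test_that("normalization removes per-sample depth up to the provable global factor", {
  # scaling one of n samples by c multiplies every per-site geometric mean
  # by c^(1/n), so every normalized track scales by exactly that global
  # factor; all cross-sample structure is exactly invariant
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  samples <- forward_model(ts, polymerase_rates(),
                           noise_config(replicates = 1), seed = 3)
  scaled <- samples
  c0 <- 3.7
  scaled[[2]]$track$top <- scaled[[2]]$track$top * c0
  scaled[[2]]$track$bottom <- scaled[[2]]$track$bottom * c0
  scaled[[2]]$site_counts <- scaled[[2]]$site_counts * c0
  n1 <- normalize_by_sites(samples)
  n2 <- normalize_by_sites(scaled)
  leak <- c0^(1 / length(samples))
  for (i in seq_along(samples)) {
    expect_equal(n2[[i]]$track$top, leak * n1[[i]]$track$top,
                 tolerance = 1e-12)
    expect_equal(n2[[i]]$track$bottom, leak * n1[[i]]$track$bottom,
                 tolerance = 1e-12)
  }
  # renormalizing normalized samples gives factors of 1
  n3 <- normalize_by_sites(n1)
  expect_true(all(abs(vapply(n3, function(s) s$norm_factor,
                             numeric(1)) - 1) < 1e-12))
})

test_that("replicate averaging takes per-bin means after normalization only", {
  a <- tiny_sample(c(4, 4), value = 2)
  b <- tiny_sample(c(4, 4), value = 4, replicate = 2)
  expect_error(average_replicates(list(a, b)), "normalized")
  ab <- normalize_by_sites(list(a, b))
  m <- average_replicates(ab)
  expect_equal(m$track$top, rep(3, 10))
  expect_equal(m$replicate, "mean")
  expect_equal(attr(m, "n_replicates"), 2)
  # identical replicates average to themselves; (0, 3, 6) averages to 3
  expect_equal(average_replicates(normalize_by_sites(
    list(a, a)))[["track"]]$top, rep(2, 10))
  trio <- normalize_by_sites(list(tiny_sample(c(4, 4), value = 0),
                                  tiny_sample(c(4, 4), value = 3),
                                  tiny_sample(c(4, 4), value = 6)))
  expect_equal(average_replicates(trio)$track$top, rep(3, 10))
  wrong <- normalize_by_sites(list(a, tiny_sample(c(4, 4),
                                                  strain = "delta-variant")))
  expect_error(average_replicates(wrong), "strains")
})

test_that("control subtraction floors at zero and keeps the raw difference", {
  mk <- function(value, treatment) {
    s <- tiny_sample(c(4, 4), value = value, treatment = treatment)
    s$norm_factor <- 1
    s
  }
  y <- subtract_control(mk(5, "treated"), mk(2, "control"))
  expect_equal(y$top, rep(3, 10))
  y2 <- subtract_control(mk(1, "treated"), mk(4, "control"))
  expect_equal(y2$top, rep(0, 10))
  expect_equal(attr(y2, "unfloored")$top, rep(-3, 10))
  # zero control leaves the treated track untouched
  y3 <- subtract_control(mk(5, "treated"), mk(0, "control"))
  expect_equal(y3$top, rep(5, 10))
  bad <- mk(2, "control")
  bad$strain <- "delta-variant"
  expect_error(subtract_control(mk(5, "treated"), bad), "strains")
})

test_that("sample sheets round trip through bedGraph files", {
  ts <- simulate_replication(single_origin_program(), n_iterations = 1,
                             seed = 1)
  samples <- forward_model(ts, polymerase_rates(),
                           noise_config(replicates = 1), seed = 3,
                           strains = "wild-type")
  dir <- tempfile(); dir.create(dir)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    tp <- file.path(dir, paste0("s", i, "_top.bedgraph"))
    bp <- file.path(dir, paste0("s", i, "_bot.bedgraph"))
    write_bedgraph(s$track, tp, "top")
    write_bedgraph(s$track, bp, "bottom")
    data.frame(top_path = tp, bottom_path = bp, strain = s$strain,
               treatment = s$treatment, replicate = s$replicate)
  })
  sheet <- file.path(dir, "sheet.tsv")
  utils::write.table(do.call(rbind, rows), sheet, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sites <- attr(samples, "sites")
  back <- read_samples(sheet, sites, c(chr1 = 100000), 50)
  expect_length(back, length(samples))
  expect_equal(back[[1]]$track$top, samples[[1]]$track$top)
  expect_equal(back[[1]]$strain, samples[[1]]$strain)
})
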