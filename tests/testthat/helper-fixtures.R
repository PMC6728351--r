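# Shared fixture builders. Everything is generated in code; no files.

# one origin mid-chromosome, deterministic firing
single_origin_program <- function(l_coll = 2000, ...) {
  replication_program(c(chr1 = 100000),
                      data.frame(chrom = "chr1", pos = 50000, t_fire = 10),
                      v_f = 2000, sigma_t = 0, l_coll = l_coll, ...)
}

# two origins at 1/4 and 3/4, simultaneous firing
two_origin_program <- function(t_fire = c(5, 5), sigma_t = 0, v_f = 2000,
                               l_coll = 2000, len = 200000,
                               pos = c(50000, 150000), ...) {
  replication_program(c(chr1 = len),
                      data.frame(chrom = "chr1", pos = pos, t_fire = t_fire),
                      v_f = v_f, sigma_t = sigma_t, l_coll = l_coll, ...)
}

# reference rates with well-separated wild-type/variant values
test_rates <- function() {
  polymerase_rates(s_alpha = 0.05, s_delta = 0.01, s_epsilon = 0.004,
                   s_alpha_var = 0.5, s_delta_var = 0.1, s_epsilon_var = 0.04)
}

# noiseless strain tracks for given fraction matrices (one row per bin) and w
noiseless_tracks <- function(f_top, f_bot = f_top, w_top = 1, w_bot = w_top,
                             rates = test_rates(), bin_width = 50) {
  n <- nrow(f_top)
  grid <- strand_track(c(chr1 = bin_width * n), bin_width)
  mk <- function(strain) {
    tr <- grid
    tr$top <- w_top * polusage:::strain_density(strain, rates, f_top[, 1],
                                                f_top[, 2], f_top[, 3])
    tr$bottom <- w_bot * polusage:::strain_density(strain, rates, f_bot[, 1],
                                                   f_bot[, 2], f_bot[, 3])
    tr
  }
  list("wild-type" = mk("wild-type"),
       "alpha-variant" = mk("alpha-variant"),
       "delta-variant" = mk("delta-variant"),
       "epsilon-variant" = mk("epsilon-variant"))
}

# random points on the 3-simplex
random_simplex <- function(n) {
  f <- matrix(stats::rexp(3 * n), ncol = 3)
  f / rowSums(f)
}

# a minimal endcount sample on a tiny grid with given site counts
tiny_sample <- function(site_counts, value = 10, strain = "wild-type",
                        treatment = "treated", replicate = 1) {
  tr <- strand_track(c(chr1 = 500), 50)
  tr$top <- rep(value, 10)
  tr$bottom <- rep(value, 10)
  endcount_sample(strain, treatment, replicate, tr,
                  stats::setNames(site_counts,
                                  paste0("s", seq_along(site_counts))))
}

# fractions object with constant f_epsilon per strand (for DDAF endpoints)
flat_fractions <- function(fe_top, fe_bot, n = 20) {
  grid <- strand_track(c(chr1 = 50 * n), 50)
  fa <- grid; fd <- grid; fe <- grid; w <- grid
  rest_top <- (1 - fe_top) / 2; rest_bot <- (1 - fe_bot) / 2
  fa$top <- rep(rest_top, n); fa$bottom <- rep(rest_bot, n)
  fd$top <- rep(rest_top, n); fd$bottom <- rep(rest_bot, n)
  fe$top <- rep(fe_top, n); fe$bottom <- rep(fe_bot, n)
  w$top <- rep(1, n); w$bottom <- rep(1, n)
  new_synthesis_fractions(fa, fd, fe, w)
}
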