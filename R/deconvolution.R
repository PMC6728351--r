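#' Select single-origin calibration windows from a strandedness track
#'
#' Rate calibration needs genomic windows replicated by forks from a single
#' origin at least `threshold` of the time, where the canonical division of
#' labor holds: there the end density of a variant strain equals that
#' variant's incorporation rate. Windows are maximal runs of bins with
#' F_lead,top >= threshold (top strand purely leading, bottom purely lagging)
#' or <= 1 - threshold (roles swapped), minus an exclusion mask covering
#' origins and termination zones.
#'
#' @param strandedness a `strand_track` from [leading_strandedness()]
#' @param threshold purity threshold in (0.5, 1], default 0.9
#' @param exclude optional mask: data frame with `chrom`, `start`, `end`
#'   (origin initiation tracts and collision tracts); overlapping bins are
#'   dropped before runs are formed
#' @param min_len minimum window length, bp
#' @return tibble of class `calibration_windows`: `chrom`, `start`, `end`,
#'   `strand`, `role` (`pure-leading` / `pure-lagging`); each region appears
#'   twice, once per strand, with complementary roles. The threshold is kept
#'   in attribute `threshold`.
#' @export
select_calibration_windows <- function(strandedness, threshold = 0.9,
                                       exclude = NULL, min_len = 1000) {
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  bw <- bin_width(strandedness)
  masked <- rep(FALSE, nrow(strandedness))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      masked <- masked | (strandedness$chrom == exclude$chrom[i] &
                            strandedness$start < exclude$end[i] &
                            strandedness$end > exclude$start[i])
    }
  }
  runs_of <- function(flag) {
    out <- list()
    for (cm in unique(strandedness$chrom)) {
      sel <- strandedness$chrom == cm
      f <- flag[sel] & !masked[sel]
      f[is.na(f)] <- FALSE
      r <- rle(f)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        s_bp <- strandedness$start[sel][starts[k]]
        e_bp <- strandedness$end[sel][ends[k]]
        if (e_bp - s_bp >= min_len) {
          out[[length(out) + 1L]] <- tibble::tibble(chrom = cm, start = s_bp,
                                                    end = e_bp)
        }
      }
    }
    if (length(out) > 0) do.call(rbind, out) else
      tibble::tibble(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  }
  lead_top <- runs_of(strandedness$top >= threshold)
  lead_bot <- runs_of(strandedness$top <= 1 - threshold)
  two_rows <- function(regions, lead_strand) {
    lag_strand <- setdiff(c("top", "bottom"), lead_strand)
    rbind(cbind(regions, strand = lead_strand, role = "pure-leading"),
          cbind(regions, strand = lag_strand, role = "pure-lagging"))
  }
  out <- rbind(two_rows(lead_top, "top"), two_rows(lead_bot, "bottom"))
  if (nrow(out) == 0) {
    stop("no calibration windows found; consider relaxing the purity threshold")
  }
  out <- tibble::as_tibble(out)
  attr(out, "threshold") <- threshold
  attr(out, "bin_width") <- bw
  class(out) <- c("calibration_windows", class(out))
  out
}

#' Write calibration windows as BED6
#' @param windows a `calibration_windows`
#' @param path output BED file (name = role, strand column = window strand)
#' @export
write_windows_bed <- function(windows, path) {
  df <- data.frame(windows$chrom, windows$start, windows$end, windows$role,
                   0, ifelse(windows$strand == "top", "+", "-"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# mean corrected density over the window bins of one role, per strain track
window_mean <- function(track, windows, role) {
  w <- windows[windows$role == role, ]
  vals <- numeric(0)
  for (i in seq_len(nrow(w))) {
    sel <- track$chrom == w$chrom[i] & track$start >= w$start[i] &
      track$end <= w$end[i]
    vals <- c(vals, track[[w$strand[i]]][sel])
  }
  if (length(vals) == 0 || all(is.na(vals))) {
    stop("no usable bins for role ", role)
  }
  mean(vals, na.rm = TRUE)
}

#' Estimate incorporation rates from calibration windows
#'
#' In pure-leading windows the corrected end density of the Pol epsilon
#' variant strain reads out `s_epsilon_var` directly, and the other strains
#' read out `s_epsilon`; pure-lagging windows read out the Okazaki mixture
#' `h * s_alpha + (1-h) * s_delta` (and its variant-strain analogues), where
#' `h` is the Pol alpha head fraction of an Okazaki fragment. Before rates
#' are extracted, each variant strain is rescaled so that windows synthesized
#' there by wild-type polymerases match the wild-type strain (leading windows
#' for the delta/alpha variants, lagging windows for the epsilon variant).
#'
#' Window means identify `s_epsilon`, `s_epsilon_var` and the three lagging
#' mixtures; splitting Pol alpha from Pol delta additionally requires `h` and
#' the wild-type alpha:delta rate ratio, supplied as priors.
#'
#' @param corrected named list of corrected `strand_track`s (from
#'   [subtract_control()]) with entries `wild-type`, `alpha-variant`,
#'   `delta-variant`, `epsilon-variant`
#' @param windows a `calibration_windows`
#' @param head_fraction Pol alpha head fraction of an Okazaki fragment
#'   (`primer_len / okazaki_len` of the matching program)
#' @param alpha_delta_ratio prior wild-type ratio `s_alpha / s_delta`
#' @return a list of class `rate_estimate`: `rates` (a
#'   [polymerase_rates()]), `rescale_factors`, and `corrected` (the input
#'   tracks with variant strains rescaled — use these for
#'   [solve_fractions()]).
#' @export
estimate_rates <- function(corrected, windows, head_fraction = 25 / 165,
                           alpha_delta_ratio = 8) {
  need <- c("wild-type", "alpha-variant", "delta-variant", "epsilon-variant")
  if (!all(need %in% names(corrected))) {
    stop("corrected tracks required for strains: ",
         paste(setdiff(need, names(corrected)), collapse = ", "))
  }
  lead_wt <- window_mean(corrected[["wild-type"]], windows, "pure-leading")
  lag_wt <- window_mean(corrected[["wild-type"]], windows, "pure-lagging")
  if (lead_wt <= 0 || lag_wt <= 0) {
    stop("zero mean density in a required wild-type window class")
  }
  fac <- c(
    "wild-type" = 1,
    "alpha-variant" = lead_wt /
      window_mean(corrected[["alpha-variant"]], windows, "pure-leading"),
    "delta-variant" = lead_wt /
      window_mean(corrected[["delta-variant"]], windows, "pure-leading"),
    "epsilon-variant" = lag_wt /
      window_mean(corrected[["epsilon-variant"]], windows, "pure-lagging"))
  if (any(!is.finite(fac)) || any(fac <= 0)) {
    stop("degenerate cross-strain rescale factor")
  }
  rescaled <- corrected
  for (s in need) {
    rescaled[[s]]$top <- corrected[[s]]$top * fac[[s]]
    rescaled[[s]]$bottom <- corrected[[s]]$bottom * fac[[s]]
  }
  h <- head_fraction
  rho <- alpha_delta_ratio
  s_epsilon <- lead_wt
  s_epsilon_var <- window_mean(rescaled[["epsilon-variant"]], windows,
                               "pure-leading")
  m_wt <- lag_wt                                  # h s_a + (1-h) s_d
  m_dv <- window_mean(rescaled[["delta-variant"]], windows, "pure-lagging")
  m_av <- window_mean(rescaled[["alpha-variant"]], windows, "pure-lagging")
  s_delta <- m_wt / (rho * h + (1 - h))
  s_alpha <- rho * s_delta
  s_delta_var <- (m_dv - s_alpha * h) / (1 - h)
  s_alpha_var <- (m_av - s_delta * (1 - h)) / h
  rates <- polymerase_rates(s_alpha, s_delta, s_epsilon, s_alpha_var,
                            s_delta_var, s_epsilon_var)
  structure(list(rates = rates, rescale_factors = fac, corrected = rescaled,
                 head_fraction = h, alpha_delta_ratio = rho),
            class = "rate_estimate")
}

#' Solve the three-strain system for per-bin synthesis fractions
#'
#' Per bin and strand, with corrected end counts y from the epsilon-, delta-
#' and alpha-variant strains and the six incorporation rates, the fraction of
#' Pol delta synthesis has the closed form f_delta = (CE - FB)/(FA - CD),
#' where A..F are the bilinear coefficients obtained by eliminating the noise
#' factor w between strain pairs; f_alpha follows by back-substitution,
#' f_epsilon = 1 - f_alpha - f_delta, and w from the epsilon-variant
#' measurement equation.
#'
#' @param y named list of corrected `strand_track`s with entries
#'   `epsilon-variant`, `delta-variant`, `alpha-variant` (use the rescaled
#'   tracks from [estimate_rates()]); `alpha-variant` may be omitted in
#'   two-variant mode.
#' @param rates a [polymerase_rates()]
#' @param coverage_floor bins where any required y falls below this value are
#'   emitted as missing (`NA`), not zero.
#' @param mode `"three-variant"` (full system) or `"two-variant"`: with only
#'   delta- and epsilon-variant strains, Pol alpha is lumped into Pol delta
#'   (f_delta = -B/A, f_alpha = 0); f_epsilon — all the DDAF needs — is
#'   unchanged where true alpha usage is zero.
#' @return a [new_synthesis_fractions()]; degenerate bins (|FA - CD| below a
#'   relative guard) have `solvable = 0` and `NA` fractions.
#' @export
solve_fractions <- function(y, rates, coverage_floor = 0,
                            mode = c("three-variant", "two-variant")) {
  mode <- match.arg(mode)
  need <- c("epsilon-variant", "delta-variant")
  if (mode == "three-variant") need <- c(need, "alpha-variant")
  if (!all(need %in% names(y))) {
    stop("missing corrected tracks for: ",
         paste(setdiff(need, names(y)), collapse = ", "))
  }
  ye <- y[["epsilon-variant"]]
  yd <- y[["delta-variant"]]
  check_same_grid(ye, yd)
  if (mode == "three-variant") check_same_grid(ye, y[["alpha-variant"]])
  grid <- ye
  out <- list(f_alpha = grid, f_delta = grid, f_epsilon = grid, w = grid,
              solvable = grid)
  for (strand in c("top", "bottom")) {
    v_e <- ye[[strand]]
    v_d <- yd[[strand]]
    v_a <- if (mode == "three-variant") y[["alpha-variant"]][[strand]] else NULL
    low <- is.na(v_e) | is.na(v_d) | v_e < coverage_floor |
      v_d < coverage_floor
    if (!is.null(v_a)) low <- low | is.na(v_a) | v_a < coverage_floor
    A <- v_d * (rates$s_delta - rates$s_epsilon_var) -
      v_e * (rates$s_delta_var - rates$s_epsilon)
    B <- v_d * rates$s_epsilon_var - v_e * rates$s_epsilon
    if (mode == "three-variant") {
      C <- v_e * (rates$s_alpha - rates$s_epsilon) -
        v_d * (rates$s_alpha - rates$s_epsilon_var)
      D <- v_a * (rates$s_delta - rates$s_epsilon_var) -
        v_e * (rates$s_delta - rates$s_epsilon)
      E <- v_a * rates$s_epsilon_var - v_e * rates$s_epsilon
      FF <- v_e * (rates$s_alpha_var - rates$s_epsilon) -
        v_a * (rates$s_alpha - rates$s_epsilon_var)
      den <- FF * A - C * D
      degen <- abs(den) < 1e-12 * (abs(FF * A) + abs(C * D) + 1e-300)
      f_d <- ifelse(degen, NA_real_, (C * E - FF * B) / den)
      f_a <- ifelse(degen, NA_real_, (f_d * A + B) / C)
    } else {
      den <- A
      degen <- abs(den) < 1e-12 * (abs(v_d * (rates$s_delta - rates$s_epsilon_var)) +
                                     abs(v_e * (rates$s_delta_var - rates$s_epsilon)) +
                                     1e-300)
      f_d <- ifelse(degen, NA_real_, -B / den)
      f_a <- ifelse(degen, NA_real_, 0)
    }
    f_e <- 1 - f_a - f_d
    w <- v_e / (rates$s_alpha * f_a + rates$s_epsilon_var * f_e +
                  rates$s_delta * f_d)
    f_d[low] <- NA_real_; f_a[low] <- NA_real_; f_e[low] <- NA_real_
    w[low] <- NA_real_
    out$f_alpha[[strand]] <- f_a
    out$f_delta[[strand]] <- f_d
    out$f_epsilon[[strand]] <- f_e
    out$w[[strand]] <- w
    out$solvable[[strand]] <- as.numeric(!(degen | low))
  }
  new_synthesis_fractions(out$f_alpha, out$f_delta, out$f_epsilon, out$w,
                          out$solvable)
}

#' Rescale Pol epsilon fractions so the smoothed maximum is 1
#'
#' Because calibration windows are only >= 90% single-origin, incorporation
#' rates are slightly underestimated and solved f_epsilon tops out below (or
#' noise pushes it above) 1. The correction divides f_epsilon on both strands
#' by the genome-wide maximum of its smoothed track. This linear rescale
#' changes neither the positions nor the shapes of DDAF peaks, only their
#' scale.
#'
#' @param fractions a `synthesis_fractions`
#' @param window smoothing window in bp used to locate the maximum
#' @return the fractions with `f_epsilon` divided by the maximum and
#'   `epsilon_scale` recording the factor applied
#' @export
rescale_epsilon <- function(fractions, window = 1000) {
  sm <- smooth_track(fractions$f_epsilon, window)
  mx <- max(c(sm$top, sm$bottom), na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("maximum smoothed f_epsilon is not positive; cannot rescale")
  }
  fractions$f_epsilon$top <- fractions$f_epsilon$top / mx
  fractions$f_epsilon$bottom <- fractions$f_epsilon$bottom / mx
  fractions$epsilon_scale <- mx
  fractions
}

#' Noise-factor spread across the three measurement equations
#'
#' On noisy data the three strain equations give slightly different w values;
#' this diagnostic reports, per bin/strand, the w implied by each strain and
#' their relative spread (max - min)/mean.
#'
#' @inheritParams solve_fractions
#' @param fractions solved `synthesis_fractions` for the same grid
#' @return list with per-strand tibbles of w_epsilon, w_delta, w_alpha and
#'   `spread`
#' @export
w_spread <- function(y, rates, fractions) {
  out <- list()
  for (strand in c("top", "bottom")) {
    f_a <- fractions$f_alpha[[strand]]
    f_d <- fractions$f_delta[[strand]]
    f_e <- fractions$f_epsilon[[strand]]
    w_e <- y[["epsilon-variant"]][[strand]] /
      (rates$s_alpha * f_a + rates$s_epsilon_var * f_e + rates$s_delta * f_d)
    w_d <- y[["delta-variant"]][[strand]] /
      (rates$s_alpha * f_a + rates$s_epsilon * f_e + rates$s_delta_var * f_d)
    w_a <- if ("alpha-variant" %in% names(y)) {
      y[["alpha-variant"]][[strand]] /
        (rates$s_alpha_var * f_a + rates$s_epsilon * f_e + rates$s_delta * f_d)
    } else NA_real_
    m <- cbind(w_e, w_d, w_a)
    spread <- (apply(m, 1, max) - apply(m, 1, min)) / rowMeans(m)
    out[[strand]] <- tibble::tibble(w_epsilon = w_e, w_delta = w_d,
                                    w_alpha = w_a, spread = spread)
  }
  out
}
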