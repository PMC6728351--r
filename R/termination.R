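#' Monte Carlo simulation of fork collision tracts
#'
#' Lightweight version of the replication simulator that tracks only firing,
#' passivation and collision points. Per iteration, firing times are drawn
#' from Normal(mean x s_t, sigma_t), origins overrun by a fork before firing
#' are removed, collision points between adjacent fired origins are computed,
#' and a tract of +/- `l_coll` around each collision is laid down. The
#' density of collision tracts (fraction of iterations in which a bin lies
#' inside one; overlapping tracts in one iteration count once) accumulates
#' over iterations. Forks reaching a chromosome end terminate without a
#' collision tract.
#'
#' @param program a [replication_program()]; `v_f`, `sigma_t`, `l_coll` can
#'   be overridden to scan parameter grids without rebuilding it
#' @param v_f,sigma_t,l_coll overrides of the program's globals
#' @param n_iter iterations (the reference protocol runs 1000 near optima and
#'   500 elsewhere)
#' @param seed integer seed
#' @param bin_width density bin width, bp
#' @return list of class `collision_density`: `density` (tibble chrom, start,
#'   end, density), `efficiency` (per-origin tibble: efficiency = 1 -
#'   overrun/n_iter), `collisions` (per-iteration collision points),
#'   `params`, `n_iter`
#' @export
simulate_collisions <- function(program, v_f = program$v_f,
                                sigma_t = program$sigma_t,
                                l_coll = program$l_coll, n_iter = 500,
                                seed = 1, bin_width = 50) {
  stopifnot(inherits(program, "replication_program"), n_iter >= 1)
  set.seed(seed)
  chroms <- names(program$chrom_lengths)
  ori_by_chrom <- split(program$origins, program$origins$chrom)[chroms]
  acc <- lapply(chroms, function(cm)
    numeric(ceiling(program$chrom_lengths[[cm]] / bin_width)))
  names(acc) <- chroms
  fired_count <- stats::setNames(numeric(nrow(program$origins)),
                                 program$origins$label)
  coll <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    coll_it <- list()
    for (cm in chroms) {
      ori <- ori_by_chrom[[cm]]
      L <- program$chrom_lengths[[cm]]
      z <- stats::rnorm(nrow(ori))
      ts <- ori$t_fire * program$s_t + sigma_t * z
      fired <- fire_one(ori$pos, ts, v_f)
      fired_count[ori$label[fired]] <- fired_count[ori$label[fired]] + 1
      xc <- collision_points(ori$pos[fired], ts[fired], v_f)
      if (length(xc) == 0) next
      coll_it[[cm]] <- tibble::tibble(iter = it, chrom = cm, position = xc)
      # union of tracts, then fractional bin coverage
      a <- pmax(xc - l_coll, 0); b <- pmin(xc + l_coll, L)
      if (length(a) > 1) {
        merged_a <- a[1]; merged_b <- b[1]
        for (k in 2:length(a)) {
          if (a[k] <= merged_b[length(merged_b)]) {
            merged_b[length(merged_b)] <- max(merged_b[length(merged_b)], b[k])
          } else {
            merged_a <- c(merged_a, a[k]); merged_b <- c(merged_b, b[k])
          }
        }
        a <- merged_a; b <- merged_b
      }
      dens <- acc[[cm]]
      for (k in seq_along(a)) {
        i0 <- floor(a[k] / bin_width); i1 <- ceiling(b[k] / bin_width) - 1L
        idx <- i0:i1
        ov <- pmin(b[k], (idx + 1) * bin_width) - pmax(a[k], idx * bin_width)
        dens[idx + 1L] <- dens[idx + 1L] + ov / bin_width
      }
      acc[[cm]] <- dens
    }
    coll[[it]] <- if (length(coll_it) > 0) do.call(rbind, coll_it) else NULL
  }
  density <- do.call(rbind, lapply(chroms, function(cm) {
    nb <- length(acc[[cm]])
    tibble::tibble(chrom = cm, start = (seq_len(nb) - 1) * bin_width,
                   end = seq_len(nb) * bin_width,
                   density = acc[[cm]] / n_iter)
  }))
  attr(density, "bin_width") <- bin_width
  efficiency <- tibble::tibble(
    chrom = program$origins$chrom, pos = program$origins$pos,
    label = program$origins$label,
    efficiency = as.numeric(fired_count[program$origins$label]) / n_iter)
  collisions <- if (any(!vapply(coll, is.null, logical(1)))) {
    do.call(rbind, coll)
  } else {
    tibble::tibble(iter = integer(0), chrom = character(0),
                   position = numeric(0))
  }
  structure(list(density = density, efficiency = efficiency,
                 collisions = collisions,
                 params = list(v_f = v_f, sigma_t = sigma_t, l_coll = l_coll,
                               s_t = program$s_t),
                 n_iter = n_iter),
            class = "collision_density")
}

#' @export
print.collision_density <- function(x, ...) {
  cat(sprintf(
    "collision_density: %d iterations at v_f = %g, sigma_t = %g, l_coll = %g; sum of efficiencies %.1f\n",
    x$n_iter, x$params$v_f, x$params$sigma_t, x$params$l_coll,
    sum(x$efficiency$efficiency)))
  invisible(x)
}

#' Mean predicted collision peak positions per adjacent-origin pair
#' @param sim a `collision_density`
#' @return tibble `chrom`, `pos` (mean collision point over iterations)
#' @export
predicted_collision_peaks <- function(sim) {
  cl <- sim$collisions
  if (nrow(cl) == 0) {
    return(tibble::tibble(chrom = character(0), pos = numeric(0)))
  }
  # collisions shift pairing as origins drop in and out; bucket by the
  # inter-origin tract each collision falls in
  ori <- sim$efficiency
  key <- character(nrow(cl)); mid <- numeric(nrow(cl))
  for (cm in unique(cl$chrom)) {
    p <- ori$pos[ori$chrom == cm]
    sel <- cl$chrom == cm
    tract <- findInterval(cl$position[sel], p)
    key[sel] <- paste0(cm, "_", tract)
  }
  agg <- stats::aggregate(cl$position, by = list(chrom = cl$chrom, key = key),
                          FUN = mean)
  tibble::tibble(chrom = agg$chrom, pos = agg$x)[order(agg$chrom, agg$x), ]
}

# locate an interior extremum of a cubic fitted to (x, y)
cubic_extremum <- function(x, y, type = c("min", "max")) {
  type <- match.arg(type)
  fit <- stats::lm(y ~ stats::poly(x, 3, raw = TRUE))
  co <- unname(stats::coef(fit))                  # c0 + c1 x + c2 x^2 + c3 x^3
  disc <- (2 * co[3])^2 - 4 * (3 * co[4]) * co[2]
  x_star <- NA_real_
  flagged <- TRUE
  if (is.finite(disc) && disc >= 0 && co[4] != 0) {
    roots <- (-2 * co[3] + c(-1, 1) * sqrt(disc)) / (2 * 3 * co[4])
    curv <- 6 * co[4] * roots + 2 * co[3]
    ok <- roots >= min(x) & roots <= max(x) &
      (if (type == "min") curv > 0 else curv < 0)
    if (any(ok)) {
      x_star <- roots[ok][1]
      flagged <- FALSE
    }
  }
  if (flagged) {
    x_star <- x[if (type == "min") which.min(y) else which.max(y)]
  }
  predict_at <- function(v) co[1] + co[2] * v + co[3] * v^2 + co[4] * v^3
  list(coefficients = co, x_star = x_star, y_star = predict_at(x_star),
       flagged = flagged, predict = predict_at)
}

# RMSD between predicted collision peaks and observed peaks, pairing each
# predicted peak with the nearest observed peak inside the same inter-origin
# tract; unpaired peaks contribute a penalty capped at half the tract length
peak_rmsd <- function(predicted, observed, origins) {
  if (nrow(predicted) == 0) return(NA_real_)
  d2 <- numeric(nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    cm <- predicted$chrom[i]
    p <- sort(origins$pos[origins$chrom == cm])
    k <- findInterval(predicted$pos[i], p)
    lo <- if (k >= 1) p[k] else 0
    hi <- if (k < length(p)) p[k + 1] else Inf
    obs <- observed$pos[observed$chrom == cm & observed$pos > lo &
                          observed$pos < hi]
    cap <- if (is.finite(hi)) (hi - lo) / 2 else 25000
    d2[i] <- if (length(obs) == 0) cap^2 else
      min(min(abs(obs - predicted$pos[i])), cap)^2
  }
  sqrt(mean(d2))
}

#' Fit the global fork velocity against observed DDAF peak positions
#'
#' Scans a velocity grid, simulating collision peaks at each velocity and
#' scoring the RMSD between predicted collision peaks and observed DDAF peak
#' positions; the scan is fit with a third-order polynomial and the local
#' minimum reported. If no interior minimum exists the best grid value is
#' returned and the result flagged.
#'
#' @param observed_peaks tibble `chrom`, `pos` of observed (termination) DDAF
#'   peak positions
#' @param program a [replication_program()]
#' @param v_grid velocity grid, bp/min (>= 4 points)
#' @param n_iter iterations per grid point
#' @param seed integer seed (one independent stream per grid point)
#' @return list of class `fit_result`
#' @export
fit_velocity <- function(observed_peaks, program, v_grid, n_iter = 500,
                         seed = 1) {
  stopifnot(length(v_grid) >= 4)
  rmsd <- vapply(seq_along(v_grid), function(i) {
    sim <- simulate_collisions(program, v_f = v_grid[i], n_iter = n_iter,
                               seed = seed)
    peak_rmsd(predicted_collision_peaks(sim), observed_peaks,
              program$origins)
  }, numeric(1))
  ext <- cubic_extremum(v_grid, rmsd, "min")
  structure(list(parameter = "v_f", grid = v_grid, objective = rmsd,
                 objective_name = "rmsd_bp",
                 coefficients = ext$coefficients, optimum = ext$x_star,
                 objective_at_optimum = ext$y_star, flagged = ext$flagged,
                 n_iter = n_iter),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s optimum %.4g (%s%s)\n", x$parameter, x$optimum,
              x$objective_name,
              if (x$flagged) ", flagged: no interior extremum" else ""))
  invisible(x)
}

# R^2 (coefficient of determination, 1 - SS_res/SS_tot) of the simulated
# collision density against an observed track over inter-origin tracts,
# excluding a margin around each origin. Computed on the absolute scale:
# both tracks are per-iteration probabilities, and the density amplitude is
# what identifies the collision tract length (rescaling the tracks would
# leave only shape, which barely constrains l_coll). Both tracks receive the
# same moving-average smoothing: an asymmetric kernel would bias the
# tract-length fit, since a longer collision tract mimics smoothing.
ddaf_sim_r2 <- function(sim_density, observed, origins,
                        origin_exclude = 2000, smooth = 0) {
  val_col <- setdiff(names(observed), c("chrom", "start", "end"))[1]
  if (smooth > 0) {
    bw <- attr(sim_density, "bin_width")
    if (is.null(bw)) bw <- sim_density$end[1] - sim_density$start[1]
    for (cm in unique(sim_density$chrom)) {
      sel <- sim_density$chrom == cm
      sim_density$density[sel] <-
        moving_average(sim_density$density[sel], smooth, bw)
    }
    for (cm in unique(observed$chrom)) {
      sel <- observed$chrom == cm
      observed[[val_col]][sel] <-
        moving_average(observed[[val_col]][sel], smooth, bw)
    }
  }
  idx <- match(paste(sim_density$chrom, sim_density$start),
               paste(observed$chrom, observed$start))
  x <- sim_density$density
  y <- observed[[val_col]][idx]
  keep <- !is.na(idx)
  for (i in seq_len(nrow(origins))) {
    keep <- keep & !(sim_density$chrom == origins$chrom[i] &
                       abs(sim_density$start - origins$pos[i]) < origin_exclude)
  }
  x <- x[keep]; y <- y[keep]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  1 - sum((y - x)^2) / sum((y - mean(y))^2)
}

#' Fit firing-time dispersion and collision tract length to an observed DDAF
#'
#' Given the fitted fork velocity: for each candidate `l_coll`, the R^2 of
#' the simulated collision density against the observed DDAF (absolute
#' scale, inter-origin tracts only, identical smoothing on both) is scanned
#' over the `sigma_t` grid and fit with a cubic whose local maximum gives
#' the optimal sigma_t at that l_coll. All scan points share one random
#' stream (common random numbers), so objective differences across the grid
#' reflect the parameters rather than sampling noise. The
#' optimal sigma_t values follow an exponential in l_coll (fit on the log
#' scale); a cubic through (l_coll, max R^2) locates the optimal l_coll, and
#' the exponential gives its sigma_t. A verification run at the joint
#' optimum checks the polynomial prediction within `tolerance` (relative).
#'
#' @param observed a `ddaf_track` (or any chrom/start/end/value tibble
#'   co-binned with the simulation)
#' @param program a [replication_program()]
#' @param v_f fitted fork velocity, bp/min
#' @param sigma_grid,lcoll_grid scan grids (>= 4 points each)
#' @param n_iter iterations per scan point; the verification run uses
#'   `n_iter_verify`
#' @param n_iter_verify iterations for the confirmation run at the optimum
#' @param seed integer seed
#' @param origin_exclude bp around each origin excluded from the comparison
#' @param smooth moving-average window (bp) applied identically to both the
#'   observed track and each simulated density before scoring; symmetric
#'   smoothing is essential since one-sided smoothing mimics a longer
#'   collision tract
#' @param tolerance relative tolerance of the verification (default 0.02)
#' @return list of class `sigma_lcoll_fit`: per-l_coll sigma fits, the
#'   exponential sigma(l_coll) fit with its R^2, the l_coll fit, the joint
#'   optimum, and the verification record
#' @export
fit_sigma_lcoll <- function(observed, program, v_f, sigma_grid, lcoll_grid,
                            n_iter = 500, n_iter_verify = 1000, seed = 1,
                            origin_exclude = 2000, smooth = 1000,
                            tolerance = 0.02) {
  stopifnot(length(sigma_grid) >= 4, length(lcoll_grid) >= 4)
  per_l <- list()
  for (li in seq_along(lcoll_grid)) {
    r2 <- vapply(seq_along(sigma_grid), function(si) {
      sim <- simulate_collisions(program, v_f = v_f,
                                 sigma_t = sigma_grid[si],
                                 l_coll = lcoll_grid[li], n_iter = n_iter,
                                 seed = seed)
      ddaf_sim_r2(sim$density, observed, program$origins, origin_exclude,
                  smooth)
    }, numeric(1))
    ext <- cubic_extremum(sigma_grid, r2, "max")
    per_l[[li]] <- list(l_coll = lcoll_grid[li], sigma_grid = sigma_grid,
                        r2 = r2, sigma_star = ext$x_star,
                        r2_at_star = ext$y_star, flagged = ext$flagged)
  }
  sigma_star <- vapply(per_l, function(p) p$sigma_star, numeric(1))
  r2_max <- vapply(per_l, function(p) p$r2_at_star, numeric(1))
  # exponential sigma*(l_coll) = a exp(b l), fit on the log scale
  ok <- sigma_star > 0
  exp_fit <- stats::lm(log(sigma_star[ok]) ~ lcoll_grid[ok])
  exp_a <- exp(unname(stats::coef(exp_fit)[1]))
  exp_b <- unname(stats::coef(exp_fit)[2])
  exp_r2 <- summary(exp_fit)$r.squared
  l_ext <- cubic_extremum(lcoll_grid, r2_max, "max")
  l_opt <- l_ext$x_star
  sigma_opt <- exp_a * exp(exp_b * l_opt)
  verify_sim <- simulate_collisions(program, v_f = v_f, sigma_t = sigma_opt,
                                    l_coll = l_opt, n_iter = n_iter_verify,
                                    seed = seed + 10007L)
  r2_verify <- ddaf_sim_r2(verify_sim$density, observed, program$origins,
                           origin_exclude, smooth)
  r2_pred <- l_ext$y_star
  verified <- is.finite(r2_verify) && is.finite(r2_pred) &&
    abs(r2_verify - r2_pred) <= tolerance * abs(r2_pred)
  structure(list(
    per_lcoll = per_l,
    sigma_of_lcoll = list(a = exp_a, b = exp_b, r_squared = exp_r2),
    lcoll_fit = list(grid = lcoll_grid, r2_max = r2_max,
                     coefficients = l_ext$coefficients,
                     flagged = l_ext$flagged),
    optimum = list(l_coll = l_opt, sigma_t = sigma_opt, v_f = v_f),
    verification = list(r2_predicted = r2_pred, r2_observed = r2_verify,
                        tolerance = tolerance, verified = verified),
    efficiency = verify_sim$efficiency),
    class = "sigma_lcoll_fit")
}

#' @export
print.sigma_lcoll_fit <- function(x, ...) {
  cat(sprintf(
    "sigma_lcoll_fit: l_coll* = %.0f bp, sigma_t* = %.3g min (exp link R^2 = %.4f)\n",
    x$optimum$l_coll, x$optimum$sigma_t, x$sigma_of_lcoll$r_squared))
  cat(sprintf("  verification: R^2 %.4f vs predicted %.4f (%s)\n",
              x$verification$r2_observed, x$verification$r2_predicted,
              if (x$verification$verified) "within tolerance" else
                "OUTSIDE tolerance"))
  invisible(x)
}

#' Locate broad termination DDAF peaks in inter-origin tracts
#'
#' For each tract between adjacent origins, the position of the maximum of
#' the (optionally smoothed) DDAF outside an exclusion margin around the
#' flanking origins. Tracts shorter than twice the margin are skipped.
#'
#' @param ddaf a `ddaf_track`
#' @param origins tibble with `chrom`, `pos`
#' @param smooth moving-average window in bp applied before peak picking
#' @param origin_exclude margin around each origin, bp
#' @return tibble `chrom`, `pos`, `height`
#' @export
termination_peaks <- function(ddaf, origins, smooth = 2000,
                              origin_exclude = 2000) {
  bw <- attr(ddaf, "bin_width")
  out <- list()
  for (cm in unique(ddaf$chrom)) {
    sel <- ddaf$chrom == cm
    v <- moving_average(ddaf$ddaf[sel], smooth, bw)
    starts <- ddaf$start[sel]
    p <- sort(origins$pos[origins$chrom == cm])
    if (length(p) < 2) next
    for (k in seq_len(length(p) - 1L)) {
      lo <- p[k] + origin_exclude; hi <- p[k + 1L] - origin_exclude
      if (hi - lo < bw) next
      inside <- which(starts >= lo & starts < hi & !is.na(v))
      if (length(inside) == 0) next
      i <- inside[which.max(v[inside])]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = cm, pos = starts[i] + bw / 2, height = v[i])
    }
  }
  if (length(out) > 0) do.call(rbind, out) else
    tibble::tibble(chrom = character(0), pos = numeric(0),
                   height = numeric(0))
}

#' Fitted-parameter presets for the two reference firing-time scales
#'
#' Shipped optimization endpoints for the standard origin timing programs:
#' at the fast clock (alpha-factor-style timing, s_t = 1) v_f = 6 kb/min and
#' sigma_t = 2.6 min; at the slow clock (cdc7-style timing, s_t = 3.75)
#' v_f = 1.6 kb/min and sigma_t = 9.75 min; l_coll = 4.6 kb for both.
#'
#' @param timing `"fast"` or `"slow"`
#' @return named list with v_f, sigma_t, s_t, l_coll
#' @export
termination_presets <- function(timing = c("fast", "slow")) {
  timing <- match.arg(timing)
  if (timing == "fast") {
    list(v_f = 6000, sigma_t = 2.6, s_t = 1, l_coll = 4600)
  } else {
    list(v_f = 1600, sigma_t = 9.75, s_t = 3.75, l_coll = 4600)
  }
}
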