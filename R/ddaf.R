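#' Compute the DDAF track
#'
#' The deviation from the expected Pol delta and alpha fraction of synthesis:
#' DDAF = 1 - f_epsilon,top - f_epsilon,bottom per bin. The canonical
#' division of labor (one strand all epsilon, the other all delta/alpha)
#' gives 0; both strands synthesized by Pols delta and alpha gives 1; both
#' strands by Pol epsilon gives -1. Missing bins propagate.
#'
#' @param fractions a `synthesis_fractions` with (rescaled) f_epsilon on both
#'   strands
#' @param smooth optional moving-average window in bp (0 = unsmoothed)
#' @return tibble of class `ddaf_track` with columns `chrom`, `start`, `end`,
#'   `ddaf`; attributes `bin_width`, `smooth_window` and `epsilon_scale`
#'   (provenance of the f_epsilon rescale).
#' @export
compute_ddaf <- function(fractions, smooth = 0) {
  fe <- fractions$f_epsilon
  ddaf <- 1 - fe$top - fe$bottom
  out <- tibble::tibble(chrom = fe$chrom, start = fe$start, end = fe$end,
                        ddaf = ddaf)
  bw <- bin_width(fe)
  if (smooth > 0) {
    for (cm in unique(out$chrom)) {
      sel <- out$chrom == cm
      out$ddaf[sel] <- moving_average(out$ddaf[sel], smooth, bw)
    }
  }
  attr(out, "bin_width") <- bw
  attr(out, "smooth_window") <- smooth
  attr(out, "epsilon_scale") <- fractions$epsilon_scale
  class(out) <- c("ddaf_track", class(out))
  out
}

#' Write a DDAF (or any single-value) track as bedGraph
#' @param track a `ddaf_track`
#' @param path output file
#' @export
write_ddaf_bedgraph <- function(track, path) {
  keep <- !is.na(track$ddaf)
  utils::write.table(
    data.frame(track$chrom[keep], track$start[keep], track$end[keep],
               track$ddaf[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Anchor-aligned meta-profile of a track
#'
#' Extracts the track in a window of `flank` bp on either side of each
#' oriented anchor (e.g. replication origins oriented by their ACS strand, or
#' predicted collision points). Rows of minus-oriented anchors are reversed
#' so that all rows read left-to-right in anchor orientation. Cells beyond
#' the chromosome end, and cells beyond per-anchor truncation limits (e.g.
#' the member origins flanking a termination zone), are missing and are
#' ignored by the mean curve.
#'
#' @param track a `ddaf_track` (or tibble with chrom/start/end and a value
#'   column)
#' @param anchors data frame with `chrom`, `pos`, optional `strand`
#'   (`"+"`/`"-"`, default `"+"`), optional `trunc_left`/`trunc_right`
#'   (genomic bp; cells outside `[trunc_left, trunc_right]` are dropped)
#' @param flank half-window, bp
#' @param value column of `track` to aggregate (default `"ddaf"`)
#' @return list with `matrix` (anchors x offset bins), `offsets` (bp, bin
#'   centers relative to the anchor), `mean_curve` (column means ignoring
#'   missing cells)
#' @export
aggregate_at_anchors <- function(track, anchors, flank = 1000,
                                 value = "ddaf") {
  bw <- attr(track, "bin_width")
  if (is.null(bw)) bw <- unique(track$end - track$start)[1]
  nb <- as.integer(ceiling(flank / bw))
  offsets <- (seq(-nb, nb - 1L) + 0.5) * bw
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = 2L * nb)
  for (i in seq_len(nrow(anchors))) {
    sel <- which(track$chrom == anchors$chrom[i])
    if (length(sel) == 0) stop("anchor on unknown chromosome: ",
                               anchors$chrom[i])
    anchor_bin <- floor(anchors$pos[i] / bw)
    want <- anchor_bin + seq(-nb, nb - 1L)
    ok <- want >= 0 & want < length(sel)
    row <- rep(NA_real_, 2L * nb)
    row[ok] <- track[[value]][sel[want[ok] + 1L]]
    if ("trunc_left" %in% names(anchors)) {
      centers <- anchors$pos[i] + offsets
      tl <- anchors$trunc_left[i]
      tr <- anchors$trunc_right[i]
      if (!is.na(tl)) row[centers < tl] <- NA_real_
      if (!is.na(tr)) row[centers > tr] <- NA_real_
    }
    if (anchors$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  if ("label" %in% names(anchors)) rownames(mat) <- anchors$label
  mean_curve <- colMeans(mat, na.rm = TRUE)
  mean_curve[is.nan(mean_curve)] <- NA_real_
  list(matrix = mat, offsets = offsets, mean_curve = mean_curve,
       bin_width = bw)
}

#' Baseline-subtracted area under a meta-profile curve
#'
#' The baseline is the mean of the outer `baseline_flank` fraction of bins at
#' each end of the curve (an aggressive estimate, used in the absence of a
#' true baseline; over-subtraction is later corrected by the area-vs-
#' efficiency fit). The area is the sum of (curve - baseline) times bin width
#' over the interior bins; negative areas are permitted.
#'
#' @param curve numeric vector (a `mean_curve`), length >= 10
#' @param bin_width bin width, bp
#' @param baseline_flank fraction of bins per side used for the baseline
#'   (default 0.15, the middle of the 10--20% convention)
#' @return list with `baseline` (DDAF units) and `area` (DDAF x bp)
#' @export
peak_area <- function(curve, bin_width = 50, baseline_flank = 0.15) {
  n <- length(curve)
  if (n < 10) stop("curve too short for baseline estimation")
  k <- max(1L, floor(baseline_flank * n))
  flank_vals <- c(curve[seq_len(k)], curve[seq(n - k + 1L, n)])
  if (all(is.na(flank_vals))) stop("all baseline flank bins are missing")
  baseline <- mean(flank_vals, na.rm = TRUE)
  interior <- curve[seq(k + 1L, n - k)]
  area <- sum(interior - baseline, na.rm = TRUE) * bin_width
  list(baseline = baseline, area = area)
}

#' Per-anchor baseline-subtracted peak areas
#'
#' Applies [peak_area()] to each row of an anchor-aligned matrix (one origin
#' or collision point per row), yielding the per-anchor areas that feed the
#' area-vs-efficiency fit.
#'
#' @inheritParams aggregate_at_anchors
#' @inheritParams peak_area
#' @return tibble with one row per anchor: `area`, `baseline` plus any
#'   `label`/`efficiency` columns carried over from `anchors`
#' @export
peak_areas_by_anchor <- function(track, anchors, flank = 1000,
                                 baseline_flank = 0.15, value = "ddaf") {
  agg <- aggregate_at_anchors(track, anchors, flank, value)
  res <- lapply(seq_len(nrow(agg$matrix)), function(i)
    peak_area(agg$matrix[i, ], agg$bin_width, baseline_flank))
  out <- tibble::tibble(area = vapply(res, `[[`, numeric(1), "area"),
                        baseline = vapply(res, `[[`, numeric(1), "baseline"))
  for (col in intersect(c("label", "efficiency"), names(anchors))) {
    out[[col]] <- anchors[[col]]
  }
  out
}

#' Fit DDAF peak area against origin efficiency
#'
#' Ordinary least squares of per-origin baseline-subtracted peak areas on
#' origin efficiencies. Because the aggressive baseline over-subtracts, the
#' synthesis tract length of a perfectly efficient origin is read off as the
#' extrapolated area at efficiency 1 (slope + intercept).
#'
#' @param areas numeric vector of per-origin areas (DDAF x bp)
#' @param efficiencies matching origin efficiencies in `[0, 1]`
#' @return list of class `peak_fit`: `slope`, `intercept`, `r_squared`,
#'   `area_at_full_efficiency` (bp), `n`
#' @export
tract_length_fit <- function(areas, efficiencies) {
  stopifnot(length(areas) == length(efficiencies))
  if (length(areas) < 3) stop("need at least 3 origins for the fit")
  if (any(efficiencies < 0 | efficiencies > 1)) {
    stop("efficiencies must lie in [0, 1]")
  }
  if (stats::var(efficiencies) == 0) {
    stop("zero variance in efficiency; fit is undefined")
  }
  fit <- stats::lm(areas ~ efficiencies)
  # direct R^2; summary() warns on exact fits
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((areas - mean(areas))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 area_at_full_efficiency = unname(sum(stats::coef(fit))),
                 n = length(areas)),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf(
    "peak_fit: area = %.1f x efficiency + %.1f (R^2 = %.3f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  extrapolated tract at efficiency 1: %.1f bp\n",
              x$area_at_full_efficiency))
  invisible(x)
}
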