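#' Call replication origins from abrupt shifts in Pol epsilon fractions
#'
#' Active origins appear as abrupt, strand-concordant transitions in
#' f_epsilon: on the top strand the fraction steps up left-to-right (lagging
#' to leading), on the bottom strand it steps down. The step statistic at the
#' boundary after bin i is mean(f over the next `window`) minus mean(f over
#' the previous `window`). A call requires a local maximum of the top-strand
#' statistic above `min_shift` paired with a local minimum of the
#' bottom-strand statistic below `-min_shift` within `2 * window` bp; the
#' call position is the midpoint of the paired transition boundaries.
#'
#' @param f_epsilon a `strand_track` of (rescaled) Pol epsilon fractions
#' @param window half-window of the step statistic, bp (>= 2 bins)
#' @param min_shift minimum shift height, fractions (applies after the
#'   f_epsilon rescale)
#' @param mask optional data frame (`chrom`, `start`, `end`) of non-unique
#'   regions (transposons, telomeres, ...); calls inside it are dropped
#' @return tibble of class `origin_calls`, sorted by mean |shift|: `chrom`,
#'   `pos`, `shift_top`, `shift_bottom`, `concordance` (min/max ratio of the
#'   two |shift|s)
#' @export
call_origins <- function(f_epsilon, window = 1000, min_shift = 0.1,
                         mask = NULL) {
  bw <- bin_width(f_epsilon)
  wb <- as.integer(window / bw)
  if (wb < 2) stop("window must span at least 2 bins")
  calls <- list()
  for (cm in unique(f_epsilon$chrom)) {
    sel <- f_epsilon$chrom == cm
    n <- sum(sel)
    if (wb >= n) stop("window longer than chromosome ", cm)
    st <- step_statistic(f_epsilon$top[sel], wb)
    sb <- step_statistic(f_epsilon$bottom[sel], wb)
    up <- local_extrema(st, wb, "max")
    up <- up[st[up] > min_shift]
    dn <- local_extrema(sb, wb, "min")
    dn <- dn[sb[dn] < -min_shift]
    if (length(up) == 0 || length(dn) == 0) next
    for (i in up) {
      j <- dn[which.min(abs(dn - i))]
      if (abs(j - i) * bw > 2 * window) next
      pos <- (i + j) / 2 * bw   # boundary after bin k is at k * bw
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = cm, pos = pos, shift_top = st[i], shift_bottom = sb[j],
        concordance = min(st[i], -sb[j]) / max(st[i], -sb[j]))
    }
  }
  out <- if (length(calls) > 0) do.call(rbind, calls) else
    tibble::tibble(chrom = character(0), pos = numeric(0),
                   shift_top = numeric(0), shift_bottom = numeric(0),
                   concordance = numeric(0))
  if (!is.null(mask) && nrow(out) > 0) {
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(mask))) {
      drop <- drop | (out$chrom == mask$chrom[i] & out$pos >= mask$start[i] &
                        out$pos < mask$end[i])
    }
    out <- out[!drop, ]
  }
  out <- out[order(-(abs(out$shift_top) + abs(out$shift_bottom)) / 2), ]
  class(out) <- c("origin_calls", class(out))
  out
}

# step statistic indexed by the boundary after bin i:
# mean(x[i+1 .. i+w]) - mean(x[i-w+1 .. i]); NA where the window is truncated
step_statistic <- function(x, wb) {
  n <- length(x)
  cs <- c(0, cumsum(ifelse(is.na(x), 0, x)))
  cn <- c(0, cumsum(as.numeric(!is.na(x))))
  i <- seq_len(n)
  right_n <- pmin(i + wb, n) - i
  left_n <- i - pmax(i - wb, 0L)
  num_r <- cs[pmin(i + wb, n) + 1L] - cs[i + 1L]
  den_r <- cn[pmin(i + wb, n) + 1L] - cn[i + 1L]
  num_l <- cs[i + 1L] - cs[pmax(i - wb, 0L) + 1L]
  den_l <- cn[i + 1L] - cn[pmax(i - wb, 0L) + 1L]
  out <- ifelse(den_r > 0 & den_l > 0, num_r / den_r - num_l / den_l,
                NA_real_)
  out[right_n < wb | left_n < wb] <- NA_real_
  out
}

# indices that achieve the extremum of their +/- wb neighborhood (first
# index wins on exact ties, so a flat plateau yields a single candidate)
local_extrema <- function(s, wb, type) {
  n <- length(s)
  s2 <- if (type == "max") ifelse(is.na(s), -Inf, s) else
    ifelse(is.na(s), Inf, -s)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(s[i])) next
    lo <- max(1L, i - wb); hi <- min(n, i + wb)
    nb <- s2[lo:hi]
    if (i - lo + 1L == which.max(nb) && is.finite(max(nb))) idx <- c(idx, i)
  }
  idx
}

#' Write origin calls as BED6 (score = 1000 x mean |shift|, capped at 1000)
#' @param calls an `origin_calls` tibble
#' @param path output BED file
#' @export
write_calls_bed <- function(calls, path) {
  score <- pmin(1000, round(1000 * (abs(calls$shift_top) +
                                      abs(calls$shift_bottom)) / 2))
  df <- data.frame(calls$chrom, pmax(0, calls$pos - 1), calls$pos,
                   paste0("call_", seq_len(nrow(calls))), score, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
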