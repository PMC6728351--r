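#' Binned strand-specific genome tracks
#'
#' A `strand_track` holds one value per fixed-width genomic bin for each of the
#' two strands. Bins tile each chromosome without gaps; all bins share one
#' width. This is the container used for raw end counts, corrected end counts,
#' polymerase synthesis fractions (one track per polymerase) and leading-strand
#' probabilities throughout the package.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp); each
#'   length must be a positive multiple of `bin_width`.
#' @param bin_width bin width in bp (default 50, the resolution at which end
#'   counts are analyzed).
#' @param top,bottom optional numeric vectors of per-bin values (top strand is
#'   5'->3' left-to-right). Default 0.
#' @return a tibble of class `strand_track` with columns `chrom`, `start`,
#'   `end`, `top`, `bottom` (0-based, half-open bins) and attribute
#'   `bin_width`.
#' @export
strand_track <- function(chrom_lengths, bin_width = 50, top = NULL, bottom = NULL) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            bin_width >= 1)
  if (any(chrom_lengths <= 0) || any(chrom_lengths %% bin_width != 0)) {
    stop("chromosome lengths must be positive multiples of the bin width")
  }
  nb <- as.integer(chrom_lengths / bin_width)
  chrom <- rep(names(chrom_lengths), nb)
  start <- unlist(lapply(nb, function(n) (seq_len(n) - 1L) * bin_width),
                  use.names = FALSE)
  n <- length(start)
  if (is.null(top)) top <- numeric(n)
  if (is.null(bottom)) bottom <- numeric(n)
  stopifnot(length(top) == n, length(bottom) == n)
  out <- tibble::tibble(chrom = chrom, start = start, end = start + bin_width,
                        top = as.numeric(top), bottom = as.numeric(bottom))
  attr(out, "bin_width") <- as.numeric(bin_width)
  class(out) <- c("strand_track", class(out))
  out
}

#' @export
bin_width <- function(x) attr(x, "bin_width")

#' Chromosome lengths of a binned track
#' @param x a `strand_track` (or any binned tibble with `chrom` and `end`)
#' @return named numeric vector
#' @export
track_chrom_lengths <- function(x) {
  vapply(split(x$end, factor(x$chrom, levels = unique(x$chrom))), max,
         numeric(1))
}

# keep class/attrs through base subsetting done internally
restore_track <- function(new, template) {
  attr(new, "bin_width") <- attr(template, "bin_width")
  class(new) <- class(template)
  new
}

same_grid <- function(a, b) {
  isTRUE(all.equal(bin_width(a), bin_width(b))) &&
    nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$start == b$start)
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("bin grids mismatch between tracks")
  invisible(TRUE)
}

#' Write one strand of a track as bedGraph
#'
#' Plain 4-column bedGraph (chrom, start, end, value). `NA` bins are dropped,
#' as is conventional for sparse coverage files.
#'
#' @param track a `strand_track`
#' @param path output file
#' @param strand `"top"` or `"bottom"`
#' @export
write_bedgraph <- function(track, path, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  v <- track[[strand]]
  keep <- !is.na(v)
  df <- data.frame(track$chrom[keep], track$start[keep], track$end[keep],
                   v[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-strand bedGraph pair onto a bin grid
#'
#' @param top_path,bottom_path bedGraph files for the two strands
#' @param chrom_lengths,bin_width grid definition; values must land exactly on
#'   this grid (one value per bin).
#' @return a `strand_track`; bins absent from a file are `NA`.
#' @export
read_bedgraph_pair <- function(top_path, bottom_path, chrom_lengths,
                               bin_width = 50) {
  tr <- strand_track(chrom_lengths, bin_width,
                     top = rep(NA_real_, sum(chrom_lengths) / bin_width),
                     bottom = rep(NA_real_, sum(chrom_lengths) / bin_width))
  fill <- function(path, col) {
    bg <- utils::read.table(path, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric"))
    if (any(bg$end - bg$start != bin_width) || any(bg$start %% bin_width != 0))
      stop("bedGraph intervals do not match the bin grid: ", path)
    idx <- match(paste(bg$chrom, bg$start), paste(tr$chrom, tr$start))
    if (anyNA(idx)) stop("bedGraph interval outside the bin grid: ", path)
    tr[[col]][idx] <<- bg$value
  }
  fill(top_path, "top")
  fill(bottom_path, "bottom")
  tr
}

#' Centered moving average of a per-bin vector
#'
#' Centered mean over a window expressed in bp. Missing bins are excluded and
#' the mean renormalized over the covered bins; at chromosome edges the
#' available part of the window is used. For an even number of bins the window
#' extends one bin further to the left.
#'
#' @param x numeric vector of per-bin values (may contain `NA`)
#' @param window window size in bp (positive multiple of `bin_width`)
#' @param bin_width bin width in bp
#' @return numeric vector, same length; `NA` where no bin in the window is
#'   observed.
#' @export
moving_average <- function(x, window, bin_width = 50) {
  if (window < bin_width) stop("smoothing window smaller than bin width")
  if (window %% bin_width != 0) stop("window must be a multiple of bin width")
  nb <- as.integer(window / bin_width)
  if (nb == 1L) return(x)
  left <- (nb - 1L) %/% 2L + (1L - nb %% 2L)  # even windows lean left
  right <- nb - 1L - left
  n <- length(x)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Apply a moving average per chromosome to both strands of a track
#' @inheritParams moving_average
#' @param track a `strand_track`
#' @export
smooth_track <- function(track, window) {
  bw <- bin_width(track)
  for (cm in unique(track$chrom)) {
    sel <- track$chrom == cm
    track$top[sel] <- moving_average(track$top[sel], window, bw)
    track$bottom[sel] <- moving_average(track$bottom[sel], window, bw)
  }
  track
}
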