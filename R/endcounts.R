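#' Normalize samples by restriction-site internal standards
#'
#' For every restriction site, the geometric mean of its end counts across all
#' samples is computed; each sample's normalization factor is the median over
#' sites of (site count / site geometric mean). All track values and site
#' counts are divided by that factor. Sites with a zero count in one or more
#' samples are excluded from the factor computation (no pseudocounts).
#' Restriction sites are used instead of total mapped reads because cut-site
#' ends are blind to ribonucleotide incorporation, making them clean internal
#' standards.
#'
#' @param samples list of [endcount_sample()]s sharing one site panel
#' @return the samples, normalized, each with `norm_factor` set; attribute
#'   `excluded_sites` lists sites dropped by the zero filter.
#' @export
normalize_by_sites <- function(samples) {
  stopifnot(length(samples) >= 1)
  ids <- names(samples[[1]]$site_counts)
  counts <- vapply(samples, function(s) {
    if (!identical(names(s$site_counts), ids)) {
      stop("restriction-site ids differ across samples")
    }
    s$site_counts
  }, numeric(length(ids)))
  counts <- matrix(counts, nrow = length(ids),
                   dimnames = list(ids, NULL))
  keep <- apply(counts > 0, 1, all)
  if (!any(keep)) stop("no restriction site has nonzero counts in all samples")
  cnt <- counts[keep, , drop = FALSE]
  gm <- exp(rowMeans(log(cnt)))
  factors <- apply(cnt / gm, 2, stats::median)
  out <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    s$track$top <- s$track$top / factors[i]
    s$track$bottom <- s$track$bottom / factors[i]
    s$site_counts <- s$site_counts / factors[i]
    s$norm_factor <- factors[i]
    s
  })
  attr(out, "excluded_sites") <- ids[!keep]
  out
}

#' Average replicate samples (after normalization, before background subtraction)
#'
#' @param samples list of normalized [endcount_sample()]s of one strain and
#'   treatment
#' @return a single `endcount_sample` with per-bin arithmetic means,
#'   `replicate = "mean"`; attribute `n_replicates` records the count.
#' @export
average_replicates <- function(samples) {
  stopifnot(length(samples) >= 1)
  strain <- unique(vapply(samples, function(s) s$strain, character(1)))
  treatment <- unique(vapply(samples, function(s) s$treatment, character(1)))
  if (length(strain) != 1) stop("cannot average across strains")
  if (length(treatment) != 1) stop("cannot average across treatments")
  if (any(vapply(samples, function(s) is.na(s$norm_factor), logical(1)))) {
    stop("samples must be normalized before averaging")
  }
  tr <- samples[[1]]$track
  for (s in samples[-1]) check_same_grid(tr, s$track)
  tr$top <- rowMeans(vapply(samples, function(s) s$track$top,
                            numeric(nrow(tr))))
  tr$bottom <- rowMeans(vapply(samples, function(s) s$track$bottom,
                               numeric(nrow(tr))))
  sc <- rowMeans(matrix(unlist(lapply(samples, function(s) s$site_counts)),
                        nrow = length(samples[[1]]$site_counts)))
  names(sc) <- names(samples[[1]]$site_counts)
  out <- endcount_sample(strain, treatment, "mean", tr, sc, norm_factor = 1)
  attr(out, "n_replicates") <- length(samples)
  out
}

#' Subtract the untreated-control background from a treated sample
#'
#' Corrected end counts y = treated - control per bin and strand, floored at
#' zero (negative ribonucleotide densities are unphysical; the raw difference
#' is kept in attribute `unfloored` since the deconvolution algebra tolerates
#' it).
#'
#' @param treated,control replicate-averaged, normalized
#'   [endcount_sample()]s of the same strain
#' @return a `strand_track` of corrected end counts
#' @export
subtract_control <- function(treated, control) {
  if (treated$strain != control$strain) {
    stop("treated and control are from different strains")
  }
  check_same_grid(treated$track, control$track)
  raw <- treated$track
  raw$top <- treated$track$top - control$track$top
  raw$bottom <- treated$track$bottom - control$track$bottom
  out <- raw
  out$top <- pmax(out$top, 0)
  out$bottom <- pmax(out$bottom, 0)
  attr(out, "unfloored") <- raw
  out
}

#' Read a sample sheet and load end-count samples from bedGraph files
#'
#' The sample sheet is a TSV with columns `top_path`, `bottom_path`,
#' `strain`, `treatment`, `replicate`. Site counts are extracted from each
#' track around the given site positions.
#'
#' @param sheet_path sample sheet TSV
#' @param sites data frame with `chrom`, `pos` (e.g. read from a BED3 via
#'   [read_sites_bed()])
#' @param chrom_lengths,bin_width grid the bedGraphs live on
#' @param site_pad bins on each side of a site summed into its count
#' @return list of [endcount_sample()]s
#' @export
read_samples <- function(sheet_path, sites, chrom_lengths, bin_width = 50,
                         site_pad = 1L) {
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  lapply(seq_len(nrow(sheet)), function(i) {
    tr <- read_bedgraph_pair(sheet$top_path[i], sheet$bottom_path[i],
                             chrom_lengths, bin_width)
    sc <- site_counts_from_track(tr, sites, pad = site_pad)
    endcount_sample(sheet$strain[i], sheet$treatment[i], sheet$replicate[i],
                    tr, sc)
  })
}

#' Read restriction-site positions from a BED3 file
#' @param path BED3 file; the site position is taken as the interval start
#' @return tibble with `chrom`, `pos`
#' @export
read_sites_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(chrom = bed[[1]], pos = bed[[2]])
}
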