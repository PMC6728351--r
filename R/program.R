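#' Define a replication program
#'
#' A replication program is the ground truth the simulator runs on: origin
#' positions with mean firing times, a single global fork velocity, a global
#' firing-time dispersion, and the tract lengths governing which polymerase
#' synthesizes which nucleotide.
#'
#' @param chrom_lengths named numeric vector, chromosome lengths in bp.
#' @param origins data frame with columns `chrom`, `pos` (bp), `t_fire`
#'   (mean firing time, minutes) and optionally `label`.
#' @param v_f global fork velocity, bp/min.
#' @param sigma_t standard deviation of firing times, minutes (>= 0).
#' @param s_t dimensionless time scale; all mean firing times are multiplied
#'   by `s_t` before sampling (used to express the same program on a slower
#'   replication clock, e.g. a 3.75-fold stretched S phase).
#' @param l_coll collision half-tract length, bp: within `l_coll` of a fork
#'   collision point the leading strand is synthesized by Pol delta instead of
#'   Pol epsilon, so each collision marks a `2*l_coll` tract.
#' @param l_init total leading-strand initiation tract per origin, bp. Each of
#'   the two leading strands leaving an origin starts with one Okazaki-like
#'   unit of length `l_init/2` (a Pol alpha head of `primer_len` bp, Pol delta
#'   for the rest) before Pol epsilon takes over, so a fully efficient origin
#'   contributes `l_init` bp of non-epsilon leading-strand DNA in total —
#'   roughly one Okazaki fragment at the default 180 bp.
#' @param primer_len Pol alpha head length per synthesis start, bp.
#' @param okazaki_len lagging-strand Okazaki fragment length, bp; each fragment
#'   is a `primer_len` Pol alpha head plus a Pol delta body.
#' @return an object of class `replication_program`.
#' @export
replication_program <- function(chrom_lengths, origins, v_f = 6000,
                                sigma_t = 2.6, s_t = 1, l_coll = 4600,
                                l_init = 180, primer_len = 25,
                                okazaki_len = 165) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  origins <- tibble::as_tibble(origins)
  stopifnot(all(c("chrom", "pos", "t_fire") %in% names(origins)))
  if (!"label" %in% names(origins)) {
    origins$label <- paste0("ori_", seq_len(nrow(origins)))
  }
  if (v_f <= 0 || l_coll <= 0 || l_init <= 0 || primer_len <= 0 ||
      okazaki_len <= 0 || s_t <= 0) {
    stop("v_f, s_t and all tract lengths must be strictly positive")
  }
  if (sigma_t < 0) stop("sigma_t must be >= 0")
  if (primer_len > l_init / 2) {
    stop("primer_len exceeds the per-fork initiation unit (l_init/2)")
  }
  if (primer_len >= okazaki_len) stop("primer_len must be < okazaki_len")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  missing_ori <- setdiff(names(chrom_lengths), unique(origins$chrom))
  if (length(missing_ori) > 0) {
    stop("chromosome(s) without any origin would stay unreplicated: ",
         paste(missing_ori, collapse = ", "))
  }
  if (!all(origins$chrom %in% names(chrom_lengths))) {
    stop("origin on unknown chromosome")
  }
  for (cm in unique(origins$chrom)) {
    p <- origins$pos[origins$chrom == cm]
    if (any(p <= 0) || any(p >= chrom_lengths[[cm]])) {
      stop("origin position outside chromosome bounds on ", cm)
    }
    if (any(diff(p) <= 0)) {
      stop("origin positions must be strictly increasing on ", cm)
    }
  }
  structure(list(chrom_lengths = chrom_lengths, origins = origins, v_f = v_f,
                 sigma_t = sigma_t, s_t = s_t, l_coll = l_coll,
                 l_init = l_init, primer_len = primer_len,
                 okazaki_len = okazaki_len),
            class = "replication_program")
}

#' @export
print.replication_program <- function(x, ...) {
  cat("replication_program:", length(x$chrom_lengths), "chromosome(s),",
      nrow(x$origins), "origins\n")
  cat(sprintf("  v_f = %g bp/min, sigma_t = %g min, s_t = %g\n",
              x$v_f, x$sigma_t, x$s_t))
  cat(sprintf("  l_coll = %g bp, l_init = %g bp, primer = %g bp, okazaki = %g bp\n",
              x$l_coll, x$l_init, x$primer_len, x$okazaki_len))
  invisible(x)
}

#' Read/write a replication program as a YAML config plus origin table
#'
#' The YAML file stores the global parameters and chromosome lengths; the
#' origin table is a TSV with columns chrom, pos, t_fire, label. If
#' `origin_path` is NULL, the origins are embedded in the YAML.
#'
#' @param path YAML file
#' @param origin_path optional TSV with the origin table
#' @return a `replication_program`
#' @export
read_program <- function(path, origin_path = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(origin_path)) {
    ori <- utils::read.table(origin_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  } else {
    ori <- do.call(rbind, lapply(cfg$origins, as.data.frame))
  }
  cl <- unlist(cfg$chrom_lengths)
  args <- cfg[intersect(names(cfg),
                        c("v_f", "sigma_t", "s_t", "l_coll", "l_init",
                          "primer_len", "okazaki_len"))]
  do.call(replication_program,
          c(list(chrom_lengths = cl, origins = ori), args))
}

#' @rdname read_program
#' @param program a `replication_program`
#' @export
write_program <- function(program, path, origin_path = NULL) {
  cfg <- list(chrom_lengths = as.list(program$chrom_lengths),
              v_f = program$v_f, sigma_t = program$sigma_t, s_t = program$s_t,
              l_coll = program$l_coll, l_init = program$l_init,
              primer_len = program$primer_len,
              okazaki_len = program$okazaki_len)
  if (is.null(origin_path)) {
    cfg$origins <- lapply(seq_len(nrow(program$origins)), function(i)
      as.list(program$origins[i, c("chrom", "pos", "t_fire", "label")]))
  } else {
    utils::write.table(program$origins, origin_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
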