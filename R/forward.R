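#' Noise and sequencing-depth configuration for the forward model
#'
#' @param depth sequencing depth scale converting end density into expected
#'   counts: expected treated counts per bin are `depth * w * sum_k(s_k f_k)`
#'   (so with the default rates, wild-type leading-strand bins average about
#'   80 counts at `depth = 1e5`). `depth = 1` with noise off returns the bare
#'   densities of the measurement model.
#' @param w_sd log-scale standard deviation of the multiplicative noise
#'   factor w, drawn log-normal once per bin/strand and shared across strains
#'   and treatments (w depends on position and strand but not on the
#'   polymerase background). 0 disables w noise (w = 1 everywhere).
#' @param count_noise if TRUE, counts are Poisson-sampled around their
#'   expectation; if FALSE the expectation itself is emitted.
#' @param background expected untreated-control end density per nucleotide
#'   (nicks and residual breakage); added to treated samples as well.
#' @param depth_jitter_sd log-scale sd of the per-sample relative depth
#'   factor (library-size variation removed by normalization). 0 disables.
#' @param site_strength expected restriction-site end count per unit of
#'   `depth` (so each site averages `site_strength * depth` counts before
#'   per-sample depth jitter); cut-site ends scale with sequencing depth just
#'   like everything else in the library.
#' @param replicates number of replicates per strain x treatment.
#' @return a list of class `noise_config`
#' @export
noise_config <- function(depth = 1e5, w_sd = 0.15, count_noise = TRUE,
                         background = 2e-5, depth_jitter_sd = 0.2,
                         site_strength = 0.05, replicates = 3) {
  stopifnot(depth > 0, w_sd >= 0, background >= 0, depth_jitter_sd >= 0,
            site_strength > 0, replicates >= 1)
  structure(list(depth = depth, w_sd = w_sd, count_noise = count_noise,
                 background = background, depth_jitter_sd = depth_jitter_sd,
                 site_strength = site_strength, replicates = replicates),
            class = "noise_config")
}

#' One strain x treatment x replicate end-count sample
#'
#' @param strain one of `"wild-type"`, `"alpha-variant"`, `"delta-variant"`,
#'   `"epsilon-variant"`
#' @param treatment `"treated"` (RNase-HII-digested) or `"control"`
#' @param replicate replicate id (character or integer)
#' @param track a `strand_track` of raw or normalized counts
#' @param site_counts named numeric vector of restriction-site end counts
#' @param norm_factor normalization factor (set by [normalize_by_sites()])
#' @return an object of class `endcount_sample`
#' @export
endcount_sample <- function(strain, treatment, replicate, track, site_counts,
                            norm_factor = NA_real_) {
  strain <- match.arg(strain, c("wild-type", "alpha-variant", "delta-variant",
                                "epsilon-variant"))
  treatment <- match.arg(treatment, c("treated", "control"))
  stopifnot(inherits(track, "strand_track"), !is.null(names(site_counts)))
  structure(list(strain = strain, treatment = treatment,
                 replicate = as.character(replicate), track = track,
                 site_counts = site_counts, norm_factor = norm_factor),
            class = "endcount_sample")
}

#' @export
print.endcount_sample <- function(x, ...) {
  cat(sprintf("endcount_sample: %s / %s / rep %s; %d bins, %d sites, factor %s\n",
              x$strain, x$treatment, x$replicate, nrow(x$track),
              length(x$site_counts),
              ifelse(is.na(x$norm_factor), "unset",
                     format(x$norm_factor, digits = 4))))
  invisible(x)
}

#' Generate end-count samples from ground-truth synthesis fractions
#'
#' The forward model of the measurement: the expected treated end count at
#' bin i, strand j, in strain K is `w_ij * sum_k s_kK * f_ijk` times the
#' depth scale, plus a uniform background; the untreated control carries the
#' background only. w is drawn once per bin/strand and shared across all
#' strains, treatments and replicates. Counts are Poisson unless noise is
#' disabled. Restriction-site counts scale with each sample's relative depth
#' factor.
#'
#' @param truth a `true_synthesis` (or bare `synthesis_fractions`)
#' @param rates a [polymerase_rates()]
#' @param noise a [noise_config()]
#' @param seed integer master seed; sample substreams are drawn in a fixed
#'   strain/treatment/replicate order.
#' @param strains strains to emit (default all four)
#' @param sites restriction-site positions: tibble/data.frame with `chrom`,
#'   `pos`; default: one site every 100 kb per chromosome.
#' @return list of [endcount_sample()]s, one per strain x treatment x
#'   replicate, with attribute `w` (the shared noise-factor track).
#' @export
forward_model <- function(truth, rates, noise = noise_config(), seed = 1,
                          strains = c("wild-type", "alpha-variant",
                                      "delta-variant", "epsilon-variant"),
                          sites = NULL) {
  fr <- if (inherits(truth, "true_synthesis")) truth$fractions else truth
  stopifnot(inherits(fr, "synthesis_fractions"),
            inherits(rates, "polymerase_rates"))
  grid <- fr$f_alpha
  bw <- bin_width(grid)
  set.seed(seed)

  if (is.null(sites)) {
    cl <- track_chrom_lengths(grid)
    sites <- do.call(rbind, lapply(names(cl), function(cm) {
      p <- seq(50000, cl[[cm]] - 1, by = 100000)
      if (length(p) == 0) p <- floor(cl[[cm]] / 2)
      data.frame(chrom = cm, pos = p)
    }))
  }
  site_ids <- paste0(sites$chrom, ":", sites$pos)

  n <- nrow(grid)
  w_top <- if (noise$w_sd > 0) stats::rlnorm(n, 0, noise$w_sd) else rep(1, n)
  w_bot <- if (noise$w_sd > 0) stats::rlnorm(n, 0, noise$w_sd) else rep(1, n)
  w_track <- grid; w_track$top <- w_top; w_track$bottom <- w_bot

  draw <- function(mu) if (noise$count_noise) stats::rpois(length(mu), mu) else mu

  out <- list()
  for (strain in strains) {
    dens_top <- strain_density(strain, rates, fr$f_alpha$top, fr$f_delta$top,
                               fr$f_epsilon$top)
    dens_bot <- strain_density(strain, rates, fr$f_alpha$bottom,
                               fr$f_delta$bottom, fr$f_epsilon$bottom)
    for (treatment in c("treated", "control")) {
      for (rep_i in seq_len(noise$replicates)) {
        rel_depth <- if (noise$depth_jitter_sd > 0) {
          stats::rlnorm(1, 0, noise$depth_jitter_sd)
        } else 1
        scale <- noise$depth * rel_depth
        if (treatment == "treated") {
          mu_top <- scale * (w_top * dens_top + noise$background)
          mu_bot <- scale * (w_bot * dens_bot + noise$background)
        } else {
          mu_top <- rep(scale * noise$background, n)
          mu_bot <- rep(scale * noise$background, n)
        }
        tr <- grid
        tr$top <- draw(mu_top)
        tr$bottom <- draw(mu_bot)
        sc <- draw(rep(noise$site_strength * noise$depth * rel_depth,
                       length(site_ids)))
        names(sc) <- site_ids
        out[[length(out) + 1L]] <- endcount_sample(
          strain, treatment, rep_i, tr, sc)
      }
    }
  }
  attr(out, "w") <- w_track
  attr(out, "sites") <- sites
  out
}

#' Extract restriction-site counts from a count track
#'
#' Sums counts (both strands) over a +/- `pad` bin window around each site
#' position, absorbing end-assignment jitter near the cut site.
#'
#' @param track a `strand_track` of counts
#' @param sites data frame with `chrom`, `pos`
#' @param pad number of bins on each side of the site bin (default 1)
#' @return named numeric vector of site counts
#' @export
site_counts_from_track <- function(track, sites, pad = 1L) {
  bw <- bin_width(track)
  out <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sel <- track$chrom == sites$chrom[i] &
      track$start >= (sites$pos[i] %/% bw - pad) * bw &
      track$start <= (sites$pos[i] %/% bw + pad) * bw
    out[i] <- sum(track$top[sel], track$bottom[sel], na.rm = TRUE)
  }
  names(out) <- paste0(sites$chrom, ":", sites$pos)
  out
}
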