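#' Per-bin, per-strand polymerase synthesis fractions
#'
#' Container for the solved (or ground-truth) division of polymerase labor:
#' four aligned `strand_track`s holding f_alpha, f_delta, f_epsilon and the
#' multiplicative noise factor w, plus a logical `solvable` track marking bins
#' where the deconvolution was degenerate or below the coverage floor (such
#' bins carry `NA` fractions and propagate as missing, never as zeros).
#'
#' @param f_alpha,f_delta,f_epsilon,w `strand_track`s on one common grid
#' @param solvable optional `strand_track` of 0/1 flags (default all 1)
#' @return an object of class `synthesis_fractions`
#' @export
new_synthesis_fractions <- function(f_alpha, f_delta, f_epsilon, w,
                                    solvable = NULL) {
  check_same_grid(f_alpha, f_delta)
  check_same_grid(f_alpha, f_epsilon)
  check_same_grid(f_alpha, w)
  if (is.null(solvable)) {
    solvable <- f_alpha
    solvable$top <- as.numeric(!is.na(f_alpha$top))
    solvable$bottom <- as.numeric(!is.na(f_alpha$bottom))
  }
  structure(list(f_alpha = f_alpha, f_delta = f_delta, f_epsilon = f_epsilon,
                 w = w, solvable = solvable, epsilon_scale = 1),
            class = "synthesis_fractions")
}

#' @export
print.synthesis_fractions <- function(x, ...) {
  n <- nrow(x$f_alpha)
  ns <- sum(x$solvable$top == 1, na.rm = TRUE) +
    sum(x$solvable$bottom == 1, na.rm = TRUE)
  cat("synthesis_fractions:", n, "bins x 2 strands;",
      ns, "solvable bin-strands;",
      "epsilon scale", format(x$epsilon_scale, digits = 4), "\n")
  invisible(x)
}

#' Polymerase-specific ribonucleotide incorporation rates
#'
#' End density per nucleotide synthesized, for the three wild-type replicases
#' and their ribonucleotide-promiscuous variants. Every variant must
#' incorporate ribonucleotides faster than its wild-type counterpart.
#'
#' @param s_alpha,s_delta,s_epsilon wild-type rates
#' @param s_alpha_var,s_delta_var,s_epsilon_var variant rates (the Pol alpha
#'   Y869A-like, Pol delta L612G-like and Pol epsilon M644G-like alleles)
#' @return an object of class `polymerase_rates`
#' @export
polymerase_rates <- function(s_alpha = 1.6e-3, s_delta = 2e-4,
                             s_epsilon = 8e-4, s_alpha_var = 1.2e-2,
                             s_delta_var = 2.4e-3, s_epsilon_var = 8e-3) {
  r <- c(s_alpha = s_alpha, s_delta = s_delta, s_epsilon = s_epsilon,
         s_alpha_var = s_alpha_var, s_delta_var = s_delta_var,
         s_epsilon_var = s_epsilon_var)
  if (any(r <= 0)) stop("all incorporation rates must be strictly positive")
  if (s_alpha_var <= s_alpha || s_delta_var <= s_delta ||
      s_epsilon_var <= s_epsilon) {
    stop("variant rates must exceed their wild-type counterparts")
  }
  structure(as.list(r), class = "polymerase_rates")
}

#' @export
print.polymerase_rates <- function(x, ...) {
  cat(sprintf(
    "polymerase_rates (ends/nt): alpha %g (var %g), delta %g (var %g), epsilon %g (var %g)\n",
    x$s_alpha, x$s_alpha_var, x$s_delta, x$s_delta_var, x$s_epsilon,
    x$s_epsilon_var))
  invisible(x)
}

# expected end density (per nt) for one strain given fraction vectors
strain_density <- function(strain, rates, fa, fd, fe) {
  s <- switch(strain,
    "wild-type" = c(rates$s_alpha, rates$s_delta, rates$s_epsilon),
    "alpha-variant" = c(rates$s_alpha_var, rates$s_delta, rates$s_epsilon),
    "delta-variant" = c(rates$s_alpha, rates$s_delta_var, rates$s_epsilon),
    "epsilon-variant" = c(rates$s_alpha, rates$s_delta, rates$s_epsilon_var),
    stop("no rate entry for strain: ", strain))
  s[1] * fa + s[2] * fd + s[3] * fe
}
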