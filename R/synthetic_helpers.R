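#' Build a program with origins of graded efficiency
#'
#' Constructs one small chromosome per target efficiency: an early-firing
#' pacemaker origin at one end and a target origin whose mean firing time is
#' set so that the pacemaker's fork passivates it with the desired
#' probability. With both firing times jittered by `sigma_t`, the target
#' fires when `t_target + sigma Z1 < d/v_f + sigma Z2`, i.e. with probability
#' `pnorm((d/v_f - t_target) / (sigma_t * sqrt(2)))`, which is inverted to
#' place `t_target`. Realized efficiencies are estimated by the simulation
#' itself and should be used as the regressor in downstream fits.
#'
#' @param efficiencies vector of target firing probabilities in (0, 1)
#' @param sigma_t firing-time standard deviation, min
#' @param v_f fork velocity, bp/min
#' @param spacing pacemaker-to-target distance, bp
#' @param chrom_len per-chromosome length, bp
#' @param l_coll collision half-tract, bp. Default 200: this fixture is built
#'   to read out the initiation tract, and conditional on a barely-firing
#'   origin the collision with the passivating fork lands right at that
#'   origin, so sizeable collision tracts would confound the origin windows;
#'   keeping them minimal isolates initiation (termination tract recovery has
#'   its own study on a multi-origin program).
#' @param ... further arguments to [replication_program()] (l_init,
#'   primer_len, okazaki_len)
#' @return a [replication_program()]; target origins are labelled
#'   `target_<i>`, pacemakers `pace_<i>`
#' @export
tiered_efficiency_program <- function(efficiencies, sigma_t = 4,
                                      v_f = 2000, spacing = 35000,
                                      chrom_len = 60000, l_coll = 200, ...) {
  stopifnot(all(efficiencies > 0 & efficiencies < 1))
  n <- length(efficiencies)
  chroms <- sprintf("eff_%02d", seq_len(n))
  t_arr <- spacing / v_f
  t_target <- t_arr - sqrt(2) * sigma_t * stats::qnorm(efficiencies)
  origins <- do.call(rbind, lapply(seq_len(n), function(i) {
    tibble::tibble(chrom = chroms[i], pos = c(5000, 5000 + spacing),
                   t_fire = c(0, t_target[i]),
                   label = c(sprintf("pace_%02d", i),
                             sprintf("target_%02d", i)))
  }))
  replication_program(stats::setNames(rep(chrom_len, n), chroms), origins,
                      v_f = v_f, sigma_t = sigma_t, l_coll = l_coll, ...)
}

#' Multi-origin program for the termination-parameter recovery study
#'
#' Two 2.5 Mb chromosomes with 15 origins each (28 inter-origin tracts),
#' origins roughly every 165 kb with deterministic position jitter and
#' cycling mean firing times between 10 and 30 min, under the fast-clock
#' parameters (v_f 6 kb/min, sigma_t 2.6 min, l_coll 4.6 kb). The varied
#' firing-time offsets displace collision points off tract midpoints, which
#' is what makes the fork velocity identifiable from peak positions.
#'
#' @param ... overrides passed to [replication_program()]
#' @return a [replication_program()]
#' @export
termination_study_program <- function(...) {
  tf <- c(10, 22, 14, 30, 12, 25, 16, 28)
  chroms <- c(chrA = 2500000, chrB = 2500000)
  origins <- do.call(rbind, lapply(names(chroms), function(cm) {
    pos <- seq(100000, 2400000, length.out = 15) +
      rep(c(0, 15000, -15000), 5)
    tibble::tibble(chrom = cm, pos = sort(pos),
                   t_fire = rep(tf, length.out = 15) + (cm == "chrB") * 3)
  }))
  args <- list(...)
  defaults <- list(chrom_lengths = chroms, origins = origins, v_f = 6000,
                   sigma_t = 2.6, l_coll = 4600)
  do.call(replication_program, utils::modifyList(defaults, args))
}
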