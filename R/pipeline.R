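#' Pipeline configuration
#'
#' Bundles the parameters of every stage. All windows are expressed in bp and
#' validated as multiples of the bin width where used.
#'
#' @param program a [replication_program()] (or path to a YAML readable by
#'   [read_program()])
#' @param outdir output directory for stage artifacts and reports (created
#'   if needed); `NULL` keeps everything in memory
#' @param seed master seed recorded in every report; stage substreams are
#'   small fixed offsets from it
#' @param bin_width bin width, bp
#' @param n_iterations iterations of the ground-truth simulation
#' @param noise a [noise_config()]
#' @param mode `"three-variant"` or `"two-variant"`
#' @param rates optional true [polymerase_rates()] for the generator
#' @param window_threshold calibration-window purity threshold
#' @param smooth_window smoothing window for the f_epsilon rescale and origin
#'   calling, bp
#' @param min_shift origin-calling shift threshold (post-rescale fractions)
#' @param flank meta-profile half-window at origins, bp
#' @param baseline_flank baseline fraction per side for peak areas
#' @param v_grid,sigma_grid,lcoll_grid termination-fit scan grids
#' @param n_iter_mc Monte Carlo iterations per scan point
#' @param head_fraction,alpha_delta_ratio rate-calibration priors (defaults
#'   derived from the program's primer and Okazaki lengths and the generator
#'   rates)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(program, outdir = NULL, seed = 1, bin_width = 50,
                            n_iterations = 200, noise = noise_config(),
                            mode = c("three-variant", "two-variant"),
                            rates = polymerase_rates(),
                            window_threshold = 0.9, smooth_window = 1000,
                            min_shift = 0.1, flank = 1000,
                            baseline_flank = 0.15,
                            v_grid = seq(4000, 8000, by = 1000),
                            sigma_grid = seq(1.8, 3.4, by = 0.4),
                            lcoll_grid = seq(2600, 6600, by = 1000),
                            n_iter_mc = 500,
                            head_fraction = NULL, alpha_delta_ratio = NULL) {
  mode <- match.arg(mode)
  if (is.character(program)) program <- read_program(program)
  stopifnot(inherits(program, "replication_program"))
  if (is.null(head_fraction)) {
    head_fraction <- program$primer_len / program$okazaki_len
  }
  if (is.null(alpha_delta_ratio)) {
    alpha_delta_ratio <- rates$s_alpha / rates$s_delta
  }
  structure(as.list(environment()), class = "pipeline_config")
}

state_require <- function(state, what, stage) {
  missing <- setdiff(what, names(state))
  if (length(missing) > 0) {
    stop("stage '", stage, "' needs upstream artifact(s): ",
         paste(missing, collapse = ", "),
         "; run the earlier stage(s) first")
  }
}

report_write <- function(config, name, report) {
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$outdir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Pipeline stages
#'
#' Each stage consumes the artifacts of earlier stages from `state` and
#' returns `state` with its own outputs added; every stage is deterministic
#' given the config and seed and emits a machine-readable JSON report under
#' `outdir`. [run_all()] chains them.
#'
#' @param config a [pipeline_config()]
#' @param state named list of upstream artifacts
#' @return the augmented `state`
#' @export
run_simulate <- function(config, state = list()) {
  truth <- simulate_replication(config$program, config$n_iterations,
                                seed = config$seed,
                                bin_width = config$bin_width)
  strains <- if (config$mode == "two-variant") {
    c("wild-type", "delta-variant", "epsilon-variant")
  } else {
    c("wild-type", "alpha-variant", "delta-variant", "epsilon-variant")
  }
  samples <- forward_model(truth, config$rates, config$noise,
                           seed = config$seed + 1L, strains = strains)
  state$truth <- truth
  state$samples <- samples
  state$report_simulate <- report_write(config, "simulate", list(
    seed = config$seed, n_iterations = config$n_iterations,
    n_samples = length(samples), strains = strains,
    mean_efficiency = mean(truth$efficiency$efficiency),
    sum_efficiency = sum(truth$efficiency$efficiency)))
  if (!is.null(config$outdir)) {
    write_efficiency_bed(truth, file.path(config$outdir,
                                          "true_efficiency.bed"))
  }
  state
}

#' @rdname run_simulate
#' @export
run_normalize <- function(config, state) {
  state_require(state, "samples", "normalize")
  normalized <- normalize_by_sites(state$samples)
  strains <- unique(vapply(normalized, function(s) s$strain, character(1)))
  corrected <- list()
  for (strain in strains) {
    treated <- average_replicates(Filter(function(s)
      s$strain == strain && s$treatment == "treated", normalized))
    control <- average_replicates(Filter(function(s)
      s$strain == strain && s$treatment == "control", normalized))
    corrected[[strain]] <- subtract_control(treated, control)
  }
  state$corrected <- corrected
  state$report_normalize <- report_write(config, "normalize", list(
    factors = lapply(normalized, function(s)
      list(strain = s$strain, treatment = s$treatment,
           replicate = s$replicate, factor = s$norm_factor)),
    excluded_sites = attr(normalized, "excluded_sites"),
    n_replicates = config$noise$replicates))
  state
}

#' Exclusion mask around origins and expected termination zones
#'
#' Origin initiation tracts and inter-origin collision neighborhoods,
#' padded; used to keep calibration windows off origins and termination
#' zones.
#'
#' @param program a [replication_program()]
#' @param pad extra bp on each side
#' @return tibble `chrom`, `start`, `end`
#' @export
program_exclusion_mask <- function(program, pad = 1000) {
  ori <- program$origins
  rows <- list()
  for (cm in unique(ori$chrom)) {
    p <- sort(ori$pos[ori$chrom == cm])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = cm, start = pmax(0, p - program$l_init / 2 - pad),
      end = p + program$l_init / 2 + pad)
    if (length(p) > 1) {
      mid <- (p[-length(p)] + p[-1]) / 2
      half <- program$l_coll + program$v_f * program$sigma_t *
        program$s_t + pad
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = cm, start = pmax(0, mid - half), end = mid + half)
    }
  }
  do.call(rbind, rows)
}

#' @rdname run_simulate
#' @export
run_deconvolve <- function(config, state) {
  state_require(state, c("corrected", "truth"), "deconvolve")
  mask <- program_exclusion_mask(config$program)
  windows <- select_calibration_windows(state$truth$strandedness,
                                        threshold = config$window_threshold,
                                        exclude = mask)
  if (config$mode == "three-variant") {
    cal <- estimate_rates(state$corrected, windows,
                          head_fraction = config$head_fraction,
                          alpha_delta_ratio = config$alpha_delta_ratio)
    y <- cal$corrected
    rates <- cal$rates
    state$calibration <- cal
  } else {
    # two-variant designs: rates for the two variant strains only; the
    # wild-type epsilon rate still comes from leading windows
    need <- c("wild-type", "delta-variant", "epsilon-variant")
    absent <- setdiff(need, names(state$corrected))
    if (length(absent) > 0) {
      stop("missing corrected tracks for: ", paste(absent, collapse = ", "))
    }
    lead_wt <- window_mean(state$corrected[["wild-type"]], windows,
                           "pure-leading")
    lag_wt <- window_mean(state$corrected[["wild-type"]], windows,
                          "pure-lagging")
    h <- config$head_fraction
    rho <- config$alpha_delta_ratio
    s_delta <- lag_wt / (rho * h + (1 - h))
    rates <- polymerase_rates(
      s_alpha = rho * s_delta, s_delta = s_delta, s_epsilon = lead_wt,
      s_alpha_var = rho * s_delta * 10,   # unused placeholder in this mode
      s_delta_var = (window_mean(state$corrected[["delta-variant"]], windows,
                                 "pure-lagging") - rho * s_delta * h) /
        (1 - h),
      s_epsilon_var = window_mean(state$corrected[["epsilon-variant"]],
                                  windows, "pure-leading"))
    y <- state$corrected
  }
  fractions <- solve_fractions(y, rates, mode = config$mode)
  fractions <- rescale_epsilon(fractions, window = config$smooth_window)
  state$windows <- windows
  state$rates <- rates
  state$fractions <- fractions
  state$report_deconvolve <- report_write(config, "deconvolve", list(
    n_windows = nrow(windows), threshold = config$window_threshold,
    rates = unclass(rates),
    rescale_factors = if (config$mode == "three-variant")
      as.list(state$calibration$rescale_factors) else NULL,
    epsilon_scale = fractions$epsilon_scale,
    unsolvable_bins = sum(fractions$solvable$top == 0) +
      sum(fractions$solvable$bottom == 0)))
  state
}

#' @rdname run_simulate
#' @export
run_ddaf <- function(config, state) {
  state_require(state, c("fractions", "truth"), "ddaf")
  ddaf <- compute_ddaf(state$fractions)
  anchors <- tibble::tibble(chrom = state$truth$efficiency$chrom,
                            pos = state$truth$efficiency$pos,
                            label = state$truth$efficiency$label,
                            efficiency = state$truth$efficiency$efficiency,
                            strand = "+")
  areas <- peak_areas_by_anchor(ddaf, anchors, flank = config$flank,
                                baseline_flank = config$baseline_flank)
  fit <- tract_length_fit(areas$area, areas$efficiency)
  state$ddaf <- ddaf
  state$origin_areas <- areas
  state$tract_fit <- fit
  state$report_ddaf <- report_write(config, "ddaf", list(
    flank = config$flank, baseline_flank = config$baseline_flank,
    slope = fit$slope, intercept = fit$intercept,
    r_squared = fit$r_squared,
    area_at_full_efficiency = fit$area_at_full_efficiency))
  if (!is.null(config$outdir)) {
    write_ddaf_bedgraph(ddaf, file.path(config$outdir, "ddaf.bedgraph"))
    utils::write.table(areas, file.path(config$outdir, "origin_areas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state
}

#' @rdname run_simulate
#' @export
run_call_origins <- function(config, state) {
  state_require(state, "fractions", "call-origins")
  calls <- call_origins(state$fractions$f_epsilon,
                        window = config$smooth_window,
                        min_shift = config$min_shift)
  state$origin_calls <- calls
  state$report_call_origins <- report_write(config, "call_origins", list(
    n_calls = nrow(calls), window = config$smooth_window,
    min_shift = config$min_shift))
  if (!is.null(config$outdir) && nrow(calls) > 0) {
    write_calls_bed(calls, file.path(config$outdir, "origin_calls.bed"))
  }
  state
}

#' @rdname run_simulate
#' @export
run_fit_termination <- function(config, state) {
  state_require(state, "ddaf", "fit-termination")
  obs_peaks <- termination_peaks(state$ddaf, config$program$origins)
  vfit <- fit_velocity(obs_peaks, config$program, config$v_grid,
                       n_iter = config$n_iter_mc, seed = config$seed + 2L)
  slfit <- fit_sigma_lcoll(state$ddaf, config$program, vfit$optimum,
                           config$sigma_grid, config$lcoll_grid,
                           n_iter = config$n_iter_mc,
                           seed = config$seed + 3L)
  state$velocity_fit <- vfit
  state$sigma_lcoll_fit <- slfit
  state$report_termination <- report_write(config, "fit_termination", list(
    v_grid = config$v_grid, rmsd = vfit$objective, v_opt = vfit$optimum,
    v_flagged = vfit$flagged,
    sigma_grid = config$sigma_grid, lcoll_grid = config$lcoll_grid,
    sigma_opt = slfit$optimum$sigma_t, lcoll_opt = slfit$optimum$l_coll,
    exp_link_r2 = slfit$sigma_of_lcoll$r_squared,
    verification = slfit$verification,
    sum_efficiency = sum(slfit$efficiency$efficiency)))
  state
}

#' @rdname run_simulate
#' @param stages which stages [run_all()] executes, in order
#' @export
run_all <- function(config,
                    stages = c("simulate", "normalize", "deconvolve", "ddaf",
                               "call-origins", "fit-termination")) {
  state <- list()
  for (stage in stages) {
    state <- switch(stage,
      "simulate" = run_simulate(config, state),
      "normalize" = run_normalize(config, state),
      "deconvolve" = run_deconvolve(config, state),
      "ddaf" = run_ddaf(config, state),
      "call-origins" = run_call_origins(config, state),
      "fit-termination" = run_fit_termination(config, state),
      stop("unknown stage: ", stage))
  }
  report <- c(list(seed = config$seed, bin_width = config$bin_width,
                   mode = config$mode),
              state[grep("^report_", names(state))])
  state$report <- report_write(config, "run_report", report)
  state
}
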