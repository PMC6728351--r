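# Core single-iteration firing/passivation engine.
#
# With a constant fork velocity the replication time at any position x is
# min over origins o of (t_o + |x - x_o| / v_f), and an origin fires iff no
# fork from another origin reaches it strictly before its own sampled time
# (an origin overrun exactly at its firing time counts as fired). Chains of
# passivation are handled automatically: if o'' passivates o', then o'' also
# dominates o' at every other position (1D triangle equality), so the min over
# all origins equals the min over fired origins.
fire_one <- function(pos, t_sample, v_f) {
  n <- length(pos)
  if (n == 1L) return(rep(TRUE, n))
  arr <- abs(outer(pos, pos, "-")) / v_f +
    matrix(t_sample, n, n, byrow = TRUE)
  diag(arr) <- Inf
  t_sample <= apply(arr, 1, min)
}

# Collision points between adjacent fired origins; forks reaching a
# chromosome end terminate without a collision tract.
collision_points <- function(pos, t_sample, v_f) {
  m <- length(pos)
  if (m < 2L) return(numeric(0))
  i <- seq_len(m - 1L)
  (pos[i] + pos[i + 1L]) / 2 + v_f * (t_sample[i + 1L] - t_sample[i]) / 2
}

# Bin means of a step function. Pieces are [bp[i], bp[i+1]) (last piece runs
# to the final edge) with value val[i]; bp[1] must be 0 and edges the bin
# boundaries 0, bw, 2bw, ..., L.
step_bin_means <- function(bp, val, edges, bw) {
  seg_end <- c(bp[-1L], edges[length(edges)])
  cum <- c(0, cumsum(val * (seg_end - bp)))
  k <- findInterval(edges, bp)
  integral <- cum[k] + val[k] * (edges - bp[k])
  diff(integral) / bw
}

# Piecewise polymerase composition of one chromosome for one iteration.
# Returns a list of matrices (start, end, fa, fd) for each strand plus the
# top-strand leading indicator pieces, given fired origins and collisions.
iteration_pieces <- function(xo, to, L, program) {
  ph <- program$primer_len
  hu <- program$l_init / 2          # per-fork initiation unit (alpha + delta)
  lc <- program$l_coll
  hfrac <- program$primer_len / program$okazaki_len
  m <- length(xo)
  xc <- collision_points(xo, to, program$v_f)
  b <- c(0, xc, L)                   # region boundaries per fired origin

  top <- list(); bot <- list(); lead <- list()
  for (i in seq_len(m)) {
    s_region <- b[i]; e_region <- b[i + 1L]
    has_left_coll <- i > 1L
    has_right_coll <- i < m
    x <- xo[i]

    # rightward fork, (x, e_region): top leading, bottom lagging
    s <- x; e <- e_region
    if (e > s) {
      a1 <- min(s + ph, e)
      a2 <- min(s + hu, e)
      c1 <- if (has_right_coll) min(max(e - lc, a2), e) else e
      top[[length(top) + 1L]] <- rbind(
        c(s, a1, 1, 0),              # Pol alpha head
        c(a1, a2, 0, 1),             # Pol delta initiation
        c(a2, c1, 0, 0),             # Pol epsilon bulk
        c(c1, e, 0, 1))              # Pol delta collision tract
      bot[[length(bot) + 1L]] <- rbind(c(s, e, hfrac, 1 - hfrac))
      lead[[length(lead) + 1L]] <- rbind(c(s, e, 1))
    }

    # leftward fork, (s_region, x): bottom leading, top lagging
    s <- s_region; e <- x
    if (e > s) {
      a1 <- max(e - ph, s)
      a2 <- max(e - hu, s)
      c1 <- if (has_left_coll) max(min(s + lc, a2), s) else s
      bot[[length(bot) + 1L]] <- rbind(
        c(a1, e, 1, 0),
        c(a2, a1, 0, 1),
        c(c1, a2, 0, 0),
        c(s, c1, 0, 1))
      top[[length(top) + 1L]] <- rbind(c(s, e, hfrac, 1 - hfrac))
      lead[[length(lead) + 1L]] <- rbind(c(s, e, 0))
    }
  }
  list(top = do.call(rbind, top), bottom = do.call(rbind, bot),
       lead = do.call(rbind, lead))
}

piece_bin_means <- function(pieces, edges, bw, value_cols) {
  keep <- pieces[, 2L] > pieces[, 1L]
  pieces <- pieces[keep, , drop = FALSE]
  o <- order(pieces[, 1L])
  pieces <- pieces[o, , drop = FALSE]
  lapply(value_cols, function(j)
    step_bin_means(pieces[, 1L], pieces[, j], edges, bw))
}

#' Simulate a replication program into ground-truth polymerase usage
#'
#' Runs the fork-collision Monte Carlo at nucleotide resolution: per
#' iteration, firing times are drawn from normal distributions around each
#' origin's (time-scaled) mean, origins overrun by a fork before firing are
#' passivated, forks propagate at the global velocity and collide midway
#' (offset by half the firing-time difference times the velocity). Each
#' nucleotide of each nascent strand is assigned a polymerase: leading strands
#' start with an Okazaki-like initiation unit (Pol alpha head then Pol delta,
#' `l_init/2` per fork) before Pol epsilon, and switch back to Pol delta
#' within `l_coll` of a collision point; lagging strands are Okazaki
#' fragments, a Pol alpha head plus Pol delta body, represented by their
#' expected per-nucleotide composition. Iterations are averaged into per-bin
#' synthesis fractions.
#'
#' @param program a [replication_program()]
#' @param n_iterations number of Monte Carlo iterations (>= 1)
#' @param seed integer seed; one master stream drives all iterations in a
#'   fixed order (iterations outer, chromosomes inner), so programs differing
#'   only in a mean firing time see identical normal deviates.
#' @param bin_width bin width for the averaged tracks, bp
#' @return a `true_synthesis` object: list with `fractions` (a
#'   `synthesis_fractions`), `strandedness` (a `strand_track` whose `top`
#'   column is F_lead,top, the probability that the top strand is replicated
#'   as nascent leading strand; `bottom` is its complement), `efficiency`
#'   (tibble with per-origin realized efficiency = fraction of iterations
#'   fired) and `collisions` (tibble of per-iteration collision points).
#' @export
simulate_replication <- function(program, n_iterations = 200, seed = 1,
                                 bin_width = 50) {
  stopifnot(inherits(program, "replication_program"), n_iterations >= 1)
  if (any(program$chrom_lengths %% bin_width != 0)) {
    stop("chromosome lengths must be multiples of the bin width")
  }
  set.seed(seed)
  chroms <- names(program$chrom_lengths)
  ori_by_chrom <- split(program$origins, program$origins$chrom)[chroms]
  edges_by_chrom <- lapply(program$chrom_lengths, function(L)
    seq(0, L, by = bin_width))
  acc <- lapply(chroms, function(cm) {
    nb <- program$chrom_lengths[[cm]] / bin_width
    list(top_fa = numeric(nb), top_fd = numeric(nb),
         bot_fa = numeric(nb), bot_fd = numeric(nb), lead = numeric(nb))
  })
  names(acc) <- chroms
  fired_count <- stats::setNames(numeric(nrow(program$origins)),
                                 program$origins$label)
  coll <- vector("list", n_iterations)

  for (it in seq_len(n_iterations)) {
    coll_it <- list()
    for (cm in chroms) {
      ori <- ori_by_chrom[[cm]]
      L <- program$chrom_lengths[[cm]]
      z <- stats::rnorm(nrow(ori))
      ts <- ori$t_fire * program$s_t + program$sigma_t * z
      fired <- fire_one(ori$pos, ts, program$v_f)
      fired_count[ori$label[fired]] <- fired_count[ori$label[fired]] + 1
      xo <- ori$pos[fired]; to <- ts[fired]
      xc <- collision_points(xo, to, program$v_f)
      if (length(xc) > 0) {
        coll_it[[cm]] <- tibble::tibble(
          iter = it, chrom = cm, left = ori$label[fired][-length(xo)],
          right = ori$label[fired][-1L], position = xc)
      }
      pieces <- iteration_pieces(xo, to, L, program)
      edges <- edges_by_chrom[[cm]]
      tm <- piece_bin_means(pieces$top, edges, bin_width, c(3L, 4L))
      bm <- piece_bin_means(pieces$bottom, edges, bin_width, c(3L, 4L))
      lm_ <- piece_bin_means(pieces$lead, edges, bin_width, 3L)
      a <- acc[[cm]]
      a$top_fa <- a$top_fa + tm[[1L]]; a$top_fd <- a$top_fd + tm[[2L]]
      a$bot_fa <- a$bot_fa + bm[[1L]]; a$bot_fd <- a$bot_fd + bm[[2L]]
      a$lead <- a$lead + lm_[[1L]]
      acc[[cm]] <- a
    }
    coll[[it]] <- if (length(coll_it) > 0) do.call(rbind, coll_it) else NULL
  }

  grid <- strand_track(program$chrom_lengths, bin_width)
  f_alpha <- grid; f_delta <- grid; f_eps <- grid; strandedness <- grid
  for (cm in chroms) {
    sel <- grid$chrom == cm
    a <- acc[[cm]]
    f_alpha$top[sel] <- a$top_fa / n_iterations
    f_alpha$bottom[sel] <- a$bot_fa / n_iterations
    f_delta$top[sel] <- a$top_fd / n_iterations
    f_delta$bottom[sel] <- a$bot_fd / n_iterations
    strandedness$top[sel] <- a$lead / n_iterations
  }
  f_eps$top <- 1 - f_alpha$top - f_delta$top
  f_eps$bottom <- 1 - f_alpha$bottom - f_delta$bottom
  strandedness$bottom <- 1 - strandedness$top

  w <- grid; w$top <- rep(1, nrow(grid)); w$bottom <- rep(1, nrow(grid))
  fractions <- new_synthesis_fractions(f_alpha, f_delta, f_eps, w)
  efficiency <- tibble::tibble(
    chrom = program$origins$chrom, pos = program$origins$pos,
    label = program$origins$label,
    n_fired = as.numeric(fired_count[program$origins$label]),
    n_iterations = n_iterations,
    efficiency = as.numeric(fired_count[program$origins$label]) / n_iterations)
  collisions <- if (any(!vapply(coll, is.null, logical(1)))) {
    do.call(rbind, coll)
  } else {
    tibble::tibble(iter = integer(0), chrom = character(0),
                   left = character(0), right = character(0),
                   position = numeric(0))
  }
  structure(list(fractions = fractions, strandedness = strandedness,
                 efficiency = efficiency, collisions = collisions,
                 program = program, n_iterations = n_iterations, seed = seed),
            class = "true_synthesis")
}

#' @export
print.true_synthesis <- function(x, ...) {
  cat("true_synthesis:", x$n_iterations, "iterations,",
      nrow(x$efficiency), "origins, mean efficiency",
      round(mean(x$efficiency$efficiency), 3), "\n")
  invisible(x)
}

#' Estimate nascent leading-strandedness of the top strand
#'
#' Monte Carlo estimate of F_lead,top: the fraction of iterations in which
#' the top strand at each bin is replicated as the nascent leading strand
#' (i.e. lies right of the origin whose rightward fork replicates it).
#'
#' @inheritParams simulate_replication
#' @return a `strand_track`; `top` holds F_lead,top, `bottom` its complement.
#' @export
leading_strandedness <- function(program, n_iterations = 200, seed = 1,
                                 bin_width = 50) {
  simulate_replication(program, n_iterations, seed, bin_width)$strandedness
}

#' Export ground-truth fractions as a 6-column TSV
#' @param truth a `true_synthesis` or `synthesis_fractions`
#' @param path output TSV (chrom, start, end, strand, polymerase, fraction)
#' @export
write_fractions_tsv <- function(truth, path) {
  fr <- if (inherits(truth, "true_synthesis")) truth$fractions else truth
  long <- do.call(rbind, lapply(c("alpha", "delta", "epsilon"), function(k) {
    tr <- fr[[paste0("f_", k)]]
    do.call(rbind, lapply(c("top", "bottom"), function(s)
      data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                 strand = s, polymerase = k, fraction = tr[[s]])))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export per-origin efficiencies as BED6 (score = 1000 x efficiency)
#' @param truth a `true_synthesis` (or a tibble with chrom/pos/label/efficiency)
#' @param path output BED
#' @export
write_efficiency_bed <- function(truth, path) {
  eff <- if (inherits(truth, "true_synthesis")) truth$efficiency else truth
  df <- data.frame(eff$chrom, eff$pos - 1, eff$pos, eff$label,
                   round(1000 * eff$efficiency), ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
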