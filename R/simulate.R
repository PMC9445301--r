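default_burn_in <- function(params) {
  10 * max(1 / params$d_m, 1 / params$d_p,
           1 / (params$k_on + params$k_off))
}

derive_cell_columns <- function(df) {
  df$ats <- df$g1 + df$g2
  df$total_mrna <- df$m1 + df$m2
  df$total_protein <- df$p1 + df$p2
  df$f_mut_mrna <- ifelse(df$total_mrna > 0, df$m2 / df$total_mrna, NA_real_)
  df$f_mut_protein <- ifelse(df$total_protein > 0,
                             df$p2 / df$total_protein, NA_real_)
  df
}

#' Simulate one cell's bursting trajectory
#'
#' Event-driven (Gillespie direct method) exact simulation of the reaction
#' set {promoter OFF↔ON switching, transcription while ON, mRNA decay,
#' translation, protein decay} for every allele copy independently. Promoter
#' states are initialised at their stationary ON probability; counts start
#' at zero, so trajectories should be read after an initial relaxation.
#'
#' @param params a [burst_params()] object.
#' @param t_end end time (h), > 0.
#' @param seed integer root seed; identical seeds give identical
#'   trajectories.
#' @param times sample times (h); default 201 equally spaced points on
#'   \[0, t_end\].
#' @return A `data.frame` of class `cell_trajectory` with columns `time`,
#'   per-allele-class ON counts `g1`,`g2`, mRNA `m1`,`m2`, protein `p1`,`p2`
#'   and derived columns (`ats`, `total_mrna`, mutant fractions).
#' @export
simulate_cell <- function(params, t_end, seed = 1L, times = NULL) {
  stopifnot(inherits(params, "burst_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("`t_end` must be positive")
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  times <- sort(times)
  if (any(times < 0) || any(times > t_end))
    stop("`times` must lie in [0, t_end]")
  m <- ssa_trajectory_cpp(unclass(params), as.numeric(times),
                          as.numeric(seed))
  df <- derive_cell_columns(as.data.frame(m))
  attr(df, "params") <- params
  attr(df, "seed") <- seed
  class(df) <- c("cell_trajectory", "data.frame")
  df
}

#' Simulate a steady-state population of cells
#'
#' Simulates `n_cells` independent cells, each advanced past a burn-in of at
#' least ten relaxation times (`10 * max(1/d_m, 1/d_p, 1/(k_on+k_off))`),
#' and records one snapshot per cell — the in-silico analogue of a
#' single-time-point tissue section. Each cell runs on its own RNG stream
#' derived deterministically from the root seed.
#'
#' @inheritParams simulate_cell
#' @param n_cells number of cells (>= 1).
#' @param burn_in snapshot time (h); default is the ten-relaxation-time
#'   bound. A shorter user-supplied value triggers a warning.
#' @return An object of class `population_snapshot`: a list with `cells`
#'   (data.frame, one row per cell), `params`, `seed` and `burn_in`.
#' @examples
#' p <- burst_params(1, 3, 40, 1)
#' pop <- simulate_population(p, n_cells = 200, seed = 7)
#' mean(pop$cells$total_mrna)  # ~ 2 * 10
#' @export
simulate_population <- function(params, n_cells, burn_in = NULL, seed = 1L) {
  stopifnot(inherits(params, "burst_params"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("`n_cells` must be >= 1")
  bound <- default_burn_in(params)
  if (is.null(burn_in)) {
    burn_in <- bound
  } else if (burn_in < bound) {
    warning(sprintf(
      "burn_in = %.3g h is below the ten-relaxation-time bound (%.3g h); %s",
      burn_in, bound, "the snapshot may not be stationary"))
  }
  m <- ssa_population_cpp(unclass(params), as.integer(n_cells),
                          as.numeric(burn_in), as.numeric(seed))
  cells <- derive_cell_columns(as.data.frame(m))
  cells$cell_id <- seq_len(nrow(cells))
  structure(list(cells = cells, params = params, seed = seed,
                 burn_in = burn_in),
            class = "population_snapshot")
}

#' @export
print.population_snapshot <- function(x, ...) {
  cat(sprintf("Population snapshot: %d cells (seed %s, burn-in %.1f h)\n",
              nrow(x$cells), format(x$seed), x$burn_in))
  cat(sprintf("  mean total mRNA %.1f, var %.3g, mean aTS %.2f\n",
              mean(x$cells$total_mrna), var(x$cells$total_mrna),
              mean(x$cells$ats)))
  invisible(x)
}

#' Count visible active transcription sites
#'
#' An active transcription site (aTS) is an allele currently in the ON
#' state. With `detection_threshold = 0` (default) every ON allele is
#' visible. A positive threshold models finite FISH sensitivity: each ON
#' allele is visible only with probability
#' `P(Poisson(k_tx * tau_dwell) >= threshold)`, the chance that at least
#' `threshold` nascent transcripts occupy the site (transcript dwell time
#' `tau_dwell` at the site, default 0.1 h).
#'
#' @param cell a `cell_trajectory` row set, `population_snapshot`, or any
#'   data.frame with `g1`/`g2` columns.
#' @param detection_threshold non-negative integer, nascent transcripts
#'   needed for a site to be scored.
#' @param params [burst_params()] (needed when `threshold > 0`); taken from
#'   the object when available.
#' @param tau_dwell nascent-transcript dwell time at the site (h).
#' @param seed seed for the binomial thinning when `threshold > 0`.
#' @return Integer vector of visible aTS per cell; never exceeds the total
#'   allele copy number.
#' @export
ats_count <- function(cell, detection_threshold = 0, params = NULL,
                      tau_dwell = 0.1, seed = 1L) {
  if (inherits(cell, "population_snapshot")) {
    if (is.null(params)) params <- cell$params
    cell <- cell$cells
  }
  if (is.null(params)) params <- attr(cell, "params")
  if (!is.numeric(detection_threshold) || length(detection_threshold) != 1L ||
      detection_threshold < 0)
    stop("`detection_threshold` must be a non-negative number")
  on_alleles <- as.integer(cell$g1 + cell$g2)
  if (detection_threshold == 0) return(on_alleles)
  if (is.null(params))
    stop("`params` required when detection_threshold > 0")
  p_visible <- 1 - ppois(detection_threshold - 1,
                         lambda = params$k_tx * tau_dwell)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  rbinom(length(on_alleles), size = on_alleles, prob = p_visible)
}

#' Derived time series of allelic imbalance and force
#'
#' Converts a simulated trajectory into per-time-point mutant mRNA fraction,
#' mutant protein fraction and relative force at a query pCa. Time points
#' where a fraction is undefined (total count 0) are kept and flagged, never
#' silently dropped.
#'
#' @param trajectory a `cell_trajectory` (>= 2 time points).
#' @param map a [force_map()]; force is computed from the mutant protein
#'   fraction (undefined fractions give `NA` force).
#' @param query_pCa pCa at which force is evaluated.
#' @return data.frame with `time`, `f_mut_mrna`, `f_mut_protein`,
#'   `relative_force`, and logical flags `mrna_undefined`,
#'   `protein_undefined`.
#' @export
trajectory_summary <- function(trajectory, map = force_map(),
                               query_pCa = 5.24) {
  if (!is.data.frame(trajectory) || nrow(trajectory) < 2L)
    stop("`trajectory` must contain at least two time points")
  out <- data.frame(
    time = trajectory$time,
    f_mut_mrna = trajectory$f_mut_mrna,
    f_mut_protein = trajectory$f_mut_protein
  )
  out$mrna_undefined <- is.na(out$f_mut_mrna)
  out$protein_undefined <- is.na(out$f_mut_protein)
  out$relative_force <- force_from_mutant_fraction(out$f_mut_protein, map,
                                                   query_pCa)
  out
}
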