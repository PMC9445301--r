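#' Scenario configuration for the synthetic-data generator
#'
#' Bundles the telegraph-model kinetics, force mapping, measurement-noise
#' block and cohort sizes that one simulated "study" uses. Three scenarios
#' mirror the experimental arms:
#' \describe{
#'   \item{`donor_SNP`}{heterozygous non-pathogenic SNP (rs3729841-like):
#'     symmetric alleles, no force shift. TNNI3-calibrated kinetics
#'     (60% zero-aTS nuclei, 552 copies/cell).}
#'   \item{`TNNI3_missense`}{cTnI R145W-like missense mutation: symmetric
#'     transcription, mutant protein desensitises (delta pCa50 -0.10 at
#'     100% mutant).}
#'   \item{`MYBPC3_truncation`}{cMyBP-C truncation: second-allele
#'     transcripts removed by NMD (haploinsufficiency mosaic);
#'     MYBPC3-calibrated kinetics (about 19% zero-aTS donor nuclei, 2937
#'     copies/cell pre-decay).}
#' }
#' Default noise levels model the wet assays: log-normal band-intensity
#' error (`iod_cv` 0.10) plus replicate-level fraction scatter
#' (`replicate_sd` 5.45 percentage points); at mid-range fractions the
#' two combine to a net per-measurement SD of about 6.5 percentage points
#' — the technical scatter the multialiquot control quantifies. Cq noise
#' 0.2 cycles; force noise 5% CV.
#'
#' @param scenario one of `"donor_SNP"`, `"TNNI3_missense"`,
#'   `"MYBPC3_truncation"`.
#' @param seed root seed recorded in every generated table.
#' @param params optional [burst_params()] override.
#' @param map optional [force_map()] override.
#' @param noise named list overriding any of `iod_cv`, `cq_sd`, `force_cv`,
#'   `replicate_sd` (percentage points), `area_meanlog`, `area_sdlog`,
#'   `area_coupling`.
#' @param cohort named list overriding cohort sizes: `n_nuclei` (aTS
#'   analysis), `n_cells_counts` (copy-number cells), `n_cells_gel`,
#'   `n_aliquots`, `n_cells_force`, `n_population` (simulator population).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("donor_SNP", "TNNI3_missense",
                                         "MYBPC3_truncation"),
                            seed = 1L, params = NULL, map = NULL,
                            noise = list(), cohort = list()) {
  scenario <- match.arg(scenario)
  if (is.null(params)) {
    params <- switch(scenario,
      donor_SNP = calibrate_burst_params(0.60, 552,
                                         var_total_mrna = 3.8e5,
                                         allele_labels = c("WT", "SNP")),
      TNNI3_missense = tnni3_default_params(),
      # MYBPC3 donor summaries: ~19% zero-aTS nuclei, 2937 copies/cell.
      # The printed variance (1.1e7, Fano ~3700) exceeds the telegraph
      # model's intrinsic ceiling at this mean and ON probability
      # (~1100), so the switching timescale is set at the slow-bursting
      # limit s = d_m/10 rather than variance-matched; the remainder is
      # extrinsic noise the two-state model does not carry.
      MYBPC3_truncation = {
        p_on <- 1 - sqrt(0.19)
        s <- (log(2) / 10) / 10
        burst_params(k_on = p_on * s, k_off = (1 - p_on) * s,
                     k_tx = 2937 * (log(2) / 10) / (2 * p_on),
                     d_m = log(2) / 10,
                     allele_labels = c("WT", "trunc"), nmd = TRUE)
      }
    )
  }
  if (is.null(map)) {
    map <- switch(scenario,
      donor_SNP = force_map(pCa50_WT = 5.55, delta_pCa50_homozygous = 0,
                            nH = 2),
      TNNI3_missense = force_map(5.55, -0.10, 2),
      # truncation: force depends on WT-protein dose; the fully
      # cMyBP-C-deficient limit is calcium-sensitised (+0.12 = 2x the
      # printed heterozygous-mean shift 5.59 - 5.53)
      MYBPC3_truncation = force_map(5.53, +0.12, 2)
    )
  }
  # replicate_sd chosen so that, combined with iod_cv, the net fraction
  # scatter at 50% is the 6.5-percentage-point multialiquot technical SD
  noise_def <- list(iod_cv = 0.10, cq_sd = 0.2, force_cv = 0.05,
                    replicate_sd = 5.45, area_meanlog = log(450),
                    area_sdlog = 0.30, area_coupling = 0)
  noise_def[names(noise)] <- noise
  if (any(unlist(noise_def) < 0)) stop("noise parameters must be >= 0")
  # cohort sizes follow the printed experimental ns where available
  cohort_def <- switch(scenario,
    donor_SNP = list(n_nuclei = 300L, n_cells_counts = 41L,
                     n_cells_gel = 44L, n_aliquots = 18L,
                     n_cells_force = 20L, n_population = 10000L),
    TNNI3_missense = list(n_nuclei = 300L, n_cells_counts = 41L,
                          n_cells_gel = 40L, n_aliquots = 18L,
                          n_cells_force = 20L, n_population = 10000L),
    MYBPC3_truncation = list(n_nuclei = 300L, n_cells_counts = 61L,
                             n_cells_gel = 40L, n_aliquots = 18L,
                             n_cells_force = 28L, n_population = 10000L)
  )
  cohort_def[names(cohort)] <- cohort
  structure(list(scenario = scenario, params = params, map = map,
                 noise = noise_def, cohort = cohort_def,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate per-nucleus aTS and per-cell copy-number tables
#'
#' Draws a steady-state population from the telegraph simulator and wraps
#' it into the two measurement tables the quantification stages consume:
#' an aTS table (per-nucleus visible-site counts) and a copy-number table
#' with cell cross-sectional areas. Areas are drawn log-normally and, by
#' default, independently of copy number — the null the size-correlation
#' test should not reject; `noise$area_coupling` > 0 adds a coupling for
#' power studies.
#'
#' @param config a [scenario_config()].
#' @return List with `ats` (data.frame `individual`, `gene`, `nucleus_id`,
#'   `ats_count`), `counts` (data.frame `individual`, `gene`, `cell_id`,
#'   `copies`, `area_um2`, `censored`), and `population` (the underlying
#'   [simulate_population()] snapshot).
#' @export
gen_population_tables <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n_need <- max(config$cohort$n_nuclei, config$cohort$n_cells_counts,
                config$cohort$n_population)
  pop <- simulate_population(config$params, n_cells = n_need,
                             seed = config$seed)
  gene <- switch(config$scenario, MYBPC3_truncation = "MYBPC3", "TNNI3")
  ats <- data.frame(individual = config$scenario, gene = gene,
                    nucleus_id = seq_len(config$cohort$n_nuclei),
                    ats_count = pop$cells$ats[seq_len(config$cohort$n_nuclei)])
  idx <- seq_len(config$cohort$n_cells_counts)
  copies <- pop$cells$total_mrna[idx]
  counts <- with_seed(config$seed + 1L, {
    area <- rlnorm(length(idx),
                   meanlog = config$noise$area_meanlog +
                     config$noise$area_coupling *
                       scale(log1p(copies))[, 1],
                   sdlog = config$noise$area_sdlog)
    # detection limit mirrors the printed "<20" (TNNI3) / "<200" (MYBPC3)
    limit <- if (gene == "MYBPC3") 200 else 20
    data.frame(individual = config$scenario, gene = gene,
               cell_id = idx, copies = copies, area_um2 = area,
               censored = copies < limit)
  })
  list(ats = ats, counts = counts, population = pop)
}

#' Generate gel-lane densitometry with technical replicates
#'
#' Emulates allele-specific restriction gels: per lane, the IOD of each
#' band is `gain * molarity * fragment_length * exp(eps)` with log-normal
#' multiplicative error (`iod_cv`), independently per band and replicate.
#' Replicate-to-replicate scatter of the derived fraction is injected by
#' perturbing the true fraction per replicate with Gaussian noise of SD
#' `replicate_sd` (percentage points, truncated to \[0, 100\]), matching
#' the multialiquot picture of technical scatter.
#'
#' @param config a [scenario_config()].
#' @param true_fractions per-cell true variant fractions (percent).
#' @param assay `"MwoI_TNNI3"` or `"BbsI_SNP"` (default picked by
#'   scenario).
#' @param replicates technical replicates per cell (default 2).
#' @return data.frame with columns `lane_id`, `cell_id`, `assay`,
#'   `replicate`, `band_label`, `fragment_bp`, `iod`, `seed`.
#' @export
gen_gel_lanes <- function(config, true_fractions, assay = NULL,
                          replicates = 2L) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(true_fractions < 0 | true_fractions > 100))
    stop("fractions must lie in [0, 100]")
  if (is.null(assay))
    assay <- if (config$scenario == "donor_SNP") "BbsI_SNP" else
      "MwoI_TNNI3"
  frag <- assay_fragments()[[assay]]
  with_seed(config$seed + 2L, {
    rows <- list()
    lane <- 0L
    for (i in seq_along(true_fractions)) {
      for (r in seq_len(replicates)) {
        lane <- lane + 1L
        f <- true_fractions[i]
        if (config$noise$replicate_sd > 0)
          f <- min(100, max(0, f + rnorm(1, 0, config$noise$replicate_sd)))
        molar <- c(variant = f / 100, reference = 1 - f / 100,
                   common = 1)
        gain <- 1000
        eps <- if (config$noise$iod_cv > 0)
          rnorm(nrow(frag), 0, config$noise$iod_cv) else rep(0, nrow(frag))
        iod <- gain * molar[frag$role] * frag$fragment_bp * exp(eps)
        rows[[lane]] <- data.frame(
          lane_id = lane, cell_id = i, assay = assay, replicate = r,
          band_label = frag$band_label, fragment_bp = frag$fragment_bp,
          iod = as.numeric(iod), seed = config$seed)
      }
    }
    do.call(rbind, rows)
  })
}

#' Measure variant fractions from generated gel lanes
#'
#' Convenience reader pairing [gen_gel_lanes()] output with
#' [fraction_from_iods()]: one fraction per (cell, replicate).
#'
#' @param lanes output of [gen_gel_lanes()].
#' @return data.frame `cell_id`, `replicate`, `fraction`.
#' @export
measure_gel_fractions <- function(lanes) {
  out <- lapply(split(lanes, list(lanes$cell_id, lanes$replicate),
                      drop = TRUE), function(d) {
    frag <- assay_fragments()[[d$assay[1]]]
    d <- merge(d, frag[, c("band_label", "role")], by = "band_label")
    v <- d[d$role == "variant", ]
    r <- d[d$role == "reference", ]
    data.frame(cell_id = d$cell_id[1], replicate = d$replicate[1],
               fraction = fraction_from_iods(v$iod, r$iod,
                                             v$fragment_bp, r$fragment_bp))
  })
  out <- do.call(rbind, out)
  out[order(out$cell_id, out$replicate), , drop = FALSE]
}

#' Generate synthetic force-pCa curves
#'
#' Builds per-cell force-pCa records from mutant protein fractions via the
#' scenario's force map: `force = F_max * F_rel(pCa; f_mut) * (1 + eps)`
#' with multiplicative Gaussian noise (`force_cv`), plus a passive offset
#' at the relaxing point. The default pCa grid spans relaxing (9.0) to
#' maximal activation (4.18) through the intermediate values at which
#' contractile imbalance is scored.
#'
#' @param config a [scenario_config()].
#' @param mutant_fractions per-cell mutant protein fractions in \[0, 1\].
#' @param F_max maximal active force (kN/m^2).
#' @param passive passive force added at relaxing pCa.
#' @param pCa_grid measurement grid.
#' @return data.frame `cell_id`, `group`, `pCa`, `force_kN_m2`,
#'   `f_mut_true`.
#' @export
gen_force_curves <- function(config, mutant_fractions, F_max = 30,
                             passive = 1,
                             pCa_grid = c(9.0, 6.0, 5.9, 5.74, 5.6, 5.54,
                                          5.4, 5.24, 5.0, 4.6, 4.18)) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(mutant_fractions < 0 | mutant_fractions > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  with_seed(config$seed + 3L, {
    rows <- lapply(seq_along(mutant_fractions), function(i) {
      frel <- force_from_mutant_fraction(mutant_fractions[i], config$map,
                                         pCa_grid)
      frel[pCa_grid >= 9.0] <- 0
      eps <- if (config$noise$force_cv > 0)
        rnorm(length(pCa_grid), 0, config$noise$force_cv) else 0
      force <- pmax(0, F_max * frel * (1 + eps) + passive)
      data.frame(cell_id = i, group = config$scenario, pCa = pCa_grid,
                 force_kN_m2 = force, f_mut_true = mutant_fractions[i])
    })
    do.call(rbind, rows)
  })
}

#' Generate qPCR plates (standards and single-cell wells)
#'
#' Standards form a 10-fold dilution series over five decades; every well's
#' Cq is `intercept + slope * log10(copies) + N(0, cq_sd^2)`. Single-cell
#' wells take their true copy numbers from the caller (typically the
#' simulator).
#'
#' @param config a [scenario_config()].
#' @param true_copies per-cell true copy numbers (> 0).
#' @param slope,intercept chemistry of the reaction (default perfect
#'   doubling, slope `-1/log10(2)`).
#' @param standards_decades log10 span of the standard series.
#' @param replicates wells per sample.
#' @return data.frame `sample_id`, `gene`, `role`, `cq`, `known_copies`,
#'   `dilution`, `replicate`.
#' @export
gen_qpcr_plates <- function(config, true_copies,
                            slope = -1 / log10(2), intercept = 38,
                            standards_decades = 5L, replicates = 2L) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(true_copies <= 0)) stop("true copies must be positive")
  gene <- switch(config$scenario, MYBPC3_truncation = "MYBPC3", "TNNI3")
  std_copies <- 10^(seq_len(standards_decades + 1L) - 1L) * 10
  with_seed(config$seed + 4L, {
    mkcq <- function(copies, n) {
      slope * log10(copies) + intercept +
        rnorm(n, 0, config$noise$cq_sd)
    }
    std <- do.call(rbind, lapply(seq_along(std_copies), function(i) {
      data.frame(sample_id = sprintf("std_%d", i), gene = gene,
                 role = "standard",
                 cq = mkcq(std_copies[i], replicates),
                 known_copies = std_copies[i],
                 dilution = 10^(i - 1), replicate = seq_len(replicates))
    }))
    smp <- do.call(rbind, lapply(seq_along(true_copies), function(i) {
      data.frame(sample_id = sprintf("cell_%d", i), gene = gene,
                 role = "sample",
                 cq = mkcq(true_copies[i], replicates),
                 known_copies = NA_real_, dilution = 1,
                 replicate = seq_len(replicates))
    }))
    rbind(std, smp)
  })
}
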