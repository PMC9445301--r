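ks_distance <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  unname(suppressWarnings(ks.test(a, b)$statistic))
}

#' Run the full synthetic study pipeline
#'
#' Generates a synthetic cohort for the requested scenario (plus its donor
#' reference where the scenario is a mutation), pushes it through every
#' quantification stage, and simulates the matching telegraph-model
#' population for comparison. The report contains analogues of the study's
#' six figure-level analyses:
#' \enumerate{
#'   \item aTS distribution (measured-analogue vs simulated), with the
#'     independent-allele model fit;
#'   \item copy-number dispersion (moments, Fano, Poisson dispersion test,
#'     size correlation, bimodality);
#'   \item allelic-fraction distribution from gel densitometry with
#'     replicate QC and the multialiquot cutoff, plus the 4-group Levene
#'     variance comparison (cells vs multialiquot control);
#'   \item western protein levels vs donor (truncation scenarios);
#'   \item force-pCa fits (Hill + two-segment logit) and the donor-vs-
#'     patient location/variance contrast at an intermediate pCa;
#'   \item simulator-vs-measurement KS distances.
#' }
#'
#' @param config a [scenario_config()]; default the TNNI3 missense
#'   scenario.
#' @param out_dir optional directory; when given, per-stage CSV tables, a
#'   JSON summary and a run manifest (config hash, seed, file checksums)
#'   are written there.
#' @param query_pCa intermediate pCa at which contractile imbalance is
#'   scored (default 5.24 for missense, 5.74 for truncation scenarios).
#' @return A list of per-stage results (invisibly also written to
#'   `out_dir`), with elements `ats`, `counts`, `allelic`, `protein`,
#'   `force`, `comparison`, `manifest`.
#' @export
run_paper_pipeline <- function(config = scenario_config("TNNI3_missense"),
                               out_dir = NULL, query_pCa = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(query_pCa))
    query_pCa <- if (config$scenario == "MYBPC3_truncation") 5.74 else 5.24
  # the "respective donor": identical transcription/translation kinetics
  # with the mutation effects switched off (no NMD, no pCa50 shift)
  donor_params <- config$params
  donor_params$nmd <- FALSE
  donor_params$allele_labels <- c("WT", "SNP")
  donor_cfg <- scenario_config("donor_SNP", seed = config$seed + 100L,
                               params = donor_params,
                               cohort = config$cohort)

  ## stage 1: populations and measurement tables
  tabs <- gen_population_tables(config)
  donor_tabs <- gen_population_tables(donor_cfg)

  ## stage 2: aTS analysis
  ats_res <- list(
    distribution = ats_distribution(tabs$ats$ats_count),
    fit = fit_independent_allele_model(tabs$ats$ats_count,
                                       seed = config$seed + 11L)
  )

  ## stage 3: copy-number dispersion
  cc <- tabs$counts
  counts_res <- list(
    moments = dispersion_stats(cc$copies, cc$censored),
    poisson = poisson_dispersion_test(cc$copies, cc$censored),
    size_corr = size_correlation(cc$copies[!cc$censored],
                                 cc$area_um2[!cc$censored]),
    bimodality = bimodality_check(cc$copies, cc$censored)
  )

  ## stage 4: allelic fractions via densitometry with replicate QC
  pop_frac <- tabs$population$cells$f_mut_mrna
  true_frac <- 100 * pop_frac[!is.na(pop_frac)][seq_len(config$cohort$n_cells_gel)]
  lanes <- gen_gel_lanes(config, true_frac)
  meas <- measure_gel_fractions(lanes)
  rep1 <- meas$fraction[meas$replicate == 1]
  rep2 <- meas$fraction[meas$replicate == 2]
  ali_cfg <- config
  ali_cfg$seed <- config$seed + 5L
  ali_lanes <- gen_gel_lanes(ali_cfg, rep(49, config$cohort$n_aliquots),
                             replicates = 1L)
  ali <- measure_gel_fractions(ali_lanes)
  cutoff <- multialiquot_cutoff(ali$fraction)
  qc <- replicate_qc(rep1, rep2, cutoff = cutoff$cutoff)
  passing <- qc$mean[qc$pass]
  lv_groups <- c(rep("cells", length(passing)),
                 rep("multialiquot", nrow(ali)))
  allelic_res <- list(
    multialiquot = cutoff, qc = qc,
    fractions = passing,
    mean_fraction = mean(passing),
    levene_vs_control = levene_test(c(passing, ali$fraction), lv_groups)
  )

  ## stage 5: protein level (haploinsufficiency analogue; with NMD the
  ## mutant contributes no protein so the WT dose carries the level)
  prot_pop <- tabs$population$cells
  donor_pop <- donor_tabs$population$cells
  n_lane_p <- 6L; n_lane_d <- 12L
  mk_lanes <- function(pop, n, group, seed) {
    with_seed(seed, {
      tp <- pop$total_protein[seq_len(n)]
      load_iod <- rlnorm(n, log(1000), config$noise$iod_cv)
      data.frame(lane_id = paste0(group, seq_len(n)), group = group,
                 iod_target = tp * exp(rnorm(n, 0, config$noise$iod_cv)),
                 iod_loading = load_iod)
    })
  }
  lanes_w <- rbind(mk_lanes(donor_pop, n_lane_d, "donor",
                            config$seed + 6L),
                   mk_lanes(prot_pop, n_lane_p, config$scenario,
                            config$seed + 7L))
  protein_res <- protein_level(lanes_w, reference_group = "donor")

  ## stage 6: force-pCa of patient-analogue vs donor cohorts
  fmp <- tabs$population$cells$f_mut_protein
  fmp <- fmp[!is.na(fmp)][seq_len(config$cohort$n_cells_force)]
  if (config$scenario == "MYBPC3_truncation") {
    # force depends on the WT-protein deficit: fully deficient cells sit at
    # the homozygous end of the map
    wt <- tabs$population$cells$p1[seq_len(config$cohort$n_cells_force)]
    ref <- mean(donor_tabs$population$cells$total_protein)
    fmp <- pmin(1, pmax(0, 1 - wt / (ref / 2)))
  }
  curves_p <- gen_force_curves(config, fmp)
  donor_f <- rep(0, donor_cfg$cohort$n_cells_force)
  curves_d <- gen_force_curves(donor_cfg, donor_f)
  fit_cells <- function(curves) {
    out <- lapply(split(curves, curves$cell_id), function(d) {
      hf <- hill_fit(d$pCa, d$force_kN_m2)
      nf <- normalize_forces(d$pCa, d$force_kN_m2)
      at_q <- nf$force_norm[which.min(abs(d$pCa - query_pCa))]
      data.frame(cell_id = d$cell_id[1], F_max = hf$F_max,
                 pCa50 = hf$pCa50, nH = hf$nH, converged = hf$converged,
                 force_at_query = at_q)
    })
    do.call(rbind, out)
  }
  fits_p <- fit_cells(curves_p)
  fits_d <- fit_cells(curves_d)
  cmp <- compare_groups(fits_d$force_at_query, fits_p$force_at_query)
  force_res <- list(patient_fits = fits_p, donor_fits = fits_d,
                    query_pCa = query_pCa, contrast = cmp)

  ## stage 7: simulator-vs-measurement comparison (KS distances)
  fmp_all <- if (config$scenario == "MYBPC3_truncation") {
    pmin(1, pmax(0, 1 - tabs$population$cells$p1 /
                   (mean(donor_tabs$population$cells$total_protein) / 2)))
  } else {
    v <- tabs$population$cells$f_mut_protein
    v[!is.na(v)]
  }
  model_force <- force_from_mutant_fraction(fmp_all, config$map, query_pCa)
  comparison <- list(
    ks_copies = ks_distance(cc$copies,
                            tabs$population$cells$total_mrna),
    ks_fraction = ks_distance(passing / 100,
                              pop_frac[!is.na(pop_frac)]),
    ks_force = ks_distance(fits_p$force_at_query, model_force)
  )

  ## full-population summary (the simulator-side analogue of the printed
  ## cohort means, at the simulated population's n rather than the
  ## measured cohort's)
  pop_cells <- tabs$population$cells
  population_summary <- list(
    n = nrow(pop_cells),
    mean_total_mrna = mean(pop_cells$total_mrna),
    var_total_mrna = var(pop_cells$total_mrna),
    fano_total_mrna = var(pop_cells$total_mrna) /
      mean(pop_cells$total_mrna),
    zero_ats_pct = 100 * mean(pop_cells$ats == 0),
    mean_f_mut_mrna = mean(pop_cells$f_mut_mrna, na.rm = TRUE)
  )

  report <- list(scenario = config$scenario, seed = config$seed,
                 population = population_summary,
                 ats = ats_res, counts = counts_res,
                 allelic = allelic_res, protein = protein_res,
                 force = force_res, comparison = comparison)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      write.csv(df, path, row.names = FALSE)
      path
    }
    files <- c(
      wr(tabs$ats, "ats_table.csv"),
      wr(tabs$counts, "count_table.csv"),
      wr(lanes, "gel_lanes.csv"),
      wr(qc, "allelic_calls.csv"),
      wr(lanes_w, "western_lanes.csv"),
      wr(rbind(curves_p, curves_d), "force_curves.csv"),
      wr(rbind(fits_p, fits_d), "force_fits.csv")
    )
    summary_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      list(scenario = config$scenario, seed = config$seed,
           ats_distribution = as.list(ats_res$distribution),
           p_on_hat = ats_res$fit$p_on_hat,
           copy_moments = counts_res$moments,
           multialiquot_cutoff = cutoff$cutoff,
           mean_fraction = allelic_res$mean_fraction,
           protein_levels = protein_res$group_level,
           force_contrast = cmp,
           ks = comparison),
      summary_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, summary_path)
    manifest <- list(
      scenario = config$scenario, seed = config$seed,
      config_hash = unname(tools::md5sum(summary_path)),
      package_version = as.character(utils::packageVersion("burstmosaic")),
      timestamp = format(Sys.time(), tz = "UTC"),
      files = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    report$manifest <- manifest
  }
  report
}
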