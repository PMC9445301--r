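test_that("parameter validation enforces the model invariants", {
  expect_error(burst_params(k_on = -1, k_off = 1, k_tx = 10, d_m = 1),
               "strictly positive")
  expect_error(burst_params(1, -0.1, 10, 1), "non-negative")
  expect_error(burst_params(1, 1, 10, 0), "strictly positive")
  expect_error(burst_params(1, 1, 10, 1, ploidy = 0), "integer")
  expect_error(burst_params(1, 1, 10, 1,
                            allele_labels = "WT"), "two allele classes")
  # k_off = 0 (continuous limit) and k_tx = 0 (no source) are legal
  expect_s3_class(burst_params(1, 0, 10, 1), "burst_params")
  expect_s3_class(burst_params(1, 1, 0, 1), "burst_params")
})

test_that("closed-form stationary moments match direct formula evaluation", {
  m <- steady_state_moments(burst_params(1, 3, 40, 1))
  expect_equal(m$p_on, 0.25)
  expect_equal(m$mean_mRNA_per_allele, 10)
  expect_equal(m$fano, 7)
  expect_equal(m$var_mRNA_per_allele, 70)
  # Poisson limit: promoter never silences
  m0 <- steady_state_moments(burst_params(2, 0, 15, 0.5))
  expect_equal(m0$p_on, 1)
  expect_equal(m0$fano, 1)
  expect_equal(m0$mean_mRNA_per_allele, 30)
})

test_that("Fano factor peaks at intermediate promoter-silencing rates", {
  # over-dispersion grows with k_off while bursts lengthen relative to
  # mRNA lifetime, peaks at k_off = sqrt(k_on*(k_on+d_m)), and relaxes
  # back to Poisson when the promoter flickers much faster than decay
  fano_at <- function(koff) {
    steady_state_moments(burst_params(1, koff, 40, 1))$fano
  }
  turnover <- sqrt(1 * (1 + 1))
  rising <- vapply(c(0, 0.25, 0.5, 1, turnover), fano_at, numeric(1))
  falling <- vapply(c(turnover, 3, 10, 100), fano_at, numeric(1))
  expect_equal(rising[1], 1)
  expect_true(all(diff(rising) > 0))
  expect_true(all(diff(falling) < 0))
  expect_equal(fano_at(1e6), 1, tolerance = 1e-4)
})

test_that("trajectories are seed-deterministic and respect the no-source case", {
  p <- fast_params()
  t1 <- simulate_cell(p, t_end = 50, seed = 11)
  t2 <- simulate_cell(p, t_end = 50, seed = 11)
  t3 <- simulate_cell(p, t_end = 50, seed = 12)
  expect_identical(t1, t2)
  expect_false(identical(t1$m1, t3$m1))
  # no mRNA source: counts stay at zero for all times
  p0 <- fast_params(k_tx = 0)
  tr <- simulate_cell(p0, t_end = 100, seed = 1)
  expect_true(all(tr$total_mrna == 0))
  expect_error(simulate_cell(p, t_end = 0), "positive")
})

test_that("continuous-transcription limit gives Poisson mRNA counts", {
  p <- fast_params(k_on = 1, k_off = 0, k_tx = 10, d_m = 1)
  pop <- simulate_population(p, n_cells = 4000, seed = 3)
  m1 <- pop$cells$m1
  expect_lt(abs(mean(m1) - 10), 3 * sd(m1) / sqrt(length(m1)))
  expect_lt(abs(var(m1) - 10), 3 * se_of_variance(m1))
})

test_that("population moments agree with telegraph closed forms (3 MC SE)", {
  for (par in list(fast_params(1, 3, 40, 1),
                   fast_params(0.5, 0.5, 25, 1),
                   fast_params(2, 1, 12, 0.8))) {
    mom <- steady_state_moments(par)
    pop <- simulate_population(par, n_cells = 3000, seed = 42)
    m1 <- pop$cells$m1
    expect_lt(abs(mean(m1) - mom$mean_mRNA_per_allele),
              3 * sd(m1) / sqrt(length(m1)))
    expect_lt(abs(var(m1) - mom$var_mRNA_per_allele),
              3 * se_of_variance(m1))
  }
})

test_that("population interface validates inputs and warns on short burn-in", {
  p <- fast_params()
  expect_error(simulate_population(p, n_cells = 0), ">= 1")
  expect_warning(simulate_population(p, n_cells = 5, burn_in = 0.1,
                                     seed = 1), "burn_in")
})

test_that("symmetric alleles give balanced mutant fractions", {
  pop <- simulate_population(fast_params(), n_cells = 4000, seed = 9)
  f <- pop$cells$f_mut_mrna
  f <- f[!is.na(f)]
  expect_lt(abs(mean(f) - 0.5), 3 * sd(f) / sqrt(length(f)))
  # distribution symmetric about 0.5: f and 1-f indistinguishable
  ks <- suppressWarnings(ks.test(f, 1 - f))
  expect_gt(ks$p.value, 0.01)
})

test_that("aTS counts of a diploid population are Binomial(2, p_on)", {
  p <- fast_params()
  p_on <- steady_state_moments(p)$p_on
  pop <- simulate_population(p, n_cells = 4000, seed = 5)
  ats <- ats_count(pop)
  expect_true(all(ats >= 0 & ats <= 2))
  obs <- tabulate(ats + 1L, nbins = 3L)
  expected <- dbinom(0:2, 2, p_on) * length(ats)
  chisq <- sum((obs - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 2))
})

test_that("aTS detection threshold thins counts and validates input", {
  pop <- simulate_population(fast_params(), n_cells = 500, seed = 2)
  expect_error(ats_count(pop, detection_threshold = -1), "non-negative")
  full <- ats_count(pop)
  thin <- ats_count(pop, detection_threshold = 3, seed = 4)
  expect_true(all(thin <= full))
  # an absurdly high threshold hides every site
  none <- ats_count(pop, detection_threshold = 1000, seed = 4)
  expect_true(all(none == 0))
})

test_that("NMD mode removes mutant mRNA and protein but keeps WT mosaic", {
  p <- fast_params(nmd = TRUE)
  pop <- simulate_population(p, n_cells = 1000, seed = 6)
  expect_true(all(pop$cells$m2 == 0))
  expect_true(all(pop$cells$p2 == 0))
  expect_gt(var(pop$cells$p1), 0)
  # the silenced allele still bursts: aTS can exceed what one allele gives
  expect_gt(max(pop$cells$g2), 0)
})

test_that("force mapping follows the Hill form in the mutant fraction", {
  map <- force_map(pCa50_WT = 5.55, delta_pCa50_homozygous = -0.10, nH = 2)
  # half-maximal at the WT midpoint for a WT cell
  expect_equal(force_from_mutant_fraction(0, map, 5.55), 0.5)
  # fully mutant cell is half-maximal at the shifted midpoint
  expect_equal(force_from_mutant_fraction(1, map, 5.45), 0.5)
  expect_equal(force_from_mutant_fraction(0.5, map, 5.24),
               1 / (1 + 10^(2 * (5.24 - 5.50))), tolerance = 1e-12)
  expect_equal(round(force_from_mutant_fraction(0.5, map, 5.24), 3), 0.768)
  # monotone in f_mut, direction set by the sign of delta
  f <- force_from_mutant_fraction(seq(0, 1, 0.1), map, 5.4)
  expect_true(all(diff(f) < 0))
  map_up <- force_map(5.53, +0.12, 2)
  f2 <- force_from_mutant_fraction(seq(0, 1, 0.1), map_up, 5.6)
  expect_true(all(diff(f2) > 0))
  expect_error(force_map(nH = 0), "positive")
  expect_error(force_from_mutant_fraction(1.5, map, 5.5), "0, 1")
})

test_that("calibration inverts the zero-aTS and mean-copy summaries", {
  p <- calibrate_burst_params(0.25, 100, k_off = 1, d_m = 0.1)
  expect_equal(p$k_on / (p$k_on + p$k_off), 0.5)
  p2 <- calibrate_burst_params(0.61, 552)
  expect_equal(p2$k_on / (p2$k_on + p2$k_off), 1 - sqrt(0.61),
               tolerance = 1e-12)
  m <- steady_state_moments(p2)
  expect_equal(2 * m$mean_mRNA_per_allele, 552, tolerance = 1e-9)
  expect_error(calibrate_burst_params(0, 100), "strictly between")
  expect_error(calibrate_burst_params(1, 100), "strictly between")
})

test_that("variance-matched calibration reproduces all three summaries", {
  p <- calibrate_burst_params(0.60, 552, var_total_mrna = 3.8e5)
  m <- steady_state_moments(p)
  expect_equal(m$p_on, 1 - sqrt(0.60), tolerance = 1e-12)
  expect_equal(2 * m$mean_mRNA_per_allele, 552, tolerance = 1e-9)
  # total variance over two iid alleles = 2 * per-allele variance
  expect_equal(2 * m$var_mRNA_per_allele, 3.8e5, tolerance = 1e-6)
  # under-dispersed targets are rejected, unattainable ones capped
  expect_error(calibrate_burst_params(0.6, 552, var_total_mrna = 500),
               "Fano <= 1")
  expect_warning(
    capped <- calibrate_burst_params(0.19, 2937, var_total_mrna = 1.1e7),
    "ceiling")
  expect_lt(steady_state_moments(capped)$var_mRNA_per_allele * 2, 1.1e7)
})

test_that("trajectory summary flags undefined fractions and tracks symmetry", {
  p <- fast_params()
  tr <- simulate_cell(p, t_end = 3000, seed = 8,
                      times = seq(20, 3000, by = 1))
  expect_error(trajectory_summary(tr[1, , drop = FALSE]), "two time points")
  sm <- trajectory_summary(tr, map = force_map(5.55, -0.10, 2),
                           query_pCa = 5.24)
  expect_equal(nrow(sm), nrow(tr))
  expect_identical(sm$mrna_undefined, is.na(sm$f_mut_mrna))
  # symmetric alleles: long-run time average near 0.5
  expect_lt(abs(mean(sm$f_mut_mrna, na.rm = TRUE) - 0.5), 0.05)
  # force column present wherever the protein fraction is defined
  expect_identical(is.na(sm$relative_force), sm$protein_undefined)
})

test_that("protein fraction lags mRNA fraction when protein turns over slower", {
  p <- burst_params(k_on = 0.5, k_off = 0.5, k_tx = 20, d_m = 1,
                    k_p = 1, d_p = 0.2)
  tr <- simulate_cell(p, t_end = 4000, seed = 13,
                      times = seq(100, 4000, by = 1))
  sm <- trajectory_summary(tr)
  ok <- !is.na(sm$f_mut_mrna) & !is.na(sm$f_mut_protein)
  cc <- ccf(sm$f_mut_mrna[ok], sm$f_mut_protein[ok], lag.max = 30,
            plot = FALSE)
  best_lag <- cc$lag[which.max(cc$acf)]
  expect_lt(best_lag, 0)  # protein responds after mRNA
})
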