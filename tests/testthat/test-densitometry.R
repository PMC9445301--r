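test_that("length-normalized IODs give molar allele fractions", {
  # equimolar alleles: IOD proportional to fragment length
  expect_equal(fraction_from_iods(2.02, 1.60, 202, 160), 50)
  expect_equal(fraction_from_iods(0, 1.2, 202, 160), 0)
  # complement symmetry: swapping the bands mirrors the fraction
  f <- fraction_from_iods(3.1, 1.7, 202, 160)
  expect_equal(fraction_from_iods(1.7, 3.1, 160, 202), 100 - f,
               tolerance = 1e-12)
  # gain invariance: global rescaling leaves the fraction unchanged
  expect_equal(fraction_from_iods(31, 17, 202, 160), f)
  expect_warning(out <- fraction_from_iods(0, 0, 202, 160), "undefined")
  expect_true(is.na(out))
  expect_error(fraction_from_iods(-1, 2, 202, 160), "non-negative")
  # raw-intensity mode skips the length correction
  expect_equal(fraction_from_iods(1, 1, 202, 160,
                                  length_normalize = FALSE), 50)
})

test_that("the BbsI WT fragment equals the uncut MwoI mutant+common piece", {
  fr <- assay_fragments()
  mwo <- fr$MwoI_TNNI3
  bbs <- fr$BbsI_SNP
  expect_equal(mwo$fragment_bp[mwo$band_label == "mut_202"] +
                 mwo$fragment_bp[mwo$band_label == "common_115"],
               bbs$fragment_bp[bbs$band_label == "wt_317"])
})

test_that("known 70:30 molar mixes round-trip through synthetic lanes", {
  cfg <- scenario_config("TNNI3_missense", seed = 3,
                         noise = list(iod_cv = 0, replicate_sd = 0))
  lanes <- gen_gel_lanes(cfg, true_fractions = c(70, 30, 0, 100),
                         replicates = 1L)
  meas <- measure_gel_fractions(lanes)
  expect_equal(meas$fraction, c(70, 30, 0, 100), tolerance = 1e-9)
})

test_that("multialiquot cutoff is twice the sample SD", {
  x <- c(42.5, 49, 55.5)  # SD exactly 6.5
  mc <- multialiquot_cutoff(x)
  expect_equal(mc$sd, 6.5)
  expect_equal(mc$cutoff, 13.0)
  expect_equal(multialiquot_cutoff(rep(50, 5))$cutoff, 0)
  expect_error(multialiquot_cutoff(49), ">= 2")
})

test_that("18-aliquot cutoffs concentrate around the technical-scatter value", {
  set.seed(91)
  cuts <- replicate(200, {
    multialiquot_cutoff(pmin(100, pmax(0, rnorm(18, 49, 6.5))))$cutoff
  })
  expect_gt(mean(cuts >= 8 & cuts <= 18), 0.92)
})

test_that("replicate QC applies the strict < cutoff rule", {
  r <- replicate_qc(48, 60, cutoff = 13.0)
  expect_true(r$pass)
  expect_equal(r$mean, 54)
  expect_false(replicate_qc(40, 55, cutoff = 13.0)$pass)
  expect_true(replicate_qc(37.2, 37.2, cutoff = 0.1)$pass)
  expect_error(replicate_qc(101, 50), "0, 100")
  # vectorised over cells
  rr <- replicate_qc(c(48, 40), c(60, 55))
  expect_equal(rr$pass, c(TRUE, FALSE))
})

test_that("QC pass rate matches the analytic normal-difference probability", {
  cfg <- scenario_config("donor_SNP", seed = 12,
                         noise = list(iod_cv = 0, replicate_sd = 6.5))
  lanes <- gen_gel_lanes(cfg, true_fractions = rep(50, 1500))
  meas <- measure_gel_fractions(lanes)
  qc <- replicate_qc(meas$fraction[meas$replicate == 1],
                     meas$fraction[meas$replicate == 2], cutoff = 13)
  expected <- pnorm(13, 0, sqrt(2) * 6.5) - pnorm(-13, 0, sqrt(2) * 6.5)
  se <- sqrt(expected * (1 - expected) / 1500)
  expect_lt(abs(mean(qc$pass) - expected), 4 * se)
})

test_that("linearity RMSE matches brute-force arithmetic", {
  expect_equal(linearity_rmse(c(10, 50, 90), c(10, 50, 90)), 0)
  expect_equal(linearity_rmse(c(40, 60), c(43, 57)), 3)
  set.seed(8)
  e <- runif(9, 0, 100); o <- e + rnorm(9, 0, 4)
  expect_equal(linearity_rmse(e, o), sqrt(sum((o - e)^2) / 9),
               tolerance = 1e-12)
  expect_error(linearity_rmse(c(1, 2), c(1)), "equal length")
})

test_that("synthetic plasmid series recovers the configured assay error", {
  grid <- seq(0, 100, by = 10)
  set.seed(14)
  rmses <- replicate(150, {
    obs <- pmin(100, pmax(0, grid + rnorm(length(grid), 0, 5)))
    linearity_rmse(grid, obs)
  })
  expect_lt(abs(mean(rmses) - 5), 1)
})

test_that("western protein levels normalize to the reference-group mean", {
  lanes <- data.frame(
    lane_id = 1:6,
    group = rep(c("donor", "patient"), each = 3),
    iod_target = c(10, 10, 10, 8, 8, 8),
    iod_loading = rep(5, 6))
  pl <- protein_level(lanes, "donor")
  expect_equal(pl$group_level$level_pct[pl$group_level$group == "donor"],
               100)
  expect_equal(pl$group_level$level_pct[pl$group_level$group == "patient"],
               80)
  # zero loading-control lane is excluded, not propagated
  lanes$iod_loading[4] <- 0
  expect_warning(pl2 <- protein_level(lanes, "donor"), "excluded")
  expect_equal(nrow(pl2$per_lane), 5)
  expect_error(protein_level(lanes, "nope"), "reference group")
})

test_that("a true 59% haploinsufficiency effect is recovered under noise", {
  set.seed(23)
  recovered <- replicate(100, {
    donor <- data.frame(lane_id = 1:12, group = "donor",
                        iod_target = rlnorm(12, log(10), 0.1),
                        iod_loading = rlnorm(12, log(5), 0.1))
    pat <- data.frame(lane_id = 13:18, group = "patient",
                      iod_target = rlnorm(6, log(10 * 0.59), 0.1),
                      iod_loading = rlnorm(6, log(5), 0.1))
    pl <- protein_level(rbind(donor, pat), "donor")
    pl$group_level$level_pct[pl$group_level$group == "patient"]
  })
  expect_lt(abs(mean(recovered) - 59), 8)
})
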