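test_that("standard curves recover perfect-doubling chemistry", {
  cps <- 10^(2:6)
  cq <- 40 - (1 / log10(2)) * log10(cps)
  fit <- standard_curve_fit(cps, cq)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-4)
  expect_equal(fit$efficiency, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(standard_curve_fit(c(10, 10, 100), c(30, 30, 27)),
               "3 distinct")
  expect_error(standard_curve_fit(cps, rev(cq)), "non-monotone")
})

test_that("curve is invariant to copy-unit rescaling up to the intercept", {
  cps <- 10^(2:6)
  set.seed(41)
  cq <- 40 - 3.4 * log10(cps) + rnorm(5, 0, 0.1)
  f1 <- standard_curve_fit(cps, cq)
  f2 <- standard_curve_fit(cps * 1000, cq)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept - f1$slope * 3, tolerance = 1e-9)
})

test_that("fitted efficiency stays near 1 under realistic Cq noise", {
  set.seed(43)
  effs <- replicate(200, {
    cps <- rep(10^(2:6), each = 2)
    cq <- 40 - (1 / log10(2)) * log10(cps) + rnorm(length(cps), 0, 0.2)
    standard_curve_fit(cps, cq)$efficiency
  })
  expect_gt(mean(effs >= 0.9 & effs <= 1.1), 0.93)
})

test_that("copy quantification inverts the curve and applies scaling", {
  cps <- 10^(1:5)
  curve <- standard_curve_fit(cps, 38 - 3.3 * log10(cps))
  expect_equal(copies_from_cq(curve$intercept, curve), 1, tolerance = 1e-9)
  # inverse identity round trip
  for (c0 in c(15, 300, 7e4)) {
    expect_equal(copies_from_cq(curve_predict(curve, c0), curve), c0,
                 tolerance = 1e-9)
  }
  # strictly decreasing in Cq
  cq <- seq(20, 35, by = 0.5)
  expect_true(all(diff(copies_from_cq(cq, curve)) < 0))
  # scaling divides out pre-amplification and assayed fraction
  expect_equal(copies_from_cq(curve_predict(curve, 100), curve,
                              preamp_factor = 10, assayed_fraction = 0.5),
               100 / 5, tolerance = 1e-9)
  expect_warning(copies_from_cq(60, curve), "extrapolat")
  expect_error(copies_from_cq(25, curve, preamp_factor = 0), "positive")
})

test_that("delta-delta-Cq fold changes behave on constructed plates", {
  mk <- function(group, tshift) {
    do.call(rbind, lapply(1:4, function(i) {
      rbind(
        data.frame(sample_id = paste0(group, i), group = group,
                   gene = "NPPA", role = "target", cq = 25 - tshift),
        data.frame(sample_id = paste0(group, i), group = group,
                   gene = paste0("ref", 1:4), role = "reference", cq = 20)
      )
    }))
  }
  same <- rbind(mk("donor", 0), mk("patient", 0))
  re <- relative_expression(same, calibrator_group = "donor")
  expect_equal(re$group_fold$fold, c(1, 1))
  # one cycle lower target Cq doubles expression
  up <- rbind(mk("donor", 0), mk("patient", 1))
  re2 <- relative_expression(up, calibrator_group = "donor")
  expect_equal(re2$group_fold$fold[re2$group_fold$group == "patient"], 2)
  # a sample missing a reference gene is excluded with a warning
  broken <- up[!(up$sample_id == "patient1" & up$gene == "ref4"), ]
  expect_warning(re3 <- relative_expression(broken, "donor"), "excluded")
  expect_equal(re3$group_fold$n[re3$group_fold$group == "patient"], 3L)
})

test_that("a 3-fold upregulation is recovered under duplicate noise", {
  set.seed(47)
  folds <- replicate(100, {
    mk_noisy <- function(group, shift) {
      do.call(rbind, lapply(1:5, function(i) {
        rbind(
          data.frame(sample_id = paste0(group, i), group = group,
                     gene = "NPPA", role = "target",
                     cq = 25 - shift + rnorm(2, 0, 0.3),
                     stringsAsFactors = FALSE),
          data.frame(sample_id = paste0(group, i), group = group,
                     gene = rep(paste0("ref", 1:4), each = 2),
                     role = "reference", cq = 20 + rnorm(8, 0, 0.3))
        )
      }))
    }
    d <- rbind(mk_noisy("donor", 0), mk_noisy("patient", log2(3)))
    re <- relative_expression(d, "donor")
    re$group_fold$fold[re$group_fold$group == "patient"]
  })
  expect_lt(abs(mean(folds) - 3), 0.6)
})

test_that("simulator copies survive the qPCR round trip", {
  cfg <- scenario_config("donor_SNP", seed = 5)
  pop <- simulate_population(fast_params(2, 2, 60, 0.5), 60, seed = 5)
  truth <- pop$cells$total_mrna
  truth <- pmax(truth, 1)
  plates <- gen_qpcr_plates(cfg, truth)
  stds <- plates[plates$role == "standard", ]
  curve <- standard_curve_fit(stds$known_copies, stds$cq)
  smp <- plates[plates$role == "sample", ]
  cqm <- tapply(smp$cq, smp$sample_id, mean)
  est <- copies_from_cq(cqm, curve)
  est <- est[paste0("cell_", seq_along(truth))]
  expect_lt(abs(mean(est) / mean(truth) - 1), 0.10)
  # zero Cq noise reproduces the truth exactly
  cfg0 <- scenario_config("donor_SNP", seed = 5, noise = list(cq_sd = 0))
  p0 <- gen_qpcr_plates(cfg0, truth)
  s0 <- p0[p0$role == "standard", ]
  c0 <- standard_curve_fit(s0$known_copies, s0$cq)
  m0 <- p0[p0$role == "sample", ]
  est0 <- copies_from_cq(tapply(m0$cq, m0$sample_id, mean), c0)
  est0 <- est0[paste0("cell_", seq_along(truth))]
  expect_equal(as.numeric(est0), truth, tolerance = 1e-6)
})
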