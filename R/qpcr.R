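#' Fit a qPCR standard curve
#'
#' Least-squares regression `Cq = slope * log10(copies) + intercept` on a
#' serial-dilution series of standards with known copy numbers.
#' Amplification efficiency is `10^(-1/slope) - 1` (1.0 = perfect doubling
#' per cycle, slope -3.3219).
#'
#' @param known_copies copy numbers of the standards (> 0, >= 3 distinct
#'   concentrations).
#' @param cq measured Cq values, same length.
#' @return Object of class `qpcr_curve`: list with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `log10_range`.
#' @examples
#' cps <- 10^(2:6)
#' standard_curve_fit(cps, 40 - (1 / log10(2)) * log10(cps))$efficiency  # 1
#' @export
standard_curve_fit <- function(known_copies, cq) {
  stopifnot(length(known_copies) == length(cq))
  if (any(known_copies <= 0)) stop("standard copies must be positive")
  if (length(unique(known_copies)) < 3L)
    stop("need >= 3 distinct standard concentrations")
  lx <- log10(known_copies)
  fit <- lm(cq ~ lx)
  slope <- unname(coef(fit)[2])
  if (slope >= 0)
    stop("standards are non-monotone (non-negative slope): ",
         "Cq must decrease with template amount")
  # r^2 computed directly (avoids the perfect-fit corner of summary.lm,
  # which noiseless standards legitimately hit)
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else NA_real_
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 log10_range = range(lx)),
            class = "qpcr_curve")
}

#' Predict Cq from copy number on a fitted curve
#'
#' @param curve a `qpcr_curve`.
#' @param copies copy numbers (> 0).
#' @return Predicted Cq values.
#' @export
curve_predict <- function(curve, copies) {
  stopifnot(inherits(curve, "qpcr_curve"))
  curve$slope * log10(copies) + curve$intercept
}

#' Absolute copies per cell from a Cq value
#'
#' Inverts the standard curve, `copies = 10^((cq - intercept)/slope)`, and
#' rescales by the pre-amplification factor and the fraction of the cell
#' lysate assayed, yielding RNA copies per cell. Cq values more than one
#' log10 outside the standard range trigger an extrapolation warning.
#'
#' @param cq measured Cq value(s).
#' @param curve a fitted `qpcr_curve`.
#' @param preamp_factor fold pre-amplification before quantification (> 0).
#' @param assayed_fraction fraction of the per-cell material assayed
#'   (0 < f <= 1).
#' @return Copies per cell (numeric, same length as `cq`).
#' @export
copies_from_cq <- function(cq, curve, preamp_factor = 1,
                           assayed_fraction = 1) {
  stopifnot(inherits(curve, "qpcr_curve"))
  if (preamp_factor <= 0 || assayed_fraction <= 0)
    stop("scaling factors must be positive")
  lcop <- (cq - curve$intercept) / curve$slope
  lo <- curve$log10_range[1] - 1
  hi <- curve$log10_range[2] + 1
  if (any(lcop < lo | lcop > hi, na.rm = TRUE))
    warning("Cq value(s) far outside the standard range; ",
            "copy numbers are extrapolated")
  10^lcop / (preamp_factor * assayed_fraction)
}

#' Relative expression by the delta-delta-Cq method
#'
#' Normalises each sample's target Cq against the arithmetic mean Cq of
#' the reference genes (equivalent to the geometric mean of their linear
#' quantities), then expresses each group as fold change over the
#' calibrator group: `fold = 2^-(dCq_sample - mean dCq_calibrator)`.
#' Duplicate wells are averaged at the Cq level first. Samples missing any
#' reference gene are excluded with a warning.
#'
#' @param data data.frame with columns `sample_id`, `group`, `gene`,
#'   `role` (`"target"`/`"reference"`), `cq`.
#' @param calibrator_group group label serving as the fold-1 baseline.
#' @param n_reference_required number of reference genes each sample must
#'   have (default 4).
#' @return List with `per_sample` (data.frame `sample_id`, `group`,
#'   `delta_cq`, `fold`) and `group_fold` (data.frame `group`, `n`,
#'   `fold`).
#' @export
relative_expression <- function(data, calibrator_group,
                                n_reference_required = 4L) {
  need <- c("sample_id", "group", "gene", "role", "cq")
  if (!all(need %in% names(data)))
    stop("`data` must have columns ", paste(need, collapse = ", "))
  if (!calibrator_group %in% data$group) stop("calibrator group missing")
  # average duplicates at the Cq level
  agg <- aggregate(cq ~ sample_id + group + gene + role, data = data,
                   FUN = mean)
  per_sample <- lapply(split(agg, agg$sample_id), function(d) {
    refs <- d[d$role == "reference", ]
    tgt <- d[d$role == "target", ]
    if (nrow(tgt) != 1L || length(unique(refs$gene)) < n_reference_required)
      return(NULL)
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               delta_cq = tgt$cq - mean(refs$cq))
  })
  dropped <- sum(vapply(per_sample, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " sample(s) missing reference genes were excluded")
  ps <- do.call(rbind, Filter(Negate(is.null), per_sample))
  if (is.null(ps) || !calibrator_group %in% ps$group)
    stop("no complete sample in the calibrator group")
  base <- mean(ps$delta_cq[ps$group == calibrator_group])
  ps$fold <- 2^(-(ps$delta_cq - base))
  gf <- aggregate(fold ~ group, data = ps,
                  FUN = function(f) 2^mean(log2(f)))
  gf$n <- as.integer(table(ps$group)[gf$group])
  list(per_sample = ps, group_fold = gf[, c("group", "n", "fold")])
}
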