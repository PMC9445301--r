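#' Normalize a force-pCa record
#'
#' Subtracts the passive force measured under relaxing conditions (pCa >=
#' `passive_pCa`) and divides by the active force at the maximal-activation
#' reference point, so the reference maps to exactly 1.
#'
#' @param pCa vector of pCa values (distinct).
#' @param force measured forces (same length, >= 0), any units.
#' @param reference_pCa maximal-activation point (default 4.18).
#' @param passive_pCa pCa at/above which the preparation is relaxed
#'   (default 9.0).
#' @return List with `pCa`, `force_norm`, `passive`, `active_max`, and
#'   `flag` (`"no_active_force"` when the reference force does not exceed
#'   the passive force; `force_norm` is then `NA`).
#' @export
normalize_forces <- function(pCa, force, reference_pCa = 4.18,
                             passive_pCa = 9.0) {
  stopifnot(length(pCa) == length(force))
  if (anyDuplicated(pCa)) stop("pCa values must be distinct")
  if (any(force < 0)) stop("forces must be non-negative")
  if (!any(pCa >= passive_pCa))
    stop("no relaxing (passive) point measured")
  iref <- which.min(abs(pCa - reference_pCa))
  if (abs(pCa[iref] - reference_pCa) > 1e-6)
    stop("reference pCa not measured")
  passive <- mean(force[pCa >= passive_pCa])
  active_max <- force[iref] - passive
  if (active_max <= 0)
    return(list(pCa = pCa, force_norm = rep(NA_real_, length(pCa)),
                passive = passive, active_max = active_max,
                flag = "no_active_force"))
  list(pCa = pCa, force_norm = (force - passive) / active_max,
       passive = passive, active_max = active_max, flag = NA_character_)
}

hill_force <- function(pCa, F_max, pCa50, nH) {
  F_max / (1 + 10^(nH * (pCa - pCa50)))
}

#' Hill fit of a force-pCa relation
#'
#' Least-squares fit of `F(pCa) = F_max / (1 + 10^(nH*(pCa - pCa50)))` to
#' the activating points of one cardiomyocyte after subtraction of the
#' passive force at the relaxing pCa. Initialisation is deterministic:
#' `pCa50` starts at the measured pCa whose force is closest to half the
#' maximum, `nH` at 2 and `F_max` at the maximal active force.
#'
#' @inheritParams normalize_forces
#' @return List with `F_max`, `pCa50`, `nH`, `residuals`, `converged`. On
#'   non-convergence the record is flagged (`converged = FALSE`) and the
#'   parameters are `NA`, never fabricated.
#' @examples
#' pca <- c(9, 6, 5.8, 5.6, 5.4, 5.2, 5, 4.18)
#' f <- 30 / (1 + 10^(2.5 * (pca - 5.55))); f[1] <- 0
#' hill_fit(pca, f)  # recovers F_max 30, pCa50 5.55, nH 2.5
#' @export
hill_fit <- function(pCa, force, passive_pCa = 9.0) {
  stopifnot(length(pCa) == length(force))
  passive <- if (any(pCa >= passive_pCa))
    mean(force[pCa >= passive_pCa]) else 0
  act <- pCa < passive_pCa
  x <- pCa[act]
  y <- force[act] - passive
  if (length(x) < 4L) stop("need >= 4 activating points")
  if (length(unique(y)) < 2L) stop("activating forces are all identical")
  f_max0 <- max(y)
  pca50_0 <- x[which.min(abs(y - f_max0 / 2))]
  fit <- try(minpack.lm::nlsLM(
    y ~ F_max / (1 + 10^(nH * (x - pCa50))),
    start = list(F_max = f_max0, pCa50 = pca50_0, nH = 2),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(F_max = NA_real_, pCa50 = NA_real_, nH = NA_real_,
                residuals = NULL, converged = FALSE))
  cf <- coef(fit)
  list(F_max = unname(cf["F_max"]), pCa50 = unname(cf["pCa50"]),
       nH = unname(cf["nH"]), residuals = unname(resid(fit)),
       converged = TRUE)
}

#' Two-segment linear fit of logit-transformed forces
#'
#' For an exact Hill curve the logit of normalized force is linear in pCa
#' with slope `-nH*ln(10)` everywhere; a force-pCa relation that flattens at
#' high calcium (low pCa) instead shows a shallower slope below a breakpoint.
#' This fit regresses `ln(F/(1-F))` on pCa as a continuous piecewise-linear
#' function. The breakpoint is either fixed (e.g. 5.54) or chosen among the
#' interior measured pCa values to minimize the residual sum of squares,
#' requiring at least `min_per_segment` points per segment. Points with
#' normalized force outside the clipping band are excluded (logit undefined
#' at 0 and 1).
#'
#' @param pCa measured pCa values.
#' @param force_norm normalized forces (0..1 scale).
#' @param breakpoint `"auto"` (grid search over measured pCa) or a numeric
#'   pCa.
#' @param clip keep only points with `force_norm` strictly inside this
#'   band; default `c(0.01, 0.99)`.
#' @param min_per_segment minimum points on each side of the breakpoint.
#' @return List with `slope_high_ca` (pCa < breakpoint side),
#'   `slope_low_ca` (pCa >= breakpoint side), `breakpoint`, `sse`,
#'   `n_used`.
#' @export
logit_two_segment_fit <- function(pCa, force_norm, breakpoint = "auto",
                                  clip = c(0.01, 0.99),
                                  min_per_segment = 3L) {
  stopifnot(length(pCa) == length(force_norm))
  keep <- !is.na(force_norm) & force_norm > clip[1] & force_norm < clip[2]
  x <- pCa[keep]
  y <- log(force_norm[keep] / (1 - force_norm[keep]))
  fit_at <- function(bp) {
    lo <- x < bp            # high-calcium side
    if (sum(lo) < min_per_segment || sum(!lo) < min_per_segment)
      return(NULL)
    # continuous piecewise-linear basis hinged at bp
    z1 <- pmin(x - bp, 0)   # active on the high-Ca side
    z2 <- pmax(x - bp, 0)   # active on the low-Ca side
    fit <- lm(y ~ z1 + z2)
    list(slope_high_ca = unname(coef(fit)["z1"]),
         slope_low_ca = unname(coef(fit)["z2"]),
         breakpoint = bp, sse = sum(resid(fit)^2), n_used = length(x))
  }
  if (identical(breakpoint, "auto")) {
    cands <- sort(unique(x))
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    if (length(fits) == 0L)
      stop("no breakpoint leaves >= ", min_per_segment,
           " points per segment")
    fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  } else {
    out <- fit_at(as.numeric(breakpoint))
    if (is.null(out))
      stop("fewer than ", min_per_segment, " points in one segment")
    out
  }
}

#' Location and variance comparison of two cell groups
#'
#' Two-sided Mann-Whitney U test for a location difference, classical
#' (mean-centered) Levene test for variance heterogeneity, and the variance
#' fold change `var(b)/var(a)` — the contrast used to quantify contractile
#' imbalance between patient and donor cardiomyocytes.
#'
#' @param values_a,values_b numeric vectors (n >= 3 each); `values_a` is
#'   the reference (e.g. donor) group.
#' @param center Levene centering, `"mean"` (classical) or `"median"`
#'   (Brown-Forsythe).
#' @return List with `U_p`, `levene_W`, `levene_p`, `variance_fold`, and
#'   `flag` (`"degenerate"` for tie-only input).
#' @export
compare_groups <- function(values_a, values_b, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("each group needs >= 3 values")
  flag <- NA_character_
  if (length(unique(c(values_a, values_b))) == 1L)
    return(list(U_p = NA_real_, levene_W = NA_real_, levene_p = NA_real_,
                variance_fold = 1, flag = "degenerate"))
  u <- mann_whitney_u(values_a, values_b)
  lv <- levene_test(c(values_a, values_b),
                    rep(c("a", "b"), c(length(values_a), length(values_b))),
                    center = center)
  list(U_p = u$p_two_sided, levene_W = lv$W, levene_p = lv$p,
       variance_fold = var(values_b) / var(values_a), flag = flag)
}
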