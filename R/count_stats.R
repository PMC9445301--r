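drop_censored <- function(copies, censored) {
  if (is.null(censored)) return(copies)
  stopifnot(length(censored) == length(copies))
  copies[!censored]
}

#' Moments and Fano factor of per-cell mRNA copy numbers
#'
#' Sample mean, variance (denominator n-1), SD and Fano factor
#' (variance/mean) of per-cell copy numbers. Continuous transcription at a
#' constant rate predicts Poisson counts (Fano 1); burst-like transcription
#' is over-dispersed (Fano >> 1). Cells below the detection limit are
#' left-censored and excluded by default.
#'
#' @param copies non-negative numeric vector of per-cell mRNA copies.
#' @param censored optional logical vector flagging below-detection cells
#'   (excluded).
#' @return List with `n`, `mean`, `variance`, `sd`, `fano`.
#' @examples
#' dispersion_stats(c(1, 2, 3))  # mean 2, variance 1, fano 0.5
#' @export
dispersion_stats <- function(copies, censored = NULL) {
  x <- drop_censored(copies, censored)
  if (length(x) < 2L) stop("need >= 2 uncensored cells")
  if (any(x < 0)) stop("copy numbers must be non-negative")
  m <- mean(x)
  v <- var(x)
  list(n = length(x), mean = m, variance = v, sd = sqrt(v),
       fano = if (m > 0) v / m else NA_real_)
}

#' Chi-square dispersion test against the Poisson hypothesis
#'
#' The classical dispersion index `D = (n-1) * variance / mean` is referred
#' to a chi-square distribution with n-1 degrees of freedom; the reported
#' p-value is one-sided against over-dispersion (the burst-like
#' alternative).
#'
#' @inheritParams dispersion_stats
#' @return List with `dispersion_index`, `df`, `p_value`, and `flag`
#'   (`"mean_zero"` when the test is undefined).
#' @export
poisson_dispersion_test <- function(copies, censored = NULL) {
  x <- drop_censored(copies, censored)
  if (length(x) < 2L) stop("need >= 2 cells")
  m <- mean(x)
  if (m == 0)
    return(list(dispersion_index = NA_real_, df = length(x) - 1L,
                p_value = NA_real_, flag = "mean_zero"))
  D <- (length(x) - 1) * var(x) / m
  list(dispersion_index = D, df = length(x) - 1L,
       p_value = pchisq(D, df = length(x) - 1, lower.tail = FALSE),
       flag = NA_character_)
}

#' Correlation of mRNA copy number with cell size
#'
#' Pearson correlation between per-cell copy number and cross-sectional
#' area, with the two-sided t-test p-value. Cell-size-coupled transcription
#' would show a positive correlation; burst-dominated expression does not.
#'
#' @param copies per-cell mRNA copies.
#' @param area_um2 cell cross-sectional areas (um^2), same length.
#' @return List with `pearson_r`, `n`, `p_value`, and `flag`
#'   (`"zero_variance"` when undefined).
#' @export
size_correlation <- function(copies, area_um2) {
  keep <- !is.na(copies) & !is.na(area_um2)
  x <- copies[keep]; a <- area_um2[keep]
  if (length(x) < 3L) stop("need >= 3 cells with both copies and area")
  if (any(a <= 0)) stop("areas must be positive")
  if (var(x) == 0 || var(a) == 0)
    return(list(pearson_r = NA_real_, n = length(x), p_value = NA_real_,
                flag = "zero_variance"))
  ct <- cor.test(x, a, method = "pearson")
  list(pearson_r = unname(ct$estimate), n = length(x),
       p_value = ct$p.value, flag = NA_character_)
}

#' Bimodality check of the copy-number distribution
#'
#' Compares 1- vs 2-component Gaussian mixtures on log1p-transformed
#' counts via BIC (continuous transcription from mixed mono- and
#' binucleated cells would produce two modes). `delta_BIC` is
#' BIC(1 component) - BIC(2 components) on the conventional
#' smaller-is-better scale; the verdict is "bimodal" iff the 2-component
#' model improves BIC by more than 10.
#'
#' @inheritParams dispersion_stats
#' @param delta_threshold BIC improvement required to call bimodality.
#' @return List with `delta_BIC`, `verdict` ("bimodal"/"unimodal"), and
#'   `flag` (`"degenerate"` when the mixture fit fails, e.g. on a
#'   zero-variance sample; the verdict is then "unimodal" by default).
#' @export
bimodality_check <- function(copies, censored = NULL, delta_threshold = 10) {
  x <- drop_censored(copies, censored)
  if (length(x) < 10L) stop("need >= 10 cells")
  y <- log1p(x)
  if (var(y) == 0)
    return(list(delta_BIC = NA_real_, verdict = "unimodal",
                flag = "degenerate"))
  fit <- try(suppressWarnings(
    Mclust(y, G = 1:2, modelNames = "V", verbose = FALSE)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || is.null(fit))
    return(list(delta_BIC = NA_real_, verdict = "unimodal",
                flag = "em_failed"))
  # mclust BIC = 2*loglik - k*log(n) (larger is better); convert to the
  # classical -2*loglik + k*log(n) scale
  b <- suppressWarnings(-apply(fit$BIC, 1, max, na.rm = TRUE))
  if (length(b) < 2 || any(!is.finite(b)))
    return(list(delta_BIC = NA_real_, verdict = "unimodal",
                flag = "em_failed"))
  delta <- unname(b[1] - b[2])  # >0 favours two components
  list(delta_BIC = delta,
       verdict = if (delta > delta_threshold) "bimodal" else "unimodal",
       flag = NA_character_)
}
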