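ats_bin_labels <- c("0", "1", "2", "3", "4", ">4")

bin_ats_counts <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) == 0L) stop("no aTS counts supplied")
  if (any(is.na(counts)) || any(counts < 0))
    stop("aTS counts must be non-negative integers")
  tab <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts == 3), sum(counts == 4), sum(counts > 4))
  setNames(tab, ats_bin_labels)
}

#' Distribution of active transcription sites per nucleus
#'
#' Bins per-nucleus aTS counts into the standard classes
#' \{0, 1, 2, 3, 4, >4\} and reports the percentage of nuclei per class
#' (unrounded; sums to 100).
#'
#' @param counts non-negative integer vector of per-nucleus aTS counts.
#' @return Named numeric vector of percentages over the six bins.
#' @examples
#' ats_distribution(c(0, 0, 1, 2))  # 50, 25, 25, 0, 0, 0
#' @export
ats_distribution <- function(counts) {
  tab <- bin_ats_counts(counts)
  100 * tab / sum(tab)
}

ats_model_probs <- function(p_on, allele_copies, weights) {
  # bin probabilities under independent-allele mixture across ploidy classes,
  # ">4" right-censored
  probs <- numeric(6L)
  for (k in seq_along(allele_copies)) {
    A <- allele_copies[k]
    pk <- dbinom(0:4, size = A, prob = p_on)
    probs[1:5] <- probs[1:5] + weights[k] * pk
    probs[6] <- probs[6] + weights[k] * max(0, 1 - sum(pk))
  }
  probs
}

#' Fit the independent-allele bursting model to an aTS distribution
#'
#' Maximum-likelihood estimate of the allele ON probability `p_on` under the
#' model that every allele copy is ON independently, i.e. aTS counts follow
#' a mixture of Binomial(A_k, p_on) across ploidy classes with allele copy
#' numbers A_k; the ">4" bin is treated as right-censored. Goodness of fit
#' is a Pearson chi-square statistic with a parametric-bootstrap p-value
#' (bins are sparse and one parameter is estimated, so the asymptotic
#' reference is not used). The paper-scale analysis argues independence
#' visually; this fit is the package's formalisation of that argument.
#'
#' @param counts_or_bins either a raw vector of per-nucleus aTS counts or a
#'   named vector of bin counts over \{0,1,2,3,4,>4\}.
#' @param ploidy_mix named numeric vector of nucleus-class weights; names
#'   are allele copy numbers (e.g. `c("2" = 0.8, "4" = 0.2)` for 80% diploid
#'   and 20% tetraploid nuclei). Default pure diploid.
#' @param n_boot parametric-bootstrap replicates for the GOF p-value.
#' @param seed bootstrap seed.
#' @return List with `p_on_hat`, `bins` (observed counts), `expected`,
#'   `chisq`, `p_value`, `boundary` (TRUE when the estimate hit 0 or 1, i.e.
#'   p_on is weakly identified), `n`.
#' @export
fit_independent_allele_model <- function(counts_or_bins,
                                         ploidy_mix = c("2" = 1),
                                         n_boot = 200L, seed = 1L) {
  bins <- if (!is.null(names(counts_or_bins)) &&
              all(names(counts_or_bins) %in% ats_bin_labels)) {
    out <- setNames(numeric(6L), ats_bin_labels)
    out[names(counts_or_bins)] <- counts_or_bins
    out
  } else {
    bin_ats_counts(counts_or_bins)
  }
  n <- sum(bins)
  if (n < 10) stop("need at least 10 nuclei to fit the model")
  weights <- ploidy_mix / sum(ploidy_mix)
  allele_copies <- as.integer(names(ploidy_mix))
  if (any(is.na(allele_copies)) || any(allele_copies < 1))
    stop("`ploidy_mix` names must be allele copy numbers (integers >= 1)")

  nll <- function(p) {
    pr <- ats_model_probs(p, allele_copies, weights)
    -sum(bins * log(pmax(pr, 1e-300)))
  }
  opt <- optimize(nll, interval = c(1e-9, 1 - 1e-9))
  p_hat <- opt$minimum
  # boundary estimates (all nuclei silent, or all at the maximum) leave
  # p_on weakly identified; flag rather than bootstrap
  boundary <- p_hat < 1e-3 || p_hat > 1 - 1e-3
  if (bins[1] == n) { p_hat <- 0; boundary <- TRUE }

  expected <- n * ats_model_probs(p_hat, allele_copies, weights)
  chisq_stat <- function(obs, exp) {
    keep <- exp > 0
    sum((obs[keep] - exp[keep])^2 / exp[keep])
  }
  chisq <- chisq_stat(as.numeric(bins), expected)

  p_value <- NA_real_
  if (!boundary && n_boot > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    pr <- ats_model_probs(p_hat, allele_copies, weights)
    exceed <- 0L
    for (b in seq_len(n_boot)) {
      sim <- as.numeric(rmultinom(1, size = n, prob = pr))
      nll_b <- function(p) {
        prb <- ats_model_probs(p, allele_copies, weights)
        -sum(sim * log(pmax(prb, 1e-300)))
      }
      p_b <- optimize(nll_b, interval = c(1e-9, 1 - 1e-9))$minimum
      exp_b <- n * ats_model_probs(p_b, allele_copies, weights)
      if (chisq_stat(sim, exp_b) >= chisq) exceed <- exceed + 1L
    }
    p_value <- (exceed + 1) / (n_boot + 1)
  }
  list(p_on_hat = p_hat, bins = bins, expected = setNames(expected,
                                                          ats_bin_labels),
       chisq = chisq, p_value = p_value, boundary = boundary, n = n)
}
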