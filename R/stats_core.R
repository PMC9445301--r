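#' Mann-Whitney U test
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]: the exact null
#' distribution when both samples are small (total n <= `exact_max`) and
#' untied, otherwise the normal approximation with midranks and tie
#' correction.
#'
#' @param a,b numeric vectors (each n >= 1).
#' @param exact_max largest combined sample size for which the exact
#'   distribution is used (default 14).
#' @return List with `U` (statistic for sample `a`), `p_two_sided`,
#'   `exact`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_max = 14L) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)
  )
  list(U = unname(wt$statistic), p_two_sided = min(1, wt$p.value),
       exact = use_exact)
}

#' Levene test of variance homogeneity
#'
#' Classical Levene W: a one-way ANOVA F statistic computed on absolute
#' deviations `|x - center_g|` from each group's mean (or median, the
#' Brown-Forsythe variant), referred to F(k-1, N-k).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length (each group n >= 2).
#' @param center `"mean"` (classical, default) or `"median"`.
#' @return List with `W`, `df` (c(k-1, N-k)), `p`, and `flag`
#'   (`"degenerate"` when all deviations are zero).
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  cfun <- if (center == "mean") mean else median
  ctr <- tapply(values, groups, cfun)
  z <- abs(values - ctr[groups])
  k <- nlevels(groups)
  N <- length(values)
  if (all(z == 0))
    return(list(W = NA_real_, df = c(k - 1L, N - k), p = NA_real_,
                flag = "degenerate"))
  zbar_g <- tapply(z, groups, mean)
  n_g <- as.numeric(table(groups))
  zbar <- mean(z)
  ss_between <- sum(n_g * (zbar_g - zbar)^2)
  ss_within <- sum((z - zbar_g[groups])^2)
  W <- (ss_between / (k - 1)) / (ss_within / (N - k))
  list(W = W, df = c(k - 1L, N - k),
       p = pf(W, k - 1, N - k, lower.tail = FALSE), flag = NA_character_)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Standard one-way ANOVA ([stats::aov()]) followed by Dunnett's test of
#' every group against the control, with familywise-adjusted p-values from
#' the equicorrelated multivariate-t null distribution
#' ([multcomp::glht()]).
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param control_label label of the control/reference group.
#' @return List with `F`, `df` (c(k-1, N-k)), `p`, and `dunnett`
#'   (data.frame `group`, `estimate`, `p_adj`).
#' @export
anova_dunnett <- function(values, groups, control_label) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!control_label %in% groups) stop("control group missing")
  g <- factor(groups, levels = c(control_label,
                                 setdiff(sort(unique(groups)),
                                         control_label)))
  dat <- data.frame(y = values, g = g)
  if (var(values) == 0) {
    # all observations identical: no variation to test
    k <- nlevels(g); N <- length(values)
    return(list(F = 0, df = c(k - 1L, N - k), p = 1,
                dunnett = data.frame(group = levels(g)[-1], estimate = 0,
                                     p_adj = 1)))
  }
  fit <- aov(y ~ g, data = dat)
  av <- summary(fit)[[1]]
  Fstat <- av[["F value"]][1]
  dfs <- av[["Df"]]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  comp <- sub(" - .*$", "", names(sm$test$coefficients))
  list(F = Fstat, df = dfs, p = av[["Pr(>F)"]][1],
       dunnett = data.frame(group = comp,
                            estimate = unname(sm$test$coefficients),
                            p_adj = unname(as.numeric(sm$test$pvalues))))
}

#' Pearson correlation with t-test p-value
#'
#' Product-moment correlation and the two-sided t-test with n-2 degrees of
#' freedom ([stats::cor.test()]).
#'
#' @param x,y numeric vectors (n >= 3, non-zero variance).
#' @return List with `r`, `n`, `p`, and `flag` (`"zero_variance"` when
#'   undefined).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0)
    return(list(r = NA_real_, n = length(x), p = NA_real_,
                flag = "zero_variance"))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value,
       flag = NA_character_)
}
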