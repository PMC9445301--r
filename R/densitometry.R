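#' Restriction-fragment tables for the allele-specific assays
#'
#' Fragment sizes (bp) produced by allele-specific restriction of the nested
#' TNNI3 RT-PCR product: MwoI cuts the c.433C>T product into a 202 bp
#' mutant-specific fragment, a 160 bp WT-specific fragment and a 115 bp
#' fragment common to both alleles; BbsI distinguishes the rs3729841 donor
#' SNP with a 317 bp WT and a 273 bp SNP fragment (the 317 bp WT fragment is
#' the uncut 202 + 115 bp portion of the same amplicon). Only the
#' allele-specific bands are informative for the ratio; the common fragment
#' is excluded.
#'
#' @return Named list of per-assay data.frames with columns `band_label`,
#'   `fragment_bp`, `role` (one of `"variant"`, `"reference"`, `"common"`).
#' @export
assay_fragments <- function() {
  list(
    MwoI_TNNI3 = data.frame(
      band_label = c("mut_202", "wt_160", "common_115"),
      fragment_bp = c(202L, 160L, 115L),
      role = c("variant", "reference", "common"),
      stringsAsFactors = FALSE
    ),
    BbsI_SNP = data.frame(
      band_label = c("wt_317", "snp_273"),
      fragment_bp = c(317L, 273L),
      role = c("reference", "variant"),
      stringsAsFactors = FALSE
    )
  )
}

#' Allele fraction from band integrated optical densities
#'
#' Converts the IODs of the two allele-specific restriction fragments in
#' one gel lane into the variant-allele fraction. Because intercalating
#' stain signal grows with fragment length, IODs are divided by fragment
#' length to obtain molar amounts before the ratio is formed
#' (`length_normalize = FALSE` switches to raw intensities for sensitivity
#' analysis): `fraction = 100 * molar_variant / (molar_variant +
#' molar_reference)`.
#'
#' @param iod_variant,iod_reference band IODs (arbitrary units, >= 0).
#' @param bp_variant,bp_reference fragment lengths (bp, > 0).
#' @param length_normalize divide IODs by fragment length first (default
#'   TRUE).
#' @return Variant-allele fraction in percent, vectorised; `NA` with a
#'   warning when both IODs are zero.
#' @examples
#' fraction_from_iods(2.02, 1.60, 202, 160)  # equimolar -> 50
#' @export
fraction_from_iods <- function(iod_variant, iod_reference,
                               bp_variant = 202, bp_reference = 160,
                               length_normalize = TRUE) {
  if (any(c(iod_variant, iod_reference) < 0, na.rm = TRUE))
    stop("IODs must be non-negative")
  if (any(c(bp_variant, bp_reference) <= 0))
    stop("fragment lengths must be positive")
  mv <- if (length_normalize) iod_variant / bp_variant else iod_variant
  mr <- if (length_normalize) iod_reference / bp_reference else iod_reference
  tot <- mv + mr
  undef <- tot == 0
  if (any(undef, na.rm = TRUE))
    warning("both allele IODs are zero in ", sum(undef),
            " lane(s); fraction undefined")
  out <- 100 * mv / tot
  out[undef] <- NA_real_
  out
}

#' Technical-scatter cutoff from a multialiquot control
#'
#' Repeated analyses of one pooled RNA sample diluted to single-cell level
#' estimate pure technical scatter of the allele-fraction assay. The
#' replicate-agreement cutoff is twice the sample SD of the aliquot
#' fractions.
#'
#' @param fractions aliquot allele fractions (percent), n >= 2.
#' @return List with `n`, `mean`, `sd`, `cutoff` (= 2*sd, percent).
#' @examples
#' # aliquots with SD 6.5 percentage points give the 13.0% cutoff
#' multialiquot_cutoff(c(42.5, 49, 55.5))$cutoff
#' @export
multialiquot_cutoff <- function(fractions) {
  if (length(fractions) < 2L) stop("need >= 2 aliquots")
  s <- sd(fractions)
  list(n = length(fractions), mean = mean(fractions), sd = s,
       cutoff = 2 * s)
}

#' Replicate quality control of per-cell allele fractions
#'
#' A cell passes QC iff its two technical replicates differ by less than
#' the cutoff; the reported per-cell fraction is the replicate mean.
#' Failing cells are excluded from downstream analysis, never imputed.
#'
#' @param rep1,rep2 replicate allele fractions (percent, in \[0, 100\]).
#' @param cutoff agreement cutoff in percentage points (default 13.0, the
#'   2-SD multialiquot value).
#' @return data.frame with `rep1`, `rep2`, `mean`, `abs_diff`, `pass`,
#'   `cutoff`.
#' @examples
#' replicate_qc(48, 60)$pass  # |diff| = 12 < 13 -> TRUE
#' @export
replicate_qc <- function(rep1, rep2, cutoff = 13.0) {
  if (any(c(rep1, rep2) < 0 | c(rep1, rep2) > 100, na.rm = TRUE))
    stop("fractions must lie in [0, 100]")
  d <- abs(rep1 - rep2)
  data.frame(rep1 = rep1, rep2 = rep2, mean = (rep1 + rep2) / 2,
             abs_diff = d, pass = d < cutoff, cutoff = cutoff)
}

#' Root-mean-square error of an assay linearity series
#'
#' Accuracy of the densitometric assay over a known mixing series (e.g.
#' plasmid mixtures of the two alleles): `sqrt(mean((observed -
#' expected)^2))`, in percentage points.
#'
#' @param expected,observed equal-length vectors of mixed-in and measured
#'   variant fractions (percent).
#' @return RMSE in percentage points.
#' @examples
#' linearity_rmse(c(40, 60), c(43, 57))  # 3
#' @export
linearity_rmse <- function(expected, observed) {
  if (length(expected) != length(observed))
    stop("`expected` and `observed` must have equal length")
  if (length(expected) < 1L) stop("need at least one point")
  sqrt(mean((observed - expected)^2))
}

#' Relative protein level from western-blot lanes
#'
#' Per-lane target/loading-control IOD ratio (e.g. cMyBP-C / alpha-actinin),
#' and per-group mean ratio expressed as percent of the reference-group
#' mean. Lanes with zero loading-control IOD are excluded with a warning.
#'
#' @param lanes data.frame with columns `lane_id`, `group`, `iod_target`,
#'   `iod_loading`.
#' @param reference_group group label used as the 100% reference.
#' @return List with `per_lane` (data.frame incl. `ratio`) and `group_level`
#'   (data.frame `group`, `n`, `mean_ratio`, `level_pct`).
#' @export
protein_level <- function(lanes, reference_group) {
  need <- c("lane_id", "group", "iod_target", "iod_loading")
  if (!all(need %in% names(lanes)))
    stop("`lanes` must have columns ", paste(need, collapse = ", "))
  if (!reference_group %in% lanes$group)
    stop("reference group not present in `lanes`")
  bad <- lanes$iod_loading <= 0
  if (any(bad)) {
    warning(sum(bad), " lane(s) with non-positive loading IOD excluded")
    lanes <- lanes[!bad, , drop = FALSE]
  }
  lanes$ratio <- lanes$iod_target / lanes$iod_loading
  agg <- aggregate(ratio ~ group, data = lanes, FUN = mean)
  names(agg)[2] <- "mean_ratio"
  agg$n <- as.integer(table(lanes$group)[agg$group])
  ref <- agg$mean_ratio[agg$group == reference_group]
  agg$level_pct <- 100 * agg$mean_ratio / ref
  list(per_lane = lanes, group_level = agg[, c("group", "n", "mean_ratio",
                                               "level_pct")])
}
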