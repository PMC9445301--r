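---
title: "From transcriptional bursts to contractile imbalance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transcriptional bursts to contractile imbalance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstmosaic)
```

## The scientific problem

Most genes are transcribed in bursts: each allele's promoter switches
stochastically between a silent (OFF) and an active (ON) state, and mRNA is
made only while ON. Because the two alleles of a heterozygous gene burst
independently, individual cells carry different mixtures of transcript from
each allele at any moment, even though the tissue-level average is 50:50.

In cardiomyocytes this matters clinically. Heterozygous mutations in
sarcomeric genes — missense mutations in cardiac troponin I (*TNNI3*) that
desensitise the myofilament to calcium, or truncating *MYBPC3* mutations
whose transcripts are removed by nonsense-mediated decay (NMD), causing
cMyBP-C haploinsufficiency — alter force generation. If allelic expression
is a cell-to-cell mosaic, the mutant protein dose, and therefore the
force–calcium relation, varies from cell to cell: *contractile imbalance*
inside one heart. `burstmosaic` implements the full computational chain of
that argument: a stochastic bursting simulator with mRNA and protein
turnover and a mutant-dose→force map, plus every quantification stage used
to measure the mosaic (active-transcription-site statistics, copy-number
dispersion, densitometric allelic ratios with replicate QC, western-blot
protein levels, qPCR quantification, force–pCa fitting and
variance-heterogeneity tests), driven end to end by a seeded synthetic-data
generator.

## The telegraph model and its simulator

Each allele copy follows the two-state telegraph model with reactions (all
rates per hour):

* OFF → ON at `k_on`, ON → OFF at `k_off`;
* transcription at `k_tx` while ON; mRNA decay at `d_m` per molecule;
* translation at `k_p` per mRNA; protein decay at `d_p` per molecule.

A diploid nucleus carries one copy of each allele (`ploidy = 1` per allele
class); polyploid nuclei are supported by raising `ploidy`. In NMD mode the
second allele still bursts (it produces a visible transcription site) but
its transcripts are degraded immediately, so it contributes neither mRNA
nor protein — the truncation-mutation situation.

Simulation is exact (Gillespie direct method; compiled core). Each cell runs
on its own RNG stream derived deterministically from the root seed by a
splitmix64 hash, so populations are byte-reproducible and independent of
simulation order. Population snapshots are taken after a burn-in of ten
relaxation times, `10 * max(1/d_m, 1/d_p, 1/(k_on + k_off))`, the in-silico
analogue of a single-time-point tissue section; a shorter user-supplied
burn-in triggers a warning rather than an error.

The stationary mRNA moments have closed forms that serve as the simulator's
analytic oracle (`steady_state_moments()`):

$$p_\mathrm{on} = \frac{k_{on}}{k_{on}+k_{off}},\qquad
\mu = p_\mathrm{on}\frac{k_{tx}}{d_m},\qquad
F = 1 + \frac{k_{tx}\,k_{off}}{(k_{on}+k_{off})(k_{on}+k_{off}+d_m)}.$$

The Fano factor $F$ is 1 in the continuous-transcription limit
(`k_off = 0`) and, at fixed other rates, rises with `k_off` up to
$k_{off}^\* = \sqrt{k_{on}(k_{on}+d_m)}$ before relaxing back toward 1 when
the promoter flickers much faster than mRNA decays — over-dispersion needs
switching that is slow on the mRNA-lifetime scale.

## Calibration: which numbers pin down the rates

Only population summaries are available for calibration, and
`calibrate_burst_params()` inverts them in closed form:

* the fraction of nuclei without an active transcription site (aTS) gives
  $p_\mathrm{on} = 1 - f_0^{1/A}$ for $A$ total allele copies, because
  independent alleles make the zero-aTS fraction $(1-p_\mathrm{on})^A$;
* the mean total copy number gives $k_{tx} = \bar{m}\,d_m/(A\,p_\mathrm{on})$;
* the per-cell copy-number **variance** (when supplied) fixes the switching
  timescale $s = k_{on}+k_{off}$ through
  $F - 1 = k_{tx}(1-p_\mathrm{on})/(s+d_m)$.

The default *TNNI3* parameter set uses 60% zero-aTS nuclei, 552 copies/cell
and variance $3.8\times10^5$ (SD 613). The variance term is what makes the
model genuinely bursty: it yields ON periods of roughly two days'
spacing, and simulated allelic fractions then span the full 0–100% range
from cell to cell — the mosaic the downstream assays measure. Without it
(e.g. with promoter switching on the one-hour scale) the same mean and
zero-aTS fraction produce a far narrower mosaic and an order of magnitude
less copy-number dispersion than observed.

The telegraph model has an intrinsic noise ceiling: as $s \to 0$,
$F \le 1 + \mu_\mathrm{allele}(1-p_\mathrm{on})/p_\mathrm{on}$. The printed
*MYBPC3* dispersion (variance $1.1\times10^7$ at mean 2937, Fano ≈ 3700)
exceeds that ceiling (≈ 1100 at its ON probability) at any mRNA half-life,
so the truncation scenario uses the slow-switching limit $s = d_m/10$ and
treats the remainder as extrinsic noise that a two-state intrinsic model
cannot carry. `calibrate_burst_params()` warns when asked for an
unattainable variance.

Free choices, made once and documented here: mRNA half-life 10 h
(`d_m = ln2/10`), protein half-life 24 h, `k_p = 0.02`/h. The requirement
with scientific content is `d_p < d_m`: protein must integrate over bursts,
lagging the mRNA fraction (a property the tests verify by
cross-correlation). The absolute protein scale is arbitrary — only
fractions and ratios are consumed downstream — and is kept at a discrete
count level where event-driven simulation stays cheap.

## The force map

The calcium dependence of relative force is a Hill curve in pCa
($-\log_{10}[\mathrm{Ca}^{2+}]$),
$$F_\mathrm{rel}(\mathrm{pCa}) = \frac{1}{1 + 10^{\,n_H(\mathrm{pCa} - \mathrm{pCa}_{50})}},$$
and a cell's calcium sensitivity interpolates linearly with its mutant
protein fraction $f$: $\mathrm{pCa}_{50}(f) = \mathrm{pCa}_{50}^{WT} + f\,\delta$.
Linearity is the minimal assumption consistent with a monotone dose effect;
a logistic mixing of two Hill curves would be the natural alternative if
interaction data ever warranted it. Defaults: $\mathrm{pCa}_{50}^{WT} = 5.55$
(donor mean), $\delta = -0.10$ for the desensitising missense scenario —
twice the observed heterozygous-mean shift (5.50 vs 5.55), since the
population mean mutant fraction is 0.5 — and $+0.12$ for the sensitised
truncation scenario (5.59 vs 5.53), driven there by the WT-protein deficit
rather than mutant incorporation. $n_H = 2$ (cooperative thin-filament
activation; the value is configurable and nothing downstream is sensitive
to it within the plausible 2–3 band).

An aTS is, by default, an allele in the ON state. Real FISH sensitivity is
finite, so `ats_count()` offers a detection threshold: with threshold
$t > 0$ an ON allele is scored only with probability
$P(\mathrm{Poisson}(k_{tx}\tau) \ge t)$, where $\tau$ (default 0.1 h) is
the nascent-transcript dwell time at the site. This is a deliberately
minimal detectability model; it thins counts binomially and preserves the
independence structure.

## Quantification stages

**aTS distributions** (`ats_distribution()`, `fit_independent_allele_model()`).
Per-nucleus counts are binned into {0, 1, 2, 3, 4, >4} percentages. The
independence argument — bursting alleles should make aTS counts binomial —
is formalised as a maximum-likelihood fit of Binomial($A_k$, $p_\mathrm{on}$)
mixed over ploidy classes, with the >4 bin right-censored and a
parametric-bootstrap chi-square goodness of fit (the asymptotic reference is
unreliable with six sparse bins and an estimated parameter). This fit is an
extension: the original argument was visual.

**Copy-number dispersion** (`dispersion_stats()`,
`poisson_dispersion_test()`, `size_correlation()`, `bimodality_check()`).
Continuous transcription predicts Poisson counts; the classical chi-square
dispersion index $(n-1)s^2/\bar{x}$ tests that one-sidedly against
over-dispersion. Cells printed as below a detection limit are treated as
left-censored and excluded from moments by default (substituting limit/2 is
available); their handling upstream is unknown, so exclusion is the
conservative documented choice. Bimodality — which pooled mono- and
binucleated cells would produce under continuous transcription — is scored
by BIC between 1- and 2-component Gaussian mixtures on log1p counts, with a
conventional threshold of 10; no specific test was named in the original
analysis, so the mixture criterion is this package's documented choice.

**Densitometry** (`fraction_from_iods()`, `multialiquot_cutoff()`,
`replicate_qc()`, `linearity_rmse()`, `protein_level()`). Band IODs are
divided by fragment length before the allele ratio is formed, because
intercalating-stain signal scales with base pairs at equal molarity; a
raw-intensity mode exists for sensitivity analysis. Only allele-specific
fragments enter the ratio (the 115 bp MwoI fragment is common to both
alleles and excluded; sub-quantifiable small fragments may run off the
gel). Technical scatter is estimated from a multialiquot control — repeated
single-cell-equivalent aliquots of one pooled sample — and twice its SD is
the replicate-agreement cutoff; cells whose duplicates differ by more are
excluded, never imputed. Western protein levels are per-lane
target/loading-control ratios expressed against the donor-group mean.

**Contractility** (`normalize_forces()`, `hill_fit()`,
`logit_two_segment_fit()`, `compare_groups()`). Passive force at the
relaxing point (pCa 9.0) is subtracted and curves normalised to the maximal
activation point (pCa 4.18). Hill fits are deterministic least squares
(Levenberg–Marquardt) with documented initialisation: pCa50 starts at the
measured point nearest half-max, $n_H$ at 2, $F_{max}$ at the maximal
active force; $F_{max}$ floats, since fixing it to the measured maximum
would propagate single-point noise into every parameter. For exact Hill
data the logit of normalised force is linear in pCa with slope
$-n_H\ln 10$ everywhere, so a two-segment continuous piecewise-linear fit
of the logit (breakpoint on the measured grid by least squares, or fixed at
pCa 5.54) detects flattening at high calcium: equal segment slopes mean
Hill-consistent data. Points with normalised force outside [0.01, 0.99] are
excluded from the logit (it is undefined at 0 and 1). Group contrasts
report the two-sided Mann-Whitney p, the classical mean-centred Levene test
(median centring — Brown–Forsythe — as an option) and the variance fold,
the quantity that operationalises contractile imbalance.

**qPCR** (`standard_curve_fit()`, `copies_from_cq()`,
`relative_expression()`). Absolute quantification inverts a
serial-dilution standard curve `Cq = slope*log10(copies) + intercept`
(efficiency $10^{-1/\mathrm{slope}}-1$), rescaled by a pre-amplification
factor and assayed fraction (defaults 1; both configurable placeholders).
Relative expression uses ΔΔCq against the arithmetic mean Cq of four
reference genes — equivalent to the geometric mean of their linear
quantities — with duplicates averaged at the Cq level and an
efficiency-corrected variant available through the fitted slopes.

**Statistics** (`mann_whitney_u()`, `levene_test()`, `anova_dunnett()`,
`pearson()`). The U test is exact for small untied samples (combined n ≤
14) and continuity-corrected normal with midranks and tie correction
otherwise; at the crossover size the approximation deviates from the exact
two-sided p by at most 0.0124 (enumerable). Levene's W is computed directly
as the one-way ANOVA F on absolute deviations from group centres. Dunnett's
many-to-one comparisons use the equicorrelated multivariate-t distribution.

## The synthetic-data generator

`scenario_config()` bundles kinetics, force map, noise block and cohort
sizes for three arms: `donor_SNP` (symmetric alleles distinguished by a
non-pathogenic SNP; no force shift), `TNNI3_missense` (desensitising,
$\delta = -0.10$) and `MYBPC3_truncation` (NMD haploinsufficiency,
sensitised via WT deficit). Cohort sizes default to the measured ns (41
copy-number cells for *TNNI3*, 61–63 for *MYBPC3*, 18 multialiquot
aliquots, 20/28 force cells, 10^4 simulated cells — the package's desk
scale; distributional comparisons are sample-size aware).

Noise families are chosen for positivity and simplicity: log-normal band
intensity (`iod_cv = 0.10`), Gaussian replicate-level fraction scatter
(`replicate_sd = 5.45` percentage points — together these give a net
per-measurement SD of 6.5 points at mid-range fractions, the multialiquot
technical scatter), Gaussian Cq noise (0.2 cycles), multiplicative force
error (5% CV). Cell cross-sectional areas are log-normal and independent of
copy number by default (the null the size-correlation test should not
reject); an optional coupling parameter exists for power studies.

What the generator does **not** emulate: image-level FISH detection,
partial NMD escape, extrinsic (cell-state) expression noise beyond the
telegraph process, gel saturation or background subtraction artefacts, and
cell-damage selection in force assays. Passing tests therefore demonstrate
the pipeline's correctness on data with the assumed statistical structure,
not the absence of these real-data complications.

## Numerical choices and degenerate inputs

* Undefined fractions (total count 0) are flagged, never silently dropped.
* Boundary ML estimates (all nuclei silent) are flagged instead of
  bootstrapped.
* Zero loading-control IODs exclude the lane with a warning; zero-IOD
  allele pairs give `NA` fractions with a warning.
* Non-converged Hill fits return flagged records with absent parameters.
* The qPCR curve refuses non-monotone standards; quantification more than
  one decade outside the standard range warns about extrapolation.
* All generators and the simulator are seed-deterministic; regenerating
  with the same configuration byte-reproduces every output, and the
  pipeline manifest records md5 checksums to prove it.

## Known limitations

The protein scale is schematic (counts of order 10^2–10^3 per allele, not
absolute molecule numbers); binucleation is not modelled separately from
ploidy; the force map ignores cooperative interactions between mutant dose
and $n_H$; and the *MYBPC3* scenario's dispersion is capped at the
telegraph model's intrinsic ceiling, below the measured value, so its
simulated copy-number spread understates the data. These are documented
modelling bounds, not implementation gaps.
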