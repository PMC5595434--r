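---
title: "Mapping recessive loci by identity-by-descent in founder populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive loci by identity-by-descent in founder populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdmapr)
```

## The problem

In a population that passed through a recent bottleneck (a *founder
population*), pairs of superficially unrelated individuals share long
genomic tracts inherited identical-by-descent (IBD) from common ancestors
a handful of generations back. A rare recessive disease allele that
entered on one founder haplotype therefore travels inside a recognisable
haplotype: carriers share overlapping IBD tracts at the locus, and
affected individuals carry two copies of the shared haplotype. `ibdmapr`
implements the full chain that exploits this signal:

1. detect pairwise IBD segments between phased haplotypes
   (`detect_ibd()`),
2. clean them with region masks and a sharing-depth filter
   (`apply_mask()`, `depth_filter()`),
3. cluster overlapping tracts into *cliques* of three or more haplotypes
   and encode per-sample dosages 0/1/2 (`cluster_cliques()`,
   `encode_dosage()`),
4. test cliques against a quantitative trait under a recessive model
   (`height_zscores()`, `recessive_scan()`),
5. characterise carriers phenome-wide against binary diagnosis codes
   with three logistic engines (`phewas_test()`),
6. summarise population-level sharing and estimate the historical
   effective population size from the tract-length spectrum
   (`tract_spectrum()`, `estimate_ne()`), and
7. scan for recent positive selection with the integrated haplotype
   score (`ihs_scan()`).

Every stage is testable without protected data because the package ships
a forward Wright–Fisher generator (`simulate_cohort()`) whose ground
truth — true IBD, the planted variant, the trait model — is exact by
construction.

## The simulator: what it emulates and what it does not

`simulate_cohort()` runs a forward Wright–Fisher simulation with
founder-label copying. Founder haplotypes carry unique integer labels;
each offspring haplotype is a recombinant mosaic of one parent's two
haplotypes with crossovers placed as a Poisson process of rate 1 per
Morgan. True IBD between two present-day haplotypes is a maximal run of
equal founder labels — no inference involved. Marker alleles are then
copied down from founder haplotypes whose allele frequencies are drawn
from a Beta(0.8, 0.8) distribution truncated to [0.02, 0.98), which keeps
simulated panels comfortably above the conventional MAF > 1% input
filter.

The default demography is a bottlenecked founder population: ancestral
effective size 10000, a dip to Ne = 2500 during generations 9–14 before
present, and growth to 50000 in the most recent eight generations, over
25 generations in total. These values are stand-ins chosen to reproduce
the qualitative signatures of a Caribbean founder population — elevated
pairwise IBD sharing and a tract-length spectrum dominated by
bottleneck-era coalescence — at desk scale (one 100 cM chromosome with a
uniform 1 cM = 1 Mb map; map non-linearity is exercised separately by the
genetic-map unit tests). The default marker density, 1000 sites on
100 cM, is far sparser than a genotyping array; it keeps the detector
honest (word seeds span ~2.5 cM) while remaining cheap.

**The planted variant.** A single founder haplotype cannot drift from
frequency 1/20000 to ~1% through a 2500-strong bottleneck in 25
generations; the realistic reading is that the allele was already common
in the founding gene pool. The generator therefore picks, at the planted
site, the founder lineage whose realized descendant frequency is closest
to half the target carrier rate (default carrier rate 2%, i.e. ~1:50) and
plants the allele on it. An error is raised if no lineage reaches a tenth
of the target rate.

**Homozygotes and endogamy.** Under random mating a haplotype at
frequency ~1% yields `n p^2 ≈ 0.26` homozygotes in a cohort of 2600 —
a recessive design would essentially never be estimable, whereas real
founder-population case series report several homozygotes at such
frequencies. Founder populations are not panmictic: homozygotes for a
kindred haplotype overwhelmingly arise from unions within the extended
kindred. The generator makes this explicit: a deterministic
`round(n_samples * hom_rate)` individuals (default `hom_rate = 0.002`,
so 5 in a cohort of 2600) are produced by consanguineous carrier unions —
both parental meioses descend from one generation-1 carrier, with
transmission of the carrying haplotype forced at the planted site (an
exact conditional draw, by phase symmetry). Consequently a planted
homozygote's two haplotypes share a long tract around the locus, the way
real founder-kindred homozygotes share a multi-centimorgan boundary,
rather than only the heavily eroded founder-label run. What passing
tests show is therefore recovery of a kindred-structured recessive
signal, not of homozygotes arising by panmictic chance — the latter do
not exist at these frequencies.

**The trait.** `simulate_trait()` is a recessive z-scale model:
`z = beta_hom * [dosage == 2] + polygenic + noise` with
`beta_hom = -3.78` s.d. by default and a polygenic variance of 0.4. The
polygenic term is an independent normal component of the stated variance;
it is not transmitted through the pedigree, which is sufficient for
testing a scan that conditions on dosage but would not support
heritability estimation. Heights are laid out on sex-specific log-normal
scales (means 68.2 in for men, 62.8 in for women; s.d. 3.2/2.8 in) with a
mild age slope so that the age adjustment in `height_zscores()` has work
to do. Ages are uniform on 20–79, so a small realistic fraction of
samples falls under the adult inclusion window and is excluded, as in
real cohorts.

**Diagnosis codes.** `simulate_codes()` draws each code from
`logit(P) = logit(prev) + log(OR) * carrier + 0.01 (age - 50) +
0.1 [sex = F]`. The default code set mirrors a carrier-enriched
musculoskeletal profile (odds ratios 5–35 at sub-percent baseline
prevalence) plus null codes.

## The detector

`detect_ibd()` is a word-hash scan in the GERMLINE tradition with the
standard founder-population settings (`min_m = 3` cM, `err_het = 2`,
`bits = 25`, haploid matching). The marker axis is cut into consecutive
25-marker words; haplotypes with an identical word become seed pairs;
seeds are extended word-by-word while the per-word mismatch count stays
within budget; finally segment ends are refined to the outermost
matching marker. Two design points deserve a note:

* *No merging across over-budget words.* Extension runs are maximal word
  intervals, so two segments of the same pair are always separated by a
  word that exceeded the budget; bridging it would violate the budget
  and, with a zero error budget, break the exact equivalence with
  brute-force maximal identical runs that the test suite asserts.
* *Seed visibility.* A tract can only be detected if it contains one
  aligned, fully identical word — the defining granularity of
  hash-seeded detection. At the default densities a 3 cM tract spans
  at least 61 markers when markers sit every 0.05 cM, so any reportable
  tract is seedable; the oracle tests are built on that arithmetic.

The detector does not promise call-identical output to any external
tool; its contracts are the brute-force oracle at `err_het = 0` and
recall of simulated truth (≥ 90% of true segments ≥ 5 cM).

## Filters and cliques

Masking (`apply_mask()`) removes any segment that *touches* a masked
interval (centromeres, telomeres, low-complexity regions): one base of
overlap suffices, and survivors are never truncated. The depth filter
(`depth_filter()`) is the complementary excision step: marker sites whose
sharing depth exceeds the genome-wide mean by more than four standard
deviations define excluded regions; segments are cut at region
boundaries and pieces shorter than `min_m` are dropped. It runs as a
single pass — it is a quality-control step, not an iterated estimator.

`cluster_cliques()` slides non-overlapping 0.5 cM windows anchored at
cM 0. A haplotype joins a window only if one of its segments covers the
window entirely, which guarantees all members overlap pairwise by at
least 0.5 cM; connected components of size ≥ 3 become cliques, and
identical components in adjacent windows merge. Cliques whose size
exceeds the mean by more than four standard deviations are removed
(`filter_cliques()`), and `encode_dosage()` produces the 0/1/2 matrix
(2 = both haplotypes in the clique). For genome-scale inputs,
`clique_hom_counts()` lets callers pre-select the recessive-testable
cliques without materializing the full dosage matrix.

## Recessive association

`height_zscores()` applies the adult inclusion window (women ≥ 18,
men ≥ 22, both < 80; the −2 s.d. short-stature boundary is inclusive),
log-transforms height and standardizes the within-sex age-regression
residual. `recessive_scan()` fits `z ~ [dosage = 2] + covariates` by
least squares per clique, restricted to cliques with at least `min_hom`
(default 3) homozygotes, and reports the Bonferroni threshold over the
tests actually performed. Genomic-control `genomic_lambda()` uses the
median chi-square convention (null median 0.4549).

## PheWAS engines

`phewas_test()` offers three engines for a rare binary predictor against
sparse binary outcomes. `glm` is plain maximum-likelihood logistic
regression with a Wald p-value — fast and anti-conservative under severe
case imbalance. `firth` maximizes the Jeffreys-penalized likelihood
(Newton with step-halving, tolerance 1e-8) and tests by penalized
likelihood ratio, with the reduced model profiled *inside the full
design* so the penalty terms are commensurable; estimates remain finite
under complete separation. `spa` is a score test for the carrier
coefficient after covariate projection, with the tail computed by a
saddlepoint approximation of the score's cumulant generating function
(safeguarded Newton, tolerance 1e-10; normal fallback flagged in
`converged`).

A calibration caveat worth stating precisely: with ~50 carriers and
~10 cases per code, the number of carrier-cases is nearly Poisson(0.1),
so attainable rejection probabilities jump from ~0.004 (two or more
carrier cases) to ~0.096 (one or more). No test — including the exact
hypergeometric — can then achieve a type-I error close to 0.05; the
saddlepoint test tracks the exact tail and lands near 0.02, plain GLM
rejects every single-carrier-case code and lands near 0.10, and the
penalized likelihood ratio sits in between. Likewise the median-based
genomic-control lambda is uninformative there, because the median code
has zero carrier cases. The suite asserts the qualitative ordering (GLM
tail-inflated, SPA at or below nominal) alongside the nominal-band
checks.

## Effective population size from the tract spectrum

The spectral fit rests on two closed forms. The pairwise coalescence
distribution is `c(g) = (1/(2 N_g)) prod_{j<g} (1 - 1/(2 N_j))`, with
mass beyond the modelled horizon lumped into the final generation.
Conditional on coalescence at `g`, the expected number of maximal
segments of genetic length at least `u` Morgans on a genome of `K`
chromosomes totalling `L` Morgans is

`Lambda(u | g) = (2 g L + K - 2 g K u) exp(-2 g u)`,

the exact finite-chromosome count (per chromosome of length `l`:
`(1 + 2 g (l - u)) e^{-2 g u}`); the familiar `(2 g L + K) e^{-2 g u}`
is its long-genome limit and `Lambda(0 | g) = 2 g L + K` either way. The
finite-size correction matters: at `u = 3 cM` it is a ~2% effect, well
outside Poisson noise at realistic pair counts, and the
`simulate_pair_segments()` oracle — which places real breakpoints on
real chromosomes — agrees with the exact form to sampling error.

`estimate_ne()` minimizes the per-pair-normalized Poisson deviance
between observed and expected bin counts over a piecewise-constant
(per-epoch) `log N_g`, with a second-difference smoothness penalty
(default weight 1e-4) and deterministic multi-start L-BFGS-B; a 1-d
constant-size profile fit provides a robust warm start. Normalizing the
deviance per pair makes the fit exactly invariant to doubling counts and
pairs together. Confidence intervals come from refitting
Poisson-resampled bin counts: the function consumes the binned spectrum,
not per-pair segment lists, so pair-level resampling is not available at
this interface. Mixture-over-`g` overdispersion (the lumped residual
mass) makes bin counts super-Poisson; the bootstrap is accordingly
mildly anti-conservative and is labelled as such. Generation time is
fixed at 25 years for reporting.

The smoothing weight trades variance against feature resolution:
epoch-level interval claims (e.g. "every epoch within 20% of a constant
truth") need the heavier weight 3e-3 to tame the weakly identified
recent epochs, while bottleneck localization needs the light default so
the dip is not flattened away. Three stylizations should be kept in mind
when reading `ne_fit` output:

* Coalescence beyond the horizon is lumped at the final generation, so
  the oldest generation absorbs all ancient history and its fitted size
  is essentially unidentified — take minima over the pre-horizon
  generations.
* The most recent epochs are weakly constrained by long-tract counts,
  so their uncertainty is large.
* Because the overwhelming majority of pairs coalesce in the lumped
  final generation under bottleneck-like trajectories, a mid-trajectory
  dip contributes well under 1% of tracts; at 5 × 10⁴ pairs the Poisson
  deviance at the true dipped trajectory can be *worse* than at a
  smooth alternative, and localization of the dip then fails for purely
  informational reasons. Constant sizes are recovered within 20% at
  that sample size; reliable dip localization needs substantially more
  pairs.

## iHS

`ihs_scan()` computes extended haplotype homozygosity for ancestral and
derived alleles outward from each core site, integrating by trapezoid on
the cM scale until EHH falls below 0.05 (the first point below the cut
closes the integral; chromosome-end truncation is flagged);
`uihs = log(iHH_A / iHH_D)` is standardized within derived-frequency
bins of width 0.02. Sites below `maf_min` (default 0.05) are skipped;
the planted ~1% variant is examined by lowering `maf_min`, and in
neutral simulations it is not an outlier (|iHS| < 3) — the haplotype
length excess of a drifted founder variant is shared by all variants of
its frequency class, which is exactly what the frequency-binned
standardization absorbs.

## Numerical and interface conventions

* Coordinates are 0-based half-open base pairs internally; VCF emission
  converts to 1-based. Chromosome labels are stored without a `chr`
  prefix. Genetic positions outside a map are clamped to the map ends
  unless extrapolation is requested.
* Sites are keyed by (chromosome, position); multi-allelic records are
  rejected at input.
* The match-file dialect has exactly ten columns
  (`sample1 hap1 sample2 hap2 chrom bp_start bp_end cm_length n_sites
  n_mismatch`) and round-trips losslessly.
* All stochastic components take explicit seeds; identical seeds give
  identical cohorts, scans and bootstraps.

## Problem sizes used by the test-suite and acceptance runs

Simulated mapping cohorts use n = 2600 samples, 1000 markers on one
100 cM chromosome (50 replicate seeds); Ne recovery uses 5 × 10⁴
haplotype pairs on a 3500 cM / 22-chromosome genome; PheWAS calibration
uses n = 5000 with 1000 null codes; iHS uses n = 200–250 with 1200–3000
markers. These sizes were chosen so that each recovery experiment has
the statistical resolution its assertion needs while a full run stays
comfortably on a laptop.

## Known limitations

* One chromosome, uniform map and no genotyping error in the generator;
  admixture, local ancestry and the X chromosome are out of scope.
* The polygenic trait component is not transmitted genetically.
* The Ne likelihood is a stylized spectral fit ("IBDNe-lite"): it is
  validated by parameter recovery on its own generative model, not by
  equality with any external tool.
* The clique pipeline inherits the aligned-window granularity: a clique
  is reported on the window grid, so a locus near a window edge is
  typically captured by the adjacent window's clique.
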