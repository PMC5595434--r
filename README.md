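# ibdmapr

Identity-by-descent (IBD) mapping of recessive disease loci in founder
populations, from phased haplotypes to association, carrier phenome
characterisation and demographic inference.

## What it does and for whom

Recent population bottlenecks leave pairs of ostensibly unrelated people
sharing long IBD haplotypes. A rare recessive allele that entered on a
founder haplotype is then mappable without pedigrees: carriers share
overlapping IBD tracts at the locus, and cases carry two copies of the
shared haplotype. `ibdmapr` is for statistical geneticists working with
biobank-scale phased genotypes from founder populations who want that
whole chain as tested, scriptable R:

* **IBD detection** — a word-hash detector over phased haplotypes
  (`detect_ibd()`; defaults `min_m = 3` cM, `bits = 25`, `err_het = 2`,
  haploid matching), with mask (`apply_mask()`) and sharing-depth
  (`depth_filter()`, mean + 4 s.d.) quality filters.
* **IBD cliques** — connected-component clustering of overlapping tracts
  (≥ 0.5 cM windows) into cliques of ≥ 3 haplotypes, encoded per sample
  as dosages 0/1/2 (`cluster_cliques()`, `encode_dosage()`).
* **Recessive mapping** — sex-stratified age-adjusted z-scores of log
  height (`height_zscores()`), a recessive linear scan over clique
  dosages restricted to cliques with ≥ 3 homozygotes
  (`recessive_scan()`), Bonferroni control and genomic-control lambda.
* **Carrier PheWAS** — binary ICD9 outcomes against carrier status with
  three engines (`phewas_test()`): maximum-likelihood logistic (Wald),
  Firth-penalized likelihood ratio, and a saddlepoint-approximation
  score test; Benjamini–Hochberg FDR; exact 2×2 tests and chart-review
  tables (`fisher_exact()`, `chart_review_table()`).
* **Population summaries** — pairwise sharing sums and medians with
  bootstrap CIs, the 0.01 cM tract-length spectrum normalised by
  `N(N-1)/2`, carrier-rate/MAF reports (`carrier_stats()`).
* **Demography** — historical effective population size fitted to the
  IBD tract-length spectrum by a Poisson-deviance spectral fit over the
  closed-form expectation
  `sum_g c(g) * Lambda(u | g)`, `Lambda(u | g) = (2gL + K - 2gKu) e^{-2gu}`
  (`expected_spectrum()`, `estimate_ne()`; 25-year generations).
* **Selection** — an integrated haplotype score scan
  (`ihs_scan()`: EHH integrated to the 0.05 cut, standardized in
  derived-frequency bins).
* **Synthetic cohorts** — a forward Wright–Fisher generator with
  founder-label copying (`simulate_cohort()`): exact true IBD, a planted
  recessive variant at a ~1:50 carrier rate with a homozygote effect of
  −3.78 s.d., carrier-enriched diagnosis codes, and a bottleneck
  demography (Ne dip to 2500 at generations 9–14).

File formats: phased VCF and a haplotype-matrix TSV, HapMap-style
genetic maps, BED masks, a ten-column GERMLINE-style match file,
phenotype/covariate TSVs. A thin CLI (`inst/exec/ibdmap`) exposes
`simulate`, `detect-ibd`, `cliques`, `ibd-assoc` and `phewas`.

## Worked example

Simulate a founder cohort with a planted recessive variant
(carrier rate ~2%, homozygote effect −3.78 s.d., planted at the 50 cM
midpoint of a 100 cM chromosome), run the full mapping pipeline, and
look at the top hit:

```r
library(ibdmapr)

cfg <- sim_config(n_samples = 2600, seed = 42)
coh <- simulate_cohort(cfg, truth_segments = FALSE)
coh
#> <sim_cohort> 2600 samples, 1000 sites; planted dosage: 28 het, 5 hom

segs <- detect_ibd(coh$panel, coh$map)
nrow(segs)
#> [1] 275248

cl <- filter_cliques(cluster_cliques(segs, samples = coh$panel$samples,
                                     map = coh$map))
cl
#> <ibd_cliques> 43518 cliques; sizes 3-165

sel <- which(clique_hom_counts(cl) >= 3)   # recessive-testable cliques
length(sel)
#> [1] 33

D <- encode_dosage(structure(cl[sel], samples = attr(cl, "samples"),
                             class = "ibd_cliques"))
z <- height_zscores(coh$pheno)
scan <- recessive_scan(D, ifelse(z$included, z$z, NA), min_hom = 3)
head(as.data.frame(scan[order(scan$p),
                        c("id", "n_hom", "freq", "beta", "se", "p")]), 3)
#>          id n_hom        freq      beta        se            p
#> 1 clq020937     5 0.008576998 -3.180628 0.4432195 9.344294e-13
#> 2 clq021048     5 0.007212476 -3.180628 0.4432195 9.344294e-13
#> 3 clq021572     5 0.010721248 -3.180628 0.4432195 9.344294e-13
```

Of 43518 cliques, 33 have at least three homozygotes and are testable
under the recessive model; the Bonferroni threshold is 0.05/33 ≈ 1.7e-3.
The top cliques (tied: the same kindred seen in adjacent 0.5 cM windows
around the planted locus) carry all 5 planted homozygotes as dosage 2
and estimate the homozygote height deficit at −3.18 ± 0.44 s.d.,
bracketing the planted −3.78, at p ≈ 9e-13 — eleven orders of magnitude
past the threshold. See the methods vignette
(`vignettes/ibd-mapping-methods.Rmd`) for the model details and the
problem sizes used in the test suite.

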