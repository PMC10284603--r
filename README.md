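# ailqtl

QTL interval mapping and variant prioritisation for two-strain **advanced
intercross lines (AILs)**.

An AIL is bred by repeatedly intercrossing the descendants of two inbred
strains beyond the F2. Each extra generation adds recombination, so the
observed recombinant fraction between linked loci expands from the
per-meiosis value *r* to

&nbsp;&nbsp;&nbsp;&nbsp;*R*<sub>*t*</sub> = ½ [1 − (1 − 2*r*)(1 − *r*)<sup>*t*−2</sup>],

roughly *rt*/2 for small *r*. Confidence intervals of QTL mapped at
generation *t* are therefore about *t*/2 times narrower than in an F2 with
the same sample size and marker density. This package implements the
analysis stack of such a study — motivated by quantitative traits of the
mouse atrial septum (flap valve length, foramen ovale width, crescent
width) and patent foramen ovale as a liability-threshold binary trait —
as reusable, tested components:

- **Interval mapping** (`scanQuantitative`): at each 0.25 cM grid position
  the trait is modelled as a three-component Gaussian mixture with
  genotype-class means and common residual SD, mixed by conditional
  genotype probabilities computed with AIL-expanded recombination
  fractions (Haldane map function, no interference); the mixture is
  maximised by EM and LOD = log10 of the likelihood ratio against the
  no-QTL null.
- **Binary traits** (`scanBinary`): logistic regression of the trait on
  expected additive dosage and dominance probability;
  LOD = (deviance<sub>null</sub> − deviance<sub>alt</sub>) / (2 ln 10).
- **Peaks** (`findPeaks`, `resolveLinkedPeaks`): local maxima above a LOD
  threshold (default 2) with 1-LOD drop-off support intervals; overlapping
  peak pairs are re-scanned with the marker nearest the higher peak as a
  fixed term in both null and alternative fits (simplified composite
  interval mapping) — the lower peak's conditional LOD decides "one QTL or
  two".
- **Effects** (`estimateEffects`): a = (mean<sub>QQ</sub> −
  mean<sub>qq</sub>)/2, d = mean<sub>Qq</sub> − midpoint, plus the additive
  effect as a percentage of the parental strain difference and the
  normal/cryptic direction call.
- **Breeding simulator** (`simulatePedigree`, `simulateGenotypes`,
  `simulatePhenotypes`, `selectExtremes`): the cascade-mating design (48
  pairs, one male + one female contributed per pair, ring mating) with
  gamete-level meiosis, additive/dominance trait models, liability
  thresholds and extreme+random sample selection — every downstream stage
  is testable without external data.
- **Variant density** (`filterHighQuality`, `binDensity`,
  `classifyDensity`, `intersectQtl`, `filterCandidates`): depth ≥ 8 /
  FDR ≤ 10% / informative-zygosity filtering, 600 kb genome bins with a
  bimodality sweep (50 kb–1.1 Mb), segments at ≥ 1000 variants per bin,
  QTL narrowing and candidate-variant summaries.
- **Networks** (`geneNetwork`, `permutationTest`, `centralityRanking`,
  `hubConnectionTest`, `substrateEnrichment`): STRING-style score > 700
  subnetworks, permutation nulls for edge count and average clustering
  coefficient with empirical p = k/N (reported "< 1/N" at k = 0),
  betweenness plus raw-count stress centrality, and one-sided Fisher tests
  for hub connectivity and kinase-substrate over-representation.
- **Feature enrichment** (`definePromoters`, `defineEnhancers`,
  `featureEnrichment`, `shuffleNull`): promoters as TSS −1000/+100 bp,
  enhancers as (H3K4me1 ∪ H3K27ac) − H3K4me3 within 50–250 kb of a TSS,
  coverage-normalized enrichment and a length-matched interval-shuffle
  null inside the QTL regions.

## Worked example

```r
library(ailqtl)

map <- geneticMap(sprintf("m%02d", 1:21), "1", seq(0, 40, by = 2))
model <- list(fvl = TraitModel(grandMean = 1.0,
  qtl = data.frame(chrom = "1", cm = 20, a = 0.08, d = 0),
  residualSd = 0.16))
design <- AILDesign(nPairs = 48, tFinal = 14, finalCohortSize = 400, seed = 7)
cohort <- simulateAILCohort(design, map, model)

scan <- scanQuantitative(cohort$genotypes, cohort$phenotypes$fvl,
                         t = 14, step = 0.25)
curve <- scan[["1"]]
curve
#> LodCurve [quantitative scan]: chr 1, 161 positions (0.00..40.00 cM),
#>   max LOD 13.48 at 20.00 cM

peaks <- findPeaks(curve, threshold = 2)
top <- peaks[which.max(peaks$lod), ]
top
#>   chrom peakCm      lod  ciLo  ciHi overlaps
#> 2     1     20 13.48482 19.25 20.75        1

P <- qtlGenotypeProbs(cohort$genotypes, "1", top$peakCm, t = 14)
estimateEffects(P, cohort$phenotypes$fvl, parentalMeans = c(Q = 1.13, q = 0.60))
#> a = 0.081, d = -0.017, attributable = 15.3%, direction = "normal"
```

The planted QTL (additive effect 0.08 mm at 20 cM) is recovered at the
right position with a 1.5 cM support interval — the t/2-fold sharpening an
F14 design buys — and an unbiased effect estimate; "normal" direction means
the allele from the strain with the longer flap valve lengthens it. The
second, flagged row of `peaks` (a shoulder whose support interval overlaps
the main peak) is what `resolveLinkedPeaks` adjudicates.

`runPipeline(pipelineConfig(...))` chains all stages — simulation,
normalization, scans, peak resolution, density segmentation, candidate
filtering, network permutation, feature enrichment — deterministically from
one seed and writes TSV/BED/JSON artifacts.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It simulates an AIL cohort, executes every stage, logs a one-line summary
of the headline quantities, and writes the JSON report to `--out`.
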