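---
title: "Models and methods in ailqtl"
author: "ailqtl maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ailqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the simulator does and does not
emulate, and the numerical and design choices made where the method left
room. It states no empirical result that the test suite does not itself
compute.

## 1. The AIL recombination model

The package targets crosses of two inbred strains intercrossed beyond the
F2. All genetic-distance arithmetic uses the **Haldane map function**
(crossover counts Poisson with mean equal to map length in Morgans, no
interference): `haldaneR(d)` converts d centimorgan to a per-meiosis
recombination fraction. This is the simplest convention consistent with
no-interference interval mapping; interference models are out of scope.

Repeated random intercrossing expands the map. For per-meiosis fraction
$r$ and generation $t$ (F2 = 2), the expected recombinant haplotype
fraction is

$$R_t = \tfrac12\left[1 - (1-2r)(1-r)^{t-2}\right],$$

implemented in `expectedRecombinantFraction()`. The form follows from
linkage-disequilibrium decay at rate $(1-r)$ per random-mating generation
starting from the F2 value: with allele frequencies ½, $R = \tfrac12 -
2D$, and $D_{t+1} = (1-r) D_t$, giving $R_{t+1} = (1-r)R_t + r/2$ whose
solution is the expression above. It reduces to $R_2 = r$ and to the
small-$r$ map expansion $R_t \approx rt/2$ that shrinks AIL support
intervals roughly $t/2$-fold relative to an F2. The gamete-level breeding
simulator is the package's independent oracle for this closed form (the
acceptance suite compares the two at $t \in \{2, 6, 10, 14\}$), and the
empirical drift of the simulated design is checked against the
doubled-effective-size expectation ($N_e = 2N$, the point of contributing
exactly two offspring per pair).

Two caveats the formula ignores, deliberately: finite population size adds
drift variance around $R_t$ (the tests absorb it via between-replicate
standard errors), and ring (cascade) mating is not exactly random mating —
at 48 cages the difference is below Monte-Carlo resolution.

## 2. Conditional genotype probabilities

`qtlGenotypeProbs()` gives $P(\text{QQ}, \text{Qq}, \text{qq})$ at any
scan position from the nearest informative flanking markers. The model
treats each of an individual's two composite gametes as an independent
two-state Markov chain along the chromosome whose switch probability over
an interval of $d$ cM is $R_t(\text{haldaneR}(d))$. Genotypes are
unordered gamete pairs, so heterozygous flanks are summed over phase with
weights given by the chain's two-locus marginals. Properties that follow:

- at $t = 2$ the probabilities are exactly the classical F2
  interval-mapping conditionals (verified against exhaustive enumeration
  of the gamete-transmission table);
- at a typed marker they collapse to the observed call;
- individuals with no informative marker on a chromosome receive the
  population prior (¼, ½, ¼).

Treating the AIL genotype process as Markov with expanded single-interval
fractions is the standard AIL modification of F2 machinery; it is an
approximation (the multi-generation process is not exactly Markov across
double intervals) adopted as the package's model and validated against the
simulator, not against the original study's code.

## 3. Quantitative scans: EM on the mixture likelihood

At each grid position, `scanQuantitative()` fits

$$y_i \sim \sum_{g \in \{qq, Qq, QQ\}} p_{ig}\,
\mathcal N(\mu_g + x_i^\top\beta,\ \sigma^2)$$

with the $p_{ig}$ from section 2, a **common residual SD** across genotype
classes (the standard interval-mapping model, fewest parameters), and
optional fixed-term covariates $x_i$. LOD = $\log_{10}$ of the maximised
likelihood ratio against the null without the $\mu_g$ split, hence LOD ≥ 0
by construction. Numerical choices:

- **Initialisation** from a Haley–Knott regression on expected dosage
  (additive $p_{QQ} - p_{qq}$ and dominance $p_{Qq}$), which also serves
  as the internal cross-check implementation of the scan.
- **Convergence**: relative log-likelihood change below `1e-8`, capped at
  200 iterations; non-convergent positions keep the best-so-far LOD and
  carry a `"noconv"` flag.
- $\sigma$ is floored at `1e-8` to keep degenerate clusters finite.
- The scan grid is `seq(first, last, by = step)` **snapped to include
  every marker position exactly** (default step 0.25 cM, the study
  convention).
- The trait must be non-degenerate (zero variance is an error); LOD is
  invariant to affine trait transformations (tested).

The EM is validated against a derivative-free iterated-grid maximiser of
the same likelihood on small instances (agreement within $10^{-4}$ LOD).

## 4. Binary scans

`scanBinary()` replaces the Gaussian model with logistic regression of the
0/1 trait on expected additive dosage and dominance probability
(`useDosage = FALSE` substitutes hard calls at typed markers — the choice
between the two was left open by the method description; dosage is the
default because it uses flanking information at untyped positions).
LOD $= (\text{dev}_0 - \text{dev}_1)/(2\ln 10)$, which is $\chi^2_2$-scaled
under the null (tested by simulation). Complete separation is detected
from fitted probabilities within `1e-8` of 0/1; such fits are capped at
the saturated-model bound ($\text{dev}_1 = 0$) and flagged
`"separation"`. The binary trait is interpreted under a liability-threshold
model: an unobserved Gaussian liability with the same QTL machinery,
dichotomised at a threshold — this is also exactly how the simulator
generates binary traits.

## 5. Peaks, support intervals and linked-peak resolution

`findPeaks()` reports local maxima with LOD at or above the threshold
(default **2.0** for AIL scans; the classical F2 levels 4.3 significant /
2.8 suggestive are carried as pipeline defaults for F2-style reporting; no
permutation-derived genome-wide threshold is computed). Each peak gets the
maximal contiguous interval where LOD ≥ peak − 1 (**1-LOD drop-off**).
Overlapping support intervals are cross-flagged.

`resolveLinkedPeaks()` re-scans with the typed marker nearest the higher
peak (ties: smaller cM distance, then lower coordinate) entered as
additive + dominance covariates in **both** the null and alternative fits
— entering it only in the alternative would make the LR conflate both
loci. The verdict is "distinct" iff the lower peak's conditional LOD (its
maximum within the lower peak's original support interval) stays at or
above the threshold. If the higher peak's support interval contains no
typed marker the call errors: at late generations with strong effects the
1-LOD interval can be narrower than the marker spacing, and silently
fixing a marker outside the stated interval would change the procedure's
meaning.

## 6. Effect estimates

`estimateEffects()` computes probability-weighted genotype means and from
them $a = (\bar y_{QQ} - \bar y_{qq})/2$, $d = \bar y_{Qq} - (\bar y_{QQ}
+ \bar y_{qq})/2$, the additive effect as a percentage of the parental
strain difference when parental means are supplied, and the direction
class — "normal" when the allele from the higher-trait strain increases
the trait, "cryptic" otherwise. One practical caveat: weighting by the
*prior* conditional probabilities is exact at typed markers but attenuates
the contrast between markers (the weights are shrunk towards the prior);
peaks land on or next to markers in practice, and callers wanting
fully efficient estimates off-marker can pass EM posterior weights
instead. Unbiasedness at the planted locus is part of the acceptance
suite. No correction for selective-genotyping bias is applied; with
extreme-selected cohorts the raw effect estimates are inflated — a
documented limitation, matching the original analysis.

## 7. The simulator as a stated world

Defaults are the study design itself: 48 breeding pairs, cascade ring
mating (the last cage's male pairs with the first cage's female), exactly
one male and one female contributed per pair (so drift corresponds to a
doubled effective size), terminal generation F14, markers every 2 cM,
trait SDs on the scale of the septal traits. The terminal generation can
be expanded (`finalCohortSize`) to emulate the large phenotyped cohort
bred from the final pairs; 400 matches the genotyped sample of the study
design. Extreme selection takes both tails per trait (half each),
deduplicates across traits, and fills with random animals balanced by sex
and cage; ties among equally extreme phenotypes are broken by table order
(the study does not state its rule — this keeps selection deterministic).

What the simulator does **not** emulate: genotyping error and missing-data
patterns, mutation, X-linked inheritance, crossover interference,
selection during breeding, shared litter environment, and real marker
informativeness gaps. A green test therefore establishes correctness of
the statistical machinery under the stated model, not robustness to those
artefacts.

Fixture generators for the downstream stages plant known structure:
two-component variant density (background ~5 per 600 kb vs blocks ~2000
per 600 kb, mimicking the blocky divergent-haplotype mosaic of inbred
strain pairs), a stochastic-block-model network with one dense community,
and an expression matrix with a known expressed set. All randomness flows
from one explicit seed through deterministic stage-specific sub-seeds.

## 8. Variant density and candidates

High-quality strain-difference variants require depth ≥ 8, estimated
FDR ≤ 10% (ingested as a per-variant field; caller error models are out of
scope), and homozygous-alternate in exactly one strain with reference or
heterozygous in the other. Binning tiles each chromosome from position 0
(the genome-concatenated alternative was rejected as it would let bins
span chromosome boundaries); terminal partial bins keep their true width.
The bin-size sweep (50 kb–1.1 Mb) scores each size by the depth of the
antimode between the two largest smoothed modes of log10(count + 1); the
600 kb default with an inclusive cutoff of **≥ 1000** variants per bin
follows the published convention (the figure-caption wording "density ≥
1000" decides inclusivity over the looser prose). Candidate filtering
keeps variants inside QTL support intervals, in expressed genes
(CPM > 1 — strictly — in ≥ 2 samples), with effect class high-impact,
deleterious-missense or non-frameshift deletion; the filters commute
(tested). QTL intervals mapped in cM are converted to bp by linear
interpolation against a marker physical-position table — the same
machinery as `convertMap()`; the synthetic pipeline uses a uniform
2 Mb/cM scale.

## 9. Network permutation and hubs

Subnetworks are induced on the gene set with combined score **strictly
greater than 700** (the high-confidence convention). The "average
clustering coefficient" is the mean of local clustering coefficients over
the set's genes with degree < 2 contributing 0 — the common graph-library
convention, flagged here because the source analysis does not define it;
set genes absent from the network also contribute 0. Permutations draw
gene sets of equal size uniformly **without replacement** from the
expressed-gene background of the relevant condition (the background is a
per-run input, never a global constant), and the empirical p is k/N with
"< 1/N" reported at k = 0; the conservative (k+1)/(N+1) is an option.
Because the statistics are integers, k/N is conservatively discrete — the
calibration tests therefore check the randomized PIT, which is exactly
uniform under exchangeability. Betweenness is fraction-weighted
(igraph); **stress** centrality (raw shortest-path counts) is computed by
a Brandes-style BFS accumulation and cross-checked against explicit path
enumeration. Fisher tests for hub connectivity and kinase substrates are
one-sided (enrichment), with degenerate 2×2 tables reported as p = 1 with
a flag, and BH adjustment across tested hubs.

## 10. Feature enrichment and the interval shuffle

Promoters are TSS −1000/+100 bp on the coding strand, clipped at
chromosome bounds; enhancers are (H3K4me1 ∪ H3K27ac) minus anything
overlapping H3K4me3, within a window of 50–250 kb of a gene-set TSS (the
window is a swept parameter). Enrichment is the proportion of QTL variants
in the feature divided by the proportion of QTL length the feature covers,
so full coverage gives exactly 1. The null re-places intervals
length-matched to the observed feature∩QTL pieces uniformly inside the
QTL regions minus exclusions, without overlap among placed intervals
(longest-first; a placement splits one free gap into two — plain numeric
bookkeeping keeps 1000 shuffles in about a second). "Equal or greater
overlap" compares raw variant counts, per the stated rule, not normalized
enrichment. By default only the complementary gene set's features are
excluded from the placement pool (the quoted rule); excluding the tested
set's own features is left to the caller via `exclusions`. Empirical p is
k/N with a normal-approximation 95% CI on the null mean.

## 11. Known limitations

- Selective-genotyping bias in effect estimates is not corrected (§6).
- No X-chromosome or sex-linked models; no epistasis; no multiple-QTL
  search beyond the single fixed-term step.
- The AIL Markov approximation (§2) and the infinite-population closed
  form (§1) are validated against the package's own simulator, not
  against the original study's code or data.
- `permutationTest()` materialises a dense background adjacency matrix:
  fine up to a few thousand background genes, wasteful beyond.
- The pipeline's cM→bp conversion in the synthetic run uses a constant
  scale; real analyses should supply a marker physical-position table.
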