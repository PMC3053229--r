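---
title: "Copy number, allele-specific transcription and homeolog evolution under canina meiosis"
author: "caninaASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number, allele-specific transcription and homeolog evolution under canina meiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninaASE)
```

## The biological system and the model

Pentaploid dogroses (*Rosa* sect. *Caninae*) reproduce sexually despite an
odd chromosome number through canina meiosis: of the five chromosome sets
(2n = 5x = 35 with base number x = 7), exactly two highly homologous sets
pair as bivalents and recombine, while the remaining three univalent sets
skip pairing altogether. Pollen carries one recombined bivalent-derived set
(n = x = 7); eggs carry one recombined set plus all three univalents
(n = 4x = 28). Fertilization restores 2n = 35. Tetraploid dogroses follow
the same scheme with one univalent set fewer (`meiosisParam(ploidy = 4)`).

Two consequences drive everything in this package:

1. **Univalent alleles are strictly maternal.** Any allele on a univalent
   set is inherited only through eggs, unrecombined.
2. **The bivalent allele is duplicated.** When the two bivalent sets
   descend from a common diploid progenitor they carry the same allele,
   so a single-copy nuclear locus shows at most four *distinct* alleles
   in a pentaploid: the duplicated bivalent allele plus up to three
   univalent alleles.

A diagnostic base carried by alleles with $k$ of the $p$ genome copies is
expected at fraction $k/p$ among molecules of genomic DNA: 0.2, 0.4, 0.6
for $k = 1, 2, 3$ at $p = 5$. Under equal per-copy transcription the same
fraction is expected in cDNA pools — this is the **copy-number null** that
both the copy-number caller and the expression tests are built on. With
per-copy transcription rates $e_a$ the expected cDNA fraction of a carrier
set $C$ generalizes to

$$ f_C \;=\; \frac{\sum_{a \in C} k_a e_a}{\sum_b k_b e_b}, $$

which depends only on rate ratios.

## The forward meiosis simulator

`makeFounder()`, `pollenGamete()`, `eggGamete()`, `fertilize()` and
`evolvePopulation()` implement a generative model of canina inheritance.
Design choices, made once:

* **Recombination** is a per-chromosome Poisson crossover count
  (`recombinationRate`, default 1 expected crossover) with uniform
  breakpoints on a unit map; loci receive map positions via `lociMap`
  (by default one locus per chromosome at position 0.5). With no genetic
  map available for these loci, the simplest exchangeable model is used; recombination only ever acts between the two bivalent sets.
* **Which recombination product enters a gamete** is chosen uniformly;
  no segregation bias is assumed.
* **Mutation** follows the infinite-alleles model: with probability
  `mutationRate` per locus per transmission, the transmitted allele gets
  a fresh, never-seen label. This is the weakest assumption that keeps
  allele identity trackable.
* Strict canina meiosis is assumed: no leakage of alleles between
  bivalent and univalent sets under rare pairing irregularities.

```{r meiosis}
g <- makeFounder("LEAFY-3", c("LEAFY-1", "LEAFY-2", "LEAFY-4"), "LEAFY")
alleleCopyNumbers(g, "LEAFY")
nChromosomes(pollenGamete(g))
```

## The pyrosequencing generator

`simulateAssay()`/`simulateExperiment()` emulate replicate diagnostic-base
fractions from a PSQ96-style instrument. The unit of simulation is the
reported allele fraction, not the pyrogram. Replicate counts are
beta-binomial: depth $N$ (default 500 reads; instruments do not expose a
read count, so the value is nominal), mean equal to the true fraction,
and intra-class correlation $\rho$ (default 0.005) capturing technical
overdispersion between replicate PCR products; $\rho = 0$ is plain
binomial sampling, and `depth = Inf` gives exact noiseless fractions for
identifiability checks. The default design mirrors the experimental
layout being emulated: per individual, two genomic PCR products and three cDNA PCR products per bud
stage (small and large), with no bud-stage effect unless one is requested
via `stageEffect`.

cDNA means can be generated in two modes:

* **composition-consistent** (`rates`): all assay means derive from one
  expression profile, hence are mutually consistent; or
* **per-assay targets** (`cdnaTargets`): each assay is given its own
  target fraction. This mode exists because real pyrosequencing assays
  carry assay-specific biases — the reference fold deviations (0.4/2.3
  for the two-copy allele, 0.2 × 2.9 for two single-copy alleles) sum to
  more than 1 as raw fractions, so the assays of a locus need not be
  mutually consistent. Per-assay targets are the default for recovery
  tests.

What the generator does **not** emulate: dispensation order and pyrogram
light-signal artifacts, homopolymer miscalls, PCR-efficiency drift between
templates, or biological variation between plants beyond the genomic
composition. Passing recovery tests therefore demonstrates statistical
correctness of the estimators under the stated noise model, not robustness
to every instrument pathology.

## Allele calling from cloned sequences

`collapseClones()` single-linkage-clusters aligned clones at a threshold
of `maxIntraAlleleDiff = 4` substitution/indel events — deliberately
mirroring the pragmatic lumping of nearly identical sub-clades into one
allele — and reports clusters with fewer than `minClones = 2` members as
putative PCR-error singletons instead of alleles. A contiguous indel run
counts as a single event in the clustering distance and is excluded
entirely from `pairwiseDivergence()` percentages. Consensus ties become
IUPAC ambiguity codes, and such columns are never offered as diagnostic
SNPs.

`detectChimeras()` scores every clone against every ordered allele pair
and a single breakpoint, calling a clone chimeric only when the best
mosaic beats the best single parent by `minImprovement = 3` mismatches
with at least `minFlankSites = 1` parent-supporting diagnostic site on
each flank; breakpoints are reported as the 0-based half-open column
interval between the flanking diagnostic sites.

`findDiagnosticSnps()` proposes assays at coding columns where one base
splits the alleles into a carrier set of at most `carrierMax = 2` versus
the rest, with gap-free, monomorphic flanks of 3 columns on both sides.
The flank-monomorphism rule is a *proxy* for pyrosequencing suitability
(real assay design also weighs dispensation chemistry), so SNP counts on
real data may differ from those a manual assay designer would pick; carrier sets of size two are
allowed because some assays cannot separate closely related alleles and
then measure their combined frequency. Empty results are legitimate — a
locus can lack any usable SNP for a given allele.

## Copy-number inference

`inferCopyNumbers()` enumerates every positive integer composition of the
ploidy over the alleles (`enumerateCompositions()`), computes each assay's
expected fraction $\sum_{a \in C} k_a / p$, and maximizes the likelihood
of the observed gDNA fractions: beta-binomial on counts when read depths
are available, otherwise Gaussian on fractions with a pooled replicate
variance (floored at $10^{-6}$ to keep noiseless data identifiable).
Alleles no assay covers absorb the residual copies; likelihood ties are
resolved toward the most even residual split, then by allele label order,
and flagged. Calls are per individual, because compositions genuinely
differ between plants. `flagAnomalousAssays()` marks assays whose mean
gDNA fraction sits more than `zThreshold = 3` noise standard deviations
from the fitted mean — the signature of assay bias or a mis-specified
carrier set, as in the case of an observed 0.778 against an expected 0.6.

## Allele-specific expression

`foldDeviation()` reports `mean(cDNA)/expected`, with values below one
phrased as "(1/fold)-fold lower", and a seeded percentile bootstrap CI.
Fractions are analyzed untransformed (a logit switch was considered and
rejected: classical GLM analyses of pyrosequencing data operate on raw
frequencies, and at the observed effect sizes the transform changes
nothing of substance).

`glmTemplateTest()` is the template (gDNA vs cDNA) test with individual
as a random factor, realized as the classical expected-mean-squares
ANOVA, $F = MS(\text{template}) / MS(\text{template} \times
\text{individual})$ on $(1, n_{ind}-1)$ degrees of freedom, rather than a
REML mixed model: with three individuals REML gains nothing, the EMS test
is exact for this layout under normal errors regardless of replicate
imbalance, and it has no fitting-failure modes. Degenerate inputs have
fixed conventions: an identically zero template effect returns $F = 0,
p = 1$; a constant response is a flagged no-test. SPSS-style GLM output depends on unstated choices (interaction term,
sums-of-squares type), so exact agreement with any particular GLM
implementation is not claimed — the calibration target is the test's actual type-I error,
which the suite verifies to lie in $[0.03, 0.07]$ at $\alpha = 0.05$
under the default noise model.

`aseReport()` groups individuals sharing a genomic composition per assay
(individuals with a different call, and hence a different null, get their
own row) and reports raw p-values alongside Benjamini–Hochberg adjusted
ones; per-SNP p-values for such designs are conventionally read
uncorrected, so both are kept.

## Molecular evolution of the homeologs

`countSubstitutions()` classifies each polymorphic codon column by
minimum-change parsimony on the codon graph (single-nucleotide steps):
observed codons are joined by a deterministic minimum spanning tree and
each edge is pathway-averaged over all minimal mutation orderings,
excluding stop-crossing paths. Per-locus substitution totals depend on
whether columns are counted once or summed over sequence pairs; the
column-wise convention used here is the one checked against an
exhaustive path-enumeration oracle, and that convention sensitivity is
why agreement with counts from other conventions is only expected up to
rounding. Codons with a gap or ambiguity in any sequence are dropped
(complete deletion); indel events are maximal runs of columns sharing a
gap pattern.

`ng86()` is Nei–Gojobori (1986): degeneracy-based site counts (changes to
stop codons count as non-synonymous), pathway-averaged difference counts
and Jukes–Cantor correction, erroring explicitly when $p \ge 3/4$.

`m0Fit()` is a Goldman–Yang codon model: GY94 rate matrix with one
$\omega$ and one $\kappa$, F3x4 codon frequencies from the data (stop
codons excluded and renormalized), free branch lengths, likelihood by
Felsenstein pruning (compiled; transition probabilities via the symmetric
eigendecomposition of the reversible generator). Optimization is bounded
L-BFGS-B on log-parameters from three documented $\omega$ starts (0.1,
0.5, 1.5); the suite checks that restarts agree in log-likelihood to
$10^{-4}$. $dS$ and $dN$ are per-site tree distances computed from the
fitted rate matrix's synonymous/non-synonymous flux split against the
$\omega = 1$ opportunity, which makes $dN/dS$ equal the fitted $\omega$
by construction — the codeml reporting convention. Log-likelihood values are not
comparable across implementations (they depend on data constants and
deletion conventions); $\omega$, $dS$ and $dN$ are the comparable
quantities. `twoRatioLrt()` gives the pendant branches of multi-copy
alleles their own $\omega$ and tests it against the one-ratio null by a
1-df likelihood ratio test, starting the alternative at the null solution
so nesting holds numerically.

For relative rates, the package deliberately uses **Tajima's (1993)
test** (`tajimaRrt()`, with Benjamini–Hochberg control across pairs in
`tajimaRrtBatch()`) instead of an ML relative rate test under a codon
model: Tajima's test is fully specified, assumption-light and
desk-verifiable, and it addresses the same scientific question — whether
any homeolog pair evolves at unequal rates against an outgroup.

`simulateCodons()` evolves codons along a tree under exactly the process
`m0Fit()` assumes (optionally with a foreground branch class), closing
the loop for parameter-recovery tests.

## Problem sizes and numerical choices

The simulation-based checks run at sizes chosen to give stable Monte
Carlo estimates while staying desk-scale: 200 seeds for fold recovery,
500 datasets for composition recovery, 2,000 replicates for the ANOVA
size check, 20 seeds of 400-codon, 4-taxon alignments for codon-model
recovery and 200 simulations for the LRT size check. Optimizer bounds are
$\omega, \kappa \in [10^{-4}, \sim 50]$ and branch lengths
$[10^{-6}, \sim 20]$ on the log scale; an $\omega$ estimate at the lower
bound is flagged rather than silently reported.

## Known limitations

* The chimera screen assumes a single breakpoint; double recombinants are
  scored as the best single-break mosaic.
* The copy-number model treats assays as conditionally independent given
  the composition; a strongly biased assay is only *flagged*, not
  down-weighted.
* NG86 and the F3x4 parameterization inherit their textbook biases at
  high divergence or strongly skewed composition; the dogrose alleles are
  well inside the comfortable regime (< 5% divergence).
* The four-allele ceiling assumes the founder population shares the
  bivalent allele; crossing lineages with different bivalent alleles can
  transiently show five distinct alleles, which the simulator permits —
  the ceiling applies to the canonical duplicated-bivalent configuration.
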