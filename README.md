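# caninaASE

Dogroses (*Rosa* sect. *Caninae*) are mostly pentaploid (2n = 5x = 35) yet
sexual, thanks to the unique **canina meiosis**: two homologous chromosome
sets pair as bivalents and recombine, while the other three are univalents
transmitted only through the egg. Pollen is haploid (n = x = 7), eggs are
tetraploid (n = 4x = 28). One consequence is that a single-copy nuclear
gene shows at most four distinct alleles, one of them — the allele on the
bivalent-forming sets — present in two identical copies.

`caninaASE` is an R package for asking, quantitatively, whether the
alleles ("homeologs") on recombining versus non-recombining chromosome
sets diverge in sequence or in transcription. It implements the full
analysis chain around the **copy-number null**: a diagnostic base carried
by alleles with *k* of the *p* genome copies is expected at fraction
*k/p* in genomic DNA (0.2, 0.4, 0.6 for k = 1, 2, 3 in a pentaploid) and,
under equal per-copy transcription, in cDNA pools as well. Deviations of
cDNA fractions from that null are allele-specific expression.

The package provides:

* **Canina meiosis simulator** — founders, pollen/egg gametes, zygotes
  and multi-generation populations with Poisson recombination between the
  bivalents and infinite-alleles mutation (`makeFounder`, `pollenGamete`,
  `eggGamete`, `fertilize`, `evolvePopulation`).
* **Pyrosequencing generator** — beta-binomial replicate fractions for
  gDNA and cDNA pools under an expression profile or per-assay target
  fractions (`simulateAssay`, `simulateExperiment`).
* **Allele calling** — single-linkage collapsing of cloned sequences into
  allele consensi, PCR-chimera screening, pairwise divergence, and
  discovery of pyrosequencing-suitable diagnostic SNPs
  (`collapseClones`, `detectChimeras`, `pairwiseDivergence`,
  `findDiagnosticSnps`).
* **Copy-number inference** — maximum-likelihood integer compositions of
  the ploidy from gDNA fractions, with ranked alternatives and anomaly
  flagging (`enumerateCompositions`, `inferCopyNumbers`,
  `flagAnomalousAssays`).
* **Allele-specific expression** — fold deviations with bootstrap CIs and
  a mixed-model ANOVA comparing templates with individual as random
  factor, plus Benjamini–Hochberg adjustment (`foldDeviation`,
  `glmTemplateTest`, `anovaNuisanceTest`, `aseReport`).
* **Molecular evolution** — minimum-change substitution counting,
  Nei–Gojobori dN/dS, a Goldman–Yang codon model (one- and two-ratio,
  compiled pruning likelihood), Tajima relative rate tests with FDR
  control, and a GY94 codon simulator (`countSubstitutions`, `ng86`,
  `m0Fit`, `twoRatioLrt`, `tajimaRrt`, `simulateCodons`).
* **Pipeline and I/O** — FASTA/BED-like/TSV readers and writers and an
  end-to-end simulated pipeline with a reproducibility manifest
  (`runPipeline`).

## Worked example

A LEAFY-like locus: four alleles, the third one duplicated on the
bivalents, three diagnostic assays, and cDNA pools in which the two-copy
allele is transcribed well below its 0.4 expectation:

```r
library(caninaASE)

g <- makeFounder("LEAFY-3", c("LEAFY-1", "LEAFY-2", "LEAFY-4"), "LEAFY")
alleleCopyNumbers(g, "LEAFY")
#> LEAFY-1 LEAFY-2 LEAFY-3 LEAFY-4
#>       1       1       2       1

assays <- data.frame(
  assay_id = c("LEAFY_SNP1", "LEAFY_SNP3", "LEAFY_SNP4"),
  locus = "LEAFY", position = c(12L, 45L, 90L),
  diagnostic_base = c("A", "G", "T"),
  carriers = c("LEAFY-1", "LEAFY-3", "LEAFY-4"))

obs <- simulateExperiment(g, assays, locus = "LEAFY", seed = 8,
                          cdnaTargets = c(LEAFY_SNP3 = 0.174,
                                          LEAFY_SNP1 = 0.58,
                                          LEAFY_SNP4 = 0.58))

calls <- inferCopyNumbers(obs, assays, paste0("LEAFY-", 1:4))
calls[["H13"]]
#> CopyNumberCall LEAFY / H13: LEAFY-1=1, LEAFY-2=1, LEAFY-3=2, LEAFY-4=1 (logLik -25.56)
#>   log-likelihood gap to runner-up: 24.68

aseReport(calls, obs, assays, seed = 3)[, c("assay_id", "expected",
                                            "meanCdna", "foldReported",
                                            "direction", "p")]
#>     assay_id expected  meanCdna foldReported direction            p
#> 1 LEAFY_SNP1      0.2 0.5771111     2.885556        up 0.0002111968
#> 2 LEAFY_SNP3      0.4 0.1704444     2.346806      down 0.0015313646
#> 3 LEAFY_SNP4      0.2 0.5798889     2.899444        up 0.0039623219
```

Read: the gDNA fractions identify the (2,1,1,1) composition (the
unassayed LEAFY-2 absorbs the residual copy); in the cDNA pools the
two-copy allele runs ~2.3-fold below its copy-number expectation while
the single-copy alleles run ~2.9-fold above it, each with the
mixed-model p-value for the gDNA-vs-cDNA contrast.

The fully simulated end-to-end pipeline (clones → alleles → SNPs →
pyrosequencing → copy numbers → ASE → dN/dS) runs with
`runPipeline(outDir, seed = 17)` and writes stage TSVs plus a checksummed
manifest.

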