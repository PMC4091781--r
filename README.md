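# scClonality

Deep sequencing of an unfractionated tumor yields a model of its clonal
architecture: somatic SNVs cluster at common variant allele fractions
(VAFs), each cluster marking a clonal expansion, clone frequencies are
proportional to cluster mean VAFs, and lower-frequency clones nest within
higher-frequency ones. Whether those predictions hold inside individual
cells can be tested by sorting single cells, amplifying their genomes
(WGA), and genotyping the validated SNVs — at the cost of heavy missing
data (locus dropout) and allelic dropout (ADO) that turns heterozygous
sites into apparent homozygotes.

`scClonality` implements that validation workflow end to end for
secondary-AML-style data, for analysts who want to stress-test bulk-derived
clonal models against single-cell genotypes (real or simulated):

- **simulate** — clonal hierarchies (nested clone frequencies + a
  non-tumor fraction), bulk read counts, and single-cell / two-cell read
  counts under a WGA noise model: per-allele dropout with probability *d*,
  zero-inflated negative-binomial coverage, per-read miscalls.
- **genotype** — a binomial maximum-likelihood caller gated at ≥25×
  coverage, plus allele-level benchmarking (TPR/FPR/FNR stratified by
  truth zygosity), ADO symmetry testing, and per-locus dropout
  concordance.
- **cellularity** — the core statistic: at each covered somatic locus the
  variant read count is modeled as *k* ~ Bin(*n*, *p*) with
  *p* = *f*(1−*e*) + (1−*f*)*e*, where *f* ∈ {0, 0.25, 0.5} is the source
  VAF implied by a candidate pair of clones (0.25 being the two-cell
  dilution of a private heterozygous variant) and *e* is a per-cluster
  error rate estimated from other subjects' cells. The best same-clone
  (pure) and best distinct-clone (mixed) hypotheses are compared by a
  likelihood-ratio test on a one-sided χ²₁.
- **clonality** — assignment of each cell to the deepest consistently
  observed cluster, discrimination of ADO from cryptic substructure,
  detection of mutually exclusive variant sets (evolutionary branch
  points) with family-wise error control, rescue of outlier SNVs by
  ADO-tolerant pattern matching, and clone-frequency concordance with
  bulk predictions.
- **phylo** — pairwise-deletion binary distances between cells, neighbor
  joining with a deterministic tie-break, nonparametric bootstrap branch
  support (≥75% flagged strong), and a two-state Felsenstein pruning
  likelihood for comparing fixed trees.

## Worked example

Twelve single cells from the biclonal subject UPN288033, simulated at
study-like noise, genotyped, benchmarked and mapped back to clones:

```r
library(scClonality)

arch <- samlArchitectures()[["UPN288033"]]
arch
#> ClonalArchitecture for subject UPN288033
#>   2 clones + 7% non-tumor
#>   clone1 (cluster 1, 62%) [founding]
#>   clone2 (cluster 2, 31%) <- clone1

expectedBulkVAF(arch, "2")
#> [1] 0.155      # half the cumulative prevalence of cluster 2

catalog <- samlLocusCatalog()          # 1,953 somatic SNVs: 872/777/304
sim <- simulateCells(arch, catalog, wgaNoiseModel(), nCells = 12, seed = 7)
gm  <- callMatrix(sim$counts)
gm
#> GenotypeMatrix: 12 cells x 2403 loci (callable threshold 25x)
#>   callable fraction: mean 0.56 (range 0.54-0.58)

benchmarkCalls(gm, sim$truth)
#> BenchmarkReport (allele-level accounting at callable sites)
#>    TP    TN FP  FN       TPR FPR       FNR
#>  2788 12927  0 341 0.8910195   0 0.1089805
#> by truth zygosity:
#>  zygosity   TP    TN FP  FN       TPR FPR       FNR
#>   hom-ref    0 12927  0   0        NA   0        NA
#>       het 2439     0  0 341 0.8773381  NA 0.1226619
#>   hom-var  349     0  0   0 1.0000000  NA 0.0000000

asn <- assignCells(gm, catalog, arch)
table(asn$assignments$clone)
#> clone1 clone2
#>      7      5
```

About 56% of sites clear the 25× gate and the het-site false-negative
rate sits near *d*/2 = 0.12 — the WGA artifact regime the noise model is
calibrated to — yet every cell maps back to its true clone. The full
driver (`runPipeline(runConfig(seed = 1), "out/")`) adds two-cell
mixtures, cellularity classification, branch screening, bootstrap
phylogenies and a cross-subject clone-frequency concordance table, all
reproducible bit-for-bit from the seed.

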