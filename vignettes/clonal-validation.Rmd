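---
title: "Validating tumor clonal architecture with single-cell genotypes"
author: "scClonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating tumor clonal architecture with single-cell genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scClonality)
```

## The problem

Bulk deep sequencing of a tumor produces, for each validated somatic SNV,
a variant allele fraction (VAF). SNVs that arose in the same clonal
expansion share a VAF and form a cluster; the cluster's mean VAF is half
the fraction of cells carrying it (every somatic SNV being heterozygous at
a diploid locus), and under linear evolution each successive clone nests
inside its parent. These are predictions about *single cells*: clustered
SNVs should co-occur in the same cells, clone frequencies should match
cluster VAFs, and cells should form a nested hierarchy. `scClonality`
implements the machinery to test those predictions with targeted
single-cell genotyping, and a simulator faithful enough to the technical
noise of whole-genome amplification (WGA) that every downstream stage can
be exercised and calibrated without any external data.

The package ships the three secondary-AML study subjects as built-in
models (`samlArchitectures()`): a five-clone nested hierarchy with 10%
non-tumor cells (6/4/33/33/14%), and two biclonal subjects (13/52% with
35% non-tumor; 62/31% with 7% non-tumor). The built-in capture design
(`samlLocusCatalog()`) carries their 872, 777 and 304 targeted somatic
SNVs (1,953 in total). The 60-variant size of the fifth cluster of the
five-clone subject is fixed by the study design; the remaining loci are
divided evenly among each subject's other clusters, a package choice with
no downstream consequence beyond per-cluster locus counts. Germline SNP
counts (200 heterozygous, 200 homozygous-reference, 50 homozygous-variant
per subject by default) are likewise package defaults chosen to give
benchmarking reasonable resolution; the study's published tables report
per-library callable positions, not panel totals, so no printed value
constrains them.

## The WGA noise model

`wgaNoiseModel()` has five parameters, all per cell × locus:

| parameter | default | meaning |
|---|---|---|
| `adoProb` (*d*) | 0.24 | one allele of a het pair is lost before amplification; the lost allele is uniform, so the variant allele is silenced with probability *d*/2 ≈ 0.12, the het-site false-negative rate the study attributes to ADO |
| `seqError` | 0.01 | per-read miscall probability |
| `depthMean` | 113 | mean on-target coverage of single-cell libraries |
| `depthDispersion` | 0.45 | negative-binomial size; WGA coverage is far from Poisson |
| `locusDropoutProb` | 0.10 | zero-coverage point mass (failed amplification) |

ADO is modeled *pre-amplification* as whole-allele loss, which is what
makes a het site genotype as a clean homozygote rather than a skewed
het — matching the observation that erroneous calls at known het SNPs are
homozygous in either direction at roughly equal rates (a property the
test suite checks with an exact binomial test). Dropout is i.i.d. across
cells and loci by default; `locusEffectSD` adds an optional shared
per-locus multiplier for studying site-specific dropout, but defaults to
off because stochastic effects dominate in this data type (shared locus
effects explain only a minority of dropout-rate variance, and
`locusDropoutConcordance()` exists precisely to measure this).

Coverage is zero-inflated negative binomial. The two free parameters were
calibrated once, jointly, to the single published constraint — roughly
55% of targeted sites reach the 25× callable threshold at mean coverage
113× — giving `locusDropoutProb = 0.10` and size 0.45
(0.9 × P(NB(0.45, 113) ≥ 25) ≈ 0.553). No distributional form is
published; zero-inflated NB is the smallest model that can hit both the
mean and the callable fraction.

Every cell is simulated over **all** subjects' somatic loci: a cell's
genome is reference at other subjects' private SNVs, exactly as in a
pooled capture experiment. This is not a convenience — it is what lets
subjects serve as mutual error controls for the cellularity model below.

Two-cell ("doublet") samples pool the four alleles of two cells with
equal amplification weight by default (`weightA = 0.5`); a locus het in
exactly one of the two cells then has expected VAF 0.25, the dilution
signature that separates genuine doublets from pure cells.

## Genotyping and its error budget

`callSite()` compares three binomial likelihoods — variant-read
probability `seqError` (hom-ref), 0.5 (het), `1 - seqError` (hom-var) —
at sites with ≥25× coverage, with two conservative guards: a non-reference
call needs ≥3 variant reads (so sequencing error cannot buy a variant
call at high depth), and likelihood ties break toward the reference. The
benchmark (`benchmarkCalls()`) uses allele-level definitions — a call is
positive if it contains at least one non-reference allele — and refuses
to report sensitivity where no true positives can exist (hom-ref truth)
or specificity where no true negatives can (het truth). With the default
noise model, benchmarking at germline het sites lands near TPR 0.88 and
FNR 0.12, the regime in which the downstream clonality logic must work.

## The cellularity likelihood-ratio test

For one sorted sample, restricted to covered somatic cluster loci, the
variant read count at a locus is modeled as

$$k \sim \mathrm{Bin}(n,\; p), \qquad p = f(1-e) + (1-f)\,e,$$

where *f* is the VAF of the source population and *e* a per-cluster
cumulative error rate. Candidate sources are all unordered pairs over
{clones ∪ non-tumor}: a pair implies *f* = 0.5 for clusters carried by
both members, 0.25 for clusters carried by exactly one, and 0 otherwise.
Identical pairs form the *pure* null (the model cannot, and does not try
to, distinguish one cell from two cells of the same clone); distinct
pairs are the *mixed* alternative. The statistic
2(ℓ_mixed − ℓ_pure), floored at zero, is referred to a one-sided χ²₁;
`classifySample()` calls a sample mixed when p < α (default 0.05).

Design choices worth stating:

- *e* is estimated per cluster, not per locus, by pooling the reads of
  other subjects' single cells at this subject's cluster loci
  (`estimateErrorProfile()`, clipped to [10⁻⁶, 0.5)); those cells are
  reference at every such locus, so their VAF *is* the cumulative
  error of WGA + library + sequencing.
- Germline het loci are excluded from the likelihood: *f* = 0.5 under
  every hypothesis (note *p* = 0.5 whenever *f* = 0.5, for any *e*), so
  they carry no discriminating signal.
- Per-locus log-likelihoods are summed with per-cluster *f* — the
  literal reading of the binomial model; zero-depth loci contribute
  nothing, and a sample with no covered cluster loci is classified
  `indeterminate` rather than forced.

Under study-default noise, ~94–95% of simulated pure cells classify pure
at α = 0.05 (the χ²₁ reference is conservative here because the pure
null sits on the boundary of the mixed space), and distinct-clone
doublets with ≥20 private loci at depth ≥50 are detected essentially
always — both properties are pinned in the acceptance suite at the ≥90%
and ≥80% levels.

## From genotypes to clones

`assignCells()` declares a cluster observed in a cell when at least half
of its ≥3 callable sites carry a variant call (`tauDetect = 0.5`,
`minCallable = 3`). With FNR ≈ 0.12 a majority rule separates presence
from dropout by a wide margin; no published numeric rule exists, so the
threshold is a package default. The assigned clone is the deepest
observed cluster whose ancestors are all observed; cells observing
nothing are non-tumor, and cells with a lineage gap (descendant observed,
ancestor not) are flagged `inconsistent` rather than force-assigned,
because such profiles are either dropout or substructure and deserve
inspection, not a new clone.

`referenceCallExcess()` asks whether reference calls inside
expected-variant clusters exceed the dropout expectation: exact binomial
tails per cell and (Bonferroni-corrected) per locus, with flagged loci
sharing an identical reference-cell pattern (≥2 loci × ≥2 cells)
reported as candidate substructure blocks — aggregation is what
separates substructure from scattered ADO.

`rescueOutliers()` assigns an unclustered SNV to a cluster only when its
presence/absence pattern matches the cluster's carrier cells with
mismatches exclusively in the variant→reference direction (ADO can hide
a variant, never invent one — a variant call in a non-carrier cell is a
hard disqualifier) and at most ⌈FNR × carriers⌉ of them; SNVs callable
in <4 cells, spanning <2 clones, or matching several clusters stay
unassigned. Outlier loci are represented simply as loci outside the
cluster definitions; the generator has no "spurious SNV" dial, since no
default rate could be defended.

### Branch detection and its null model

Mutually exclusive variant sets — set A variant in cells where set B is
reference and vice versa — are the signature of a branch point hidden
inside a bulk cluster. The statistical danger is selection: candidate
sets are found *in* the data, loci fragment into patterns through the
very dropout events being priced, and under linear nesting a descendant
cluster's loci are *genuinely* reference in ancestor-only cells. A naive
"probability that all cross-wise reference calls are dropout" computed on
pattern-matched groups mistakes both effects for evidence and reports
branches in almost every simulated linear dataset.

`detectBranches()` therefore (1) judges exclusivity against the given
cluster model, counting a reference call as evidence only in cells whose
assigned clone carries the locus's cluster; (2) scores each candidate
pair of disjoint cell sets by the *number of exclusive loci per side*
against that count's dropout-expected Poisson rate
(λ = Σ fnr^{callable expected-variant cross entries}), multiplying the
two sides' tails; and (3) Bonferroni-corrects over the 3^cells possible
disjoint cell-set pairs, which prices the data-driven choice of sides.
The result is conservative — branch points in this data type are
reported qualitatively and deserve conservatism — but retains full power
for real splits, where each side contributes many loci against a
near-zero expectation. On strictly linear simulations at study noise the
family-wise false-branch rate is controlled at the nominal level (the
acceptance suite checks 200 null replicates); running the detector with
a deliberately collapsed cluster model is how within-cluster splits are
discovered.

## Phylogeny

Cell-level trees are built independently of the cluster model: distances
are mismatch fractions over sites callable in both cells (pairwise
deletion — with ~45% no-calls, listwise deletion would leave nothing),
treating hom-ref as one state and variant-present as the other. The
binary simplification is deliberate: at validated somatic SNV sites the
biological signal is presence/absence of the variant, and nucleotide
substitution models add parameters the data cannot inform. Neighbor
joining uses the standard Q-criterion with negative branch lengths
clamped at zero and ties broken by lexicographic subtree labels, making
the output deterministic and row-order invariant; the test suite proves
exact recovery of additive distances against an exhaustive least-squares
topology search. `bootstrapSupport()` resamples loci with replacement
(1000 iterations by default; edges ≥75% flagged strong), and
`twoStateLogLik()` scores fixed trees by Felsenstein pruning under a
symmetric two-state model with transition probability
(1 − e^{−2rt})/2, marginalizing no-calls; tree *search* under this
likelihood is intentionally out of scope.

## Reproducibility and problem sizes

All randomness descends from one master seed through deterministic child
streams (`runPipeline()` writes the seed and a configuration hash into
its manifest; identical configurations give bit-identical outputs). The
test and acceptance suites run at deliberately desk-sized problems —
12–15 cells per subject, tens to hundreds of loci per check,
10⁴-locus Monte Carlo for rate-convergence checks, 200 replicates for
the type-I and power properties, 25–100 bootstrap iterations in tests
(1000 remains the analysis default) — sizes chosen so the full suite
completes in well under a minute while leaving every statistical check
adequately powered.

## What the simulations do and do not show

The generator reproduces the *statistical* structure of the study —
nested clone frequencies, binomial read sampling around expected VAFs,
symmetric whole-allele dropout, zero-inflated overdispersed coverage,
shared-panel cross-subject controls, equal-amplification doublets. It
does not model copy-number alteration or aneuploidy (all loci are
diploid, so the complex-karyotype subject is idealized), capture-bait
chemistry, alignment artifacts, doublets of three or more cells, or
amplification imbalance between the two cells of a doublet beyond the
`weightA` knob. Passing tests therefore demonstrate that the analysis
stages are correct and calibrated under the stated noise model, not that
the noise model captures every failure mode of real WGA libraries; on
real data the error profile should be re-estimated from the data itself,
as `estimateErrorProfile()` does.
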