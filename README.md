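# torporCAGE

Mice deprived of food at a cool ambient temperature enter *daily torpor* —
an active hypometabolic state in which oxygen consumption can fall below
30% of the normal rate while body temperature drifts towards ambient.
`torporCAGE` is an R/Bioconductor-style package for dissecting this state
at promoter resolution from CAGE (Cap Analysis of Gene Expression) data,
combined with Bayesian phenotyping of the animals themselves.  It is
aimed at regulatory-genomics and physiology groups who want the whole
chain — promoter calling, torpor-specific classification, motif geometry,
torpor detection, knockout phenotype modelling — as tested, reusable
functions that run end-to-end on synthetic data with known ground truth.

## What it computes

**Promoter calling and architecture.** CAGE-defined TSSs (CTSSs) are
single-base tag counts on a stranded genome.  Same-strand CTSSs at most
`maxGap` (20) bp apart are single-linkage clustered; clusters with fewer
than `minTags` (10) pooled tags are dropped; the dominant TSS is the
pooled argmax (ties to the 5' end).  Each promoter gets an entropy-based
shape index over the ±50 bp window around its peak,

    SI = 2 + Σᵢ pᵢ log₂ pᵢ ,

so all tags on one base give SI = 2 (singleton promoter), a uniform
spread over N bases gives 2 − log₂N, and SI < −1 marks a broad promoter.
GC content is computed over the same window.

**Differential expression and torpor-specific sets.** Counts are
TMM-normalised (trimmed mean of M-values, 30%/5% double trim,
precision-weighted), a common negative-binomial dispersion φ is estimated
by conditional maximum likelihood, and each contrast is tested with the
exact conditional NB test (binomial split test in the φ → 0 limit), with
Benjamini–Hochberg FDR control.  Promoters are then classified, each
direction-matched at FDR < 0.05:

* *reversible*: up Pre→Mid **and** down Mid→Post (or the mirror image);
* *hypometabolic*: changed towards the torpid state in both HiT→Mid and
  Fed→Mid (the two torpor-prevention conditions);
* *torpor-specific*: the intersection of the two;
* *deprivation-specific*: changed in Dep vs Mid, with the overlap against
  the torpor-specific set reported (the upstream-regulator candidates).

**Motif geometry.** JASPAR-format PWMs are scanned (log₂-odds, both
strands, N scores 0) over the −300/+100 bp windows around each dominant
TSS; set-level enrichment uses Fisher's exact test with Bonferroni
correction, and positional profiles report where in the window a motif
concentrates (e.g. a site planted 79 bp upstream of the TSS is reported
at offset −79).

**Torpor detection.** Day-1 body temperature and VO₂ are fitted with a
Bayesian two-harmonic circadian regression; a time point is torpid iff
every available signal falls below the lower 99.9% posterior-predictive
bound for its time of day *and* the point lies in ZT 12–24.  Minimal T_B
and VO₂ over the torpid points are the phenotypes fed into the knockout
model.

**Knockout phenotyping.** Minimal phenotypes across lines g and alleles a
follow a hierarchical two-state model

    Y_NORMAL ~ Normal(α + β[g,a], σ_NORMAL)
    Y_TORPOR ~ Normal(α + β[g,a] + γ[g,a], σ_TORPOR)
    β ~ Normal(0, σ_β),  γ ~ Normal(0, σ_γ)

with Half-Cauchy(0, 2.5) priors on σ_β, σ_γ and HalfNormal(10) on the
residual scales.  Knockout effects are read off the posterior of
γ[g,a] − γ[g,wt], summarised by the median and 89% HPDI, with split R-hat
and effective-sample-size diagnostics.  A ΔΔCT estimator for qPCR uses
the same machinery.

A synthetic-data module (`simConfig`, `genGenome`, `genCTSS`,
`genPhysio`, `genKOPhenotypes`) generates every input with the
statistical structure the analysis assumes, so the full pipeline is
testable without any download.

## Worked example

Simulate a study-sized experiment (Pre 4 / Mid 8 / Post 4 / HiT 4 /
Fed 4 / Dep 4, NB dispersion 0.2) with three planted torpor-specific
promoters, and recover them:

```r
library(torporCAGE)

cfg <- simConfig(seed = 42, nGenes = 120, genomeLength = 4e5,
                 librarySize = 1e5, dispersion = 0.2,
                 effectTable = torporEffectTable(up = c("gene0007", "gene0101"),
                                                 down = "gene0055", lfc = 2))
gg <- genGenome(cfg)
tracks <- genCTSS(cfg, gg$genome, gg$genes)
clusters <- clusterCTSS(tracks, maxGap = 20, minTags = 10)
clusters <- annotateClusters(clusters, gg$genes)
clusters <- gcContent(shapeIndex(clusters), gg$genome)
clusters
#> TagClusters with 120 promoters
#>   pooled tags: 2791743
#>   SI range: [-3.18, -0.83]
#>   gene-associated: 120

counts <- countCTSS(tracks, clusters)
normFactors(counts) <- tmmFactors(counts)
phi <- estimateCommonDispersion(counts)
round(phi, 3)
#> [1] 0.19

de <- list(entry = nbExactTest(counts, "Pre", "Mid", phi),
           exit  = nbExactTest(counts, "Mid", "Post", phi),
           hit   = nbExactTest(counts, "HiT", "Mid", phi),
           fed   = nbExactTest(counts, "Fed", "Mid", phi))
sets <- torporSpecific(classifyReversible(de$entry, de$exit),
                       classifyHypometabolic(de$hit, de$fed))
sets
#> $up
#> [1] "chr1:21484-21585,+"   "chr1:336078-336178,-"
#> $down
#> [1] "chr1:181303-181402,+"

rankByTotalFC(sets$up, de$entry, de$hit)
#>            promoter_id   logFC1   logFC2 total_fc
#> 1   chr1:21484-21585,+ 2.153766 2.777135 4.930901
#> 2 chr1:336078-336178,- 2.092196 1.887762 3.979958
```

The three recovered promoters map back (via `annotateClusters`) to
exactly the three planted genes; the estimated dispersion 0.19 matches
the simulated 0.2; the ranked log-fold-changes sit near the planted
|log₂FC| = 2 per contrast.  `runPipeline()` chains all stages (including
torpor detection and the KO model) into one output directory with
provenance headers on every file.

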