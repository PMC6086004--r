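# corepress

Consensus calling of gene panels co-regulated by two transcription factors
from multi-shRNA knockdown RNA-seq.

## The problem

Knockdown screens that ask whether two regulators (say, a transcription
factor and the catalytic subunit of a chromatin-modifying complex) jointly
sustain a set of target genes typically use one control hairpin (e.g.
shGFP) and **two independent shRNA clones per factor**, in replicate. Two
clones guard against off-target effects, but they complicate the analysis:
clone 1 of each factor may perturb the *other* factor's expression
(cross-enhancement), so the two clones cannot simply be pooled. The
analysis this package implements keeps the clones separate and demands
consensus across them.

For each gene *g* and clone *c*, the repression efficiency is

    r_c(g) = 1 − FC_c(g),   FC_c(g) = mean normalized expression (knockdown)
                                      / mean normalized expression (control)

so `r = 0.30` means "repressed by 30%" and negative `r` means enhancement.
A gene enters the **consensus (co-repressed) panel** iff

1. `r_A1 ≥ 0.30` and `r_B1 ≥ 0.30` (stringent clone-1 repression by both
   factors),
2. BH-adjusted P `q_A1 ≤ 0.05` and `q_B1 ≤ 0.05`, and
3. `r_A2 ≥ 0` and `r_B2 ≥ 0` (no enhancement by the confirmatory clones).

The panel is ranked by the **co-repression score**, the common part of the
two clone-averaged repression efficiencies:

    score(g) = min( (r_A1 + r_A2)/2 , (r_B1 + r_B2)/2 )

Complementary partitions use clone averages: *A-only* genes
(`mean r_A ≥ 0.30`, `mean r_B ≤ 0.10`), *B-only* symmetrically, and
*co-activated* genes (`min(mean a_A, mean a_B) ≥ 0.47` with activation
`a = −r`). Panels are evaluated by intersection with prior panels and by
gene-set over-representation: one-sided hypergeometric (Fisher exact)
P values with fold enrichment `(k/n)/(K/N)` and BH FDR across a GMT
collection.

Because such studies rarely release raw reads, the package includes a
seeded negative-binomial simulator that emulates the 5-condition ×
3-replicate design with planted co-repressed / exclusive / co-activated /
null gene classes (plus marker genes carrying the cross-enhancement
pattern), so the entire pipeline is verifiable against known truth.

## Worked example

```r
library(corepress)

se <- simulateKnockdown(simParams(nGenes = 2000, seed = 1))
rp <- repressionProfiles(se)        # normalize + per-clone r, p, q
gp <- callPanels(rp)
gp
#> GenePanels (score convention: min_of_clone_averages )
#>   consensus 196 | factor-A only 82 | factor-B only 91 | co-activated 112

head(as.data.frame(consensusPanel(gp))[, 1:6], 3)
#>        gene     score      r_A1      r_A2      r_B1      r_B2
#> g0108 g0108 0.6935014 0.7128319 0.7928882 0.7077390 0.6792638
#> g0177 g0177 0.6737470 0.7298614 0.6246068 0.6582572 0.6892369
#> g0144 g0144 0.6711712 0.7397467 0.7286018 0.6949108 0.6474316
```

The simulation planted 10% of genes (200) as co-repressed at 60%
efficiency; the consensus call recovers 196 of them (the panel's `score`
column sits near the planted 0.6, inflated slightly by selection). Against
a simulated gene-set collection with one set planted at 90% co-repressed
membership:

```r
tt  <- truthTable(se)
gsc <- simulateGeneSets(tt, nSets = 10, plantedEnrichment = 0.9, seed = 1)
head(as.data.frame(enrichCollection(consensusPanel(gp)$gene, gsc,
                                    universe = tt$gene)), 3)
#>                           set  k  K expected     fold            p            q
#> cycle_like         cycle_like 44 50 4.892661 8.993061 3.281858e-40 3.610043e-39
#> random_set_009 random_set_009  9 50 4.892661 1.839490 4.942425e-02 1.812222e-01
#> random_set_010 random_set_010  9 50 4.892661 1.839490 4.942425e-02 1.812222e-01
```

The planted set ranks first at 9-fold enrichment; the uniform sets hover
around fold 1. `overlapPanels()` reports panel intersections with
flag compositions, `relativeExpressionDdct()` /
`relativeExpressionEqualInput()` handle RT-qPCR validation tables, and
`runPipeline()` drives the whole analysis from a YAML configuration,
writing every intermediate TSV plus a JSON run report.

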