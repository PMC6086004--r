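---
title: "Methods: consensus panel calling from multi-shRNA knockdown RNA-seq"
author: "corepress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus panel calling from multi-shRNA knockdown RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepress)
```

# The experimental design and its statistical consequences

The pipeline targets a specific screen layout: one control hairpin and two
independent shRNA clones against each of two factors (call them A and B),
each condition in replicate — five conditions in all. Two clones per
factor exist to control off-target effects, but the clones are not
exchangeable: a clone that knocks down factor A can *elevate* factor B's
transcript (and vice versa), a compensatory cross-enhancement that makes
clone-1 contrasts systematically different from clone-2 contrasts. The
panel definitions therefore treat clones asymmetrically: stringent
repression and significance requirements on the clone-1 contrasts, and
only a sign constraint (no enhancement) on the clone-2 contrasts.

# Repression profiles

## Normalization

Counts are normalized by median-of-ratios size factors: each sample's
factor is the median, over genes with all-positive counts, of the ratio of
its count to the gene's geometric mean across samples (computed on the log
scale, so an even number of retained genes takes the geometric midpoint of
the two central ratios). This anchors scaling on the majority of genes and
is insensitive to the minority of strongly regulated ones, which matters
here because up to a quarter of simulated genes are planted as regulated.
Degenerate inputs fail loudly: an all-zero matrix, or any sample with zero
total count, is an error naming the sample.

## Fold change and repression

Per gene and clone, the fold change is the ratio of group means of
normalized counts, with a pseudocount in numerator and denominator:

$$FC_c = \frac{\overline{x}_{kd,c} + \delta}{\overline{x}_{ctrl} + \delta},
\qquad r_c = 1 - FC_c.$$

The ratio-of-means form (rather than mean of per-replicate ratios) matches
how qPCR-style relative expression is conventionally summarized and is
stable at small counts. The pseudocount `δ` defaults to 0.5 counts; it
bounds fold changes for genes that drop to zero and is the same offset
used inside the log transform for testing. Note one consequence: exact
invariance of `FC` under rescaling a sample holds at `δ = 0` (the size
factors absorb the rescaling), and only approximately for `δ > 0`.

## Testing

P values come from a two-sided test on `log2(normalized + δ)` comparing
each clone's replicates against the control replicates. The default is a
moderated t (limma): per-gene variances are shrunk toward a mean–variance
trend estimated across genes. With the replicate numbers these designs
actually use (triplicates), an unmoderated per-gene Welch test discards
too much information: its per-gene variance estimates at 2 degrees of
freedom make the BH-adjusted clone-1 significance criterion miss a
substantial fraction of genuinely co-repressed genes. Sharing variance
information across genes is the standard remedy and is what makes the
planted-panel recovery guarantee (below) attainable; the plain Welch
variant remains available as `test = "welch"` for users who want fully
independent per-gene tests. The trend fit engages when at least 100 genes
are available; below that a constant prior is used. Degenerate rows under
the Welch test (zero variance in both groups) are resolved by the data:
p = 1 when the group means agree, p = 0 otherwise.

Benjamini–Hochberg adjustment is applied within each clone's gene-wise P
vector — each clone contrast is its own testing family, since the panel
criteria consume per-contrast adjusted P values.

## The expression floor

Genes whose mean normalized control expression falls below
`expressionFloor` (default 5 counts) are flagged `low_expression` and made
ineligible for every panel, but never dropped from the profile table. The
floor prevents pseudocount-driven artifacts: at very low counts the
pseudocount dominates the fold change and repression estimates become
uninterpretable.

# Panel definitions

* **Consensus**: `r_A1 ≥ 0.30`, `r_B1 ≥ 0.30`, `q_A1 ≤ 0.05`,
  `q_B1 ≤ 0.05`, `r_A2 ≥ 0`, `r_B2 ≥ 0`. The clone-2 criterion is applied
  to each clone individually, as a sign constraint.
* **Score and ranking**: the "efficiency of co-repression" by the two
  factors is read as the *common part* of the two clone-averaged
  repression efficiencies, i.e. their minimum. Alternative readings (the
  mean of the two averages, or their product) would let strong repression
  by one factor compensate for weak repression by the other, which is
  exactly what a co-regulation ranking must not do. The convention is
  recorded in the `GenePanels` provenance. Ties are broken
  lexicographically by gene identifier, everywhere, so rankings are stable
  across runs and platforms.
* **Exclusive panels** apply to clone averages (own factor ≥ 0.30, other
  factor ≤ 0.10): the definitions speak of repression "by factor A"
  collectively, and averaging the two clones is the natural collective
  summary. The deliberate gap between 0.10 and 0.30 leaves weakly
  cross-repressed genes unassigned rather than forcing a label.
* **Co-activated panel**: activation `a = −r`; a gene qualifies when the
  *weaker* factor's clone-averaged activation reaches 0.47, and the panel
  is ranked by that minimum — the mirror image of the co-repression score.

Under the default thresholds the consensus panel is provably disjoint from
both exclusive panels, and every consensus gene's score is at least 0.15
(worst case: 0.30 and 0 averaged on each side). Raising any minimum
threshold can only shrink a panel; this antitonicity is exercised as a
property test.

# Enrichment and overlap

Over-representation uses the one-sided hypergeometric (Fisher exact) upper
tail, with expected overlap `nK/N` and fold enrichment `(k/n)/(K/N)`; an
empty overlap reports fold 0. The background universe `N` defaults to
21,000 — the approximate size of a genome-wide functional-annotation
database — but whenever the tested genes are known (as in the pipeline),
the tested-gene universe is used instead: enrichment against the measured
universe is the statistically defensible default. A two-sided variant is
available behind a flag. BH is applied across the collection, and results
are sorted by adjusted P, then decreasing fold, then set name.

Gene identifiers are matched by case-insensitive exact symbol comparison;
no alias resolution is attempted, and users mixing annotation sources
should harmonize symbols beforehand. Reported compositions (the share of
an overlap carrying an annotation flag) are rounded **half-up** to integer
percentages, matching how such figures are conventionally quoted; R's
default banker's rounding would turn 12.5% into 12%.

The packaged fixture `inst/extdata/table1_overlap_genes.gmt` carries the
39 cell-cycle-annotated genes of a published 54-gene panel overlap
(GINS2 through MAD2L1). The companion 20-gene DNA-replication sub-list was
marked only by color in its source and is not machine-recoverable, so it
is not packaged.

# RT-qPCR relative quantification

The comparative-Ct calculator supports the two normalization modes used in
validation experiments: classical ΔΔCt against an internal reference gene
(`ΔCt = Ct_target − Ct_ref`, calibrated to a designated condition,
relative expression `2^−ΔΔCt`), and an equal-input mode (`ΔCt = Ct`) for
situations where the reference gene itself responds to the perturbation.
Replicates are aggregated on the ΔCt scale — the geometric mean of
relative expressions — with per-condition ranges reported. Amplification
efficiency is fixed at perfect doubling; efficiency-corrected
quantification would need standard-curve data the table format does not
carry. When the reference gene is flat across samples the two modes agree
exactly; this equivalence is a unit test.

# The simulator: what it emulates, and what it does not

`simulateKnockdown()` draws counts from a negative-binomial model:
gene *g* in sample *s* has mean
`baseline_g × (1 − r[g, clone(s)]) × libFactor_s` and shared dispersion
`φ` (variance `μ + φμ²`). Defaults, chosen once as the simulated study
conditions:

| parameter | default | rationale |
|---|---|---|
| genes | 5,000 | large enough for stable FDR behavior, small enough for fast tests |
| replicates | 3 | triplicate design |
| planted classes | 10% co-repressed, 5% each A-only / B-only / co-activated | a sizeable but minority regulated fraction |
| true repression | 0.6 on all relevant clones (co-activated: 2-fold activation) | comfortably above the 0.30 call threshold, as expected of genuine direct targets |
| dispersion φ | 0.05 | low biological variability typical of clonal cell-line triplicates |
| baseline | log-normal, meanlog = log(2000), sdlog = 1 | concentrates a full polyA library (~15–20M usable counts) on the simulated gene panel, keeping per-sample depth — and hence the mean–variance regime and normalization behavior — realistic despite simulating only a few thousand genes |
| library factors | all 1 | configurable, to exercise normalization |

Three marker genes reproduce the cross-enhancement confound: each factor's
own transcript is repressed 80% by its two clones and elevated 1.5-fold by
the other factor's clone 1, plus one neutral control gene. Markers are
labelled as their own class so they never contaminate class statistics.

All draws flow from a single seeded generator, and the caller's RNG state
is saved and restored, so identical parameters give bitwise-identical
matrices and simulation never perturbs user code.

What the simulator does **not** model: read-level noise (no FASTQ or
alignment), transcript isoforms, GC/length bias, batch effects,
gene–gene correlation, or outlier samples. Passing the recovery tests
therefore demonstrates that the pipeline's inference machinery is correct
and calibrated under its stated noise model — not that real libraries meet
that model. On real data, dispersion varies across genes and samples can
fail QC; the moderated test tolerates the former, but the latter is the
user's responsibility.

# Verification strategy and problem sizes

The test suite checks every computational primitive against an independent
oracle implemented naively in the tests themselves: BH against an explicit
double-loop step-up, the hypergeometric tail against a sum of point masses
(instances up to N = 500), size factors against a gene-by-gene
recomputation (with an odd gene count, where the ratio-scale and log-scale
medians coincide exactly) and against an established implementation, panel
calls against row-by-row predicate evaluation, ranking against a
brute-force sort, and ΔΔCt against a spreadsheet-style recomputation.
Floating-point agreement is asserted at 1e-12 where the arithmetic is
exact, 1e-9/1e-10 where normalization or text round-trips intervene.

The distributional guarantees use the default study conditions: an
all-null simulation of 5,000 genes for test calibration (rejection rate at
p < 0.05 expected in 0.05 ± 0.02), and five seeded replicates of the
planted design for consensus-panel recovery (sensitivity ≥ 0.95,
false-discovery proportion ≤ 0.05). These sizes keep the full suite and
the acceptance script to well under a minute each while leaving the
binomial noise on the measured rates far inside the asserted bands.

# Known limitations

* The DE stage offers no dispersion shrinkage on the count scale, GLM
  offsets, batch covariates, or isoform-level testing; it is a
  normalized-log-scale analysis tuned for the balanced 5-condition design.
* Published panel sizes from any particular study depend on that study's
  unreleased raw data, read processing, and annotation versions; this
  package reproduces the *procedure* and its arithmetic, not those
  specific gene lists.
* Enrichment results depend entirely on the supplied GMT collections; the
  package ships no annotation database.
* The pipeline's interface is R functions plus a YAML-configured
  `runPipeline()`; there is no shell executable, in keeping with how
  analysis packages of this kind are used interactively and scripted via
  `Rscript`.
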