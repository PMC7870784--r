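---
title: "Methods: pathway-level miRSNP network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-level miRSNP network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnpnet)
```

## The analysis in one paragraph

`mirsnpnet` asks how single-nucleotide polymorphisms that sit in miRNA
genes or in miRNA binding sites (miRSNPs) could rewire disease biology at
the pathway level. Starting from a curated disease risk-gene list, it
identifies the risk pathways that list is over-represented in, tests which
pathway pairs share more genes than chance (crosstalk), integrates
multi-tool miRNA-target predictions into a consensus target map, tests
which miRNAs significantly target which risk pathways, overlays
database-supported miRSNPs onto the resulting bipartite miRNA-pathway
network (the PMSN), and finally enumerates miRSNP -> miRNA -> risk gene ->
pathway axes: a SNP in a binding site shared by a family of miRNAs, on a
risk gene, reaching the pathways that gene and those miRNAs connect to.

## The core statistic

Every significance test in the package is the same over-representation
test. For a universe of $m$ genes, a reference set of $j$ genes, a query
set of $n$ genes and an observed overlap of $x$ genes, the probability of
an overlap at least as large under hypergeometric sampling is

$$P(X \ge x) \;=\; \sum_{i=x}^{\min(j,n)}
\frac{\binom{j}{i}\binom{m-j}{n-i}}{\binom{m}{n}}.$$

The three applications differ only in what plays the role of the query
set: the risk-gene list (pathway enrichment), a second pathway (crosstalk;
the statistic is symmetric in $j$ and $n$), or a miRNA's consensus target
set (miRNA-pathway targeting). Within each family of tests, p-values are
adjusted by the Benjamini-Hochberg step-up and compared to a single
threshold, 0.01 by default, used consistently at every stage.

### Tail direction

The cumulative hypergeometric sum is sometimes written as a lower tail,
$\sum_{i=0}^{x}$. For over-representation that tail is the wrong one — it
is large, not small, for surprisingly big overlaps. `hypergeom_lower()`
implements the literal lower tail and every pipeline stage accepts
`tail = "lower"` for comparison, but the default throughout is the upper
tail `hypergeom_upper()`, which is the quantity an enrichment or crosstalk
claim is actually about. The two are linked by
$P(X \ge x) = 1 - P(X \le x-1)$, which the test suite sweeps exhaustively.

### Numerical choices

Tail sums are accumulated on the log scale via `lchoose` with a max-shift
before exponentiation, so genome-scale universes ($m = 20{,}000$ and
larger) neither overflow nor lose the tiny probabilities the tests trade
in; agreement with an exact-rational oracle is at the $10^{-12}$ level for
every instance with $m \le 25$, and the degenerate tails ($x = 0$, full
support) return exactly 1. Impossible parameter combinations (overlap
larger than either set, sets larger than the universe, non-integers) are
domain errors naming the offending field, never silent clamps.

Two properties of the BH step-up deserve a note. The adjusted vector is a
fixed point of the *monotonicity* step — adjusted values never decrease
with raw-p rank — and the test suite asserts this together with
order-preservation and agreement with an independently coded step-up on
random vectors. Re-running the full adjustment on its own output, however,
is not an identity (each pass multiplies by $M/\mathrm{rank}$ again), so
adjusted p-values are treated strictly as end products, never re-fed.

### Multiple-testing families

Which tests form one BH family is a genuine modelling choice:

* **Pathway enrichment** corrects across *all* pathways in the collection,
  including those with zero overlap with the query. The tested family is
  the collection, not the lucky subset with hits; excluding zero-overlap
  pathways from the family would overstate significance. Pathways with
  $x = 0$ are omitted from the result table but counted in $M$.
* **Crosstalk** corrects across all unordered pairs of the supplied
  pathways. By default only the significant risk pathways are tested
  (`crosstalk_scope = "risk-only"`); testing risk pathways against an
  entire collection is available as `"vs-all"`.
* **miRNA-pathway targeting** corrects globally across the full miRNA
  $\times$ pathway grid, which controls the FDR of the reported pair list
  as a whole — that list is the result. Per-miRNA correction is available
  via `fdr_scope = "per_mirna"` for sensitivity analysis.

All candidate risk pathways are tested against every consensus miRNA and
significance decides which pathways enter the network; no pathway subset
is fixed in advance.

### The universe

The universe $m$ defaults to the union of all genes in the pathway
collection — the only universe derivable from the inputs alone. An
explicit universe file restricts both pathways and query to it (query
genes outside the universe are dropped from $n$ with a warning, standard
over-representation practice), and a fixed integer `m` can stand in for an
unenumerated "whole genome" when that is the intended reference. All three
conventions give identical overlap counts; they differ only through $m$ in
the tail probability, which is why the choice is exposed rather than baked
in.

## Evidence filters

Two consensus rules gate the evidence before any network is built:

* A (miRNA, gene) prediction is kept when at least `k = 4` of the
  (default 10) prediction tools agree; duplicate rows from one tool count
  once. Raising `k` can only shrink target sets — a monotonicity the tests
  assert.
* A miRSNP record — one (rsID, miRNA, gene) triple for binding-site SNPs,
  one (rsID, miRNA) for SNPs in miRNA genes — is kept when it is
  experimentally validated *or* supported by at least `min_dbs = 2`
  distinct databases. The two clauses are read as a disjunction:
  experimental validation is stronger evidence than a second database, so
  it suffices on its own. Database rosters are per-class configuration
  (default sizes 4 and 3), not hard-coded names.

## The PMSN and its topology

The retained miRNA-pathway pairs form an undirected bipartite graph.
Binding-site SNPs annotate an *edge* (miRNA, pathway) exactly when that
edge exists and the SNP's gene belongs to that pathway; miRNA-gene SNPs
annotate their miRNA's *node* when present. SNPs that attach nowhere are
returned in an `unattached` report rather than dropped, because a SNP that
fails to attach is diagnostic (its gene left the pathway after universe
restriction, or its pair fell below the threshold).

Topology is computed on the bipartite graph as-is, without projection,
since the network of interest is the single mixed miRNA/pathway graph:
exact degrees, exact betweenness centrality normalized by
$(N-1)(N-2)/2$ (so a star hub scores 1 and leaves 0), and a power-law fit
to the pooled degree histogram. The fit is a least-squares line on
$\log_{10}$ frequency versus $\log_{10}$ degree over non-empty bins —
the "fitted curve on a histogram" convention — reporting the exponent as
the negated slope together with $R^2$; a maximum-likelihood exponent
(continuous approximation) is available via `method = "mle"` for
comparison. Degenerate inputs are defined, not errors: single-node and
two-node graphs have betweenness 0, and a single-bin histogram returns an
`NA` fit.

## Axis extraction

Retained binding-site SNPs are grouped by (rsID, gene). The miRNA family
structure is *emergent*: miRNAs belong to one axis because they share the
same SNP-gene binding site, not because a family annotation file says so —
seed-sharing families fall out of the data. A group becomes an axis when
the gene is on the risk list and is a consensus target of every miRNA in
the group; the axis reaches every pathway that contains the gene and has a
retained pair with *at least one* of the group's miRNAs (different family
members may carry the link to different pathways). Axes re-validate
against an exhaustive independent scan in the tests, and output order is
fixed by (rsID, gene).

## What the synthetic generator emulates

`synth_config()` defaults define the study conditions: a 20,000-gene
universe; 300 pathways with sizes log-uniform on 20-300; a 54-gene risk
list, 60% of it planted into 5 designated pathways; 500 miRNAs with
log-uniform 20-200 true targets; 10 prediction tools behaving as
independent Bernoulli detectors (sensitivity 0.7) plus uniform false
positives (rate 0.001); 42 binding-site and 12 miRNA-gene SNPs that
survive the evidence filter, plus deliberately under-supported noise
records; and optional planted axes via `plant_axis()`.

Several choices make the planted ground truth *exact by construction*
rather than approximate:

* Planted pathways occupy disjoint gene segments except for shared blocks
  between consecutive pathways — the planted crosstalk chain. The block is
  capped at a quarter of the smaller neighbor so even the smallest pathway
  keeps enough exclusive genes to carry its planted signals.
* Planted risk genes are spread evenly over the planted pathways'
  exclusive genes, so every planted pathway receives a strong overlap
  rather than a lucky draw.
* miRNAs without a planted link draw targets entirely outside the planted
  pathways, and planted targeting samples only a pathway's exclusive
  genes. A retained non-planted pair is therefore a genuine false
  positive, not an accounting ambiguity, and the expected count is
  essentially zero under the source-noise model (a false prediction would
  need to recur in 4 of 10 tools).
* Planted axes force their (miRNA, gene) predictions to at least `k`
  sources and mark their shared SNP as validated, so axis survival is
  deterministic; axis SNPs get fresh genes and fresh miRNAs so they cannot
  collide with other planted structure. One side effect is real: axis
  genes placed into several planted pathways add genuine shared genes, so
  two pathways hosting the same axis genes can acquire a crosstalk edge
  beyond the planted chain — those edges are correct, they are simply not
  part of the chain bookkeeping.

What the generator does **not** emulate: sequence-level realism (no seed
matches, binding energies or 3'-UTR coordinates), inter-tool correlation
(real prediction tools share algorithms and training data; here sources
err independently, which makes the $\ge k$-of-$N$ rule better behaved
than it is in practice), identifier messiness, and annotation bias in
pathway membership. Passing the planted-recovery suite therefore shows the
pipeline's logic and statistics are correct under its own model — it does
not certify performance on real database snapshots.

## Problem sizes used by the test suite

Unit tests run the generator at a reduced scale (4,000 genes, 60 pathways,
80 miRNAs) chosen to preserve every planted structure class while keeping
each test in the low seconds; the end-to-end recovery checks and the
acceptance script run the full default scale (20,000 genes, 300 pathways,
500 miRNAs), which completes in a few seconds per run. Oracle sweeps use
every hypergeometric instance with $m \le 25$, 10,000 random BH vectors,
and random bipartite graphs up to 30 nodes for betweenness.

## Known limitations

* Gene identifiers are uppercased symbols; no identifier mapping is
  attempted, so inputs must share a naming convention.
* The packaged worked-example bundle is a hand-constructed input fixture:
  its filler genes are synthetic and its pair statistics are illustrative
  inputs, not computed results.
* The power-law fit is descriptive, matching the histogram-plus-line
  convention; it is not a formal scale-free hypothesis test, and no
  small-world statistic is computed.
* Crosstalk is gene-overlap crosstalk only; interaction-based measures
  (shared regulators, protein-protein edges) are out of scope.
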