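---
title: "Motif-based target prioritization in macrophage regulatory networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based target prioritization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamnet)
library(dplyr)
```

`tamnet` turns a directed regulatory network of macrophage signaling plus
expression data into a shortlist of drug-repurposing targets. This
vignette explains the underlying models, the parameters that matter, the
numerical conventions, and the design decisions that were genuinely open —
together with what the synthetic test bed does and does not demonstrate.

## The pipeline model

The working hypothesis is that small regulatory motifs — feedback loops
(FBLs, directed cycles) and feed-forward loops (FFLs, a regulator acting
on a target both directly and through intermediates) — are where
deregulation concentrates, so genes sitting in differentially expressed,
topologically central motifs are the most promising intervention points in
tumor-associated macrophages (TAMs).

### Expression pruning

Bulk counts are converted to transcripts per million,
$\mathrm{TPM}_g = \frac{c_g / \ell_g}{\sum_j c_j/\ell_j} \times 10^6$,
with $\ell_g$ the transcript length in bases; each sample column then sums
to $10^6$ (checked in tests to a relative $10^{-6}$). A node survives
pruning only with mean TPM **strictly greater than** the threshold
(default 10 TPM) *and* degree at least one. The two conditions interact:
removing a silent node can orphan a neighbour. We therefore iterate
isolate removal to a fixed point, which makes the result order-independent
and the operation idempotent. The pipeline never forces a single connected
component; `glance()` reports the component count so fragmentation is
visible rather than silently repaired.

### Single-cell stage

Quality control keeps cells with at least 120 detected features and a
mitochondrial read fraction of at most 25% (a cell exactly at 25% is
kept; strictly above is discarded). TAMs are gated by requiring strictly
more than 1 normalized expression in at least two of CD68, CD163 and
CD14 — a deliberately stringent, contamination-averse rule. Both filters
are per-cell predicates, so QC and gating commute (a tested property).

Expression is normalized as $\ln(1 + 10^4\, c / C)$ with $C$ the cell
total — the standard library-size log transform; thresholds referring to
"expression" are applied on the de-logged per-10k linear scale. Genes
detected in at least 1% of cells in *both* groups are tested with a
two-sided Wilcoxon rank-sum test. The fold change is computed on the
de-logged scale with a pseudocount of one:
$\log_2 \frac{\overline{\exp(x_{\mathrm{TAM}})-1} + 1}
{\overline{\exp(x_{\mathrm{CTRL}})-1} + 1}$.
Multiple testing uses Bonferroni over the *tested* genes by default; a
`bonferroni_m = "total"` option corrects over all genes instead, since
either convention is defensible and they differ only in stringency (the
"total" variant never calls more genes — also a tested property).

The rank-sum p-value is exact whenever the combined group size is at most
30: a shift-algorithm dynamic program over the tie-aware rank multiset
(midranks doubled onto an integer grid) yields the exact conditional null
distribution, ties included. Larger groups use the classical normal
approximation with tie and continuity corrections. Tests verify the exact
branch against full enumeration of all group assignments.

### Motif enumeration

Seven templates are matched: the self-loop FBL1, directed cycles FBL2–4,
the three-node FFL, a four-node chain with shortcut, and a four-node
diamond. This mix of four feedback and three feed-forward loop types
follows common practice in regulatory-network motif analysis, but there
is no single canonical pattern table, so the set is a documented default:
alternative patterns can be supplied as YAML and are matched by the same
engine.

Matching is injective but not induced: all template edges must exist,
extra edges are allowed, and the interaction sign is ignored (sign-aware
matching would require sign conventions that are not standardized).
An instance is identified by (template, node set, edge set), which makes
rotation-equivalent cycle traversals one instance while keeping
reversed cycles and differently-rolled FFLs distinct. The matcher is
validated against an exhaustive subset/permutation oracle on hundreds of
random digraphs.

### Scoring and Pareto selection

Each motif gets three features: mean log2 fold change over its nodes
(genes without a differential-expression record contribute zero — absence
of evidence is treated as no change), mean betweenness centrality, and
mean degree. Betweenness is exact, directed, endpoint-excluding, computed
on the simple digraph, with unreachable pairs contributing zero, and
normalized by $(n-1)(n-2)$; an undirected mode exists because network
analysis tools differ in their treatment of direction, but directed is
the default for a directed network.

The score is $\mathrm{Score}_i = w_1 FC_i + w_2 BC_i + w_3 D_i$ with
$w_1 = 0.5$ and $w_2 \in \{0.05, 0.10, \ldots, 0.45\}$,
$w_3 = 0.5 - w_2$: nine weight settings, always summing to one. Two
choices here were genuinely open:

* **Feature normalization.** Raw degrees are integers in the tens,
  betweenness lives in $[0,1]$, fold changes around $\pm 2$; without
  rescaling, the $w_2/w_3$ sweep would be meaningless because degree
  would dominate every grid point. Each feature is therefore min–max
  scaled to $[0,1]$ across motifs before weighting (a constant feature
  maps to zero). Raw mode remains available (`normalize = FALSE`).
* **Combining Pareto optimality with a top-100 cut.** Pareto-optimal
  selection and a fixed-size top-100 cut pull in different directions
  (a frontier has whatever size the data dictate), and there is more than
  one defensible way to compose them. We peel successive Pareto frontiers
  of the 9-dimensional score vectors and rank within each layer by the
  mean score over the grid, stopping once 100 motifs are ranked. Ties are
  broken by the sorted node tuple, so the ranking is fully deterministic;
  no randomness exists anywhere in scoring.

The frontier itself is exact non-dominance under component-wise
maximization (duplicates of a frontier vector are all retained) and is
checked against an $O(n^2)$ dominance oracle.

### Core network and target rules

The core is the union of the top motifs' node sets. Which edges the
core should carry admits two readings, so both are implemented: the
induced subgraph (default) or, via `motif_only` mode, only the edges
realizing the motifs — the latter edge set is provably a subset of the
former. Target filtering is rule-based: significantly upregulated
(log2FC > 0 and Bonferroni-adjusted p < 0.05), not housekeeping, not a
transcription factor, and member of a user-supplied inflammation gene
set. Genes without a differential-expression record are excluded as
unassessable rather than given the benefit of the doubt. A small
inflammation list ships under `inst/extdata/` for tests and examples
only; real analyses must supply their own curated lists.

### Screening post-processing

Pharmacophore FIT scores and docking energies are produced by external
commercial software; this package only consumes their tables. The rules:
FIT at least 0.3 (inclusive), drugs covering at least 10 of the 13
screened targets (distinct targets, duplicates collapsed), then
drug–target pairs ranked by best pose, where best means minimum energy —
docking-style energies are more favorable when more negative, and a flag
flips the convention for score-style inputs. An optional synonym map
merges multiple compound identifiers of one marketed drug before
ranking.

## The synthetic test bed

The generators in `synthetic_spec()` stand in for the study's real inputs
(a curated macrophage network and two public expression datasets, plus
screening software output). Reference conditions, chosen once:

* **Network**: 300 nodes, Erdős–Rényi background with edge probability
  0.015 (mean total degree ≈ 9, comparable to the density of curated
  signaling maps), a 20-node planted core wired into overlapping
  triangles, FFLs, a self-loop, a 2-cycle and a 4-cycle, bridged into the
  background; 30% of background nodes get mean TPM ≤ 10 so pruning has
  work to do, planted nodes get 100–500 TPM.
* **Expression**: two groups of 200 cells, negative-binomial counts with
  per-gene lognormal baseline means around 1 and dispersion 0.5 (variance
  $\mu + 0.5\mu^2$, typical scRNA-seq overdispersion), planted four-fold
  (log2FC = 2) changes on the core genes, CD68/CD163/CD14 elevated in
  the TAM group, 10 mitochondrial genes at a 5% read share, and 2% each
  of planted low-depth and high-mitochondria cells so QC is exercised.
* **Screening**: 40 drugs × 13 targets; one planted drug passes FIT on 12
  targets and holds the global minimum energy; every decoy drug covers at
  most 9 targets after the FIT filter.

These sizes keep the full pipeline run in seconds while leaving every
stage non-trivial; the acceptance checks use five consecutive seeds.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, zero-inflation beyond the negative binomial, scale-free degree
structure (available via config but not the default), realistic gene–gene
correlation, or adversarial screening tables. Passing tests therefore
demonstrate correctness of the algorithms and recoverability of planted
signal under clean conditions — not robustness to the artifacts of real
data, which only a run on real inputs can show.

## Numerical conventions and degenerate inputs

* Threshold semantics are taken literally from their wording: TPM
  strictly above 10; *at least* 120 features; *more than* 25%
  mitochondrial reads removed; marker expression strictly greater than 1;
  FIT *at least* 0.3; *at least* 10 of 13 targets. All are asserted at
  their exact boundaries in the tests.
* Exact Wilcoxon comparisons use a $10^{-9}$ slack when comparing rank
  deviations, and betweenness agreement with the path-enumeration oracle
  is required to $10^{-9}$.
* An all-zero sample in TPM conversion is a hard error by default
  (`zero_sample = "zero"` opts into an all-zero column); an all-tied
  rank-sum input returns p = 1; an empty motif list yields an empty core
  with a warning; requesting more top motifs than exist returns all of
  them with a warning.
* Gene symbols are upper-cased at ingest; inputs must already be human
  symbols (no orthology mapping).

## Known limitations

* The seven motif templates are a default, not a standard; a different
  pattern set (e.g. no self-loops, a different four-node FFL variant)
  yields different counts. The template YAML hook exists precisely for
  this.
* Batch correction is out of scope; the two-group comparison is consumed
  as given, and pre-corrected input can be supplied instead of raw
  counts.
* The inflammation/housekeeping/transcription-factor calls are exactly as
  good as the user-supplied lists; the bundled list is a test fixture,
  not a curation.
* Structure availability screening of targets (whether a protein has a
  dockable structure) is a manual step outside the package.
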