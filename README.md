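# tamnet

Network-motif target prioritization for macrophage drug repurposing.

Tumor-associated macrophages (TAMs) are a largely immunosuppressive cell
population in solid tumors, and reprogramming them — rather than depleting
them — is an attractive therapeutic angle. `tamnet` implements a
computational pipeline that starts from a literature-curated directed
regulatory network of macrophage signaling and ends at a ranked list of
drug–target pairs for repurposing:

1. **Expression pruning.** Bulk RNA-seq counts are converted to TPM
   (`compute_tpm()`, `mean_tpm()`); network nodes are kept only with an
   average TPM strictly above 10 and a non-zero degree, with isolate
   removal iterated to a fixed point (`prune_by_expression()`).
2. **Single-cell differential expression.** Cells need at least 120
   detected features and at most 25% mitochondrial reads
   (`qc_filter_cells()`); TAMs are gated by requiring more than 1
   (normalized) expression in at least two of CD68/CD163/CD14
   (`gate_tams()`). Genes detected in at least 1% of cells in both groups
   are tested with a two-sided Wilcoxon rank-sum test — exact for small
   groups, tie-corrected normal approximation otherwise — and
   Bonferroni-corrected (`differential_expression()`). Macrophage
   polarization can be called from M1/M2 markers
   (`classify_polarization()`).
3. **Motif enumeration.** All instances of four feedback-loop and three
   feed-forward-loop templates on at most 4 nodes are matched in the
   pruned network (`enumerate_motifs()`), each distinct
   (template, node set, edge set) realization exactly once.
4. **Motif scoring.** Each motif *i* is scored as

   `Score_i = w1·FC_i + w2·BC_i + w3·D_i`

   where `FC_i`, `BC_i` and `D_i` are the motif's mean log2 fold change,
   mean betweenness centrality and mean node degree (min–max scaled across
   motifs by default). `w1` is fixed at 0.5 and `w2` sweeps 0.05–0.45 in
   0.05 steps with `w3 = 0.5 − w2`, giving a 9-dimensional score vector
   per motif (`score_motifs()`). The Pareto frontier of these vectors is
   extracted and successive frontiers are peeled, ranking within each
   layer by mean score, until the top 100 motifs are selected
   (`pareto_frontier()`, `rank_top_motifs()`).
5. **Core network and target filter.** The union of the top motifs' nodes
   with their induced edges forms the core network (`extract_core()`).
   Candidate targets must be significantly upregulated in TAMs, be neither
   housekeeping genes nor transcription factors, and belong to a supplied
   inflammation gene set (`filter_targets()`).
6. **Screening post-processing.** Externally produced pharmacophore FIT
   tables are filtered at FIT ≥ 0.3, drugs must cover at least 10 of the
   13 screened targets, and surviving drug–target pairs are ranked by
   best (lowest) docking energy (`filter_fit()`, `drug_coverage()`,
   `rank_pairs()`, or `screen_rank()` for the whole stage).

A seeded synthetic-data module (`synthetic_spec()`, `gen_network()`,
`gen_expression()`, `gen_screening()`) generates networks with a planted
motif cluster, negative-binomial two-group counts with planted fold
changes and marker genes, and screening tables with a planted hit, so the
entire pipeline is testable without any downloads.

## Worked example

Everything below is computed from the synthetic reference conditions at
seed 1 (a 300-node network with a 20-node planted core):

```r
library(tamnet)
library(dplyr)

spec <- synthetic_spec(seed = 1)
nw  <- gen_network(spec)
net <- prune_by_expression(nw$network)
glance(net)
#> # A tibble: 1 × 5
#>   n_nodes n_edges n_components n_annotated  n_de
#>     <int>   <int>        <dbl>       <int> <int>
#> 1     218     798            1         218    20
```

Pruning removed the 82 nodes with average TPM at or below 10 together
with the isolates that removal created. Motif enumeration and scoring:

```r
motifs <- enumerate_motifs(net)
count_by_template(motifs, default_templates())
#> # A tibble: 7 × 2
#>   template_id      n
#>   <chr>        <int>
#> 1 FBL1             1
#> 2 FBL2            11
#> 3 FBL3            24
#> 4 FBL4            66
#> 5 FFL3            54
#> 6 FFL4_chain     228
#> 7 FFL4_diamond    96

topo   <- topology_features(net)
de     <- filter(net$nodes, !is.na(log2fc))   # planted DE annotations
scores <- score_motifs(motif_features(motifs, de, topo))
top    <- rank_top_motifs(scores, k = 100)
core   <- extract_core(net, filter(motifs, motif_id %in% top$motif_id))
core
#> <tam_core> 37 nodes, 93 edges (induced edges), from 100 motifs
```

The 480 motifs collapse to a 37-node core; all 20 planted genes are in
it. The target filter then removes the planted transcription factors and
housekeeping genes and keeps the 16 upregulated inflammation genes:

```r
targets <- filter_targets(core, de, housekeeping = nw$housekeeping,
                          tfs = nw$tfs, inflammation = nw$inflammation)
head(targets, 4)
#> # A tibble: 4 × 5
#>   gene  log2fc    p_adj flags retained
#>   <chr>  <dbl>    <dbl> <chr> <lgl>
#> 1 G0129   2.12 0.000001 ""    TRUE
#> 2 G0165   2.10 0.000001 ""    TRUE
#> 3 G0167   2.07 0.000001 ""    TRUE
#> 4 G0079   2.02 0.000001 ""    TRUE
sum(targets$retained)
#> [1] 16
```

Screening-table post-processing recovers the planted drug at rank 1:

```r
scr <- gen_screening(spec)
res <- screen_rank(scr$fit, scr$dock)
head(res$ranking, 3)
#> # A tibble: 3 × 4
#>   drug_id    target_id best_energy  rank
#>   <chr>      <chr>           <dbl> <int>
#> 1 ZINC415065 T01             -55.0     1
#> 2 ZINC415065 T13             -44.5     2
#> 3 ZINC415065 T08             -44.2     3
```

`run_pipeline()` chains all stages, writes every table as TSV plus a
`manifest.json` of resolved parameters and per-stage counts, and is also
exposed as a command-line tool (`inst/scripts/tamnet-cli.R`) with
`simulate`, `prune`, `de`, `motifs`, `topology`, `screen-rank` and
`run-all` subcommands.

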