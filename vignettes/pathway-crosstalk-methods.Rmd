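---
title: "Weighted pathway crosstalk: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted pathway crosstalk: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crosspath)
```

## The model

`crosspath` asks a directional question: given a *source* gene set that is
known to be perturbed — the motivating case is a recurrent microdeletion
whose genes are constitutively down-regulated in carriers — which other
pathways does the perturbation propagate into through physical
interactions?

The answer is computed on a two-layer directed graph. Pathway nodes link to
their member genes; gene nodes link to each other wherever a
protein–protein interaction (PPI) of high confidence (combined score ≥ 900
on the 0–1000 scale used by STRING-style edge lists) exists. Every relation
contributes two directed edges. An edge costs the weight of the node it
points *at*:

$$ w(T) \;=\; 1 - \frac{1}{1 + e^{-2(|T|-3)}} $$

where $T$ is the gene's differential-expression t-statistic, and an edge
into a pathway node costs 0. The transform maps the whole real line into
$(0,1)$, crosses $0.5$ at $|T| = 3$, and decays quickly: a gene at
$|T| = 6$ costs about $0.0025$. Walking through strongly regulated genes is
therefore cheap, and a cheap path from the source into another pathway is
evidence that the two processes respond together.

A *significant path* is a directed path from the source pathway node to a
candidate pathway node with **at least three edges** — so that it contains
at least one PPI edge rather than hopping pathway→gene→pathway through a
shared member — and edge-weight sum $l$ strictly below a threshold
$l_{max}$. Paths are enumerated greedily per candidate:

1. find the minimum-weight directed path from source to candidate;
2. stop if none exists or $l \ge l_{max}$;
3. a two-edge path is discarded and its last edge deleted from the working
   copy (exposing longer alternatives);
4. a path with ≥ 3 edges is stored and all its edges except the first and
   last are deleted; repeat.

Each iteration deletes at least one edge, so the loop terminates; stored
paths are interior-edge-disjoint. The candidate's interaction score is
$\mathrm{Score} = \sum_i 1/l_i$ over its stored paths, so many short,
low-weight connections give a large score.

Because pathway size alone inflates raw scores, significance is assessed by
a **stratified permutation test**: the candidate's membership is replaced
by randomly chosen network genes, preserving the number of members with
weight at or below 0.8 (the stratum from which cheap paths can come) and
the number above. The empirical p-value is the fraction of permuted
networks whose score is greater than or equal to the observed score;
candidates with $p < 0.05$ are selected. After selection, paths are
re-collected at a relaxed threshold and filtered with a two-tier rule —
three-edge paths must have $l < 0.9$, longer paths $l < 1.4$ — which admits
paths through moderately regulated genes whose partners are strongly
regulated, while removing short paths of large weight. The union of
interior genes of the kept paths is the contributing-gene set of the final
network.

Two companion analyses close the loop: a standardized hypergeometric
overrepresentation analysis (ORA) that ranks pathways by
$z = (r - nR/N)\,/\,\sqrt{n \tfrac{R}{N}(1-\tfrac{R}{N})(1-\tfrac{n-1}{N-1})}$
with unadjusted upper-tail p-values, and a disease-annotation step that
intersects the detected genes with curated disease–gene associations and,
for a two-arm design sharing one control group, extracts the disease genes
exclusive to one arm together with their induced PPI subnetwork.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `string_min_score` | 900 | inclusive minimum PPI combined score (0–1000) |
| `screen_l_max` | 0.9 | strict path-weight bound during screening |
| `collect_l_max` | 1.4 | relaxed bound for the final path collection |
| `tier_three` / `tier_longer` | 0.9 / 1.4 | final filter for 3-edge / longer paths |
| `n_samples` | 1000 | permutations per candidate pathway |
| `weight_split` | 0.8 | stratum boundary for membership replacement (inclusive; `strict_below` flips it) |
| `alpha` | 0.05 | strict cutoff on the empirical p |
| `p_max`, `lfc_min` | 0.05, 0.15 | ORA gene criteria: strict on p, inclusive on \|log2FC\| (0.15 ≈ 10% regulation) |
| `min_sig_genes` | 3 | minimum significant members for an ORA rank |

All thresholds follow the printed comparisons of the method they implement:
`< 0.9` to continue the path loop (at-or-above stops), `>= 900` to keep a
PPI edge, `< 0.05` to select, `>= 0.15` to flag a gene.

## Design decisions

Several points were genuinely open and were settled as follows.

* **Probe collapse.** "The probe with the median log2FC" is ambiguous for
  even probe counts; the *lower* median probe is taken, so a real observed
  probe, never an average of rows, represents the gene. Remaining ties
  break on lexicographic probe id.
* **Moderated vs Welch statistics.** The built-in differential-expression
  stage is a vectorised Welch t-test; a precomputed `(gene, t, p, log2fc)`
  table can be injected instead, so moderated statistics from a dedicated
  DE package drop in without code changes.
* **Orphan PPI genes.** Genes present only in the PPI file belong to no
  pathway and are excluded from the network by default (the gene universe
  is built *from the pathways* and merely extended by interactions);
  `include_orphan_ppi_genes = TRUE` admits them.
* **Interior pathway nodes** are structurally excluded from paths: the
  working graph contains membership edges of the two endpoint pathways
  only. A path hopping through a third pathway node would contain no PPI
  edge and would exploit the zero cost of pathway-headed edges.
* **Per-candidate loop.** The enumeration repeats for the *same* candidate
  until the stop condition, since the score sums over $n$ paths per
  candidate; only then does the next candidate start.
* **Empirical p source.** P-values are computed from the `l_max = 0.9`
  screen scores; the relaxed collection only determines the final gene and
  path network of the already-selected pathways.
* **Literal p.** `p = count/n` as printed, which can return 0;
  `pseudo_count = TRUE` reports `(count+1)/(n+1)` for users who need
  strictly positive p-values.
* **Replacement universe.** Membership permutations draw from the gene
  nodes of the network, not the whole measured genome: genes outside the
  network can never form paths, so admitting them would only deflate null
  scores.
* **Determinism.** Ties between equal-weight shortest paths break on
  lexicographic node-sequence order; each pathway's permutation stream is
  derived from the master seed by a stable hash of the pathway id, so
  adding or removing a candidate never changes another candidate's
  p-value.

## Numerical choices

The shortest-path search runs in compiled code (reverse Dijkstra from the
candidate plus a forward walk that, among edges achieving the optimum,
always steps to the lexicographically smallest neighbour). All edge weights
are non-negative, so the search is exact. The logistic weight is evaluated
as $e^{-a}/(1+e^{-a})$ with $a = 2(|T|-3)$ — algebraically identical to the
displayed formula but free of the cancellation that would round weights of
extreme statistics ($|T| \gtrsim 21$) to exactly 0 and break the
open-interval contract. Degenerate inputs fail loudly: non-finite
t-statistics, weights outside $(0,1)$, identifier collisions between gene
and pathway namespaces, and permutation strata smaller than the required
replacement count are all errors, not silent drops. Pathways that lose all
weighted members, unmapped probes, and sub-threshold PPI rows are dropped
with a warning or message that carries the count.

## What the synthetic generator emulates

`generate_scenario()` reproduces the statistical structure of the kind of
cohort this method targets: one healthy control arm (66 samples by
default) shared by two case arms (19 and 27), a source gene set whose
members are strongly down-regulated in both arms (deletion mimic, $T=-8$),
planted PPI chains of connector genes leading from the source into
designated target pathways in one contrast (connectors at $|T| = 6$, so a
two-connector chain yields a three-edge path with
$l = 2\,w(6) \approx 0.0049$), a large block of moderately differentially
expressed genes ($|T| \sim U(2.5, 4)$, shared by both arms) organised into
a few large co-regulated "module" gene sets — the analogue of the broad
immune signature of whole blood, and the population that fills the
permutation test's low-weight stratum — and null genes whose target
statistics have SD 0.4, chosen so that together with the sampling noise of
the t-statistic the realised null dispersion stays near 1.

Three generator behaviours are worth knowing:

* **Calibrated plants.** Deleted source members and planted connectors are
  shifted by a constant in the case arm so their *realised* Welch T equals
  the configured level exactly; this is what makes the planted truth labels
  sharp. All other genes are stochastic around their targets.
* **Edge rejection.** Background PPI edges are sampled after the
  expression, and any pair that would complete a three-edge
  source-to-pathway path with realised weight sum below 0.9 (including
  source–source pairs) is rejected. Planted chains are therefore the only
  sub-threshold three-edge routes; longer accidental paths are allowed and
  left to the permutation test.
* **A null configuration.** With `de_placement = "background"` the
  candidate gene sets partition a single pool that includes the
  deleted-region genes, so membership carries no expression information at
  all and observed memberships are exchangeable with the stratified
  replacements. This is the configuration used to check the calibration of
  the empirical p-values; with the default `"modules"` placement the
  candidate sets are deliberately *not* exchangeable (they are null-pool
  only), which makes their p-values conservative.

What the generator does **not** emulate: probe-level array noise and
normalisation artifacts (one probe per gene, unit within-group SD),
correlated expression beyond the shared DE block, realistic PPI topology
(background edges are uniform rather than scale-free), or the sheer scale
of a genome-wide study. Passing tests therefore demonstrate that the
implementation realises the method's contracts and recovers planted
structure under a faithful miniature of the study design — not that the
method's biological conclusions transfer to any particular real dataset.

## Validation problem sizes

The test suite validates the path enumeration against an exhaustive
brute-force replay on over one hundred random graphs of at most ten gene
nodes with dyadic-rational weights (exact in binary, so tie detection is
unambiguous); ORA scores against direct enumeration of the hypergeometric
mass for all universes up to $N = 12$ and sampled universes up to
$N = 50$; permutation calibration on 200 replicates of the exchangeable
null configuration (100 genes, 8 candidate sets, 99 permutations); and
end-to-end recovery on ten seeds of the default scenario (1740 genes, 50
candidate pathways, 5 planted targets, 199 permutations), requiring all
five targets at $p < 0.05$ with at most one non-planted selection in at
least nine of the ten seeds.

## Known limitations

* The greedy remove-and-repeat enumeration yields interior-disjoint paths
  in discovery order; it is a heuristic decomposition, not an exhaustive
  census of admissible paths, and a different deletion rule would yield a
  different (also defensible) path set.
* Empirical p-values are reported unadjusted, matching the method's own
  practice; with hundreds of candidates a multiplicity correction may be
  warranted downstream.
* P-values for candidates whose membership is informative about expression
  (as curated pathways usually are) are conservative by construction; the
  test is calibrated only under membership-random nulls.
* Identifier matching is verbatim after whitespace trimming and case
  folding; no identifier mapping service is consulted, so mixed-namespace
  inputs need a user-supplied mapping table.
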