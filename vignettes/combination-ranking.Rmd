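---
title: "Knockout stability and entropy-weighted ranking of compound combinations"
author: "netcontrib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout stability and entropy-weighted ranking of compound combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-herb formulas act through dozens to hundreds of ingredient compounds
hitting overlapping protein targets. When a formula shows activity against a
disease — here the motivating application is liver fibrosis treated with an
eight-herb decoction — the practical question is which *small* subset of
compounds carries that activity, so that a defined, reproducible combination
can replace the crude extract. netcontrib implements a network-based answer:
build the formula–syndrome–disease target network, measure how much each
compound (and each compound combination) stabilizes that network, and rank
all combinations by an entropy-weighted contribution score.

## The pipeline

1. **Compound screen.** Candidate compounds are filtered on oral
   bioavailability (OB ≥ 30%) and drug-likeness (DL ≥ 0.18), both inclusive
   as is conventional for these pharmacokinetic screens.
2. **Syndrome arm.** A two-group expression matrix (e.g. patient blood
   transcriptomes, 16 vs 16) is quantile-normalized and filtered to
   differentially expressed genes (DEGs) at fold change > 1.5 and p < 0.05
   (both strict). Fold change is the ratio of group geometric means; the p
   value comes from Welch's two-sample test on log2 intensities.
3. **Formula arm.** Targets of the screened compounds are expanded one
   neighbourhood round through a scored protein–protein interactome, using
   edges with confidence strictly above 0.850.
4. **Venn intersection.** The formula targets, the syndrome DEGs and a
   disease target list are intersected; the common targets define the
   network's target layer.
5. **Network and core.** A typed herb–compound–target network is assembled
   (simple graph; duplicate edges and self-loops dropped). A core network is
   extracted by topological gating: by default a node is retained when its
   degree, betweenness and closeness all strictly exceed the network
   medians; clustering and topological coefficients are reported but do not
   gate. All five parameters and the comparison mode are configurable.
6. **Knockouts.** Each compound set is knocked out by deleting the compound
   node(s) and *all* adjacent targets (shared targets included; an
   exclusive-targets mode exists behind `shared_targets = FALSE`). The
   surviving graph is summarised by four stability indicators.
7. **Scoring and ranking.** The n × 4 indicator matrix is min–max
   normalized, entropy-weighted, and collapsed to a contribution score per
   entity; all combinations of the retained core compounds are enumerated
   and ranked.

## The stability indicators

For a (surviving) graph with $n$ nodes, $m$ edges and degrees $d_i$:

- **NC** (network centralization): $\frac{n}{n-2}\left(\frac{d_{max}}{n-1} -
  \frac{2m}{n(n-1)}\right)$ — 1 for a star, 0 for any regular graph.
- **CPL** (characteristic path length): the mean shortest-path length over
  connected unordered pairs. Disconnected pairs are excluded rather than
  imputed with a penalty distance; this keeps CPL finite on fragmented
  survivors at the cost of occasionally *shortening* the average when long
  paths are destroyed (see the discussion of retention modes below).
- **NH** (network heterogeneity): the coefficient of variation of the degree
  sequence (population variance), 0 iff the graph is regular.
- **R** (robustness): $C/(N - N_r)$, where $C$ is the largest-component size
  of the survivor, $N$ the original node count and $N_r$ the number of
  removed nodes; $R = 1$ iff the survivor is connected. The defining text of
  this measure is typeset ambiguously in the source literature
  ("R=C(N − Nr)"); a product of a component size and a node count is
  unbounded and cannot be a stability fraction, so netcontrib implements the
  quotient, and `robustness()` exposes the raw $C$, $N$, $N_r$ so either
  convention can be recomputed.

Closeness is computed within connected components; betweenness is normalized
by $(n-1)(n-2)/2$; the topological coefficient of a node $v$ with $k_v \ge 2$
neighbours is the mean of $(\mathrm{shared}(v,m) + [m \sim v])/k_v$ over all
nodes $m$ sharing at least one neighbour with $v$. Isolated and
degree-deficient nodes score 0 by convention.

## Entropy weighting and the contribution score

Each indicator column carries an **orientation**. The default — CPL and NH
"positive", NC and R "inverse" — encodes the view that an important
compound's knockout leaves a more fragmented survivor: longer surviving
paths, more heterogeneous degrees, lower centralization, smaller largest
component. Normalization maps every column to $[0,1]$ with 1 = most
destabilizing:

$$z_{ij} = \frac{x_{ij} - \min_i x_{ij}}{\max_i x_{ij} - \min_i x_{ij}}
\quad\text{(positive)},\qquad
z_{ij} = \frac{\max_i x_{ij} - x_{ij}}{\max_i x_{ij} - \min_i x_{ij}}
\quad\text{(inverse)}.$$

Entropy weights follow the standard multi-criteria scheme: proportions
$b_{ij} = z_{ij}/\sum_i z_{ij}$, entropies $e_j = -\frac{1}{\ln n}\sum_i
b_{ij}\ln b_{ij}$ (with $0\ln 0 := 0$), difference coefficients
$d_j = 1 - e_j$, weights $w_j = d_j/\sum_j d_j$. An indicator that varies
little across knockouts has entropy near 1 and weight near 0. A constant
column is flagged during normalization and assigned $e_j = 1$, $w_j = 0$
exactly; if *every* column is constant the weighting is refused as
uninformative.

The contribution score doubles the robustness weight:

$$\mathrm{score}_i = z_{i,\mathrm{nc}} w_{\mathrm{nc}} +
z_{i,\mathrm{cpl}} w_{\mathrm{cpl}} + z_{i,\mathrm{nh}} w_{\mathrm{nh}} +
z_{i,\mathrm{r}} \,(2 w_{\mathrm{r}}).$$

The doubling is applied exactly as the method prescribes, with no
renormalization; the plain weighted sum is reported alongside
(`score_undoubled`). Scores consume the normalized $z$ values by default:
the raw indicators live on incommensurate scales (CPL in edges, NC in
$[0,1]$), and the normalization step exists precisely to make them
comparable. A raw-value mode is available (`raw_values = TRUE`) for
sensitivity analysis.

Combination-level weights are recomputed over the $2^p - 1$ combination rows
rather than reused from the single-compound analysis, so combinations are
scored on their own scale. Ties in the ranking are broken by the
lexicographic combination id, making the full report deterministic.

```{r example}
library(netcontrib)

nw <- synth_pharm_network(synth_config(n_herbs = 3, n_compounds = 17,
                                       n_targets = 120, seed = 7))
nodes <- network_nodes(nw$network)
compounds <- sort(nodes$id[nodes$kind == "compound"])

singles <- build_indicator_matrix(nw$network, as.list(compounds))
core <- select_core_compounds(singles, fraction = 0.5, method = "score")
ranking <- rank_combinations(nw$network, core, top_k = 10)
tidy(ranking)
autoplot(ranking)
```

## Core-compound retention: two readings of "top 50%"

After single-compound knockouts, the top half of the compounds is retained
before combinations are enumerated. Two modes are provided because the
retention rule admits two natural readings:

- `method = "per_indicator"` (default): per indicator, keep the entities in
  the top 50% of that column's evaluation values (ties at the cutoff all
  retained), then intersect the four sets — a Venn-style demand that a core
  compound score consistently well on *every* indicator.
- `method = "score"`: keep the top 50% by the combined contribution score.

The per-indicator reading is strict in a way that interacts with the
geometry of hub knockouts: removing a hub compound's targets tends to
*lower* the survivor's degree heterogeneity (the hubs are gone) and can
lower CPL (long paths are destroyed, and disconnected pairs leave the
average), so a genuinely high-impact compound may fall outside the NH or CPL
top half while dominating NC and R. In the package's planted-hub recovery
analysis (see the test suite), the score-based retention passes the planted
compound through in every seeded replicate, while the per-indicator
intersection loses it in roughly a fifth of replicates. Analyses that aim at
recovering high-impact compounds should therefore prefer
`method = "score"` (exposed in the pipeline configuration as
`selection_method`); the per-indicator mode remains the default because it
is the conventional Venn reading of the retention step. If the intersection
comes out empty, the function falls back to score-based retention with a
warning.

## The synthetic-data generator

Every stage has a generator with planted ground truth, so the pipeline can
be validated end to end without any external data:

- `synth_pharm_network()` builds a tripartite herb–compound–target network.
  The target layer is scale-free (preferential attachment, 2 edges per
  node), matching the heavy-tailed degree distributions of real
  interactomes; a `uniform` model is available. Unplanted compounds attach
  to ~5 random targets (Poisson); planted compounds attach to the
  *highest-degree* targets with a boosted target count (default boost 5), so
  their knockout removes hubs. Defaults emulate an eight-herb formula at
  catalog scale (8 herbs, 170 compounds, 800 targets).
- `synth_gene_lists()` realizes an exactly specified seven-region Venn
  design over disease/syndrome/formula gene sets; the default design
  produces a 181-gene triple intersection at list sizes in the low
  thousands, the magnitudes typical of disease-target and DEG lists.
- `synth_expression()` draws log-normal intensities (baseline log2 means
  $\mathcal{N}(8, 1.5^2)$, sample noise $\mathcal{N}(0, \sigma^2)$ on the
  log2 scale) for 16 + 16 samples, with `n_deg` planted genes shifted by
  ±log2fc in group 1 (alternating up/down). Defaults: 1000 genes, 100
  planted DEGs, $|\log_2 FC| = 1.5$, $\sigma = 0.5$.

Every generator is a pure function of its configuration: the seed fixes all
stochastic choices and the caller's RNG state is restored.

What the generators deliberately do **not** emulate: correlated gene-gene
expression, probe-level artefacts or batch effects, biased annotation of
hub proteins, compound-target edge noise, or realistic chemistry. Passing
tests on these generators therefore demonstrate that the *algorithms* are
implemented correctly and that the planted signal class is recoverable —
not that the protocol is robust to the full failure modes of mined TCM
databases and microarray data.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to exercise every code path while
staying desk-scale: topology metrics are compared with brute-force oracles
on every connected labeled graph with up to 5 nodes and on seeded random
graphs up to 30 nodes; entropy weighting is checked against direct
summation on 1000 random 17 × 4 matrices (17 is the canonical core-network
compound count) at 1e-12; planted-hub recovery uses 100 seeded networks of
17 compounds and 120 targets — core-network scale, where knockout analysis
actually operates — and the DEG operating point uses 20 seeded 1000 × 32
matrices. End-to-end runs use a 20-compound, 150-target bundle.

Other numerical conventions: symbols are matched case-insensitively after
trimming whitespace, with no alias resolution; min–max normalization of a
constant column yields zeros plus a flag rather than 0/0; Welch p values on
zero-variance rows are 1 (equal means) or 0 (unequal); zero intensities are
offset by a configurable pseudo-value (default 1) before logging, and the
offset is recorded on the result. Knockouts that leave a survivor too
degenerate to summarise (fewer than 3 nodes, no edges, or empty) are
excluded from the indicator matrix with a logged reason rather than
imputed.

## Known limitations

- The printed contribution scores of the motivating study are not
  reproducible here: the mined compound–target network behind them was
  never published. The package reproduces the *method* — enumeration
  counts, formula identities, invariants — not those specific numbers.
- PPI expansion is exactly one neighbourhood round. The expansion depth is
  genuinely underdetermined in the protocol; one round matches the printed
  growth of the target sets, while a transitive closure over a
  high-confidence interactome would absorb most of the proteome.
- Combination ranking is exhaustive ($2^p - 1$ knockouts); it is meant for
  the post-selection core (p ≤ ~12), not for whole catalogs.
- The DEG stage is a plain two-group filter; it does not model paired
  designs, covariates, or moderated variance estimators.
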