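---
title: "Network-pharmacology screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-pharmacology screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The screening problem

A multi-component agent — here the motivating case is an essential oil
profiled by GC-MS — acts through many chemicals hitting many proteins at
once. Network-pharmacology screening turns that into a sequence of set and
graph operations:

1. **Compound screen.** Chromatographic peaks are kept when their relative
   area exceeds a reporting threshold (default 0.12%, strict `>`), and
   compounds are then filtered on predicted pharmacokinetics: GI
   absorption, blood–brain-barrier permeation, P-glycoprotein substrate
   status and rule-based drug-likeness (ADMET flags of the kind SwissADME
   reports).
2. **Target sets.** Predicted targets of the surviving compounds (one
   gene-symbol set per compound, optionally score-filtered at 0.8) are
   intersected with the union of per-database disease gene lists. The
   intersection is the *drug–disease common target* set, and the
   compound–target restriction to it is a bipartite network.
3. **PPI core.** The common targets' protein–protein interaction edges are
   thresholded at confidence ≥ 0.9, and the induced graph is reduced to a
   core subnetwork by iterative above-median filtering on four
   centralities: degree (DC), betweenness (BC), closeness (CC) and
   eigenvector (EC).
4. **Enrichment.** The common (or core) set is tested for
   over-representation against GO-style and pathway-style collections with
   the hypergeometric upper tail, Benjamini–Hochberg adjusted within each
   category, reporting the top 10 GO terms per branch and top 30 pathways
   at p ≤ 0.05.
5. **Bioassay arithmetic.** Viability is normalized as
   $(OD_{treated}-OD_{blank})/(OD_{control}-OD_{blank})\times 100$,
   dose–response curves are fitted with a four-parameter logistic to
   estimate the IC50, and annexin/PI quadrant counts are summarized as
   apoptosis rates.

The package performs no database or web access: all inputs are plain-text
files, and a seeded generator suite can synthesize every one of them with
planted ground truth.

## Centralities: definitions and numerics

All four centralities are computed on the unweighted simple graph obtained
after score thresholding (edge weights play no role in shortest paths,
matching the defaults of the usual Cytoscape tooling).

* **Degree** is the neighbor count.
* **Betweenness** is unnormalized shortest-path betweenness
  $bc(v)=\sum_{s<t,\,s\neq v\neq t}\sigma_{st}(v)/\sigma_{st}$, computed by
  Brandes' accumulation with each unordered pair counted once and
  endpoints excluded. Unnormalized values are used because published hub
  tables report magnitudes far above 1.
* **Closeness** is computed per connected component as
  $cc(v)=(|C|-1)/\sum_{u\in C}d(v,u)$, which keeps values in $[0,1]$ and
  gives isolated nodes 0. Component-wise handling is our choice; the
  screening literature is generally silent on disconnected graphs.
* **Eigenvector** centrality is the principal eigenvector of the adjacency
  matrix of the largest connected component (ties broken towards the
  component containing the lexicographically smallest gene), max-normalized
  to 1, with nodes outside that component at 0. It is found by power
  iteration from a uniform start with tolerance `1e-10` and at most 10,000
  iterations; non-convergence is an error, never a silent result. The
  iteration actually runs on $A+I$: on bipartite components the plain
  iteration oscillates between two accumulation points (the spectrum is
  symmetric, $\pm\lambda_1$), while the unit shift leaves eigenvectors
  unchanged and makes the dominant eigenvalue strictly dominant on every
  connected graph.

Correctness is established against independent oracles rather than spot
values: distances and shortest-path counts from adjacency-matrix powers
(a length-$d(s,t)$ walk is necessarily a shortest path, so
$\sigma_{st}=(A^{d})_{st}$), and a dense symmetric eigensolver for EC. The
test suite compares all four centralities on **every** labeled connected
graph with up to 6 nodes (27,475 graphs) plus 200 random graphs with up to
8 nodes, at `1e-9` (`1e-6` for EC).

## Core extraction

One filter round computes the selected centralities, takes each metric's
median over the current nodes, and keeps nodes **strictly greater** than
the median on **every** selected metric, then induces the subgraph. "Larger
than the median" is read as strict `>`; the conjunction over metrics
mirrors the common CytoNCA double-screening practice. Both choices are
configurable (`mode = "any"` gives the disjunctive variant). Two rounds is
the default, matching the two-stage reductions reported in screening
studies; a round that would empty the graph stops extraction early with an
`exhausted` flag and keeps the previous subgraph, so degenerate inputs
(e.g. vertex-transitive graphs, where every node ties on every metric)
fail loudly rather than silently. Final core genes are ranked by degree
within the core, ties broken alphabetically, making extraction fully
deterministic.

## Hypergeometric enrichment

For a query of size $n$ drawn from a universe of size $N$ with $K$ genes
annotated to a term, the enrichment p-value is the upper tail
$P(X\ge k)$ of the hypergeometric distribution, evaluated through R's
log-space-stable distribution function. Design choices:

* Terms are intersected with the universe before testing; query genes
  outside the universe are dropped with a message.
* Terms with zero overlap are omitted rather than reported at p = 1,
  matching common ORA tools.
* BH adjustment is applied within each category (BP/CC/MF/pathway); the
  default report filter uses the raw p ≤ 0.05 — mirroring the prevailing
  reporting convention in this literature — with `filter_on = "p_adjusted"`
  available for the more rigorous variant.
* When no universe is supplied it defaults to the union of all collection
  members. This is logged prominently because the background choice
  materially changes p-values.

The exactness of the tail is verified against exhaustive enumeration of
all $n$-subsets for every valid $(k, K, n, N)$ with $N \le 12$, and the BH
step against a hand-written step-up implementation.

## Dose–response model

The 4PL curve is parameterized on log-dose,
$v(d) = L + (U-L)\,/\,(1+e^{h(\log d - \log IC_{50})})$, fitted by
Levenberg–Marquardt least squares with data-driven starting values
(asymptotes from the data range, inflection from the dose nearest
mid-viability, initial Hill slope 1). Replicate wells are averaged before
fitting; at least four distinct dose levels are required. The reported
IC50 is the inflection dose (*relative* IC50) because the estimator is
rarely stated explicitly in assay reports; the *absolute* 50%-crossing
variant is available by flag and coincides with the relative one when the
asymptotes are 0 and 100. Fits with non-positive Hill slope, swapped
asymptotes, or an IC50 outside $[\min(d)/10,\ 10\max(d)]$ are flagged
`out_of_range` with a warning — the signature of non-decreasing viability.
Viability values are deliberately not clamped to $[0, 100]$.

## What the synthetic generators emulate

Each generator is a pure function of a single config (one master seed
drives a named substream per generator, so adding one generator never
perturbs another; identical configs give byte-identical files):

* `gen_compounds` — a GC-MS-style compound table with valid elemental
  formulas and ADMET flags arranged so that exactly
  `round(n × admet_pass_fraction)` rows pass the default screen.
* `gen_target_universe` — per-database disease lists with a designated
  shared core present in every source, plus exact union/intersection
  counts in the manifest.
* `gen_ppi` — an Erdős–Rényi periphery (density 0.03) with a planted
  near-clique core (10 of 100 nodes at density 0.9). Core–periphery pairs
  are wired at the geometric mean of the two densities
  ($\approx 0.16$): a planted core must be *high-centrality* to be
  recoverable, and a pure clique is not — its members are mutually
  adjacent, so almost no shortest paths pass through them and their
  betweenness is low. Hub-like cross wiring reproduces how real
  interactome cores acquire betweenness (rich-club structure). With it,
  two-round median filtering recovers the planted core essentially
  perfectly; without it, betweenness vetoes part of the core under the
  conjunctive filter.
* `gen_gene_sets` — random gene sets plus one planted term sharing a fixed
  number of genes (default 15 of a 20-gene query) with the emitted query.
* `gen_plate` — OD plates at the seven conventional assay doses
  (50–1000 µg/mL) from a 4PL with true IC50 524 µg/mL and Hill slope 2,
  with Gaussian OD noise at 3% of the blank–control dynamic range.

What the generators do **not** emulate: realistic interactome topology
beyond planted-core ER graphs, GO DAG structure, gene-identifier aliasing,
correlated ADMET properties, or plate-position effects. Passing the
recovery suites therefore demonstrates that the algorithms recover known
structure under clean assumptions — not that any particular biological
claim holds on real data.

## Scale and determinism

Default problem sizes are desk-size on purpose: a 100-node interactome,
five disease sources totalling a few hundred genes, 200 gene sets over an
800-gene pool, 20-seed/50-seed/100-seed simulation batches. These sizes
give stable medians and rates while keeping the whole verification suite
fast. Real studies pull tens of thousands of disease genes from live
databases; those counts depend on unversioned database snapshots and are
treated as context, not as reproducible targets — the pipeline instead
checks its stage counts against the generator manifests, where the truth
is known exactly.

Every stochastic step flows through an explicit integer seed. The pipeline
itself is deterministic: rerunning on identical inputs produces a
byte-identical `report.json` (timings go to stderr, never into the
report).

## Known limitations

* Gene identifiers are uppercased symbols with no alias resolution;
  lists from sources using different symbol conventions will
  under-intersect.
* The ADMET screen trusts the flags in the input table; no chemistry is
  computed from SMILES (they are carried as opaque text; molecular weight
  comes from the formula column).
* The compound screen's published rule set ("BBB yes") conflicts with
  published compound tables that retain BBB-negative rows; the default
  rules therefore leave BBB unconstrained and tolerate one drug-likeness
  violation, with the stricter rule set available as the
  `"strict_swissadme"` preset.
* The reduction from a core subnetwork to a shortlist of "therapeutic
  targets" has no published criterion; the package stops at the ranked
  core list rather than inventing one.
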