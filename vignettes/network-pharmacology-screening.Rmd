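---
title: "Methods: a local, testable network-pharmacology screening chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a local, testable network-pharmacology screening chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Network pharmacology treats a multi-compound herbal medicine as a
perturbation of a disease network rather than a single ligand hitting a
single target. The standard screening chain runs: assemble a compound
library for the herb; keep compounds with drug-like, orally absorbable
profiles; predict their protein targets; assemble a disease target set from
several curated databases; intersect the two clusters; find hub genes in
the protein–protein interaction (PPI) network of the intersection; rank the
pathways those hubs annotate to; and assemble a compound–target–pathway
network whose node degrees nominate the most promising compounds and
targets. Downstream, candidate targets are checked in vitro by qRT-PCR with
2^−ΔΔCt relative quantification.

In practice each link of that chain is a different web tool (compound
databases, an ADME predictor, a target predictor, disease databases, a PPI
database, an annotation server). That makes published analyses hard to
reproduce: the inputs are live snapshots, and the decision rules are
distributed across tools. `netpharm` re-implements the chain as local,
deterministic functions over plain files, and pairs it with seeded
synthetic generators that produce inputs with known planted structure, so
every stage can be tested against ground truth.

## Compound ingestion and deduplication

Compound tables (CSV/TSV; configurable column dialect) are validated on
ingestion: rows without a positive-integer PubChem CID or without a SMILES
string are rejected with a reason and counted, never silently dropped.
Deduplication is keyed on the CID — identifiers, not structures, are what
the upstream databases deduplicate on — keeping the first-seen record's
name and SMILES and merging source labels. SMILES canonicalization is
deliberately not used for deduplication; name-level duplicates with
distinct CIDs are treated as distinct compounds, since there is no
principled local way to merge them. The operation is idempotent and
order-stable.

Molecular descriptors sit behind a backend contract. The `openbabel`
backend computes the full 14-descriptor vector (MW, TPSA, Wildman–Crippen
logP, H-bond donors/acceptors, rotatable bonds, molar refractivity, atom
and ring counts) from SMILES with the Open Babel CLI. Open Babel provides a
single Wildman–Crippen logP estimate, which fills the `wlogp` slot and also
stands in for the `mlogp`/`xlogp` slots; when method-specific lipophilicity
estimates matter (the Lipinski variant used here thresholds MLOGP, Muegge
thresholds XLOGP3), descriptors should be supplied through the `table`
backend from a precomputed CSV, which is also the pipeline default. This
split exists because descriptor engines disagree; the screening logic is
defined over the descriptor vector, not over any one engine.

## The superior-property screen

Three conditions must all hold for a compound to be retained:

1. **High gastrointestinal absorption.** A binary classifier: the point
   (TPSA, WLOGP) must fall inside or on a calibrated ellipse (center near
   (71.1 Å², 2.29), semi-axes ≈ 71.0 Å² and 4.37, rotation ≈ −1.03°). The
   closed-region convention (boundary counts as inside) keeps the
   classifier deterministic. The parameters live in configuration, not
   code.
2. **4 or 5 YES drug-likeness rules.** The five filters with their
   published thresholds: Lipinski (MW ≤ 500, MLOGP ≤ 4.15, HBD ≤ 5,
   HBA ≤ 10; YES allowed with ≤ 1 violation), Ghose (160 ≤ MW ≤ 480,
   −0.4 ≤ WLOGP ≤ 5.6, 40 ≤ MR ≤ 130, 20 ≤ atoms ≤ 70), Veber
   (rotatable bonds ≤ 10, TPSA ≤ 140), Egan (WLOGP ≤ 5.88, TPSA ≤ 131.6)
   and Muegge (200 ≤ MW ≤ 600, −2 ≤ XLOGP ≤ 5, TPSA ≤ 150, rings ≤ 7,
   carbons > 4, heteroatoms > 1, rotatable bonds ≤ 15, HBA ≤ 10, HBD ≤ 5).
   Each rule reports a violation count alongside its YES/NO.
3. **No violations within the YES rules.** Read literally: the violation
   counts of the rules that answered YES must sum to zero. Only Lipinski
   can answer YES while violated, so this condition bites exactly when
   Lipinski's one-violation allowance was used. The alternative reading
   ("no rule reports any violation") is available as
   `violation_scope = "all_rules"`.

## Target set algebra

Compound-target predictions keep rows with probability strictly greater
than zero, collapsing duplicate (compound, target) pairs at the maximum
probability. Disease targets are assembled per source: sources with
ranking scores (inference score, relevance score) are cut to their top
1000 symbols, the others pass through unranked; the clusters are then
unioned. Ties at the rank-N boundary are broken by lexicographic symbol
order — the sources themselves do not define a tie order, and this makes
the cut invariant to input row order. All symbols are uppercased and
trimmed before any set operation. Venn partitions over up to five labeled
sets report all 2^k − 1 disjoint region counts; the regions always sum to
the union.

## PPI centralities and the crucial gene cluster

STRING-style TSV exports parse to an undirected simple graph (A–B/B–A
duplicates collapse at the maximum combined score; self-loops drop). No
confidence cutoff is applied by default — the upstream export is taken as
the network — but `min_score` exists. Centralities are computed on the
unweighted graph, the convention consistent with integer degree medians
reported by desktop network analyzers: degree is the incident edge count;
betweenness is the shortest-path pair-dependency sum normalized by
(n−1)(n−2)/2 with n the whole-graph node count; closeness of a node in a
connected component of size m is (m−1) divided by the sum of its distances
within the component, 0 for isolated nodes. The crucial gene cluster
retains nodes whose degree, betweenness and closeness all *strictly*
exceed the respective medians over all nodes (even-length medians are the
mean of the two middle order statistics). With all-distinct metrics this
retains at most ⌈n/2⌉ − 1 nodes.

The implementation delegates the graph algorithms to igraph; the test
suite validates them against an independent brute-force oracle (distances
by Floyd–Warshall, shortest-path counts by matrix powers — a walk whose
length equals the distance cannot revisit a vertex) on hundreds of random
graphs with up to 8 nodes.

## Enrichment

Over-representation is the hypergeometric upper tail P(X ≥ k) for an
overlap of k query genes with a K-gene term, a query of n genes and a
background of N genes. The conservative EASE variant (the tail evaluated
at k − 1) is a switch, not the default: the plain hypergeometric is exact
and is what the enumeration oracle tests. The background defaults to the
union of all term gene sets, mirroring the implicit annotation background
of enrichment servers. Adjustment is Benjamini–Hochberg within each
category (BP/CC/MF/KEGG separately), matching per-category reporting;
Bonferroni-style alternatives can be layered on the raw p-values if
needed. Terms with zero overlap are omitted. Top-k selection orders GO
categories by adjusted p ascending and KEGG by overlap count descending
(the ordering used in pathway bubble charts), with lexicographic term-id
tie-breaks.

Because the statistic is discrete, null p-values are super-uniform on a
lattice rather than exactly uniform; the null-behavior test therefore
compares observed p-values to exact-null simulation and checks the tail is
not anti-conservative, instead of applying a plain uniformity test.

## The tripartite network

Compound–target edges come from the filtered prediction table restricted
to crucial-cluster targets; target–pathway edges come from the overlap
genes of the top-10 pathways. Target nodes are the crucial targets
annotated to at least one top pathway — the pathway-connected core — which
is why the network can hold fewer targets than the crucial cluster.
Degrees rank each node type separately, ties again broken
lexicographically: top 9 targets and top 5 compounds by default.

## qPCR quantification

Technical replicates are averaged on the Ct scale. ΔCt is the target Ct
minus the reference-gene Ct per sample; ΔΔCt subtracts the arithmetic mean
of the control group's ΔCt per gene (the Livak formulation), and
rq = 2^−ΔΔCt. By construction the control group's mean ΔΔCt is 0 and its
geometric-mean rq is 1; rq is invariant to adding a constant to every Ct.
Group comparisons use a two-sided paired t-test per gene, pairing samples
by sorted sample id within group (the pairing key is an explicit choice;
wells are paired by index, as in plate-matched designs), on the ΔCt scale
by default since rq is log-normal under Gaussian Ct noise. Significance
tiers use strict thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
`ns` otherwise — p = 0.05 exactly is not significant.

## What the synthetic generators emulate

Each generator plants the structure its downstream stage is supposed to
find and returns a ground-truth ledger:

- `gen_compound_library(n, pass_fraction, seed)` places exactly
  `round(n × pass_fraction)` descriptor vectors inside every rule box and
  the GI ellipse; the rest carry one of three planted failure modes (GI
  point outside the ellipse with all rules clean; ≤ 3 YES rules; 4 YES
  rules with a used Lipinski allowance). Generation self-checks that the
  screen recovers the plant exactly.
- `gen_disease_tables()` controls the union size and the planted shared
  symbols exactly; planted symbols receive ranked-source scores in a band
  strictly above the others so any top-N cut at the configured size keeps
  them. Planted symbols are placed in every source large enough to hold
  them; at study scale (1000/1000/339/30/30 with 134 planted) the two
  30-symbol sources cannot host the full planted set.
- `gen_ppi_planted_hubs(n, n_hubs, p_in, p_out)` wires hubs to non-hubs
  with probability `p_in` and non-hub pairs with `p_out`; hub–hub edges
  default off so the `p_in = 1, p_out = 0` limit gives hub degree exactly
  `n − n_hubs`.
- `gen_annotations(..., factor)` forces the planted term's query overlap
  to `factor ×` the null expectation `nK/N`; `factor = 1` produces a pure
  null catalog.
- `gen_ct_table()` plants per-gene fold changes as `−log2(fold)` cycle
  shifts with Gaussian noise on the target-gene Ct only, so the noise-free
  case recovers folds exactly.

The study-scale preset `synth_preset_study()` chains these at the sizes of
a published screen of this shape: a 90-row compound table with 4 CID
duplicates (86 distinct, 17 passing), 410 compound targets sharing exactly
134 planted symbols with a 2081-symbol disease cluster, a planted-hub PPI
graph over the 134, and a four-category annotation catalog.

What the generators do **not** emulate: real descriptor correlations
(descriptors are drawn independently within boxes), sequence- or
structure-based target prediction, scale-free PPI topology (hubs are
planted on an Erdős–Rényi background), GO DAG structure, or
amplification-efficiency artifacts in qPCR. Passing tests therefore show
that the decision rules and statistics are implemented correctly, not that
the pipeline's biological conclusions transfer to any particular real
dataset.

## Numerical and design choices

- Boundary points of the GI ellipse classify as high (closed region), with
  a 1e-9 relative tolerance on the ellipse equation for floating-point
  robustness.
- All rank cuts (top-1000 targets, top-10 pathways, top-9 targets, top-5
  compounds) are configuration, defaulting to the conventional values.
- Strict inequalities in the median filter mean an all-identical network
  retains nothing.
- Stage problem sizes in the test suite (graphs up to 8 nodes for the
  exhaustive oracle battery, enumeration up to N = 20, 100-replicate
  recovery runs) were chosen as the smallest sizes at which the checked
  properties are non-trivial.
- Pipeline configs are YAML; intermediates are plain CSV/TSV/GMT/SIF/
  GraphML so any stage can be inspected or re-run in isolation. The
  pipeline itself consumes no randomness: identical inputs give identical
  reports.
- Errors carry condition classes (`np_format_error`, `np_value_error`,
  `np_data_error`, ...) so callers can react to the failure kind rather
  than matching messages; pipeline stage failures wrap the cause and name
  the stage, and leave a `FAILED` marker in the output directory.

## Known limitations

- The Open Babel backend's single logP estimate makes the Lipinski and
  Muegge lipophilicity sub-conditions approximate when descriptors are not
  supplied from a dedicated engine.
- Gene identifiers are compared as uppercase symbols; no HGNC/UniProt
  mapping is attempted, so cross-database symbol drift must be resolved
  upstream.
- Closeness and betweenness are unweighted; confidence-weighted
  centralities are out of scope.
- The qPCR module implements the 2^−ΔΔCt method only; efficiency-corrected
  quantification (Pfaffl) is not provided.

## A worked run

```{r example, eval = FALSE}
library(netpharm)
preset <- synth_preset_study(seed = 1, dir = tempfile("inputs"))
cfg <- run_config(
  compounds = preset$paths$compounds,
  descriptors = preset$paths$descriptors,
  predictions = preset$paths$predictions,
  disease = preset$paths$disease,
  ppi = preset$paths$ppi,
  gmt = preset$paths$gmt
)
report <- run_pipeline(cfg)
report
```
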