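# netpharm

A local, fully testable implementation of the network-pharmacology
screening chain used to study multi-compound herbal medicines against
complex diseases: from a raw compound table to a ranked
compound–target–pathway network, plus 2^−ΔΔCt quantification for the qPCR
follow-up. Every stage that is normally a web tool (compound databases, an
ADME predictor, a target predictor, disease-target databases, a PPI
server, an enrichment server) is replaced by deterministic functions over
plain files, and by seeded synthetic generators that produce inputs with
known planted structure — so the whole chain runs offline and every
decision rule is testable against ground truth.

It is written for computational pharmacology / systems-biology researchers
who want to reproduce, audit or adapt this style of analysis without
depending on live database snapshots.

## The chain

1. **Compounds** — ingest CSV/TSV compound tables, reject rows without a
   PubChem CID, deduplicate by CID (first-seen wins, source sets merge).
2. **ADME screen** — five drug-likeness rules with violation accounting
   (Lipinski MW ≤ 500, MLOGP ≤ 4.15, HBD ≤ 5, HBA ≤ 10 with a
   one-violation allowance; Ghose; Veber; Egan; Muegge) and an
   ellipse-based high/low gastrointestinal-absorption classifier on
   (TPSA, WLOGP). Retained: GI high ∧ YES count ∈ {4, 5} ∧ zero
   violations within the YES rules.
3. **Targets** — keep predictions with probability > 0; per-source top-1000
   disease targets by score for ranked sources; union; intersection of the
   compound and disease clusters; Venn partitions.
4. **PPI hubs** — parse STRING-style TSV, compute degree, normalized
   betweenness and closeness on the unweighted graph, and keep nodes
   strictly above the median on *all three* (the crucial gene cluster).
5. **Enrichment** — hypergeometric upper tail
   P(X ≥ k) = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n) (EASE variant optional),
   Benjamini–Hochberg within each category, top-10 pathway selection with
   KEGG ordered by count.
6. **Tripartite network** — compound–target and target–pathway edges only;
   degree ranking nominates the top targets and compounds.
7. **qPCR** — 2^−ΔΔCt with reference-gene normalization, paired t-tests,
   strict significance tiers (`***` < 0.001, `**` < 0.01, `*` < 0.05).

## Worked example

Generate the study-scale synthetic input bundle (86 distinct compounds of
which 17 pass the screen by construction, 410 compound targets sharing
exactly 134 planted symbols with a 2081-target disease cluster, a
planted-hub PPI graph, a four-category annotation catalog) and run the
pipeline over the written files:

```r
library(netpharm)
preset <- synth_preset_study(seed = 1, dir = tempfile("inputs"))
cfg <- run_config(
  compounds   = preset$paths$compounds,
  descriptors = preset$paths$descriptors,
  predictions = preset$paths$predictions,
  disease     = preset$paths$disease,
  ppi         = preset$paths$ppi,
  gmt         = preset$paths$gmt
)
report <- run_pipeline(cfg)
report
#> netpharm run report
#>   library_rows           90
#>   library_compounds      86
#>   superior_compounds     17
#>   compound_targets       410
#>   disease_targets        2081
#>   intersection_targets   134
#>   ppi_nodes              134
#>   ppi_edges              1260
#>   crucial_targets        56
#>   network_nodes          80
#>   network_edges          252
#>   top targets: XT0039, XT0050, XT0008, XT0015, XT0059, XT0076, XT0080, XT0109, XT0001
#>   top compounds: 428245, 193297, 375704, 419648, 656276
```

Reading the counts: 90 raw rows collapse to 86 distinct CIDs; 17 survive
the three-condition ADME screen; their filtered predictions cover 410
targets, of which exactly the 134 planted symbols also occur in the
2081-symbol disease cluster; the triple-median filter keeps 56 of the 134
PPI nodes as the crucial cluster; the tripartite network over the
pathway-connected core has 80 nodes, and its degree ranking lists the top
9 targets and top 5 compounds. All intermediates (centrality CSV, symbol
lists, enrichment CSV, SIF/GraphML exports, JSON report) are written to
`cfg$out_dir`.

The same run is available from a shell via the thin wrapper:

```sh
Rscript inst/scripts/netpharm-pipeline.R --preset study --seed 1 --out /tmp/run
```

or from a YAML config (`run_pipeline("run.yaml")`); see
`?read_run_config`.

## Package layout

- `R/compounds.R`, `R/descriptors.R` — ingestion, CID dedup, descriptor
  backends (Open Babel CLI or precomputed table).
- `R/adme.R` — rule thresholds, GI ellipse, the superior-property screen.
- `R/targets.R` — prediction filtering, top-N cuts, set algebra, Venn.
- `R/ppi.R` — STRING TSV parsing, centralities, triple-median filter.
- `R/enrich.R` — GMT I/O, hypergeometric/EASE, BH, top-term selection.
- `R/ctpnet.R` — tripartite assembly and degree ranking.
- `R/pcr.R` — 2^−ΔΔCt, paired t-tests, significance tiers.
- `R/synth.R`, `R/presets.R` — seeded generators with ground-truth ledgers.
- `R/pipeline.R` — end-to-end orchestration and the run report.
- `vignettes/network-pharmacology-screening.Rmd` — the methods account:
  model conventions, parameter defaults, generator design, limitations.
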