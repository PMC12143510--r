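---
title: "EDG discovery and driver prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EDG discovery and driver prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccdriver)
```

## The biological model

Extrachromosomal circular DNA (eccDNA) can drive overexpression in two
ways: a gene carried whole on an amplified circle can be transcribed at
elevated copy number, and an enhancer carried on a circle can be
repositioned against new promoters. `eccdriver` operationalizes both as
strict *full containment* in linear genomic coordinates:

* **EEG (eccDNA-encoded gene)** — any transcript of the gene, extended
  upstream of its transcription start site by a core-promoter pad, lies
  entirely inside an eccDNA interval on the same chromosome.
* **ERG (eccDNA-regulated gene)** — an enhancer lies entirely inside an
  eccDNA, and the gene is that enhancer's single top-ranked candidate
  target by the gene-enhancer interaction score S\_GE. Only the top-1
  target is called, following the enhancer release-and-retargeting view
  that a relocated enhancer chiefly acts on its strongest partner.

The *full* strategy deliberately discards truncated fragments: a gene
fragment without its promoter, or an enhancer fragment missing its core
binding sites, cannot be presumed functional. The *partial* mode
(≥ 1 bp overlap) is retained for comparison with overlap-based
catalogues; for identical inputs the full-mode call set is always a
subset of the partial-mode set, a property the test suite asserts on
randomized fixtures.

EEGs ∪ ERGs are the EDGs. Protein-coding EDGs are the working set for
driver analysis; other biotypes are kept in a separate non-coding
partition. EDGs recurring across datasets (different cancers, libraries)
are common EDGs (CEDGs).

## Driver prioritization

Candidate drivers are ranked on a reference PPI network combined with a
tumor-vs-normal differential expression table (DEGs: |log2FC| > 1 and
q < 0.01, strict inequalities). For each EDG *v*:

1. **K(v)** — degree in the full, confidence-thresholded PPI network;
   EDGs absent from the network are removed.
2. **Local network** — the subgraph induced on: *v* (source); every DEG
   within two hops (targets); every non-source one-hop node adjacent to
   at least one two-hop DEG (intermediates; a one-hop DEG that also
   bridges carries both roles). One-hop non-DEGs with no DEG behind them
   are excluded — they carry no information about *v*'s transcriptional
   reach.
3. **N(v)** — number of direct DEG neighbors; **Q(v) = Σ\_{u∈Γ(v)} N(u)**
   — the DEG content one further hop out, through any neighbor.
4. **α = Σ N(v)² / Σ Q(v)** over the analyzed EDG set — a single shared
   weight that discounts next-nearest relative to nearest neighbors.
5. **C\_WL(v) = N(v) + α·Q(v)** and
   **EGIS(v) = (K(v)+1)·(C\_WL(v)+1)**; rank by EGIS descending, flag the
   top 100 as candidate drivers.

The two-hop horizon is the method's definition, not a tuning knob: it is
what distinguishes this weighted semi-local centrality from the original
four-hop, unweighted semi-local centrality, trading a small loss of
global context for robustness and linear-time evaluation.

```{r toy}
g <- ppi_graph(ppi_edges(data.frame(
  gene_a = c("S", "S", "u1", "u1"), gene_b = c("u1", "d1", "d2", "d3"),
  confidence = 900)))
as.data.frame(rank_drivers("S", g, c("d1", "d2", "d3")))
```

This small network is fully hand-traceable: Γ(S) = {u1, d1}, N(S) = 1,
N(u1) = 2, N(d1) = 0, so Q(S) = 2; with a single EDG, α = 1²/2 = 0.5,
C\_WL = 2, and EGIS = (2+1)(2+1) = 9.

## Parameters, defaults and why

| Parameter | Default | Meaning |
|---|---|---|
| `pad_bp` | 35 bp | upstream core-promoter pad added before the containment test; base-pair-resolution promoter models place the minimal initiation signal within ~35 bp of the TSS |
| `mode` | `full` | strict containment; `partial` reproduces overlap-based catalogues |
| `min_confidence` | 700 | PPI edge threshold on a 0–1000 STRING-like scale; 700 is the conventional "high confidence" cut, and the source of the interaction scores does not pin a specific value, so it is exposed as a parameter |
| `lfc_threshold`, `q_threshold` | 1, 0.01 | strict DEG inequalities, applied exactly as stated |
| `max_depth` | 2 | local-network horizon; part of the method's definition |
| `top_m` | 100 | candidate-driver cutoff |
| `min_fraction` | 0.5 (strict) | a CEDG must recur in a strict majority of datasets; "most datasets" has no canonical fraction, so the strict majority is the default and the fraction is exposed |

Open choices resolved in this implementation:

* **N and Q restricted to the local network** (`restrict_to_local = TRUE`):
  the influence being measured is defined *in the local network*, so
  neighbors excluded by the local-network rule contribute nothing. A flag
  allows full-PPI counting for sensitivity analysis; on the toy network
  above both agree.
* **α is computed once per run** over the EDG set that survives the PPI
  filter (the sums in its definition range over the EDG set); EDGs with
  empty local networks contribute N = Q = 0. When Σ Q = 0 the weight is
  defined as 0 and C\_WL degenerates to N — and with no DEGs at all the
  ranking degenerates to degree order, which is the correct limit.
* **CEDGs are intersected at the level of gene calls**, not genomic
  regions: genes are the reporting unit throughout, and region-level
  intersection would re-introduce coordinate ambiguity across datasets
  with different eccDNA boundaries.
* **Ties**: equal S\_GE scores resolve to the lexicographically smallest
  gene id; equal EGIS resolves by higher K, then gene id. Both rules
  exist only to make output deterministic.

## The 17-gene CEDG risk signature

`cedg17_model()` packages a fixed linear prognostic model over 17 CEDGs
(11 positive, 6 negative coefficients; the coefficients sum to 0.5178).
Expression is standardized per gene to zero mean; the default also
scales to unit variance using the population standard deviation, since
the model is applied to cohort-standardized values and mean-only
centering is available via `normalization = "center"`. The per-sample
score is the coefficient-weighted sum; the median score splits samples
into risk groups, with samples tied at the median assigned to the
low-risk group (high risk is *strictly above* the cutoff). Model fitting
(Cox screening, LASSO, stepwise selection) is out of scope: only the
fitted model is packaged, with `MTL5`/`SAPS3` kept as published and
cross-referenced to their current symbols `TESMIN`/`PPP6R3`.

## Benchmarking

`confusion_metrics()` computes TP/TN/FP/FN and accuracy, precision and
recall of a predicted set against a benchmark driver list. TN — and
therefore accuracy — depends entirely on the assumed gene universe, so
the universe is a required argument rather than a hidden default; a
natural choice is the node set of the thresholded PPI network. Published
benchmark tables built on specific external corpora (proprietary eccDNA
sets, full enhancer databases, reference PPI releases, curated driver
censuses) are not reproducible from synthetic data; this module
guarantees the metric arithmetic, which the tests verify by enumeration
and by the precision/recall swap symmetry on random set triples.

## What the synthetic generators emulate — and what they do not

The generators exist so every pipeline stage can be tested end to end
with known ground truth:

* `make_annotation()` allocates transcripts and enhancers into disjoint
  slabs along one chromosome (50 bp margins), so nothing overlaps except
  where planted. Strands are random; ~80% of genes are protein-coding;
  enhancers carry 1–3 scored targets.
* `make_eccdna()` plants eccDNAs that strictly contain padded transcripts
  (EEG truth) or enhancers (ERG truth), partial-overlap decoys that are
  callable only in partial mode, and background circles containing
  nothing. Slab allocation makes recovery exact: full-mode calls equal
  the planted truth, with no chance containments.
* `make_ppi_and_degs()` draws an Erdős–Rényi (or preferential-attachment)
  graph, wires the planted driver to 15 extra neighbors, labels nodes as
  DEGs with probability 0.9 within two hops of the driver and 0.05
  elsewhere, and synthesizes log2FC/q values consistent with those labels
  under the strict thresholds. The defaults (200 nodes, mean degree 6)
  keep a full 100-seed recovery study under a few minutes on one core
  while leaving the driver's advantage statistical, not hard-coded.
* `make_expression()` draws Gaussian expression with per-gene mean
  shifts.

Each generator consumes one explicitly seeded RNG stream and restores
the caller's RNG state, so outputs are pure functions of their
arguments.

What they deliberately do **not** emulate: real eccDNA length
distributions and hotspot chemistry (CpG islands, chromatin
accessibility), circularization junctions (elements spanning the
junction of a circle are not representable in linear coordinates and are
out of scope), scale-free PPI topology with confidence-correlated
degree, correlated expression structure, or batch effects. Passing tests
therefore demonstrate that the *rules* are implemented exactly and that
a strongly planted signal is recovered — not that the method's power on
real tumor data matches any published figure.

## Numerical and degenerate-input behavior

* Coordinates are 0-based half-open everywhere internally; GTF input is
  converted on read. Containment at the boundary is strict in the
  half-open sense: an element ending exactly at the eccDNA end is
  contained; one starting at the eccDNA end shares no base.
* Padding clamps at position 0; unknown-strand transcripts are an error
  unless the caller opts into assume-plus padding (with a warning).
* Loaders reject, never repair: non-integer coordinates, end ≤ start,
  inconsistent enhancer coordinates, negative scores, q-values outside
  [0, 1], empty node names and duplicate ids are all errors naming the
  offending record.
* Constant expression rows z-score to zero with a warning; a
  single-sample matrix is an error.
* All writers emit deterministically ordered rows, so repeated runs are
  byte-identical; `run_pipeline()` logs every effective parameter and a
  configuration hash in `manifest.json`.

## Problem sizes used in the shipped studies

The test suite and the acceptance script run entirely on generated data
chosen to make the properties sharp while staying light: exhaustive
enumeration of all labelled 4-node graphs for the local-network rule;
100 random graphs of 10–50 nodes against an independent brute-force
evaluation of the centrality definitions (agreement demanded to 1e-12);
50 containment fixtures of 12 genes; 100 seeded 200-node networks for
planted-driver recovery; 1000 random set triples for the benchmark
symmetries. These sizes are the package's own choices and are large
enough that every claimed invariant is exercised across regimes
(empty DEG sets, isolated nodes, ties, decoys).

## Known limitations

* Linear-coordinate containment cannot see elements that span the
  circularization junction.
* The top-1 S\_GE rule ignores secondary enhancer targets by design.
* α is a single global weight; cancer-type-specific runs should be
  executed per dataset rather than pooled.
* The benchmark module reports arithmetic on user-supplied truth sets;
  it does not ship a driver-gene census.
* The signature is a fixed published model; refitting to new cohorts is
  intentionally out of scope.
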