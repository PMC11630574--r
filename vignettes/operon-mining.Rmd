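---
title: "Detecting iac/iad auxin-degradation operons in annotated genomes"
author: "iaaminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting iac/iad auxin-degradation operons in annotated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaaminer)
```

## The problem and the model

Bacteria degrade the plant hormone indole-3-acetic acid (IAA) through
two aerobic catabolic clusters: the *iac* operon (degradation via
catechol) and the *iad* operon (via anthranilate). `iaaminer`
operationalises a two-part decision rule for calling a genome a
potential IAA degrader from its annotation alone:

1. **Marker homology.** The proteins IacA and IacE (for *iac*) and IadD
   and IadE (for *iad*) are essential to each pathway and serve as
   anchors. Every CDS protein is aligned to each marker with optimal
   Smith–Waterman local alignment under affine gaps, and a hit requires
   identity strictly above 50 % and template coverage strictly above
   60 %.
2. **Co-localization.** Operon genes are physically clustered, so both
   markers of a pair must lie near each other on one contig. Distances
   are counted in CDS ordinals — the rank of a coding sequence among all
   CDS of its contig — never in base pairs: an iacA/iacE hit pair must
   be less than 7 CDS apart (strict), and iadD must be adjacent to iadE
   (ordinal distance at most 1). Genomes satisfying both rules are typed
   `both`; one rule, `iac` or `iad`; neither, `none`.

Homology alone over-calls (isolated marker-like genes occur outside
functional clusters), and co-localization alone is meaningless without
the homology gate; the conjunction is the method.

## Alignment conventions

The identity denominator is the number of aligned columns, counting gap
columns — the convention of BLAST-family protein search tools. Coverage
is measured on the **template** (marker), not the query: a short gene
fragment that matches a marker perfectly over 30 % of its length is not
evidence of a functional marker gene. Scoring uses BLOSUM62 with gap
open 11 and extension 1, and a gap of length $L$ costs
$11 + L \cdot 1$.

The kernel (compiled, in `src/`) reports the first-encountered optimal
cell in row-major order and breaks traceback ties by preferring
diagonal, then gap-in-query, then gap-in-template steps, with opening
preferred over extension — every output is deterministic. The test
suite pins the kernel to an independently written brute-force
dynamic-programming oracle (exact score and identity agreement on 200
random pairs) and cross-checked it against `Biostrings::pairwiseAlignment`
during development.

Boundary behavior is strict everywhere because the thresholds are
written as strict inequalities: identity exactly 50.0, coverage exactly
60.0, an iacA–iacE distance of exactly 7, and an iadD–iadE distance of
2 are all negative. Tests assert each boundary on constructed fixtures.

## Tunable parameters

All cutoffs live in one `threshold_config()` object:

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 50 (%) | marker hit gate, strict `>` |
| `min_coverage` | 60 (%) | template coverage gate, strict `>` |
| `max_cds_gap_iac` | 7 (CDS) | iacA–iacE ordinal distance, strict `<` |
| `iad_adjacency_gap` | 1 (CDS) | maximum iadD–iadE distance, `<=` |
| `cluster_gap` | 3 (CDS) | non-template genes bridged inside a cluster |
| `matrix`, `gap_open`, `gap_extend` | BLOSUM62, 11, 1 | alignment scoring |

Two documented alternatives are exposed rather than silently chosen.
First, `preset = "relaxed"` lowers `min_identity` to 40, the value used
for annotation-figure labelling in the source screen (its methods and
figure legend state different cutoffs; the package defaults to the
methods value and supports both). Second,
`iac_gap_counts_intervening = TRUE` reads "less than 7 CDS" as "at most
7 intervening CDS" (ordinal distance ≤ 8); the default reads it as an
ordinal difference < 7. "Adjacent" for iad is interpreted
strand-agnostically as consecutive ordinals, because real clusters mix
strands.

## Cluster reconstruction and completeness

For a positive genome, every gene of the whole-operon template set
(iacA–I + regulator iacR; iadA–N + iadR) is mapped at the same gates,
and the cluster is grown from the anchor pair as the maximal run of
template-hit CDS in which consecutive members are separated by at most
`cluster_gap` (3) non-template CDS. Genes inside the span without a
template match are reported as `unknown` — real clusters carry such
genes. A cluster is `complete` when the full catabolic core set
(iacA–iacI or iadA–iadN) is present, `fragmented` otherwise; the
regulator is mapped but not required, and the core set is configurable
because "complete" admits no single canonical definition. Additional
template runs elsewhere in the genome (at least two template genes) are
reported as extra clusters, since some genomes carry two fragmentary
copies.

## Surveys, quality filtering and rounding

MAG-based surveys first pass a quality filter: completeness ≥ 90 %,
contamination ≤ 5 %, and quality score
$q = \text{completeness} - 5 \times \text{contamination} \ge 65$, all
boundaries inclusive. Isolates without CheckM-style estimates pass by
default and are flagged (`assumed_pass`) rather than silently dropped,
because isolate screens are run without MAG filters. Prevalence
percentages are rounded **half-up** to two decimals; this choice
reproduces the printed percentages of the source survey (5/132 → 3.79,
8/492 → 1.63, 66/544 → 12.13, 5/382 → 1.31, 21/183 → 11.48). Two of
that survey's printed figures are arithmetically inconsistent with any
rounding of their own counts (2/304 printed as 0.65 where half-up gives
0.66, and a discussion figure of 7.84 % for 131/1,465, which is
8.94 %); the package reproduces counts and documents, rather than
imitates, those two numbers.

## Gene-cluster versus genome trees

To quantify the observation that cluster relatedness does not track
organismal relatedness, the package concatenates cluster proteins in a
fixed, configured gene order, computes pairwise p-distances (1 − global
Needleman–Wunsch identity fraction, gap columns in the denominator),
builds a neighbor-joining tree (`ape::nj`, taxa sorted before joining so
input order never changes the topology), and reports the unrooted
Robinson–Foulds distance (`phangorn::RF.dist`) against a supplied
whole-genome tree pruned to the same taxa. This deliberately substitutes
a simple, fully documented distance for a multiple-alignment + model
workflow: the claim being supported is *incongruence* — a topology-level
statement — not branch-length fidelity. The NJ step is validated by
exact recovery (RF = 0) of random 8-taxon additive topologies. Genomes
missing a requested gene are excluded with a warning rather than padded.

## The colorimetric screen

The Salkowski assay is linear in the working range, so the standard
curve is an ordinary least-squares line of OD530 on IAA concentration
(mM); two standards give the exact interpolation line, and identical
concentrations are a degenerate-design error. Percent degradation is
$D = 100\,(c_0 - c_t)/c_0$ with the initial concentration
$c_0 = 0.4$ mM by default. Readings that invert to negative
concentrations (blank noise) are clipped to zero and flagged, not
errors; $c_t > c_0$ clips $D$ to 0 with a flag. A strain is
screen-positive when $D > 60$ strictly — "over 60 %" means 60.0 is
negative. Blank subtraction is available but off by default, since
background handling varies between plate setups.

## The synthetic-genome generator

Every stage is testable without downloads because the generator plants
operons with known ground truth into decoy genomes:

* **Decoys** are random-composition proteins (lengths 150–450, average
  bacterial amino-acid frequencies) — not shuffled real proteins, which
  avoids accidental marker homology.
* **Planted genes** are template copies mutated at uniformly chosen
  positions until `align_local` identity is within ±2 points of the
  target; spacing, order, strand and fragmentation are controlled by
  `plant_spec()`.
* **Templates** are themselves synthetic: a fixed-seed random set of
  25 proteins (250–500 residues) standing in for the curated operon
  references, generated in code and identical in every session. The
  pipeline treats them exactly as a curated FASTA.
* **Surveys** allocate planted positives deterministically
  (`round(n × prevalence)` per stratum), so survey tests are exact.
  Everything is byte-reproducible under a fixed seed.

The generator's truth labels record the call its geometry implies; a
plant is only labelled positive when its target identity clears the
50 % gate by more than the ±2-point mutation tolerance, so truth is
never ambiguous at the gate.

What passing these tests shows — and does not. The validation suite
(55 genomes by default: intact plants at 70–85 % identity, fragmented
clusters, marker pairs placed just beyond the distance limits, plants
below the identity gate, pure decoys, dual-operon genomes) establishes
that the implementation applies its stated rule with sensitivity and
specificity 1.0 against construction. It cannot establish that the rule
itself is biologically complete: real genomes contain paralogs with
intermediate identity, operons split across contig breaks in fragmented
assemblies, and divergent degraders below any fixed identity gate. Those
are properties of the screen being implemented, not of the
implementation.

## Numerical and design choices

* Coordinates are stored 1-based inclusive as annotated; all distance
  arithmetic uses CDS ordinals (assigned per contig by ascending start;
  ties by end, then file order).
* Best-hit flagging breaks score ties by lowest ordinal, then gene id;
  evidence pairs break distance ties by smallest minimum ordinal —
  outputs are reproducible byte for byte.
* CDS features without a protein sequence are skipped with a counted
  warning (annotation pipelines do emit such features); FASTA proteins
  without a CDS likewise.
* Problem sizes in tests and the acceptance script (55-genome suite,
  200 oracle pairs, 20 NJ replicates) were chosen to exercise every
  genome class of the generator several times over while keeping a full
  run in the minutes range on a single CPU.

## Known limitations

* Detection is protein-level only: no DNA search, no HMM profiles, no
  E-value statistics, so the gates are hard thresholds rather than
  significance-calibrated.
* Operons split across contigs are missed by construction — the
  co-localization rule cannot fire across a break (reported as
  not-co-localized, never as a large distance).
* The shipped templates are synthetic stand-ins; scanning real genomes
  for real operons requires supplying curated marker/operon FASTA files,
  which drop in without code changes.
* The phylogeny module is a topology-level tool; for publication-grade
  trees use a dedicated multiple-alignment + inference workflow and feed
  the result back through `rf_distance()`.
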