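---
title: "Methods: profiling the ITS1-5.8S-ITS2 region and screening for rDNA pseudogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling the ITS1-5.8S-ITS2 region and screening for rDNA pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsprofiler)
```

## The problem

The nuclear 45S rDNA unit (18S–ITS1–5.8S–ITS2–26S) occurs in thousands of
tandem copies. Concerted evolution normally homogenises these copies, but
when it is incomplete — as in many hybrid and polyploid plants such as
cultivated bananas — divergent paralogs persist, including silenced
pseudogenes. Pseudogenic ITS copies accumulate mutations free of
functional constraint, so leaving them in a phylogenetic dataset distorts
the tree, while recognising them is informative in its own right.
Conversely, because parental rDNA arrays can persist intact in hybrids,
the set of distinct ITS copies in an accession can reveal its genome
constitution (for bananas: the A, B, S and T genomes of *Musa acuminata*,
*M. balbisiana*, *M. schizocarpa* and *M. textilis*).

`itsprofiler` implements this analysis as a reusable, fully testable
pipeline: sub-region delimitation, composition statistics, conserved-motif
and secondary-structure screening, a pseudogene classifier, clone-library
typing, neighbour-joining phylogeny with bootstrap, genome-constitution
assignment, read-depth profiling, and a seeded synthetic-data generator
that stands in for study data.

## Delimitation

Region boundaries are transferred from an annotated reference by pairwise
alignment (global in the reference, local in the record, match +1 /
mismatch −1 / gap open 4 / extend 1). Boundary columns landing in record
gaps are resolved toward the 5.8S, whose conservation anchors the
alignment; the inner boundaries are derived from the mapped 5.8S interval
so the annotation is always ordered and contiguous. Delimitation refuses
to answer (rather than guessing) when identity over the 5.8S falls below
a floor (default 0.6). The packaged default reference is the synthetic
template described below; any annotated reference can be supplied.

## Composition statistics

GC content is computed over unambiguous bases only. Percent identity
excludes N columns and gap–gap columns and counts gap-vs-base as a
mismatch; this single convention reproduces both of the worked
single-difference cases that motivated it (two substitutions over 600 nt
= 99.67%; one 1-nt insertion = 99.83%). Nucleotide diversity (π) is the
average pairwise difference per site with pairwise deletion of gap/N
columns. The p-distances feeding the phylogeny use pairwise deletion as
well — note this intentionally differs from percent identity, which
scores indels.

## Motif scanning

The three conserved angiosperm 5.8S motifs are fixed constants: M1
`CGATGAAGAACGTAGC`, M2 `GAATTGCAGAATCC`, M3 `TTTGAACGCA`. Each is slid
ungapped along the 5.8S; the best offset minimises Hamming distance (ties
to the left, N counts as a mismatch), and deviations are reported
per-position within the motif. When the best ungapped match still exceeds
a ceiling (default 4 mismatches), a gapped alignment (global in the
motif) is tried; if it is cleaner and contains a gap, an indel flag is
raised rather than inventing substitution positions.

## Secondary structure

The original analyses in this field use thermodynamic folding (mFOLD) and
interactive structure editors. This package substitutes deterministic
maximum base-pair (Nussinov-style) folding over the canonical pair set
(AT, GC, GT wobble; minimum hairpin loop 3), because the screening surface
is *topology* — four helices, TGGT in helix III, a pyrimidine–pyrimidine
bulge in helix II, and satisfiability of six prescribed 5.8S helix
constraints — not free energies.

Two numerical choices matter and are deliberate:

* **Stacking tie-break.** The number of pairs is the primary objective
  (verified against exhaustive enumeration in the tests); among
  maximum-cardinality structures the traceback maximises stacked
  adjacencies. Pure maximum-pairing is massively degenerate, and an
  arbitrary optimum can scatter a designed helix after a single
  substitution; preferring stacked structures makes the reported fold
  stable without changing the score.
* **Helix significance floor.** Maximal stacks (allowing bulges of up to
  2 nt per strand) of ≥ 3 pairs are reported as helices, but only helices
  of ≥ 5 pairs participate in the I–IV numbering of the topology check.
  Functional ITS2 stems are well above 5 bp, whereas incidental 3–4 pair
  runs between unpaired linkers are ubiquitous under maximum-pairing
  folding and carry no signal.

The 5.8S constraint check is independent of folding: a constraint
`(i, j, k)` (helices B4–B8 at the positions used in the original
structure reconstructions, e.g. B4 = 38/98/3) is satisfiable iff every
prescribed pair `(i+t, j−t)` is canonical. The "F i j k" settings are
read with the standard folding-constraint convention — positions
`i..i+k−1` pair `j..j−k+1` — and the convention is isolated in
`helix_constraints()` so it can be changed in one place.

## Pseudogene classification

Evidence is split into two tiers. Sequence-intrinsic defects — any motif
mismatch, failure of the four-helix ITS2 topology, or any failed 5.8S
helix constraint — are individually sufficient for
`putative_pseudogene`. Cohort-relative anomalies — total-region GC
z-score below −2 against the functional cohort, or ITS1 length outside
the cohort range by more than 5 nt — only raise `suspect`, because they
are meaningless without a cohort and a 41-bp deletion alone does not
prove silencing. "Lower GC content" is nowhere quantified in the
literature this mirrors; z < −2 is this package's reproducible
operationalisation and is exposed as a parameter. A CpG-deamination
counter (template-aligned C→T / G→A at CpG sites) provides the
methylation-signature evidence; it requires a designated functional
template, typically the most supported ITS type of the accession.

## Clone typing

Clone libraries (15–85 members in the emulated study) are aligned
progressively: pairwise global alignments give guide p-distances, a UPGMA
guide tree orders profile–profile merges (match +1 / mismatch −1 on
column base frequencies, linear gap −1.5), and input order is removed by
canonical id sorting. Types are single-linkage clusters at a percent
identity threshold; clusters below 2 members are treated as PCR/cloning
singletons and absorbed into the nearest type. Consensus is column-wise
majority, ties to the first-observed base, gap-majority columns dropped.

The threshold default is **99.5%**, chosen from the error model rather
than convention: one error per ~600-nt clone puts within-type pairs near
99.7% identity, while two templates 5 substitutions apart sit near
99.15%. A 99.0% threshold — the obvious round number — fails its own
purpose: whenever a clone's random error happens to land on a
template-difference column (a few percent of libraries), the resulting
cross pair sits at exactly 5 differences ≈ 99.15% > 99%, and single
linkage chains both templates into one type. 99.5% is the midpoint of
the separating margin; chaining then needs two coincident "helpful"
errors, which is negligible.

## Phylogeny and genome assignment

Distances are uncorrected p or Jukes–Cantor (`d = −¾ ln(1 − 4p/3)`,
error on saturation at p ≥ 0.75 unless a ceiling is requested).
Neighbour joining is the classical Saitou–Nei algorithm with
deterministic tie-breaking (lexicographically smallest pair of subtree
representative labels); negative branch lengths are clamped to zero with
the deficit reported. NJ is exact on additive matrices, which the tests
exploit as an oracle. Nonparametric bootstrap resamples alignment columns
with replacement (seeded), rebuilds NJ per pseudoreplicate, and reports
per-bipartition percentages; trees are midpoint-rooted for display.
Bayesian inference, substitution-model selection and richer distance
models are deliberately out of scope — the NJ branch alone carries the
clade structure this pipeline needs.

Genome constitution is assigned per query ITS type by smallest mean
(JC) distance to labelled reference groups, with the margin to the
second-best group reported and an ambiguity flag below a floor (default
0.005 substitutions/site). Mean-distance placement was chosen over formal
monophyly testing because it is robust for single-query placement and
needs no re-estimated tree per query.

## The synthetic world

The generator emulates the statistical structure of the study the
pipeline was built around; its defaults are the stated conditions, chosen
once:

* **Template.** ITS1 219 nt (GC 0.56, 18 CpG sites), 5.8S 155 nt
  (GC 0.52) carrying exact M1–M3 and satisfying all six helix
  constraints by construction, ITS2 211 nt folded from four designed
  stem-loop cassettes (stems 15 bp, A-rich linkers, TGGT in loop III,
  T|T bulge in stem II), partial 18S/26S flanks of 60 nt. Region lengths
  (216–223 / 154–155 / 205–227, total 578–601, 544 after the 41-bp ITS1
  deletion) match the printed ranges of the emulated study.
* **Lineage.** Seven leaves (A, S, B, Rhodochlamys-, T-, Australimusa-,
  Ensete-like) with per-edge per-site substitution probabilities at the
  few-percent divergences typical of within-family ITS data; all
  substitutions equiprobable, matching the JC distances used downstream.
* **Selection.** 5.8S motif and constraint positions and the ITS2
  structural core never mutate in functional templates; unconstrained
  5.8S positions evolve at 0.2× and flanks at 0.1× the spacer rate; ITS2
  linker substitutions that would destroy the four-helix topology are
  reverted (purifying selection on structure). This is what makes
  "functional template ⇒ classified functional" a construction guarantee
  rather than a tuning outcome.
* **Pseudogenisation.** Operators mirror the described defect spectrum:
  targeted motif transitions (M1@{11,16}, M1@{12}, M2@{9,14}, M3@{7,8}),
  designated helix-constraint breaks, a contiguous ITS2 stem disruption,
  CpG deamination in ITS1 (default rate 0.3 per site strand), and the
  41-bp ITS1 block deletion.
* **Libraries and reads.** Clone libraries default to 15 members with
  i.i.d. per-base error 1/600 (or an exact per-clone error count);
  shotgun reads are uniform over both strands with
  `round(coverage · L / read_len)` reads so mean depth equals coverage.

What the synthetic world does *not* emulate — and hence what a green test
does not establish: real ITS2 GC content (the designed ITS2 is ~0.39 GC
because unpaired regions are A-rich for fold stability; real ITS2 is
0.56–0.71), homopolymer-specific 454 error, chimeric/recombinant ITS
sequences, thermodynamic folding detail, and real rDNA copy-number
effects. The classifier benchmark measures recovery of *injected* defects
through the whole pipeline (delimitation → scanning → folding →
classification), not biological discovery.

## Known limitations

* Chimera detection is out of scope; recombinant types in hybrids must be
  inspected manually.
* The progressive aligner is adequate for the near-identical sequences of
  clone libraries and within-family references; deeply divergent inputs
  (< 50% identity) trigger a warning, not a better algorithm.
* Maximum-pairing folding is a screening stand-in: its structures are
  topologically, not thermodynamically, meaningful.
* The pipeline's GC rule needs a functional cohort; single-record studies
  must disable it.
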