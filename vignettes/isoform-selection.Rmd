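---
title: "Selecting the isoform to model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the isoform to model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoselect)
```

## The problem

A missense mutation reported at the protein level names a residue position,
but a gene usually expresses several isoforms and the position only makes
sense on some of them. At the same time, a homology model can only be built
where experimentally determined template structures cover the sequence.
`isoselect` scores every isoform of a gene on both axes and selects the one
most useful for modelling, while reporting the full mutation-to-isoform map
so a user can overrule the choice (for instance when a mutation of special
interest sits on a lower-ranked isoform).

## The scoring model

For an isoform with `Total AA` residues, of which `Covered AA` are covered
by the selected template combination, and for a gene with `F` mutations
mapping onto at least one isoform of which `M` are modellable on this
isoform:

* Structural function `SF = Covered AA / Total AA`
* Mutation function `MF = M / F` (defined as 0 when `F = 0`, so genes
  without mappable mutations are still ranked, by structure alone)
* `Selection = w1 * SF + w2 * MF`, defaults `w1 = w2 = 10`

Both weights are user-tunable, dimensionless, and only their ratio affects
the ranking: scaling both by a constant scales every score without
reordering. With `w2 = 0` the ranking degenerates to coverage alone, with
`w1 = 0` to mutation coverage alone; the test suite asserts both
degenerations and the monotonicity of `Selection` in each component.

### What counts as "covered"

A template residue covers a target position only when the aligned residues
are identical (and both are standard amino acids — the tolerated codes X,
U, B and Z never count). Counting full aligned spans instead would inflate
coverage over mismatched regions; counting identities is also the only
definition under which the worked example in the README is internally
consistent (7 and 6 covered residues for the two isoforms), so it is the
definition this package commits to.

### What counts as "modellable"

A mutation maps onto an isoform when the isoform carries the stated
wild-type residue at the stated position; no renumbering between isoforms
is attempted, each isoform is tested literally and independently. Whether
the `MF` numerator should additionally require the position to lie inside
the covered region is a genuinely open modelling question — a mutation
outside all templates maps fine but cannot be modelled. The package
defaults to requiring coverage (`count_mode = "covered"`, matching the word
"modelled") and exposes `count_mode = "mapped"` for the laxer reading. The
two modes differ only for mapped-but-uncovered mutations, which the test
suite demonstrates on a constructed case.

## Template handling

Templates arrive as a per-gene catalog (tab-separated: id, chain,
resolution, chain sequence), standing in for whatever homologue search
produced them; this keeps the engine fully offline and deterministic.

* **Alignment.** Each template chain is aligned to each isoform with a
  local Smith–Waterman alignment, BLOSUM62, gap open 11 / extend 1 — the
  scheme is pinned so results are reproducible across machines. Alignment
  identity is recomputed as identical columns over aligned (non-gap)
  columns, the most common convention, and catalog-supplied identities are
  never trusted. An independently implemented dynamic-programming aligner
  in the test suite cross-checks optimal scores on random small instances.
* **Filtering.** Identity ≥ 25 % and resolution ≤ 4.5 Å by default, both
  inclusive (nothing in the thresholds' definition suggests strictness,
  and inclusivity is the documented, configurable choice). Templates
  without a resolution (NMR ensembles, models) pass the resolution filter
  but rank after resolved entries so they are only used when they add
  something.
* **Greedy cover.** The minimal-set question is a maximum-coverage set
  cover; the package uses the standard greedy loop — repeatedly take the
  template adding the most new identically matched positions, ties broken
  by larger total identity count, then alphabetically by id — and stops
  when nothing new can be added. The greedy union always equals the union
  over the whole filtered catalog; tests verify against exhaustive subset
  enumeration (hundreds of random instances with ≤ 8 templates) that this
  is the maximum achievable coverage, at a set size no smaller than the
  optimum guarantees.
* **Structure cleaning.** Raw PDB text can be cleaned for template use:
  waters, hetero ligands, non-standard residues and alternate-location
  duplicates (first altloc per atom wins) are dropped, per-chain one-letter
  sequences extracted, and surviving coordinate lines preserved
  byte-for-byte.

## Reports and alignments

`report.log` echoes the full configuration and, per gene, the ranked score
components, every mapped mutation with the isoforms it maps on, the
mutations found on no isoform, and the selected isoform. `report.csv`
holds one row per (gene, mutation, isoform) with mapped/covered flags.
`covered_intervals.txt` lists each selected template's newly contributed
1-based closed intervals.

PIR (NBRF) alignments are written for the winner's wild type and each
mapped, non-silent variant. The target is trimmed to the covered region;
interior uncovered runs shorter than `max_interior_gap` (default 20
residues — long enough to keep loops between covered segments in one
model, short enough not to span whole missing domains) are retained, while
longer runs split the target into per-domain files, since modelling two
domains with no common template says nothing about their relative
orientation.

## Input conventions and degenerate cases

* Mutation tokens accept one-letter (`T2A`) and three-letter
  (`Thr2Ala`, any case) notation; whitespace of any kind separates tokens.
  Ambiguity codes are rejected as mutation residues. Duplicate mutations
  are collapsed before counting so `MF` counts distinct substitutions.
  Silent tokens (`wt == mut`) are kept with a warning for reporting but
  excluded from variant building.
* Database headers follow the two UniProt FASTA dialects; the gene symbol
  comes from `GN=` or, failing that, the entry-name prefix. Alternative
  isoforms attach to a gene by base accession or gene symbol
  (case-insensitive, no synonym expansion — deterministic and offline).
  Duplicate canonical entries keep the first with a warning. Malformed
  records are collected per record and never abort a database read.
* A gene missing from the canonical database, or lacking a template
  catalog, is reported and scored accordingly (coverage 0); the run
  continues. An unmapped mutation records why (`wt_mismatch` vs
  `out_of_range`).
* Ranking ties break canonical-first, then lowest isoform suffix, then
  accession — invented but deterministic plumbing, documented here because
  no published rule exists.

## The synthetic-fixture generator

`generate_fixture()` builds complete input trees (databases, catalogs,
mutation lists) whose expected outputs are known by construction, with
every expectation computed by direct arithmetic on the planted quantities
and recorded in `manifest.json` — never by running the engine:

* the canonical sequence has a shared region (positions 1–40) and a tail
  (41–60) drawn from disjoint amino-acid alphabets;
* alternative isoforms truncate the shared region (lengths 30–38) and
  carry one or two conservative substitutions (strictly positive BLOSUM62
  pairs), which provably leave the planted gapless alignment optimal and
  remove exactly one identical column each;
* in-range templates are exact substrings common to all isoforms; a tail
  template covers only the canonical (the disjoint alphabet makes identical
  matches on alternatives impossible); a below-threshold decoy checks the
  resolution filter;
* mutations are planted inside covered intervals: "shared" ones map
  everywhere, one "tail" mutation maps only on the canonical, one
  impossible mutation maps nowhere.

The generator is a pinned Mersenne–Twister function of its seed and
parameters; identical calls reproduce byte-identical trees. What it does
*not* emulate: realistic homologue divergence (gapped alignments, partial
identity), paralogous cross-matches, sequencing noise, or structures with
real coordinate defects. Passing the recovery tests therefore shows the
engine's bookkeeping is exact under controlled conditions, not that
template search on real proteins is well-posed.

## Problem sizes used by the tests

The suite checks greedy-vs-exhaustive cover agreement on 500 random
instances (≤ 8 templates, targets ≤ 30 residues — small enough for full
subset enumeration), exact fixture recovery (to 1e-12) across 100 seeds of
the generator, 30–50-case property loops for notation equivalence and
mapping purity, and byte-identical rerun checks on the worked example.
These sizes give the enumeration oracles full coverage of the
combinatorics while keeping the default test run fast.

## Known limitations

Multiple co-occurring point mutations are not modelled jointly — variants
are single-substitution models for pairwise comparison. Insertions,
deletions and frameshifts are out of scope, as is mapping mutations across
isoforms by alignment (a position is tested literally per isoform). The
selected isoform is the most *modellable* one, which is not guaranteed to
be the most functionally relevant one. Template discovery itself (homologue
search, MSA construction) is outside the package: the catalog is the
interface, and its quality bounds the result.
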