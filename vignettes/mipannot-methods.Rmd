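---
title: "Methods: how mipannot classifies and annotates MIP families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mipannot classifies and annotates MIP families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mipannot` annotates plant major intrinsic protein (MIP/aquaporin)
families from protein sequences and gene models. This vignette explains
the models and procedures behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the accompanying tests
do and do not demonstrate.

```{r setup, message = FALSE}
library(mipannot)
library(dplyr)
```

## Diagnostic residues and template mapping

The pore selectivity of an MIP is governed by a small set of residues:
the two NPA motifs (three residues each, loops LB and LE), the
aromatic/arginine filter (H2, H5, LE1, LE2), Froger's positions P1–P5
and, for non-aqua substrates, nine specificity-determining positions
(SDPs). `mipannot` locates these in a query protein by pairwise global
alignment to a reference template whose diagnostic coordinates are
curated in a position table.

Three choices matter here:

* **Pairwise, not multiple, alignment.** Published family surveys
  typically read diagnostic residues off a multiple alignment against a
  structure-resolved reference. Per-query pairwise global alignment is
  simpler, fully deterministic, needs no external alignment tool, and is
  sufficient because every residue of interest is defined by a template
  coordinate: the query's residue is whatever aligns to that column.
  The cost is that information shared across queries (e.g. a
  family-wide insertion) is not exploited; for the divergence levels
  within an MIP family (pairwise identities rarely below ~20%) the
  diagnostic columns remain stable, and the planted-profile tests below
  quantify this.
* **Scoring.** BLOSUM62 with affine gaps, opening 10 and extension 0.5
  per gap position (a gap of length L costs 10 + 0.5 L). These are
  conventional protein-alignment defaults; all of `align_to_template()`,
  `identity_matrix()` and the annotation pipeline accept overrides.
  Alignment is delegated to `Biostrings::pairwiseAlignment()`, whose
  dynamic program resolves score ties deterministically, so repeated
  runs are byte-identical. The test suite cross-checks its scores
  against exhaustive enumeration of all alignments on short sequences.
* **Missing data.** A template position deleted in the query yields an
  explicit `NA` (never an empty string); an NPA motif is `NA` if any of
  its three columns is unmapped. Truncated proteins therefore produce
  partially observed profiles rather than errors — the packaged family
  contains exactly such a member (a 208-residue XIP retaining only the
  LB-side features), and the classifier and reporters tolerate it.

The packaged template is **synthetic**: a fixed 290-residue backbone
with canonical PIP-like residues planted at the coordinates of
`positions_synthetic.tsv`. It exists so the geometry of the pipeline is
testable without distributing third-party sequences; a real analysis
should substitute a curated template (e.g. a structure-resolved PIP)
and its position table, which are plain files with a two-column schema.
The published coordinates available for this family cover only the two
phosphosites and the Froger positions of the bacterial references, so
any shipped position table must be validated against known profile
tables rather than copied from a single source — the fixture-regression
tests play that role here.

## Subfamily classification: a rule cascade

Family surveys classify by phylogeny with reference proteomes. To make
classification reproducible without reference downloads, `mipannot`
instead uses an ordered residue-rule cascade derived from the union of
subfamily signatures observable in a diagnostic-profile table:

1. **PIP** iff the ar/R filter is exactly F-H-T-R (universal in PIPs and
   absent elsewhere);
2. **NIP** iff Froger P5 ∈ {I, L, M} (all other subfamilies carry
   aromatic W at P5);
3. **XIP** iff Froger P2 = C, or the LB motif starts with S, or the LB
   motif is NPV/NPI;
4. **TIP** iff P4 = Y and H2 ∈ {H, N};
5. **SIP** iff P4 = Y;
6. otherwise **UNCLASSIFIED** (including the all-missing profile — an
   outcome, not an error).

Order is part of the contract: PIP must precede TIP (both have
conserved P4/P5 pairs that would otherwise collide), and TIP must
precede the P4-based SIP catch-all, which is intentionally the weakest
rule. The cascade is configuration (`rules.yaml`), not code: each rule
is an OR over clauses, each clause an AND over profile fields with
allowed-value lists (a trailing `*` is a prefix wildcard). On the
packaged 37-protein castor bean table the cascade reproduces the
published labels 37/37 with counts 10/9/8/6/4.

Subgroups follow the same mechanism: XIP1/XIP2/XIP3 by exact ar/R match
(V-F-V-R, I-F-V-R, V-Y-A-R) with a *missing-tolerant* mode so that a
truncated profile whose observed residues are consistent with a filter
still places (first match in rule order wins — the documented
tie-break for profiles compatible with several filters); NIP I
(W-V-A-R / W-A-A-R), NIP III (G-S-G-R) and NIP II (NPS/NPV motifs or
H2 ∈ {A, T}). Numbered subgroups inside PIP and TIP (PIP1 vs PIP2,
TIP1–TIP5) are *not* decidable from diagnostic residues; they are
assigned only when a labelled reference set is supplied
(`assign_subgroup_by_reference()`), by nearest-neighbour identity vote
with a 55% identity floor below which the verdict is UNASSIGNED.

As classification support, `identity_matrix()` computes
global-alignment fractional identity (matches over alignment columns)
and `nj_tree()` builds a neighbor-joining tree from it (Saitou–Nei
Q-criterion via `ape::nj`). NJ here is a distance-based placement aid,
not a reproduction of any published maximum-likelihood topology —
bootstrap ML trees are out of scope. Negative NJ branch lengths, which
arise on non-additive inputs, are clamped to zero with the deficit
moved to the sister edge, preserving path lengths where possible; on
additive matrices the generating tree is recovered exactly, which the
tests verify against brute-force least-squares fits over all unrooted
topologies for 4 and 5 leaves.

## Substrate prediction

Three independent lines of evidence are reported side by side, never
merged into a single verdict, because they answer different questions:

* **NPA typing** labels each motif CANONICAL (`NPA`) or
  `VARIANT:<motif>`;
* **Froger classification** scores each of P1–P5 as GLP-like (aromatic
  P1, acidic P2, basic P3, proline P4, non-aromatic P5) or AqpZ-like,
  calling the protein WATER_TYPE (0 GLP-like positions), GLYCEROL_TYPE
  (5), MIXED (1–4) or INCOMPLETE. The chemical classes are parameters;
  the defaults take aromatic = {F, W, Y} (histidine excluded, since H
  at these positions does not behave as a pore aromatic), acidic =
  {D, E}, basic = {K, R, H};
* **SDP matching** compares nine observed residues against a
  substrate's allowed sets. The category logic: TYPICAL = no deviation
  and nothing missing; NOVEL_CANDIDATE = at most
  `max_novel_deviations` deviations (default 1, generalising the
  practice of flagging single substitutions as novel transporter
  variants); NO_MATCH = more; INCOMPLETE = no deviations but missing
  positions. Missing positions never count as deviations. Widening any
  allowed set can only improve a category (a monotonicity the tests
  assert).

The packaged rule table covers NH₃, boric acid, CO₂, H₂O₂, silicic acid
and urea. On the packaged per-substrate observation table the matcher
flags exactly the thirteen known deviating positions of the castor bean
family (one NH₃, six CO₂, three H₂O₂, two silicic acid, one urea) and
no others.

## Gene structure and protein properties

Gene spans are start-to-stop-codon (UTRs excluded), so total intron
length is `gene_len − cds_len` and the family-wide mean intron length
averages *per intron* (total intron length over total intron count);
per-gene averaging would weight short multi-intron genes differently
and is not what family surveys report. On the packaged table this mean
is ≈386 bp.

Molecular weight is the sum of average residue masses plus one water
(Expasy-style table, stored in the source). The isoelectric point is
the root of the net-charge equation — Henderson–Hasselbalch sums over
the termini and the D, E, C, Y, H, K, R side chains with EMBOSS-style
pKa values — found by bisection on pH 0–14 to 1e-4. Published tables
compute pI with a slightly different pKa set; recomputed values agree
with an independent implementation (`seqinr::computePI`) to a few
tenths of a pH unit, and summary statistics over packaged fixtures use
the fixtures' printed values verbatim rather than recomputation.
Presentation rounding is half away from zero at two decimals; all
internal arithmetic is full precision.

## Expression

Read cleaning follows the standard cascade, in order, each read counted
once: adaptor trimming (a read left empty is removed as adaptor-only),
removal when the N fraction strictly exceeds 10%, removal when strictly
more than 50% of bases have Phred quality ≤ 5. The inequalities are
strict, so a 100-bp read with exactly 10 N and exactly 50 low-quality
bases is kept. The Phred offset defaults to 33.

Expression is RPKM: `counts × 10⁹ / (lib_size × transcript_len)`. The
library size is taken as total clean reads per library (not total
mapped reads — the two differ when the library contains reads outside
the family; the choice is a parameter of `expression_set()`).
`expression_summary()` reports detected genes per tissue (RPKM strictly
above a threshold, default 0 — surveys rarely state their cut-off, so
the default treats any signal as detection and the threshold is
exposed), per-subfamily totals, each gene's share of its subfamily
total (computed on RPKM, matching how dominant-isoform percentages are
reported), and each gene's tissue of maximal expression. Heatmaps use
`log10(RPKM + 1)` with rows ordered by average-linkage hierarchical
clustering on Euclidean distance of the log values; published figures
rarely state a linkage, so the choice is documented here rather than
hidden.

## The synthetic-data generator

`gen_family()` builds sequences on the template backbone, plants the
subfamily signature at the diagnostic coordinates, and mutates every
other position independently with probability `mutation_rate` to a
uniformly drawn different residue. Diagnostic columns are never
mutated: the generator's contract is *known ground truth*, so tests can
demand 100% recovery rather than estimate error rates. What this does
not emulate: indels, membrane-protein compositional bias, correlated
divergence along a phylogeny, or diagnostic-site variation within a
subfamily. Passing the recovery suite therefore demonstrates that
template mapping and the cascade are correct mechanisms, not that real
families classify without error.

`gen_gene_models()` draws intron counts from an architecture mix
defaulting to the packaged family's spectrum (3/37 intronless up to
10/37 with four introns) and intron lengths from a shifted lognormal
(minimum 46 bp, a few hundred bp on average), matching the order of
magnitude seen in the packaged family. `gen_counts()` plants
dominant-isoform shares and tissue-specific zeros into expected counts
and draws negative-binomial counts around them (variance
`mu + noise·mu²`); `noise = 0` degenerates to rounded expectations so
planted structure is exactly recoverable. Each generator consumes its
own seeded RNG stream (`withr::with_seed`), so adding a generator never
perturbs existing output, and regeneration with the same seed is
byte-identical.

## Test problem sizes

The recovery suite runs 50 sequences (10 per subfamily) at mutation
rate 0.2 across three seeds; the NJ-versus-least-squares comparison
enumerates all unrooted topologies for 4 and 5 leaves over several
random additive matrices; alignment scores are checked against
exhaustive enumeration for sequences up to length 6. These sizes were
chosen to exercise every code path with exact oracles while keeping
the default test run fast; scaling `n_per_subfamily` or the leaf count
up is a one-line change for anyone wanting heavier evidence.

## Known limitations

* Classification rests on diagnostic residues only; a protein with an
  aberrant filter (or a profile reduced to fields no rule inspects)
  lands in UNCLASSIFIED rather than being forced into a subfamily.
* The shipped template is synthetic; accuracy on real proteomes depends
  on the curated template and position table supplied by the user.
* pI and Mw are sequence-only estimates (no post-translational
  modifications, no folded-state pKa shifts).
* NJ support is placement aid, not phylogenetics: no bootstrap, no
  model of sequence evolution.
* One fixture caveat: the packaged gene table records scaffold IDs
  verbatim from its source, whose prose summary of scaffold
  multiplicities does not obviously tally with the table; the fixture
  preserves the table and leaves the discrepancy documented rather
  than resolved.
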