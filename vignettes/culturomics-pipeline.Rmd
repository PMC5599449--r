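---
title: "Identifying cultivated bacteria from barcoded amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cultivated bacteria from barcoded amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturoscope)
```

## The problem

Cultivation experiments that plate a complex community (here: the dense
bacteriomes of high-microbial-abundance marine sponges) and read out growth by
16S rRNA gene amplicon sequencing face three entangled inference problems:

1. **Which colony is which?** When hundreds of picked colonies are sequenced
   in one run, each colony must be tagged by a unique *combination* of a
   forward and a reverse barcode, and reads must be demultiplexed twice.
2. **What actually grew?** Scraping all biomass off a plate recovers not only
   colonies but also residual inoculum cells that never divided. A taxon can
   therefore be "detected" on a plate without having grown — the central
   artefact this package's growth criteria exist to reject.
3. **Is it new?** Cultivated OTUs are scored for taxonomic novelty by their
   16S identity to the closest described type strain.

culturoscope implements this whole chain — simulation, double-barcode
demultiplexing, quality filtering, open-reference OTU clustering, colony
identification, growth calling, novelty classification, and the supporting
community statistics — as composable functions over tibbles, so that each
stage can be tested against ground truth.

## Sequence identity

Every threshold in the pipeline (97% clustering, the 95%/89% novelty bands,
the >97% isolate confirmation) is defined over one identity measure,
implemented in C++ (`global_align()`, `percent_identity()`):

* Needleman–Wunsch with affine gaps (match +5, mismatch −4, a gap of length
  $L$ costs $10 + L$), configurable via `align_scoring()`.
* Terminal gaps are free and excluded from the identity denominator;
  internal gap columns count as mismatches. For near-full-length amplicons
  this approximates the local (blastn-style) identities customarily quoted
  for 16S comparisons, while remaining a deterministic global computation —
  the field's reported "% identity" values rarely state their alignment
  parameters, so the scoring is deliberately exposed rather than hidden.
* Ties are broken deterministically (substitution ≻ gap in the second
  sequence ≻ gap in the first), so identical inputs always produce identical
  alignments, partitions and downstream calls.
* `N` never matches anything (conservative for uncalled bases); IUPAC
  ambiguity codes are honoured only in primer matching
  (`iupac_mismatches()`), where an `N` in the read satisfies no primer
  position.

All coordinates in the package are 0-based, half-open.

## Read retention rules

`quality_filter()` applies four rules in a fixed order, reporting the first
failure: mean Phred quality strictly greater than 25 (a mean of exactly 25.0
fails); no single-base run longer than 6 (a run of 7 fails, N runs
included); post-trim length at least 200 bp; zero mismatches against the 5'
primer. The mean quality is computed over the post-trim biological sequence;
whether the original assay computed it before or after trimming is not
documented, so the choice is fixed here and stated. Barcode matching is
exact — no error correction — because error-corrected demultiplexing was not
demonstrably part of the original analysis chain; both choices are
config-exposed.

## OTU picking and taxonomy

`pick_otus_open_reference()` runs the standard two-stage greedy scheme at a
97% identity threshold: reads matching a reference sequence join a
closed-reference OTU named after that reference (best hit, ties by
lexicographic id); the remainder are clustered de novo, in descending order
of duplicate count, then length, then first-read id — the conventional
abundance-sorted ordering for greedy centroid clustering, fixed here because
the upstream tools never documented theirs. Centroids are founding reads and
are not recomputed as members join. De novo lineages are transferred from
the best reference hit and truncated by identity bands
(`taxonomy_bands()`: ≥97 species, ≥95 genus, ≥90 family, ≥85 order,
≥80 class/phylum, else Unassigned), anchored to the field's 95%
genus-level and ~89% order-level novelty conventions.

A simplified single-crossover bimera screen (`flag_bimeras()`) ships
disabled: it flags an OTU only when a two-parent split beats the best single
parent by a margin with both segments near-identical to their parents. It is
a stand-in for profile-based chimera detectors, documented as such, and is
not part of the default pipeline.

## Colony identification

`assign_colonies()` applies a strict majority rule: a colony is assigned an
OTU only when that OTU accounts for more than half of the colony's reads; a
50/50 split stays unassigned. By default the denominator includes reads that
received no OTU label — the conservative reading of "reads obtained for that
colony" — with `count_unlabelled = FALSE` available because the original
wording does not settle the question. Isolate confirmation
(`confirm_isolates()`) requires strictly more than 97% identity between a
Sanger read and the representative of the target OTU, over their overlap.

## Growth criteria

For each scraped community paired with its inoculum, `call_growth()` flags
every detected OTU on three criteria: (I) strictly increased relative
abundance versus the inoculum (an OTU absent from the inoculum trivially
increased from zero — this is what lets a plate-dominating fast grower that
is undetectable in the source sample be called cultivated); (II) relative
abundance ≥ 0.2% (inclusive); (III) ≥ 20 visible colonies in the scraped
community (inclusive). `grew` is the conjunction. Criterion I is the
carry-over rejector: carried-over cells can clear the 0.2% floor when
carry-over is heavy, but they cannot *increase* relative to the inoculum
they came from. The acceptance suite verifies exactly this flip behaviour.

Novelty (`classify_novelty()`) uses the V1–V2 representative, not
full-length genes: an OTU is novel at ≤95% identity (inclusive — 95.0
counts) to the closest type strain and order-level novel below 89%
(exclusive). The inclusive 95 boundary is exposed as a parameter because
usage in the literature wobbles around it.

## Community statistics

* `shannon()`: $H' = -\sum p_i \ln p_i$, natural log by default (log2
  available for the older QIIME convention — the convention behind published
  values is often unstated).
* `rarefaction_curve()`: seeded subsampling without replacement; its mean is
  tested against the hypergeometric closed form
  $E[S_d] = \sum_i \left(1 - \binom{N - N_i}{d}\big/\binom{N}{d}\right)$
  (via `vegan::rarefy`) rather than against itself.
* `bray_curtis()` / `bray_curtis_matrix()`:
  $\sum_i |x_i - y_i| \,/\, \sum_i (x_i + y_i)$, with the matrix route
  delegated to `vegan::vegdist`.
* `hclust_upgma()`: average linkage via `stats::hclust`. UPGMA is chosen as
  the standard companion to Bray–Curtis profiles; the linkage behind the
  published dendrograms is not documented, so it is config-visible in the
  code rather than baked in.
* `simper()`: for every cross-group sample pair, the Bray–Curtis
  dissimilarity on square-root-transformed relative abundances decomposes
  additively over OTUs; the per-OTU mean over pairs is its contribution, and
  contributions sum to the average between-group dissimilarity to within
  1e-9 (a tested invariant). Hierarchical clustering runs on untransformed
  relative abundances while SIMPER square-root-transforms them — the
  asymmetry mirrors standard practice and is intentional. Permutation
  significance testing is deliberately omitted.

## The synthetic experiment

The generator modules exist so every downstream stage can be scored against
known truth without downloading anything:

* `generate_reference_db()` produces type strains as random sequences with
  45–55% GC and a designated 311 bp V1–V2 window, mutually <90% identical in
  the window so taxa cannot collapse into one 97% OTU. They are *not* real
  16S genes; `refdb_from_files()` accepts a real reference FASTA + taxonomy
  TSV for users who have one.
* `mutate_to_divergence()` plants substitution-only variants at a target
  divergence (verified to ±0.5 points by `percent_identity`), giving novelty
  classification known answers at e.g. 5, 11 and 18 points.
* `simulate_community()` draws log-normal abundances — the standard
  rank-abundance model for microbial communities.
* `simulate_plating()` composes the scraped community as
  `(1 − carryover) ×` growth-weighted colony mixture `+ carryover ×`
  inoculum, so a taxon with zero growth probability appears only through
  carry-over and is recorded as not-grown — the exact artefact the growth
  criteria must reject.
* `simulate_reads()` assembles `adaptor + barcode + primer + template`
  (+ reverse primer and barcode for colony reads), realizes degenerate
  primer positions, then applies per-base substitutions, homopolymer ±1
  run-length errors with probability proportional to run length (the
  characteristic pyrosequencing failure), and two-state good/bad qualities.
  No published error-rate estimates exist for the emulated runs; the
  defaults (`error_model()`: 0.4% substitutions, 0.2% per-run-length-unit
  homopolymer errors, 3% bad-quality bases) are order-of-magnitude
  pyrosequencing values and are assumptions, not claims.

`run_pipeline()` wires a scaled-down version of the full design — three
sponge inocula; scraped communities across media, agar/filter surfaces and
harvest days; double-barcoded picked colonies in plate groups — with one
designated fast-growing taxon absent from the inocula that overruns agar
plates (`dominance_factor`, default 25) but not filter membranes
(`dominance_filter`, default 1). The filter surface is what keeps slower
growers recoverable by criterion I in the demo scenario; on agar the
overgrowth artefact dominates, as it does in real plate-scraping data. The
default run sizes (300/150/16 reads for inoculum/scraped/colony samples, 10
reference types, 7 taxa per community, 2 planted novel members per sponge at
8 and 18 points divergence) are the package's choice of a desk-scale
experiment: large enough that every stage has signal, small enough to run in
about a minute.

## What passing tests do and do not show

The simulator reproduces the *statistical structure* the analysis assumes —
barcode bookkeeping, carry-over, overgrowth, substitution and homopolymer
noise — not real 16S sequence space: no chimeras by default, no conserved/
variable region structure, no primer-template mismatch biology, no
flowgram-level noise. Tests against ground truth therefore validate the
*decision logic* (demultiplexing, filtering boundaries, clustering rule,
majority rule, growth criteria, novelty thresholds, statistical identities),
not the field performance of any particular error model. Published headline
numbers from real runs (total read counts, OTU totals, per-sponge Shannon
indices) depend on the original raw data and a 454-era toolchain, and are
out of scope by design; the validation metrics (`validate_against_truth()`)
are computed on synthetic truth instead.

Degenerate inputs are handled explicitly: zero-read colonies are recorded
as unassigned rather than erroring; zero-count samples are dropped from
relative abundances with a warning; an all-zero abundance vector is an error
for `shannon()` and `bray_curtis()`; empty read sets yield empty OTU lists.

Reported Shannon values in the literature sometimes carry subsample-derived
standard deviations; the replication depth behind those is unstated, so
`rarefaction_curve()` exposes seeded subsampling with explicit `n_reps`
rather than pretending to match.

## Reproducibility

Every stochastic function takes a seed; `run_pipeline()` derives
per-stage streams from one master seed and echoes its effective
configuration (`config.yaml`) and an audit log of every threshold applied
(`run.log`) into the run directory. Two runs with the same configuration are
byte-identical — this is enforced by the test suite.
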