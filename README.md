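# culturoscope

Culturomics by double-barcoded 16S rRNA gene amplicon sequencing.

When a complex bacterial community — such as the dense bacteriome of a
high-microbial-abundance marine sponge — is plated on agar, two readouts are
possible: scrape all colony biomass off a plate and sequence it as one
community, or pick individual colonies tagged with a unique *pair* of
forward/reverse barcodes so that hundreds of colonies can be identified in a
single amplicon run. Both readouts are confounded in characteristic ways:
scraped biomass contains residual inoculum cells that never grew
("carry-over"), and fast-growing taxa (classically *Pseudovibrio*-like
alphaproteobacteria) overrun plates and mask everything else.

culturoscope is an R package implementing the full analysis chain for such
experiments, plus a seeded synthetic-data generator that emulates the whole
experiment so every stage can be scored against known ground truth:

* **Demultiplexing & filtering** — exact forward-barcode binning, a second
  reverse-barcode step for colony reads, and four retention rules applied in
  a fixed order: mean Phred > 25 (strict), no homopolymer run > 6, post-trim
  length ≥ 200 bp, zero 5'-primer mismatches (IUPAC-aware).
* **Open-reference OTU picking** at 97% identity: closed-reference
  assignment to the best reference, then greedy abundance-sorted de novo
  clustering with centroid representatives; taxonomy transfer truncated by
  identity bands; optional simplified bimera screen (off by default).
* **Colony identification** — an OTU is assigned to a colony only if it
  accounts for >50% of that colony's reads; isolates are confirmed when a
  Sanger read is >97% identical to the OTU representative.
* **Growth calling** — an OTU in a scraped community is called *grown* only
  if (I) its relative abundance increased versus the inoculum, (II) it
  reached ≥ 0.2% relative abundance, and (III) the community comprised ≥ 20
  visible colonies. Criterion I is what rejects carried-over cells.
* **Novelty classification** — ≤ 95% identity (inclusive) to the closest
  type strain marks a novel OTU; < 89% marks potential order-level novelty.
* **Community statistics** — Shannon diversity
  (H' = −Σ pᵢ ln pᵢ), seeded rarefaction, Bray–Curtis dissimilarity
  (Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)), UPGMA clustering with Newick export, and SIMPER:
  per-OTU contributions δᵢ to between-group dissimilarity on square-rooted
  relative abundances, with Σδᵢ equal to the mean cross-pair Bray–Curtis
  dissimilarity by construction.

The alignment core (Needleman–Wunsch, affine gaps, free end gaps excluded
from the identity denominator) is implemented in C++ and drives every
identity threshold in the package. All user-facing functions take and return
tibbles, so stages compose with the pipe; SIMPER results support
`tidy()`/`glance()`/`autoplot()`.

## A worked example

Simulate the full experiment — three sponge inocula, plate-scraped
communities on two media × agar/filter, double-barcoded picked colonies,
error-bearing 454-style reads — and analyse it end to end:

```r
library(culturoscope)

config <- run_config(seed = 1L, out_dir = "demo_run")
res <- run_pipeline(config)
print(res)
#> <cs_run> demo_run
#> 51 samples, 16 OTUs, 36/36 colonies assigned, 23 growth calls

validate_against_truth("demo_run")
#> # A tibble: 4 × 3
#>   metric             value     n
#>   <chr>              <dbl> <int>
#> 1 colony_id_accuracy 1        36
#> 2 growth_precision   1        13
#> 3 growth_recall      0.619    21
#> 4 novelty_accuracy   1        16
```

Reading those numbers: all 36 picked colonies were identified, and every
identification matches the colony's true taxon. All 13 taxa called *grown*
really grew (precision 1). Recall is 0.62 because several taxa that truly
grew *decreased* in relative abundance under overgrowth by the dominant
fast grower — the growth criteria are deliberately conservative, and this
is the expected cost of rejecting carry-over. Novelty calls are correct for
all 16 OTUs.

The run directory contains every intermediate as plain text (`otu_table.tsv`,
`colony_assignments.tsv`, `growth_calls.tsv`, `novelty.tsv`, `venn.tsv`,
`simper.tsv`, `dendrogram.nwk`, `rarefaction.tsv`, ...), a consolidated
`report.md`, the echoed `config.yaml`, and a `run.log` recording every
threshold applied. The novel-OTU report looks like a type-strain novelty
table:

```r
res$table1
#> # A tibble: 5 × 7
#>   otu_id  closest_type_strain identity n_samples max_rel_abundance sponges media
#> 1 denovo3 TS0004                  82.0         1            0.121  AA      MA
#> 2 denovo1 TS0001                  82.1         2            0.315  CC      MA,MH
#> 3 denovo2 TS0003                  92.0         1            0.318  AA      MA
#> 4 denovo4 TS0006                  92.0         2            0.0787 CC      MA,MH
#> 5 denovo5 TS0009                  92.0         2            0.0458 PF      MA,MH
```

Here the two OTUs at ~82% identity are the planted deeply novel members
(18 points divergence, below the 89% order-level line); the ~92% OTUs are
the planted 8-point-divergence members.

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/culturoscope run --seed 1 --out demo_run
Rscript inst/exec/culturoscope validate --dir demo_run
```

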