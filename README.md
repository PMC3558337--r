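# mitocomp

Comparative characterization of chromadorean nematode mitochondrial
genomes in R.

Chromadorean mitogenomes are compact circular chromosomes (~14–22 kb)
carrying 36 genes — 12 protein-coding genes (no *atp8*), 22 tRNAs and 2
rRNAs — all transcribed from one strand, under the invertebrate
mitochondrial genetic code (NCBI table 5). Characterizing a newly
sequenced genome of this kind involves a recurring set of computations
that this package implements as a tested pipeline:

* **Circular-coordinate bookkeeping** — 1-based inclusive spans that may
  wrap the origin; censuses of intergenic gaps and gene overlaps around
  the circle; the reconciliation identity
  `Σ(gene spans) + Σ(gaps) − Σ(overlaps) = genome length`.
* **Protein-coding gene verification** — start codons read from the
  annotated span; termination classified from span length mod 3, with the
  incomplete stops `T` and `TA` (completed to `TAA` by polyadenylation)
  accepted at feature ends; internal stops flagged. Stop codons are
  excluded from all coding-length and codon-usage accounting, so
  `codon total × 3 = coding length`.
* **Composition and codon usage** — partitioned base composition (whole
  genome, coding sequence by codon position, rRNA, tRNA, non-coding
  region) and 64-codon usage tables, with round-half-up reporting at the
  conventional precisions.
* **tRNA folding** — exhaustive placement search under the nematode
  structural model: a 7-bp acceptor stem, 4-bp DHU arm, 5-bp anticodon
  stem with 7-nt loop, and a TV-replacement loop in place of the TΨC arm;
  the two serine isoacceptors instead lack the DHU arm and carry a TΨC
  stem-loop. Watson–Crick plus G·U pairing, one mismatch allowed per stem.
* **Tandem-repeat discovery** in AT-rich control regions by
  period-by-period self-comparison with consensus-based mismatch counting.
* **Gene-order comparison** — directed adjacency sets of circular orders,
  shared two-gene blocks, breakpoint distances
  (`36 − |shared adjacencies|`), translocation reports, and
  neighbor-joining trees on breakpoint matrices.
* **Phylogenetic matrix preparation** — translation, deterministic protein
  alignment, back-translation to codon alignments, partitioned
  concatenation, third-codon-position exclusion, and PHYLIP/NEXUS/RAxML
  partition output.
* **A synthetic-mitogenome generator** whose specs fix gene layout, codon
  distribution, per-class base composition, planted tandem repeats and the
  tRNA model, so every stage is testable against known truth. The two
  template layouts packaged under `inst/extdata/` transcribe the published
  organization tables of *Bursaphelenchus xylophilus* (14,778 bp) and
  *Pratylenchus vulnus* (21,656 bp).

## Worked example

```r
library(mitocomp)

sim <- generate_genome(bx_genome_spec(), seed = 1)   # 14.8-kb template genome
pr  <- partition_report(sim$features, sim$genome)
glance(pr)
#> # A tibble: 1 × 7
#>   genome_id             genome_length n_gaps n_overlaps overlap_bp residual reconciled
#>   <chr>                         <int>  <int>      <int>      <int>    <int> <lgl>
#> 1 Bxylophilus_synthetic         14778      9          4          9        0 TRUE
```

Nine intergenic intervals and four gene overlaps (9 bp in total) account
for the genome length exactly. The coding partition and codon usage
cross-check:

```r
pr$length[pr$partition == "pcg_coding"]
#> [1] 10182
cu <- codon_usage(sim$features, sim$genome)
attr(cu, "total_codons")
#> [1] 3394
```

10,182 coding bases are 3,394 codons: the 12 genes minus 32 bp of
termination codons (nine `TAA`, one `TAG`, two incomplete `T`). The tRNA
complement folds under the nematode model:

```r
tv <- validate_trnas(sim$features, sim$genome)
table(tv$variant); range(tv$length)
#> TPsiC    TV
#>     2    20
#> [1] 53 60
```

and the control region carries its three planted repeat families:

```r
nc <- ncr_report(sim$features, sim$genome, min_unit = 40,
                 min_copies = 3, max_mismatch_per_copy = 1)
nc$repeats[[which(nc$left_gene == "nad4")]][, 1:5]
#> # A tibble: 3 × 5
#>   start unit_length copies consensus    total_mismatches
#> 1     1         147      4 TATATTTAA...                0
#> 2   589         101      4 ATTTTTAAA...                0
#> 3   993          56      3 AGATATAGT...                1
```

Gene-order comparison against the second template:

```r
bx <- gene_order(read_feature_tsv(system.file("extdata", "bxylophilus_table1.tsv", package = "mitocomp")), "Bx")
pv <- gene_order(read_feature_tsv(system.file("extdata", "pvulnus_table1.tsv", package = "mitocomp")), "Pv")
breakpoint_distance(bx, pv)
#> [1] 31
shared_adjacencies(bx, pv)
#> # A tibble: 5 × 2  (rrnL→nad3, nad6→nad4L, nad2→trnI, cox3→trnN, trnA→trnP)
```

Only five directed adjacencies survive between the two genomes — the
four published two-gene blocks plus `trnA→trnP`.

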