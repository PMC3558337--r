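---
title: "Methods: comparative mitogenome characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

This vignette is the package's own account of the models and conventions
it implements: what is computed, under which assumptions, and where the
design was genuinely open.

## The genome model and its conventions

Everything runs on 1-based inclusive coordinates over a circular
chromosome, the convention of published mitogenome organization tables.
A span with `end < start` wraps the origin and has length
`(L - start + 1) + end`. The tab-separated feature dialect preserves
wrapping spans; the GFF3 dialect cannot (the standard has no wrap
representation) and refuses them.

Three accounting conventions matter, and each is forced by the
requirement that the per-class totals, interval counts and grand totals
of a 36-gene table reconcile *exactly* with the genome length:

* **Non-coding-region features are kept in tables but excluded from the
  gene ring.** Censuses, gene orders and the reconciliation identity run
  over the 36 genes only; an explicit NCR's span then appears as part of
  the flanking intergenic interval. This is the only reading under which
  a 14,778-bp genome shows 9 intergenic intervals (the largest being the
  1,650-bp control region) and a 21,656-bp genome shows 24 intervals
  totalling 8,821 bp, including an 11-bp interval at the circular
  junction after the last tRNA.
* **Termination codons are excluded from coding lengths and codon
  counts** — 3 bp for a complete stop, 1 or 2 bp for the incomplete
  `T`/`TA` forms. Under this convention (and no other) the coding totals
  10,182 bp and 10,002 bp of the two template genomes equal 3 × their
  codon totals (3,394 and 3,334), and differ from the raw span sums by
  exactly the per-gene stop lengths (32 and 36 bp). `codon_usage()` has
  an `include_stops` switch for other conventions.
* **Overlapping bases count once per feature** in per-class compositions
  (each gene contributes its full span); the genome-length reconciliation
  lives in `partition_report()`, which treats overlaps as negative
  spacing instead.

Reconciliation failure is never silent: `glance()` on a partition report
carries the residual, and a warning fires.

`N` residues are tolerated (draft assemblies): they pair with nothing in
tRNA folding, and composition percentages are computed over non-N
residues only. All fixtures are single-strand, but strand is carried
everywhere and minus-strand features are reverse-complemented before
translation or folding.

## Protein-coding gene verification

The start codon is simply the first triplet of the annotated span. The
stop is classified from span length mod 3: remainder 0 demands a complete
stop codon in the final triplet; remainders 1 and 2 demand the trailing
`T` or `TA` of an incomplete, polyadenylation-completed stop. Incomplete
stops are accepted only at the span end — completion by polyadenylation
is positional. Any internal stop is reported as a violation; the
annotation history of real genomes sometimes involves curated exceptions,
but this package takes the strict view and leaves overrides to the
caller.

The ORF scanner uses the start-codon set `{ATT, ATA, ATG, TTG, TTA, GTG}`
by default: the union of codons observed or canonical across nematode
mitogenomes. ATG is canonical, ATT/ATA/TTG dominate in these genomes, TTA
occurs in some taxa, and GTG is included for generality; the set is a
single overridable argument. A scanned frame that runs off the sequence
end is only reported when it ends in a permitted incomplete stop. Note
that in AT-rich sequence the first in-frame start codon upstream of a
gene's true start is usually not the annotated one, so scanning recovers
each annotated gene's frame and terminator exactly but may extend its 5'
end; the tests assert containment plus exact (end, frame) for that
reason.

One deliberate non-feature: a genetic-code idiosyncrasy reported in a
related burrowing nematode, where `TAA` is reassigned to tyrosine, is not
modelled. The code table is strictly NCBI-table-driven
(`Biostrings::getGeneticCode`), and a custom map can express such a
variant if ever needed.

## The tRNA structural model

The folding model is the nematode-specific architecture: acceptor stem of
7 pairs, DHU stem of 4 pairs with loop, anticodon stem of 5 pairs with
loop, and a TV-replacement loop in place of the TΨC arm and variable
loop; the two serine isoacceptors lack the DHU arm (an unpaired
replacement loop) and carry a TΨC stem-loop of 3–5 pairs with a 3–8-nt
loop. Conventions the structural description leaves open, all overridable
in `trna_model()`:

* anticodon loop fixed at 7 nt with the anticodon central (canonical);
* DHU loop 4–9 nt, TV loop 4–12 nt, serine DHU-replacement loop 2–12 nt —
  ranges wide enough to tile every observed gene length (52–60 nt) while
  keeping the placement search small;
* no spacer nucleotides between arms (the simplest layout consistent with
  the stem sizes); generator and folder share the same layout, so the
  choice is internally consistent.

Pairing is Watson–Crick plus G·U at full weight, with at most one
mismatch per stem by default — mitochondrial stems are degenerate and
published structures were accepted by eye. Scoring is paired-base count
minus mismatches; with sequences ≤ 75 nt the full placement enumeration
is trivial and no thermodynamic model is warranted. Ties break
deterministically (score, mismatches, TV before serine, smaller
replacement loop, leftmost DHU loop).

Because a random sequence occasionally admits an alternative placement
scoring at least as high as the planted one, `generate_trna()` verifies
each draw by folding it and redraws until the planted variant and
anticodon are recovered as the unique best structure (bounded retries).
The generator/folder round trip is therefore exact by construction — a
property of the generator, deliberately, not of arbitrary sequences.

Isoacceptor labels follow the anticodon convention: leucine `CUN` → L1
and `UUR` → L2, serine `AGN` → S1 and `UCN` → S2; anticodons decode via
the reverse complement under the active genetic code.

## Composition and codon usage

Percentages are rounded half away from zero — 1 decimal for composition,
2 for codon usage — matching the conventions of published tables (base R
`round()` is half-even and reproduces neither). The A+T percentage is
rounded from the unrounded sum of A and T. The packaged codon-usage
transcription reproduces all 128 of its printed percentages from its
printed counts under exactly this rule.

`top_codons()` reports the summed *unrounded* frequency of the k most
frequent codons at 1 decimal. Summing the rounded per-codon percentages
can differ in the second decimal, which is worth knowing when comparing
against numbers quoted in text.

## Tandem-repeat discovery

For each candidate period the sequence is compared against itself at that
lag (vectorized); anchor positions where adjacent windows agree within
twice the per-copy budget are extended window by window against a running
consensus (majority vote, ties keeping the incumbent base — so a deviant
*first* copy is correctly attributed once later copies outvote it).
Within one period of the first anchor, all candidate phases are evaluated
and the extension with most copies, then fewest mismatches, then leftmost
start wins; contained reports of the same or a harmonically related
period are suppressed in favour of the maximal one. The scan is
O(L × P) — entirely adequate below ~25 kb, which is why no suffix
structure is used.

Two inherent ambiguities are documented rather than hidden: when flanking
background happens to continue the periodicity, the array's phase (start
position) is ambiguous by up to one unit; and a substitution at the very
edge of an array is indistinguishable from a one-base shift of a perfect
array. Planted-truth tests therefore pin unit length, copy number and
mismatch count exactly, and the start only to within one unit.

The generator places repeat families contiguously at the 5' end of their
non-coding region, with planned mismatches injected into the first copy —
an assumption, since interleaving is not observable from summary
statistics.

## Gene-order comparison

Adjacencies are directed ordered pairs, because in these genomes all 36
genes are co-oriented and orientation carries no extra signal; a circular
order of n genes has exactly n adjacencies, and the breakpoint distance
is `n − |shared|`. NCRs are excluded from orders. Anchoring (rotating
`cox1` to the front) only normalizes display — every comparison is
rotation-invariant. Orders for further taxa are user-supplied files;
nothing beyond the two packaged layouts is bundled.

The neighbor-joining step is deliberately bought, not built: `ape::nj`
is the field-standard implementation, wrapped to clamp negative branch
lengths at zero and write Newick. Tests verify the closed-form 3-taxon
solution and exact recovery of additive 5-taxon matrices.

The single-gene translocation driver resamples any move that would
reinsert a gene between its original circular neighbours (such a "move"
is a rotation, not a rearrangement), so one move always destroys exactly
three adjacencies.

## Alignment preparation

The built-in aligner is a deterministic Needleman–Wunsch with affine gaps
(a gap of length k costs `open + k·extend`; defaults match 2, mismatch
−1, open −4, extend −1), extended to multiple sequences by center-star
progressive merging under "once a gap, always a gap". It exists so that
back-translation — the implementable core of codon-alignment preparation —
is testable without an external aligner; externally produced FASTA
alignments import via `read_alignment_fasta()` and flow through
identically. No attempt is made to reproduce any specific external
aligner's output bit-for-bit; pairwise scores are instead verified
against an exhaustive enumeration oracle on short inputs.

Back-translation maps each residue column to its source codon and each
gap to `---`, after verifying that every degapped row equals the
translation of its stop-stripped CDS; incomplete stops contribute no
residue. Concatenation orders genes alphabetically (`atp6, cob, cox1…`);
since a partition table accompanies every supermatrix, the order is
immaterial downstream, and `nad4L` sorting between `nad4` and `nad5` is
accepted as the plain string order. Third-position exclusion keeps
positions 1–2 of every codon per partition and commutes with
concatenation (tested).

## The synthetic-data generator

A `genome_spec()` fixes: the layout (the packaged organization-table
transcriptions, or arbitrary tables); a 64-codon distribution with zero
stop entries (template specs use the published codon counts, so the
generated coding sequence recovers the published usage within multinomial
sampling error); per-class base frequencies (template values target the
published partition compositions; background between genes uses the
control-region frequencies); repeat plans; and the tRNA model. Generation
is deterministic given (spec, seed), confines all randomness to one
seeded stream, and restores the caller's RNG state.

Overlaps are realised by constrained sequence sharing. All planned codon
bases (PCG starts and stops) are written first; each feature is then
generated conditional on any bases already fixed in its span — codon
draws are restricted to codons matching the shared bases, tRNA stem
partners of fixed bases are complemented — and plans whose shared bases
cannot satisfy both neighbours fail loudly rather than silently mutate.
The two-base and five-base overlaps of the 14.8-kb template (a stop
shared with a downstream tRNA, and a stop overlapping a downstream start)
are the motivating cases and are covered by tests.

What the generator does *not* emulate: real rRNA secondary structure,
site-to-site rate variation, phylogenetic covariation between the two
genomes, or the true per-base sequence of the deposited accessions (only
their printed marginal statistics). Passing tests therefore demonstrate
correctness of the *accounting and inference machinery* on data with the
documented statistical structure — not that any biological conclusion
about real sequences is reproduced beyond the published summary numbers.

## Problem sizes and numerical choices

The test suite generates both full-size template genomes once (14,778 and
21,656 bp) and several hundred compact synthetic genomes (~1–2 kb; 3
PCGs, 4 tRNAs, one rRNA, optionally an NCR with a planted array) for
property-style checks — small enough to iterate quickly, structurally
complete enough to exercise every code path. Composition assertions on
generated genomes use 3-sigma sampling bands (≈1% A+T at 14.8 kb);
codon-count recovery uses Bonferroni-corrected 99% binomial bands across
the 64 codons. Alignment oracle checks run at ≤ 8 residues, where
exhaustive enumeration is feasible. All stochastic tests fix their seeds.

## Known limitations

* Homology-based gene identification is out of scope: PCG and rRNA spans
  come from the feature table, as in curation practice.
* The ORF scanner reports maximal frames, not curated gene boundaries.
* Dispersed (non-tandem) repeats are not discovered.
* Breakpoint distance is the only rearrangement metric; no
  inversion/DCJ distances or ancestral reconstruction.
* Tree inference beyond neighbor joining on breakpoint matrices —
  likelihood or Bayesian analysis of the prepared supermatrices — is the
  job of external engines; this package prepares their inputs
  (PHYLIP/NEXUS/partition files) and stops there.
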