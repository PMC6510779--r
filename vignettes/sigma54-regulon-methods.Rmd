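---
title: "Predicting and perturbing sigma-54 regulons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and perturbing sigma-54 regulons: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigma54scope)
```

σ⁵⁴ is the one bacterial sigma factor outside the σ⁷⁰ family. Its
holoenzyme binds a bipartite −12/−24 promoter element and, unlike σ⁷⁰
holoenzymes, cannot open the promoter without an enhancer binding protein
(EBP) — an AAA+ ATPase acting from upstream. In solventogenic *Clostridium*
this regulator sits over carbon metabolism: alcohol dehydrogenases, PTS
sugar transporters and polyol utilisation operons carry σ⁵⁴ sites, and a
single missense change in the DNA-recognition helix of the factor is enough
to collapse solvent production. `sigma54scope` implements the computational
layer of such a study — regulon prediction, cross-strain comparison, variant
annotation, knockout design arithmetic and RT-qPCR quantification — with a
seeded synthetic-genome generator in place of real assemblies, so every
stage can be verified against known truth.

## Coordinate model

All interval arithmetic inside the package is 0-based half-open; every file
boundary (FASTA/GFF3/GenBank/VCF and all TSV reports) is 1-based inclusive,
which matches how mutation tables print CDS positions. The conversion
happens exactly once, in the readers and writers. Codon arithmetic follows
`codon = ⌊(p − 1)/3⌋ + 1`, `offset = (p − 1) mod 3 + 1` for a 1-based CDS
nucleotide position `p`; a CDS position of 1,097 therefore lies at the
second position of codon 366, which is how a C→T there becomes an S→F
substitution in the report. Translation uses NCBI table 11 via the
Biostrings genetic-code tables, with no special treatment of initiator
codons (effect classification does not need it) and stop codons rendered as
the sentinel `X`, so nonsense changes print as `Q -> X`.

## Consensus scanning

The scanner performs exact degenerate matching of an IUPAC consensus
(default `TGGCANNNNNNTTGCW`, 16 positions, N = any base, W = A/T) on both
strands, reporting minus-strand hits in forward coordinates with the matched
sequence in coding-strand orientation. Matching is delegated to
`Biostrings::matchPattern(fixed = "subject")`; because that mode lets a
literal `N` in the genome match the pattern's `N`, hits whose window
contains any ambiguity code are discarded — an `N` in the assembly can never
produce a site. Overlapping occurrences are all reported; the count
convention (both strands, overlaps included) is stated in the output so
users can also derive the strand-collapsed count.

Under an i.i.d. equal-frequency background, one window on one strand matches
with probability Π |allowed|/4 = (1/4)⁹ × (1/2) = 1/524288, giving the
closed-form expectation `2 Σ_contigs (L − 15) / 524288` — about 3.8 sites
per Mb. `scan_statistics()` reports this analytic expectation and the
observed/expected enrichment; the test suite checks seeded Monte-Carlo
genomes against it within three standard errors. Genomes at clostridial GC
(≈30%) have a different per-window probability; the closed form deliberately
models only the uniform background and is reported as such.

## Regulon assignment

σ⁵⁴ promoters are directional and the consensus is non-palindromic, so
assignment is strand-matched: a site is linked to the nearest downstream CDS
start *on its own strand*. Distance is measured from the motif's 3′
(promoter-proximal) edge to the start codon and the window is inclusive,
`0 ≤ d ≤ 500` bp — "up to 500 bp upstream" is taken literally at both ends.
Nearest start wins; other same-strand starts inside the window are kept as
alternatives; assignment never crosses a contig. A motif overlapping an
upstream gene's CDS is allowed but flagged, since real intergenic regions
are often shorter than the window.

Transcriptional units are built by downstream operon extension: the maximal
run of co-directional, consecutive CDS with intergenic gaps ≤ 50 bp (a
common prokaryotic heuristic; configurable). A gene on the opposite strand
interrupts the run regardless of gap. EBP vicinity is a keyword search
("sigma-54 dependent", "enhancer", "PAS", "AAA", case-insensitive) over
product annotations within 3 kb of the unit's extent — the same span the
synthetic generator uses when placing EBP genes, so flags are comparable to
truth. Real EBPs can act from further away; the span is a reporting choice,
not a biological limit.

## Cross-strain conservation

The original comparison of predicted regulons across strains used a web
synteny platform whose criteria are unpublished; the package substitutes a
transparent reciprocal-best-hit (RBH) map: all-vs-all Smith–Waterman local
alignment of translated CDS (BLOSUM62, gap open 11 / extend 1, minimum
score 50 — BLAST-like defaults), mutual best pairs, ties broken by longer
alignment then lexicographic id. A regulon unit is then
*conserved-with-motif* if any member gene's ortholog belongs to a
motif-assigned unit in the target genome, *conserved-gene-only* if an
ortholog exists without a motif, and *absent* otherwise (the pattern of a
strain-specific gene such as a secondary-alcohol dehydrogenase present in
only one strain). Units are matched through any member gene because operon
composition may differ between strains. An externally supplied ortholog TSV
can replace the built-in aligner when replaying real genomes.

## Variant effects

Only single-nucleotide substitutions are supported (indels are rejected with
a clear message); the reference base is verified against the genome and a
mismatch is a hard error carrying the observed base, because it almost
always signals a wrong assembly or coordinate convention. For minus-strand
genes the ref/alt bases are complemented before the codon edit. The effect
classes follow the mutation-report conventions: `None` for synonymous
changes, `Truncation` when the alternate codon is a stop and the reference
is not, `Substitution` otherwise (stop-loss, which has no precedent in such
reports, is classified as Substitution with a `stop_loss` flag), and
`Intergenic` when no CDS contains the position. Variants inside overlapping
CDS produce one row per feature. Positions whose reference codon carries an
ambiguity code return an explicit `Ambiguous` class rather than guessing.

## Editing design

Band-size prediction is pure arithmetic, so primer binding is exact-match
(no melting-temperature model): the forward primer must occur exactly once,
the reverse complement of the reverse primer exactly once downstream, and
the amplicon runs 5′ end to 5′ end inclusive. A deletion shifts downstream
features left by its length, truncates overlapping features (flagged) and
drops swallowed ones. Protospacer enumeration assumes SpCas9: 20-mers with
an NGG PAM immediately 3′ on either strand, with the blunt cut modelled 3 bp
5′ of the PAM (between protospacer positions 17 and 18); a protospacer is
reported when its position-17 base lies inside the target interval.
`residual_orf()` splices the deletion out of the CDS, translates from the
original start and counts residues before the first stop — frameshifting
deletions produce early stops naturally, and the count excludes the stop, so
a knockout truncating at codon 14 reports 13 residues.
`deletion_locus_fixture()` builds a locus dimensioned like a typical sigL
knockout (464-codon CDS, 1406 bp wild-type amplicon, 736 bp deletion, stop
at codon 14) for tests and demonstrations.

## RT-qPCR quantification

Relative expression uses the efficiency-corrected (Pfaffl) form with
per-target fold-per-cycle efficiencies `E = 10^(−1/slope)` from
standard-curve slopes:

ratio = E_t^(C̄q_t,cal − C̄q_t,s) / E_ref^(C̄q_ref,cal − C̄q_ref,s)

with replicate-mean Cq, a housekeeping reference target and a calibrator
sample whose own ratio is 1 by construction. When every efficiency is
exactly 2 this reduces to the classical `2^(−ΔΔCq)`, which the tests verify
against an independent oracle to 1e−12. Efficiencies are expected in
[1, 2]; values in the 50–110 range are treated as percentages and converted
with a warning, and values outside [1.5, 2.1] are flagged. Replicates are
aggregated by arithmetic mean of Cq, and the replicate range is propagated
as a ratio interval.

The Cq generator inverts this model: per-target baseline cycles and
per-sample loading factors are drawn, template amounts follow the prescribed
ratios, and Gaussian noise (default σ = 0.15 cycles) is added per replicate.
A noiseless table therefore inverts exactly. With noise the recovered
log-ratio is Gaussian with standard deviation
`σ · sqrt(2/replicates) · sqrt(ln²E_t + ln²E_ref)` — about 0.14 (14%) for
duplicates at σ = 0.15 and E ≈ 1.9–2.0. Recovery checks should therefore be
read against this error model: the unit tests assert a 4-sigma envelope,
and any fixed relative-error threshold near 15% sits at roughly one sigma
under these conditions and will fail for a substantial fraction of random
draws.

## The synthetic generator

`generate_genome()` packs the genome structurally rather than by rejection:
each regulon unit is one block carrying its consensus instance (degenerate
positions randomised) immediately upstream of its first transcribed gene at
a distance drawn uniformly from [0, 500]; intra-unit gaps are ≤ 50 bp so
operon extension reconstructs the unit; EBP genes attach to their unit at
100–800 bp (beyond the operon gap, inside the vicinity span); and
inter-block gaps exceed the window, so no site can be claimed by a
neighbouring block. Gene sequences are ATG + random sense codons + TAA,
guaranteeing translatability and synonymous/nonsense edit sites for the
variant generator. With `background_motif_free = TRUE` (default) the whole
genome — including derived genomes of a conservation family — is
regenerated until the scanner finds exactly the planted sites (retry cap
1000; at the default 50 kb the spontaneous rate is ≈0.2 per genome, so one
or two attempts suffice). Defaults are one 50 kb contig, 30 genes of
300–1200 bp, five regulon units, two EBPs, uniform base composition with a
low-GC (≈30%, *Clostridium*-like) option.

What the generator does *not* emulate: real intergenic composition bias,
overlapping genes, pseudogenes, mobile elements, sequencing errors, or
motif-like decoys at near-consensus distance. Passing the recovery tests
therefore demonstrates correctness of the arithmetic and bookkeeping, not
sensitivity/specificity on real chromosomes — on a real multi-Mb genome the
same scan will, by the closed form above, also return background-level hits
that no truth table adjudicates.

## Problem sizes and determinism

The shipped tests run the scanner–oracle comparison on 500 random sequences
(0.5–2 kb), Monte-Carlo scans of 100 × 50 kb i.i.d. genomes, regulon
recovery on ten 120 kb genomes with 20 planted units each, ten 3-genome
conservation families, and a 1,020-variant round trip — sizes chosen so the
whole suite completes in a few minutes on a laptop while still exercising
every code path at meaningful multiplicity. All generators consume a single
integer seed and are fully deterministic given (configuration, seed);
truth tables carry everything downstream checks need, so no hidden state
crosses a module boundary.

## Known limitations

- The consensus model is exact-match; no position-weight-matrix scoring,
  mismatch tolerance or spacer-length variation, so diverged σ⁵⁴ sites are
  invisible by design.
- RBH orthology is a deliberate simplification of synteny-based comparison
  and can mispair recent paralogs; the external-table override exists for
  exactly that case.
- The in-silico PCR model has no primer thermodynamics and will refuse
  (rather than resolve) multi-site binding.
- GenBank support covers the flat-file subset bacterial annotations use
  (gene/CDS, `locus_tag`, `complement()` spans); joined locations are
  rejected.
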