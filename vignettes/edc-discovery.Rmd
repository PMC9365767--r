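---
title: "Rule-based discovery of epidermal differentiation complex genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based discovery of epidermal differentiation complex genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcscan)
```

## The problem

The epidermal differentiation complex (EDC) is the gene cluster, bordered
by *S100A11* and *S100A16*, that supplies the structural proteins of the
cornified skin barrier. Its two hallmark gene families resist ordinary
annotation. SFTP genes (S100 fused-type proteins) pair a conserved,
alignable S100 domain with a long tail of extremely low sequence
complexity; SEDC genes (single-coding-exon EDC genes) consist of one
non-coding exon and one coding exon whose product is short, repetitive,
and compositionally biased toward the residues of cornification —
glutamine and lysine (transglutamination substrates), proline, glycine,
serine, cysteine. Homology search finds the S100 domains but not the
tails; ab initio predictors are misled by the low complexity and the
single-coding-exon structure. EDC annotation therefore uses a dedicated
rule-based procedure, which this package implements end to end, together
with a simulator that generates loci with known truth so every rule is
testable.

## The discovery procedure

All coordinates in the package are 1-based closed intervals, the
convention of IRanges/GRanges and of GFF3 itself; strand is explicit
everywhere, and minus-strand logic is implemented by mirroring into
coding orientation, applying the plus-strand rule, and mirroring back.

**Anchors.** The two anchor S100-domain peptides are searched against the
genome in all six reading frames: each frame translation (stops rendered
`*`, N-containing codons `X`) is aligned to the query by Smith–Waterman
with BLOSUM62 and affine gaps (open 11, extend 1 — the classic
protein-search defaults), iterating with masking so multiple domain copies
are all found. Low-complexity masking is never applied, since the very
proteins of interest are low-complexity. An anchor that is absent or has
two equally scoring best hits is an error, not a guess. The reported locus
is the interval strictly between the two anchor coding sequences.

**SFTP versus S100A.** Hits on a consistent strand within
`group_max_gap` (default 1000 nt) form one candidate gene, so a domain
split across two coding exons is one gene while neighboring paralogs
(typically ≥ 1.5 kb apart) are not merged. From the 3' end of the domain
region the reading frame is extended to the first stop codon; if the stop
falls within 50 nt, a spliced extension across one canonical intron is
attempted: every `GT` between the domain and the stop is considered as a
donor, every downstream `AG` within the intron-length bounds (20–2000 nt)
as an acceptor, and the donor–acceptor pair maximizing the in-frame
extension wins. The classification rule is: **SFTP** if the coding
sequence extends more than 400 nt past the S100 domain (and no second
domain lies in the extension); **S100A** if the gene encodes two
consecutive S100 domains or the extension is at most 400 nt. The CDS 5'
end is taken as the nearest in-frame ATG upstream of the domain with no
intervening stop — in S100 proteins the domain starts at protein position
2, and the nearest-ATG rule is robust to upstream intron content, which a
"5'-most ATG" rule would not be.

**SEDC calling.** The inter-anchor region is translated in all six
frames. An ORF runs from an ATG to the next in-frame stop (a stop must
exist); nested starts sharing a stop are resolved to the 5'-most ATG.
Candidates must (i) encode at least 50 residues; (ii) carry a biased
composition — defaults G+S ≥ 0.30 (loricrin-like), Q ≥ 0.20
(involucrin-like), P ≥ 0.15 (SPRR-like), C ≥ 0.10 (EDCRP-like), the class
with the largest content/threshold ratio winning when several apply;
(iii) have a splice-acceptor `AG` ending within 50 nt upstream of the
start codon (an optional polypyrimidine-tract check is off by default,
since the canonical acceptor dinucleotide is the only universally agreed
motif); and (iv) be transcribed: at least one read must match the
predicted coding sequence perfectly in some tissue. Candidates
overlapping already-placed S100A/SFTP coding sequence are discarded;
overlapping candidates in different frames are resolved by the higher
composition ratio, then the longer ORF. Because no gene predictor is
involved, a called SEDC is exactly its ORF: one coding exon from start
codon through stop.

**Validation from reads.** The non-coding exon 1 is reconstructed by
exact two-block matching of reads across the junction: a read splits into
a prefix matching the genome upstream and a suffix matching at the
acceptor-adjacent exon start, with the skipped interval beginning `GT`
and ending `AG` and each block at least 8 nt. Exon 1 is the maximal
read-supported interval upstream of the donor; a TATA box (`TATAAA`,
≤ 1 mismatch) is then sought within 100 nt upstream of exon 1. TATA and
splice flags are recorded as validation evidence but do not veto a call —
the class rules above decide, the flags describe.

**Expression.** Per tissue, the package counts reads (once each) whose
six-frame translation matches a gene-specific peptide query at 100%
identity over the full overlap, with at least 16 residues of overlap at
read edges. Counts are reported beside library sizes and never
normalized: the design supports comparing one gene across tissues, not
genes against each other, because query length and composition set each
gene's detection probability. The counting unit is the read; a
window-counting mode (`mode = "hsps"`) is provided for users who prefer
counting every matching window.

**Orthology.** Between two loci, peptides are scored all-against-all with
the same local aligner; reciprocal best hits are reported, and the
highest-scoring positionally consistent chain is kept as the ortholog set
(crossing pairs are reported separately as synteny conflicts, unpaired
genes as lineage-specific). We read "reciprocal best similarity plus
shared local synteny" as: the reciprocal relation identifies candidate
pairs, the non-crossing chain certifies them.

## The simulator: what it emulates, and what it does not

`simulate_locus()` builds a locus as flank — anchor A — SFTPs — SEDCs —
anchor B — flank, with 1.5–3 kb of intergenic background between genes
and random gene orientations. Every gene gets a TATA box planted
25–35 nt upstream of a 60–90 nt non-coding exon 1 and a canonical
90–300 nt intron. SEDC coding exons carry a 10–40 nt 5' UTR (so the
acceptor offset is nonzero), 80–160 codons of class-biased sequence
(involucrin-like bodies include runs of 3–5 consecutive glutamines), and
SFTPs carry a 60-residue S100 domain in their first coding exon and a
200–350 residue P/Q/K/S-rich tail in the second. Anchor, anchor and SFTP
domains are diverged copies (35% substitutions) of one base domain, so
cross-hits between queries occur, as they do between real S100 family
members. `simulate_reads()` draws error-free reads with uniform start
positions from the spliced transcripts: each SFTP/SEDC gene at abundance
0.02 in skin and 0 elsewhere (the observed pattern for EDC genes), the
anchors at 0.02 uniformly across all six tissues (doubling as
housekeeping controls), the remainder from random background transcripts.
Whenever a gene has reads in a tissue, at least one read is guaranteed to
span the exon-1/exon-2 junction with ≥ 8 nt on each side, so exon-1
evidence exists whenever geometry allows.

Several sequence-design choices make perfect recovery a fair target
rather than an accident:

* intron interiors contain stop codons in all three forward frames just
  after the donor, no internal `AG`, and no `ATG`, so the spliced
  extension has a unique maximal solution and the ORF scanner cannot
  start early inside an intron;
* SFTP tails are encoded with an AG-free codon alphabet, so no spurious
  acceptor lies between the true donor and acceptor;
* coding bodies carry periodic "frame-blocker" dipeptides placing stops
  in the shifted and reverse frames, keeping overlapping spurious ORFs
  short;
* intergenic and flanking sequence is rid of all ORFs of ≥ 50 codons by
  planting in-frame stops (re-drawing the segment in the rare case where
  stop planting re-creates a start codon at a boundary).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequencing errors and polymorphism (the
perfect-identity counting rule would undercount in their presence),
non-canonical introns and non-ATG starts, nested or overlapping real
genes, pseudogenes, repeat-derived false domains, and genome-scale
background. The recovery results certify the correctness of the rules'
implementation under the stated assumptions, not the sensitivity of the
procedure on error-prone assemblies.

## Numerical and design choices

* **Thresholds from the procedure**: 400 nt extension, 50-residue ORF
  minimum, 50-nt acceptor window — all sharp (tested at 399/402, 49/50,
  50/51) and all configurable in `edc_params()`.
* **Composition thresholds** (0.30/0.20/0.15/0.10) are package defaults
  chosen to separate EDC-like compositions from uniform background; under
  them a uniform random 100-mer is misclassified at the binomially
  expected rate of about 2.8% (driven by the cysteine class), which the
  transcription and acceptor rules then eliminate from actual calls.
* **Score threshold instead of e-values** (default 50, identity ≥ 0.35):
  at locus scale Karlin–Altschul statistics add machinery without
  discrimination; the threshold is configurable and yields no hits on
  random DNA at query length 60.
* **Candidate ranking and domain coverage**: S100-domain candidates are
  accepted in decreasing hit-score order, discarding any whose CDS
  overlaps an accepted model on either strand — an antisense echo of a
  real domain always scores below the true gene and is dropped. A hit
  group must also cover at least 60% of the domain query
  (`min_domain_coverage`): a gene "contains" a domain only when most of
  it aligns, which removes the short chance alignments that clear a raw
  score threshold at the rate of one or two per hundred loci.
* **Determinism**: a single RNG stream per simulation keyed by the seed;
  byte-identical artifacts under a fixed seed; ties in alignment
  tracebacks resolved by the aligner deterministically.
* **Degenerate inputs**: empty read sets give zero counts with a warning;
  genes without spanning reads keep their class with validation flags
  `FALSE`; `N` in genomic sequence translates to `X` and never
  terminates an ORF.

## Problem sizes used in the packaged checks

The test suite and the acceptance script exercise the study conditions at
desk scale: 20 simulated loci (two anchors, two SFTPs, two SEDCs; about
19 kb each) with six tissues × 50,000 reads of 100 nt, oracle comparisons
on 100 random 5-kb sequences, 200 random peptide pairs, and 10,000 reads.
These sizes were chosen so that the whole suite documents the method's
behavior in a few minutes while keeping every statistical check (binomial
4-standard-deviation bands) well-powered.

## Known limitations

Locus-scale only; ATG-initiated ORFs only; canonical GT..AG introns only;
one intron per spliced extension; no isoforms; the expression analysis is
deliberately semiquantitative. The 16-residue minimum edge overlap in
read counting means the natural intuition "shortening a query never
decreases its count" holds only for containment-style counting (it is
tested in that regime); with edge overlaps, a read can overlap precisely
the part of the query that shortening removes.
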