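---
title: "Detecting integron-associated group II introns and co-located mobile elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting integron-associated group II introns and co-located mobile elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calintron)
library(tibble)
```

# The biological problem

Integrons capture and shuffle gene cassettes through site-specific
recombination at *attC* sites; clusters of *attC* sites with no neighbouring
integron integrase are called CALINs. Group II introns — self-splicing
ribozymes carrying a reverse-transcriptase/maturase ORF (the intron-encoded
protein, IEP) — sometimes insert into these arrays: the IIC-*attC* lineage
targets the folded *attC* bottom strand at a TTGT/T junction, in the
orientation opposite to cassette transcription, while IIB introns have been
found immediately downstream of *attC* sites in cassette orientation. IS*200/605*-family insertion sequences, which transpose through single-stranded
intermediates and are bounded by subterminal palindromic hairpins rather
than inverted repeats, co-occur with these arrays. calintron annotates all
of these elements in bacterial (meta)genomic sequence and ties them to
replication-strand context.

# The detection models

## attC sites

An *attC* site is modelled by its two conserved boxes, R''
(consensus `RYYYACC`) and R' (consensus `GTTRRRY`), read 5'→3' in the
cassette orientation, plus the structural constraints of the folded bottom
strand: the R'' and R' arms pair antiparallel (the R box) and an internal
pair of mutually complementary boxes (the L box) sits symmetrically around
a short terminal loop. A consequence of the consensus pair itself is that R
box pairing can never exceed 6/7 — the C:T column of
`RYYYACC`/`GTTRRRY` cannot form a Watson–Crick or G:U pair — which is why
the default R-box budget is one non-pairing column.

Default geometry (all set in `attc_config()`): motif mismatch budgets 0,
L boxes of 7 nt with perfect mutual pairing, spacers 2–10 bp with at most
2 bp of asymmetry, terminal loop 3–12 nt, total span 40–150 bp. These
defaults were chosen once from canonical attC geometry so that a random
100 kb background yields essentially no calls (the measured background rate
is about 0.05 sites per 100 kb); they deliberately trade sensitivity to
long or divergent attC sites for specificity, a limitation discussed below.
Sites are clustered into loci by single-linkage chaining with an 8 kb gap
threshold, loci need at least two sites, and a locus is a complete integron
when an ORF within 10 kb aligns to an intI reference at ≥35% identity over
≥70% of the reference; otherwise it is a CALIN.

## Group II introns

IEPs are found by aligning ORF proteins against a labelled reference panel
(local alignment, BLOSUM62). Reference domain coordinates (RT0–RT7, the X
maturase domain and, where present, the En endonuclease domain) are
projected through the alignment to give per-domain coverage, and the
catalytic YADD motif is looked up inside the projected RT5 region.
Identity is exact matches over aligned columns (terminal gaps excluded);
similarity is the fraction of aligned columns with a positive BLOSUM62
score, mirroring blast "positives" — the paper-style identity/similarity
pair. Class calls are nearest-reference: the best class must beat the
runner-up by a margin (default 5 identity points), otherwise the call is
ambiguous.

The ribozyme 3' end is found structurally: the window downstream of the ORF
(DV and DVI sit immediately after DIV, which contains the ORF) is scanned
for a pair of adjacent hairpins in which the first carries the catalytic
triad (AGC, or CGC for class C/IIC) in its 5' arm plus an A-pyrimidine
bulge, and the second carries a bulged A. Among qualifying pairs the most
proximal pair wins — DV abuts the ORF, and chance hairpins further out in
the window would otherwise outscore it; this proximity rule, rather than a
raw stem-size score, is what makes the call reproducible on noisy windows.
The 3' terminus is the first position after DVI matching `AXX(X)XRAY`;
relaxation tiers (any A-pyrimidine 2-mer; any 2-mer) accommodate deviant
boundaries and are always flagged.

The 5' end search is the least constrained problem: `GUGYG` is only five
nucleotides, so a 3 kb upstream window contains several chance matches in
expectation. Candidates are therefore gated by target-site support: for
IIA/IIB introns, exact EBS1 and EBS2 complements of the implied IBS1/IBS2
must exist in the proximal DI region (EBS2 within a short window upstream
of EBS1); for class C/IIC, the junction must read TTGT (or at least TGT)
and an upstream stem-loop — the attC bottom-strand signature — must end
within 30 nt of the boundary. An unsupported motif hit is not accepted.
Consistently, the integrity call treats an IEP whose N-terminal domain run
is absent as 5'-truncated even if an unsupported `GUGYG` hit happens to sit
upstream: the protein evidence outweighs a bare pentamer, which is also how
truncation calls are argued in practice. `full` requires both boundaries,
all RT0–RT7 and X domains present and no frame disruptions; internal
stops/frameshifts (detected as same-strand ORF fragments matching the same
reference and merged) make the call `fragmented`.

The DIV basal stem is the best antiparallel complement (≥6 bp, ≤1 mismatch,
fewest mismatches then leftmost) between the 8-mer just upstream of DV and
any window inside the ORF or within 200 bp upstream of the ORF start.

## IS200/605 elements

tnpA (HUH transposase) and tnpB ORFs are found by panel homology; hits at
most 2 kb apart form an element. Ends are anchored on hairpins within
150 bp of the outermost ORF ends, with a 10-pair stem floor; because the
ends are subterminal, the qualifying hairpin closest to the ORFs is taken,
not the largest one. tnpA and tnpB in opposite orientation with both end
hairpins is the IS605 configuration; tnpA alone with an end hairpin is an
IS200-like candidate; anything missing a component is partial. No
terminal-inverted-repeat or target-duplication test is applied — this
family has neither.

## Replication context

Given an OriC interval (an input — origin prediction is out of scope), the
terminus is placed half the genome away from the OriC midpoint, splitting
the chromosome into two replichores; with an odd length the extra base goes
to replichore 1. Within replichore 1 the top strand is the leading strand.
Features are assigned by midpoint; ter-spanning features are flagged. The
midpoint (rather than an OriC edge) anchors the half-genome offset; the two
choices differ by under a kilobase on a megabase genome and never change a
call except within that sliver around the terminus.

## Conservation statistics

Per-column Shannon information (2 − H bits for nucleotides, log2(20) − H
for proteins, no small-sample correction), sequence-logo data
(information × frequency), and minimal-IUPAC consensus calling with a
plurality threshold. Multiple alignments are consumed, not computed:
building an MSA is commodity work for any aligner, the statistics are the
part that feeds the boundary/exon analyses.

# Structure model

Secondary structure uses a maximum base-pairing (Nussinov) dynamic program
with Watson–Crick plus G:U pairs, a minimum loop of 3 nt and no
thermodynamic parameters: every structural decision in the pipeline is
qualitative (is there a helix of this size here), so counting pairs
suffices and keeps the kernel exact and fast (C++, exact DP). Co-optimal
ties are broken deterministically toward outermost pairings, which favours
contiguous stems. The hairpin scanner extends stems outward from candidate
loops, accepting a limited number of short bulges only when at least two
pairs follow, so stems end at their last genuine pair; hairpin score is
`pairs − 0.5·bulges`. Free-energy models, pseudoknots and suboptimal
ensembles are deliberately out of scope, as are the tertiary contacts
(α–α', κ–κ', ζ–ζ' …) beyond optional Watson–Crick complementarity
reporting.

# The synthetic landscape generator

`generate_landscape()` plants every supported element class at known
positions in an i.i.d. background and emits a truth table with internal
anchors (attC boxes, intron boundaries, EBS positions, hairpin stems,
ORFs), so every stage of the pipeline can be validated end to end with no
external data. The default 100 kb landscape carries a complete integron
(intI plus a four-site attC array with cassette ORFs) and, 40 kb away, a
CALIN with a IIC-attC intron inserted at the TTGT/T junction at the foot of
an attC bottom-strand hairpin in opposite orientation, a toxin–antitoxin
cassette, a IIB intron immediately downstream of an attC site in cassette
orientation, a 5'-truncated intron, and an IS605-configuration element
directly downstream of the last attC site — the co-occurrence pattern the
package is designed to resolve. Plant sequences combine fixed motif/helix
constants (with flanking bases engineered so that planted stems cannot be
extended by chance pairing, keeping truth anchors exact) and seeded random
parts (background, cassette proteins); the draw order is background, then
plants in list order, then mutation, and the same configuration always
reproduces the same bytes.

Reference proteins (IEP classes ML/CL1/CL2/A–E with domain coordinates and
the YADD motif, intI, tnpA/tnpB) are deterministic synthetic sequences:
members of a class share ~92% identity, classes are mutually unrelated.
They stand in for curated panels so that classification and domain
projection are testable; real analyses should supply curated panels via
`read_panel()`. Back-translation uses a fixed most-frequent-codon table for
reproducibility.

What the generator does not emulate — and hence what passing tests do not
show about real data: phylogenetically realistic sequence divergence (point
mutations only), attC sites longer or more degenerate than the consensus
model, nested or overlapping elements, sequencing error, and assembly
fragmentation. Recovery on these landscapes is a validity check of the
algorithms, not a sensitivity estimate for environmental metagenomes.

# Numerical and design choices

* Coordinates are 1-based inclusive throughout (the R/Bioconductor
  convention); GFF3 output is 1-based inclusive as required. Distances
  between features are counted as bases strictly between them, so the 8 kb
  clustering rule joins sites with a 7,999-base gap and splits at 8,001.
* Candidate ranking is always lexicographic and documented per function
  (mismatches before support before fold density for 5' ends; proximity
  before terminus offset for DV/DVI; fewest mismatches then leftmost for
  EBS and DIV-stem searches; score then leftmost for attC overlap
  resolution). Every tie-break is deterministic.
* ORF calling is naive six-frame scanning (bacterial starts ATG/GTG/TTG,
  genetic code 11) with 5'/3'-partial flags; no gene prediction. When an
  upstream in-frame start exists the reported start extends past a planted
  start — starts are not statistically chosen, so downstream logic anchors
  on the stop-codon side. All candidate starts are implicitly reported
  through the longest ORF plus the partial flags.
* Alignment thresholds: IEP reporting at ≥40% identity over ≥20% of the
  reference (local alignments of truncated proteins must pass), intI at
  ≥35%/70%, transposases at ≥40%/30%. A shared-k-mer prescreen (three exact
  amino-acid 4-mers) avoids full alignments for unrelated ORFs; unrelated
  random proteins share fewer than one 4-mer in expectation.
* Problem sizes used in the validation suite: 20 seeded 100 kb landscapes
  (clean), a 30-seed × 4-rate degradation grid on 20 kb landscapes, 200
  random sequences against the brute-force folding oracle, 100 random site
  configurations against the clustering oracle, and 50 random genomes
  against the rotation oracle — sizes at which every oracle is exact and
  the whole suite stays desk-scale.

# Known limitations

The consensus-anchored attC detector under-calls divergent sites relative
to covariance-model approaches; sensitivity on real accessions should be
reported, not assumed. The 5'-boundary gate trades recall at high mutation
loads for precision (an unsupported GUGYG is never accepted), which is
visible in the degradation curve. Class calls depend entirely on the
supplied panel; with the built-in synthetic panel they validate the
machinery, not real phylogeny. Promoter prediction, attI/Pc detection for
class 1–3 integrons, and origin-of-replication inference are out of scope.
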