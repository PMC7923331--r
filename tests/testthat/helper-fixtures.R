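# Hand-built planted constructs with positions computed in the test code,
# independent of the synthetic-landscape generator's internals.

# attC site from exact consensus instances: R'' GCCTACC (RYYYACC) and
# R' GTTAGGC (GTTRRRY) pair 6/7 (the C:T consensus column cannot pair);
# L'' GACTGGC and L' GCCAGTC pair 7/7; spacers 5 bp, loop 8 nt.
fixture_attc <- function() {
  parts <- c(R2 = "GCCTACC", SP1 = "ACTAC", L2 = "GACTGGC",
             LOOP = "CTTCGAAC", L1 = "GCCAGTC", SP2 = "CCTAT",
             R1 = "GTTAGGC")
  offs <- cumsum(c(0, nchar(parts)[-length(parts)]))
  names(offs) <- names(parts)
  list(seq = paste(parts, collapse = ""), parts = parts, offsets = offs + 1)
}

# DV helix: arm AAGCGCCG (AGC triad), GAAA loop, complementary arm with an
# AC (A-pyrimidine) bulge; 8 pairs, 1 bulge.
fixture_dv <- function(triad = c("AGC", "CGC")) {
  triad <- match.arg(triad)
  arm1 <- if (triad == "AGC") "AAGCGCCG" else "ACGCGCCG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm1)))
  paste0(arm1, "GAAA", substr(rc, 1, 2), "AC", substr(rc, 3, nchar(rc)))
}

# DVI helix: 8 pairs with a single bulged A in the 3' arm.
fixture_dvi <- function() {
  arm1 <- "GGCAGGCG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm1)))
  paste0(arm1, "CAAG", substr(rc, 1, 3), "A", substr(rc, 4, 8))
}

# A minimal planted 3' region: ORF stop | 8-nt spacer | DV | CCCC | DVI |
# AXXXXRAY terminus. Returns the string and the hand-computed coordinates
# of each part relative to the returned string.
fixture_three_prime_region <- function(triad = "AGC") {
  z8 <- "GATTCTAA"
  dv <- fixture_dv(triad)
  dvi <- fixture_dvi()
  term <- "ACCTCGAT"
  seqs <- c(z8, dv, "CCCC", dvi, term)
  ends <- cumsum(nchar(seqs))
  starts <- c(1, ends[-length(ends)] + 1)
  list(seq = paste(seqs, collapse = ""),
       dv = c(starts[2], ends[2]),
       dvi = c(starts[4], ends[4]),
       terminus = c(starts[5], ends[5]))
}

# Minimal IEP-bearing construct on the plus strand: a real panel protein is
# back-translated so detect_iep scores it at 100% identity.
fixture_iep_orf <- function(class = "CL1", panel = synthetic_iep_panel()) {
  back_translate(panel$protein[panel$class == class][1])
}

# One-row IEP-hit-like tibble for boundary functions that only use
# orf_start/orf_end/strand.
fixture_hit <- function(orf_start, orf_end, strand = "+") {
  tibble::tibble(orf_start = orf_start, orf_end = orf_end, strand = strand)
}

fixture_palindrome <- function(arm = "GATCGGTACGCC", loop = "GAAA") {
  paste0(arm, loop,
         as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm))))
}
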