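# Protein alignment helpers shared by the integrase, IEP and transposase
# panel searches. Alignment itself is delegated to Biostrings; identity is
# exact matches over aligned columns (terminal gaps excluded) and similarity
# is the fraction of aligned columns with a positive substitution score,
# mirroring blast conventions.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

.clean_aa <- function(x) gsub("[^A-Z*]", "", toupper(x))

# identity/similarity over aligned columns (terminal gap columns excluded)
.pair_stats <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  p_idx <- which(pc != "-"); s_idx <- which(sc != "-")
  if (length(p_idx) == 0 || length(s_idx) == 0) {
    return(c(identity = 0, similarity = 0))
  }
  core <- seq.int(max(p_idx[1], s_idx[1]),
                  min(p_idx[length(p_idx)], s_idx[length(s_idx)]))
  pc <- pc[core]; sc <- sc[core]
  matches <- sum(pc == sc & pc != "-")
  both <- pc != "-" & sc != "-"
  pos <- 0L
  if (any(both)) {
    idx <- cbind(match(pc[both], rownames(.blosum62)),
                 match(sc[both], colnames(.blosum62)))
    valid <- stats::complete.cases(idx)
    pos <- sum(.blosum62[idx[valid, , drop = FALSE]] > 0)
  }
  c(identity = 100 * matches / length(core),
    similarity = 100 * pos / length(core))
}

# Align one query against many references in a single call.
# Returns a tibble with score, identity, similarity, ref_coverage.
.align_protein_many <- function(query, refs, type = "local",
                                gap_opening = 10, gap_extension = 0.5) {
  if (nchar(query) == 0 || any(nchar(refs) == 0)) {
    abort("empty sequence in protein alignment", class = "calintron_input_error")
  }
  query <- .clean_aa(query)
  refs <- vapply(refs, .clean_aa, "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(refs), Biostrings::AAString(query),
    substitutionMatrix = .blosum62,
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = type
  )
  tibble(
    score = Biostrings::score(aln),
    # matches over aligned columns (internal gaps included), as in
    # .pair_stats; PID1 avoids materializing aligned strings per reference
    identity = Biostrings::pid(aln, type = "PID1"),
    ref_coverage = (Biostrings::end(Biostrings::pattern(aln)) -
                      Biostrings::start(Biostrings::pattern(aln)) + 1) /
      nchar(refs)
  )
}

# Single query-vs-reference alignment, additionally providing the
# reference-position -> query-position map used for domain projection.
.align_protein <- function(query, ref, type = "local",
                           gap_opening = 10, gap_extension = 0.5) {
  if (nchar(query) == 0 || nchar(ref) == 0) {
    abort("empty sequence in protein alignment", class = "calintron_input_error")
  }
  query <- .clean_aa(query)
  ref <- .clean_aa(ref)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    substitutionMatrix = .blosum62,
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = type
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  stats <- .pair_stats(p, s)
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  q_start <- Biostrings::start(Biostrings::pattern(aln))
  s_start <- Biostrings::start(Biostrings::subject(aln))
  q_pos <- q_start - 1L
  s_pos <- s_start - 1L
  map <- rep(NA_integer_, nchar(ref))
  for (k in seq_along(pc)) {
    if (pc[k] != "-") q_pos <- q_pos + 1L
    if (sc[k] != "-") {
      s_pos <- s_pos + 1L
      if (pc[k] != "-") map[s_pos] <- q_pos
    }
  }
  list(
    score = Biostrings::score(aln),
    identity = unname(stats["identity"]),
    similarity = unname(stats["similarity"]),
    q_start = q_start,
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = s_start,
    s_end = Biostrings::end(Biostrings::subject(aln)),
    ref_coverage = (Biostrings::end(Biostrings::subject(aln)) - s_start + 1) /
      nchar(ref),
    map = map
  )
}

.aa_kmers <- function(p, k = 4) {
  n <- nchar(p)
  if (n < k) return(character(0))
  unique(substring(p, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1))
}

.panel_kmers <- function(panel, k = 4) lapply(panel$protein, .aa_kmers, k = k)

# Cheap shared-k-mer screen: unrelated random proteins share <1 exact
# amino-acid 4-mer in expectation, homologs above the identity thresholds
# share many. Avoids full alignments for the bulk of candidate ORFs.
.kmer_hits <- function(q_kmers, ref_kmers, min_shared = 3) {
  sum(q_kmers %in% ref_kmers) >= min_shared
}

# Best panel hit for a protein; returns NULL when nothing clears thresholds.
.best_panel_hit <- function(protein, panel, min_identity, min_ref_coverage,
                            type = "local", panel_kmers = NULL) {
  cand <- seq_len(nrow(panel))
  if (!is.null(panel_kmers)) {
    q_kmers <- .aa_kmers(protein)
    cand <- cand[vapply(panel_kmers, .kmer_hits, logical(1),
                        q_kmers = q_kmers)]
  }
  if (length(cand) == 0) return(NULL)
  many <- .align_protein_many(protein, panel$protein[cand], type = type)
  ok <- many$identity >= min_identity & many$ref_coverage >= min_ref_coverage
  if (!any(ok)) return(NULL)
  best_i <- cand[ok][which.max(many$score[ok])]
  aln <- .align_protein(protein, panel$protein[best_i], type = type)
  list(ref = panel[best_i, ], aln = aln)
}
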