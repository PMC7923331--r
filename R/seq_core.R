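#' @useDynLib calintron, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort %||%
NULL

# IUPAC nucleotide codes as A/C/G/T bitmasks. N matches everything; a
# degenerate code matches exactly the residues it denotes.
.iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.codes_of <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- unname(.iupac_bits[chars])
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    abort(sprintf("non-IUPAC character '%s' at position %d of %s",
                  chars[bad], bad, what),
          class = "calintron_alphabet_error")
  }
  codes
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Degenerate codes are complemented by their denoted sets (R<->Y, S<->S,
#' W<->W, K<->M, B<->V, D<->H, N<->N).
#'
#' @param x Character vector of nucleotide sequences (IUPAC alphabet).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' revcomp("RYY")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  for (s in x) if (nzchar(s)) .codes_of(s)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
  unname(out)
}

#' Read nucleotide FASTA into a tibble
#'
#' One row per record, order preserved. Residues are uppercased and U is
#' normalized to T (with a message). Malformed input raises a format error
#' naming the offending line or record.
#'
#' @param path Path to a FASTA file.
#' @param topology `"linear"` or `"circular"`, recycled across records.
#' @return A tibble with columns `seq_id`, `desc`, `residues`, `topology`,
#'   `length`.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) abort(paste0("cannot read FASTA file: ", path))
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0) {
    abort(paste0("empty FASTA file (line 1): ", path),
          class = "calintron_format_error")
  }
  if (!startsWith(first[1], ">")) {
    abort(paste0("malformed FASTA: line 1 does not start with '>' in ", path),
          class = "calintron_format_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("FASTA file has headers but no records: ", path),
          class = "calintron_format_error")
  }
  res <- toupper(as.character(set))
  had_u <- vapply(res, function(s) grepl("U", s, fixed = TRUE), logical(1))
  if (any(had_u)) {
    message(sum(had_u), " record(s) contained U; normalized to T")
    res <- gsub("U", "T", res, fixed = TRUE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  for (i in seq_along(res)) {
    chars <- unique(strsplit(res[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, names(.iupac_bits))
    if (length(bad) > 0) {
      abort(sprintf("record '%s' contains non-IUPAC character(s): %s",
                    ids[i], paste(bad, collapse = " ")),
            class = "calintron_format_error")
    }
  }
  tibble(
    seq_id = ids,
    desc = headers,
    residues = unname(res),
    topology = rep_len(topology, length(res)),
    length = nchar(unname(res))
  )
}

#' Write sequences from a tibble to FASTA
#'
#' @param seqs Tibble with `seq_id` and `residues` columns (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs$residues)
  names(set) <- seqs$seq_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Finds all positions on one or both strands where `pattern` matches with at
#' most `max_mismatch` mismatching columns. A degenerate pattern code matches
#' any residue it denotes. Minus-strand hits are reported in top-strand
#' coordinates of the matched window.
#'
#' @param seq A single nucleotide string.
#' @param pattern IUPAC motif, e.g. `"GTTRRRY"`.
#' @param max_mismatch Maximum mismatching columns (default 0).
#' @param strand `"both"` (default), `"+"` or `"-"`.
#' @return Tibble with `start`, `end` (1-based inclusive), `strand`,
#'   `mismatches`, sorted by `start`.
#' @export
iupac_scan <- function(seq, pattern, max_mismatch = 0, strand = "both") {
  stopifnot(length(seq) == 1, length(pattern) == 1, max_mismatch >= 0)
  strand <- match.arg(strand, c("both", "+", "-"))
  m <- nchar(pattern)
  n <- nchar(seq)
  if (m == 0 || m > n) {
    return(tibble(start = integer(), end = integer(),
                  strand = character(), mismatches = integer()))
  }
  seq_codes <- .codes_of(seq)
  scan_one <- function(pat, strand_label) {
    pat_codes <- .codes_of(pat, "pattern")
    n_starts <- n - m + 1L
    mm <- integer(n_starts)
    for (j in seq_len(m)) {
      ok <- bitwAnd(seq_codes[j:(j + n_starts - 1L)], pat_codes[j]) > 0L
      mm <- mm + as.integer(!ok)
    }
    hit <- which(mm <= max_mismatch)
    tibble(start = hit, end = hit + m - 1L,
           strand = rep(strand_label, length(hit)),
           mismatches = mm[hit])
  }
  out <- list()
  if (strand %in% c("both", "+")) out <- c(out, list(scan_one(pattern, "+")))
  if (strand %in% c("both", "-")) out <- c(out, list(scan_one(revcomp(pattern), "-")))
  bind_rows(out) |> arrange(.data$start, .data$strand)
}

.stop_codons <- c("TAA", "TAG", "TGA")
.start_codons <- c("ATG", "GTG", "TTG")

.translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.find_orfs_strand <- function(s, min_len, allow_partial, starts) {
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    codon_starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(codon_starts) == 0 || codon_starts[1] > n - 2L) next
    codons <- substring(s, codon_starts, codon_starts + 2L)
    is_stop <- codons %in% .stop_codons
    is_start <- codons %in% starts
    seg_id <- c(0L, cumsum(is_stop))[seq_along(codons)]
    for (seg in split(seq_along(codons), seg_id)) {
      last <- seg[length(seg)]
      has_stop <- is_stop[last]
      coding <- if (has_stop) seg[-length(seg)] else seg
      if (length(coding) == 0) next
      st_idx <- coding[is_start[coding]]
      if (length(st_idx) > 0) {
        from <- st_idx[1]; has_start <- TRUE
      } else if (allow_partial) {
        from <- coding[1]; has_start <- FALSE
      } else next
      if (!has_stop && !allow_partial) next
      orf_end_codon <- if (has_stop) last else coding[length(coding)]
      start_nt <- codon_starts[from]
      end_nt <- codon_starts[orf_end_codon] + 2L
      if (end_nt - start_nt + 1L < min_len) next
      prot_codons <- codons[from:(if (has_stop) last - 1L else orf_end_codon)]
      out[[length(out) + 1L]] <- tibble(
        start = start_nt, end = end_nt, frame = frame,
        has_start = has_start, has_stop = has_stop,
        partial5 = !has_start, partial3 = !has_stop,
        protein = if (length(prot_codons)) .translate_codons(prot_codons) else ""
      )
    }
  }
  bind_rows(out)
}

#' Find open reading frames on both strands
#'
#' Naive six-frame ORF scan with bacterial starts (ATG/GTG/TTG, genetic code
#' 11 amino-acid assignments). When `allow_partial` is `TRUE`, stop-bounded
#' stretches lacking a start codon are reported with the 5'-partial flag, and
#' runs reaching a sequence end without a stop get the 3'-partial flag.
#' Coordinates are top-strand, 1-based inclusive, including the stop codon.
#'
#' @param seq A single nucleotide string.
#' @param min_len Minimum ORF span in bp (default 60).
#' @param allow_partial Report partial ORFs (default TRUE).
#' @param starts Accepted start codons.
#' @return Tibble with `start`, `end`, `strand`, `frame`, `has_start`,
#'   `has_stop`, `partial5`, `partial3`, `protein` (stop excluded).
#' @export
find_orfs <- function(seq, min_len = 60, allow_partial = TRUE,
                      starts = .start_codons) {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  fwd <- .find_orfs_strand(seq, min_len, allow_partial, starts)
  rev <- .find_orfs_strand(revcomp(seq), min_len, allow_partial, starts)
  if (nrow(fwd)) fwd$strand <- "+"
  if (nrow(rev)) {
    rev <- rev |>
      mutate(start_top = n - .data$end + 1L, end_top = n - .data$start + 1L,
             strand = "-") |>
      mutate(start = .data$start_top, end = .data$end_top) |>
      select(-"start_top", -"end_top")
  }
  bind_rows(fwd, rev) |>
    select("start", "end", "strand", "frame", "has_start", "has_stop",
           "partial5", "partial3", "protein") |>
    arrange(.data$start, .data$end, .data$strand)
}

#' Write annotation features to GFF3
#'
#' Coordinates in the output are 1-based inclusive; the `##gff-version 3`
#' pragma and attribute escaping are handled by rtracklayer.
#'
#' @param features Tibble with columns `seqid`, `type`, `start`, `end`,
#'   `strand` and optionally `score`, `ID`, `Name`, `Parent`, `source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- if ("source" %in% names(features))
    features$source else "calintron"
  S4Vectors::mcols(gr)$type <- features$type
  if ("score" %in% names(features)) S4Vectors::mcols(gr)$score <- features$score
  for (col in c("ID", "Name", "Parent")) {
    if (col %in% names(features)) S4Vectors::mcols(gr)[[col]] <- features[[col]]
  }
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

# Extract [start, end] (1-based inclusive), respecting strand: for "-" the
# reverse complement is returned (coding-orientation sequence).
.subseq_strand <- function(seq, start, end, strand = "+") {
  s <- substr(seq, start, end)
  if (strand == "-") s <- revcomp(s) else s
}
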