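# Conservation statistics for boundary/exon analyses: pairwise
# identity/similarity, per-column information content (sequence-logo data)
# and IUPAC consensus extraction. Multiple alignment itself is consumed, not
# computed: aligned FASTA from any aligner is accepted.

#' Pairwise protein identity and similarity
#'
#' Identity is exact matches over aligned columns (terminal gaps excluded);
#' similarity is the fraction of aligned columns with a positive BLOSUM62
#' score, mirroring blast "positives".
#'
#' @param a,b Protein sequences.
#' @param mode `"global"` or `"local"`.
#' @return One-row tibble with `identity`, `similarity` (percent).
#' @export
pairwise_stats <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  aln <- .align_protein(a, b, type = mode)
  tibble(identity = aln$identity, similarity = aln$similarity)
}

#' Read an aligned FASTA into a character matrix-like tibble
#'
#' @param path Aligned FASTA (equal-length rows, `-` for gaps).
#' @return Tibble with `id` and `aligned` columns.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  if (length(unique(nchar(rows))) != 1) {
    abort("alignment rows differ in length", class = "calintron_format_error")
  }
  tibble(id = sub("\\s.*$", "", names(set)), aligned = unname(rows))
}

.aln_matrix <- function(alignment) {
  rows <- if (is.data.frame(alignment)) alignment$aligned else alignment
  if (length(unique(nchar(rows))) != 1) {
    abort("alignment rows differ in length", class = "calintron_input_error")
  }
  do.call(rbind, strsplit(toupper(rows), ""))
}

#' Per-column information content of an alignment
#'
#' Shannon entropy over ungapped residues per column; information is
#' `log2(K) - entropy` with K = 4 (nucleotide) or 20 (protein). All-gap
#' columns get `NA` information. No small-sample correction is applied.
#'
#' @param alignment Character vector of aligned rows, or a tibble from
#'   [read_alignment()].
#' @param type `"auto"`, `"dna"` or `"protein"`.
#' @return Tibble with `column`, `n` (ungapped rows), `entropy`,
#'   `information` and a `counts` list-column.
#' @export
column_information <- function(alignment, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  m <- .aln_matrix(alignment)
  if (type == "auto") {
    res <- setdiff(unique(as.vector(m)), c("-", ".", "N"))
    type <- if (all(res %in% c("A", "C", "G", "T", "U"))) "dna" else "protein"
  }
  kmax <- if (type == "dna") 2 else log2(20)
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[!col %in% c("-", ".")]
    if (length(col) == 0) {
      return(tibble(column = j, n = 0L, entropy = NA_real_,
                    information = NA_real_, counts = list(integer())))
    }
    tab <- table(col)
    p <- as.numeric(tab) / length(col)
    h <- -sum(p * log2(p))
    tibble(column = j, n = length(col), entropy = h,
           information = kmax - h, counts = list(c(tab)))
  })
}

.bits_to_iupac <- function() {
  v <- .iupac_bits[!names(.iupac_bits) %in% "U"]
  stats::setNames(names(v), as.character(v))
}

#' IUPAC consensus of a nucleotide alignment
#'
#' Per column, residues are accumulated in decreasing frequency until the
#' plurality threshold is reached, and the smallest IUPAC code covering that
#' residue set is emitted. Gap-majority columns are emitted as `-`.
#'
#' @param alignment Character vector of aligned rows or [read_alignment()]
#'   tibble.
#' @param plurality Fraction in (0.5, 1] (default 0.7).
#' @return Consensus string.
#' @export
consensus <- function(alignment, plurality = 0.7) {
  stopifnot(plurality > 0.5, plurality <= 1)
  m <- .aln_matrix(alignment)
  out <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (mean(col %in% c("-", ".")) > 0.5) return("-")
    col <- col[!col %in% c("-", ".")]
    tab <- sort(table(col), decreasing = TRUE)
    # deterministic tie-break: alphabetical within equal counts
    ord <- order(-as.numeric(tab), names(tab))
    tab <- tab[ord]
    freq <- cumsum(as.numeric(tab)) / length(col)
    k <- which(freq >= plurality)[1]
    set <- names(tab)[seq_len(k)]
    bits <- sum(.iupac_bits[set])
    unname(.bits_to_iupac()[as.character(bits)])
  }, "")
  paste(out, collapse = "")
}

#' Sequence-logo data from an alignment
#'
#' Per-column residue heights (`information * frequency`), the quantity
#' plotted by standard logo renderers.
#'
#' @inheritParams column_information
#' @return Tibble with `column`, `residue`, `freq`, `height`.
#' @export
logo_data <- function(alignment, type = c("auto", "dna", "protein")) {
  info <- column_information(alignment, type)
  purrr::map_dfr(seq_len(nrow(info)), function(i) {
    cnt <- info$counts[[i]]
    if (length(cnt) == 0) return(tibble())
    tibble(column = info$column[i], residue = names(cnt),
           freq = as.numeric(cnt) / info$n[i],
           height = info$information[i] * as.numeric(cnt) / info$n[i])
  })
}

#' Write logo data as TSV
#' @param alignment Alignment rows or tibble.
#' @param path Output TSV path.
#' @inheritParams column_information
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(alignment, path, type = c("auto", "dna", "protein")) {
  ld <- logo_data(alignment, type)
  utils::write.table(ld, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
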