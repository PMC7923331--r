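#' Maximum base-pairing fold of a sequence window
#'
#' Nussinov-style dynamic programming maximizing the number of Watson-Crick
#' (A:T/U, G:C) plus G:U pairs subject to non-crossing and a minimum hairpin
#' loop. The energy model is a pure pair count: structure is used
#' qualitatively (presence and shape of helices), not thermodynamically.
#' Among co-optimal structures the traceback deterministically prefers
#' outermost pairings, which favours contiguous stems.
#'
#' @param window Nucleotide string (DNA or RNA alphabet), length <= 10000.
#' @param min_loop Minimum unpaired loop length (default 3).
#' @return A `fold_result` list: `sequence`, `dot_bracket`, `max_pairs`,
#'   `pairs` (tibble of 1-based `i`, `j`).
#' @examples
#' nussinov_fold("GGGGAAAACCCC")$max_pairs
#' @export
nussinov_fold <- function(window, min_loop = 3) {
  stopifnot(length(window) == 1, min_loop >= 0)
  res <- .nussinov_cpp(toupper(window), as.integer(min_loop))
  pairs <- res$pairs
  out <- list(
    sequence = toupper(window),
    dot_bracket = res$dot_bracket,
    max_pairs = res$max_pairs,
    pairs = tibble(i = pairs[, 1], j = pairs[, 2])
  )
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, rna = TRUE, ...) {
  seq_disp <- if (rna) chartr("T", "U", x$sequence) else x$sequence
  cat(seq_disp, "\n", x$dot_bracket, "\n", sep = "")
  cat("max pairs:", x$max_pairs, "\n")
  invisible(x)
}

.pairable <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

#' Pairing fraction of two boxes placed antiparallel
#'
#' Fraction of columns forming Watson-Crick or G:U pairs when `b1` is placed
#' antiparallel against `b2` (position i of `b1` against position n+1-i of
#' `b2`). Used for the R and L boxes of attC sites, whose arms pair in the
#' folded bottom strand.
#'
#' @param b1,b2 Nucleotide strings of equal or near-equal length (difference
#'   at most 2; columns beyond the shorter box are ignored).
#' @return Pairing fraction in `[0, 1]`.
#' @export
pair_boxes <- function(b1, b2) {
  if (abs(nchar(b1) - nchar(b2)) > 2) {
    abort("box length difference exceeds 2", class = "calintron_geometry_error")
  }
  .pair_fraction_cpp(toupper(b1), toupper(b2))
}

# Extend a stem outward from loop boundaries [ls-1, le+1]. Bulges (up to
# max_bulge events of up to max_bulge_len nt on either arm) are accepted only
# when at least two consecutive pairs follow, so stems end at their last
# genuine pair.
.extend_stem <- function(chars, ls, le, max_bulge, max_bulge_len) {
  n <- length(chars)
  i <- ls - 1L; j <- le + 1L
  pairs <- matrix(integer(0), ncol = 2)
  bulges <- list()
  repeat {
    if (i < 1L || j > n) break
    if (.pairable(chars[i], chars[j])) {
      pairs <- rbind(pairs, c(i, j))
      i <- i - 1L; j <- j + 1L
      next
    }
    if (length(bulges) >= max_bulge || nrow(pairs) < 1L) break
    advanced <- FALSE
    for (blen in seq_len(max_bulge_len)) {
      # bulge on the 5' arm
      i2 <- i - blen
      if (i2 >= 2L && j <= n - 1L &&
          .pairable(chars[i2], chars[j]) && .pairable(chars[i2 - 1L], chars[j + 1L])) {
        bulges[[length(bulges) + 1L]] <- list(side = "5p", start = i2 + 1L, end = i,
                                              seq = paste(chars[(i2 + 1L):i], collapse = ""))
        i <- i2
        advanced <- TRUE
        break
      }
      # bulge on the 3' arm
      j2 <- j + blen
      if (j2 <= n - 1L && i >= 2L &&
          .pairable(chars[i], chars[j2]) && .pairable(chars[i - 1L], chars[j2 + 1L])) {
        bulges[[length(bulges) + 1L]] <- list(side = "3p", start = j, end = j2 - 1L,
                                              seq = paste(chars[j:(j2 - 1L)], collapse = ""))
        j <- j2
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }
  list(pairs = pairs, bulges = bulges)
}

#' Find local stem-loop (hairpin) structures
#'
#' Scans all candidate loops within `loop_range` and extends a stem outward,
#' allowing a limited number of short bulges. Hairpins whose stem reaches
#' `min_stem` pairs are reported with score `pairs - 0.5 * bulges`, sorted by
#' score descending then leftmost. Overlapping lower-scoring variants of the
#' same stem are suppressed.
#'
#' @param seq Nucleotide string.
#' @param min_stem Minimum stem pairs (default 5).
#' @param loop_range Length-2 inclusive range of loop sizes (default 3-12).
#' @param max_bulge Maximum bulge events per hairpin (default 1).
#' @param max_bulge_len Maximum bulged nucleotides per event (default 3).
#' @param dedup Suppress overlapping lower-scoring variants (default TRUE).
#' @return Tibble with `start`, `end`, `stem_pairs`, `loop_start`,
#'   `loop_end`, `loop_len`, `bulges`, `score`, and list-columns
#'   `pair_list` (two-column matrix of paired indices) and `bulge_info`.
#' @export
find_stem_loops <- function(seq, min_stem = 5, loop_range = c(3, 12),
                            max_bulge = 1, max_bulge_len = 3, dedup = TRUE) {
  stopifnot(length(seq) == 1, min_stem >= 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  acc <- list(start = integer(), end = integer(), stem_pairs = integer(),
              loop_start = integer(), loop_end = integer(),
              loop_len = integer(), bulges = integer(), score = numeric(),
              pair_list = list(), bulge_info = list())
  k <- 0L
  for (ll in seq.int(loop_range[1], loop_range[2])) {
    if (n < ll + 2L * min_stem) next
    for (ls in seq.int(min_stem + 1L, n - ll + 1L - min_stem)) {
      le <- ls + ll - 1L
      ext <- .extend_stem(chars, ls, le, max_bulge, max_bulge_len)
      np <- nrow(ext$pairs)
      if (np < min_stem) next
      k <- k + 1L
      acc$start[k] <- ext$pairs[np, 1]; acc$end[k] <- ext$pairs[np, 2]
      acc$stem_pairs[k] <- np
      acc$loop_start[k] <- ls; acc$loop_end[k] <- le; acc$loop_len[k] <- ll
      acc$bulges[k] <- length(ext$bulges)
      acc$score[k] <- np - 0.5 * length(ext$bulges)
      acc$pair_list[[k]] <- ext$pairs
      acc$bulge_info[[k]] <- ext$bulges
    }
  }
  all_h <- tibble(
    start = acc$start, end = acc$end, stem_pairs = acc$stem_pairs,
    loop_start = acc$loop_start, loop_end = acc$loop_end,
    loop_len = acc$loop_len, bulges = acc$bulges, score = acc$score,
    pair_list = acc$pair_list, bulge_info = acc$bulge_info
  )
  if (k == 0L) return(all_h)
  all_h <- all_h |> arrange(desc(.data$score), .data$start)
  if (!dedup) return(all_h)
  # suppress overlapping lower-scoring variants of the same stem
  keep <- logical(nrow(all_h))
  for (k in seq_len(nrow(all_h))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- all_h[keep, ]
      ov <- pmax(0, pmin(kept$end, all_h$end[k]) - pmax(kept$start, all_h$start[k]) + 1)
      span <- all_h$end[k] - all_h$start[k] + 1
      if (any(ov > 0.25 * span)) ok <- FALSE
    }
    keep[k] <- ok
  }
  all_h[keep, ]
}

# Best hairpin (by score then leftmost) in a subsequence window; coordinates
# returned in the parent sequence frame. NULL if none.
.best_hairpin <- function(seq, from, to, ...) {
  from <- max(1L, from); to <- min(nchar(seq), to)
  if (to - from + 1 < 12) return(NULL)
  h <- find_stem_loops(substr(seq, from, to), ...)
  if (nrow(h) == 0) return(NULL)
  h <- h[1, ]
  h$start <- h$start + from - 1L
  h$end <- h$end + from - 1L
  h$loop_start <- h$loop_start + from - 1L
  h$loop_end <- h$loop_end + from - 1L
  h$pair_list <- list(h$pair_list[[1]] + from - 1L)
  h
}
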