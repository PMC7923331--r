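# IS200/605-superfamily element detection: tnpA/tnpB homology, ORF
# configuration, and subterminal palindromic end hairpins (this family has
# no terminal inverted repeats; hairpin structures mark both ends).

.nt_submat <- local({
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                baseOnly = FALSE)
  m
})

.align_nt_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = .nt_submat, gapOpening = 10, gapExtension = 1,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  p_range <- range(which(p != "-")); s_range <- range(which(s != "-"))
  core <- seq.int(max(p_range[1], s_range[1]), min(p_range[2], s_range[2]))
  100 * sum(p[core] == s[core] & p[core] != "-") / length(core)
}

#' Detect IS200/605-family insertion sequences
#'
#' ORFs matching tnpA (HUH transposase) or tnpB references are grouped into
#' elements when at most `pair_gap` apart; element boundaries are anchored
#' on the best hairpin within `end_window_bp` of the outermost ORF ends.
#' Group call: tnpA + tnpB in opposite orientation with both end hairpins is
#' the IS605 configuration; tnpA alone with at least one hairpin is an
#' IS200-like candidate; elements missing a component are `partial`.
#'
#' @param seq Nucleotide string.
#' @param tnp_refs Panel tibble with classes `tnpA` and `tnpB`.
#' @param end_window_bp Hairpin search window beyond the ORFs (default 150).
#' @param pair_gap Maximum tnpA-tnpB gap (default 2000).
#' @param min_identity,min_ref_coverage Homology thresholds.
#' @param min_stem Minimum end-hairpin stem pairs (default 10).
#' @param seq_id Identifier used in the output.
#' @return Tibble of elements with ORF/hairpin coordinates, identities,
#'   `configuration` and `group_call`, plus `element_seq`.
#' @export
find_is_elements <- function(seq, tnp_refs, end_window_bp = 150,
                             pair_gap = 2000, min_identity = 40,
                             min_ref_coverage = 0.3, min_stem = 10,
                             seq_id = "seq") {
  if (is.null(tnp_refs) || nrow(tnp_refs) == 0) {
    abort("empty tnpA/tnpB reference panel", class = "calintron_config_error")
  }
  seq <- toupper(seq)
  orfs <- find_orfs(seq, min_len = 240, allow_partial = TRUE) |>
    filter(nchar(.data$protein) >= 80)
  pk <- .panel_kmers(tnp_refs)
  hits <- list()
  for (i in seq_len(nrow(orfs))) {
    h <- .best_panel_hit(orfs$protein[i], tnp_refs,
                         min_identity, min_ref_coverage, panel_kmers = pk)
    if (is.null(h)) next
    hits[[length(hits) + 1L]] <- tibble(
      start = orfs$start[i], end = orfs$end[i], strand = orfs$strand[i],
      label = h$ref$class, ref = h$ref$id, identity = h$aln$identity,
      score = h$aln$score, partial = orfs$partial5[i] | orfs$partial3[i]
    )
  }
  empty <- tibble(seq_id = character(), start = integer(), end = integer(),
                  tnpA_start = integer(), tnpA_end = integer(),
                  tnpA_strand = character(), tnpA_identity = numeric(),
                  tnpB_start = integer(), tnpB_end = integer(),
                  tnpB_strand = character(), tnpB_identity = numeric(),
                  configuration = character(), group_call = character(),
                  left_hp_start = integer(), left_hp_end = integer(),
                  left_stem = integer(), left_loop = integer(),
                  right_hp_start = integer(), right_hp_end = integer(),
                  right_stem = integer(), right_loop = integer(),
                  element_seq = character())
  if (length(hits) == 0) return(empty)
  hits <- bind_rows(hits) |> arrange(.data$start)
  # deduplicate overlapping hits of the same label (nested partial ORFs)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(hits)) != i & hits$label == hits$label[i] &
                  hits$start <= hits$end[i] & hits$end >= hits$start[i])
    for (j in ov) if (hits$score[j] <= hits$score[i]) keep[j] <- FALSE
  }
  hits <- hits[keep, ]
  chain <- cumsum(c(0L, as.integer(
    hits$start[-1] - hits$end[-nrow(hits)] - 1L > pair_gap)))
  out <- list()
  for (g in split(seq_len(nrow(hits)), chain)) {
    sub <- hits[g, ]
    pick <- function(lbl) {
      s <- sub |> filter(.data$label == lbl)
      if (nrow(s) == 0) NULL else s[which.max(s$score), ]
    }
    ta <- pick("tnpA"); tb <- pick("tnpB")
    lo <- min(sub$start); hi <- max(sub$end)
    # subterminal ends: the qualifying hairpin closest to the ORFs wins
    end_hairpin <- function(from, to, proximal_side) {
      from <- max(1L, from); to <- min(nchar(seq), to)
      if (to - from + 1 < 2 * min_stem + 3) return(NULL)
      h <- find_stem_loops(substr(seq, from, to), min_stem = min_stem,
                           max_bulge = 1, dedup = FALSE)
      if (nrow(h) == 0) return(NULL)
      h <- if (proximal_side == "right") {
        h |> arrange(desc(.data$end), desc(.data$start))
      } else {
        h |> arrange(.data$start, .data$end)
      }
      h <- h[1, ]
      h$start <- h$start + from - 1L
      h$end <- h$end + from - 1L
      h
    }
    left <- end_hairpin(lo - end_window_bp, lo - 1L, "right")
    right <- end_hairpin(hi + 1L, hi + end_window_bp, "left")
    configuration <- if (!is.null(ta) && !is.null(tb)) {
      if (ta$strand != tb$strand) "opposite_orientation" else "same_orientation"
    } else if (!is.null(ta)) "tnpA_only" else "tnpB_only"
    both_hp <- !is.null(left) && !is.null(right)
    group_call <- if (configuration == "opposite_orientation" && both_hp &&
                      !isTRUE(ta$partial) && !isTRUE(tb$partial)) {
      "IS605_group"
    } else if (configuration == "tnpA_only" &&
               (!is.null(left) || !is.null(right))) {
      "IS200_like"
    } else if (configuration == "same_orientation" && both_hp) {
      "unclassified"
    } else "partial"
    el_start <- if (!is.null(left)) left$start else lo
    el_end <- if (!is.null(right)) right$end else hi
    out[[length(out) + 1L]] <- tibble(
      seq_id = seq_id, start = el_start, end = el_end,
      tnpA_start = if (is.null(ta)) NA_integer_ else ta$start,
      tnpA_end = if (is.null(ta)) NA_integer_ else ta$end,
      tnpA_strand = if (is.null(ta)) NA_character_ else ta$strand,
      tnpA_identity = if (is.null(ta)) NA_real_ else ta$identity,
      tnpB_start = if (is.null(tb)) NA_integer_ else tb$start,
      tnpB_end = if (is.null(tb)) NA_integer_ else tb$end,
      tnpB_strand = if (is.null(tb)) NA_character_ else tb$strand,
      tnpB_identity = if (is.null(tb)) NA_real_ else tb$identity,
      configuration = configuration, group_call = group_call,
      left_hp_start = if (is.null(left)) NA_integer_ else left$start,
      left_hp_end = if (is.null(left)) NA_integer_ else left$end,
      left_stem = if (is.null(left)) NA_integer_ else left$stem_pairs,
      left_loop = if (is.null(left)) NA_integer_ else left$loop_len,
      right_hp_start = if (is.null(right)) NA_integer_ else right$start,
      right_hp_end = if (is.null(right)) NA_integer_ else right$end,
      right_stem = if (is.null(right)) NA_integer_ else right$stem_pairs,
      right_loop = if (is.null(right)) NA_integer_ else right$loop_len,
      element_seq = substr(seq, el_start, el_end)
    )
  }
  bind_rows(out)
}

#' Compare two IS elements
#'
#' Global nucleotide identity of the element spans plus per-end comparison
#' of stem length, loop length and identity of the end-hairpin windows.
#'
#' @param a,b One-row tibbles from [find_is_elements()].
#' @return List with `nt_identity` and an `ends` tibble.
#' @export
compare_elements <- function(a, b) {
  nt_id <- .align_nt_identity(a$element_seq, b$element_seq)
  end_seq <- function(el, side) {
    s <- el[[paste0(side, "_hp_start")]]; e <- el[[paste0(side, "_hp_end")]]
    if (is.na(s)) return(NULL)
    substr(el$element_seq, s - el$start + 1L, e - el$start + 1L)
  }
  ends <- purrr::map_dfr(c("left", "right"), function(side) {
    sa <- end_seq(a, side); sb <- end_seq(b, side)
    tibble(
      end = side,
      stem_diff = abs(a[[paste0(side, "_stem")]] - b[[paste0(side, "_stem")]]),
      loop_diff = abs(a[[paste0(side, "_loop")]] - b[[paste0(side, "_loop")]]),
      seq_identity = if (is.null(sa) || is.null(sb)) NA_real_
                     else .align_nt_identity(sa, sb)
    )
  })
  list(nt_identity = nt_id, ends = ends)
}
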