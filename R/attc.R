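#' Configuration for attC site detection
#'
#' The detector anchors on the two conserved boxes of an attC site, R''
#' (consensus `RYYYACC`) and R' (consensus `GTTRRRY`), requires them in
#' correct order and orientation within a total-length range, and then
#' demands the structural signature of the folded bottom strand: the R''/R'
#' arms pairing antiparallel (R box) and an internal pair of mutually
#' complementary boxes (L box) placed symmetrically around a short terminal
#' loop. Note the consensus pair itself caps R-box pairing at 6/7 (the C:T
#' column cannot pair), so `r_box_budget = 1` is the strictest usable value.
#'
#' @param r1_pattern,r2_pattern IUPAC consensus for R' and R''.
#' @param r1_max_mismatch,r2_max_mismatch Mismatch budgets for the two motifs.
#' @param r_box_budget Allowed non-pairing columns in the R box.
#' @param l_box_len L'' / L' box length in nt.
#' @param l_box_budget Allowed non-pairing columns in the L box.
#' @param spacer_range Range of the R''-L'' and L'-R' spacer lengths (bp).
#' @param loop_range Range of the L''-L' terminal loop length (bp).
#' @param max_spacer_asym Maximum difference between the two spacers (bp).
#' @param span_range Total site length range R'' start to R' end (bp).
#' @return A list of class `attc_config`.
#' @export
attc_config <- function(r1_pattern = "GTTRRRY", r2_pattern = "RYYYACC",
                        r1_max_mismatch = 0, r2_max_mismatch = 0,
                        r_box_budget = 1, l_box_len = 7, l_box_budget = 0,
                        spacer_range = c(2, 10), loop_range = c(3, 12),
                        max_spacer_asym = 2, span_range = c(40, 150)) {
  cfg <- list(
    r1_pattern = r1_pattern, r2_pattern = r2_pattern,
    r1_max_mismatch = r1_max_mismatch, r2_max_mismatch = r2_max_mismatch,
    r_box_budget = r_box_budget, l_box_len = l_box_len,
    l_box_budget = l_box_budget, spacer_range = spacer_range,
    loop_range = loop_range, max_spacer_asym = max_spacer_asym,
    span_range = span_range
  )
  class(cfg) <- "attc_config"
  cfg
}

.empty_attc <- function() {
  tibble(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), bs_strand = character(),
    r2_start = integer(), r2_end = integer(),
    l2_start = integer(), l2_end = integer(),
    l1_start = integer(), l1_end = integer(),
    r1_start = integer(), r1_end = integer(),
    r_box_pairing = numeric(), l_box_pairing = numeric(),
    fold_score = numeric(), score = numeric()
  )
}

# Scan one orientation: R'' ... R' read 5'->3' on the given strand sequence.
.scan_attc_one <- function(s, cfg, strand_label) {
  m1 <- nchar(cfg$r1_pattern); m2 <- nchar(cfg$r2_pattern)
  llen <- cfg$l_box_len
  r1 <- iupac_scan(s, cfg$r1_pattern, cfg$r1_max_mismatch, strand = "+")
  r2 <- iupac_scan(s, cfg$r2_pattern, cfg$r2_max_mismatch, strand = "+")
  if (nrow(r1) == 0 || nrow(r2) == 0) return(NULL)
  min_r_pair <- (m2 - cfg$r_box_budget) / m2
  min_l_pair <- (llen - cfg$l_box_budget) / llen
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- list()
  for (a in seq_len(nrow(r1))) {
    r1s <- r1$start[a]; r1e <- r1$end[a]
    cand <- which(r2$start >= r1e - cfg$span_range[2] + 1 &
                    r2$start <= r1e - cfg$span_range[1] + 1 &
                    r2$end < r1s)
    for (b in cand) {
      r2s <- r2$start[b]; r2e <- r2$end[b]
      r_pair <- pair_boxes(substr(s, r2s, r2e), substr(s, r1s, r1e))
      if (r_pair < min_r_pair) next
      # L box search between the R arms
      best_l <- NULL
      for (d1 in seq.int(cfg$spacer_range[1], cfg$spacer_range[2])) {
        l2s <- r2e + d1 + 1L
        l2e <- l2s + llen - 1L
        for (d2 in seq.int(max(cfg$spacer_range[1], d1 - cfg$max_spacer_asym),
                           min(cfg$spacer_range[2], d1 + cfg$max_spacer_asym))) {
          l1e <- r1s - d2 - 1L
          l1s <- l1e - llen + 1L
          loop <- l1s - l2e - 1L
          if (loop < cfg$loop_range[1] || loop > cfg$loop_range[2]) next
          if (l2s <= r2e || l1e >= r1s || l1s <= l2e) next
          l_pair <- pair_boxes(substr(s, l2s, l2e), substr(s, l1s, l1e))
          if (l_pair < min_l_pair) next
          if (is.null(best_l) || l_pair > best_l$l_pair ||
              (l_pair == best_l$l_pair && abs(d1 - d2) < best_l$asym)) {
            best_l <- list(l2s = l2s, l2e = l2e, l1s = l1s, l1e = l1e,
                           l_pair = l_pair, asym = abs(d1 - d2))
          }
        }
      }
      if (is.null(best_l)) next
      bs <- revcomp(substr(s, r2s, r1e))
      fold <- nussinov_fold(bs)
      fold_score <- 2 * fold$max_pairs / nchar(bs)
      out[[length(out) + 1L]] <- tibble(
        start = r2s, end = r1e, strand = strand_label,
        r2_start = r2s, r2_end = r2e,
        l2_start = best_l$l2s, l2_end = best_l$l2e,
        l1_start = best_l$l1s, l1_end = best_l$l1e,
        r1_start = r1s, r1_end = r1e,
        r_box_pairing = r_pair, l_box_pairing = best_l$l_pair,
        fold_score = fold_score,
        score = r_pair + best_l$l_pair + fold_score
      )
    }
  }
  if (length(out)) bind_rows(out) else NULL
}

.mirror_coords <- function(df, n, cols) {
  for (cp in cols) {
    s <- df[[cp[1]]]; e <- df[[cp[2]]]
    df[[cp[1]]] <- n - e + 1L
    df[[cp[2]]] <- n - s + 1L
  }
  df
}

#' Detect attC recombination sites
#'
#' Scans both strands for candidate attC sites (see [attc_config()] for the
#' model). The reported `strand` is the orientation in which the R''..R'
#' consensus reads 5'->3' (the cassette orientation); `bs_strand` is the
#' opposite strand, whose folded bottom strand is the recombinogenic hairpin.
#' Overlapping candidates are resolved greedily by score, then leftmost.
#'
#' @param seq Nucleotide string.
#' @param config An [attc_config()].
#' @param seq_id Identifier used in the output.
#' @return Tibble of sites with box coordinates (top strand, 1-based
#'   inclusive), pairing fractions, bottom-strand fold score and total score.
#' @export
scan_attc <- function(seq, config = attc_config(), seq_id = "seq") {
  seq <- toupper(seq)
  n <- nchar(seq)
  fwd <- .scan_attc_one(seq, config, "+")
  rev <- .scan_attc_one(revcomp(seq), config, "-")
  if (!is.null(rev)) {
    rev <- .mirror_coords(rev, n, list(
      c("start", "end"), c("r2_start", "r2_end"), c("l2_start", "l2_end"),
      c("l1_start", "l1_end"), c("r1_start", "r1_end")
    ))
  }
  sites <- bind_rows(fwd, rev)
  if (nrow(sites) == 0) return(.empty_attc())
  sites <- sites |> arrange(desc(.data$score), .data$start)
  keep <- logical(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    kept <- sites[keep, ]
    ov <- pmin(kept$end, sites$end[k]) - pmax(kept$start, sites$start[k]) + 1
    keep[k] <- all(ov <= 0)
  }
  sites <- sites[keep, ] |> arrange(.data$start)
  sites$bs_strand <- ifelse(sites$strand == "+", "-", "+")
  sites$seq_id <- seq_id
  sites |> select(names(.empty_attc()))
}

#' Cluster attC sites into integron loci / CALINs
#'
#' Single-linkage chaining: successive sites whose gap is at most
#' `threshold_bp` join one locus; loci with fewer than 2 sites are discarded.
#' The gap between successive sites is the number of bases strictly between
#' them (`start(next) - end(prev) - 1`).
#'
#' @param sites Tibble from [scan_attc()] (a single `seq_id`).
#' @param threshold_bp Maximum gap (default 8000).
#' @return Tibble with one row per locus: `locus_id`, `seq_id`, `start`,
#'   `end`, `n_sites`, and list-column `sites`.
#' @export
cluster_attc <- function(sites, threshold_bp = 8000) {
  if (nrow(sites) == 0) {
    return(tibble(locus_id = character(), seq_id = character(),
                  start = integer(), end = integer(), n_sites = integer(),
                  sites = list()))
  }
  if (length(unique(sites$seq_id)) > 1) {
    abort("cluster_attc expects sites from a single sequence",
          class = "calintron_input_error")
  }
  sites <- sites |> arrange(.data$start)
  gap <- sites$start[-1] - sites$end[-nrow(sites)] - 1L
  locus <- cumsum(c(0L, as.integer(gap > threshold_bp)))
  grp <- split(seq_len(nrow(sites)), locus)
  grp <- grp[vapply(grp, length, integer(1)) >= 2]
  if (length(grp) == 0) {
    return(tibble(locus_id = character(), seq_id = character(),
                  start = integer(), end = integer(), n_sites = integer(),
                  sites = list()))
  }
  purrr::imap_dfr(unname(grp), function(idx, i) {
    sub <- sites[idx, ]
    tibble(
      locus_id = paste0(sub$seq_id[1], "_locus", i),
      seq_id = sub$seq_id[1],
      start = min(sub$start), end = max(sub$end),
      n_sites = nrow(sub), sites = list(sub)
    )
  })
}

#' Delineate gene cassettes within integron loci
#'
#' One cassette per inter-site segment, plus the leader segment preceding the
#' first site (up to `leader_bp`). ORFs are assigned to the cassette
#' containing their midpoint; ORFs extending beyond their cassette are
#' flagged boundary-spanning.
#'
#' @param loci Tibble from [cluster_attc()].
#' @param orfs Tibble from [find_orfs()] for the same sequence.
#' @param leader_bp Leader segment length before the first site (default 2000).
#' @return `loci` with a `cassettes` list-column (tibbles with `cassette`,
#'   `start`, `end`, `n_orfs` and an `orfs` list-column carrying a
#'   `boundary_spanning` flag).
#' @export
delineate_cassettes <- function(loci, orfs, leader_bp = 2000) {
  if (nrow(loci) == 0) { loci$cassettes <- list(); return(loci) }
  loci$cassettes <- purrr::map(seq_len(nrow(loci)), function(i) {
    st <- loci$sites[[i]] |> arrange(.data$start)
    k <- nrow(st)
    seg_start <- c(max(1L, st$start[1] - leader_bp),
                   if (k > 1) st$end[-k] + 1L)
    seg_end <- c(st$start[1] - 1L, if (k > 1) st$start[-1] - 1L)
    purrr::map_dfr(seq_along(seg_start), function(ci) {
      a <- seg_start[ci]; b <- seg_end[ci]
      sub <- orfs |>
        filter((.data$start + .data$end) / 2 >= a,
               (.data$start + .data$end) / 2 <= b) |>
        mutate(boundary_spanning = .data$start < a | .data$end > b)
      tibble(cassette = ci, start = a, end = b,
             n_orfs = nrow(sub), orfs = list(sub))
    })
  })
  loci
}

#' Classify a locus as complete integron or CALIN
#'
#' A locus is a complete integron when an ORF within `window_bp` of the locus
#' ends aligns to an integron-integrase (intI) reference at or above the
#' identity and reference-coverage thresholds; otherwise it is a CALIN
#' (cluster of attC sites lacking a neighboring integrase).
#'
#' @param loci Tibble from [cluster_attc()].
#' @param orfs ORF tibble with `protein` column for the same sequence.
#' @param intI_refs Reference panel tibble with `id` and `protein` columns.
#' @param window_bp Search window beyond the locus ends (default 10000).
#' @param min_identity,min_ref_coverage Homology thresholds (defaults 35%
#'   identity over 70% of the reference).
#' @return `loci` with `classification`, `intI_start`, `intI_end`,
#'   `intI_identity` columns.
#' @export
classify_locus <- function(loci, orfs, intI_refs, window_bp = 10000,
                           min_identity = 35, min_ref_coverage = 0.7) {
  if (is.null(intI_refs) || nrow(intI_refs) == 0) {
    abort("empty intI reference panel", class = "calintron_config_error")
  }
  loci$classification <- NA_character_
  loci$intI_start <- NA_integer_
  loci$intI_end <- NA_integer_
  loci$intI_identity <- NA_real_
  pk <- .panel_kmers(intI_refs)
  for (i in seq_len(nrow(loci))) {
    win <- orfs |>
      filter(.data$end >= loci$start[i] - window_bp,
             .data$start <= loci$end[i] + window_bp,
             nchar(.data$protein) >= 100)
    hit <- NULL
    for (j in seq_len(nrow(win))) {
      h <- .best_panel_hit(win$protein[j], intI_refs,
                           min_identity, min_ref_coverage, panel_kmers = pk)
      if (!is.null(h) && (is.null(hit) || h$aln$score > hit$h$aln$score)) {
        hit <- list(h = h, row = win[j, ])
      }
    }
    if (!is.null(hit)) {
      loci$classification[i] <- "complete_integron"
      loci$intI_start[i] <- hit$row$start
      loci$intI_end[i] <- hit$row$end
      loci$intI_identity[i] <- hit$h$aln$identity
    } else {
      loci$classification[i] <- "CALIN"
    }
  }
  loci
}
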