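# Group II intron annotation: IEP detection against a labelled reference
# panel, ribozyme 3'/5' boundary inference, DIV basal stem, EBS-IBS target
# pairing, IIC-attC context and integrity calling.

.to_coding <- function(pos, n, strand) if (strand == "-") n - pos + 1L else pos

.coding_seq <- function(seq, strand) if (strand == "-") revcomp(seq) else seq

.motif_at <- function(s, pattern, pos) {
  m <- nchar(pattern)
  if (pos < 1 || pos + m - 1 > nchar(s)) return(FALSE)
  win <- .codes_of(substr(s, pos, pos + m - 1))
  pat <- .codes_of(pattern, "pattern")
  all(bitwAnd(win, pat) > 0L)
}

.domain_status <- function(frac) {
  ifelse(frac >= 0.8, "present", ifelse(frac >= 0.2, "partial", "absent"))
}

.orf_domain_coverage <- function(aln, ref_domains, query_protein) {
  purrr::map_dfr(seq_len(nrow(ref_domains)), function(d) {
    rng <- ref_domains$start[d]:ref_domains$end[d]
    aligned <- aln$map[rng]
    frac <- mean(!is.na(aligned))
    tibble(domain = ref_domains$domain[d], frac = frac,
           status = .domain_status(frac),
           q_start = if (any(!is.na(aligned))) min(aligned, na.rm = TRUE) else NA_integer_,
           q_end = if (any(!is.na(aligned))) max(aligned, na.rm = TRUE) else NA_integer_)
  })
}

#' Detect intron-encoded proteins (IEPs) among ORFs
#'
#' Aligns each ORF protein against a labelled IEP reference panel
#' (Biostrings local alignment, BLOSUM62), reports the best reference with
#' identity/similarity, projects the reference RT0-RT7/X/En domain
#' coordinates through the alignment to obtain per-domain coverage, and
#' locates the catalytic YADD motif within the projected RT5 region.
#' Same-strand ORF fragments matching the same reference within `merge_gap`
#' bp are merged into one hit; the number of joins is reported as
#' `frame_disruptions` (internal stops / frameshifts split naive ORFs).
#'
#' @param orfs ORF tibble from [find_orfs()] (needs `protein`).
#' @param iep_refs Panel tibble with `id`, `class`, `protein`, `domains`
#'   (domain annotations are required).
#' @param min_identity,min_ref_coverage Reporting thresholds.
#' @param min_aa Minimum ORF protein length considered (default 150).
#' @param merge_gap Maximum genomic gap when merging fragments (default 600).
#' @return Tibble of IEP hits with `orf_start`, `orf_end`, `strand`,
#'   `best_ref`, `class`, `identity`, `similarity`, `yadd`,
#'   `frame_disruptions`, `n_parts`, list-columns `domains` and `parts`.
#' @export
detect_iep <- function(orfs, iep_refs, min_identity = 40,
                       min_ref_coverage = 0.2, min_aa = 150, merge_gap = 600) {
  if (is.null(iep_refs) || nrow(iep_refs) == 0 ||
      any(vapply(iep_refs$domains, nrow, integer(1)) == 0)) {
    abort("IEP reference panel must carry domain annotations",
          class = "calintron_config_error")
  }
  cand <- orfs |> filter(nchar(.data$protein) >= min_aa)
  pk <- .panel_kmers(iep_refs)
  per_orf <- list()
  for (i in seq_len(nrow(cand))) {
    hit <- .best_panel_hit(cand$protein[i], iep_refs,
                           min_identity, min_ref_coverage, panel_kmers = pk)
    if (is.null(hit)) next
    dom <- .orf_domain_coverage(hit$aln, hit$ref$domains[[1]], cand$protein[i])
    rt5 <- dom |> filter(.data$domain == "RT5")
    yadd <- FALSE
    if (nrow(rt5) == 1 && rt5$status != "absent" && !is.na(rt5$q_start)) {
      reg <- substr(cand$protein[i], max(1, rt5$q_start - 3), rt5$q_end + 3)
      yadd <- grepl("YADD", reg, fixed = TRUE)
    }
    per_orf[[length(per_orf) + 1L]] <- tibble(
      orf_start = cand$start[i], orf_end = cand$end[i],
      strand = cand$strand[i],
      best_ref = hit$ref$id, class = hit$ref$class,
      identity = hit$aln$identity, similarity = hit$aln$similarity,
      score = hit$aln$score, yadd = yadd,
      domains = list(dom), protein = cand$protein[i],
      orf_row = list(cand[i, ])
    )
  }
  if (length(per_orf) == 0) {
    return(tibble(orf_start = integer(), orf_end = integer(),
                  strand = character(), best_ref = character(),
                  class = character(), identity = numeric(),
                  similarity = numeric(), yadd = logical(),
                  frame_disruptions = integer(), n_parts = integer(),
                  domains = list(), protein = character(), parts = list()))
  }
  hits <- bind_rows(per_orf) |> arrange(.data$strand, .data$best_ref, .data$orf_start)
  # merge same-strand fragments hitting the same reference
  out <- list()
  grp_key <- paste(hits$strand, hits$best_ref)
  for (g in split(seq_len(nrow(hits)), grp_key)) {
    sub <- hits[g, ] |> arrange(.data$orf_start)
    chain <- cumsum(c(0L, as.integer(
      sub$orf_start[-1] - sub$orf_end[-nrow(sub)] - 1L > merge_gap)))
    for (cc in split(seq_len(nrow(sub)), chain)) {
      parts <- sub[cc, ]
      dom <- parts$domains[[1]]
      if (nrow(parts) > 1) {
        fr <- purrr::map(parts$domains, "frac")
        frac <- pmin(1, Reduce(`+`, fr))
        dom$frac <- frac
        dom$status <- .domain_status(frac)
      }
      best <- which.max(parts$score)
      out[[length(out) + 1L]] <- tibble(
        orf_start = min(parts$orf_start), orf_end = max(parts$orf_end),
        strand = parts$strand[1],
        best_ref = parts$best_ref[1], class = parts$class[1],
        identity = parts$identity[best], similarity = parts$similarity[best],
        yadd = any(parts$yadd),
        frame_disruptions = nrow(parts) - 1L, n_parts = nrow(parts),
        domains = list(dom),
        protein = paste(parts$protein, collapse = "/"),
        parts = list(bind_rows(parts$orf_row))
      )
    }
  }
  bind_rows(out) |> arrange(.data$orf_start)
}

#' Classify an intron by nearest-reference IEP identity
#'
#' The class of the best-matching reference wins if it beats the best
#' reference of any other class by at least `margin` identity points;
#' otherwise the call is `"ambiguous"` with the top two classes listed.
#'
#' @param protein IEP protein sequence.
#' @param iep_refs Labelled panel.
#' @param margin Identity margin in percentage points (default 5).
#' @return One-row tibble with `call`, `best_class`, `best_identity`,
#'   `runner_class`, `runner_identity`.
#' @export
classify_intron <- function(protein, iep_refs, margin = 5) {
  qp <- gsub("/", "", protein, fixed = TRUE)
  many <- .align_protein_many(qp, iep_refs$protein)
  per_class <- tibble(class = iep_refs$class, identity = many$identity) |>
    group_by(.data$class) |>
    summarise(identity = max(.data$identity), .groups = "drop") |>
    arrange(desc(.data$identity))
  if (nrow(per_class) < 2) {
    abort("classification needs references from at least 2 classes",
          class = "calintron_config_error")
  }
  best <- per_class[1, ]; runner <- per_class[2, ]
  tibble(
    call = if (best$identity - runner$identity >= margin) best$class else "ambiguous",
    best_class = best$class, best_identity = best$identity,
    runner_class = runner$class, runner_identity = runner$identity
  )
}

.shift_hairpin <- function(h, off) {
  h$start <- h$start + off; h$end <- h$end + off
  h$loop_start <- h$loop_start + off; h$loop_end <- h$loop_end + off
  h$bulge_info <- list(purrr::map(h$bulge_info[[1]], function(b) {
    b$start <- b$start + off; b$end <- b$end + off; b
  }))
  h
}

#' Infer DV, DVI and the 3' boundary of a group II intron
#'
#' Searches the window downstream of the IEP ORF for the best-scoring pair
#' of adjacent hairpins where the first (DV) contains the catalytic triad
#' (AGC, or CGC for class C/IIC introns) in its 5' arm plus an AY bulge, and
#' the second (DVI) contains a bulged A. The 3' terminus is the first
#' position after DVI matching the `AXX(X)XRAY` consensus; relaxation tiers
#' (`"ay"`: any 2-mer ending A-pyrimidine; `"any"`: any 2-mer, flagged)
#' handle deviant boundaries.
#'
#' @param seq Top-strand nucleotide string.
#' @param iep_hit One row of [detect_iep()] output.
#' @param window_bp Search window downstream of the ORF (default 400).
#' @param intron_class Class label; `"C"`/`"IIC"` selects the CGC triad.
#' @param relax `"none"`, `"ay"` or `"any"`.
#' @param max_pair_gap Maximum DV-DVI gap (default 40).
#' @return List with `dv`, `dvi`, `three_prime` (top strand),
#'   `three_prime_coding`, `terminus_tier`, `deviant`; or `NULL` when no
#'   qualifying helix pair exists (3' unresolved).
#' @export
find_three_prime_end <- function(seq, iep_hit, window_bp = 400,
                                 intron_class = "CL1", relax = "none",
                                 max_pair_gap = 40) {
  relax <- match.arg(relax, c("none", "ay", "any"))
  n <- nchar(seq)
  cs <- .coding_seq(seq, iep_hit$strand)
  oe <- .to_coding(if (iep_hit$strand == "+") iep_hit$orf_end else iep_hit$orf_start,
                   n, iep_hit$strand)
  triad <- if (intron_class %in% c("C", "IIC")) "CGC" else "AGC"
  # DV/DVI sit close to the ORF end; scan a proximal window first and fall
  # back to the full window only when nothing qualifies
  for (wb in unique(c(min(150L, window_bp), window_bp))) {
    res <- .find_three_prime_window(cs, n, oe, wb, triad, relax,
                                    max_pair_gap, iep_hit$strand)
    if (!is.null(res)) return(res)
  }
  NULL
}

.find_three_prime_window <- function(cs, n, oe, window_bp, triad, relax,
                                     max_pair_gap, strand) {
  win_end <- min(n, oe + window_bp)
  if (win_end - oe < 30) return(NULL)
  win <- substr(cs, oe + 1L, win_end)
  hp <- find_stem_loops(win, min_stem = 5, loop_range = c(3, 12),
                        max_bulge = 1, max_bulge_len = 3, dedup = FALSE)
  if (nrow(hp) < 2) return(NULL)
  hp <- hp |> arrange(.data$start, .data$end)
  best <- NULL
  better <- function(cand, cur) {
    # DV lies immediately downstream of the ORF (DIV); the 3' terminus abuts
    # DVI. Prefer the proximal DV, then the pair whose terminus starts
    # closest after DVI, then the stricter terminus tier, then proximal DVI.
    if (is.null(cur)) return(TRUE)
    key <- function(x) c(x$h1$start, x$offset, x$tier, x$h2$start)
    a <- key(cand); b <- key(cur)
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  for (i in seq_len(nrow(hp) - 1)) {
    if (!is.null(best) && hp$start[i] > best$h1$start) break
    for (j in seq_len(nrow(hp))) {
      if (j == i) next
      h1 <- hp[i, ]; h2 <- hp[j, ]
      gap <- h2$start - h1$end - 1L
      if (gap < 0 || gap > max_pair_gap) next
      arm1 <- substr(win, h1$start, h1$loop_start - 1L)
      if (!grepl(triad, arm1, fixed = TRUE)) next
      b1 <- vapply(h1$bulge_info[[1]], function(b) b$seq, "")
      if (!any(grepl("A[CT]|[CT]A", b1))) next
      b2 <- h2$bulge_info[[1]]
      a_b <- vapply(b2, function(b) grepl("A", b$seq, fixed = TRUE), logical(1))
      if (!any(a_b)) next
      tp <- NULL; tier <- NA_integer_; o_found <- NA_integer_
      for (o in (h2$end + 1L):(h2$end + 10L)) {
        if (.motif_at(win, "ANNNNRAY", o)) { tp <- o + 7L; tier <- 1L; o_found <- o; break }
        if (.motif_at(win, "ANNNRAY", o)) { tp <- o + 6L; tier <- 1L; o_found <- o; break }
      }
      if (is.null(tp) && relax %in% c("ay", "any")) {
        for (o in (h2$end + 1L):(h2$end + 10L)) {
          if (.motif_at(win, "AY", o)) { tp <- o + 1L; tier <- 2L; o_found <- o; break }
        }
      }
      if (is.null(tp) && relax == "any") {
        tp <- h2$end + 2L; tier <- 3L; o_found <- h2$end + 1L
      }
      if (is.null(tp) || tp > nchar(win)) next
      cand <- list(h1 = h1, h2 = h2, tp = tp, tier = tier,
                   offset = o_found - h2$end - 1L,
                   bulged_a = b2[a_b][[1]])
      if (better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  off <- oe
  h1 <- .shift_hairpin(best$h1, off); h2 <- .shift_hairpin(best$h2, off)
  tp_c <- best$tp + off
  list(
    dv = list(start_c = h1$start, end_c = h1$end,
              start = min(.to_coding(h1$start, n, strand),
                          .to_coding(h1$end, n, strand)),
              end = max(.to_coding(h1$start, n, strand),
                        .to_coding(h1$end, n, strand)),
              stem_pairs = h1$stem_pairs, score = h1$score,
              triad = triad, ay_bulge = TRUE),
    dvi = list(start_c = h2$start, end_c = h2$end,
               start = min(.to_coding(h2$start, n, strand),
                           .to_coding(h2$end, n, strand)),
               end = max(.to_coding(h2$start, n, strand),
                         .to_coding(h2$end, n, strand)),
               stem_pairs = h2$stem_pairs, score = h2$score,
               bulged_a_pos_c = best$bulged_a$start + off),
    three_prime_coding = tp_c,
    three_prime = .to_coding(tp_c, n, strand),
    terminus_tier = best$tier,
    deviant = best$tier > 1L
  )
}

#' Infer the 5' boundary of a group II intron
#'
#' Scans the window upstream of the IEP ORF for the GUGYG consensus
#' (`max_mismatch` tolerated, deviants flagged). Because short motifs recur
#' by chance, candidates are ranked and gated by target-site support: for
#' class C/IIC, the TTGT junction plus an upstream stem-loop (the attC
#' bottom-strand signature); for other classes, exact EBS1 and EBS2
#' complements of the implied IBS1/IBS2 within the proximal DI region.
#' With `require_support = TRUE` (default) an unsupported motif hit is not
#' accepted and the boundary stays unresolved (candidate truncation).
#'
#' @param seq Top-strand nucleotide string.
#' @param iep_hit One row of [detect_iep()] output.
#' @param window_bp Search window upstream of the ORF (default 3000).
#' @param max_mismatch GUGYG mismatch budget (default 1).
#' @param intron_class Class label.
#' @param require_support Gate acceptance on target-site support.
#' @param di_cap Proximal DI span searched for EBS complements (default 600).
#' @return List with `position` (top strand), `position_coding`,
#'   `mismatches`, `deviant`, `support` and a `candidates` tibble; `NULL`
#'   when no supported candidate exists.
#' @export
find_five_prime_end <- function(seq, iep_hit, window_bp = 3000,
                                max_mismatch = 1, intron_class = "CL1",
                                require_support = TRUE, di_cap = 600) {
  n <- nchar(seq)
  cs <- .coding_seq(seq, iep_hit$strand)
  os <- .to_coding(if (iep_hit$strand == "+") iep_hit$orf_start else iep_hit$orf_end,
                   n, iep_hit$strand)
  win_start <- max(14L, os - window_bp)
  win_end <- os - 30L
  if (win_end <= win_start) return(NULL)
  sub <- substr(cs, win_start, win_end)
  cand <- iupac_scan(sub, "GTGYG", max_mismatch, strand = "+")
  if (nrow(cand) == 0) return(NULL)
  iic <- intron_class %in% c("C", "IIC")
  rows <- purrr::map_dfr(seq_len(nrow(cand)), function(k) {
    p <- cand$start[k] + win_start - 1L
    support <- 0L
    if (iic) {
      jun4 <- substr(cs, p - 4L, p - 1L)
      jun_ok <- if (identical(jun4, "TTGT")) 2L
                else if (identical(substr(jun4, 2, 4), "TGT")) 1L else 0L
      if (jun_ok > 0L) {
        # only junction-consistent candidates pay for the hairpin scan
        w_from <- max(1L, p - 80L)
        hps <- find_stem_loops(substr(cs, w_from, p - 1L), min_stem = 5)
        if (nrow(hps) > 0 && any(hps$end + w_from - 1L >= p - 30L)) {
          support <- jun_ok
        }
      }
    } else {
      ibs1 <- substr(cs, p - 6L, p - 1L)
      ibs2 <- substr(cs, p - 12L, p - 7L)
      di_to <- min(p + di_cap, os - 1L)
      if (di_to > p + 5L && nchar(ibs1) == 6) {
        di <- substr(cs, p + 5L, di_to)
        e1 <- gregexpr(revcomp(ibs1), di, fixed = TRUE)[[1]]
        if (e1[1] != -1) {
          support <- 1L
          for (q in as.integer(e1)) {
            lo <- max(1L, q - 26L)
            if (q > 1 &&
                grepl(revcomp(ibs2), substr(di, lo, q - 1L), fixed = TRUE)) {
              support <- 2L; break
            }
          }
        }
      }
    }
    tibble(position_coding = p, mismatches = cand$mismatches[k],
           support = support)
  })
  # DI fold-compatibility density is only needed to break ties among
  # equally supported minimum-mismatch candidates
  rows <- rows |> arrange(.data$mismatches, desc(.data$support))
  top_tie <- rows$mismatches == rows$mismatches[1] &
    rows$support == rows$support[1]
  rows$fold_density <- 0
  for (k in which(top_tie)) {
    p <- rows$position_coding[k]
    dens_to <- min(p + 150L, os)
    if (dens_to - p > 20) {
      rows$fold_density[k] <-
        2 * nussinov_fold(substr(cs, p, dens_to))$max_pairs / (dens_to - p + 1)
    }
  }
  rows <- rows |>
    arrange(.data$mismatches, desc(.data$support), desc(.data$fold_density),
            .data$position_coding)
  need <- if (iic) 1L else 2L
  acc <- if (require_support) rows |> filter(.data$support >= need) else rows
  if (nrow(acc) == 0) return(NULL)
  top <- acc[1, ]
  list(position = .to_coding(top$position_coding, n, iep_hit$strand),
       position_coding = top$position_coding,
       mismatches = top$mismatches, deviant = top$mismatches > 0,
       support = top$support, candidates = rows)
}

#' Locate the DIV basal stem
#'
#' Finds the best antiparallel complement (>= 6 bp, <= 1 mismatch; longer
#' then leftmost wins) between the k-mer immediately 5' of DV and any window
#' inside the IEP ORF or within `upstream_bp` of the ORF start.
#'
#' @param seq Top-strand nucleotide string.
#' @param iep_hit One row of [detect_iep()] output.
#' @param dv The `dv` element from [find_three_prime_end()].
#' @param upstream_bp Window upstream of the ORF start (default 200).
#' @param k Length of the anchor just upstream of DV (default 8).
#' @return List with `upstream_c`, `partner_c` (coding coordinate pairs),
#'   `length`, `mismatches`; or `NULL`.
#' @export
find_div_basal_stem <- function(seq, iep_hit, dv, upstream_bp = 200, k = 8) {
  n <- nchar(seq)
  cs <- .coding_seq(seq, iep_hit$strand)
  os <- .to_coding(if (iep_hit$strand == "+") iep_hit$orf_start else iep_hit$orf_end,
                   n, iep_hit$strand)
  oe <- .to_coding(if (iep_hit$strand == "+") iep_hit$orf_end else iep_hit$orf_start,
                   n, iep_hit$strand)
  if (dv$start_c - k < 1) return(NULL)
  u <- substr(cs, dv$start_c - k, dv$start_c - 1L)
  sp_from <- max(1L, os - upstream_bp); sp_to <- oe
  space <- substr(cs, sp_from, sp_to)
  for (L in seq.int(k, 6)) {
    uL <- substr(u, k - L + 1L, k)
    mm_allow <- if (L > 6) 1L else 0L
    hits <- iupac_scan(space, revcomp(uL), mm_allow, strand = "+")
    if (nrow(hits) > 0) {
      hits <- hits |> arrange(.data$mismatches, .data$start)
      h <- hits[1, ]
      return(list(
        upstream_c = c(dv$start_c - L, dv$start_c - 1L),
        partner_c = c(h$start + sp_from - 1L, h$end + sp_from - 1L),
        length = L, mismatches = h$mismatches
      ))
    }
  }
  NULL
}

#' Map EBS-IBS target-site pairings
#'
#' IBS1 is the last 6 nt of the 5' exon (3-4 nt for class C/IIC), IBS2 the 6
#' nt preceding IBS1 (not reported for IIC). The proximal DI region is
#' searched for antiparallel complements (EBS1/EBS2, <= 1 mismatch); EBS3 is
#' a single base complementary to the first nt of the 3' exon, looked up in
#' the window immediately 5' of EBS1.
#'
#' @param model List with `five_prime_coding`, `three_prime_coding`,
#'   `orf_start_coding` set (see [annotate_introns()]).
#' @param seq Top-strand nucleotide string.
#' @param intron_class Class label.
#' @param di_cap Proximal DI span searched (default 600).
#' @return List report; `computable = FALSE` when a boundary is unresolved.
#' @export
map_ebs_ibs <- function(model, seq, intron_class = "CL1", di_cap = 600) {
  if (is.null(model$five_prime_coding) || is.null(model$three_prime_coding)) {
    return(list(computable = FALSE))
  }
  cs <- .coding_seq(seq, model$strand)
  fp <- model$five_prime_coding; tp <- model$three_prime_coding
  os <- model$orf_start_coding
  iic <- intron_class %in% c("C", "IIC")
  di_to <- min(fp + di_cap, if (!is.null(os)) os - 1L else fp + di_cap)
  di <- substr(cs, fp + 5L, di_to)
  find_ebs <- function(ibs) {
    hits <- iupac_scan(di, revcomp(ibs), 1, strand = "+")
    if (nrow(hits) == 0) return(NULL)
    hits <- hits |> arrange(.data$mismatches, .data$start)
    h <- hits[1, ]
    list(start_c = h$start + fp + 4L, end_c = h$end + fp + 4L,
         mismatches = h$mismatches)
  }
  ibs1 <- NULL; ebs1 <- NULL; len1_used <- NA_integer_
  for (len1 in if (iic) c(4L, 3L) else 6L) {
    ibs1_try <- substr(cs, fp - len1, fp - 1L)
    e <- find_ebs(ibs1_try)
    if (!is.null(e)) { ibs1 <- ibs1_try; ebs1 <- e; len1_used <- len1; break }
  }
  ibs2_rep <- NULL
  if (!iic && !is.null(ebs1)) {
    ibs2 <- substr(cs, fp - 12L, fp - 7L)
    reg_lo <- max(1L, (ebs1$start_c - fp - 4L) - 26L)
    reg <- substr(di, reg_lo, ebs1$start_c - fp - 5L)
    hits <- iupac_scan(reg, revcomp(ibs2), 1, strand = "+")
    if (nrow(hits) > 0) {
      hits <- hits |> arrange(.data$mismatches, desc(.data$start))
      h <- hits[1, ]
      ibs2_rep <- list(matched_len = 6L, mismatches = h$mismatches,
                       start_c = h$start + reg_lo + fp + 3L)
    }
  }
  ebs3 <- list(found = NA, position_c = NA_integer_)
  if (!is.null(ebs1)) {
    b3 <- substr(cs, tp + 1L, tp + 1L)
    w_from <- max(1L, ebs1$start_c - 8L)
    wchars <- strsplit(substr(cs, w_from, ebs1$start_c - 1L), "")[[1]]
    hit <- which(vapply(wchars, .pairable, logical(1), b = b3))
    ebs3 <- list(found = length(hit) > 0,
                 position_c = if (length(hit)) w_from + hit[length(hit)] - 1L
                              else NA_integer_)
  }
  list(
    computable = TRUE,
    ibs1 = if (!is.null(ebs1))
      list(matched_len = len1_used, mismatches = ebs1$mismatches,
           ebs1_start_c = ebs1$start_c, ebs1_end_c = ebs1$end_c)
      else list(matched_len = 0L, mismatches = NA_integer_),
    ibs2 = ibs2_rep,
    ebs3 = ebs3,
    upstream_hairpin = .best_hairpin(cs, fp - 80L, fp - 1L, min_stem = 5)
  )
}

#' Check the IIC-attC insertion context of an intron
#'
#' Flags whether the intron junction lies within/immediately at an attC
#' bottom-strand stem-loop, whether the junction matches the TTGT/T
#' consensus on the intron coding strand, and whether the intron runs
#' opposite to the cassette orientation of the nearest attC site.
#'
#' @param model Intron model list (needs coding boundaries and `strand`).
#' @param attc_sites Tibble from [scan_attc()].
#' @param seq Top-strand nucleotide string.
#' @param max_dist Maximum distance to the nearest attC site (default 1000).
#' @return One-row tibble of flags plus nearest-site info.
#' @export
check_iic_attc_context <- function(model, attc_sites, seq, max_dist = 1000) {
  none <- tibble(attc_adjacent = FALSE, inside_attc_bs = FALSE,
                 ttgt_junction = FALSE, orientation_opposite = FALSE,
                 nearest_site_start = NA_integer_, distance = NA_integer_)
  if (is.null(attc_sites) || nrow(attc_sites) == 0) return(none)
  istart <- min(model$start, model$end); iend <- max(model$start, model$end)
  d <- pmax(0L, pmax(attc_sites$start - iend, istart - attc_sites$end))
  k <- which.min(d)
  if (d[k] > max_dist) return(none)
  site <- attc_sites[k, ]
  n <- nchar(seq)
  cs <- .coding_seq(seq, model$strand)
  fp <- model$five_prime_coding
  junction_top <- if (!is.null(fp)) .to_coding(fp, n, model$strand) else istart
  inside <- junction_top >= site$start - 20L & junction_top <= site$end + 20L
  ttgt <- FALSE
  if (!is.null(fp) && !is.null(model$three_prime_coding)) {
    ttgt <- identical(substr(cs, fp - 4L, fp - 1L), "TTGT") &&
      identical(substr(cs, model$three_prime_coding + 1L,
                       model$three_prime_coding + 1L), "T")
  }
  tibble(attc_adjacent = TRUE, inside_attc_bs = inside,
         ttgt_junction = ttgt,
         orientation_opposite = model$strand != site$strand,
         nearest_site_start = site$start, distance = d[k])
}

#' Call intron integrity
#'
#' `full`: both boundaries resolved, all RT0-RT7 and X domains present, no
#' frame disruptions. `five_prime_truncated`: 3' end resolved, no internal
#' disruptions, and either the 5' boundary is unresolved or the IEP's
#' N-terminal domain run is absent (the protein evidence outweighs a bare
#' upstream motif hit). Everything else is `fragmented`.
#'
#' @param model Intron model list.
#' @param iep_hit One row of [detect_iep()] output.
#' @return `"full"`, `"five_prime_truncated"` or `"fragmented"`.
#' @export
call_integrity <- function(model, iep_hit) {
  dom <- iep_hit$domains[[1]]
  core <- dom |> filter(.data$domain %in% c(paste0("RT", 0:7), "X"))
  all_present <- all(core$status == "present")
  rt_order <- core$status[match(paste0("RT", 0:7), core$domain)]
  lead_absent <- cumprod(rt_order == "absent")
  nterm_truncated <- sum(lead_absent, na.rm = TRUE) >= 2
  disrupted <- iep_hit$frame_disruptions > 0
  three_ok <- !is.null(model$three_prime_coding)
  five_ok <- !is.null(model$five_prime_coding)
  if (three_ok && five_ok && all_present && !disrupted) return("full")
  if (three_ok && !disrupted && (!five_ok || nterm_truncated)) {
    return("five_prime_truncated")
  }
  "fragmented"
}

#' Annotate group II introns on a sequence
#'
#' End-to-end intron annotation: IEP detection, class call, 3' boundary
#' (DV/DVI + terminus), DIV basal stem, 5' boundary (class-aware,
#' support-gated), EBS-IBS mapping, attC context and integrity. When the
#' IEP's N-terminal domains are absent the 5' boundary is reported
#' unresolved even if unsupported motif candidates exist.
#'
#' @param seq Top-strand nucleotide string.
#' @param iep_refs Labelled IEP panel with domain annotations.
#' @param seq_id Sequence identifier.
#' @param orfs Optional precomputed ORFs (default: `find_orfs(seq, 600)`).
#' @param attc_sites Optional [scan_attc()] output for context flags.
#' @param relax_three_prime Relaxation tier passed to
#'   [find_three_prime_end()].
#' @return List of `intron_model` objects.
#' @export
annotate_introns <- function(seq, iep_refs, seq_id = "seq", orfs = NULL,
                             attc_sites = NULL, relax_three_prime = "none") {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (is.null(orfs)) orfs <- find_orfs(seq, min_len = 600)
  hits <- detect_iep(orfs, iep_refs)
  models <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    cls <- classify_intron(hit$protein, iep_refs)
    class_rule <- if (cls$call == "ambiguous") cls$best_class else cls$call
    three <- find_three_prime_end(seq, hit, intron_class = class_rule,
                                  relax = relax_three_prime)
    div_stem <- if (!is.null(three))
      find_div_basal_stem(seq, hit, three$dv) else NULL
    dom <- hit$domains[[1]]
    rt01 <- dom$status[match(c("RT0", "RT1"), dom$domain)]
    nterm_gone <- all(rt01 == "absent")
    five <- if (!nterm_gone)
      find_five_prime_end(seq, hit, intron_class = class_rule) else NULL
    os_c <- .to_coding(if (hit$strand == "+") hit$orf_start else hit$orf_end,
                       n, hit$strand)
    model <- list(
      seq_id = seq_id, seq_length = n, strand = hit$strand,
      class_call = cls,
      iep = hit,
      orf_start_coding = os_c,
      five_prime = if (!is.null(five)) five$position else NULL,
      five_prime_coding = if (!is.null(five)) five$position_coding else NULL,
      five_prime_mismatches = if (!is.null(five)) five$mismatches else NA_integer_,
      five_prime_deviant = if (!is.null(five)) five$deviant else NA,
      three_prime = if (!is.null(three)) three$three_prime else NULL,
      three_prime_coding = if (!is.null(three)) three$three_prime_coding else NULL,
      terminus_tier = if (!is.null(three)) three$terminus_tier else NA_integer_,
      dv = if (!is.null(three)) three$dv else NULL,
      dvi = if (!is.null(three)) three$dvi else NULL,
      div_basal_stem = div_stem
    )
    # genomic extent: resolved boundaries where available, else ORF limits
    ends_top <- c(
      if (!is.null(model$five_prime)) model$five_prime,
      if (!is.null(model$three_prime)) model$three_prime,
      hit$orf_start, hit$orf_end,
      if (!is.null(model$dv)) c(model$dv$start, model$dv$end)
    )
    model$start <- min(ends_top); model$end <- max(ends_top)
    model$target_site <- map_ebs_ibs(model, seq, intron_class = class_rule)
    model$context <- check_iic_attc_context(model, attc_sites, seq)
    model$orientation_vs_cassettes <-
      if (isTRUE(model$context$attc_adjacent)) {
        if (model$context$orientation_opposite) "opposite" else "same"
      } else NA_character_
    model$integrity <- call_integrity(model, hit)
    class(model) <- "intron_model"
    models[[length(models) + 1L]] <- model
  }
  models
}

#' @export
print.intron_model <- function(x, ...) {
  cat("<intron_model>", x$seq_id, "strand", x$strand, "\n")
  cat("  class:", x$class_call$call,
      sprintf("(best %s %.1f%%)", x$class_call$best_class,
              x$class_call$best_identity), "\n")
  cat("  5':", if (is.null(x$five_prime)) "unresolved" else x$five_prime,
      " 3':", if (is.null(x$three_prime)) "unresolved" else x$three_prime, "\n")
  cat("  integrity:", x$integrity, "\n")
  invisible(x)
}
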