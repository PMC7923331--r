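# Synthetic mobile-element landscapes with planted ground truth. Every
# supported element class can be planted at a known position with known
# internal anchors (boxes, boundaries, EBS positions, hairpin stems), so the
# whole pipeline is testable end to end without external data. Plants are
# assembled from fixed sequence constants (motifs, stems, pads engineered so
# hairpin stems end exactly at their planted base pairs) plus seeded random
# parts (background, cassette proteins); the draw order is background, then
# plants in list order, then mutation.

.ATTC <- list(R2 = "GCCTACC", SP1 = "ACTAC", L2 = "GACTGGC",
              LOOP = "CTTCGAAC", L1 = "GCCAGTC", SP2 = "CCTAT",
              R1 = "GTTAGGC")

.attc_site_seq <- function() {
  paste0(.ATTC$R2, .ATTC$SP1, .ATTC$L2, .ATTC$LOOP, .ATTC$L1, .ATTC$SP2,
         .ATTC$R1)
}

# truth rows for one attC site whose R'' starts at `at` (top strand, "+")
.attc_truth <- function(at, plant_id) {
  w <- vapply(.ATTC, nchar, integer(1))
  off <- cumsum(c(0, unname(w[-length(w)])))
  names(off) <- names(w)
  box <- function(name, feature) {
    tibble(plant_id = plant_id, kind = "attc_site", feature = feature,
           start = at + off[[name]], end = at + off[[name]] + w[[name]] - 1L,
           strand = "+", class = NA_character_)
  }
  bind_rows(
    tibble(plant_id = plant_id, kind = "attc_site", feature = "site",
           start = at, end = at + sum(w) - 1L, strand = "+",
           class = NA_character_),
    box("R2", "box_r2"), box("L2", "box_l2"),
    box("L1", "box_l1"), box("R1", "box_r1")
  )
}

.rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- plant builders: each returns list(seq, truth) in plant-local coords ---

.build_attc_array <- function(n_sites, orf_aa = 140, gc = 0.5,
                              plant_id = "array") {
  site <- .attc_site_seq()
  seqs <- character(0)
  truth <- list()
  pos <- 1L
  for (k in seq_len(n_sites)) {
    truth[[length(truth) + 1L]] <- .attc_truth(pos, plant_id)
    seqs <- c(seqs, site)
    pos <- pos + nchar(site)
    if (k < n_sites) {
      pad1 <- .rand_dna(30, gc)
      orf_nt <- back_translate(paste0("M", .random_protein(orf_aa - 1)))
      pad2 <- .rand_dna(30, gc)
      truth[[length(truth) + 1L]] <- tibble(
        plant_id = plant_id, kind = "cassette_orf", feature = "orf",
        start = pos + 30L, end = pos + 30L + nchar(orf_nt) - 1L,
        strand = "+", class = NA_character_)
      seqs <- c(seqs, pad1, orf_nt, pad2)
      pos <- pos + 60L + nchar(orf_nt)
    }
  }
  list(seq = paste(seqs, collapse = ""), truth = bind_rows(truth))
}

.Z8 <- "GATTCTAA"
.DV_ARM1 <- c(default = "AAGCGCCG", iic = "ACGCGCCG")
.TERMINUS <- "ACCTCGAT"

.dv_seq <- function(iic = FALSE) {
  arm1 <- if (iic) .DV_ARM1[["iic"]] else .DV_ARM1[["default"]]
  rc <- revcomp(arm1)
  arm2 <- paste0(substr(rc, 1, 2), "AC", substr(rc, 3, nchar(rc)))
  paste0(arm1, "GAAA", arm2)
}

.dvi_seq <- function() {
  arm1 <- "GGCAGGCG"
  rc <- revcomp(arm1) # CGCCTGCC
  arm2 <- paste0(substr(rc, 1, 3), "A", substr(rc, 4, 8))
  paste0(arm1, "CAAG", arm2)
}

# Core intron in coding orientation. Returns seq + local anchors.
.build_intron_core <- function(iep_protein, class, include_five = TRUE,
                               ibs1 = "CTTGAC", ibs2 = "GAGTCC",
                               ebs3_present = TRUE) {
  iic <- class %in% c("C", "IIC")
  orf_nt <- back_translate(iep_protein)
  dv <- .dv_seq(iic)
  dvi <- .dvi_seq()
  parts <- character(0)
  anchors <- list()
  add <- function(feature, len, record = TRUE) {
    pos <- sum(nchar(parts)) + 1L
    if (record) anchors[[feature]] <<- c(pos, pos + len - 1L)
    pos
  }
  if (include_five) {
    add("five_prime", 1L); parts <- c(parts, "GTGCG")
    parts <- c(parts, "CCTACCATCACCTCCACA") # pad A (18)
    if (!iic) {
      add("ebs2", 6L); parts <- c(parts, revcomp(ibs2))
      parts <- c(parts, "CCT")
    }
    parts <- c(parts, if (ebs3_present) "CCCACCCC" else "CCCTCCCC")
    add("ebs1", nchar(ibs1)); parts <- c(parts, revcomp(ibs1))
    parts <- c(parts, "CCATCACCTTCACCATCCACCTTCCATCACCATCCTCACC") # pad B (40)
    add("div_partner", 8L); parts <- c(parts, revcomp(.Z8))
    parts <- c(parts, "CCTCACCATCCACCTTCACC") # pad C (20)
  }
  add("orf", nchar(orf_nt)); parts <- c(parts, orf_nt)
  parts <- c(parts, .Z8)
  add("dv", nchar(dv)); parts <- c(parts, dv)
  parts <- c(parts, "CCCC")
  add("dvi", nchar(dvi)); parts <- c(parts, dvi)
  tp <- add("terminus", nchar(.TERMINUS)); parts <- c(parts, .TERMINUS)
  seq <- paste(parts, collapse = "")
  anchors[["three_prime"]] <- c(nchar(seq), nchar(seq))
  anchors[["five_prime"]] <- if (include_five) c(1L, 1L) else NULL
  list(seq = seq, anchors = anchors)
}

.anchor_rows <- function(anchors, kind, plant_id, offset, strand, total_len,
                         class) {
  purrr::imap_dfr(anchors, function(rng, feature) {
    if (is.null(rng)) return(tibble())
    if (strand == "+") {
      s <- offset + rng[1] - 1L; e <- offset + rng[2] - 1L
    } else {
      # plant-local coding coords on the minus strand of a segment of length
      # total_len starting at `offset` on the top strand
      s <- offset + total_len - rng[2]
      e <- offset + total_len - rng[1]
    }
    tibble(plant_id = plant_id, kind = kind, feature = feature,
           start = s, end = e, strand = strand, class = class)
  })
}

.build_iib_intron <- function(iep_refs, truncated = FALSE,
                              ebs3_present = TRUE, plant_id = "iib") {
  class <- if (truncated) "E" else "CL1"
  prot <- iep_refs$protein[iep_refs$class == class][1]
  if (truncated) prot <- paste0("M", substr(prot, 172, nchar(prot)))
  core <- .build_intron_core(prot, class, include_five = !truncated,
                             ebs3_present = ebs3_present)
  if (truncated) {
    pre <- "CACCTC"
    seq <- paste0(pre, core$seq, "TATTTATT")
    off <- nchar(pre) + 1L
    truth <- .anchor_rows(core$anchors, "intron_truncated", plant_id, off,
                          "+", nchar(core$seq), class)
    truth <- bind_rows(truth, tibble(
      plant_id = plant_id, kind = "intron_truncated", feature = "intron",
      start = off, end = off + nchar(core$seq) - 1L, strand = "+",
      class = class))
    return(list(seq = seq, truth = truth))
  }
  site <- .attc_site_seq()
  pre <- paste0(site, "CACCTC", "GAGTCC", "CTTGAC")
  seq <- paste0(pre, core$seq, "T", "ATTTATT")
  off <- nchar(pre) + 1L
  truth <- bind_rows(
    .attc_truth(1L, plant_id),
    .anchor_rows(core$anchors, "intron_iib", plant_id, off, "+",
                 nchar(core$seq), class),
    tibble(plant_id = plant_id, kind = "intron_iib", feature = "intron",
           start = off, end = off + nchar(core$seq) - 1L, strand = "+",
           class = class)
  )
  list(seq = seq, truth = truth)
}

.build_iic_intron <- function(iep_refs, plant_id = "iic") {
  prot <- iep_refs$protein[iep_refs$class == "C"][1]
  core <- .build_intron_core(prot, "C", include_five = TRUE, ibs1 = "TTGT")
  li <- nchar(core$seq)
  site <- .attc_site_seq()
  seq <- paste0("A", revcomp(core$seq), "ACAA", site)
  truth <- bind_rows(
    .anchor_rows(core$anchors, "intron_iic", plant_id, 2L, "-", li, "C"),
    tibble(plant_id = plant_id, kind = "intron_iic", feature = "intron",
           start = 2L, end = li + 1L, strand = "-", class = "C"),
    .attc_truth(li + 6L, plant_id)
  )
  list(seq = seq, truth = truth)
}

.IS_ARM <- "GATCGGTACGCC"

.build_is605 <- function(tnp_refs, include_tnpB = TRUE, plant_id = "is") {
  hp <- paste0(.IS_ARM, "GAAA", revcomp(.IS_ARM))
  tnpA_nt <- back_translate(tnp_refs$protein[tnp_refs$class == "tnpA"][1])
  tnpB_nt <- back_translate(tnp_refs$protein[tnp_refs$class == "tnpB"][1])
  parts <- c("CACC", hp, "CCAC", revcomp(tnpA_nt), "CCAAC",
             if (include_tnpB) tnpB_nt, "CACC", hp, "CCAC")
  seq <- paste(parts, collapse = "")
  cum <- cumsum(c(0, nchar(parts)))
  p <- function(i) cum[i] + 1L
  el_start <- p(2); el_end <- cum[3]
  tnpA_start <- p(4); tnpA_end <- cum[5]
  idx_hp2 <- length(parts) - 1L
  truth <- bind_rows(
    tibble(plant_id = plant_id, kind = "is605", feature = "element",
           start = p(2), end = cum[idx_hp2 + 1L], strand = "+",
           class = if (include_tnpB) "IS605_group" else "partial"),
    tibble(plant_id = plant_id, kind = "is605", feature = "tnpA",
           start = tnpA_start, end = tnpA_end, strand = "-",
           class = NA_character_),
    if (include_tnpB)
      tibble(plant_id = plant_id, kind = "is605", feature = "tnpB",
             start = p(6), end = cum[7], strand = "+", class = NA_character_),
    tibble(plant_id = plant_id, kind = "is605", feature = "hairpin_left",
           start = p(2), end = cum[3], strand = "+", class = NA_character_),
    tibble(plant_id = plant_id, kind = "is605", feature = "hairpin_right",
           start = p(idx_hp2), end = cum[idx_hp2 + 1L], strand = "+",
           class = NA_character_)
  )
  list(seq = seq, truth = truth)
}

.build_ta_operon <- function(plant_id = "ta") {
  tox <- back_translate(paste0("M", .random_protein(84)))
  anti <- back_translate(paste0("M", .random_protein(64)))
  seq <- paste0(tox, "CCAAT", anti)
  truth <- bind_rows(
    tibble(plant_id = plant_id, kind = "ta_operon", feature = "toxin",
           start = 1L, end = nchar(tox), strand = "+", class = NA_character_),
    tibble(plant_id = plant_id, kind = "ta_operon", feature = "antitoxin",
           start = nchar(tox) + 6L, end = nchar(tox) + 5L + nchar(anti),
           strand = "+", class = NA_character_)
  )
  list(seq = seq, truth = truth)
}

.build_intI <- function(intI_refs, plant_id = "intI") {
  nt <- back_translate(intI_refs$protein[1])
  list(seq = nt,
       truth = tibble(plant_id = plant_id, kind = "intI_gene",
                      feature = "orf", start = 1L, end = nchar(nt),
                      strand = "+", class = "intI"))
}

#' Default plant list for a synthetic landscape
#'
#' For landscapes of at least 60 kb: a complete integron (intI gene plus a
#' 4-site attC array with cassette ORFs) and, well-separated, a CALIN
#' carrying a IIC-attC intron inserted at the TTGT/T junction of an attC
#' bottom strand in opposite orientation, a toxin-antitoxin cassette, a IIB
#' intron immediately downstream of an attC in cassette orientation, a
#' 5'-truncated intron, and an IS605-configuration element directly
#' downstream of the last attC site. Smaller landscapes get the same CALIN
#' block without the intI/locus-classification geometry.
#'
#' @param length Landscape length in bp.
#' @return Tibble with `kind`, `at`, and a `params` list-column.
#' @export
default_plants <- function(length = 1e5) {
  if (length >= 60000) {
    tibble(
      kind = c("intI_gene", "attc_array", "attc_array", "iic_attc_intron",
               "ta_operon", "iib_intron", "truncated_intron", "attc_array",
               "is605_element"),
      at = c(12000L, 14000L, 55000L, 56600L, 58200L, 58900L, 60600L,
             61500L, 61700L),
      params = list(list(), list(n_sites = 4), list(n_sites = 2), list(),
                    list(), list(), list(), list(n_sites = 1), list())
    )
  } else {
    base <- c(2000L, 6000L, 7600L, 9200L, 9900L, 11600L, 12500L, 12700L)
    tibble(
      kind = c("attc_array", "attc_array", "iic_attc_intron", "ta_operon",
               "iib_intron", "truncated_intron", "attc_array",
               "is605_element"),
      at = base,
      params = list(list(n_sites = 2), list(n_sites = 2), list(), list(),
                    list(), list(), list(n_sites = 1), list())
    )
  }
}

#' Configuration for the synthetic landscape generator
#'
#' @param seed Master seed (all randomness derives from it).
#' @param length Landscape length in bp (default 100000).
#' @param gc_content Background GC fraction (default 0.5).
#' @param mutation_rate Per-site substitution probability applied last
#'   (default 0).
#' @param plants Plant table (default [default_plants()]).
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(seed = 1, length = 1e5, gc_content = 0.5,
                             mutation_rate = 0, plants = NULL) {
  if (is.null(plants)) plants <- default_plants(length)
  cfg <- list(seed = seed, length = as.integer(length),
              gc_content = gc_content, mutation_rate = mutation_rate,
              plants = plants)
  class(cfg) <- "landscape_config"
  cfg
}

#' Substitute bases at a fixed per-site rate
#'
#' Each position is independently substituted (to one of the three other
#' bases, uniformly) with probability `rate`.
#'
#' @param seq Nucleotide string.
#' @param rate Substitution probability in `[0, 1]`.
#' @param seed Optional seed (isolated from the caller's RNG state).
#' @return Mutated sequence.
#' @export
mutate_seq <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Generate a synthetic mobile-element landscape with ground truth
#'
#' Background i.i.d. nucleotides at the configured GC content; each plant is
#' realized at its position and every planted feature is recorded with its
#' internal anchors (attC boxes, intron boundaries, EBS positions, hairpin
#' stems, ORFs); point mutations are applied last. The same configuration
#' always yields byte-identical output.
#'
#' @param config A [landscape_config()].
#' @return List of class `synthetic_landscape`: `seq`, `truth` tibble,
#'   `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  iep_refs <- synthetic_iep_panel()
  intI_refs <- synthetic_intI_panel()
  tnp_refs <- synthetic_tnp_panel()
  .with_seed(config$seed, {
    bg <- strsplit(.rand_dna(config$length, config$gc_content), "")[[1]]
    occupied <- tibble(start = integer(), end = integer(), id = character())
    truth <- list()
    for (i in seq_len(nrow(config$plants))) {
      kind <- config$plants$kind[i]
      at <- config$plants$at[i]
      par <- config$plants$params[[i]]
      pid <- paste0(kind, "_", i)
      built <- switch(
        kind,
        attc_array = .build_attc_array(
          n_sites = par$n_sites %||% 3,
          orf_aa = par$orf_aa %||% 140,
          gc = config$gc_content, plant_id = pid),
        iic_attc_intron = .build_iic_intron(iep_refs, plant_id = pid),
        iib_intron = .build_iib_intron(iep_refs, truncated = FALSE,
                                       ebs3_present = par$ebs3_present %||% TRUE,
                                       plant_id = pid),
        truncated_intron = .build_iib_intron(iep_refs, truncated = TRUE,
                                             plant_id = pid),
        is605_element = .build_is605(tnp_refs,
                                     include_tnpB = par$include_tnpB %||% TRUE,
                                     plant_id = pid),
        ta_operon = .build_ta_operon(plant_id = pid),
        intI_gene = .build_intI(intI_refs, plant_id = pid),
        abort(paste0("unknown plant kind: ", kind))
      )
      len <- nchar(built$seq)
      if (at + len - 1L > config$length) {
        abort(sprintf("plant %s does not fit at %d (needs %d bp)",
                      pid, at, len))
      }
      clash <- occupied |> filter(.data$start <= at + len - 1L,
                                  .data$end >= at)
      if (nrow(clash) > 0) {
        abort(sprintf("plants overlap: %s and %s", pid, clash$id[1]),
              class = "calintron_placement_error")
      }
      occupied <- bind_rows(occupied,
                            tibble(start = at, end = at + len - 1L, id = pid))
      bg[at:(at + len - 1L)] <- strsplit(built$seq, "")[[1]]
      tr <- built$truth
      tr$start <- tr$start + at - 1L
      tr$end <- tr$end + at - 1L
      truth[[length(truth) + 1L]] <- tr
    }
    seq <- paste(bg, collapse = "")
    if (config$mutation_rate > 0) {
      seq <- mutate_seq(seq, config$mutation_rate)
    }
    out <- list(seq = seq, truth = bind_rows(truth), config = config)
    class(out) <- "synthetic_landscape"
    out
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("<synthetic_landscape>", nchar(x$seq), "bp;",
      nrow(x$truth), "truth rows;",
      length(unique(x$truth$plant_id)), "plants\n")
  invisible(x)
}

#' Write a synthetic landscape to FASTA + GFF3 + JSON truth
#'
#' @param landscape A [generate_landscape()] result.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Named character vector of written paths, invisibly.
#' @export
export_landscape <- function(landscape, dir, name = "landscape") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fasta"))
  write_fasta(tibble(seq_id = name, residues = landscape$seq), fa)
  gff <- file.path(dir, paste0(name, "_truth.gff3"))
  feats <- landscape$truth |>
    mutate(seqid = name,
           type = ifelse(.data$feature == "site", "attC_site",
                         paste0(.data$kind, "_", .data$feature)),
           ID = paste0(.data$plant_id, "_", .data$feature, "_",
                       dplyr::row_number()))
  write_gff3(feats, gff)
  js <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(
    list(config = list(seed = landscape$config$seed,
                       length = landscape$config$length,
                       gc_content = landscape$config$gc_content,
                       mutation_rate = landscape$config$mutation_rate),
         truth = landscape$truth |> select(-any_of("params"))),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, gff3 = gff, json = js))
}
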