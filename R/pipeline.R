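# End-to-end orchestration: attC/CALIN detection -> ORF annotation ->
# cassette delineation -> locus classification -> group II intron
# annotation -> IS200/605 detection -> replication-strand context, with
# machine-readable outputs (GFF3 + JSON report).

#' Pipeline configuration
#'
#' @param attc [attc_config()] for the attC stage.
#' @param cluster_threshold_bp attC clustering threshold (default 8000).
#' @param leader_bp Leader cassette length (default 2000).
#' @param intI_window_bp intI search window beyond locus ends.
#' @param cassette_orf_min_len,iep_orf_min_len ORF length floors (bp).
#' @param relax_three_prime 3'-terminus relaxation tier.
#' @param is_link_bp Distance within which an IS element is linked to a
#'   locus (default 2000).
#' @param oric Optional `c(start, end)` OriC interval for strand context
#'   (circular genomes).
#' @param stages Character vector of stages to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(attc = attc_config(), cluster_threshold_bp = 8000,
                            leader_bp = 2000, intI_window_bp = 10000,
                            cassette_orf_min_len = 150,
                            iep_orf_min_len = 600,
                            relax_three_prime = "none", is_link_bp = 2000,
                            oric = NULL,
                            stages = c("attc", "orfs", "introns", "is",
                                       "replication")) {
  cfg <- list(attc = attc, cluster_threshold_bp = cluster_threshold_bp,
              leader_bp = leader_bp, intI_window_bp = intI_window_bp,
              cassette_orf_min_len = cassette_orf_min_len,
              iep_orf_min_len = iep_orf_min_len,
              relax_three_prime = relax_three_prime, is_link_bp = is_link_bp,
              oric = oric, stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

.intron_row <- function(m) {
  tibble(
    seq_id = m$seq_id, start = m$start, end = m$end, strand = m$strand,
    class = m$class_call$call, best_class = m$class_call$best_class,
    identity = m$iep$identity, similarity = m$iep$similarity,
    five_prime = m$five_prime %||% NA_integer_,
    three_prime = m$three_prime %||% NA_integer_,
    terminus_tier = m$terminus_tier,
    yadd = m$iep$yadd,
    frame_disruptions = m$iep$frame_disruptions,
    integrity = m$integrity,
    orientation_vs_cassettes = m$orientation_vs_cassettes,
    ttgt_junction = m$context$ttgt_junction,
    inside_attc_bs = m$context$inside_attc_bs,
    ebs1_len = if (isTRUE(m$target_site$computable))
      m$target_site$ibs1$matched_len else NA_integer_,
    ebs3_found = if (isTRUE(m$target_site$computable))
      m$target_site$ebs3$found else NA
  )
}

#' Run the full mobile-element annotation pipeline
#'
#' Stages run in order: attC detection and clustering, ORF annotation and
#' cassette delineation, locus classification (complete integron vs CALIN),
#' group II intron annotation, IS200/605 detection (elements linked to loci
#' within `is_link_bp`), and leading/lagging strand context when an OriC is
#' supplied. Zero findings is a valid result.
#'
#' @param seqs Tibble from [read_fasta()] (or a single sequence string).
#' @param iep_refs,intI_refs,tnp_refs Reference panels; defaults are the
#'   package's synthetic panels.
#' @param config A [pipeline_config()].
#' @return A `run_report` list: per-sequence results and summary counters.
#' @export
run_pipeline <- function(seqs, iep_refs = synthetic_iep_panel(),
                         intI_refs = synthetic_intI_panel(),
                         tnp_refs = synthetic_tnp_panel(),
                         config = pipeline_config()) {
  if (is.character(seqs)) {
    seqs <- tibble(seq_id = paste0("seq", seq_along(seqs)), residues = seqs,
                   topology = "linear", length = nchar(seqs))
  }
  per_seq <- purrr::map(seq_len(nrow(seqs)), function(i) {
    sid <- seqs$seq_id[i]
    s <- toupper(seqs$residues[i])
    res <- list(seq_id = sid, length = nchar(s))
    sites <- if ("attc" %in% config$stages)
      scan_attc(s, config$attc, seq_id = sid) else .empty_attc()
    loci <- cluster_attc(sites, config$cluster_threshold_bp)
    orfs <- if ("orfs" %in% config$stages)
      find_orfs(s, min_len = config$cassette_orf_min_len) else
        find_orfs(s, min_len = 1e9)
    loci <- delineate_cassettes(loci, orfs, config$leader_bp)
    if (nrow(loci) > 0) {
      loci <- classify_locus(loci, orfs, intI_refs,
                             window_bp = config$intI_window_bp)
    } else {
      loci$classification <- character(0)
    }
    introns <- list()
    if ("introns" %in% config$stages) {
      iep_orfs <- find_orfs(s, min_len = config$iep_orf_min_len)
      introns <- annotate_introns(
        s, iep_refs, seq_id = sid, orfs = iep_orfs, attc_sites = sites,
        relax_three_prime = config$relax_three_prime)
    }
    is_el <- if ("is" %in% config$stages)
      find_is_elements(s, tnp_refs, seq_id = sid) else NULL
    if (!is.null(is_el) && nrow(is_el) > 0 && nrow(loci) > 0) {
      locus_gap <- function(k) {
        pmax(0L, pmax(loci$start - is_el$end[k], is_el$start[k] - loci$end))
      }
      is_el$linked_locus <- purrr::map_chr(seq_len(nrow(is_el)), function(k) {
        d <- locus_gap(k)
        if (min(d) <= config$is_link_bp) loci$locus_id[which.min(d)]
        else NA_character_
      })
      is_el$locus_distance <- purrr::map_int(seq_len(nrow(is_el)), function(k) {
        as.integer(min(locus_gap(k)))
      })
    }
    strand_ctx <- NULL
    if ("replication" %in% config$stages && !is.null(config$oric)) {
      ctx <- replication_context(nchar(s), config$oric[1], config$oric[2])
      feats <- bind_rows(
        if (nrow(sites)) sites |>
          transmute(feature = "attC_bs", .data$start, .data$end,
                    strand = .data$bs_strand),
        if (length(introns)) purrr::map_dfr(introns, function(m)
          tibble(feature = "intron", start = m$start, end = m$end,
                 strand = m$strand)),
        if (!is.null(is_el) && nrow(is_el)) is_el |>
          transmute(feature = "is_element", .data$start, .data$end,
                    strand = "+")
      )
      strand_ctx <- if (!is.null(feats) && nrow(feats))
        assign_strand(feats, ctx) else feats
    }
    res$attc_sites <- sites
    res$loci <- loci
    res$orfs <- orfs
    res$introns <- introns
    res$intron_table <- if (length(introns))
      purrr::map_dfr(introns, .intron_row) else tibble()
    res$is_elements <- is_el
    res$strand_context <- strand_ctx
    res
  })
  summary <- purrr::map_dfr(per_seq, function(r) {
    tibble(seq_id = r$seq_id, length = r$length,
           n_attc = nrow(r$attc_sites), n_loci = nrow(r$loci),
           n_calin = sum(r$loci$classification == "CALIN"),
           n_integron = sum(r$loci$classification == "complete_integron"),
           n_introns = length(r$introns),
           n_is = if (is.null(r$is_elements)) 0L else nrow(r$is_elements))
  })
  out <- list(version = as.character(utils::packageVersion("calintron")),
              config = config, sequences = per_seq, summary = summary)
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> calintron", x$version, "\n")
  print(x$summary)
  invisible(x)
}

#' Collect all pipeline features as a GFF3-ready tibble
#' @param report A [run_pipeline()] report.
#' @return Tibble of features.
#' @export
report_features <- function(report) {
  purrr::map_dfr(report$sequences, function(r) {
    bind_rows(
      if (nrow(r$attc_sites)) r$attc_sites |>
        transmute(seqid = .data$seq_id, type = "attC_site", .data$start,
                  .data$end, strand = .data$strand, score = .data$score,
                  ID = paste0(.data$seq_id, "_attC", dplyr::row_number())),
      if (nrow(r$loci)) r$loci |>
        transmute(seqid = .data$seq_id,
                  type = ifelse(.data$classification == "complete_integron",
                                "integron", "CALIN"),
                  .data$start, .data$end, strand = "+",
                  ID = .data$locus_id),
      if (nrow(r$intron_table)) r$intron_table |>
        transmute(seqid = .data$seq_id, type = "group_II_intron",
                  .data$start, .data$end, strand = .data$strand,
                  ID = paste0(.data$seq_id, "_intron", dplyr::row_number())),
      if (!is.null(r$is_elements) && nrow(r$is_elements)) r$is_elements |>
        transmute(seqid = .data$seq_id, type = "insertion_sequence",
                  .data$start, .data$end, strand = "+",
                  ID = paste0(.data$seq_id, "_IS", dplyr::row_number()))
    )
  })
}

#' Write pipeline outputs (GFF3 + JSON report)
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "features.gff3")
  write_gff3(report_features(report), gff)
  js <- file.path(dir, "report.json")
  payload <- list(
    version = report$version,
    summary = report$summary,
    sequences = purrr::map(report$sequences, function(r) {
      list(seq_id = r$seq_id, length = r$length,
           attc_sites = r$attc_sites,
           loci = r$loci |> select(-any_of(c("sites", "cassettes"))),
           introns = r$intron_table,
           is_elements = r$is_elements)
    })
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(gff3 = gff, json = js))
}

# ---- planted-truth recovery -------------------------------------------------

.match_interval <- function(df, start, end, strand = NULL, tol = 0L) {
  if (is.null(df) || nrow(df) == 0) return(FALSE)
  ok <- abs(df$start - start) <= tol & abs(df$end - end) <= tol
  if (!is.null(strand)) ok <- ok & df$strand == strand
  any(ok)
}

#' Score recovery of planted features by a pipeline report
#'
#' Feature-kind-specific criteria: attC sites must be recovered with exact
#' R''/R' box coordinates; cassette/TA/intI ORFs with exact intervals;
#' introns with exact boundary nucleotides, correct class and integrity
#' call (and, for IIC-attC, the TTGT/opposite-orientation context flags);
#' IS elements within +/-3 bp (hairpin-anchored ends) and the IS605 group
#' call; locus classifications must match the planted geometry.
#'
#' @param landscape A [generate_landscape()] result.
#' @param report A [run_pipeline()] report for that landscape.
#' @return Tibble with `kind`, `n_planted`, `n_recovered`.
#' @export
evaluate_recovery <- function(landscape, report) {
  r <- report$sequences[[1]]
  truth <- landscape$truth
  intr <- r$intron_table
  res <- list()
  tally <- function(kind, planted, recovered) {
    res[[length(res) + 1L]] <<- tibble(kind = kind, n_planted = planted,
                                       n_recovered = recovered)
  }
  # attC sites: exact boxes
  tr_sites <- truth |> filter(.data$kind == "attc_site", .data$feature == "site")
  if (nrow(tr_sites)) {
    tr_r2 <- truth |> filter(.data$kind == "attc_site", .data$feature == "box_r2")
    tr_r1 <- truth |> filter(.data$kind == "attc_site", .data$feature == "box_r1")
    got <- vapply(seq_len(nrow(tr_sites)), function(k) {
      pid <- tr_sites$plant_id[k]; site_start <- tr_sites$start[k]
      r2 <- tr_r2 |> filter(.data$plant_id == pid, .data$start >= site_start - 1,
                            .data$start <= tr_sites$end[k])
      r1 <- tr_r1 |> filter(.data$plant_id == pid, .data$end <= tr_sites$end[k] + 1,
                            .data$start >= site_start)
      any(r$attc_sites$r2_start %in% r2$start &
            r$attc_sites$r2_end %in% r2$end &
            r$attc_sites$r1_start %in% r1$start &
            r$attc_sites$r1_end %in% r1$end)
    }, logical(1))
    tally("attc_site", nrow(tr_sites), sum(got))
  }
  # plain ORFs: anchored at the stop-codon side; naive ORF calling may
  # extend the start to an upstream in-frame start codon, so the call must
  # cover the planted start in frame.
  orf_recovered <- function(start, end, strand) {
    if (is.null(r$orfs) || nrow(r$orfs) == 0) return(FALSE)
    if (strand == "+") {
      any(r$orfs$strand == "+" & r$orfs$end == end & r$orfs$start <= start &
            (start - r$orfs$start) %% 3 == 0)
    } else {
      any(r$orfs$strand == "-" & r$orfs$start == start & r$orfs$end >= end &
            (r$orfs$end - end) %% 3 == 0)
    }
  }
  for (kd in c("cassette_orf", "ta_operon", "intI_gene")) {
    tr <- truth |> filter(.data$kind == kd,
                          .data$feature %in% c("orf", "toxin", "antitoxin"))
    if (nrow(tr) == 0) next
    got <- vapply(seq_len(nrow(tr)), function(k) {
      orf_recovered(tr$start[k], tr$end[k], tr$strand[k])
    }, logical(1))
    tally(kd, nrow(tr), sum(got))
  }
  # introns
  check_intron <- function(kd, expect_class, expect_integrity, ctx = FALSE,
                           need_five = TRUE) {
    tr <- truth |> filter(.data$kind == kd, .data$feature == "intron")
    if (nrow(tr) == 0) return()
    tr5 <- truth |> filter(.data$kind == kd, .data$feature == "five_prime")
    tr3 <- truth |> filter(.data$kind == kd, .data$feature == "three_prime")
    got <- vapply(seq_len(nrow(tr)), function(k) {
      pid <- tr$plant_id[k]
      t3 <- tr3 |> filter(.data$plant_id == pid)
      cand <- intr
      if (nrow(cand) == 0) return(FALSE)
      ok <- cand$strand == tr$strand[k] &
        !is.na(cand$three_prime) & cand$three_prime == t3$start[1] &
        cand$class == expect_class & cand$integrity == expect_integrity
      if (need_five) {
        t5 <- tr5 |> filter(.data$plant_id == pid)
        ok <- ok & !is.na(cand$five_prime) & cand$five_prime == t5$start[1]
      }
      if (ctx) {
        ok <- ok & isTRUE(any(cand$ttgt_junction & cand$inside_attc_bs &
                                cand$orientation_vs_cassettes == "opposite" & ok))
      }
      any(ok)
    }, logical(1))
    tally(kd, nrow(tr), sum(got))
  }
  check_intron("intron_iic", "C", "full", ctx = TRUE)
  check_intron("intron_iib", "CL1", "full")
  check_intron("intron_truncated", "E", "five_prime_truncated",
               need_five = FALSE)
  # IS elements: +/-3 bp, group call
  tr_is <- truth |> filter(.data$kind == "is605", .data$feature == "element")
  if (nrow(tr_is)) {
    got <- vapply(seq_len(nrow(tr_is)), function(k) {
      if (is.null(r$is_elements) || nrow(r$is_elements) == 0) return(FALSE)
      any(abs(r$is_elements$start - tr_is$start[k]) <= 3 &
            abs(r$is_elements$end - tr_is$end[k]) <= 3 &
            r$is_elements$group_call == tr_is$class[k] |
            (tr_is$class[k] != "IS605_group" &
               abs(r$is_elements$start - tr_is$start[k]) <= 200 &
               r$is_elements$group_call == "partial"))
    }, logical(1))
    tally("is605", nrow(tr_is), sum(got))
  }
  # locus classifications (only landscapes with the full geometry)
  if (any(truth$kind == "intI_gene")) {
    n_int <- sum(r$loci$classification == "complete_integron")
    n_cal <- sum(r$loci$classification == "CALIN")
    tally("locus_integron", 1L, as.integer(n_int == 1))
    tally("locus_calin", 1L, as.integer(n_cal >= 1))
  }
  bind_rows(res)
}

#' Overall recovery rate of a landscape run
#' @inheritParams evaluate_recovery
#' @return Fraction of planted features recovered.
#' @export
recovery_rate <- function(landscape, report) {
  ev <- evaluate_recovery(landscape, report)
  sum(ev$n_recovered) / sum(ev$n_planted)
}
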