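# Synthetic, deterministically generated reference panels. Real analyses use
# user-supplied panels (labelled FASTA + domain table); these built-in panels
# exist so the synthetic landscapes and the test-suite have labelled
# references with known domain coordinates without any external data. They
# are synthetic sequences, not curated proteins.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evaluate expr under a fixed RNG state without disturbing the caller's.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.random_protein <- function(n) paste(sample(.aa20, n, replace = TRUE), collapse = "")

.mutate_protein <- function(p, rate) {
  chars <- strsplit(p, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(.aa20, chars[i]), 1)
  paste(chars, collapse = "")
}

.iep_domain_table <- function(with_en = FALSE) {
  d <- tibble(
    domain = c("RT0", "RT1", "RT2", "RT3", "RT4", "RT5", "RT6", "RT7", "X"),
    start = c(2L, 41L, 76L, 111L, 146L, 181L, 226L, 261L, 296L),
    end = c(40L, 75L, 110L, 145L, 180L, 225L, 260L, 295L, 380L)
  )
  if (with_en) d <- bind_rows(d, tibble(domain = "En", start = 381L, end = 420L))
  d
}

#' Synthetic intron-encoded-protein reference panel
#'
#' Two labelled members per IEP class (ML, CL1, CL2 and bacterial A-E), each
#' a deterministic synthetic protein of ~380-420 aa with annotated RT0-RT7,
#' X (and, for ML, En) domain coordinates and the conserved YADD motif inside
#' RT5. Members of a class share ~92% identity; classes are mutually
#' unrelated. Only ML carries an En domain, reflecting the prevalence of
#' En-minus bacterial IEPs.
#'
#' @param members Members per class (default 2).
#' @return Tibble with `id`, `class`, `protein` and a `domains` list-column.
#' @export
synthetic_iep_panel <- function(members = 2) {
  classes <- c("ML", "CL1", "CL2", "A", "B", "C", "D", "E")
  .with_seed(20210301, {
    purrr::map_dfr(classes, function(cl) {
      with_en <- cl == "ML"
      len <- if (with_en) 420L else 380L
      core <- strsplit(.random_protein(len), "")[[1]]
      core[1] <- "M"
      core[198:201] <- c("Y", "A", "D", "D") # inside RT5
      core <- paste(core, collapse = "")
      prots <- c(core,
                 if (members > 1)
                   vapply(seq_len(members - 1),
                          function(i) .mutate_protein(core, 0.08), ""))
      # keep the catalytic motif and start in mutated members
      prots <- vapply(prots, function(p) {
        ch <- strsplit(p, "")[[1]]
        ch[1] <- "M"; ch[198:201] <- c("Y", "A", "D", "D")
        paste(ch, collapse = "")
      }, "")
      tibble(
        id = paste0("IEP_", cl, "_", seq_len(members)),
        class = cl,
        protein = unname(prots),
        domains = rep(list(.iep_domain_table(with_en)), members)
      )
    })
  })
}

#' Synthetic integron-integrase (intI) reference panel
#' @param members Number of references (default 2).
#' @return Tibble with `id`, `class`, `protein`, `domains` columns.
#' @export
synthetic_intI_panel <- function(members = 2) {
  .with_seed(19770401, {
    core <- .random_protein(320)
    core <- paste0("M", substr(core, 2, 320))
    prots <- c(core, if (members > 1)
      vapply(seq_len(members - 1), function(i) .mutate_protein(core, 0.1), ""))
    prots <- vapply(prots, function(p) paste0("M", substr(p, 2, nchar(p))), "")
    tibble(id = paste0("intI_", seq_len(members)), class = "intI",
           protein = unname(prots), domains = rep(list(tibble()), members))
  })
}

#' Synthetic tnpA / tnpB reference panel (IS200/605 superfamily)
#'
#' Deterministic synthetic stand-ins for the HUH transposase (tnpA, ~160 aa)
#' and the accessory tnpB protein (~380 aa).
#'
#' @param members Members per label (default 2).
#' @return Tibble with `id`, `class` (`"tnpA"`/`"tnpB"`), `protein`, `domains`.
#' @export
synthetic_tnp_panel <- function(members = 2) {
  .with_seed(16052005, {
    lens <- c(tnpA = 160L, tnpB = 380L)
    purrr::map_dfr(names(lens), function(nm) {
      len <- lens[[nm]]
      core <- paste0("M", substr(.random_protein(len), 2, len))
      prots <- c(core, if (members > 1)
        vapply(seq_len(members - 1), function(i) .mutate_protein(core, 0.1), ""))
      prots <- vapply(prots, function(p) paste0("M", substr(p, 2, nchar(p))), "")
      tibble(id = paste0(nm, "_", seq_len(members)), class = nm,
             protein = unname(prots), domains = rep(list(tibble()), members))
    })
  })
}

# Most-used E. coli codon per amino acid; deterministic back-translation.
.codon_table <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG", "*" = "TAA", X = "GCT"
)

#' Back-translate a protein with fixed most-frequent codons
#'
#' Deterministic: each amino acid always maps to the same codon, so a
#' back-translated ORF is byte-reproducible. A terminal stop codon (TAA) is
#' appended unless the protein already ends in `*`.
#'
#' @param protein Amino-acid string (may contain `*`).
#' @param add_stop Append TAA (default TRUE).
#' @return Nucleotide string.
#' @export
back_translate <- function(protein, add_stop = TRUE) {
  aa <- strsplit(toupper(protein), "")[[1]]
  codons <- .codon_table[aa]
  if (anyNA(codons)) abort("unknown amino acid in back_translate")
  out <- paste(codons, collapse = "")
  if (add_stop && (length(aa) == 0 || aa[length(aa)] != "*")) {
    out <- paste0(out, "TAA")
  }
  out
}

#' Write a reference panel to FASTA (plus optional domain table)
#'
#' Headers carry the class label as `id class=LABEL`; domain coordinates go
#' to a sidecar TSV (`id`, `domain`, `start`, `end`).
#'
#' @param panel Panel tibble (`id`, `class`, `protein`, `domains`).
#' @param fasta Output FASTA path.
#' @param domains_tsv Optional output TSV path for domain coordinates.
#' @return `fasta`, invisibly.
#' @export
write_panel <- function(panel, fasta, domains_tsv = NULL) {
  set <- Biostrings::AAStringSet(panel$protein)
  names(set) <- paste0(panel$id, " class=", panel$class)
  Biostrings::writeXStringSet(set, fasta)
  if (!is.null(domains_tsv)) {
    dom <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
      d <- panel$domains[[i]]
      if (nrow(d) == 0) return(tibble())
      mutate(d, id = panel$id[i], .before = 1)
    })
    utils::write.table(dom, domains_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta)
}

#' Read a reference panel from FASTA (plus optional domain table)
#'
#' @param fasta Protein FASTA whose headers carry `class=LABEL`.
#' @param domains_tsv Optional TSV with `id`, `domain`, `start`, `end`.
#' @return Panel tibble as produced by [synthetic_iep_panel()].
#' @export
read_panel <- function(fasta, domains_tsv = NULL) {
  set <- Biostrings::readAAStringSet(fasta)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  cls <- ifelse(grepl("class=", headers),
                sub(".*class=(\\S+).*", "\\1", headers), NA_character_)
  dom_all <- if (!is.null(domains_tsv)) {
    utils::read.table(domains_tsv, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  tibble(
    id = ids, class = cls, protein = unname(as.character(set)),
    domains = purrr::map(ids, function(id) {
      if (is.null(dom_all)) return(tibble())
      as_tibble(dom_all[dom_all$id == id, c("domain", "start", "end")])
    })
  )
}
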