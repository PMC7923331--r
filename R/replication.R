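#' Replication context of a circular genome
#'
#' Given an origin of replication (OriC) interval, the terminus is placed
#' half the genome away from the OriC midpoint (the half-genome rule), which
#' partitions the chromosome into two replichores. With an odd genome
#' length, the extra base goes to replichore 1.
#'
#' @param genome_length Genome size in bp.
#' @param oric_start,oric_end OriC interval, 1-based inclusive (as printed
#'   by origin predictors).
#' @return A `replication_context` list: `genome_length`, `oric_start`,
#'   `oric_end`, `oric_mid`, `ter_position`, and the replichore 1 half-span.
#' @export
replication_context <- function(genome_length, oric_start, oric_end) {
  stopifnot(genome_length >= 2, oric_start >= 1, oric_end <= genome_length,
            oric_start <= oric_end)
  mid <- (oric_start + oric_end) %/% 2L
  half1 <- as.integer(ceiling(genome_length / 2))
  ter <- ((mid - 1L + half1) %% genome_length) + 1L
  ctx <- list(genome_length = as.integer(genome_length),
              oric_start = as.integer(oric_start),
              oric_end = as.integer(oric_end),
              oric_mid = as.integer(mid),
              ter_position = as.integer(ter),
              replichore1_len = half1)
  class(ctx) <- "replication_context"
  ctx
}

#' @export
print.replication_context <- function(x, ...) {
  cat("<replication_context> genome", x$genome_length, "bp; OriC",
      x$oric_start, "-", x$oric_end, "; ter ~", x$ter_position, "\n")
  invisible(x)
}

#' Assign leading/lagging strand to features
#'
#' Within replichore 1 (OriC midpoint to terminus in ascending circular
#' coordinates) the top strand is replicated as the leading strand; within
#' replichore 2 the bottom strand is. A feature is assigned by its midpoint;
#' features spanning the terminus (or the origin) are flagged.
#'
#' @param features Tibble with `start`, `end`, `strand`.
#' @param ctx A [replication_context()].
#' @return `features` with `replichore`, `replication_strand`
#'   (`"leading"`/`"lagging"`) and `spans_ter` columns.
#' @export
assign_strand <- function(features, ctx) {
  L <- ctx$genome_length
  if (nrow(features) > 0 &&
      (any(features$start < 1) || any(features$end > L))) {
    abort("feature coordinates outside [1, genome_length]",
          class = "calintron_coordinate_error")
  }
  offset_of <- function(pos) (pos - ctx$oric_mid) %% L
  mid_feat <- ((features$start + features$end) %/% 2L)
  off <- offset_of(mid_feat)
  in_r1 <- off < ctx$replichore1_len
  leading <- (in_r1 & features$strand == "+") |
    (!in_r1 & features$strand == "-")
  off_s <- offset_of(features$start); off_e <- offset_of(features$end)
  spans_break <- off_e < off_s |
    (off_s < ctx$replichore1_len & off_e >= ctx$replichore1_len)
  features |>
    mutate(replichore = ifelse(in_r1, 1L, 2L),
           replication_strand = ifelse(leading, "leading", "lagging"),
           spans_ter = spans_break)
}
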