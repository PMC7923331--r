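#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an intron model into an anchor table
#'
#' One row per resolved anchor (boundaries, DV, DVI, DIV basal stem, EBS1),
#' top-strand coordinates.
#'
#' @param x An `intron_model` from [annotate_introns()].
#' @param ... Unused.
#' @return Tibble with `anchor`, `start`, `end`, `strand`.
#' @export
tidy.intron_model <- function(x, ...) {
  to_top <- function(pos) .to_coding(pos, x$seq_length, x$strand)
  n_anchor <- function(anchor, s, e) {
    if (is.null(s)) return(tibble())
    tibble(anchor = anchor, start = min(s, e), end = max(s, e),
           strand = x$strand)
  }
  bind_rows(
    n_anchor("five_prime", x$five_prime, x$five_prime),
    n_anchor("three_prime", x$three_prime, x$three_prime),
    if (!is.null(x$dv)) n_anchor("DV", x$dv$start, x$dv$end),
    if (!is.null(x$dvi)) n_anchor("DVI", x$dvi$start, x$dvi$end),
    if (!is.null(x$div_basal_stem))
      n_anchor("DIV_basal_partner",
               to_top(x$div_basal_stem$partner_c[1]),
               to_top(x$div_basal_stem$partner_c[2])),
    if (isTRUE(x$target_site$computable) && x$target_site$ibs1$matched_len > 0)
      n_anchor("EBS1", to_top(x$target_site$ibs1$ebs1_start_c),
               to_top(x$target_site$ibs1$ebs1_end_c))
  )
}

#' One-row summary of an intron model
#' @inheritParams tidy.intron_model
#' @return One-row tibble.
#' @export
glance.intron_model <- function(x, ...) {
  .intron_row(x)
}

#' Tidy a replication context
#' @param x A [replication_context()].
#' @param ... Unused.
#' @return Tibble with the two replichore spans.
#' @export
tidy.replication_context <- function(x, ...) {
  tibble(replichore = c(1L, 2L),
         from = c(x$oric_mid, x$ter_position),
         to = c(x$ter_position, x$oric_mid),
         leading_strand = c("+", "-"))
}

#' Feature map of a synthetic landscape or run report
#'
#' Draws each feature as a horizontal segment per track (feature kind),
#' strand shown by colour.
#'
#' @param object A `synthetic_landscape` or `run_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_landscape <- function(object, ...) {
  df <- object$truth |>
    filter(.data$feature %in% c("site", "orf", "intron", "element", "toxin",
                                "antitoxin"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$kind, yend = .data$kind,
                                   colour = .data$strand)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Planted features") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.synthetic_landscape
#' @export
autoplot.run_report <- function(object, ...) {
  df <- report_features(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$type, yend = .data$type,
                                   colour = .data$strand)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_wrap(~seqid, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Detected features") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Logo-style conservation plot of an alignment
#'
#' Stacked per-column residue heights (information times frequency).
#'
#' @param alignment Aligned rows or [read_alignment()] tibble.
#' @param type Passed to [logo_data()].
#' @return A ggplot object.
#' @export
plot_logo <- function(alignment, type = "auto") {
  ld <- logo_data(alignment, type)
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$column, y = .data$height,
                                   fill = .data$residue,
                                   label = .data$residue)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "alignment column", y = "bits") +
    ggplot2::theme_minimal()
}
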