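# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene-body positional frequency profile
#'
#' One line per codon across relative-position bins; a dual-meaning codon
#' is expected to dip in the terminal bins relative to its synonymous
#' companions, a plain sense codon to track them.
#'
#' @param object A [gene_body_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_body_profile <- function(object, ...) {
  target <- attr(object, "target")
  df <- as_tibble(object) |>
    mutate(role = ifelse(.data$codon == target, "target", "synonymous"),
           codon = codon_rna(.data$codon))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$freq,
                                   colour = .data$codon,
                                   linewidth = .data$role)) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth_manual(values = c(target = 1.2,
                                               synonymous = 0.4),
                                    guide = "none") +
    ggplot2::labs(x = "relative position bin (5' to 3')",
                  y = "frequency (per codon)",
                  colour = "codon",
                  title = sprintf("Gene-body distribution of %s",
                                  codon_rna(target))) +
    ggplot2::theme_minimal()
}

#' Plot codon-meaning logo counts
#'
#' Single-column bar rendering of the conserved-site vote: the frequency
#' of each modal amino acid among qualifying sites.
#'
#' @param object A `codon_meaning` from [infer_codon_meaning()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codon_meaning <- function(object, ...) {
  df <- logo_counts(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$aa, -.data$freq),
                                   y = .data$freq)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "modal amino acid at conserved sites", y = "frequency",
                  title = sprintf("%s: %d conserved sites, top %s (%.1f%%)",
                                  codon_rna(object$codon), object$n_sites,
                                  object$top_aa,
                                  100 * object$top_fraction)) +
    ggplot2::theme_minimal()
}

#' Plot a C-terminus stop-context tally
#'
#' @param object A `stop_context_tally` from [tally_cterm_codons()].
#' @param top_n Show the most frequent `top_n` codons.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stop_context_tally <- function(object, top_n = 10L, ...) {
  df <- as_tibble(object) |>
    slice_head(n = top_n) |>
    mutate(codon = codon_rna(.data$codon),
           is_stop = .data$codon %in% c("UAA", "UAG", "UGA"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$codon, -.data$n),
                                   y = .data$fraction,
                                   fill = .data$is_stop)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "codon 3' of full C-terminus alignments",
                  y = "fraction of alignments") +
    ggplot2::theme_minimal()
}
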