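# Codon-usage statistics: stop-codon usage, relative synonymous usage of
# the reassigned codon, internal-codon prevalence, and GC content. All
# gene-level statistics are restricted to complete genes (predicted start
# and stop codon, in frame, no internal stop).

#' Stop-codon usage over complete genes
#'
#' Counts the terminal codon of every complete gene. The denominator is
#' the number of complete genes whose terminal codon is a stop under the
#' applied table; a gene flagged complete whose terminal codon is not a
#' stop is excluded and reported.
#'
#' @param cds Tibble from [translate_cds()].
#' @param code A [genetic_code()].
#' @return Tibble `codon`, `n`, `fraction` over the three standard stops
#'   (sense codons under `code` report 0).
#' @export
stop_usage <- function(cds, code) {
  keep <- cds[cds$complete, ]
  term <- map_chr(keep$codons, \(x) x[[length(x)]])
  ok <- term %in% code$stop_codons
  if (any(!ok)) {
    inform(sprintf(
      "%d complete gene(s) do not end on a stop codon under table %d; excluded",
      sum(!ok), code$table_id))
  }
  term <- term[ok]
  std <- c("TAA", "TAG", "TGA")
  n <- unname(vapply(std, \(s) sum(term == s), integer(1)))
  tibble(codon = std, n = n, fraction = if (sum(n) > 0) n / sum(n) else NA_real_)
}

#' Relative synonymous codon usage within one amino-acid family
#'
#' Counts internal codons (terminal stop excluded) of complete genes over
#' the synonymous family of `amino_acid` under the applied table — under a
#' variant table the reassigned codon is a full member of its new family
#' (e.g. TAG is the seventh leucine codon under table 16).
#'
#' @param cds Tibble from [translate_cds()].
#' @param code A [genetic_code()].
#' @param amino_acid One-letter amino acid whose family is profiled.
#' @param include_codon Optional codon that must belong to the family (a
#'   guard for the reassigned codon); an error if it does not.
#' @return Tibble `codon`, `n`, `fraction` (fractions sum to 1 over the
#'   family).
#' @export
synonymous_usage <- function(cds, code, amino_acid, include_codon = NULL) {
  fam <- codon_family(code, amino_acid)
  if (!is.null(include_codon)) {
    include_codon <- codon_dna(include_codon)
    if (!include_codon %in% fam) {
      abort(sprintf("codon %s does not encode %s under table %d",
                    include_codon, amino_acid, code$table_id))
    }
  }
  keep <- cds[cds$complete, ]
  internal <- unlist(map2(keep$codons, keep$has_stop, internal_codons))
  internal <- internal[internal %in% fam]
  n <- unname(vapply(fam, \(cd) sum(internal == cd), integer(1)))
  tibble(codon = fam, n = n,
         fraction = if (sum(n) > 0) n / sum(n) else NA_real_) |>
    arrange(dplyr::desc(.data$n))
}

#' Fraction of complete genes containing an internal occurrence of a codon
#'
#' @param cds Tibble from [translate_cds()].
#' @param codon Target codon.
#' @return Fraction of complete genes with at least one internal
#'   occurrence.
#' @export
internal_codon_prevalence <- function(cds, codon) {
  codon <- codon_dna(codon)
  keep <- cds[cds$complete, ]
  if (nrow(keep) == 0) abort("no complete genes; prevalence undefined")
  has <- map2_lgl(keep$codons, keep$has_stop,
                  \(x, s) codon %in% internal_codons(x, s))
  mean(has)
}

#' GC content of a genome assembly
#'
#' (G + C) / (A + C + G + T); ambiguous bases are excluded from the
#' denominator.
#'
#' @param genome Named contig sequences (or a single sequence).
#' @return Fraction in (0, 1).
#' @export
gc_content <- function(genome) {
  if (is.null(names(genome)) && length(genome) == 1) names(genome) <- "seq"
  x <- Biostrings::DNAStringSet(as_genome(genome))
  f <- colSums(Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"),
                                                drop = FALSE])
  if (sum(f) == 0) abort("genome contains no unambiguous A/C/G/T bases")
  unname((f[["G"]] + f[["C"]]) / sum(f))
}

#' One-row codon-usage report for a genome
#'
#' @param genome Named contig sequences.
#' @param cds Tibble from [translate_cds()].
#' @param code The applied [genetic_code()].
#' @param target_codon The candidate reassigned codon (default TAG).
#' @param genome_id Label for the report row.
#' @return One-row tibble: complete-gene count, per-stop fractions,
#'   target-codon family usage (when the codon is sense under `code`),
#'   internal prevalence and assembly GC.
#' @export
usage_report <- function(genome, cds, code, target_codon = "TAG",
                         genome_id = "genome") {
  target_codon <- codon_dna(target_codon)
  su <- stop_usage(cds, code)
  fr <- setNames(su$fraction, su$codon)
  aa <- unname(code$codon_map[[target_codon]])
  fam_usage <- NA_real_
  if (aa != STOP_CHAR) {
    fu <- synonymous_usage(cds, code, aa, include_codon = target_codon)
    fam_usage <- fu$fraction[fu$codon == target_codon]
  }
  tibble(genome_id = genome_id,
         n_complete_genes = sum(cds$complete),
         stop_TAA = fr[["TAA"]], stop_TAG = fr[["TAG"]],
         stop_TGA = fr[["TGA"]],
         target_codon = target_codon,
         target_aa = aa,
         target_family_usage = fam_usage,
         internal_prevalence = internal_codon_prevalence(cds, target_codon),
         gc = gc_content(genome))
}
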