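# Configuration object for the synthetic-data generators.

# Background amino-acid frequencies (average eukaryotic proteome
# composition); renormalised at load. Leucine ~9.7%, glutamine ~4% — the
# two families that receive the reassigned codon under tables 16 and 15.
AA_FREQ <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.017, Q = 0.040,
  E = 0.062, G = 0.066, H = 0.022, I = 0.056, L = 0.096, K = 0.058,
  M = 0.024, F = 0.040, P = 0.047, S = 0.073, T = 0.057, W = 0.011,
  Y = 0.032, V = 0.063)
AA_FREQ <- AA_FREQ / sum(AA_FREQ)

default_stop_usage <- function(table_id) {
  switch(as.character(table_id),
         "1" = c(TAA = 0.80, TAG = 0.13, TGA = 0.07),
         "6" = c(TAA = 0, TAG = 0, TGA = 1),
         c(TAA = 0.95, TAG = 0, TGA = 0.05))
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the simulators with validated defaults. The
#' defaults emulate a ciliate-like nuclear genome: AT-rich coding sequence,
#' UAA-dominated stop usage, and (under variant tables) a reassigned UAG
#' codon written at a configurable share of its amino-acid family.
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_taxa Number of taxa per orthogroup alignment (query plus
#'   `n_taxa - 1` background rows); must be at least 5.
#' @param query_table_id NCBI translation table of the query genome
#'   (1, 6, 15 or 16).
#' @param n_orthogroups Number of orthogroup alignments to emit.
#' @param genes_per_genome Number of genes simulated per genome.
#' @param mean_gene_len_codons Mean gene length in codons (minimum 30).
#' @param conserved_column_fraction Probability that an alignment column is
#'   evolutionarily conserved.
#' @param column_identity_at_conserved Probability that a background row
#'   carries the query residue at a conserved column; must lie in
#'   \[0.7, 1\].
#' @param reassigned_codon_family_usage Share of the reassigned amino
#'   acid's positions written with the reassigned (former stop) codon.
#' @param stop_usage Named probabilities over `TAA`, `TAG`, `TGA` summing
#'   to 1; mass on a codon that is sense under `query_table_id` is an
#'   error. Defaults depend on the table.
#' @param gc_bias Probability of G/C at degenerate third positions and in
#'   intergenic sequence.
#' @param partial_gene_fraction Fraction of genes emitted without a start
#'   and/or stop codon (truncated gene models).
#' @param gap_rate Per-cell gap probability in background alignment rows.
#' @param genes_per_contig Genes placed on each contig.
#' @param mean_intergenic_len Mean intergenic spacer length (nt).
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @param target_tail_exclusion Fraction of each gene's 3' codons in which
#'   the reassigned codon is never written (0 = uniform usage; positive
#'   values emulate a dual-meaning codon avoided near the true stop).
#' @param introns If `TRUE`, complete genes receive one GT..AG intron at a
#'   codon boundary (two CDS segments); default single-segment models.
#' @param suppressor_trna Emit suppressor tRNA gene(s) with CTA anticodons.
#' @param n_suppressors Number of suppressor tRNAs when `suppressor_trna`.
#' @param telomere_cap Cap contigs with ciliate telomeric repeats
#'   (CCCCAAA / GGGGTTT).
#' @param query_id Row name used for the query sequence in alignments.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_taxa = 10L,
                         query_table_id = 16L,
                         n_orthogroups = 50L,
                         genes_per_genome = 200L,
                         mean_gene_len_codons = 300L,
                         conserved_column_fraction = 0.5,
                         column_identity_at_conserved = 0.85,
                         reassigned_codon_family_usage = 0.08,
                         stop_usage = NULL,
                         gc_bias = 0.35,
                         partial_gene_fraction = 0.1,
                         gap_rate = 0.05,
                         genes_per_contig = 10L,
                         mean_intergenic_len = 60L,
                         minus_strand_fraction = 0.5,
                         target_tail_exclusion = 0,
                         introns = FALSE,
                         suppressor_trna = TRUE,
                         n_suppressors = 1L,
                         telomere_cap = FALSE,
                         query_id = "query_taxon") {
  code <- genetic_code(query_table_id)
  stop_usage <- stop_usage %||% default_stop_usage(query_table_id)
  stop_usage <- stop_usage[c("TAA", "TAG", "TGA")]
  stop_usage[is.na(stop_usage)] <- 0
  names(stop_usage) <- c("TAA", "TAG", "TGA")
  probs <- c(conserved_column_fraction, reassigned_codon_family_usage,
             gc_bias, partial_gene_fraction, gap_rate,
             minus_strand_fraction, target_tail_exclusion, stop_usage)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities in a synth_config must lie in [0, 1]")
  }
  if (column_identity_at_conserved < 0.7 || column_identity_at_conserved > 1) {
    abort("column_identity_at_conserved must lie in [0.7, 1]")
  }
  if (abs(sum(stop_usage) - 1) > 1e-8) {
    abort("stop_usage must sum to 1 over TAA, TAG, TGA")
  }
  sense <- setdiff(names(stop_usage), code$stop_codons)
  if (any(stop_usage[sense] > 0)) {
    abort(sprintf(
      "stop_usage assigns mass to %s, which is a sense codon under table %d",
      paste(sense[stop_usage[sense] > 0], collapse = ", "), code$table_id))
  }
  structure(
    list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
         query_table_id = as.integer(query_table_id),
         n_orthogroups = as.integer(n_orthogroups),
         genes_per_genome = as.integer(genes_per_genome),
         mean_gene_len_codons = as.integer(mean_gene_len_codons),
         conserved_column_fraction = conserved_column_fraction,
         column_identity_at_conserved = column_identity_at_conserved,
         reassigned_codon_family_usage = reassigned_codon_family_usage,
         stop_usage = stop_usage, gc_bias = gc_bias,
         partial_gene_fraction = partial_gene_fraction,
         gap_rate = gap_rate, genes_per_contig = as.integer(genes_per_contig),
         mean_intergenic_len = as.integer(mean_intergenic_len),
         minus_strand_fraction = minus_strand_fraction,
         target_tail_exclusion = target_tail_exclusion,
         introns = introns,
         suppressor_trna = suppressor_trna,
         n_suppressors = as.integer(n_suppressors),
         telomere_cap = telomere_cap, query_id = query_id),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> seed %d, table %d, %d genes, %d orthogroups, %d taxa\n",
    x$seed, x$query_table_id, x$genes_per_genome, x$n_orthogroups, x$n_taxa))
  cat(sprintf("  stop usage: TAA %.2f  TAG %.2f  TGA %.2f | reassigned-family usage %.3f\n",
              x$stop_usage[["TAA"]], x$stop_usage[["TAG"]],
              x$stop_usage[["TGA"]], x$reassigned_codon_family_usage))
  invisible(x)
}

# Reassigned codons = family members that are stop codons under table 1.
reassigned_codons <- function(code) {
  std_stops <- c("TAA", "TAG", "TGA")
  intersect(names(code$codon_map)[code$codon_map != STOP_CHAR], std_stops)
}
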