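# Conserved-site codon-meaning voting: the core statistic. Candidate
# (masked) codons are located in orthogroup alignment columns; columns that
# are highly conserved across the background rows vote with their modal
# residue, and the votes are summarised per codon.

#' Map masked residues of a gene to alignment columns
#'
#' Walks the query row of an orthogroup alignment alongside the gene's
#' codons and returns, for every masked (`"X"`) residue, the 0-based
#' alignment column holding it together with the underlying codon. Gap
#' characters in the query row consume no codon. Residues are checked
#' against the gene's masked protein position-by-position (a mask character
#' on either side matches anything).
#'
#' @param cds One row of a [translate_cds()] tibble (or a list with
#'   `gene_id`, `codons`, `protein`, `has_stop`).
#' @param msa Named character vector of aligned rows.
#' @param query_id Name of the query row in `msa`.
#' @return Tibble with columns `column` (0-based) and `codon`.
#' @export
map_codons_to_columns <- function(cds, msa, query_id) {
  if (is.data.frame(cds)) {
    stopifnot(nrow(cds) == 1)
    cds <- as.list(cds)
    cds$codons <- cds$codons[[1]]
  }
  row <- msa[[query_id]]
  if (is.null(row)) abort(sprintf("query row '%s' absent from alignment", query_id))
  chars <- str_chars(row)
  resid_cols <- which(chars != "-")
  prot <- str_chars(cds$protein)
  if (length(resid_cols) != length(prot)) {
    abort(sprintf(
      "gene '%s': ungapped query row has %d residues but the protein has %d",
      cds$gene_id, length(resid_cols), length(prot)))
  }
  row_res <- chars[resid_cols]
  clash <- row_res != prot & row_res != MASK_CHAR & prot != MASK_CHAR
  if (any(clash)) {
    abort(sprintf("gene '%s': query row disagrees with the protein at %d position(s)",
                  cds$gene_id, sum(clash)))
  }
  codons <- internal_codons(cds$codons, isTRUE(cds$has_stop))
  masked <- which(prot == MASK_CHAR)
  tibble(column = resid_cols[masked] - 1L, codon = codons[masked])
}

#' Conservation of one alignment column
#'
#' Tallies the non-query rows at a column, excluding gaps and mask
#' characters from both the mode and the identity denominator. Returns
#' `NULL` when fewer than `min_depth` background residues remain or when
#' the mode is tied (such sites are discarded rather than split).
#'
#' @param msa Named character vector of aligned rows.
#' @param column 0-based column index.
#' @param query_id Name of the query row (excluded from the tally).
#' @param min_depth Minimum number of scoring background residues.
#' @return A list `(modal_aa, identity, n_background)`, or `NULL`.
#' @export
column_conservation <- function(msa, column, query_id, min_depth = 4L) {
  if (column < 0 || column >= nchar(msa[[1]])) {
    abort(sprintf("column %d outside alignment of width %d", column,
                  nchar(msa[[1]])))
  }
  bg <- msa[names(msa) != query_id]
  res <- substring(bg, column + 1L, column + 1L)
  res <- res[!res %in% c("-", ".", MASK_CHAR)]
  n <- length(res)
  if (n < min_depth) return(NULL)
  tab <- sort(table(res), decreasing = TRUE)
  if (length(tab) > 1 && tab[[1]] == tab[[2]]) return(NULL)  # tied mode
  list(modal_aa = names(tab)[[1]], identity = unname(tab[[1]]) / n,
       n_background = n)
}

#' Collect conserved-site hits for one gene against its orthogroup
#'
#' @param cds One row of a [translate_cds()] tibble.
#' @param msa Named character vector of aligned rows.
#' @param query_id Name of the query row.
#' @param orthogroup_id Identifier recorded on each hit.
#' @param min_depth Passed to [column_conservation()].
#' @return Tibble of hits: `orthogroup_id`, `column`, `query_codon`,
#'   `n_background`, `modal_aa`, `identity`.
#' @export
conserved_site_hits <- function(cds, msa, query_id, orthogroup_id,
                                min_depth = 4L) {
  sites <- map_codons_to_columns(cds, msa, query_id)
  if (nrow(sites) == 0) {
    return(tibble(orthogroup_id = character(0), column = integer(0),
                  query_codon = character(0), n_background = integer(0),
                  modal_aa = character(0), identity = double(0)))
  }
  cons <- map(sites$column, column_conservation, msa = msa,
              query_id = query_id, min_depth = min_depth)
  ok <- !map_lgl(cons, is.null)
  tibble(orthogroup_id = orthogroup_id,
         column = sites$column[ok],
         query_codon = sites$codon[ok],
         n_background = map_int(cons[ok], "n_background"),
         modal_aa = map_chr(cons[ok], "modal_aa"),
         identity = map_dbl(cons[ok], "identity"))
}

#' Infer the amino-acid meaning of a codon from conserved-site hits
#'
#' Restricts the hits to those at highly conserved columns (identity at or
#' above `threshold`; the bound is inclusive, so a column at exactly 0.70
#' contributes) and tallies the modal amino acid over the qualifying
#' sites. The most numerous amino acid and its share of the sites are the
#' evidence for the codon's meaning.
#'
#' @param hits Tibble from [conserved_site_hits()] (rows for other codons
#'   are ignored after filtering on `codon`).
#' @param codon Candidate codon (DNA or RNA spelling).
#' @param threshold Conservation threshold, default 0.70.
#' @return Object of class `codon_meaning`: list with `codon`, `n_sites`,
#'   `aa_counts`, `top_aa`, `top_fraction`, `threshold`. When no site
#'   qualifies, `n_sites` is 0, `top_aa` is `NA` and the object is flagged
#'   `insufficient_evidence`.
#' @export
infer_codon_meaning <- function(hits, codon, threshold = 0.70) {
  codon <- codon_dna(codon)
  use <- hits[hits$query_codon == codon & hits$identity >= threshold, ]
  counts <- sort(table(use$modal_aa), decreasing = TRUE)
  counts <- setNames(as.integer(counts),
                     names(counts) %||% character(0))
  n <- nrow(use)
  structure(
    list(codon = codon,
         n_sites = n,
         aa_counts = counts,
         top_aa = if (n > 0) names(counts)[[1]] else NA_character_,
         top_fraction = if (n > 0) unname(counts[[1]]) / n else NA_real_,
         threshold = threshold,
         insufficient_evidence = n == 0),
    class = "codon_meaning")
}

#' @export
print.codon_meaning <- function(x, ...) {
  cat(sprintf("<codon_meaning> %s: %d conserved site(s)", codon_rna(x$codon),
              x$n_sites))
  if (x$insufficient_evidence) {
    cat(" — insufficient evidence\n")
  } else {
    cat(sprintf("; top %s (%.1f%%)\n", x$top_aa, 100 * x$top_fraction))
  }
  invisible(x)
}

#' Normalised residue frequencies for a sequence logo
#'
#' @param summary A `codon_meaning` object with at least one site.
#' @return Tibble `aa`, `count`, `freq` (frequencies sum to 1), ordered by
#'   decreasing frequency — the single-column logo of the codon's meaning.
#' @export
logo_counts <- function(summary) {
  stopifnot(inherits(summary, "codon_meaning"))
  if (summary$n_sites == 0) {
    abort(sprintf("no qualifying sites for codon %s; cannot build logo counts",
                  summary$codon))
  }
  tibble(aa = names(summary$aa_counts),
         count = as.integer(summary$aa_counts),
         freq = as.integer(summary$aa_counts) / summary$n_sites)
}

#' Scan candidate codons across a genome and its orthogroup alignments
#'
#' Runs the full masked-translation + conserved-site voting procedure for
#' each candidate codon (by default the three standard stops). Genes are
#' translated under `table_id` with every candidate codon masked to `"X"`;
#' each orthogroup alignment (named by its query gene) is scanned for
#' masked residues at conserved columns; and each codon is called
#' "sense" for amino acid Z when at least `call_floor` qualifying sites
#' agree at `call_fraction` or more, else "stop/undetermined".
#'
#' @param genome Named contig sequences.
#' @param models CDS segment tibble ([read_gene_models()]).
#' @param msas Named list of alignments; each name must be the gene id of
#'   the alignment's query sequence.
#' @param table_id Base translation table used for translation (default 1).
#' @param codons Candidate codons (default `TAA`, `TAG`, `TGA`).
#' @param query_id Name of the query row inside each alignment.
#' @param min_depth,threshold Conservation filters (see
#'   [column_conservation()] and [infer_codon_meaning()]).
#' @param call_floor Minimum qualifying sites to call a codon sense.
#' @param call_fraction Minimum top-residue fraction to call a codon sense.
#' @return Object of class `codon_scan`: tibble with one row per codon
#'   (`codon`, `call`, `aa`, `n_sites`, `top_fraction`), plus attributes
#'   `summaries` (the `codon_meaning` objects) and `hits` (all conserved
#'   site hits).
#' @export
scan_all_codons <- function(genome, models, msas, table_id = 1L,
                            codons = c("TAA", "TAG", "TGA"),
                            query_id = "query_taxon",
                            min_depth = 4L, threshold = 0.70,
                            call_floor = 20L, call_fraction = 0.5) {
  codons <- codon_dna(codons)
  code <- genetic_code(table_id)
  cds <- extract_cds(genome, models)
  cds <- suppressWarnings(translate_cds(cds, code, mask_codons = codons))
  gene_ids <- intersect(names(msas), cds$gene_id)
  if (length(gene_ids) == 0) {
    abort("no alignment names match gene ids; name each alignment by its query gene")
  }
  cds_by_gene <- split(cds, cds$gene_id)
  hits <- map(gene_ids, \(g) {
    conserved_site_hits(cds_by_gene[[g]], msas[[g]], query_id,
                        orthogroup_id = g, min_depth = min_depth)
  }) |> bind_rows()
  summaries <- map(codons, \(cd) infer_codon_meaning(hits, cd, threshold))
  names(summaries) <- codons
  res <- tibble(
    codon = unname(codons),
    n_sites = unname(map_int(summaries, "n_sites")),
    top_fraction = unname(map_dbl(summaries, \(s) s$top_fraction %||% NA_real_)),
    aa = unname(map_chr(summaries, \(s) s$top_aa %||% NA_character_))) |>
    mutate(call = ifelse(
      .data$n_sites >= call_floor & !is.na(.data$top_fraction) &
        .data$top_fraction >= call_fraction,
      paste0("sense:", .data$aa), "stop/undetermined")) |>
    select("codon", "call", "aa", "n_sites", "top_fraction")
  attr(res, "summaries") <- summaries
  attr(res, "hits") <- hits
  class(res) <- c("codon_scan", class(res))
  res
}
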