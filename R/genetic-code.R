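# Genetic-code tables, CDS extraction and masked translation.

the <- new.env(parent = emptyenv())

codon_table_data <- function() {
  if (is.null(the$codon_tables)) {
    path <- system.file("extdata", "genetic_code_tables.tsv",
                        package = "stopscan", mustWork = TRUE)
    the$codon_tables <- readr::read_tsv(path, show_col_types = FALSE,
                                        progress = FALSE)
  }
  the$codon_tables
}

#' Load an NCBI translation table
#'
#' Returns the 64-codon map for one of the nuclear genetic codes handled by
#' the pipeline: table 1 (standard), table 6 (ciliate nuclear, UAA/UAG =
#' Gln), table 15 (UAG = Gln, UAA/UGA stop) and table 16 (UAG = Leu,
#' UAA/UGA stop). Codons are keyed as DNA trinucleotides; stops map to
#' `"*"`.
#'
#' @param table_id Integer NCBI translation-table number (1, 6, 15 or 16).
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `name`, `codon_map` (named character of length 64), `stop_codons` and
#'   `start_codons`.
#' @examples
#' genetic_code(16)$codon_map[["TAG"]]  # "L"
#' @export
genetic_code <- function(table_id) {
  tab <- codon_table_data()
  ids <- unique(tab$table_id)
  if (length(table_id) != 1 || !table_id %in% ids) {
    abort(sprintf("unsupported translation table '%s'; supported tables: %s",
                  paste(table_id, collapse = ","),
                  paste(sort(ids), collapse = ", ")))
  }
  rows <- tab[tab$table_id == table_id, ]
  structure(
    list(table_id = as.integer(table_id),
         name = rows$name[[1]],
         codon_map = setNames(rows$aa, rows$codon),
         stop_codons = rows$codon[rows$aa == STOP_CHAR],
         start_codons = "ATG"),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> NCBI table %d (%s)\n", x$table_id, x$name))
  cat("  stop codons:", paste(codon_rna(x$stop_codons), collapse = " "), "\n")
  invisible(x)
}

#' Synonymous codon family of an amino acid
#'
#' @param code A [genetic_code()].
#' @param amino_acid One-letter amino-acid code.
#' @return Character vector of codons mapping to `amino_acid` under `code`.
#' @export
codon_family <- function(code, amino_acid) {
  fam <- names(code$codon_map)[code$codon_map == amino_acid]
  if (length(fam) == 0) {
    abort(sprintf("amino acid '%s' is not encoded by table %d",
                  amino_acid, code$table_id))
  }
  fam
}

#' Read gene models from GFF3
#'
#' Imports CDS features (1-based inclusive on disk) and returns one row per
#' CDS segment with 0-based half-open coordinates, ordered 5'-to-3' in
#' transcript orientation within each gene. The gene identifier is taken
#' from the `Parent` attribute when present, else from `ID`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `seq_id`, `strand`, `start`,
#'   `end` (0-based half-open) and `phase`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  parent_raw <- S4Vectors::mcols(gr)$Parent
  parent <- vapply(as.list(parent_raw),
                   \(p) if (length(p) > 0) p[[1]] else NA_character_,
                   character(1))
  id <- as.character(S4Vectors::mcols(gr)$ID %||% rep(NA_character_, length(gr)))
  gene_id <- ifelse(is.na(parent), id, sub("^mRNA:", "", parent))
  phase <- suppressWarnings(as.integer(as.character(S4Vectors::mcols(gr)$phase)))
  if (all(is.na(phase))) {
    inform("GFF3 CDS features carry no phase; assuming phase 0")
    phase <- rep(0L, length(gr))
  }
  phase[is.na(phase)] <- 0L
  tbl <- tibble(
    gene_id = gene_id,
    seq_id = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    phase = phase)
  tbl |>
    group_by(.data$gene_id) |>
    arrange(if (first(.data$strand) == "-") dplyr::desc(.data$start) else .data$start,
            .by_group = TRUE) |>
    ungroup()
}

#' Extract coding sequences from a genome and gene models
#'
#' Concatenates CDS segments in transcript orientation (minus-strand
#' segments are reverse-complemented), honours the phase of the first
#' segment, and splits the spliced sequence into codons. Completeness with
#' respect to a genetic code is assigned later by [translate_cds()]; here
#' only the start codon and frame are checked.
#'
#' @param genome Named character vector of contig sequences (see
#'   [read_genome()]).
#' @param models Tibble of CDS segments as returned by [read_gene_models()].
#' @return Tibble with one row per gene: `gene_id`, `seq_id`, `strand`,
#'   `codons` (list-column of codon vectors), `n_codons`, `has_start`,
#'   `frame_ok` (spliced length divisible by 3).
#' @export
extract_cds <- function(genome, models) {
  genome <- as_genome(genome)
  missing <- setdiff(unique(models$seq_id), names(genome))
  if (length(missing) > 0) {
    abort(sprintf("contigs absent from genome: %s",
                  paste(missing, collapse = ", ")))
  }
  lens <- nchar(genome)
  bad <- models$end > lens[models$seq_id] | models$start < 0
  if (any(bad)) {
    abort(sprintf("CDS coordinates out of contig bounds for gene(s): %s",
                  paste(unique(models$gene_id[bad]), collapse = ", ")))
  }
  per_gene <- models |>
    mutate(piece = substring(genome[.data$seq_id], .data$start + 1L, .data$end)) |>
    group_by(.data$gene_id) |>
    summarise(seq_id = first(.data$seq_id),
              strand = first(.data$strand),
              phase = first(.data$phase),
              spliced = {
                p <- .data$piece
                if (first(.data$strand) == "-") p <- revcomp(p)
                paste(p, collapse = "")
              },
              .groups = "drop")
  per_gene |>
    mutate(spliced = substring(.data$spliced, .data$phase + 1L),
           codons = map(.data$spliced, split_codons),
           n_codons = lengths(.data$codons),
           has_start = map_lgl(.data$codons,
                               \(x) length(x) > 0 && x[[1]] == "ATG"),
           frame_ok = nchar(.data$spliced) %% 3L == 0L) |>
    select("gene_id", "seq_id", "strand", "codons", "n_codons",
           "has_start", "frame_ok")
}

# Translate one codon vector. Returns list(protein, has_stop, truncated).
translate_one <- function(codons, map, stop_codons, mask_codons) {
  if (length(codons) == 0) {
    return(list(protein = "", has_stop = FALSE, truncated = FALSE))
  }
  n <- length(codons)
  has_stop <- codons[[n]] %in% stop_codons
  body <- if (has_stop) codons[-n] else codons
  aa <- unname(map[body])
  aa[is.na(aa) | grepl("N", body, fixed = TRUE)] <- MASK_CHAR
  if (!is.null(mask_codons)) aa[body %in% mask_codons] <- MASK_CHAR
  truncated <- FALSE
  internal_stop <- which(aa == STOP_CHAR)
  if (length(internal_stop) > 0) {
    truncated <- TRUE
    aa <- aa[seq_len(internal_stop[[1]] - 1L)]
  }
  list(protein = paste(aa, collapse = ""), has_stop = has_stop,
       truncated = truncated)
}

#' Translate coding sequences under a genetic code, with codon masking
#'
#' Translates each gene's codons under `code`. Any codon listed in
#' `mask_codons` is rendered as `"X"` regardless of its meaning under the
#' table — this is the masking device used to carry candidate stop codons
#' through orthogroup alignment. Codons containing `N` also become `"X"`.
#' A terminal stop contributes no residue; an internal, unmasked stop
#' triggers a warning and truncation of the protein at that codon, and the
#' gene is flagged so downstream complete-gene statistics exclude it.
#'
#' @param cds Tibble from [extract_cds()].
#' @param code A [genetic_code()].
#' @param mask_codons Character vector of codons to mask to `"X"`, or
#'   `NULL`.
#' @return `cds` with added columns `protein`, `has_stop`, `truncated` and
#'   `complete` (start + stop + in-frame + no internal stop).
#' @export
translate_cds <- function(cds, code, mask_codons = NULL) {
  if (!is.null(mask_codons)) mask_codons <- codon_dna(mask_codons)
  tr <- map(cds$codons, translate_one, map = code$codon_map,
            stop_codons = code$stop_codons, mask_codons = mask_codons)
  out <- cds |>
    mutate(protein = map_chr(tr, "protein"),
           has_stop = map_lgl(tr, "has_stop"),
           truncated = map_lgl(tr, "truncated"),
           complete = .data$has_start & .data$has_stop & .data$frame_ok &
             !.data$truncated)
  n_trunc <- sum(out$truncated)
  if (n_trunc > 0) {
    warn(sprintf(
      "%d gene(s) carry an internal stop codon under table %d and were truncated",
      n_trunc, code$table_id))
  }
  out
}

# Internal codons of one gene: terminal stop removed when present.
internal_codons <- function(codons, has_stop) {
  if (has_stop && length(codons) > 0) codons[-length(codons)] else codons
}
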