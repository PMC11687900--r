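# Dual-meaning (stop-vs-sense) tests that are independent of the genome
# annotation: the C-terminus alignment codon tally and the gene-body
# positional frequency profile with its depletion test.

PAF_COLS <- c("query_id", "query_len", "query_start", "query_end", "strand",
              "target_id", "target_len", "target_start", "target_end",
              "n_match", "block_len", "mapq")

#' Read protein-to-genome alignments (PAF, protein-query dialect)
#'
#' Reads the first 12 standard PAF columns (optional SAM-style tags are
#' ignored). Query coordinates are residues, target coordinates
#' nucleotides; both half-open, as emitted by spliced protein aligners.
#'
#' @param path Path to a PAF file.
#' @return Tibble of alignment records.
#' @export
read_paf <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(raw) < 12) abort(sprintf("'%s' has %d columns; PAF needs 12", path, ncol(raw)))
  raw <- raw[, 1:12]
  names(raw) <- PAF_COLS
  raw |>
    mutate(across(c("query_len", "query_start", "query_end", "target_len",
                    "target_start", "target_end", "n_match", "block_len",
                    "mapq"), as.integer),
           strand = as.character(.data$strand))
}

write_paf <- function(alignments, path) {
  readr::write_tsv(alignments[, PAF_COLS], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read alignments from the simplified tabular dialect
#'
#' A header-bearing TSV with the alignment-record fields (any order):
#' `query_id`, `query_len`, `query_start`, `query_end`, `strand`,
#' `target_id`, `target_start`, `target_end` (plus optional extras).
#'
#' @param path Path to the TSV file.
#' @return Tibble of alignment records.
#' @export
read_alignments_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(PAF_COLS[c(1:9)], c("target_len", names(x)))
  if (length(need) > 0) {
    abort(sprintf("alignment TSV lacks column(s): %s", paste(need, collapse = ", ")))
  }
  x
}

#' Tally the codon immediately 3' of full-C-terminus alignments
#'
#' Keeps alignments whose query aligns through its final residue
#' (`query_end == query_len`), locates the in-frame trinucleotide
#' immediately 3' of the last aligned codon — in alignment orientation,
#' reverse-complementing on the minus strand — and counts codons at these
#' positions. In a genome where the candidate codon is a true stop these
#' positions are dominated by stop codons; records whose post-alignment
#' codon falls off the contig end are kept in a separate
#' truncated-at-contig-end bucket.
#'
#' @param alignments Tibble of alignment records ([read_paf()]).
#' @param genome Named contig sequences.
#' @param best_per_query Keep only the best alignment (longest query
#'   span, ties by `n_match`) per query before tallying; default `TRUE`.
#' @return Object of class `stop_context_tally`: tibble `codon`, `n`,
#'   `fraction` with attributes `n_cterm`, `n_non_cterm`,
#'   `n_truncated_at_end`.
#' @export
tally_cterm_codons <- function(alignments, genome, best_per_query = TRUE) {
  genome <- as_genome(genome)
  missing <- setdiff(unique(alignments$target_id), names(genome))
  if (length(missing) > 0) {
    abort(sprintf("alignment targets absent from genome: %s",
                  paste(missing, collapse = ", ")))
  }
  if (best_per_query && nrow(alignments) > 0) {
    alignments <- alignments |>
      mutate(.span = .data$query_end - .data$query_start) |>
      group_by(.data$query_id) |>
      arrange(dplyr::desc(.data$.span), dplyr::desc(.data$n_match),
              .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      select(-".span")
  }
  cterm <- alignments$query_end == alignments$query_len
  n_non <- sum(!cterm)
  al <- alignments[cterm, ]
  tlen <- nchar(genome)[al$target_id]
  plus <- al$strand == "+"
  lo <- ifelse(plus, al$target_end, al$target_start - 3L)
  in_bounds <- lo >= 0L & lo + 3L <= tlen
  n_trunc <- sum(!in_bounds)
  al <- al[in_bounds, ]
  lo <- lo[in_bounds]
  codon <- substring(genome[al$target_id], lo + 1L, lo + 3L)
  minus <- al$strand == "-"
  if (any(minus)) codon[minus] <- revcomp(codon[minus])
  counts <- sort(table(codon), decreasing = TRUE)
  out <- tibble(codon = names(counts), n = as.integer(counts)) |>
    mutate(fraction = .data$n / sum(.data$n))
  attr(out, "n_cterm") <- nrow(al)
  attr(out, "n_non_cterm") <- n_non
  attr(out, "n_truncated_at_end") <- n_trunc
  class(out) <- c("stop_context_tally", class(out))
  out
}

#' Compare C-terminus alignment tallies across translation tables
#'
#' When a genome truly translates a candidate stop codon as sense,
#' aligning with a table that treats it as a stop truncates alignments at
#' the first internal occurrence, so fewer queries reach their C-terminus.
#' This compares the full-C-terminus counts (and per-stop-codon fractions)
#' across alignment sets produced under different tables and flags the
#' table maximising the count.
#'
#' @param alignment_sets Named list (names = table ids) of alignment
#'   tibbles over the same genome.
#' @param genome Named contig sequences.
#' @param best_per_query Passed to [tally_cterm_codons()].
#' @return Tibble: `table_id`, `n_cterm`, `frac_TAA`, `frac_TAG`,
#'   `frac_TGA`, `best`.
#' @export
compare_tables <- function(alignment_sets, genome, best_per_query = TRUE) {
  if (length(alignment_sets) < 2) {
    abort("compare_tables needs alignment sets for at least two tables")
  }
  rows <- imap(alignment_sets, \(al, id) {
    tl <- tally_cterm_codons(al, genome, best_per_query = best_per_query)
    fr <- setNames(tl$fraction, tl$codon)
    get0 <- function(k) if (k %in% names(fr)) fr[[k]] else 0
    tibble(table_id = as.integer(id),
           n_cterm = attr(tl, "n_cterm"),
           frac_TAA = get0("TAA"),
           frac_TAG = get0("TAG"),
           frac_TGA = get0("TGA"))
  })
  bind_rows(rows) |>
    mutate(best = .data$n_cterm == max(.data$n_cterm))
}

#' Positional frequency profile of a codon across gene bodies
#'
#' Assigns every internal occurrence of the target codon — and of each
#' synonymous companion codon — to one of `n_bins` equal relative-position
#' bins: occurrence at codon index p (0-based) of a gene with L internal
#' codons falls in bin `floor(n_bins * p / L)`. Only complete genes
#' contribute, and the terminal stop codon is excluded from positions.
#' Per-codon profiles are normalised to sum to 1.
#'
#' @param cds Tibble from [translate_cds()].
#' @param codon Target codon.
#' @param synonymous Character vector of companion (synonymous) codons.
#' @param n_bins Number of relative-position bins (default 20).
#' @return Object of class `gene_body_profile`: tibble `codon`, `bin`,
#'   `count`, `freq`, with attributes `target`, `synonymous`, `n_bins` and
#'   `per_gene` (per-gene bin counts, used by [depletion_test()]).
#' @export
gene_body_profile <- function(cds, codon, synonymous, n_bins = 20L) {
  codon <- codon_dna(codon)
  synonymous <- setdiff(codon_dna(synonymous), codon)
  keep <- cds[cds$complete, ]
  want <- c(codon, synonymous)
  per_gene <- pmap(list(keep$gene_id, keep$codons, keep$has_stop),
                   function(gid, cod, hstop) {
    internal <- internal_codons(cod, hstop)
    L <- length(internal)
    hit <- which(internal %in% want)
    if (length(hit) == 0) return(NULL)
    tibble(gene_id = gid, codon = internal[hit],
           bin = as.integer(floor(n_bins * (hit - 1L) / L)))
  }) |> bind_rows()
  if (nrow(per_gene) == 0) {
    per_gene <- tibble(gene_id = character(0), codon = character(0),
                       bin = integer(0))
  }
  grid <- tidyr::expand_grid(codon = want, bin = 0:(n_bins - 1L))
  counts <- per_gene |>
    count(.data$codon, .data$bin, name = "count") |>
    right_join(grid, by = c("codon", "bin")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    arrange(match(.data$codon, want), .data$bin) |>
    group_by(.data$codon) |>
    mutate(freq = if (sum(.data$count) > 0) .data$count / sum(.data$count)
           else NA_real_) |>
    ungroup()
  attr(counts, "target") <- codon
  attr(counts, "synonymous") <- synonymous
  attr(counts, "n_bins") <- as.integer(n_bins)
  attr(counts, "per_gene") <- per_gene |>
    count(.data$gene_id, .data$codon, .data$bin, name = "count")
  class(counts) <- c("gene_body_profile", class(counts))
  counts
}

#' Test for depletion of a codon near the annotated stop
#'
#' A codon with a dual stop/sense meaning is expected to be avoided close
#' to the true termination codon; a plain sense codon is not. The
#' statistic is the ratio of the target codon's relative mass in the
#' terminal `tail_fraction` of bins to the pooled synonymous codons' mass
#' in the same bins. A bootstrap over genes gives a confidence interval;
#' the verdict is "depleted" exactly when the CI upper bound is below 1.
#'
#' @param profile A [gene_body_profile()] built from at least
#'   `min_occurrences` target-codon occurrences.
#' @param tail_fraction Fraction of bins counted as the 3' tail.
#' @param n_boot Bootstrap replicates over genes.
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param min_occurrences Minimum target occurrences (default 50).
#' @return Object of class `depletion_test`: list with `ratio`,
#'   `ci_lower`, `ci_upper`, `verdict` ("depleted" / "not depleted" /
#'   "insufficient data"), `n_target`, `tail_bins`.
#' @export
depletion_test <- function(profile, tail_fraction = 0.1, n_boot = 1000L,
                           seed = NULL, conf = 0.95, min_occurrences = 50L) {
  stopifnot(inherits(profile, "gene_body_profile"))
  n_bins <- attr(profile, "n_bins")
  target <- attr(profile, "target")
  per_gene <- attr(profile, "per_gene")
  n_tail <- max(1L, as.integer(ceiling(tail_fraction * n_bins)))
  tail_bins <- (n_bins - n_tail):(n_bins - 1L)
  n_target <- sum(per_gene$count[per_gene$codon == target])
  out <- list(ratio = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
              verdict = "insufficient data", n_target = n_target,
              tail_bins = tail_bins, tail_fraction = tail_fraction,
              n_boot = n_boot, conf = conf)
  class(out) <- "depletion_test"
  if (n_target < min_occurrences) return(out)

  # per-gene counts: target/synonymous x tail/total
  pg <- per_gene |>
    mutate(class = ifelse(.data$codon == target, "t", "s"),
           in_tail = .data$bin %in% tail_bins) |>
    group_by(.data$gene_id) |>
    summarise(t_tail = sum(.data$count[.data$class == "t" & .data$in_tail]),
              t_tot = sum(.data$count[.data$class == "t"]),
              s_tail = sum(.data$count[.data$class == "s" & .data$in_tail]),
              s_tot = sum(.data$count[.data$class == "s"]),
              .groups = "drop")
  ratio_of <- function(idx) {
    t_tail <- sum(pg$t_tail[idx]); t_tot <- sum(pg$t_tot[idx])
    s_tail <- sum(pg$s_tail[idx]); s_tot <- sum(pg$s_tot[idx])
    if (t_tot == 0 || s_tot == 0 || s_tail == 0) return(NA_real_)
    (t_tail / t_tot) / (s_tail / s_tot)
  }
  n_gene <- nrow(pg)
  boot <- withr::with_seed(seed %||% 0L, {
    vapply(seq_len(n_boot),
           \(i) ratio_of(sample.int(n_gene, n_gene, replace = TRUE)),
           numeric(1))
  })
  ci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  out$ratio <- ratio_of(seq_len(n_gene))
  out$ci_lower <- ci[[1]]
  out$ci_upper <- ci[[2]]
  out$verdict <- if (!is.na(ci[[2]]) && ci[[2]] < 1) "depleted" else "not depleted"
  out
}

#' @export
print.depletion_test <- function(x, ...) {
  cat(sprintf("<depletion_test> tail ratio %.3f [%.3f, %.3f] over %d occurrences: %s\n",
              x$ratio, x$ci_lower, x$ci_upper, x$n_target, x$verdict))
  invisible(x)
}
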