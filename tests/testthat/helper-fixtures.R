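# Shared fixture builders. Everything is constructed in code; no binary
# fixtures.

# A small, fast configuration for property-style tests.
quick_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, genes_per_genome = 40L, n_orthogroups = 20L,
         mean_gene_len_codons = 120L),
    list(...))
  do.call(synth_config, args)
}

# Hand-built single-segment gene model tibble.
model_row <- function(gene_id, seq_id, strand, start, end, phase = 0L) {
  tibble::tibble(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 phase = as.integer(phase))
}

# Build a translate_cds()-shaped tibble directly from codon vectors, for
# unit tests that do not need a genome. `complete` is computed the same
# way as the pipeline: ATG start + terminal stop under the table.
cds_from_codons <- function(codon_list, code, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sprintf("t%03d", seq_along(codon_list))
  cds <- tibble::tibble(
    gene_id = gene_ids, seq_id = "ctg", strand = "+",
    codons = codon_list,
    n_codons = lengths(codon_list),
    has_start = vapply(codon_list, function(x) x[[1]] == "ATG", logical(1)),
    frame_ok = TRUE)
  translate_cds(cds, code)
}

`%||%` <- rlang::`%||%`

# Independent brute-force recount of conserved-site votes for one codon,
# re-reading the raw bundle files and the ground truth with plain loops.
# Used as the oracle against scan_all_codons(); deliberately shares no
# code with the package internals.
recount_aa_counts <- function(bundle_dir, codon = "TAG", threshold = 0.70,
                              min_depth = 4L, query_id = "query_taxon") {
  truth <- utils::read.delim(file.path(bundle_dir, "truth_genes.tsv"))
  msa_files <- list.files(file.path(bundle_dir, "msa"), full.names = TRUE)
  counts <- integer(0)
  for (f in msa_files) {
    gid <- sub("\\.fa$", "", basename(f))
    cds_nt <- truth$cds[truth$gene_id == gid]
    n <- nchar(cds_nt)
    codons <- substring(cds_nt, seq(1, n - 2, 3), seq(3, n, 3))
    if (truth$has_stop[truth$gene_id == gid]) {
      codons <- codons[-length(codons)]
    }
    # read aligned fasta naively
    lines <- readLines(f)
    ids <- which(startsWith(lines, ">"))
    rows <- list()
    for (k in seq_along(ids)) {
      to <- if (k < length(ids)) ids[k + 1] - 1 else length(lines)
      rows[[sub("^>", "", lines[ids[k]])]] <-
        paste(lines[(ids[k] + 1):to], collapse = "")
    }
    qrow <- strsplit(rows[[query_id]], "")[[1]]
    bg <- rows[names(rows) != query_id]
    resid_cols <- which(qrow != "-")
    ci <- 0L
    for (col in resid_cols) {
      ci <- ci + 1L
      if (qrow[col] != "X" || codons[ci] != codon) next
      obs <- vapply(bg, function(r) substr(r, col, col), character(1))
      obs <- obs[!obs %in% c("-", ".", "X")]
      if (length(obs) < min_depth) next
      tb <- table(obs)
      top <- max(tb)
      if (sum(tb == top) > 1) next          # tied mode: discard
      if (top / length(obs) < threshold) next
      aa <- names(tb)[which.max(tb)]
      counts[aa] <- (if (aa %in% names(counts)) counts[[aa]] else 0L) + 1L
    }
  }
  if (length(counts) == 0) return(setNames(integer(0), character(0)))
  counts[order(-counts, names(counts))]
}
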