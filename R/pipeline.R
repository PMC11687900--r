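# Orchestration: run the full analysis over one genome's inputs, and
# materialise a complete synthetic bundle on disk.

write_gff3 <- function(models, path, source = "stopscan") {
  genes <- models |>
    group_by(.data$gene_id) |>
    summarise(seq_id = first(.data$seq_id), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  gene_lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        genes$seq_id, source, genes$start + 1L, genes$end,
                        genes$strand, genes$gene_id)
  cds_lines <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                       models$seq_id, source, models$start + 1L, models$end,
                       models$strand, models$phase, models$gene_id,
                       models$gene_id)
  ord <- order(c(genes$start, models$start))
  readr::write_lines(c("##gff-version 3", c(gene_lines, cds_lines)[ord]), path)
  invisible(path)
}

#' Write a complete synthetic input bundle to disk
#'
#' Runs all four generators under one configuration and writes every file
#' the analysis pipeline consumes — genome FASTA, GFF3 gene models, masked
#' protein FASTA, per-orthogroup aligned FASTA, PAF alignments under table
#' 1 and the query table, tRNAscan-style predictions with sequences and
#' structures — plus ground-truth TSVs and a checksum manifest.
#' Regenerating with the same config yields identical manifest hashes.
#'
#' @param config A [synth_config()].
#' @param outdir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, a list with the simulation objects and the manifest
#'   tibble (`file`, `md5`).
#' @export
run_synth <- function(config, outdir, overwrite = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !overwrite) {
    abort(sprintf("output directory '%s' is not empty; set overwrite = TRUE",
                  outdir))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gff3(sim$models, file.path(outdir, "genes.gff3"))
  write_fasta(sim$masked_proteins, file.path(outdir, "proteins.faa"))

  ortho <- NULL
  if (config$n_orthogroups > 0) {
    ortho <- simulate_orthogroups(config, sim$proteins, sim$masked_proteins)
    msa_dir <- file.path(outdir, "msa")
    dir.create(msa_dir, showWarnings = FALSE)
    for (og in names(ortho$msas)) {
      write_fasta(ortho$msas[[og]], file.path(msa_dir, paste0(og, ".fa")))
    }
    readr::write_tsv(ortho$truth, file.path(outdir, "truth_columns.tsv"),
                     progress = FALSE)
  }

  for (tid in unique(c(1L, config$query_table_id))) {
    al <- simulate_alignments(config, sim, table_id = tid)
    write_paf(al, file.path(outdir, sprintf("aln_table%d.paf", tid)))
  }

  trnas <- simulate_trnas(config)
  write_trnascan(trnas$trnas, file.path(outdir, "trnas.tsv"))
  write_fasta(setNames(trnas$trnas$sequence, trnas$trnas$trna_id),
              file.path(outdir, "trna.fa"))
  readr::write_tsv(trnas$trnas[, c("trna_id", "sequence", "structure")],
                   file.path(outdir, "trna_struct.tsv"), progress = FALSE)
  write_fasta(trnas$contigs, file.path(outdir, "trna_contigs.fa"))
  readr::write_tsv(trnas$truth, file.path(outdir, "truth_trnas.tsv"),
                   progress = FALSE)

  readr::write_tsv(
    sim$truth |>
      mutate(cds = map_chr(.data$codons, paste, collapse = "")) |>
      select(-"codons"),
    file.path(outdir, "truth_genes.tsv"), progress = FALSE)

  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(outdir, files))))
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  invisible(list(sim = sim, ortho = ortho, trnas = trnas,
                 manifest = manifest, outdir = outdir))
}

#' Run the full reassignment analysis on one genome
#'
#' Executes the pipeline stages in order — CDS extraction and masked
#' translation, conserved-site codon-meaning voting, the C-terminus
#' stop-context tally, the gene-body depletion test, codon-usage
#' statistics and the suppressor-tRNA survey — and assembles a structured
#' report. Sections whose optional inputs are absent are marked
#' `"not run"` rather than failing.
#'
#' @param genome_fa Path to the genome FASTA.
#' @param gff Path to the GFF3 gene models.
#' @param msa_dir Directory of per-orthogroup aligned FASTA files, each
#'   named `<gene_id>.fa` after its query gene; `NULL` skips code
#'   inference.
#' @param alignments Named list (names = table ids) of PAF paths or
#'   alignment tibbles; `NULL` skips the stop-context section.
#' @param trna_tsv,trna_struct Paths to tRNAscan-SE output and a
#'   sequence/structure TSV (`trna_id`, `sequence`, `structure`); `NULL`
#'   skips the tRNA section.
#' @param table_id Base translation table for masked translation.
#' @param candidate_codons Codons scanned for reassignment.
#' @param query_id Query row name inside each alignment.
#' @param min_depth,threshold,call_floor,call_fraction Conservation and
#'   calling parameters (see [scan_all_codons()]).
#' @param n_bins,tail_fraction,n_boot Gene-body profile parameters.
#' @param seed Seed for the bootstrap.
#' @param out_dir If non-`NULL`, write `report.json` and TSV outputs here.
#' @return A list of class `genome_report` with sections
#'   `code_inference`, `stop_context`, `gene_body`, `usage`, `trna` and
#'   `provenance`.
#' @export
run_analysis <- function(genome_fa, gff, msa_dir = NULL, alignments = NULL,
                         trna_tsv = NULL, trna_struct = NULL,
                         table_id = 1L,
                         candidate_codons = c("TAA", "TAG", "TGA"),
                         query_id = "query_taxon",
                         min_depth = 4L, threshold = 0.70,
                         call_floor = 20L, call_fraction = 0.5,
                         n_bins = 20L, tail_fraction = 0.1, n_boot = 1000L,
                         seed = 0L, out_dir = NULL) {
  genome <- read_genome(genome_fa)
  models <- read_gene_models(gff)
  code <- genetic_code(table_id)
  cds_raw <- extract_cds(genome, models)
  config_hash <- rlang::hash(list(table_id, candidate_codons, min_depth,
                                  threshold, call_floor, call_fraction,
                                  n_bins, tail_fraction, n_boot, seed))
  report <- list(provenance = list(
    package = "stopscan",
    version = as.character(utils::packageVersion("stopscan")),
    table_id = table_id, seed = seed, config_hash = config_hash))

  # conserved-site voting
  if (!is.null(msa_dir)) {
    paths <- list.files(msa_dir, pattern = "\\.(fa|fasta|faa)$",
                        full.names = TRUE)
    msas <- map(paths, read_msa)
    names(msas) <- sub("\\.(fa|fasta|faa)$", "", basename(paths))
    scan <- scan_all_codons(genome, models, msas, table_id = table_id,
                            codons = candidate_codons, query_id = query_id,
                            min_depth = min_depth, threshold = threshold,
                            call_floor = call_floor,
                            call_fraction = call_fraction)
    report$code_inference <- scan
    inform(sprintf("code inference: %d alignments scanned, %d conserved-site hits",
                   length(msas), nrow(attr(scan, "hits"))))
  } else {
    report$code_inference <- "not run"
  }

  # stop-context tally across tables
  if (!is.null(alignments) && length(alignments) >= 1) {
    sets <- map(alignments, \(a) if (is.character(a)) read_paf(a) else a)
    report$stop_context <- if (length(sets) >= 2) {
      compare_tables(sets, genome)
    } else {
      tally_cterm_codons(sets[[1]], genome)
    }
  } else {
    report$stop_context <- "not run"
  }

  # usage + gene-body depletion under the working (variant) code
  scan_tbl <- report$code_inference
  work_table <- table_id
  target <- "TAG"
  if (is.data.frame(scan_tbl)) {
    called <- scan_tbl[grepl("^sense:", scan_tbl$call), ]
    if (nrow(called) > 0) {
      target <- called$codon[[which.max(called$n_sites)]]
      aa <- called$aa[[which.max(called$n_sites)]]
      # adopt the matching variant table when the call corresponds to one
      work_table <- if (target == "TAG" && aa == "L") 16L
        else if (target == "TAG" && aa == "Q") 15L
        else table_id
    }
  }
  work_code <- genetic_code(work_table)
  cds <- suppressWarnings(translate_cds(cds_raw, work_code))
  n_in <- nrow(cds); n_complete <- sum(cds$complete)
  inform(sprintf("complete-gene filter: %d of %d gene models kept",
                 n_complete, n_in))
  report$usage <- usage_report(genome, cds, work_code, target_codon = target)
  aa_target <- unname(work_code$codon_map[[target]])
  if (aa_target != STOP_CHAR) {
    fam <- codon_family(work_code, aa_target)
    prof <- gene_body_profile(cds, target, setdiff(fam, target),
                              n_bins = n_bins)
    report$gene_body <- depletion_test(prof, tail_fraction = tail_fraction,
                                       n_boot = n_boot, seed = seed)
    report$gene_body_profile <- prof
  } else {
    report$gene_body <- "not run"
  }

  # suppressor tRNA survey
  if (!is.null(trna_tsv)) {
    trnas <- parse_trnascan(trna_tsv)
    if (!is.null(trna_struct)) {
      ss <- readr::read_tsv(trna_struct, show_col_types = FALSE,
                            progress = FALSE)
      if (nrow(ss) == nrow(trnas)) {  # rows are emitted in file order
        trnas$trna_id <- ss$trna_id
        trnas$sequence <- ss$sequence
        trnas$structure <- ss$structure
      }
    }
    sup <- find_suppressors(trnas)
    trna_section <- list(n_trnas = nrow(trnas), suppressors = sup)
    if (nrow(sup) > 0 && !is.null(trna_struct)) {
      canon <- trnas[!trnas$trna_id %in% sup$trna_id, ]
      trna_section$elements <- map(seq_len(nrow(sup)), \(i) {
        tryCatch(check_identity_elements(sup[i, ]),
                 error = function(e) conditionMessage(e))
      })
      names(trna_section$elements) <- sup$trna_id
      if (nrow(canon) > 0) {
        trna_section$nearest <- map(seq_len(nrow(sup)),
                                    \(i) nearest_isotype(sup[i, ], canon)) |>
          bind_rows()
      }
    }
    report$trna <- trna_section
  } else {
    report$trna <- "not run"
  }

  class(report) <- "genome_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_json <- function(report) {
  as_plain <- function(x) {
    if (is.data.frame(x)) as.data.frame(x)
    else if (inherits(x, "depletion_test")) unclass(x)
    else if (is.list(x)) map(x, as_plain)
    else x
  }
  body <- map(report[setdiff(names(report), "gene_body_profile")], as_plain)
  jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   na = "null", force = TRUE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_file(paste0(report_json(report), "\n"),
                    file.path(out_dir, "report.json"))
  if (is.data.frame(report$code_inference)) {
    readr::write_tsv(as_tibble(report$code_inference),
                     file.path(out_dir, "code_inference.tsv"),
                     progress = FALSE)
    readr::write_tsv(attr(report$code_inference, "hits"),
                     file.path(out_dir, "conserved_site_hits.tsv"),
                     progress = FALSE)
  }
  if (is.data.frame(report$stop_context)) {
    readr::write_tsv(as_tibble(report$stop_context),
                     file.path(out_dir, "stop_context.tsv"), progress = FALSE)
  }
  readr::write_tsv(report$usage, file.path(out_dir, "usage.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}

#' @export
print.genome_report <- function(x, ...) {
  cat("<genome_report>\n")
  if (is.data.frame(x$code_inference)) {
    cat("  code inference:\n")
    for (i in seq_len(nrow(x$code_inference))) {
      r <- x$code_inference[i, ]
      cat(sprintf("    %s -> %s (%d sites, top %.1f%%)\n",
                  codon_rna(r$codon), r$call, r$n_sites,
                  100 * (r$top_fraction %||% NA_real_)))
    }
  }
  if (is.data.frame(x$usage)) {
    cat(sprintf("  usage: %d complete genes; stop UAA %.3f UAG %.3f UGA %.3f\n",
                x$usage$n_complete_genes, x$usage$stop_TAA, x$usage$stop_TAG,
                x$usage$stop_TGA))
  }
  if (inherits(x$gene_body, "depletion_test")) {
    cat(sprintf("  gene body: ratio %.3f [%s]\n", x$gene_body$ratio,
                x$gene_body$verdict))
  }
  if (is.list(x$trna)) {
    cat(sprintf("  tRNA: %d predicted, %d suppressor(s)\n",
                x$trna$n_trnas, nrow(x$trna$suppressors)))
  }
  invisible(x)
}
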