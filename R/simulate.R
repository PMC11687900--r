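# Seeded generators for every input the pipeline consumes: genome + gene
# models, orthogroup alignments, protein-to-genome alignments and tRNA
# predictions, each with ground truth. All randomness is drawn inside
# withr::with_seed() on offsets of config$seed, so a config is a complete,
# reproducible description of a dataset.

SEED_GENOME <- 11L
SEED_ORTHO <- 23L
SEED_ALN <- 37L
SEED_TRNA <- 53L

TELOMERE_5P <- "CCCCAAA"
TELOMERE_3P <- "GGGGTTT"

sample_nt <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# Choose codons for a vector of amino acids under `code`, with GC bias at
# degenerate third positions. Reassigned (former stop) codons are excluded
# here; they are injected separately at the configured family usage.
sample_standard_codons <- function(aa, code, gc) {
  out <- character(length(aa))
  reass <- reassigned_codons(code)
  for (a in unique(aa)) {
    fam <- setdiff(codon_family(code, a), reass)
    w <- ifelse(substring(fam, 3, 3) %in% c("G", "C"), gc, 1 - gc)
    idx <- which(aa == a)
    out[idx] <- if (length(fam) == 1) fam else
      sample(fam, length(idx), replace = TRUE, prob = w / sum(w))
  }
  out
}

#' Simulate a genome with gene models and known ground truth
#'
#' Emits multi-gene contigs under the configured genetic code. Complete
#' genes begin with ATG and end with a stop codon drawn from
#' `config$stop_usage`; under a variant table the reassigned codon is
#' written at a fraction `reassigned_codon_family_usage` of its amino-acid
#' family's positions (never inside the terminal `target_tail_exclusion`
#' fraction of the gene when that is positive). A
#' `partial_gene_fraction` of genes lack their start and/or stop codon.
#' Contigs optionally carry telomeric caps and (behind the `introns` flag)
#' one GT..AG intron per gene.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_genome`: `genome` (named contig
#'   sequences), `models` (CDS segment tibble, 0-based half-open),
#'   `truth` (per-gene tibble with true protein, codons, stop codon and
#'   completeness), `proteins` / `masked_proteins` (named vectors; masked
#'   proteins carry `"X"` at reassigned-codon positions), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  code <- genetic_code(config$query_table_id)
  reass <- reassigned_codons(code)
  reass_aa <- unique(unname(code$codon_map[reass]))
  withr::with_seed(config$seed + SEED_GENOME, {
    n <- config$genes_per_genome
    gene_id <- sprintf("g%04d", seq_len(n))
    body_len <- 29L + rpois(n, max(config$mean_gene_len_codons - 30L, 1L))

    # residues for all gene bodies at once, then codons
    aa_all <- sample(names(AA_FREQ), sum(body_len), replace = TRUE,
                     prob = AA_FREQ)
    gene_of <- rep.int(seq_len(n), body_len)
    pos_in_gene <- sequence(body_len)
    codon_all <- sample_standard_codons(aa_all, code, config$gc_bias)
    if (length(reass) > 0 && config$reassigned_codon_family_usage > 0) {
      in_tail <- pos_in_gene > (1 - config$target_tail_exclusion) *
        body_len[gene_of]
      eligible <- aa_all %in% reass_aa & !in_tail
      use <- eligible &
        runif(length(aa_all)) < config$reassigned_codon_family_usage
      if (any(use)) {
        codon_all[use] <- sample(reass, sum(use), replace = TRUE)
      }
    }
    stops <- sample(names(config$stop_usage), n, replace = TRUE,
                    prob = config$stop_usage)

    codons <- split(codon_all, gene_of)
    names(codons) <- gene_id
    codons <- map2(codons, stops, \(b, s) c("ATG", b, s))

    # partial gene models: trim start codons and/or drop the stop
    is_partial <- runif(n) < config$partial_gene_fraction
    partial_kind <- sample(c("start", "stop", "both"), n, replace = TRUE,
                           prob = c(0.4, 0.4, 0.2))
    has_start <- has_stop <- rep(TRUE, n)
    for (i in which(is_partial)) {
      k <- partial_kind[[i]]
      if (k %in% c("start", "both")) {
        drop <- sample.int(5L, 1L)
        codons[[i]] <- codons[[i]][-seq_len(drop)]
        has_start[i] <- FALSE
      }
      if (k %in% c("stop", "both")) {
        codons[[i]] <- codons[[i]][-length(codons[[i]])]
        has_stop[i] <- FALSE
        # a 3'-truncated model must not end on a reassigned codon: the
        # annotation translation would read a terminal standard-stop
        # trinucleotide as the model's predicted stop
        last <- length(codons[[i]])
        if (codons[[i]][[last]] %in% reass) {
          aa_last <- unname(code$codon_map[[codons[[i]][[last]]]])
          codons[[i]][[last]] <-
            sample_standard_codons(aa_last, code, config$gc_bias)
        }
      }
    }

    internal <- map2(codons, has_stop, internal_codons)
    protein <- map_chr(internal, \(x) paste(code$codon_map[x], collapse = ""))
    masked_protein <- map_chr(internal, \(x) {
      aa <- code$codon_map[x]
      aa[x %in% reass] <- MASK_CHAR
      paste(aa, collapse = "")
    })

    # lay genes onto contigs
    strand <- ifelse(runif(n) < config$minus_strand_fraction, "-", "+")
    contig_of <- (seq_len(n) - 1L) %/% config$genes_per_contig + 1L
    contig_id <- sprintf("contig_%03d", contig_of)
    cap5 <- if (config$telomere_cap) strrep(TELOMERE_5P, 3L) else ""
    cap3 <- if (config$telomere_cap) strrep(TELOMERE_3P, 3L) else ""

    model_rows <- vector("list", n)
    contigs <- character(0)
    for (ct in unique(contig_of)) {
      idx <- which(contig_of == ct)
      pieces <- character(0)
      at <- nchar(cap5)  # 0-based cursor
      if (nzchar(cap5)) pieces <- cap5
      for (i in idx) {
        spacer <- paste(sample_nt(20L + rpois(1L, config$mean_intergenic_len),
                                  config$gc_bias), collapse = "")
        pieces <- c(pieces, spacer)
        at <- at + nchar(spacer)
        cds_nt <- paste(codons[[i]], collapse = "")
        oriented <- if (strand[i] == "-") revcomp(cds_nt) else cds_nt
        n_cod <- length(codons[[i]])
        if (config$introns && n_cod >= 40L) {
          # split at a codon boundary; GT..AG intron, phase 0 both sides
          cut <- 3L * sample(10:(n_cod - 10L), 1L)
          intr <- paste0("GT", paste(sample_nt(46L, config$gc_bias),
                                     collapse = ""), "AG")
          if (strand[i] == "-") {
            cut_g <- nchar(cds_nt) - cut  # boundary in plus orientation
            seq_out <- paste0(substring(oriented, 1, cut_g), intr,
                              substring(oriented, cut_g + 1))
            segs <- tibble(start = c(at, at + cut_g + nchar(intr)),
                           end = c(at + cut_g,
                                   at + nchar(cds_nt) + nchar(intr)))
          } else {
            seq_out <- paste0(substring(oriented, 1, cut), intr,
                              substring(oriented, cut + 1))
            segs <- tibble(start = c(at, at + cut + nchar(intr)),
                           end = c(at + cut,
                                   at + nchar(cds_nt) + nchar(intr)))
          }
        } else {
          seq_out <- oriented
          segs <- tibble(start = at, end = at + nchar(cds_nt))
        }
        model_rows[[i]] <- tibble(
          gene_id = gene_id[i], seq_id = contig_id[i], strand = strand[i],
          start = segs$start, end = segs$end, phase = 0L)
        pieces <- c(pieces, seq_out)
        at <- at + nchar(seq_out)
      }
      tail_sp <- paste(sample_nt(20L + rpois(1L, config$mean_intergenic_len),
                                 config$gc_bias), collapse = "")
      pieces <- c(pieces, tail_sp, cap3)
      contigs[[sprintf("contig_%03d", ct)]] <- paste(pieces, collapse = "")
    }

    models <- bind_rows(model_rows) |>
      group_by(.data$gene_id) |>
      arrange(if (first(.data$strand) == "-") dplyr::desc(.data$start)
              else .data$start, .by_group = TRUE) |>
      ungroup()

    truth <- tibble(
      gene_id = gene_id, seq_id = contig_id, strand = strand,
      codons = unname(codons),
      protein = unname(protein),
      masked_protein = unname(masked_protein),
      stop_codon = ifelse(has_stop, stops, NA_character_),
      has_start = has_start, has_stop = has_stop,
      complete = has_start & has_stop,
      n_internal_reassigned = map_int(
        internal, \(x) sum(x %in% reass)))

    structure(list(genome = contigs, models = models, truth = truth,
                   proteins = setNames(truth$protein, gene_id),
                   masked_proteins = setNames(truth$masked_protein, gene_id),
                   config = config),
              class = "synth_genome")
  })
}

#' Simulate orthogroup protein alignments with known column truth
#'
#' Builds one alignment per orthogroup: the query row (masked protein,
#' `"X"` at reassigned-codon positions) plus `n_taxa - 1` background rows.
#' A `conserved_column_fraction` of columns are conserved — each background
#' row carries the query's true residue with probability
#' `column_identity_at_conserved`; other columns draw residues from a flat
#' Dirichlet column profile. Background cells gap out at `gap_rate`.
#'
#' @param config A [synth_config()].
#' @param proteins Named vector of true (unmasked) query proteins.
#' @param masked Named vector of masked query proteins; defaults to
#'   `proteins` (no masked residues).
#' @return List of class `synth_orthogroups`: `msas` (named list of
#'   aligned named character vectors) and `truth` (tibble of per-column
#'   conservation state and true residue).
#' @export
simulate_orthogroups <- function(config, proteins, masked = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_taxa < 5) {
    abort("n_taxa must be >= 5: conservation voting is undefined at tiny depth")
  }
  masked <- masked %||% proteins
  n_og <- min(config$n_orthogroups, length(proteins))
  ids <- names(proteins)[seq_len(n_og)]
  n_bg <- config$n_taxa - 1L
  taxa <- sprintf("taxon_%02d", seq_len(n_bg) + 1L)
  withr::with_seed(config$seed + SEED_ORTHO, {
    msas <- vector("list", n_og)
    truths <- vector("list", n_og)
    for (k in seq_len(n_og)) {
      true_aa <- str_chars(proteins[[ids[[k]]]])
      L <- length(true_aa)
      conserved <- runif(L) < config$conserved_column_fraction
      m <- matrix("", nrow = n_bg, ncol = L)
      if (any(conserved)) {
        cc <- which(conserved)
        keep <- matrix(runif(n_bg * length(cc)) <
                         config$column_identity_at_conserved,
                       nrow = n_bg)
        rnd <- matrix(sample(AA_ONE, n_bg * length(cc), replace = TRUE,
                             prob = AA_FREQ[AA_ONE]), nrow = n_bg)
        m[, cc] <- ifelse(keep, rep(true_aa[cc], each = n_bg), rnd)
      }
      if (any(!conserved)) {
        # one flat-Dirichlet profile per column, sampled via Gumbel-max
        nc <- sum(!conserved)
        logp <- matrix(log(rexp(20L * nc)), nrow = 20L)
        gumbel <- -log(-log(matrix(runif(20L * nc * n_bg), nrow = 20L)))
        pick <- max.col(t(logp[, rep(seq_len(nc), each = n_bg)] + gumbel))
        m[, !conserved] <- AA_ONE[pick]
      }
      m[matrix(runif(n_bg * L) < config$gap_rate, nrow = n_bg)] <- "-"
      rows <- apply(m, 1, paste, collapse = "")
      msa <- c(setNames(masked[[ids[[k]]]], config$query_id),
               setNames(rows, taxa))
      msas[[k]] <- msa
      truths[[k]] <- tibble(orthogroup_id = ids[[k]],
                            column = seq_len(L) - 1L,
                            conserved = conserved, true_aa = true_aa)
    }
    names(msas) <- ids
    structure(list(msas = msas, truth = bind_rows(truths)),
              class = "synth_orthogroups")
  })
}

# Map a spliced-CDS nucleotide offset (0-based boundary) to a genomic
# 0-based boundary, walking CDS segments in transcript order.
spliced_to_genomic <- function(segs, offset, strand) {
  lens <- segs$end - segs$start
  cum <- cumsum(lens)
  i <- which(offset <= cum)[1]
  prev <- if (i > 1) cum[i - 1] else 0L
  within <- offset - prev
  if (strand == "+") segs$start[i] + within else segs$end[i] - within
}

#' Simulate protein-to-genome alignments under an evaluation table
#'
#' Emits one alignment per gene of a pseudo-reference protein identical to
#' the gene's true protein. When the evaluation table treats an internal
#' codon as a stop, the alignment is truncated at the first such codon so
#' the query C-terminus does not align; otherwise it extends through the
#' last sense codon, leaving the genomic stop codon immediately 3' of the
#' aligned block. Query coordinates are in residues, target coordinates in
#' nucleotides (PAF protein-query dialect).
#'
#' @param config A [synth_config()].
#' @param sim A `synth_genome` from [simulate_genome()].
#' @param table_id Evaluation translation table (which codons are treated
#'   as stops during alignment), not necessarily the generating table.
#' @return Tibble of alignment records (see [read_paf()] for columns).
#' @export
simulate_alignments <- function(config, sim, table_id = 1L) {
  stopifnot(inherits(sim, "synth_genome"))
  eval_stops <- genetic_code(table_id)$stop_codons
  segs_by_gene <- split(sim$models, sim$models$gene_id)
  tlen <- nchar(sim$genome)
  withr::with_seed(config$seed + SEED_ALN + as.integer(table_id), {
    rows <- pmap(list(sim$truth$gene_id, sim$truth$codons,
                      sim$truth$has_stop, sim$truth$strand,
                      sim$truth$seq_id),
                 function(gid, cod, hstop, strand, seqid) {
      internal <- internal_codons(cod, hstop)
      qlen <- length(internal)
      hit <- which(internal %in% eval_stops)
      qend <- if (length(hit) > 0) hit[[1]] - 1L else qlen
      if (qend == 0L) return(NULL)
      segs <- segs_by_gene[[gid]]
      g1 <- spliced_to_genomic(segs, 0L, strand)
      g2 <- spliced_to_genomic(segs, 3L * qend, strand)
      tibble(query_id = paste0("ref_", gid), query_len = qlen,
             query_start = 0L, query_end = qend, strand = strand,
             target_id = seqid, target_len = unname(tlen[[seqid]]),
             target_start = min(g1, g2), target_end = max(g1, g2),
             n_match = 3L * qend, block_len = abs(g2 - g1),
             mapq = 60L)
    })
    bind_rows(rows)
  })
}

#' Simulate tRNA gene predictions
#'
#' Emits a tRNAscan-SE-style prediction set on dedicated small contigs:
#' canonical decoys (Leu-CAA, Leu-TAA, Gln-TTG) always, plus — when
#' `config$suppressor_trna` — `n_suppressors` suppressor tRNAs with CTA
#' anticodons built from the canonical leucine template, carrying the
#' leucyl-synthetase identity elements (discriminator A, G5:C68 and A4:U69
#' acceptor pairs, long variable arm, invariant loop nucleotides). When
#' two or more suppressors are requested, the second differs from the
#' first at exactly five positions: one in the anticodon loop and four in
#' the variable loop. The suppressor contig is telomere-capped when
#' `config$telomere_cap` is set.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_trnas`: `trnas` (tibble with coordinates,
#'   isotype, anticodon, score, sequence, structure), `contigs` (named
#'   contig sequences) and `truth` (role of every emitted gene).
#' @export
simulate_trnas <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  leu <- trna_template("Leu")
  gln <- trna_template("Gln")
  withr::with_seed(config$seed + SEED_TRNA, {
    specs <- list(
      list(id = "decoy_Leu_CAA", role = "decoy", isotype = "Leu",
           seq = set_anticodon(leu, "CAA"), struct = leu$structure,
           anticodon = "CAA"),
      list(id = "decoy_Leu_TAA", role = "decoy", isotype = "Leu",
           seq = set_anticodon(leu, "TAA"), struct = leu$structure,
           anticodon = "TAA"),
      list(id = "decoy_Gln_TTG", role = "decoy", isotype = "Gln",
           seq = set_anticodon(gln, "TTG"), struct = gln$structure,
           anticodon = "TTG"))
    n_sup <- if (config$suppressor_trna) config$n_suppressors else 0L
    sup_seqs <- character(0)
    if (n_sup >= 1) sup_seqs <- set_anticodon(leu, "CTA")
    if (n_sup >= 2) {
      second <- mutate_positions(
        sup_seqs[[1]],
        c(sample(leu$anticodon_loop_flanks, 1L),
          sample(leu$variable_loop, 4L)))
      sup_seqs <- c(sup_seqs, second)
      if (n_sup > 2) {
        for (i in 3:n_sup) {
          extra <- mutate_positions(sup_seqs[[1]],
                                    sample(leu$variable_loop, 2L))
          sup_seqs <- c(sup_seqs, extra)
        }
      }
    }
    for (i in seq_along(sup_seqs)) {
      specs <- c(specs, list(list(
        id = sprintf("suppressor_%02d", i), role = "suppressor",
        isotype = "Leu", seq = sup_seqs[[i]], struct = leu$structure,
        anticodon = "CTA")))
    }
    rows <- vector("list", length(specs))
    contigs <- character(0)
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      seq_trna <- sp$seq
      minus <- sp$role == "decoy" && i == 2L  # one decoy on the minus strand
      flank5 <- paste(sample_nt(40L, config$gc_bias), collapse = "")
      flank3 <- paste(sample_nt(40L, config$gc_bias), collapse = "")
      cap <- config$telomere_cap && sp$role == "suppressor"
      cap5 <- if (cap) strrep(TELOMERE_5P, 3L) else ""
      cap3 <- if (cap) strrep(TELOMERE_3P, 3L) else ""
      insert <- if (minus) revcomp(seq_trna) else seq_trna
      contig <- paste0(cap5, flank5, insert, flank3, cap3)
      cid <- sprintf("trna_contig_%02d", i)
      contigs[[cid]] <- contig
      b0 <- nchar(cap5) + nchar(flank5)            # 0-based start
      e0 <- b0 + nchar(seq_trna)                   # 0-based end
      rows[[i]] <- tibble(
        seq_id = cid, trna_id = sp$id,
        begin = if (minus) e0 else b0 + 1L,        # tRNAscan 1-based,
        end = if (minus) b0 + 1L else e0,          # begin>end on minus
        isotype = sp$isotype, anticodon = sp$anticodon,
        intron_begin = 0L, intron_end = 0L,
        score = round(runif(1, 60, 85), 1),
        sequence = seq_trna, structure = sp$struct)
    }
    trnas <- bind_rows(rows)
    truth <- tibble(trna_id = trnas$trna_id,
                    role = map_chr(specs, "role"),
                    isotype = trnas$isotype, anticodon = trnas$anticodon)
    structure(list(trnas = trnas, contigs = contigs, truth = truth),
              class = "synth_trnas")
  })
}
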