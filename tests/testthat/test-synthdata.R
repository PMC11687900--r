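test_that("all four generators are byte-identical under a fixed seed", {
  cfg <- quick_config(seed = 9, n_suppressors = 2L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  oa <- simulate_orthogroups(cfg, a$proteins, a$masked_proteins)
  ob <- simulate_orthogroups(cfg, b$proteins, b$masked_proteins)
  expect_identical(oa$msas, ob$msas)
  expect_identical(simulate_alignments(cfg, a, 1L),
                   simulate_alignments(cfg, b, 1L))
  expect_identical(simulate_trnas(cfg)$trnas, simulate_trnas(cfg)$trnas)
})

test_that("a degenerate stop distribution puts every complete gene on that stop", {
  cfg <- quick_config(seed = 2, genes_per_genome = 50L,
                      stop_usage = c(TAA = 1, TAG = 0, TGA = 0),
                      partial_gene_fraction = 0)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$complete))
  expect_true(all(sim$truth$stop_codon == "TAA"))
  term <- vapply(sim$truth$codons, function(x) x[[length(x)]], character(1))
  expect_true(all(term == "TAA"))
})

test_that("reassigned-codon family usage matches its configured rate (binomial 99% CI)", {
  cfg <- synth_config(seed = 3, genes_per_genome = 400L,
                      mean_gene_len_codons = 300L, query_table_id = 16L,
                      reassigned_codon_family_usage = 0.1,
                      partial_gene_fraction = 0)
  sim <- simulate_genome(cfg)
  code <- genetic_code(16)
  internal <- unlist(lapply(sim$truth$codons, function(x) x[-length(x)]))
  leu <- internal[code$codon_map[internal] == "L"]
  n <- length(leu)
  expect_gt(n, 1e4)
  phat <- mean(leu == "TAG")
  half <- 2.576 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(phat - 0.1), half)
})

test_that("orthogroup columns honour the conservation configuration", {
  # degenerate settings: every column monomorphic at the true residue
  cfg <- quick_config(seed = 4, conserved_column_fraction = 1,
                      column_identity_at_conserved = 1, gap_rate = 0)
  sim <- simulate_genome(cfg)
  og <- simulate_orthogroups(cfg, sim$proteins, sim$masked_proteins)
  msa <- og$msas[[1]]
  bg <- msa[names(msa) != cfg$query_id]
  truth1 <- og$truth[og$truth$orthogroup_id == names(og$msas)[[1]], ]
  for (j in seq_len(nchar(bg[[1]]))) {
    col <- substring(bg, j, j)
    expect_true(all(col == truth1$true_aa[[j]]))
  }
  # measured fraction of columns passing the 0.70 rule tracks the
  # configured conserved fraction (recount over the generated MSAs)
  cfg2 <- quick_config(seed = 6, n_orthogroups = 20L,
                       conserved_column_fraction = 0.4,
                       column_identity_at_conserved = 0.95, gap_rate = 0)
  sim2 <- simulate_genome(cfg2)
  og2 <- simulate_orthogroups(cfg2, sim2$proteins, sim2$masked_proteins)
  pass <- unlist(lapply(og2$msas, function(msa) {
    bg <- msa[names(msa) != cfg2$query_id]
    vapply(seq_len(nchar(bg[[1]])), function(j) {
      col <- substring(bg, j, j)
      tb <- table(col)
      max(tb) / length(col) >= 0.70
    }, logical(1))
  }))
  # with identity 0.95 essentially every conserved column passes; a few
  # non-conserved columns pass by chance, hence the loose upper margin
  expect_gt(mean(pass), 0.35)
  expect_lt(mean(pass), 0.55)
  expect_error(simulate_orthogroups(quick_config(n_taxa = 4L),
                                    sim$proteins),
               "n_taxa")
})

test_that("simulated alignments truncate exactly at the first internal stop of the evaluation table", {
  cfg <- quick_config(seed = 11, genes_per_genome = 100L,
                      partial_gene_fraction = 0)
  sim <- simulate_genome(cfg)
  al1 <- simulate_alignments(cfg, sim, table_id = 1L)
  al16 <- simulate_alignments(cfg, sim, table_id = 16L)
  truth <- sim$truth
  internal <- lapply(truth$codons, function(x) x[-length(x)])
  first_tag <- vapply(internal, function(x) {
    h <- which(x == "TAG")
    if (length(h)) h[[1]] else NA_integer_
  }, integer(1))
  qlen <- lengths(internal)
  for (i in seq_len(nrow(truth))) {
    r1 <- al1[al1$query_id == paste0("ref_", truth$gene_id[[i]]), ]
    r16 <- al16[al16$query_id == paste0("ref_", truth$gene_id[[i]]), ]
    expect_identical(r16$query_end, qlen[[i]])      # TAG is sense here
    if (is.na(first_tag[[i]])) {
      expect_identical(r1$query_end, qlen[[i]])
    } else {
      expect_identical(r1$query_end, first_tag[[i]] - 1L)
      expect_lt(r1$query_end, r1$query_len)
    }
  }
  # counting oracle: with internal TAGs present, the table treating TAG
  # as sense yields strictly more full-C-terminus alignments
  n_with_tag <- sum(!is.na(first_tag))
  expect_gt(n_with_tag, 0)
  expect_identical(sum(al16$query_end == al16$query_len) -
                     sum(al1$query_end == al1$query_len), n_with_tag)
})

test_that("tRNA generation controls suppressors and their mutation distances", {
  cfg_off <- quick_config(seed = 8, suppressor_trna = FALSE)
  expect_identical(nrow(find_suppressors(simulate_trnas(cfg_off)$trnas)), 0L)
  cfg_on <- quick_config(seed = 8, n_suppressors = 2L)
  tr <- simulate_trnas(cfg_on)
  sup <- find_suppressors(tr$trnas)
  expect_identical(nrow(sup), 2L)
  expect_true(all(sup$anticodon == "CTA"))
  expect_identical(tr$truth$role[match(sup$trna_id, tr$truth$trna_id)],
                   rep("suppressor", 2))
  # Hamming oracle: suppressor 1 differs from the canonical Leu-CAA decoy
  # only at the anticodon middle position; suppressor 2 differs from
  # suppressor 1 at exactly five positions
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  seqs <- setNames(tr$trnas$sequence, tr$trnas$trna_id)
  expect_identical(hamming(seqs[["suppressor_01"]], seqs[["decoy_Leu_CAA"]]),
                   1L)
  expect_identical(hamming(seqs[["suppressor_01"]], seqs[["suppressor_02"]]),
                   5L)
})

test_that("telomere-capped contigs carry the repeat at both ends and config errors are caught", {
  cfg <- quick_config(seed = 13, telomere_cap = TRUE, genes_per_genome = 10L)
  sim <- simulate_genome(cfg)
  expect_true(all(vapply(sim$genome, telomere_capped, logical(1))))
  expect_error(synth_config(query_table_id = 16,
                            stop_usage = c(TAA = 0.5, TAG = 0.5, TGA = 0)),
               "sense codon under table 16")
  expect_error(synth_config(stop_usage = c(TAA = 0.5, TAG = 0.1, TGA = 0.1),
                            query_table_id = 1),
               "sum to 1")
})
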