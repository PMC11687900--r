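aln_row <- function(query_id, qlen, qend, strand, target_id, tstart, tend,
                    tlen) {
  tibble::tibble(query_id = query_id, query_len = as.integer(qlen),
                 query_start = 0L, query_end = as.integer(qend),
                 strand = strand, target_id = target_id,
                 target_len = as.integer(tlen),
                 target_start = as.integer(tstart),
                 target_end = as.integer(tend),
                 n_match = as.integer(3 * qend),
                 block_len = as.integer(tend - tstart), mapq = 60L)
}

test_that("the C-terminus tally reads the in-frame codon 3' of the alignment on either strand", {
  #             0123456789012345
  genome <- c(ctg = "ATGAAATAACTTAGGG")
  al <- dplyr::bind_rows(
    # plus strand: aligned codons [0,6), next codon TAA at [6,9)
    aln_row("q_plus", 2, 2, "+", "ctg", 0, 6, 16),
    # minus strand: alignment at [13,16); plus-strand [10,13) reads "TTA",
    # reverse complement TAA
    aln_row("q_minus", 1, 1, "-", "ctg", 13, 16, 16),
    # not C-terminal: excluded
    aln_row("q_partial", 5, 3, "+", "ctg", 0, 9, 16),
    # C-terminal but the next codon runs off the contig end
    aln_row("q_edge", 5, 5, "+", "ctg", 0, 15, 16))
  tl <- tally_cterm_codons(al, genome)
  expect_identical(setNames(tl$n, tl$codon), c(TAA = 2L))
  expect_identical(attr(tl, "n_cterm"), 2L)
  expect_identical(attr(tl, "n_non_cterm"), 1L)
  expect_identical(attr(tl, "n_truncated_at_end"), 1L)
  # conservation: every record lands in exactly one bucket
  expect_identical(attr(tl, "n_cterm") + attr(tl, "n_non_cterm") +
                     attr(tl, "n_truncated_at_end"), nrow(al))
  expect_equal(sum(tl$fraction), 1)
})

test_that("best-per-query filtering keeps the longest span", {
  genome <- c(ctg = "ATGAAATAACTTAGGG")
  al <- dplyr::bind_rows(
    aln_row("q", 2, 2, "+", "ctg", 0, 6, 16),   # full, span 2
    aln_row("q", 2, 1, "+", "ctg", 0, 3, 16))   # partial, span 1
  tl <- tally_cterm_codons(al, genome, best_per_query = TRUE)
  expect_identical(attr(tl, "n_cterm"), 1L)
  expect_identical(tl$codon, "TAA")
  tl_all <- tally_cterm_codons(al, genome, best_per_query = FALSE)
  expect_identical(attr(tl_all, "n_non_cterm"), 1L)
})

test_that("table comparison flags the table recovering the most C-termini", {
  cfg <- quick_config(seed = 12, genes_per_genome = 60L)
  sim <- simulate_genome(cfg)
  al1 <- simulate_alignments(cfg, sim, 1L)
  al16 <- simulate_alignments(cfg, sim, 16L)
  cmp <- compare_tables(list(`1` = al1, `16` = al16), sim$genome)
  expect_true(cmp$best[cmp$table_id == 16])
  expect_gte(cmp$n_cterm[cmp$table_id == 16], cmp$n_cterm[cmp$table_id == 1])
  # identical alignment sets give identical rows
  cmp2 <- compare_tables(list(`1` = al1, `2` = al1), sim$genome)
  expect_equal(cmp2$n_cterm[1], cmp2$n_cterm[2])
  expect_equal(cmp2$frac_TAA[1], cmp2$frac_TAA[2])
  # no internal reassigned codons -> equal counts under both tables
  cfg0 <- quick_config(seed = 14, reassigned_codon_family_usage = 0)
  sim0 <- simulate_genome(cfg0)
  cmp0 <- compare_tables(list(`1` = simulate_alignments(cfg0, sim0, 1L),
                              `16` = simulate_alignments(cfg0, sim0, 16L)),
                         sim0$genome)
  expect_equal(cmp0$n_cterm[1], cmp0$n_cterm[2])
  expect_error(compare_tables(list(`1` = al1), sim$genome), "at least two")
})

test_that("gene-body binning follows floor(n_bins * position / length)", {
  code <- genetic_code(1)
  # 10 internal codons, target CAA at 0-based index 9 -> bin 9 of 10
  codons <- list(c("ATG", rep("AAA", 8), "CAA", "TAA"))
  cds <- cds_from_codons(codons, code)
  prof <- gene_body_profile(cds, "CAA", c("CAG"), n_bins = 10L)
  tgt <- prof[prof$codon == "CAA", ]
  expect_equal(tgt$freq[tgt$bin == 9], 1)
  expect_equal(sum(tgt$count), 1)
  # a gene shorter than n_bins still bins by the same formula
  short <- cds_from_codons(list(c("ATG", "CAA", "AAA", "TAA")), code)
  p2 <- gene_body_profile(short, "CAA", "CAG", n_bins = 20L)
  expect_equal(p2$count[p2$codon == "CAA" & p2$bin == 6], 1) # floor(20*1/3)
  # incomplete genes are excluded
  partial <- cds_from_codons(list(c("AAA", "CAA", "AAA")), code)
  p3 <- gene_body_profile(partial, "CAA", "CAG", n_bins = 10L)
  expect_equal(sum(p3$count), 0)
})

test_that("profiles are invariant to gene input order and near-flat for uniform usage", {
  cfg <- quick_config(seed = 17, genes_per_genome = 80L)
  sim <- simulate_genome(cfg)
  code <- genetic_code(16)
  cds <- suppressWarnings(
    translate_cds(extract_cds(sim$genome, sim$models), code))
  fam <- codon_family(code, "L")
  p <- gene_body_profile(cds, "TAG", setdiff(fam, "TAG"))
  p_shuf <- gene_body_profile(cds[sample.int(nrow(cds)), ], "TAG",
                              setdiff(fam, "TAG"))
  expect_equal(as.data.frame(p[order(p$codon, p$bin), ]),
               as.data.frame(p_shuf[order(p_shuf$codon, p_shuf$bin), ]),
               ignore_attr = TRUE)
  # uniform placement: no bin should hold a large share of TAG mass
  tgt <- p[p$codon == "TAG", ]
  expect_lt(max(tgt$freq), 0.25)
})

test_that("identical target and synonymous placement gives ratio 1 and no depletion", {
  code <- genetic_code(1)
  # genes where CAA and CAG sit at the same positions pairwise
  codons <- lapply(1:30, function(i) {
    body <- rep("AAA", 20)
    body[7] <- "CAA"; body[8] <- "CAG"
    body[19] <- "CAA"; body[20] <- "CAG"
    c("ATG", body, "TAA")
  })
  cds <- cds_from_codons(codons, code)
  prof <- gene_body_profile(cds, "CAA", "CAG", n_bins = 10L)
  dt <- depletion_test(prof, tail_fraction = 0.2, n_boot = 200L, seed = 1)
  expect_equal(dt$ratio, 1.0)
  expect_identical(dt$verdict, "not depleted")
  # too few occurrences -> insufficient data
  dt2 <- depletion_test(gene_body_profile(cds[1:3, ], "CAA", "CAG"),
                        min_occurrences = 50L)
  expect_identical(dt2$verdict, "insufficient data")
})

test_that("a generator that forbids the target codon near the stop is called depleted", {
  cfg <- quick_config(seed = 19, genes_per_genome = 120L,
                      mean_gene_len_codons = 200L,
                      target_tail_exclusion = 0.1,
                      partial_gene_fraction = 0)
  sim <- simulate_genome(cfg)
  code <- genetic_code(16)
  cds <- translate_cds(extract_cds(sim$genome, sim$models), code)
  fam <- codon_family(code, "L")
  prof <- gene_body_profile(cds, "TAG", setdiff(fam, "TAG"))
  dt <- depletion_test(prof, seed = 1)
  expect_gte(dt$n_target, 50)
  expect_identical(dt$verdict, "depleted")
  expect_lt(dt$ratio, 0.5)
})

test_that("PAF round trip preserves alignment records", {
  cfg <- quick_config(seed = 23, genes_per_genome = 20L)
  sim <- simulate_genome(cfg)
  al <- simulate_alignments(cfg, sim, 1L)
  path <- withr::local_tempfile(fileext = ".paf")
  stopscan:::write_paf(al, path)
  back <- read_paf(path)
  expect_equal(as.data.frame(back), as.data.frame(al[, names(back)]))
})
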