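leu_template <- stopscan:::trna_template("Leu")
gln_template <- stopscan:::trna_template("Gln")

test_that("tRNAscan parsing normalises coordinates and survives malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf",
    "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------",
    "chr1\t1\t100\t30\tLeu\tcta\t0\t0\t65.2",
    "chr1\t2\t200\t271\tGln\tTTG\t0\t0\t71.0",
    "broken row"), path)
  expect_message(tr <- parse_trnascan(path), "malformed")
  expect_identical(nrow(tr), 2L)
  # begin > end encodes the minus strand; 1-based inclusive -> [29, 100)
  expect_identical(tr$strand, c("-", "+"))
  expect_identical(tr$start[1], 29L)
  expect_identical(tr$end0[1], 100L)
  expect_identical(tr$anticodon, c("CTA", "TTG"))  # upper-cased DNA
  # empty file after header
  writeLines(readLines(path)[1:3], path)
  expect_identical(nrow(parse_trnascan(path)), 0L)
})

test_that("writer and parser round-trip the tabular fields", {
  cfg <- quick_config(seed = 3, n_suppressors = 1L)
  tr <- simulate_trnas(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trnascan(tr$trnas, path)
  back <- parse_trnascan(path)
  for (col in c("seq_id", "begin", "end", "isotype", "anticodon", "score")) {
    expect_identical(back[[col]], tr$trnas[[col]])
  }
})

test_that("suppressors are recognised by anticodon with their decoded stops", {
  trnas <- tibble::tibble(
    trna_id = c("a", "b", "c", "d"),
    anticodon = c("CTA", "TTA", "TCA", "AAG"))
  sup <- find_suppressors(trnas)
  expect_identical(sup$trna_id, c("a", "b", "c"))
  expect_identical(sup$decodes, c("TAG", "TAA,TAG", "TGA"))
})

test_that("cloverleaf numbering finds the discriminator, anticodon and variable arm", {
  num <- assign_numbering(leu_template$sequence, leu_template$structure)
  s <- strsplit(leu_template$sequence, "")[[1]]
  disc <- num$index[num$region == "discriminator"]
  expect_length(disc, 1)
  expect_identical(s[disc], "A")
  expect_identical(disc, nchar(leu_template$sequence))
  # anticodon positions 34-36 map onto the template's anticodon slots
  ac <- num$index[!is.na(num$label) & num$label %in% c("34", "35", "36")]
  expect_identical(ac, leu_template$anticodon_pos)
  # type-II leucine template: long variable region; glutamine short
  expect_gte(sum(num$region == "variable"), 10)
  num_gln <- assign_numbering(gln_template$sequence, gln_template$structure)
  expect_lt(sum(num_gln$region == "variable"), 10)
  # acceptor pairs are located through the structure: 4 pairs its partner
  i4 <- num$index[!is.na(num$label) & num$label == "4"]
  expect_identical(s[i4], "A")
  expect_identical(s[num$partner[i4]], "T")
  expect_error(assign_numbering("ACGT", ">>.."), "unbalanced")
  expect_error(assign_numbering("ACGTACGT", ">>>..<<<"), "cloverleaf")
})

test_that("identity elements pass on the leucine suppressor and fail per single mutation", {
  sup_seq <- stopscan:::set_anticodon(leu_template, "CTA")
  rep0 <- check_identity_elements(list(sequence = sup_seq,
                                       structure = leu_template$structure))
  expect_true(attr(rep0, "overall_pass"))
  expect_true(all(rep0$evaluable))
  # each required single-position element breaks the verdict when mutated
  num <- assign_numbering(sup_seq, leu_template$structure)
  for (lbl in c("5", "18", "19", "21", "33", "54", "55", "56", "58")) {
    i <- num$index[!is.na(num$label) & num$label == lbl]
    mut <- strsplit(sup_seq, "")[[1]]
    mut[i] <- setdiff(c("A", "C", "G", "T"), mut[i])[1]
    rep_i <- check_identity_elements(list(
      sequence = paste(mut, collapse = ""),
      structure = leu_template$structure))
    expect_false(attr(rep_i, "overall_pass"))
  }
  # the discriminator is required too
  mut <- strsplit(sup_seq, "")[[1]]
  mut[length(mut)] <- "G"
  expect_false(attr(check_identity_elements(list(
    sequence = paste(mut, collapse = ""),
    structure = leu_template$structure)), "overall_pass"))
  # swapping A4:U69 to U4:A69 fails that pair but not the overall verdict
  i4 <- num$index[!is.na(num$label) & num$label == "4"]
  mut <- strsplit(sup_seq, "")[[1]]
  mut[i4] <- "T"; mut[num$partner[i4]] <- "A"
  rep_sw <- check_identity_elements(list(sequence = paste(mut, collapse = ""),
                                         structure = leu_template$structure))
  expect_false(rep_sw$pass[rep_sw$element == "pair_4_69"])
  expect_true(attr(rep_sw, "overall_pass"))
  # the glutamine decoy fails (short variable arm, G discriminator)
  expect_false(attr(check_identity_elements(list(
    sequence = stopscan:::set_anticodon(gln_template, "TTG"),
    structure = gln_template$structure)), "overall_pass"))
})

test_that("pairwise identity follows the global alignment", {
  a <- "ACGTACGTAC"
  expect_equal(pairwise_identity(a, a)$identity, 100)
  expect_equal(pairwise_identity(a, a)$n_differences, 0)
  res <- pairwise_identity("ACGT", "ACGA")
  expect_equal(res$identity, 75)
  expect_identical(res$n_differences, 1L)
  expect_identical(res$alignment_length, 4L)
  # symmetric in argument order
  x <- "ACGTACGT"; y <- "ACGTTACG"
  expect_equal(pairwise_identity(x, y)$identity,
               pairwise_identity(y, x)$identity)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("nearest isotype recovers the template a suppressor was built from", {
  cfg <- quick_config(seed = 5, n_suppressors = 1L)
  tr <- simulate_trnas(cfg)
  sup <- tr$trnas[tr$trnas$trna_id == "suppressor_01", ]
  canon <- tr$trnas[tr$trnas$trna_id != "suppressor_01", ]
  best <- nearest_isotype(sup, canon)
  expect_identical(best$isotype, "Leu")
  expect_identical(best$trna_id, "decoy_Leu_CAA")
  # invariant to candidate ordering
  best2 <- nearest_isotype(sup, canon[rev(seq_len(nrow(canon))), ])
  expect_identical(best, best2)
  # single-candidate set returns that candidate
  one <- nearest_isotype(sup, canon[1, ])
  expect_identical(one$trna_id, canon$trna_id[1])
  expect_error(nearest_isotype(sup, canon[0, ]), "empty")
})

test_that("telomere caps are detected only when both ends carry tandem repeats", {
  mid <- strrep("ACGT", 100)
  both <- paste0(strrep("CCCCAAA", 3), mid, strrep("GGGGTTT", 3))
  expect_true(telomere_capped(both))
  expect_false(telomere_capped(mid))
  one_end <- paste0(strrep("CCCCAAA", 3), mid)
  expect_false(telomere_capped(one_end))
  single_copy <- paste0("CCCCAAA", mid, "GGGGTTT")
  expect_false(telomere_capped(single_copy, min_copies = 2))
  expect_true(telomere_capped(single_copy, min_copies = 1))
})
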