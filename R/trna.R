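# Suppressor-tRNA analysis: tRNAscan-SE parsing, suppressor anticodon
# screening, cloverleaf-based canonical numbering, leucine identity
# elements, pairwise identity and nearest-isotype assignment.

SUPPRESSOR_ANTICODONS <- c(CTA = "TAG", TTA = "TAA,TAG", TCA = "TGA")

# ---- synthetic templates ---------------------------------------------------

# Hand-built cloverleaf templates used by the simulator. The leucine
# template is type II (long variable arm) and carries the leucyl-tRNA
# synthetase identity elements at their canonical positions; the
# glutamine template has a short variable region and a G discriminator,
# so it fails the leucine element check by construction.
trna_template <- function(isotype = c("Leu", "Gln")) {
  isotype <- match.arg(isotype)
  var <- if (isotype == "Leu") "ATTCGGTACGGGTTA" else "ATTCG"
  disc <- if (isotype == "Leu") "A" else "G"
  segs <- list(
    acc5 = "GCGAGGA", link1 = "TA", dstem5 = "CTCG", dloop = "TAGTGGTA",
    dstem3 = "CGAG", link2 = "A", acstem5 = "CCAGA", acloop = "CTCAAAA",
    acstem3 = "TCTGG", var = var, tstem5 = "CGTGG", tloop = "TTCGAAT",
    tstem3 = "CCACG", acc3 = "TCCTCGC", disc = disc)
  struct <- list(
    acc5 = ">", link1 = ".", dstem5 = ">", dloop = ".", dstem3 = "<",
    link2 = ".", acstem5 = ">", acloop = ".", acstem3 = "<", var = ".",
    tstem5 = ">", tloop = ".", tstem3 = "<", acc3 = "<", disc = ".")
  lens <- nchar(unlist(segs))
  offs <- cumsum(c(0L, head(lens, -1)))
  names(offs) <- names(segs)
  idx <- function(seg) offs[[seg]] + seq_len(lens[[seg]])
  loop <- idx("acloop")
  list(isotype = isotype,
       sequence = paste(unlist(segs), collapse = ""),
       structure = paste(strrep(unlist(struct), lens), collapse = ""),
       anticodon_pos = loop[3:5],
       # anticodon-loop positions that can mutate without touching the
       # anticodon or the invariant U33 (loop position 2)
       anticodon_loop_flanks = loop[c(1, 6, 7)],
       variable_loop = idx("var"))
}

set_anticodon <- function(template, anticodon) {
  s <- str_chars(template$sequence)
  s[template$anticodon_pos] <- str_chars(codon_dna(anticodon))
  paste(s, collapse = "")
}

mutate_positions <- function(sequence, positions) {
  s <- str_chars(sequence)
  for (p in positions) {
    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  }
  paste(s, collapse = "")
}

# ---- tRNAscan-SE tabular I/O ----------------------------------------------

#' Parse tRNAscan-SE tabular output
#'
#' Reads the standard header-bearing tabular format. tRNAscan-SE reports
#' 1-based coordinates with begin > end on the minus strand; these are
#' normalised to an explicit strand plus 0-based half-open `start`/`end`.
#' Malformed rows are skipped with a message naming their line numbers.
#'
#' @param path Path to a tRNAscan-SE output file.
#' @return Tibble: `seq_id`, `trna_no`, `begin`, `end` (as reported),
#'   `isotype`, `anticodon` (upper-case DNA), `intron_begin`,
#'   `intron_end`, `score`, `strand`, `start`, `end0`.
#' @export
parse_trnascan <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  dash <- grep("^-", lines)
  body <- if (length(dash) > 0) lines[-seq_len(dash[[1]])] else lines
  lineno <- if (length(dash) > 0) seq_along(lines)[-seq_len(dash[[1]])] else
    seq_along(lines)
  keep <- nzchar(trimws(body))
  body <- body[keep]; lineno <- lineno[keep]
  fields <- strsplit(trimws(body), "\\s+")
  ok <- lengths(fields) >= 9
  if (any(!ok)) {
    inform(sprintf("skipped %d malformed tRNAscan row(s) at line(s) %s",
                   sum(!ok), paste(lineno[!ok], collapse = ", ")))
  }
  fields <- fields[ok]
  if (length(fields) == 0) {
    return(tibble(seq_id = character(0), trna_no = integer(0),
                  begin = integer(0), end = integer(0),
                  isotype = character(0), anticodon = character(0),
                  intron_begin = integer(0), intron_end = integer(0),
                  score = double(0), strand = character(0),
                  start = integer(0), end0 = integer(0)))
  }
  m <- do.call(rbind, map(fields, \(f) f[1:9]))
  out <- tibble(seq_id = m[, 1], trna_no = as.integer(m[, 2]),
                begin = as.integer(m[, 3]), end = as.integer(m[, 4]),
                isotype = m[, 5], anticodon = codon_dna(m[, 6]),
                intron_begin = as.integer(m[, 7]),
                intron_end = as.integer(m[, 8]), score = as.double(m[, 9]))
  out |>
    mutate(strand = ifelse(.data$begin > .data$end, "-", "+"),
           start = pmin(.data$begin, .data$end) - 1L,
           end0 = pmax(.data$begin, .data$end))
}

#' Write tRNA predictions in tRNAscan-SE tabular format
#'
#' @param trnas Tibble with at least `seq_id`, `begin`, `end`, `isotype`,
#'   `anticodon`, `intron_begin`, `intron_end`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trnascan <- function(trnas, path) {
  hdr <- c("Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf",
           "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
           "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------")
  rows <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%.1f",
                  trnas$seq_id, seq_len(nrow(trnas)), trnas$begin,
                  trnas$end, trnas$isotype, trnas$anticodon,
                  trnas$intron_begin, trnas$intron_end, trnas$score)
  readr::write_lines(c(hdr, rows), path)
  invisible(path)
}

#' Find suppressor tRNAs by anticodon
#'
#' Returns tRNAs whose anticodon can decode a stop codon: CTA (decodes
#' UAG), TTA (decodes UAA, and UAG by wobble) and TCA (decodes UGA). The
#' `decodes` column lists the stop codon(s) each suppressor reads.
#'
#' @param trnas Tibble with an `anticodon` column (DNA, 5'-to-3').
#' @return The suppressor rows, with a `decodes` column appended.
#' @export
find_suppressors <- function(trnas) {
  hit <- trnas[codon_dna(trnas$anticodon) %in% names(SUPPRESSOR_ANTICODONS), ]
  hit$decodes <- unname(SUPPRESSOR_ANTICODONS[codon_dna(hit$anticodon)])
  hit
}

# ---- cloverleaf numbering and identity elements ----------------------------

# Pair map from a dot-bracket / tRNAscan ("><") secondary structure.
structure_pairs <- function(structure) {
  s <- chartr("><", "()", structure)
  chars <- str_chars(s)
  stack <- integer(0)
  partner <- rep(NA_integer_, length(chars))
  for (i in seq_along(chars)) {
    if (chars[[i]] == "(") stack <- c(stack, i)
    else if (chars[[i]] == ")") {
      if (length(stack) == 0) abort("unbalanced secondary structure")
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      partner[[i]] <- j
      partner[[j]] <- i
    }
  }
  if (length(stack) > 0) abort("unbalanced secondary structure")
  partner
}

# Group base pairs into stacked helices, ordered by 5' start.
structure_helices <- function(partner) {
  fives <- which(!is.na(partner) & partner > seq_along(partner))
  if (length(fives) == 0) return(list())
  brk <- c(TRUE, diff(fives) != 1 | diff(partner[fives]) != -1)
  split(fives, cumsum(brk))
}

#' Canonical numbering of a tRNA from its cloverleaf structure
#'
#' Decomposes the secondary structure into acceptor stem, D-arm,
#' anticodon arm, optional variable arm and T-arm, and assigns canonical
#' position labels: acceptor 5' strand from 1, D-stem from 10, D-loop
#' anchored so its 3'-most residue is 21, anticodon loop anchored so the
#' anticodon is 34–36, variable-region residues labelled `V1..Vk`, T-loop
#' anchored at 54, and 3' acceptor residues labelled 73 minus their
#' partner's label. The discriminator — the last unpaired 3' residue
#' before any CCA tail — is labelled `disc`. Published position labels
#' for the 3' half differ by one between numbering conventions, so base
#' pairs are checked through structure partners rather than label
#' arithmetic.
#'
#' @param sequence tRNA sequence (DNA).
#' @param structure Equal-length dot-bracket or tRNAscan `><` string.
#' @return Tibble: `index` (1-based sequence position), `label`,
#'   `region`, `partner` (index of the paired residue or `NA`).
#' @export
assign_numbering <- function(sequence, structure) {
  if (nchar(sequence) != nchar(structure)) {
    abort("sequence and structure must have equal length")
  }
  partner <- structure_pairs(structure)
  hel <- structure_helices(partner)
  if (length(hel) < 4 || length(hel) > 5) {
    abort(sprintf(
      "structure does not decompose into a cloverleaf (found %d helices)",
      length(hel)))
  }
  n <- nchar(sequence)
  region <- rep("tail", n)
  label <- rep(NA_character_, n)

  acc <- hel[[1]]; d <- hel[[2]]; ac <- hel[[3]]
  t_ <- hel[[length(hel)]]
  varh <- if (length(hel) == 5) hel[[4]] else integer(0)

  lab <- function(idx, labels) {
    label[idx] <<- as.character(labels)
  }
  set_region <- function(idx, r) region[idx] <<- r

  # acceptor stem
  set_region(acc, "acceptor_5p"); lab(acc, seq_along(acc))
  acc3 <- partner[acc]
  set_region(acc3, "acceptor_3p")
  lab(acc3, 73 - seq_along(acc))
  # linker 8-9
  link1 <- (max(acc) + 1):(min(d) - 1)
  set_region(link1, "linker"); lab(link1, 7 + seq_along(link1))
  # D arm
  set_region(d, "dstem_5p"); lab(d, 9 + seq_along(d))
  d3 <- sort(partner[d])
  set_region(d3, "dstem_3p"); lab(d3, 21 + seq_along(d3))
  dloop <- (max(d) + 1):(min(d3) - 1)
  set_region(dloop, "dloop")
  lab(rev(dloop)[seq_len(min(8, length(dloop)))],
      21 - seq_len(min(8, length(dloop))) + 1)
  # linker 26
  link2 <- (max(d3) + 1):(min(ac) - 1)
  set_region(link2, "linker"); lab(link2, 25 + seq_along(link2))
  # anticodon arm; loop anchored so the middle triplet is 34-36
  set_region(ac, "acstem_5p"); lab(ac, 26 + seq_along(ac))
  ac3 <- sort(partner[ac])
  set_region(ac3, "acstem_3p"); lab(ac3, 38 + seq_along(ac3))
  acloop <- (max(ac) + 1):(min(ac3) - 1)
  set_region(acloop, "acloop")
  n_pre <- floor((length(acloop) - 3) / 2)
  lab(acloop, 34 - n_pre - 1 + seq_along(acloop))
  # variable region: everything between anticodon arm and T stem
  varr <- (max(ac3) + 1):(min(t_) - 1)
  varr <- union(varr, c(varh, partner[varh]))
  varr <- sort(varr[varr < min(t_)])
  if (length(varr) > 0) {
    set_region(varr, "variable"); lab(varr, paste0("V", seq_along(varr)))
  }
  # T arm
  set_region(t_, "tstem_5p"); lab(t_, 48 + seq_along(t_))
  t3 <- sort(partner[t_])
  set_region(t3, "tstem_3p"); lab(t3, 60 + seq_along(t3))
  tloop <- (max(t_) + 1):(min(t3) - 1)
  set_region(tloop, "tloop"); lab(tloop, 53 + seq_along(tloop))
  # discriminator: last unpaired 3' residue before any CCA tail
  after <- which(seq_len(n) > max(acc3))
  if (length(after) > 0) {
    disc <- if (length(after) >= 4 &&
                substring(sequence, n - 2, n) == "CCA") after[[length(after) - 3L]]
            else after[[length(after)]]
    set_region(disc, "discriminator"); label[disc] <- "disc"
  } else {
    abort("no residue 3' of the acceptor stem; discriminator undefined")
  }
  tibble(index = seq_len(n), label = label, region = region,
         partner = partner)
}

default_identity_elements <- function() {
  tibble(
    element = c("discriminator_A", "pair_4_69", "pair_5_68",
                "variable_region",
                "G18", "G19", "A21", "U33", "U54", "U55", "C56", "A58"),
    kind = c("discriminator", "pair", "pair", "variable",
             rep("invariant", 8)),
    position = c("disc", "4", "5", NA,
                 "18", "19", "21", "33", "54", "55", "56", "58"),
    expected = c("A", "A:T", "G:C", NA,
                 "G", "G", "A", "T", "T", "T", "C", "A"),
    required = c(TRUE, FALSE, TRUE, TRUE, rep(TRUE, 8)))
}

#' Check leucine-tRNA identity elements on a tRNA
#'
#' Evaluates the canonical leucyl-tRNA synthetase recognition set on a
#' cloverleaf-numbered tRNA: discriminator A, acceptor-stem pairs A4:U69
#' (optional by default — naturally occurring suppressors tolerate the
#' swapped U4:A69) and G5:C68, a large variable region, and the invariant
#' loop nucleotides G18, G19, A21, U33, U54, U55, C56 and A58. Pairs are
#' located through the secondary structure, and sequences are DNA, so U
#' reads as T. Elements at positions the numbering could not assign are
#' marked unevaluable and excluded from the overall verdict.
#'
#' @param trna A list or one-row tibble with `sequence` and `structure`.
#' @param elements Element table (see `default_identity_elements`);
#'   override to change which elements are required.
#' @param min_var_len Minimum variable-region length (nt) to count as
#'   "large" (default 10, the type-II signature).
#' @return Object of class `identity_element_report`: tibble `element`,
#'   `position`, `observed`, `expected`, `pass`, `required`, `evaluable`,
#'   with attribute `overall_pass` (all required, evaluable elements
#'   pass).
#' @export
check_identity_elements <- function(trna, elements = default_identity_elements(),
                                    min_var_len = 10L) {
  if (is.data.frame(trna)) {
    stopifnot(nrow(trna) == 1)
    trna <- as.list(trna)
  }
  num <- assign_numbering(trna$sequence, trna$structure)
  s <- str_chars(trna$sequence)
  at_label <- function(lbl) num$index[!is.na(num$label) & num$label == lbl]
  rows <- pmap(elements, function(element, kind, position, expected, required) {
    obs <- NA_character_; pass <- NA; evaluable <- TRUE
    if (kind == "variable") {
      len <- sum(num$region == "variable")
      obs <- as.character(len)
      pass <- len >= min_var_len
    } else if (kind == "discriminator") {
      i <- num$index[num$region == "discriminator"]
      if (length(i) != 1) evaluable <- FALSE else {
        obs <- s[[i]]; pass <- obs == expected
      }
    } else if (kind == "pair") {
      i <- at_label(position)
      if (length(i) != 1 || is.na(num$partner[[i]])) evaluable <- FALSE else {
        j <- num$partner[[i]]
        obs <- paste0(s[[i]], ":", s[[j]])
        pass <- obs == expected
      }
    } else {  # invariant nucleotide
      i <- at_label(position)
      if (length(i) != 1) evaluable <- FALSE else {
        obs <- s[[i]]; pass <- obs == expected
      }
    }
    tibble(element = element, position = position %||% NA_character_,
           observed = obs, expected = expected %||% NA_character_,
           pass = pass, required = required, evaluable = evaluable)
  }) |> bind_rows()
  attr(rows, "overall_pass") <-
    all(rows$pass[rows$required & rows$evaluable], na.rm = FALSE)
  class(rows) <- c("identity_element_report", class(rows))
  rows
}

# ---- pairwise identity and isotype assignment ------------------------------

#' Global pairwise identity of two nucleotide sequences
#'
#' Needleman-Wunsch global alignment (default scores: match 1, mismatch
#' -1, gap open 2, gap extend 1, as costs) via Biostrings. Identity is
#' matches over alignment length; differences count mismatches plus
#' gapped columns, which reduces to the plain substitution count when no
#' gap opens.
#'
#' @param seq_a,seq_b Nucleotide sequences (DNA).
#' @param match,mismatch,gap_open,gap_ext Alignment scores (gap values
#'   are costs, i.e. positive numbers).
#' @return One-row tibble: `identity` (percent), `n_differences`,
#'   `alignment_length`.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap_open = 2, gap_ext = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(codon_dna(seq_a), codon_dna(seq_b),
                                       type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = gap_open,
                                       gapExtension = gap_ext)
  a <- str_chars(as.character(Biostrings::alignedPattern(aln)))
  b <- str_chars(as.character(Biostrings::alignedSubject(aln)))
  len <- length(a)
  matches <- sum(a == b & a != "-")
  tibble(identity = 100 * matches / len,
         n_differences = len - matches,
         alignment_length = len)
}

#' Nearest canonical tRNA by sequence identity
#'
#' Finds the canonical tRNA most similar to a suppressor — the expected
#' evolutionary parent. Ties on identity break by higher score, then
#' lexicographic id.
#'
#' @param suppressor A list or one-row tibble with `sequence`.
#' @param canon Tibble of canonical tRNAs with `trna_id`, `isotype`,
#'   `anticodon`, `score`, `sequence`.
#' @return One-row tibble: the winning canonical tRNA's `trna_id`,
#'   `isotype`, `anticodon` plus `identity` and `n_differences`.
#' @export
nearest_isotype <- function(suppressor, canon) {
  if (nrow(canon) == 0) abort("canonical tRNA set is empty")
  if (is.data.frame(suppressor)) suppressor <- as.list(suppressor)
  ids <- map(canon$sequence, pairwise_identity, seq_a = suppressor$sequence) |>
    bind_rows()
  ord <- order(-ids$identity, -canon$score, canon$trna_id)
  i <- ord[[1]]
  tibble(trna_id = canon$trna_id[[i]], isotype = canon$isotype[[i]],
         anticodon = canon$anticodon[[i]], identity = ids$identity[[i]],
         n_differences = ids$n_differences[[i]])
}

#' Is a contig capped with telomeric repeats at both ends?
#'
#' Checks for at least `min_copies` tandem copies of the repeat unit (or
#' its reverse complement) within `window` nt of each contig end —
#' ciliate macronuclear chromosomes are capped with CCCCAAA / GGGGTTT.
#'
#' @param contig A contig sequence.
#' @param repeat_unit Telomeric repeat unit (default `CCCCAAA`).
#' @param min_copies Minimum tandem copies per end.
#' @param window Window size (nt) searched at each end.
#' @return `TRUE` iff both ends carry the tandem repeat.
#' @export
telomere_capped <- function(contig, repeat_unit = "CCCCAAA",
                            min_copies = 2L, window = 200L) {
  if (!nzchar(contig)) abort("contig must be non-empty")
  # a telomeric tract matches the unit, its reverse complement, or any
  # cyclic rotation of either (GGGGTTT is a rotated revcomp of CCCCAAA)
  rotations <- function(u) {
    n <- nchar(u)
    vapply(seq_len(n) - 1L,
           \(k) paste0(substring(u, k + 1L, n), substring(u, 1L, k)),
           character(1))
  }
  units <- unique(c(rotations(repeat_unit), rotations(revcomp(repeat_unit))))
  pat <- paste0("(?:", units, "){", min_copies, ",}", collapse = "|")
  n <- nchar(contig)
  head_seq <- substring(contig, 1, min(window, n))
  tail_seq <- substring(contig, max(1, n - window + 1), n)
  stringr::str_detect(head_seq, pat) && stringr::str_detect(tail_seq, pat)
}
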