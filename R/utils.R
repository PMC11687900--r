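# Internal sequence helpers. Sequences are plain upper-case DNA character
# vectors internally (T, not U); Biostrings handles file I/O and alignment.

STOP_CHAR <- "*"
MASK_CHAR <- "X"

AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a spliced coding sequence into codons; trailing partial codon dropped.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(character(0))
  starts <- seq.int(1L, n - (n %% 3L), by = 3L)
  substring(seq, starts, starts + 2L)
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Render a DNA codon with U for reports (paper-style RNA display).
codon_rna <- function(codon) chartr("T", "U", codon)

codon_dna <- function(codon) chartr("Uu", "Tt", toupper(codon))

#' Read a genome assembly from FASTA
#'
#' Reads a (possibly line-wrapped, multi-contig) FASTA file and returns a
#' named character vector of upper-case contig sequences. Names are
#' truncated at the first whitespace, matching common annotation practice.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || is.null(names(genome))) {
    abort("`genome` must be a named character vector or DNAStringSet")
  }
  toupper(genome)
}

write_fasta <- function(x, path, width = 80L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file (all rows the same length).
#' @return Named character vector of aligned rows.
#' @export
read_msa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  if (length(unique(nchar(out))) > 1) {
    abort(sprintf("alignment rows in '%s' differ in length", path))
  }
  out
}
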