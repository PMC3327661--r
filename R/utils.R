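#' @import data.table
#' @importFrom stats dhyper phyper rbinom setNames runif
#' @importFrom utils head tail
NULL

# Sequence-space helpers. All catalog/read sequences are held in RNA space
# internally; genomes and UTRs stay in DNA space. Conversion is a plain
# T<->U swap after upper-casing, so both helpers are idempotent.

#' Normalize a character vector of sequences to the RNA alphabet
#'
#' Upper-cases and converts `T` to `U`. Idempotent.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over `{A,C,G,U}` (unvalidated).
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Normalize a character vector of sequences to the DNA alphabet
#'
#' Upper-cases and converts `U` to `T`. Idempotent.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector over `{A,C,G,T}` (unvalidated).
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement in DNA space
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  out <- vapply(x, function(s) {
    rc <- rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]])
    paste(rc, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

is_rna_alphabet <- function(x) !grepl("[^ACGU]", x)

# FASTA I/O on plain character vectors (names carry the headers). Biostrings
# does the parsing; we keep the package-internal representation as character
# so that data.table operations stay simple.
read_fasta_chr <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(as.character(ss), names(ss))
}

write_fasta_chr <- function(x, path) {
  stopifnot(!is.null(names(x)))
  ss <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

read_tsv_dt <- function(path, required = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  if (!is.null(required)) {
    miss <- setdiff(required, names(dt))
    if (length(miss) > 0L) {
      stop("TSV ", path, " is missing required column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
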