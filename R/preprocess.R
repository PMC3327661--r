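# Read preprocessing: adapter trimming, size selection, collapsing.
#
# The platform reads through the short insert into the 3' adapter, so a read
# without a detectable adapter cannot be confirmed as a complete insert and
# is discarded. Adapter matching is exact (no mismatches): the insert ends
# at the first position where the remainder of the read equals a prefix of
# the adapter of length >= min_overlap (the adapter may run off the read
# end). Qualities are parsed but otherwise ignored.

#' Read a FASTQ file into id/sequence/quality vectors
#'
#' Plain 4-line-record FASTQ; qualities are retained but unused downstream.
#'
#' @param path FASTQ file path.
#' @return list with character vectors `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  idx <- seq(1L, length(ln), by = 4L)
  seqs <- toupper(ln[idx + 1L])
  qual <- ln[idx + 3L]
  if (any(nchar(qual) != nchar(seqs))) {
    stop("FASTQ quality length mismatch in ", path)
  }
  list(id = sub("^@", "", ln[idx]), sequence = seqs, quality = qual)
}

#' Trim the 3' adapter from reads
#'
#' Returns, for each read, the insert 5' of the first exact occurrence of an
#' adapter prefix of length at least `min_overlap` (or the full adapter)
#' whose overlap with the read matches the adapter exactly. Reads with no
#' such occurrence, or with an empty insert, yield `NA` (discard signal).
#'
#' @param reads character vector of read sequences (DNA).
#' @param adapter adapter sequence (DNA), length >= `min_overlap`.
#' @param min_overlap minimum adapter prefix length that must be observed
#'   (default 8).
#' @return character vector of inserts, `NA` where the read is discarded.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  adapter <- as_dna(adapter)
  if (nchar(adapter) < min_overlap) {
    stop("adapter (", nchar(adapter), " nt) shorter than min_overlap (",
         min_overlap, ")")
  }
  reads <- toupper(reads)
  probe <- substr(adapter, 1L, min_overlap)
  out <- rep(NA_character_, length(reads))
  remaining <- seq_along(reads)
  offset <- rep(0L, length(reads))  # chars already scanned per read
  work <- reads
  while (length(remaining)) {
    pos <- as.integer(regexpr(probe, work, fixed = TRUE))
    hit <- which(pos > 0L)
    if (!length(hit)) break
    ri <- remaining[hit]
    cut <- offset[ri] + pos[hit]          # 1-based adapter start in full read
    # verify the full overlap beyond the probe matches the adapter
    tail_len <- nchar(reads[ri]) - cut + 1L
    ov <- pmin(tail_len, nchar(adapter))
    ok <- substr(reads[ri], cut, cut + ov - 1L) == substring(adapter, 1L, ov)
    confirmed <- ri[ok]
    out[confirmed] <- substr(reads[confirmed], 1L, cut[ok] - 1L)
    # false starts: resume scanning after the failed probe position
    again <- hit[!ok]
    ri2 <- remaining[again]
    offset[ri2] <- offset[ri2] + pos[again]
    work2 <- substr(reads[ri2], offset[ri2] + 1L, nchar(reads[ri2]))
    remaining <- ri2
    work <- work2
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Size-select inserts
#'
#' @param inserts character vector (NAs allowed and dropped).
#' @param min_len,max_len inclusive length window (defaults 20 and 40).
#' @return inserts with `min_len <= length <= max_len`.
#' @export
filter_length <- function(inserts, min_len = 20L, max_len = 40L) {
  stopifnot(min_len > 0L, min_len <= max_len)
  inserts <- inserts[!is.na(inserts)]
  inserts[nchar(inserts) >= min_len & nchar(inserts) <= max_len]
}

#' Collapse inserts to unique sequences with counts
#'
#' Inserts are converted to RNA space. Output order is deterministic:
#' descending count, then lexicographic.
#'
#' @param inserts character vector of inserts (DNA or RNA).
#' @return data.table with columns `insert` (RNA) and `count`.
#' @export
collapse_reads <- function(inserts) {
  if (!length(inserts)) {
    return(data.table::data.table(insert = character(), count = integer()))
  }
  dt <- data.table::data.table(insert = as_rna(inserts))
  dt <- dt[, .(count = .N), by = insert]
  data.table::setorder(dt, -count, insert)
  dt[]
}

#' Preprocess one FASTQ library end to end
#'
#' trim -> size-select -> collapse. The result is order-stable: permuting
#' input reads does not change it.
#'
#' @param fastq path to the library FASTQ.
#' @param id library identifier.
#' @param species species code.
#' @param stage developmental stage label (e.g. `HH20`, `HH25`).
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len size-selection window.
#' @param min_overlap minimum adapter overlap for trimming.
#' @return object of class `smrna_library`: list with `id`, `species`,
#'   `stage`, `reads` (collapsed data.table), `n_raw`, `n_after_filters`.
#' @export
preprocess_library <- function(fastq, id, species, stage,
                               adapter, min_len = 20L, max_len = 40L,
                               min_overlap = 8L) {
  fq <- read_fastq(fastq)
  inserts <- trim_adapter(fq$sequence, adapter, min_overlap)
  kept <- filter_length(inserts, min_len, max_len)
  reads <- collapse_reads(kept)
  structure(list(id = id, species = species, stage = stage, reads = reads,
                 n_raw = length(fq$sequence),
                 n_after_filters = length(kept)),
            class = "smrna_library")
}

#' Write a collapsed library as FASTA (counts in headers) plus TSV mirror
#'
#' Headers follow the `seq{i}_x{count}` convention.
#'
#' @param lib an `smrna_library`.
#' @param fasta,tsv output paths (either may be `NULL` to skip).
#' @return invisibly, the library.
#' @export
write_collapsed <- function(lib, fasta = NULL, tsv = NULL) {
  if (!is.null(fasta)) {
    nm <- sprintf("seq%d_x%d", seq_len(nrow(lib$reads)), lib$reads$count)
    write_fasta_chr(setNames(lib$reads$insert, nm), fasta)
  }
  if (!is.null(tsv)) {
    data.table::fwrite(lib$reads, tsv, sep = "\t")
  }
  invisible(lib)
}
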