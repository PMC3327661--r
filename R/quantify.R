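# Quantification: miRNA x library raw counts, per-million-mapped-reads
# (PMMR) normalization, and the strict >threshold detection rule.

MIRNA_CATEGORIES <- c("known_mirna", "star_mirna", "ortholog_exact",
                      "ortholog_mismatch")

#' Build the miRNA x library count table from annotated libraries
#'
#' Collapsed-read counts are aggregated by assigned miRNA name over the
#' miRNA-bearing categories (known, star, ortholog exact, ortholog
#' mismatch). The per-library mapped-read denominator (reads in any
#' category except `unannotated`) is recorded alongside.
#'
#' @param anns list of `annotated_library` objects with distinct ids.
#' @return object of class `count_table`: list with `counts` (integer
#'   matrix, rows = miRNA names, cols = library ids), `denominators`
#'   (named integer vector), and `meta` (data.table: id, species, stage).
#' @export
build_count_table <- function(anns) {
  stopifnot(length(anns) >= 1L)
  ids <- vapply(anns, function(a) a$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate library ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  per <- lapply(anns, function(a) {
    r <- a$records[category %in% MIRNA_CATEGORIES,
                   .(count = sum(count)), by = assigned_name]
    data.table::setnames(r, "assigned_name", "name")
    r[, id := a$id]
    r
  })
  long <- data.table::rbindlist(per)
  all_names <- sort(unique(long$name))
  counts <- matrix(0L, nrow = length(all_names), ncol = length(ids),
                   dimnames = list(all_names, ids))
  if (nrow(long)) {
    counts[cbind(match(long$name, all_names), match(long$id, ids))] <-
      as.integer(long$count)
  }
  den <- vapply(anns, function(a) as.integer(a$summary$mapped_reads),
                integer(1))
  names(den) <- ids
  meta <- data.table::data.table(
    id = ids,
    species = vapply(anns, function(a) a$species %||% NA_character_,
                     character(1)),
    stage = vapply(anns, function(a) a$stage %||% NA_character_,
                   character(1)))
  structure(list(counts = counts, denominators = den, meta = meta),
            class = "count_table")
}

#' Construct a count table directly from a matrix (e.g. planted truth)
#'
#' @param counts integer matrix with rownames (miRNAs) and colnames
#'   (library ids).
#' @param denominators named positive integer vector, one per column.
#' @param meta optional data.table with `id`, `species`, `stage`.
#' @return a `count_table`.
#' @export
count_table <- function(counts, denominators, meta = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(colnames(counts) %in% names(denominators)))
  if (any(counts < 0)) stop("negative counts")
  denominators <- denominators[colnames(counts)]
  if (is.null(meta)) {
    meta <- data.table::data.table(id = colnames(counts),
                                   species = NA_character_,
                                   stage = NA_character_)
  }
  structure(list(counts = counts, denominators = denominators,
                 meta = data.table::as.data.table(meta)),
            class = "count_table")
}

#' Normalize a count table to reads per million mapped reads
#'
#' Each cell becomes `count * 1e6 / denominator` for its library.
#'
#' @param ct a `count_table`.
#' @return numeric matrix of PMMR values, same dimnames as the counts.
#' @export
normalize_pmmr <- function(ct) {
  den <- ct$denominators
  if (any(den <= 0L)) {
    stop("zero or negative mapped-read denominator for library: ",
         paste(names(den)[den <= 0L], collapse = ", "))
  }
  sweep(ct$counts, 2L, den, "/") * 1e6
}

#' Detected miRNAs under the strict PMMR threshold
#'
#' A miRNA is detected when its PMMR is strictly greater than `threshold`
#' in at least one library.
#'
#' @param pmmr numeric PMMR matrix (see [normalize_pmmr()]).
#' @param threshold detection threshold (default 15).
#' @return character vector of detected miRNA names (row order).
#' @export
detect <- function(pmmr, threshold = 15) {
  stopifnot(threshold >= 0)
  if (length(pmmr) == 0L) return(character())
  rownames(pmmr)[apply(pmmr > threshold, 1L, any)]
}

#' Write count/PMMR tables as TSV with a JSON denominator sidecar
#'
#' @param ct a `count_table`.
#' @param counts_tsv,pmmr_tsv,denominators_json output paths (any may be
#'   `NULL`).
#' @return invisibly, `ct`.
#' @export
write_count_table <- function(ct, counts_tsv = NULL, pmmr_tsv = NULL,
                              denominators_json = NULL) {
  to_dt <- function(m) {
    dt <- data.table::as.data.table(m, keep.rownames = "mirna")
    dt
  }
  if (!is.null(counts_tsv)) {
    data.table::fwrite(to_dt(ct$counts), counts_tsv, sep = "\t")
  }
  if (!is.null(pmmr_tsv)) {
    data.table::fwrite(to_dt(normalize_pmmr(ct)), pmmr_tsv, sep = "\t")
  }
  if (!is.null(denominators_json)) {
    writeLines(jsonlite::toJSON(as.list(ct$denominators), auto_unbox = TRUE),
               denominators_json)
  }
  invisible(ct)
}
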