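# Seed-match target prediction over a 3'UTR set, and hypergeometric term
# enrichment of the predicted target genes.
#
# A target site is the exact DNA reverse complement of mature positions 2-8
# in the UTR (7mer-m8); an 8mer site additionally carries an A immediately
# 3' of the match (opposite mature position 1). 6mer sites and context
# scoring are deliberately out of scope.

#' Seed of a mature miRNA (positions 2-8, 1-based inclusive)
#'
#' @param sequence mature miRNA sequence (RNA), length >= 8.
#' @return 7-nt RNA string.
#' @export
seed_of <- function(sequence) {
  s <- as_rna(sequence)
  if (nchar(s) < 8L) stop("mature sequence shorter than 8 nt: ", s)
  substr(s, 2L, 8L)
}

#' Find seed-match sites in one UTR
#'
#' All (possibly overlapping) offsets where the UTR equals the DNA reverse
#' complement of the 7-nt seed; a site followed by `A` is an `eightmer`,
#' otherwise `sevenmer_m8`. Offsets are 0-based.
#'
#' @param seed 7-nt RNA seed (see [seed_of()]).
#' @param utr DNA string.
#' @return data.table with columns `start` (0-based) and `site_type`.
#' @export
find_sites <- function(seed, utr) {
  stopifnot(nchar(seed) == 7L)
  utr <- as_dna(utr)
  site <- revcomp_dna(as_dna(seed))
  starts <- integer()
  from <- 1L
  repeat {
    p <- regexpr(site, substr(utr, from, nchar(utr)), fixed = TRUE)
    if (p < 0L) break
    starts <- c(starts, from + as.integer(p) - 2L)  # 0-based
    from <- from + as.integer(p)                    # allow overlaps
  }
  if (!length(starts)) {
    return(data.table::data.table(start = integer(), site_type = character()))
  }
  nextch <- substr(utr, starts + 8L, starts + 8L)
  data.table::data.table(start = starts,
                         site_type = ifelse(nextch == "A", "eightmer",
                                            "sevenmer_m8"))
}

#' Predict targets of a mature miRNA over a UTR set
#'
#' @param sequence mature miRNA sequence (length >= 8).
#' @param utr_set non-empty named character vector of DNA UTRs; names
#'   follow the `transcript|gene` convention (gene optional).
#' @return list with `sites` (data.table: transcript, gene, start,
#'   site_type), `n_transcripts` (distinct transcripts with >= 1 site) and
#'   `target_genes` (distinct gene ids; transcript id when no gene field).
#' @export
predict_targets <- function(sequence, utr_set) {
  if (length(utr_set) == 0L) stop("empty UTR set")
  sd <- seed_of(sequence)
  out <- list()
  for (nm in names(utr_set)) {
    hits <- find_sites(sd, utr_set[[nm]])
    if (nrow(hits)) {
      parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
      out[[length(out) + 1L]] <- data.table::data.table(
        transcript = parts[1],
        gene = if (length(parts) > 1L) parts[2] else parts[1],
        start = hits$start, site_type = hits$site_type)
    }
  }
  sites <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(transcript = character(), gene = character(),
                           start = integer(), site_type = character())
  list(sites = sites,
       n_transcripts = length(unique(sites$transcript)),
       target_genes = sort(unique(sites$gene)))
}

#' Hypergeometric term enrichment of a target-gene set
#'
#' The universe is every gene carrying at least one term annotation; query
#' genes outside the universe are dropped (their number is returned). For
#' each term with annotated size K, overlap k with the n query genes in a
#' universe of N genes, the raw p-value is the upper tail
#' `P[X >= k]` of Hypergeometric(N, K, n); Bonferroni correction is over
#' the number of terms tested.
#'
#' @param target_genes character vector of query gene ids.
#' @param term_annotations a [reference_set()] (its `term_annotations` are
#'   used) or a data.frame with columns `term_id`, `gene_id`.
#' @param alpha significance level applied to adjusted p-values
#'   (default 0.05, strict `<`).
#' @return list with `results` (data.table: term_id, k, K, n, N, p_raw,
#'   p_adj, significant) and `n_dropped` (query genes outside the
#'   universe).
#' @export
enrich_terms <- function(target_genes, term_annotations, alpha = 0.05) {
  if (inherits(term_annotations, "reference_set")) {
    term_annotations <- term_annotations$term_annotations
  }
  ann <- data.table::as.data.table(term_annotations)
  ann <- unique(ann[, .(term_id, gene_id)])
  universe <- unique(ann$gene_id)
  if (length(universe) == 0L) stop("empty annotation universe")
  query <- unique(target_genes)
  dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  N <- length(universe)
  n <- length(query)
  res <- ann[, .(K = data.table::uniqueN(gene_id),
                 k = sum(unique(gene_id) %in% query)), by = term_id]
  res[, `:=`(n = n, N = N)]
  res[, p_raw := stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)]
  res[, p_adj := pmin(1, p_raw * .N)]
  res[, significant := p_adj < alpha]
  data.table::setorder(res, p_raw, term_id)
  data.table::setcolorder(res, c("term_id", "k", "K", "n", "N", "p_raw",
                                 "p_adj", "significant"))
  list(results = res[], n_dropped = dropped)
}
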