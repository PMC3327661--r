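# Lineage-specificity screen: compile candidate miRNAs annotated only in
# avian species, then test each hairpin for presence/absence across a
# genome panel by local alignment (both strands, DNA space).

#' Compile lineage-restricted candidate miRNAs
#'
#' Matures whose annotation-status species set is non-empty and contained
#' in `annotated_in` (by default chicken and zebrafinch, the two avian
#' genomes with miRNA annotation), restricted to names in the detected set.
#'
#' @param rs a [reference_set()].
#' @param detected character vector of detected miRNA names (see
#'   [detect()]).
#' @param annotated_in species codes considered "annotated avian".
#' @return data.table of candidate matures (columns as in the catalog
#'   mature table, plus `tier`).
#' @export
compile_candidates <- function(rs, detected,
                               annotated_in = c("gga", "tgu")) {
  out <- list()
  for (tn in names(rs$tiers)) {
    m <- data.table::copy(rs$tiers[[tn]]$mature)
    sets <- species_sets(m$annotated_species)
    keep <- vapply(sets, function(s) {
      length(s) > 0L && all(s %in% annotated_in)
    }, logical(1))
    m <- m[keep & name %in% detected]
    if (nrow(m)) {
      m[, tier := tn]
      out[[tn]] <- m
    }
  }
  if (!length(out)) {
    return(data.table::data.table(name = character(), sequence = character(),
                                  hairpin_id = character(), tier = character()))
  }
  res <- data.table::rbindlist(out, fill = TRUE)
  data.table::setorder(res, name)
  res[]
}

#' Score a hairpin's presence in one genome
#'
#' Best local alignment of the hairpin (DNA space, both strands) against
#' every contig; `present` requires identity at least `identity_min` over
#' the aligned span and aligned hairpin coverage at least `coverage_min`.
#'
#' @param hairpin_seq hairpin sequence (RNA or DNA).
#' @param genome named character vector of DNA contigs (non-empty).
#' @param identity_min minimum fraction of matching columns over the local
#'   alignment span (default 0.9).
#' @param coverage_min minimum aligned-span / hairpin-length fraction
#'   (default 0.8).
#' @return list with `present`, `best_identity`, `best_coverage`.
#' @export
search_presence <- function(hairpin_seq, genome, identity_min = 0.9,
                            coverage_min = 0.8) {
  if (length(genome) == 0L) stop("empty genome")
  stopifnot(identity_min > 0, identity_min <= 1,
            coverage_min > 0, coverage_min <= 1)
  hp <- as_dna(hairpin_seq)
  hp_len <- nchar(hp)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  best_id <- 0
  best_cov <- 0
  best_score <- -Inf
  pat <- Biostrings::DNAString(hp)
  pats <- list(`+` = pat, `-` = Biostrings::reverseComplement(pat))
  for (ctg in genome) {
    subj <- Biostrings::DNAString(ctg)
    for (p in pats) {
      aln <- Biostrings::pairwiseAlignment(p, subj, type = "local",
                                           substitutionMatrix = submat,
                                           gapOpening = 5, gapExtension = 2)
      if (length(aln) == 0L) next
      span <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (span == 0L) next
      ident <- Biostrings::nmatch(aln) / span
      cov <- Biostrings::width(Biostrings::pattern(aln)) / hp_len
      sc <- Biostrings::score(aln)
      if (sc > best_score) {
        best_score <- sc
        best_id <- ident
        best_cov <- cov
      }
    }
  }
  list(present = best_id >= identity_min && best_cov >= coverage_min,
       best_identity = best_id, best_coverage = best_cov)
}

#' Presence/absence verdicts for candidate hairpins across a genome panel
#'
#' A hairpin is lineage-specific (`avian_specific`) iff it is present in
#' every avian panel member and absent from every non-avian member.
#'
#' @param hairpins data.table with columns `id`, `sequence` (one row per
#'   candidate hairpin).
#' @param genome_panel named list of genomes (species code -> contigs).
#' @param avian_set,nonavian_set species codes partitioning the panel.
#' @param identity_min,coverage_min thresholds for [search_presence()].
#' @return list with `calls` (data.table: hairpin_id, species, lineage,
#'   present, best_identity, best_coverage) and `verdicts` (data.table:
#'   hairpin_id, avian_specific).
#' @export
lineage_verdicts <- function(hairpins, genome_panel, avian_set, nonavian_set,
                             identity_min = 0.9, coverage_min = 0.8) {
  panel <- names(genome_panel)
  stray <- setdiff(panel, c(avian_set, nonavian_set))
  if (length(stray)) stop("panel species in neither avian nor non-avian set: ",
                          paste(stray, collapse = ", "))
  calls <- list()
  for (i in seq_len(nrow(hairpins))) {
    for (sp in panel) {
      res <- search_presence(hairpins$sequence[i], genome_panel[[sp]],
                             identity_min, coverage_min)
      calls[[length(calls) + 1L]] <- data.table::data.table(
        hairpin_id = hairpins$id[i], species = sp,
        lineage = if (sp %in% avian_set) "avian" else "nonavian",
        present = res$present, best_identity = res$best_identity,
        best_coverage = res$best_coverage)
    }
  }
  calls <- data.table::rbindlist(calls)
  verdicts <- calls[, .(
    avian_specific = all(present[lineage == "avian"]) &&
      !any(present[lineage == "nonavian"]) &&
      sum(lineage == "avian") > 0L), by = hairpin_id]
  list(calls = calls[], verdicts = verdicts[])
}
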