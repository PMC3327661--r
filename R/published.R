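# Packaged fixtures: the avian-candidate mature catalog (published mature
# sequences over synthetic hairpin scaffolds, hairpin files are labelled
# `synthetic`) and the published per-category summary numbers used for
# arithmetic-consistency checks.

#' The packaged avian-candidate catalog
#'
#' Six mature miRNAs annotated only in chicken and/or zebrafinch, mapping
#' to five hairpins. Mature sequences are the published ones; the hairpin
#' scaffolds are synthetic (a real precursor set is not recoverable from
#' the summary data), built so that every mature is an exact arm slice.
#'
#' @return a [mir_catalog()].
#' @export
table1_catalog <- function() {
  d <- system.file("extdata", package = "avimir")
  load_catalog(file.path(d, "table1_mature.fa"),
               file.path(d, "table1_hairpin_synthetic.fa"),
               file.path(d, "table1_sidecar.tsv"))
}

#' Published summary counts
#'
#' Key/value table of the study-level summary counts (detected miRNAs,
#' differentially expressed miRNAs, catalog tallies per cascade branch).
#'
#' @return named numeric vector.
#' @export
published_counts <- function() {
  d <- read_tsv_dt(system.file("extdata", "published_summary.tsv",
                               package = "avimir"))
  setNames(as.numeric(d$value), d$quantity)
}

#' Published per-category read percentages
#'
#' @return named numeric vector (percent of total reads per category).
#' @export
published_fractions <- function() {
  d <- read_tsv_dt(system.file("extdata", "published_fractions.tsv",
                               package = "avimir"))
  setNames(as.numeric(d$percent), d$category)
}

#' Recompute the avian-candidate list through the detection path
#'
#' Exercises the full quantification route on the packaged catalog: builds
#' a home tier holding the fixture matures plus two decoys (one annotated
#' beyond the avian genomes, one expressed below the detection threshold),
#' assembles a high-abundance library over it, annotates, counts,
#' normalizes to PMMR, applies strict >15 detection, and compiles the
#' lineage-restricted candidates.
#'
#' @param per_mirna_count reads given to each fixture mature (default
#'   100000; the low-abundance decoy gets a single read, keeping it well
#'   under 15 PMMR).
#' @return data.table of candidate matures (see [compile_candidates()]).
#' @export
acceptance_candidates <- function(per_mirna_count = 100000L) {
  cat1 <- table1_catalog()
  decoys <- data.table::data.table(
    name = c("gga-conserved-miR", "gga-rare-miR"),
    sequence = c("UGAGGUAGUAGGUUGUAUAGUU", "ACAGGUCCUAAGGCAUUGGAGU"),
    hairpin_id = "", arm = "unknown", is_star = FALSE,
    annotated_species = c("gga,hsa", "gga"))
  keep <- c("name", "sequence", "hairpin_id", "arm", "is_star",
            "annotated_species")
  tier <- mir_catalog(rbind(cat1$mature[, keep, with = FALSE], decoys),
                      cat1$hairpin)
  rs <- reference_set(list(chicken = tier))
  reads <- data.table::data.table(
    insert = tier$mature$sequence,
    count = c(rep(per_mirna_count, nrow(cat1$mature)),
              per_mirna_count, 1L))
  lib <- structure(list(id = "fixture", species = "gga", stage = "HH25",
                        reads = reads), class = "smrna_library")
  ann <- annotate_library(lib, rs)
  ct <- build_count_table(list(ann))
  detected <- detect(normalize_pmmr(ct))
  compile_candidates(rs, detected)
}
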