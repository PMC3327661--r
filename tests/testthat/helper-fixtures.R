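# Shared in-code fixtures. Everything is built programmatically; the only
# on-disk fixtures are the packaged ones under inst/extdata.

# A tiny home-tier catalog: two plain matures, one hairpin with an
# unannotated star arm, and the published miR-1559 sequence for the
# seed-mismatch examples.
tiny_home_catalog <- function() {
  # hairpin: mature arm [0,22) + loop (15) + star arm [37,59)
  m1 <- "UGAGGUAGUAGGUUGUAUAGUU"                  # let-7-like
  loop <- "GGGAUAACUAUACAA"
  star <- "CUAUACAAUCUACUGUCUUUCC"
  hp1 <- paste0(m1, loop, star)
  mature <- data.frame(
    name = c("gga-test-miR-1", "gga-test-miR-2", "gga-miR-1559"),
    sequence = c(m1, "CAUCUUACCGGACAGUGCUGGA", "UUCGAUGCUUGUAUGCUACUCC"),
    hairpin_id = c("hp-test-1", "", ""),
    arm = c("five_prime", "unknown", "unknown"),
    is_star = FALSE,
    annotated_species = c("gga", "gga", "gga"))
  hairpin <- data.frame(id = "hp-test-1", species = "gga", sequence = hp1)
  mir_catalog(mature, hairpin)
}

tiny_human_catalog <- function() {
  mir_catalog(
    data.frame(name = c("hsa-test-miR-10", "hsa-test-miR-11"),
               sequence = c("UACCCUGUAGAUCCGAAUUUGU",
                            "AGCUUAUCAGACUGAUGUUGAC"),
               hairpin_id = "", arm = "unknown", is_star = FALSE,
               annotated_species = "hsa"),
    data.frame(id = character(), species = character(),
               sequence = character()))
}

# reference set with contaminants and a genome carrying planted content
tiny_rs <- function() {
  home <- tiny_home_catalog()
  rrna <- paste0("GG", "CCCAUUCGAACGGGAUUAGAUACCCA", strrep("AGCU", 10))
  rep1 <- paste0("UUAGGGUUAGGGUUAGGGUUAGGG", strrep("ACGU", 8))
  mrna <- paste0("AUGGCUGCUGCUAAGCGUACUGAUCGAUCGAUUUAGGCAAGCAUCG",
                 strrep("GAUC", 10))
  genome <- c(ctg1 = paste0(strrep("ACTG", 25),
                            as_dna("UGCAACGGGAUCCAUGGAACAC"),
                            strrep("GTCA", 25)))
  reference_set(
    tiers = list(chicken = home, human = tiny_human_catalog()),
    contaminants = list(rrna = c(r1 = rrna), "repeat" = c(p1 = rep1),
                        mrna = c(m1 = mrna)),
    genome_panel = list(gga = genome))
}

# independent single-read comparator applying the cascade precedence with
# the per-insert operations (used as the brute-force oracle)
naive_cascade_one <- function(insert, rs, genome_species = "gga",
                              max_mm = 2L) {
  insert <- as_rna(insert)
  tiers <- names(rs$tiers)
  hit <- match_exact(insert, rs$tiers[[tiers[1]]])
  if (length(hit)) return(list(category = "known_mirna", name = hit[1]))
  st <- infer_star(insert, rs$tiers[[tiers[1]]])
  if (!is.null(st)) return(list(category = "star_mirna",
                                name = st$star_name))
  for (tn in tiers[-1]) {
    hit <- match_exact(insert, rs$tiers[[tn]])
    if (length(hit)) return(list(category = "ortholog_exact",
                                 name = hit[1]))
  }
  for (tn in tiers[-1]) {
    mm <- match_seed_preserving(insert, rs$tiers[[tn]], max_mm)
    if (nrow(mm)) return(list(category = "ortholog_mismatch",
                              name = mm$name[1]))
  }
  if (genome_species %in% names(rs$genome_panel) &&
      nrow(map_genome(insert, rs$genome_panel[[genome_species]])) > 0L) {
    return(list(category = "genome_only", name = NA_character_))
  }
  cc <- classify_contaminant(insert, rs$contaminants)
  if (!is.null(cc)) return(list(category = cc, name = NA_character_))
  list(category = "unannotated", name = NA_character_)
}

# wrap a set of inserts (with counts) as a minimal library object
as_library <- function(inserts, counts = rep(1L, length(inserts)),
                       id = "libA", species = "gga", stage = "HH20") {
  dt <- data.table::data.table(insert = as_rna(inserts),
                               count = as.integer(counts))
  structure(list(id = id, species = species, stage = stage, reads = dt,
                 n_raw = sum(counts), n_after_filters = sum(counts)),
            class = "smrna_library")
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
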