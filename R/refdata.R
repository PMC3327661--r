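# Reference data model: tiered mature/hairpin catalogs, contaminant sets,
# genome panel, UTR set and term annotations.
#
# All miRNA sequences are stored in RNA space; genome panel and UTR sets in
# DNA space. Coordinates are 0-based half-open internally.

MIRNA_LEN_BOUNDS <- c(18L, 26L)

#' Construct a miRNA catalog tier
#'
#' A catalog holds mature miRNAs together with their hairpin precursors.
#' Arm intervals are stored per mature as 0-based half-open positions within
#' the hairpin sequence; slicing the hairpin at an interval must reproduce
#' the mature sequence.
#'
#' @param mature data.frame with columns `name`, `sequence`, `hairpin_id`,
#'   `arm` (one of `five_prime`, `three_prime`, `unknown`), `is_star`
#'   (logical), `annotated_species` (comma-separated species codes), and
#'   optionally `arm_start`, `arm_end` (0-based half-open within hairpin;
#'   inferred by exact search when absent).
#' @param hairpin data.frame with columns `id`, `species`, `sequence` and
#'   optional genomic location columns `seqname`, `start`, `end`, `strand`.
#' @param len_bounds integer length-2 vector of allowed mature lengths
#'   (inclusive).
#' @return an object of class `mir_catalog`.
#' @export
mir_catalog <- function(mature, hairpin, len_bounds = MIRNA_LEN_BOUNDS) {
  mature <- data.table::as.data.table(mature)
  hairpin <- data.table::as.data.table(hairpin)
  need_m <- c("name", "sequence", "hairpin_id", "arm", "is_star",
              "annotated_species")
  miss <- setdiff(need_m, names(mature))
  if (length(miss)) stop("mature table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(c("id", "species", "sequence"), names(hairpin))
  if (length(miss)) stop("hairpin table missing column(s): ",
                         paste(miss, collapse = ", "))

  mature[, sequence := as_rna(sequence)]
  hairpin[, sequence := as_rna(sequence)]
  mature[, is_star := as.logical(is_star)]

  dup <- mature$name[duplicated(mature$name)]
  if (length(dup)) stop("duplicate mature name(s) in catalog: ",
                        paste(unique(dup), collapse = ", "))
  dup <- hairpin$id[duplicated(hairpin$id)]
  if (length(dup)) stop("duplicate hairpin id(s) in catalog: ",
                        paste(unique(dup), collapse = ", "))

  bad <- mature$name[!is_rna_alphabet(mature$sequence)]
  if (length(bad)) stop("non-RNA characters in mature sequence(s): ",
                        paste(bad, collapse = ", "))

  # Arm intervals: take them from the table if present, else locate the
  # mature inside its hairpin by exact search.
  if (!all(c("arm_start", "arm_end") %in% names(mature))) {
    mature[, `:=`(arm_start = NA_integer_, arm_end = NA_integer_)]
  }
  mature[, arm_start := suppressWarnings(as.integer(arm_start))]
  mature[, arm_end := suppressWarnings(as.integer(arm_end))]
  hp_seq <- setNames(hairpin$sequence, hairpin$id)
  for (i in seq_len(nrow(mature))) {
    hid <- mature$hairpin_id[i]
    if (is.na(hid) || !nzchar(hid)) next
    if (!hid %in% names(hp_seq)) {
      stop("mature '", mature$name[i], "' references unknown hairpin '",
           hid, "'")
    }
    if (is.na(mature$arm_start[i])) {
      pos <- regexpr(mature$sequence[i], hp_seq[[hid]], fixed = TRUE)
      if (pos < 0L) {
        stop("mature '", mature$name[i],
             "' is not a slice of its hairpin '", hid, "'")
      }
      mature[i, arm_start := as.integer(pos) - 1L]
      mature[i, arm_end := as.integer(pos) - 1L + nchar(sequence)]
    } else {
      sl <- substr(hp_seq[[hid]], mature$arm_start[i] + 1L, mature$arm_end[i])
      if (!identical(sl, mature$sequence[i])) {
        stop("mature '", mature$name[i], "' arm interval [",
             mature$arm_start[i], ", ", mature$arm_end[i],
             ") does not reproduce its sequence in hairpin '", hid, "'")
      }
    }
  }

  len <- nchar(mature$sequence)
  bad <- mature$name[len < len_bounds[1] | len > len_bounds[2]]
  if (length(bad)) stop("mature length outside [", len_bounds[1], ", ",
                        len_bounds[2], "]: ", paste(bad, collapse = ", "))

  structure(list(mature = mature[], hairpin = hairpin[],
                 len_bounds = as.integer(len_bounds)),
            class = "mir_catalog")
}

#' Load a catalog tier from FASTA files plus a TSV sidecar
#'
#' The mature FASTA carries one entry per mature miRNA (header = name);
#' the hairpin FASTA one entry per precursor (header = hairpin id). The
#' sidecar is a tab-separated table with columns `name`, `hairpin_id`,
#' `arm`, `is_star`, `annotated_species` and optional `arm_start`/`arm_end`.
#' DNA-spelled input is converted to RNA on load.
#'
#' @param mature_fasta path to the mature FASTA.
#' @param hairpin_fasta path to the hairpin FASTA (may be `NULL` for a
#'   hairpin-less tier; every `hairpin_id` in the sidecar must then be
#'   empty).
#' @param sidecar path to the TSV sidecar.
#' @param hairpin_species species code recorded for hairpins lacking a
#'   `species` column in the sidecar.
#' @return a [mir_catalog()].
#' @export
load_catalog <- function(mature_fasta, hairpin_fasta, sidecar,
                         hairpin_species = "gga") {
  seqs <- read_fasta_chr(mature_fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate mature name(s) in FASTA: ",
                        paste(unique(dup), collapse = ", "))
  side <- read_tsv_dt(sidecar, required = c("name", "hairpin_id", "arm",
                                            "is_star", "annotated_species"))
  miss <- setdiff(nm, side$name)
  if (length(miss)) stop("sidecar missing row(s) for: ",
                         paste(miss, collapse = ", "))
  side <- side[match(nm, side$name)]
  mature <- data.table::data.table(
    name = nm, sequence = as_rna(unname(seqs)),
    hairpin_id = side$hairpin_id, arm = side$arm,
    is_star = side$is_star %in% c("TRUE", "true", "1"),
    annotated_species = side$annotated_species)
  if ("arm_start" %in% names(side)) mature[, arm_start := side$arm_start]
  if ("arm_end" %in% names(side)) mature[, arm_end := side$arm_end]

  if (is.null(hairpin_fasta)) {
    if (any(nzchar(mature$hairpin_id))) {
      stop("sidecar references hairpins but no hairpin FASTA given")
    }
    hairpin <- data.table::data.table(id = character(), species = character(),
                                      sequence = character())
  } else {
    hp <- read_fasta_chr(hairpin_fasta)
    hairpin <- data.table::data.table(
      id = sub("\\s.*$", "", names(hp)),
      species = hairpin_species, sequence = as_rna(unname(hp)))
  }
  mir_catalog(mature, hairpin)
}

#' Construct a reference set
#'
#' Bundles the tiered miRNA catalogs with contaminant sequence classes, a
#' genome panel, a 3'UTR set and term annotations. Tier order is the cascade
#' search order.
#'
#' @param tiers named list of [mir_catalog()] objects; names conventionally
#'   `chicken`, `human`, `zebrafinch` in cascade order.
#' @param contaminants named list of named character vectors of sequences,
#'   with classes among `trna`, `rrna`, `snrna`, `repeat`, `mrna`.
#' @param genome_panel named list (species code -> named character vector of
#'   DNA contigs).
#' @param utr_set named character vector of DNA 3'UTRs; names follow the
#'   `transcript|gene` convention.
#' @param term_annotations data.frame with columns `term_id`, `gene_id`.
#' @param species_panel declared list of valid species codes.
#' @return an object of class `reference_set`.
#' @export
reference_set <- function(tiers,
                          contaminants = list(),
                          genome_panel = list(),
                          utr_set = character(),
                          term_annotations = NULL,
                          species_panel = c("gga", "apl", "cja", "tgu",
                                            "hsa", "mmu", "dre", "aca",
                                            "xtr")) {
  stopifnot(is.list(tiers), length(tiers) >= 1L, !is.null(names(tiers)))
  for (tn in names(tiers)) {
    if (!inherits(tiers[[tn]], "mir_catalog")) {
      stop("tier '", tn, "' is not a mir_catalog")
    }
  }
  if (is.null(term_annotations)) {
    term_annotations <- data.table::data.table(term_id = character(),
                                               gene_id = character())
  }
  term_annotations <- data.table::as.data.table(term_annotations)
  contaminants <- lapply(contaminants, function(x) as_rna(x))
  genome_panel <- lapply(genome_panel, function(x) as_dna(x))
  utr_set <- as_dna(utr_set)
  rs <- structure(list(tiers = tiers, contaminants = contaminants,
                       genome_panel = genome_panel, utr_set = utr_set,
                       term_annotations = term_annotations,
                       species_panel = species_panel),
                  class = "reference_set")
  rep <- validate_reference_set(rs)
  if (length(rep)) stop("invalid reference set:\n  ",
                        paste(rep, collapse = "\n  "))
  rs
}

#' Validate a reference set
#'
#' Checks every structural invariant and returns a report: a character
#' vector with one entry per violation, empty iff the set is consistent.
#' Unlike [reference_set()], this never throws.
#'
#' @param rs a `reference_set` (or a bare list with the same fields).
#' @return character vector of violation messages.
#' @export
validate_reference_set <- function(rs) {
  out <- character()
  all_names <- list()
  for (tn in names(rs$tiers)) {
    cat_ <- rs$tiers[[tn]]
    all_names[[tn]] <- cat_$mature$name
    # mature must slice its hairpin
    hp <- setNames(cat_$hairpin$sequence, cat_$hairpin$id)
    m <- cat_$mature
    for (i in seq_len(nrow(m))) {
      hid <- m$hairpin_id[i]
      if (is.na(hid) || !nzchar(hid)) next
      if (!hid %in% names(hp)) {
        out <- c(out, sprintf("tier %s: mature %s references missing hairpin %s",
                              tn, m$name[i], hid))
        next
      }
      L <- nchar(hp[[hid]])
      if (is.na(m$arm_start[i]) || m$arm_start[i] < 0L || m$arm_end[i] > L) {
        out <- c(out, sprintf(
          "tier %s: mature %s arm interval outside hairpin [0, %d)",
          tn, m$name[i], L))
        next
      }
      if (!identical(substr(hp[[hid]], m$arm_start[i] + 1L, m$arm_end[i]),
                     m$sequence[i])) {
        out <- c(out, sprintf(
          "tier %s: mature %s arm slice does not match its sequence",
          tn, m$name[i]))
      }
    }
    # two arms of one hairpin must not overlap
    two <- m[nzchar(hairpin_id), .N, by = hairpin_id][N > 1L]$hairpin_id
    for (hid in two) {
      iv <- m[hairpin_id == hid][order(arm_start)]
      for (j in seq_len(nrow(iv) - 1L)) {
        if (iv$arm_end[j] > iv$arm_start[j + 1L]) {
          out <- c(out, sprintf("tier %s: overlapping arm intervals in hairpin %s",
                                tn, hid))
        }
      }
    }
  }
  # tier name disjointness
  if (length(all_names) > 1L) {
    for (i in seq_along(all_names)) {
      for (j in seq_along(all_names)) {
        if (i >= j) next
        shared <- intersect(all_names[[i]], all_names[[j]])
        if (length(shared)) {
          out <- c(out, sprintf("mature name(s) present in tiers %s and %s: %s",
                                names(all_names)[i], names(all_names)[j],
                                paste(shared, collapse = ", ")))
        }
      }
    }
  }
  # species codes drawn from the declared panel
  for (tn in names(rs$tiers)) {
    sp <- unlist(strsplit(rs$tiers[[tn]]$mature$annotated_species, ","))
    sp <- trimws(sp[nzchar(trimws(sp))])
    bad <- setdiff(unique(sp), rs$species_panel)
    if (length(bad)) {
      out <- c(out, sprintf("tier %s: species code(s) outside declared panel: %s",
                            tn, paste(bad, collapse = ", ")))
    }
  }
  bad <- setdiff(names(rs$genome_panel), rs$species_panel)
  if (length(bad)) {
    out <- c(out, sprintf("genome panel species outside declared panel: %s",
                          paste(bad, collapse = ", ")))
  }
  out
}

#' Split comma-separated annotated_species into a list of code vectors
#' @param x character vector of comma-separated species codes.
#' @return list of character vectors.
#' @export
species_sets <- function(x) {
  lapply(strsplit(x, ","), function(v) trimws(v[nzchar(trimws(v))]))
}

#' Write a reference set to a directory of FASTA/TSV files
#'
#' Inverse of [read_reference_set()]; a round trip preserves all sequences
#' and metadata.
#'
#' @param rs a `reference_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(rs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tier_names <- names(rs$tiers)
  for (tn in tier_names) {
    cat_ <- rs$tiers[[tn]]
    write_fasta_chr(setNames(cat_$mature$sequence, cat_$mature$name),
                    file.path(dir, paste0("tier_", tn, "_mature.fa")))
    if (nrow(cat_$hairpin)) {
      write_fasta_chr(setNames(cat_$hairpin$sequence, cat_$hairpin$id),
                      file.path(dir, paste0("tier_", tn, "_hairpin.fa")))
    }
    data.table::fwrite(cat_$mature[, .(name, hairpin_id, arm, is_star,
                                       annotated_species, arm_start, arm_end)],
                       file.path(dir, paste0("tier_", tn, "_sidecar.tsv")),
                       sep = "\t")
    data.table::fwrite(cat_$hairpin[, .(id, species)],
                       file.path(dir, paste0("tier_", tn, "_hairpin_meta.tsv")),
                       sep = "\t")
  }
  for (cls in names(rs$contaminants)) {
    write_fasta_chr(rs$contaminants[[cls]],
                    file.path(dir, paste0("contaminant_", cls, ".fa")))
  }
  for (sp in names(rs$genome_panel)) {
    write_fasta_chr(rs$genome_panel[[sp]],
                    file.path(dir, paste0("genome_", sp, ".fa")))
  }
  if (length(rs$utr_set)) {
    write_fasta_chr(rs$utr_set, file.path(dir, "utr_set.fa"))
  }
  data.table::fwrite(rs$term_annotations, file.path(dir, "terms.tsv"),
                     sep = "\t")
  writeLines(jsonlite::toJSON(list(tiers = tier_names,
                                   contaminants = names(rs$contaminants),
                                   genomes = names(rs$genome_panel),
                                   species_panel = rs$species_panel),
                              auto_unbox = FALSE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a reference set written by [write_reference_set()]
#'
#' @param dir directory produced by [write_reference_set()].
#' @return a `reference_set`.
#' @export
read_reference_set <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  tiers <- list()
  for (tn in man$tiers) {
    hp_path <- file.path(dir, paste0("tier_", tn, "_hairpin.fa"))
    side <- file.path(dir, paste0("tier_", tn, "_sidecar.tsv"))
    cat_ <- load_catalog(file.path(dir, paste0("tier_", tn, "_mature.fa")),
                         if (file.exists(hp_path)) hp_path else NULL,
                         side)
    meta_path <- file.path(dir, paste0("tier_", tn, "_hairpin_meta.tsv"))
    if (file.exists(meta_path) && nrow(cat_$hairpin)) {
      meta <- read_tsv_dt(meta_path)
      cat_$hairpin[, species := meta$species[match(id, meta$id)]]
    }
    tiers[[tn]] <- cat_
  }
  contaminants <- list()
  for (cls in man$contaminants) {
    contaminants[[cls]] <-
      read_fasta_chr(file.path(dir, paste0("contaminant_", cls, ".fa")))
  }
  genome_panel <- list()
  for (sp in man$genomes) {
    genome_panel[[sp]] <-
      read_fasta_chr(file.path(dir, paste0("genome_", sp, ".fa")))
  }
  utr_path <- file.path(dir, "utr_set.fa")
  utr_set <- if (file.exists(utr_path)) read_fasta_chr(utr_path) else character()
  terms <- read_tsv_dt(file.path(dir, "terms.tsv"))
  reference_set(tiers, contaminants, genome_panel, utr_set, terms,
                species_panel = man$species_panel)
}
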