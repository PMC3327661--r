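# Annotation cascade: every collapsed read is assigned exactly one category
# by a first-hit, top-to-bottom rule:
#
#   known_mirna (first tier) -> star_mirna -> ortholog_exact (later tiers in
#   order) -> ortholog_mismatch (seed-preserving, 1-2 substitutions) ->
#   genome_only -> trna_rrna_snrna -> repeat -> degraded_mrna -> unannotated
#
# Seed = 1-based positions 2-8 of the mature strand; a mismatch inside the
# seed disqualifies an ortholog-mismatch hit. The mismatch model is
# substitution-only over equal-length sequences.

ANNOTATION_CATEGORIES <- c("known_mirna", "star_mirna", "ortholog_exact",
                           "ortholog_mismatch", "genome_only", "repeat",
                           "trna_rrna_snrna", "degraded_mrna", "unannotated")

SEED_POSITIONS <- 2:8

#' Exact-match an insert against a catalog tier
#'
#' @param insert a single sequence (DNA or RNA; normalized to RNA).
#' @param catalog a [mir_catalog()].
#' @return character vector of mature names whose sequence equals the
#'   insert (possibly empty), sorted.
#' @export
match_exact <- function(insert, catalog) {
  q <- as_rna(insert)
  sort(catalog$mature$name[catalog$mature$sequence == q])
}

# Opposite-arm search regions for hairpins carrying exactly one annotated
# mature arm. The unannotated star strand sits on the other side of the
# hairpin midpoint; an insert overlapping only the loop (i.e. crossing the
# midpoint) is not a star hit.
star_regions <- function(catalog) {
  m <- catalog$mature[nzchar(hairpin_id)]
  if (!nrow(m)) {
    return(data.table::data.table(star_name = character(),
                                  hairpin_id = character(),
                                  region = character()))
  }
  counts <- m[, .N, by = hairpin_id]
  singles <- counts[N == 1L]$hairpin_id
  m <- m[hairpin_id %in% singles]
  hp <- setNames(catalog$hairpin$sequence, catalog$hairpin$id)
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    L <- nchar(hp[[m$hairpin_id[i]]])
    mid <- L %/% 2L
    arm_mid <- (m$arm_start[i] + m$arm_end[i]) / 2
    region <- if (arm_mid < L / 2) {
      substr(hp[[m$hairpin_id[i]]], mid + 1L, L)          # 3' half
    } else {
      substr(hp[[m$hairpin_id[i]]], 1L, mid)              # 5' half
    }
    out[[i]] <- data.table::data.table(
      star_name = paste0(m$name[i], "-ukstar"),
      hairpin_id = m$hairpin_id[i], region = region)
  }
  data.table::rbindlist(out)
}

#' Recover an unannotated star strand
#'
#' Searches hairpins that carry exactly one annotated mature arm for an
#' exact substring occurrence of the insert within the arm opposite the
#' annotated one (the hairpin half not containing the mature). The star is
#' named `<mature-name>-ukstar`.
#'
#' @param insert a single sequence.
#' @param catalog a [mir_catalog()] whose hairpins to search.
#' @return `NULL`, or a list with `hairpin_id` and `star_name` (first hit
#'   by hairpin id order on ties).
#' @export
infer_star <- function(insert, catalog) {
  q <- as_rna(insert)
  reg <- star_regions(catalog)
  if (!nrow(reg)) return(NULL)
  data.table::setorder(reg, hairpin_id)
  hit <- which(vapply(reg$region, function(r) grepl(q, r, fixed = TRUE),
                      logical(1)))
  if (!length(hit)) return(NULL)
  list(hairpin_id = reg$hairpin_id[hit[1]], star_name = reg$star_name[hit[1]])
}

#' Seed-preserving mismatch search
#'
#' Equal-length Hamming comparison of the insert against every mature in
#' the catalog: a hit has between 1 and `max_mm` substitutions, none inside
#' seed positions 2-8 (1-based on the mature reference).
#'
#' @param insert a single sequence.
#' @param catalog a [mir_catalog()].
#' @param max_mm maximum number of substitutions (default 2).
#' @return data.table with columns `name` and `mismatch_positions` (list
#'   column of ascending integer positions); zero rows if no hit.
#' @export
match_seed_preserving <- function(insert, catalog, max_mm = 2L) {
  q <- as_rna(insert)
  cand <- catalog$mature[nchar(sequence) == nchar(q)]
  out <- list()
  if (nrow(cand)) {
    qc <- strsplit(q, "")[[1]]
    for (i in seq_len(nrow(cand))) {
      rc <- strsplit(cand$sequence[i], "")[[1]]
      mm <- which(qc != rc)
      if (length(mm) >= 1L && length(mm) <= max_mm &&
          !any(mm %in% SEED_POSITIONS)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          name = cand$name[i], mismatch_positions = list(as.integer(mm)))
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(name = character(),
                                  mismatch_positions = list()))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, name)
  res[]
}

#' Map an insert to exact genomic locations
#'
#' Full-length exact occurrences on both strands; a minus-strand hit is an
#' occurrence of the reverse complement. Coordinates are 0-based half-open.
#'
#' @param insert a single sequence.
#' @param genome named character vector of DNA contigs.
#' @return data.table with columns `seqname`, `start`, `end`, `strand`.
#' @export
map_genome <- function(insert, genome) {
  q <- as_dna(insert)
  qr <- revcomp_dna(q)
  out <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") q else qr
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
      if (length(m)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          seqname = ctg, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(seqname = character(), start = integer(),
                                  end = integer(), strand = character()))
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, seqname, start, strand)
  res[]
}

#' Classify an insert against contaminant sequence classes
#'
#' A match is an exact substring occurrence of the insert in any sequence
#' of the class. Classes are tried in fixed precedence order
#' `trna_rrna_snrna` (pooling the trna/rrna/snrna sets) -> `repeat` ->
#' `degraded_mrna`.
#'
#' @param insert a single sequence.
#' @param contaminants named list of sequence vectors with names among
#'   `trna`, `rrna`, `snrna`, `repeat`, `mrna`.
#' @return the category string, or `NULL` if no class matches.
#' @export
classify_contaminant <- function(insert, contaminants) {
  q <- as_rna(insert)
  in_class <- function(seqs) {
    length(seqs) > 0L && any(grepl(q, as_rna(seqs), fixed = TRUE))
  }
  pool <- unlist(contaminants[intersect(c("trna", "rrna", "snrna"),
                                        names(contaminants))],
                 use.names = FALSE)
  if (in_class(pool)) return("trna_rrna_snrna")
  if (in_class(contaminants[["repeat"]])) return("repeat")
  if (in_class(contaminants[["mrna"]])) return("degraded_mrna")
  NULL
}

# ---- vectorized cascade internals ---------------------------------------

# Substring presence of many inserts (RNA space) in a set of subject
# sequences; optionally on both strands. Returns a logical vector.
# Implemented as hashed membership in the per-width k-mer sets of the
# subjects, which beats suffix-tree dictionaries at these subject sizes.
bulk_substring_present <- function(inserts, subjects, both_strands = FALSE) {
  res <- rep(FALSE, length(inserts))
  if (!length(inserts) || !length(subjects)) return(res)
  subjects <- as_dna(subjects)
  dna <- as_dna(inserts)
  slen <- nchar(subjects)
  for (w in unique(nchar(dna))) {
    sel <- which(nchar(dna) == w)
    kmers <- unlist(lapply(which(slen >= w), function(i) {
      n <- slen[i]
      unique(substring(subjects[i], 1:(n - w + 1L), w:n))
    }), use.names = FALSE)
    hit <- dna[sel] %in% kmers
    if (both_strands) hit <- hit | revcomp_dna(dna[sel]) %in% kmers
    res[sel] <- hit
  }
  res
}

# Exact-match inserts against a tier; returns assigned (lexicographically
# first) name, all tied names, per insert (NA when no hit).
bulk_exact <- function(inserts, catalog) {
  seq2names <- catalog$mature[, .(all_names = paste(sort(name), collapse = ",")),
                              by = sequence]
  idx <- match(inserts, seq2names$sequence)
  all_names <- seq2names$all_names[idx]
  assigned <- vapply(strsplit(ifelse(is.na(all_names), "", all_names), ","),
                     function(v) if (length(v)) v[1] else NA_character_,
                     character(1))
  list(assigned = assigned, all_names = all_names)
}

# Seed-preserving mismatch search for many inserts; returns assigned name
# and mismatch-position string per insert (NA when no hit).
bulk_mismatch <- function(inserts, catalog, max_mm = 2L) {
  assigned <- rep(NA_character_, length(inserts))
  allnm <- rep(NA_character_, length(inserts))
  mmpos <- rep(NA_character_, length(inserts))
  if (!length(inserts) || !nrow(catalog$mature)) {
    return(list(assigned = assigned, all_names = allnm, mmpos = mmpos))
  }
  lens <- nchar(inserts)
  mat <- catalog$mature
  for (w in intersect(unique(lens), unique(nchar(mat$sequence)))) {
    sel <- which(lens == w)
    qm <- matrix(unlist(strsplit(inserts[sel], "")), ncol = w, byrow = TRUE)
    cand <- mat[nchar(sequence) == w]
    # per insert: best = all candidate names ordered; first hit wins ties
    hitlist <- vector("list", length(sel))
    for (j in seq_len(nrow(cand))) {
      rc <- strsplit(cand$sequence[j], "")[[1]]
      neq <- qm != matrix(rc, nrow = length(sel), ncol = w, byrow = TRUE)
      nmm <- rowSums(neq)
      seed_clean <- rowSums(neq[, SEED_POSITIONS, drop = FALSE]) == 0L
      ok <- which(nmm >= 1L & nmm <= max_mm & seed_clean)
      for (k in ok) {
        hitlist[[k]] <- c(hitlist[[k]], setNames(
          paste(which(neq[k, ]), collapse = ","), cand$name[j]))
      }
    }
    for (k in seq_along(sel)) {
      h <- hitlist[[k]]
      if (is.null(h)) next
      ord <- order(names(h))
      assigned[sel[k]] <- names(h)[ord[1]]
      allnm[sel[k]] <- paste(names(h)[ord], collapse = ",")
      mmpos[sel[k]] <- h[[ord[1]]]
    }
  }
  list(assigned = assigned, all_names = allnm, mmpos = mmpos)
}

#' Annotate a collapsed library through the cascade
#'
#' Applies the first-hit cascade to every collapsed read. The first tier of
#' the reference set plays the "home species" role (known miRNAs and star
#' recovery); later tiers are searched in order for exact orthologs and then
#' for seed-preserving mismatch orthologs. Genome mapping uses the
#' `genome_species` member of the panel. The mapped-read denominator is the
#' count-weighted total of reads in any category except `unannotated`.
#'
#' @param lib an `smrna_library` (see [preprocess_library()]), or any list
#'   with fields `id` and `reads` (data.table `insert`, `count`).
#' @param rs a [reference_set()].
#' @param genome_species species code of the genome used for the
#'   `genome_only` step (default `"gga"`; skipped when absent from panel).
#' @param max_mm maximum substitutions for ortholog mismatch rescue.
#' @return object of class `annotated_library`: list with `records`
#'   (data.table: insert, count, category, assigned_name, tier,
#'   mismatch_positions, all_names), `summary` (see details), `id`,
#'   `species`, `stage`.
#' @details The summary holds count-weighted `fractions` over all nine
#'   categories (summing to 1), `distinct_mirnas` tallies per miRNA-bearing
#'   category, `mapped_reads` (the denominator) and `total_reads`.
#' @export
annotate_library <- function(lib, rs, genome_species = "gga", max_mm = 2L) {
  reads <- lib$reads
  if (is.null(reads) || nrow(reads) == 0L) {
    stop("cannot annotate an empty library: ", lib$id %||% "<unnamed>")
  }
  rec <- data.table::data.table(insert = as_rna(reads$insert),
                                count = as.integer(reads$count))
  n <- nrow(rec)
  category <- rep(NA_character_, n)
  assigned <- rep(NA_character_, n)
  tier <- rep(NA_character_, n)
  mmpos <- rep(NA_character_, n)
  allnm <- rep(NA_character_, n)

  tier_names <- names(rs$tiers)
  home <- tier_names[1]

  todo <- seq_len(n)

  # 1. known miRNA (home tier, exact)
  ex <- bulk_exact(rec$insert[todo], rs$tiers[[home]])
  hit <- !is.na(ex$assigned)
  idx <- todo[hit]
  category[idx] <- "known_mirna"
  assigned[idx] <- ex$assigned[hit]
  allnm[idx] <- ex$all_names[hit]
  tier[idx] <- home
  todo <- todo[!hit]

  # 2. unannotated star strands (home tier hairpins)
  if (length(todo)) {
    reg <- star_regions(rs$tiers[[home]])
    if (nrow(reg)) {
      data.table::setorder(reg, hairpin_id)
      any_hit <- bulk_substring_present(rec$insert[todo], reg$region)
      first <- rep(NA_integer_, length(todo))
      for (k in which(any_hit)) {
        q <- rec$insert[todo[k]]
        j <- which(vapply(reg$region, function(r) grepl(q, r, fixed = TRUE),
                          logical(1)))
        first[k] <- j[1]
      }
      hit <- !is.na(first)
      idx <- todo[hit]
      category[idx] <- "star_mirna"
      assigned[idx] <- reg$star_name[first[hit]]
      allnm[idx] <- assigned[idx]
      tier[idx] <- home
      todo <- todo[!hit]
    }
  }

  # 3. ortholog exact (later tiers, in order)
  for (tn in tier_names[-1]) {
    if (!length(todo)) break
    ex <- bulk_exact(rec$insert[todo], rs$tiers[[tn]])
    hit <- !is.na(ex$assigned)
    idx <- todo[hit]
    category[idx] <- "ortholog_exact"
    assigned[idx] <- ex$assigned[hit]
    allnm[idx] <- ex$all_names[hit]
    tier[idx] <- tn
    todo <- todo[!hit]
  }

  # 4. ortholog mismatch (seed-preserving, later tiers in order)
  for (tn in tier_names[-1]) {
    if (!length(todo)) break
    mm <- bulk_mismatch(rec$insert[todo], rs$tiers[[tn]], max_mm)
    hit <- !is.na(mm$assigned)
    idx <- todo[hit]
    category[idx] <- "ortholog_mismatch"
    assigned[idx] <- mm$assigned[hit]
    allnm[idx] <- mm$all_names[hit]
    mmpos[idx] <- mm$mmpos[hit]
    tier[idx] <- tn
    todo <- todo[!hit]
  }

  # 5. genome only (exact, both strands)
  if (length(todo) && genome_species %in% names(rs$genome_panel)) {
    pres <- bulk_substring_present(rec$insert[todo],
                                   rs$genome_panel[[genome_species]],
                                   both_strands = TRUE)
    # genome mapping is full-length: restrict to full-length occurrences.
    # (substring presence of a full-length insert IS a full-length hit)
    idx <- todo[pres]
    category[idx] <- "genome_only"
    todo <- todo[!pres]
  }

  # 6. contaminant classes, fixed precedence
  pool_keys <- list(
    trna_rrna_snrna = intersect(c("trna", "rrna", "snrna"),
                                names(rs$contaminants)),
    "repeat" = intersect("repeat", names(rs$contaminants)),
    degraded_mrna = intersect("mrna", names(rs$contaminants)))
  for (cls in names(pool_keys)) {
    if (!length(todo)) break
    seqs <- unlist(rs$contaminants[pool_keys[[cls]]], use.names = FALSE)
    if (!length(seqs)) next
    pres <- bulk_substring_present(rec$insert[todo], seqs)
    idx <- todo[pres]
    category[idx] <- cls
    todo <- todo[!pres]
  }

  category[todo] <- "unannotated"

  rec[, `:=`(category = category, assigned_name = assigned, tier = tier,
             mismatch_positions = mmpos, all_names = allnm)]

  total <- sum(rec$count)
  frac <- vapply(ANNOTATION_CATEGORIES,
                 function(cl) sum(rec$count[rec$category == cl]) / total,
                 numeric(1))
  mirna_cats <- c("known_mirna", "star_mirna", "ortholog_exact",
                  "ortholog_mismatch")
  distinct <- vapply(mirna_cats, function(cl) {
    length(unique(rec$assigned_name[rec$category == cl]))
  }, integer(1))
  mapped <- total - sum(rec$count[rec$category == "unannotated"])

  structure(list(records = rec[],
                 summary = list(fractions = frac,
                                distinct_mirnas = distinct,
                                mapped_reads = mapped,
                                total_reads = total),
                 id = lib$id, species = lib$species, stage = lib$stage),
            class = "annotated_library")
}

#' Write annotation records and summary to disk
#'
#' @param ann an `annotated_library`.
#' @param tsv path for the per-read records TSV (or `NULL`).
#' @param json path for the summary JSON (or `NULL`).
#' @return invisibly, `ann`.
#' @export
write_annotation <- function(ann, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) data.table::fwrite(ann$records, tsv, sep = "\t")
  if (!is.null(json)) {
    writeLines(jsonlite::toJSON(ann$summary, auto_unbox = TRUE, digits = NA),
               json)
  }
  invisible(ann)
}
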