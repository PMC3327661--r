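# Synthetic dataset generator with planted ground truth.
#
# The generator emulates the structure of a 3-species x 2-stage small RNA
# survey: six adapter-ligated libraries whose reads are drawn multinomially
# from a planted composition. Default category fractions are the published
# per-category read percentages of the study design this emulates (known
# miRNAs 56.36%, unannotated stars 1.02%, exact orthologs 11.07%, mismatch
# orthologs 0.09%, degraded mRNA 1.03%, repeats 6.71%, tRNA/rRNA/snRNA
# 18.57%), with the residual split between genome-only reads (3.61%) and
# unannotated reads (1.55%) so that 98.45% of reads map somewhere. Catalog
# sizes are scaled down to desk scale; planted features cover every cascade
# branch: unannotated star strands, seed-preserving mismatch orthologs,
# orthologs absent from the "home" genome (assembly-gap emulation),
# avian-specific hairpins planted only in avian panel genomes, and
# programmed between-library fold changes on the PMMR scale.

DEFAULT_ADAPTER <- "TCGTATGCCGTCTTCTGCTTG"

DEFAULT_CATEGORY_FRACTIONS <- c(
  known_mirna = 0.5636, star_mirna = 0.0102, ortholog_exact = 0.1107,
  ortholog_mismatch = 0.0009, genome_only = 0.0361, "repeat" = 0.0671,
  trna_rrna_snrna = 0.1857, degraded_mrna = 0.0103, unannotated = 0.0154)

#' Construct a simulation specification
#'
#' Defaults are the stated world: 6 libraries (3 species x 2 stages),
#' published category fractions, zero substitution error, and a fixed plan
#' of planted fold changes (4-fold, i.e. log2 offset 2) covering the trend
#' classes.
#'
#' @param depth reads per library (default 1e5).
#' @param species,stages design axes (3 species x 2 stages by default).
#' @param adapter 3' adapter ligated to every insert.
#' @param read_length fixed read length; inserts are padded with random
#'   tail beyond the adapter or truncate it (never below `min_overlap`).
#' @param error_rate per-base substitution probability applied to insert
#'   bases (default 0).
#' @param category_fractions named numeric over the nine annotation
#'   categories, summing to 1.
#' @param n_known,n_star,n_ortholog_hsa,n_ortholog_tgu,n_mismatch catalog
#'   sizes: known home-tier matures, hairpins with planted unannotated
#'   stars, exact human/zebrafinch orthologs, mismatch-ortholog variants.
#' @param trend_plan data.frame with columns `trend` and `n`, planting
#'   that many known miRNAs per trend class; offsets are +/-2 log2 units.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(depth = 1e5L,
                     species = c("gga", "apl", "cja"),
                     stages = c("HH20", "HH25"),
                     adapter = DEFAULT_ADAPTER,
                     read_length = 50L,
                     error_rate = 0,
                     category_fractions = DEFAULT_CATEGORY_FRACTIONS,
                     n_known = 40L, n_star = 8L,
                     n_ortholog_hsa = 10L, n_ortholog_tgu = 2L,
                     n_mismatch = 4L,
                     trend_plan = data.frame(
                       trend = c("up_all3_HH25", "down_all3_HH25",
                                 "up_chicken_quail_only",
                                 "duck_high_both_stages",
                                 "duck_high_HH25_only",
                                 "duck_low_both_stages"),
                       n = c(2L, 2L, 1L, 1L, 1L, 1L))) {
  stopifnot(depth >= 1L, error_rate >= 0, error_rate < 1,
            nchar(adapter) >= 8L)
  fr <- category_fractions[names(DEFAULT_CATEGORY_FRACTIONS)]
  if (anyNA(fr)) stop("category_fractions must name all nine categories")
  if (abs(sum(fr) - 1) > 1e-9) stop("category fractions must sum to 1")
  if (any(fr < 0 | fr > 1)) stop("category fractions must lie in [0, 1]")
  libs <- data.table::CJ(species = species, stage = stages, sorted = FALSE)
  libs[, id := paste(species, stage, sep = "-")]
  structure(list(depth = as.integer(depth), libraries = libs[],
                 adapter = as_dna(adapter),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, category_fractions = fr,
                 n_known = n_known, n_star = n_star,
                 n_ortholog_hsa = n_ortholog_hsa,
                 n_ortholog_tgu = n_ortholog_tgu,
                 n_mismatch = n_mismatch,
                 trend_plan = data.table::as.data.table(trend_plan)),
            class = "sim_spec")
}

#' Read / write a simulation spec as a JSON config file
#'
#' @param path JSON file path.
#' @return for the reader, a [sim_spec()].
#' @export
read_sim_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  sim_spec(depth = x$depth %||% 1e5L,
           species = x$species %||% c("gga", "apl", "cja"),
           stages = x$stages %||% c("HH20", "HH25"),
           adapter = x$adapter %||% DEFAULT_ADAPTER,
           read_length = x$read_length %||% 50L,
           error_rate = x$error_rate %||% 0,
           category_fractions =
             if (!is.null(x$category_fractions))
               unlist(x$category_fractions) else DEFAULT_CATEGORY_FRACTIONS)
}

#' @rdname read_sim_spec
#' @param spec a `sim_spec`.
#' @export
write_sim_spec <- function(spec, path) {
  writeLines(jsonlite::toJSON(list(
    depth = spec$depth, species = unique(spec$libraries$species),
    stages = unique(spec$libraries$stage), adapter = spec$adapter,
    read_length = spec$read_length, error_rate = spec$error_rate,
    category_fractions = as.list(spec$category_fractions)),
    auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# -- random sequence helpers ----------------------------------------------

random_seqs <- function(n, lens, alphabet = c("A", "C", "G", "U")) {
  if (n == 0L) return(character())
  maxlen <- max(lens)
  mat <- matrix(sample(alphabet, n * maxlen, replace = TRUE), nrow = n)
  full <- apply(mat, 1L, paste, collapse = "")
  substr(full, 1L, lens)
}

# random sequences avoiding the adapter probe and an exclusion set
clean_random_seqs <- function(n, lens, adapter, exclude = character()) {
  probe <- as_rna(substr(adapter, 1L, 8L))
  out <- character(n)
  need <- seq_len(n)
  lens <- rep_len(lens, n)
  while (length(need)) {
    cand <- random_seqs(length(need), lens[need])
    ok <- !grepl(probe, cand, fixed = TRUE) & !(cand %in% exclude) &
      !duplicated(cand)
    out[need[ok]] <- cand[ok]
    exclude <- c(exclude, cand[ok])
    need <- need[!ok]
  }
  out
}

mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a reference set with planted features
#'
#' Builds the tiered catalogs (home "chicken" tier including the packaged
#' avian-candidate fixture verbatim, plus generated known miRNAs and
#' star-bearing hairpins; "human" and "zebrafinch" ortholog tiers),
#' contaminant classes, the genome panel (avian-specific hairpins planted
#' in avian genomes only, one control hairpin planted everywhere, ortholog
#' matures deliberately absent from the home genome), a UTR set seeded with
#' target sites for the fixture matures, and term annotations.
#'
#' @param spec a [sim_spec()].
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   output.
#' @return list with `rs` (a [reference_set()]) and `truth`: planted unit
#'   table (`units`: unit sequence, category, name), planted features
#'   (star names, mismatch variants, avian-specific hairpin ids, control
#'   hairpin id), and the per-library log2 offset table.
#' @export
make_reference_set <- function(spec, seed = 1L) {
  set.seed(seed)
  adapter <- spec$adapter

  t1 <- table1_catalog()
  t1_m <- data.table::copy(t1$mature)
  t1_h <- data.table::copy(t1$hairpin)

  exclude <- t1_m$sequence
  # generated known matures (home tier), with hairpins mature+loop+star-arm
  kn_seq <- clean_random_seqs(spec$n_known, sample(21:23, spec$n_known,
                                                   replace = TRUE),
                              adapter, exclude)
  exclude <- c(exclude, kn_seq)
  kn_name <- sprintf("gga-sim-miR-%03d", seq_len(spec$n_known))
  loops <- clean_random_seqs(spec$n_known, rep(15L, spec$n_known), adapter,
                             exclude)
  arm3 <- clean_random_seqs(spec$n_known, nchar(kn_seq), adapter,
                            c(exclude, loops))
  exclude <- c(exclude, loops, arm3)
  kn_hp <- paste0(kn_name, "-hp")
  kn_hp_seq <- paste0(kn_seq, loops, arm3)

  # the first n_star hairpins donate their 3' arm as an unannotated star
  star_idx <- seq_len(spec$n_star)
  star_units <- data.table::data.table(
    sequence = arm3[star_idx],
    name = paste0(kn_name[star_idx], "-ukstar"),
    category = "star_mirna")

  mature_home <- data.table::rbindlist(list(
    t1_m[, .(name, sequence, hairpin_id, arm, is_star, annotated_species)],
    data.table::data.table(name = kn_name, sequence = kn_seq,
                           hairpin_id = kn_hp, arm = "five_prime",
                           is_star = FALSE, annotated_species = "gga")))
  hairpin_home <- data.table::rbindlist(list(
    t1_h[, .(id, species, sequence)],
    data.table::data.table(id = kn_hp, species = "gga",
                           sequence = kn_hp_seq)))
  home <- mir_catalog(mature_home, hairpin_home)

  # ortholog tiers (hairpin-less): exact orthologs plus mismatch sources
  n_hsa <- spec$n_ortholog_hsa + spec$n_mismatch
  hsa_seq <- clean_random_seqs(n_hsa, sample(21:23, n_hsa, replace = TRUE),
                               adapter, exclude)
  exclude <- c(exclude, hsa_seq)
  hsa_name <- sprintf("hsa-sim-miR-%03d", seq_len(n_hsa))
  tier_hsa <- mir_catalog(
    data.table::data.table(name = hsa_name, sequence = hsa_seq,
                           hairpin_id = "", arm = "unknown", is_star = FALSE,
                           annotated_species = "hsa"),
    data.table::data.table(id = character(), species = character(),
                           sequence = character()))
  tgu_seq <- clean_random_seqs(spec$n_ortholog_tgu,
                               sample(21:23, spec$n_ortholog_tgu,
                                      replace = TRUE), adapter, exclude)
  exclude <- c(exclude, tgu_seq)
  tgu_name <- sprintf("tgu-sim-miR-%03d", seq_len(spec$n_ortholog_tgu))
  tier_tgu <- mir_catalog(
    data.table::data.table(name = tgu_name, sequence = tgu_seq,
                           hairpin_id = "", arm = "unknown", is_star = FALSE,
                           annotated_species = "tgu"),
    data.table::data.table(id = character(), species = character(),
                           sequence = character()))

  # mismatch-ortholog read variants: the last n_mismatch human matures,
  # mutated at fixed positions outside the seed (2-8)
  mm_src <- tail(seq_len(n_hsa), spec$n_mismatch)
  mm_units <- data.table::rbindlist(lapply(mm_src, function(i) {
    L <- nchar(hsa_seq[i])
    pos <- sort(sample(setdiff(9:(L - 1L), integer()), 2L))
    v <- mutate_positions(hsa_seq[i], pos)
    data.table::data.table(sequence = v, name = hsa_name[i],
                           category = "ortholog_mismatch",
                           mm_pos = paste(pos, collapse = ","))
  }))

  # contaminant classes
  contam <- list(
    trna = setNames(random_seqs(5L, rep(80L, 5L)), paste0("trna", 1:5)),
    rrna = setNames(random_seqs(2L, rep(800L, 2L)), paste0("rrna", 1:2)),
    snrna = setNames(random_seqs(4L, rep(130L, 4L)), paste0("snrna", 1:4)),
    "repeat" = setNames(random_seqs(6L, rep(300L, 6L)), paste0("rep", 1:6)),
    mrna = setNames(random_seqs(8L, rep(500L, 8L)), paste0("mrna", 1:8)))

  # genome panel: home genome has a clean fragment-source contig and a
  # contig carrying the avian hairpins; ortholog matures are NOT planted
  # (assembly-gap emulation). Avian-specific hairpins go into avian genomes
  # only; one control hairpin goes everywhere. The hp-1451 fixture hairpin
  # is planted in the home genome only (restricted, not pan-avian).
  control_hp <- as_dna(random_seqs(1L, 70L))
  avian_plant <- as_dna(t1_h[id != "hp-1451-synth"]$sequence)
  plant_into <- function(base, plants) {
    gaps <- random_seqs(length(plants) + 1L,
                        rep(300L, length(plants) + 1L), c("A", "C", "G", "T"))
    paste0(paste0(gaps[seq_along(plants)], plants, collapse = ""),
           gaps[length(plants) + 1L], base)
  }
  genome_panel <- list(
    gga = c(contig1 = random_seqs(1L, 20000L, c("A", "C", "G", "T")),
            contig2 = plant_into(random_seqs(1L, 3000L, c("A", "C", "G", "T")),
                                 c(avian_plant, control_hp,
                                   as_dna(t1_h[id == "hp-1451-synth"]$sequence)))),
    tgu = c(contig1 = plant_into(random_seqs(1L, 6000L, c("A", "C", "G", "T")),
                                 c(avian_plant, control_hp))),
    hsa = c(contig1 = plant_into(random_seqs(1L, 6000L, c("A", "C", "G", "T")),
                                 control_hp)),
    dre = c(contig1 = plant_into(random_seqs(1L, 6000L, c("A", "C", "G", "T")),
                                 control_hp)))

  # UTR set: random UTRs, with seed-match sites for the fixture matures
  # planted into the first few; two-column term annotations over the genes
  n_utr <- 30L
  utr <- random_seqs(n_utr, rep(400L, n_utr), c("A", "C", "G", "T"))
  genes <- sprintf("GENE%02d", seq_len(n_utr))
  names(utr) <- paste0(sprintf("TX%02d", seq_len(n_utr)), "|", genes)
  for (i in seq_len(min(6L, nrow(t1_m)))) {
    site <- paste0(revcomp_dna(as_dna(seed_of(t1_m$sequence[i]))), "A")
    pos <- 50L * i
    substr(utr[i], pos, pos + 7L) <- site
  }
  terms <- data.table::data.table(
    term_id = rep(c("GO:0001", "GO:0002", "GO:0003"), times = c(6L, 10L, 20L)),
    gene_id = c(genes[1:6], genes[3:12], genes[11:30]))

  rs <- reference_set(
    tiers = list(chicken = home, human = tier_hsa, zebrafinch = tier_tgu),
    contaminants = contam, genome_panel = genome_panel, utr_set = utr,
    term_annotations = terms)

  # planted per-unit read sequences for the miRNA-bearing categories
  units <- data.table::rbindlist(list(
    data.table::data.table(sequence = mature_home$sequence,
                           name = mature_home$name,
                           category = "known_mirna", mm_pos = ""),
    data.table::data.table(sequence = star_units$sequence,
                           name = star_units$name,
                           category = "star_mirna", mm_pos = ""),
    data.table::data.table(sequence = c(hsa_seq[seq_len(spec$n_ortholog_hsa)],
                                        tgu_seq),
                           name = c(hsa_name[seq_len(spec$n_ortholog_hsa)],
                                    tgu_name),
                           category = "ortholog_exact", mm_pos = ""),
    mm_units[, .(sequence, name, category, mm_pos)]))

  # trend plan: assign planted log2 offsets to generated known miRNAs
  # (never the fixture matures, which stay flat and high)
  plan <- spec$trend_plan
  targets_pool <- kn_name[-star_idx]
  need <- sum(plan$n)
  if (need > length(targets_pool)) stop("trend plan larger than catalog")
  chosen <- targets_pool[seq_len(need)]
  trend_assign <- data.table::data.table(
    name = chosen, trend = rep(plan$trend, plan$n))

  offsets <- data.table::CJ(name = units$name,
                            lib = spec$libraries$id, unique = TRUE)
  offsets[, log2_offset := 0]
  lib_meta <- spec$libraries
  for (i in seq_len(nrow(trend_assign))) {
    nm <- trend_assign$name[i]
    tr <- trend_assign$trend[i]
    for (j in seq_len(nrow(lib_meta))) {
      lid <- lib_meta$id[j]; sp <- lib_meta$species[j]
      st <- lib_meta$stage[j]
      off <- switch(tr,
        up_all3_HH25 = if (st == "HH25") 2 else 0,
        down_all3_HH25 = if (st == "HH25") -2 else 0,
        up_chicken_quail_only =
          if (st == "HH25" && sp %in% c("gga", "cja")) 2 else 0,
        duck_high_both_stages = if (sp == "apl") 2 else 0,
        duck_high_HH25_only = if (sp == "apl" && st == "HH25") 2 else 0,
        duck_low_both_stages = if (sp == "apl") -2 else 0,
        0)
      offsets[name == nm & lib == lid, log2_offset := off]
    }
  }

  list(rs = rs,
       truth = list(units = units[],
                    star_names = star_units$name,
                    mismatch_variants = mm_units[],
                    avian_hairpins = t1_h[id != "hp-1451-synth"]$id,
                    restricted_hairpin = "hp-1451-synth",
                    control_hairpin_seq = control_hp,
                    trend_assign = trend_assign[],
                    offsets = offsets[]))
}

# base weights within the known category: fixture matures high, generated
# ones log-uniform over roughly two decades
unit_base_weights <- function(units, t1_names) {
  w <- numeric(nrow(units))
  for (cat_ in unique(units$category)) {
    idx <- which(units$category == cat_)
    wi <- 10^runif(length(idx), -1, 1)
    w[idx] <- wi
  }
  w[units$name %in% t1_names] <- 12   # "relatively high levels"
  w
}

#' Simulate FASTQ libraries with planted truth
#'
#' Draws each library's reads multinomially: within-category unit weights
#' are scaled by `2^log2_offset` for that library and renormalized within
#' the category, so the planted category fractions hold exactly in
#' expectation while programmed fold changes act on the PMMR scale. Reads
#' are `insert + adapter`, truncated or padded with random tail to the
#' fixed read length; substitution errors (if any) hit insert bases
#' uniformly.
#'
#' @param spec a [sim_spec()].
#' @param ref result of [make_reference_set()].
#' @param out_dir directory for the FASTQ files (created).
#' @param seed integer RNG seed.
#' @return list with `files` (named FASTQ paths), `truth` (list:
#'   `category_counts`, `mirna_counts` data.tables, `expected_pmmr`), and
#'   `libraries` (the design table).
#' @export
simulate_libraries <- function(spec, ref, out_dir, seed = 1L) {
  set.seed(seed + 1L)
  if (spec$depth < 1000L) {
    warning("library depth < 1000: planted fractions will be unstable")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  units <- data.table::copy(ref$truth$units)
  t1_names <- table1_catalog()$mature$name
  units[, base_w := unit_base_weights(units, t1_names)]
  cat_fr <- spec$category_fractions
  offsets <- ref$truth$offsets
  contam <- ref$rs$contaminants
  genome_src <- ref$rs$genome_panel$gga[["contig1"]]

  files <- character()
  cat_counts <- list()
  mir_counts <- list()
  exp_pmmr <- list()

  for (j in seq_len(nrow(spec$libraries))) {
    lid <- spec$libraries$id[j]
    # per-library unit probabilities
    u <- data.table::copy(units)
    off <- offsets[lib == lid]
    u[, w := base_w * 2^(off$log2_offset[match(name, off$name)])]
    u[, prob := w / sum(w) * cat_fr[[category[1]]], by = category]
    # class-level probabilities
    class_probs <- c(cat_fr[["repeat"]], cat_fr[["trna_rrna_snrna"]],
                     cat_fr[["degraded_mrna"]], cat_fr[["genome_only"]],
                     cat_fr[["unannotated"]])
    probs <- c(u$prob, class_probs)
    stopifnot(abs(sum(probs) - 1) < 1e-9)
    counts <- as.integer(stats::rmultinom(1L, spec$depth, probs))
    n_units <- nrow(u)
    u[, count := counts[seq_len(n_units)]]
    cls_counts <- counts[n_units + 1:5]
    names(cls_counts) <- c("repeat", "trna_rrna_snrna", "degraded_mrna",
                           "genome_only", "unannotated")

    inserts <- rep(u$sequence, u$count)

    # contaminant fragments: random windows of class reference sequences
    frag_from <- function(refs, n) {
      if (n == 0L) return(character())
      lens <- sample(20:36, n, replace = TRUE)
      src <- sample(length(refs), n, replace = TRUE)
      reflen <- nchar(refs)[src]
      starts <- floor(runif(n) * (reflen - lens + 1L)) + 1L
      substr(refs[src], starts, starts + lens - 1L)
    }
    inserts <- c(inserts,
                 frag_from(unname(unlist(contam["repeat"])),
                           cls_counts[["repeat"]]),
                 frag_from(unname(unlist(contam[c("trna", "rrna", "snrna")])),
                           cls_counts[["trna_rrna_snrna"]]),
                 frag_from(unname(unlist(contam["mrna"])),
                           cls_counts[["degraded_mrna"]]),
                 as_rna(frag_from(genome_src, cls_counts[["genome_only"]])))
    truth_cat <- c(rep(u$category, u$count),
                   rep(c("repeat", "trna_rrna_snrna", "degraded_mrna",
                         "genome_only"),
                       cls_counts[c("repeat", "trna_rrna_snrna",
                                    "degraded_mrna", "genome_only")]))
    # unannotated: random sequences matching nothing
    n_un <- cls_counts[["unannotated"]]
    if (n_un > 0L) {
      inserts <- c(inserts, random_seqs(n_un, sample(20:24, n_un,
                                                     replace = TRUE)))
      truth_cat <- c(truth_cat, rep("unannotated", n_un))
    }

    # substitution errors on insert bases
    if (spec$error_rate > 0) {
      n_mut <- rbinom(length(inserts), nchar(inserts), spec$error_rate)
      for (k in which(n_mut > 0L)) {
        pos <- sample(nchar(inserts[k]), n_mut[k])
        inserts[k] <- mutate_positions(inserts[k], pos)
      }
    }

    # assemble reads: insert + adapter, pad/truncate to read_length
    dna <- as_dna(inserts)
    reads <- paste0(dna, spec$adapter)
    short <- nchar(reads) < spec$read_length
    if (any(short)) {
      padlen <- spec$read_length - nchar(reads[short])
      reads[short] <- paste0(reads[short],
                             random_seqs(sum(short), padlen,
                                         c("A", "C", "G", "T")))
    }
    reads <- substr(reads, 1L, spec$read_length)

    # shuffle read order (pipeline must be order-stable)
    ord <- sample(length(reads))
    reads <- reads[ord]

    path <- file.path(out_dir, paste0(lid, ".fastq"))
    qual <- strrep("I", spec$read_length)
    writeLines(paste0("@", lid, ":", seq_along(reads), "\n", reads,
                      "\n+\n", qual), path)
    files[[lid]] <- path

    cat_tab <- c(table(truth_cat))
    cat_counts[[lid]] <- data.table::data.table(
      lib = lid, category = names(cat_tab),
      count = as.integer(cat_tab))
    mir_counts[[lid]] <- data.table::data.table(
      lib = lid, name = u$name, category = u$category, count = u$count)
    mapped_expect <- spec$depth * (1 - cat_fr[["unannotated"]])
    exp_pmmr[[lid]] <- data.table::data.table(
      lib = lid, name = u$name,
      pmmr = u$prob * spec$depth / mapped_expect * 1e6)
  }

  list(files = files,
       truth = list(category_counts = data.table::rbindlist(cat_counts),
                    mirna_counts = data.table::rbindlist(mir_counts),
                    expected_pmmr = data.table::rbindlist(exp_pmmr)),
       libraries = spec$libraries)
}
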