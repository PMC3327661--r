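test_that("compile_candidates applies annotation-status and detection rules", {
  cat1 <- table1_catalog()
  # add a decoy annotated beyond the avian genomes, and keep one fixture
  # mature out of the detected set
  decoy <- data.table::data.table(
    name = "gga-decoy-miR", sequence = "UGAGGUAGUAGGUUGUAUAGUU",
    hairpin_id = "", arm = "unknown", is_star = FALSE,
    annotated_species = "gga,hsa")
  mature <- rbind(cat1$mature[, names(decoy), with = FALSE], decoy)
  tier <- mir_catalog(mature, cat1$hairpin)
  rs <- reference_set(list(chicken = tier))

  all6 <- cat1$mature$name
  got <- compile_candidates(rs, detected = c(all6, "gga-decoy-miR"))
  expect_setequal(got$name, all6)
  expect_equal(length(unique(got$hairpin_id)), 5L)
  # mature also annotated in human: excluded
  expect_false("gga-decoy-miR" %in% got$name)
  # avian-only mature not detected: excluded
  got2 <- compile_candidates(rs, detected = setdiff(all6, "gga-miR-1451"))
  expect_setequal(got2$name, setdiff(all6, "gga-miR-1451"))
})

test_that("search_presence scores planted and mutated hairpins", {
  set.seed(71)
  hp <- paste(sample(c("A", "C", "G", "T"), 70, replace = TRUE),
              collapse = "")
  genome <- c(ctg = paste0(random_dna(1, 500), hp, random_dna(1, 500)))
  res <- search_presence(hp, genome)
  expect_true(res$present)
  expect_equal(res$best_identity, 1)
  expect_equal(res$best_coverage, 1)
  # no homolog in a random genome
  res2 <- search_presence(hp, c(ctg = random_dna(1, 2000)))
  expect_false(res2$present)
  # planted copy with 15% substitutions fails identity_min = 0.9
  ch <- strsplit(hp, "")[[1]]
  pos <- sample(70, 11)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  mut <- paste(ch, collapse = "")
  genome_mut <- c(ctg = paste0(random_dna(1, 300), mut, random_dna(1, 300)))
  res3 <- search_presence(hp, genome_mut)
  expect_false(res3$present)
  expect_lt(res3$best_identity, 0.9)
  expect_error(search_presence(hp, character()), "empty genome")
})

test_that("lineage_verdicts requires pan-avian presence and non-avian absence", {
  set.seed(72)
  hps <- data.table::data.table(
    id = c("hp_avian", "hp_everywhere", "hp_chicken_only"),
    sequence = random_dna(3, 70))
  embed <- function(...) {
    c(ctg = paste0(random_dna(1, 200),
                   paste(unlist(list(...)), random_dna(length(list(...)), 150),
                         sep = "", collapse = ""),
                   random_dna(1, 200)))
  }
  panel <- list(
    gga = embed(hps$sequence[1], hps$sequence[2], hps$sequence[3]),
    tgu = embed(hps$sequence[1], hps$sequence[2]),
    hsa = embed(hps$sequence[2]),
    dre = embed(hps$sequence[2]))
  out <- lineage_verdicts(hps, panel, avian_set = c("gga", "tgu"),
                          nonavian_set = c("hsa", "dre"))
  v <- setNames(out$verdicts$avian_specific, out$verdicts$hairpin_id)
  expect_true(v[["hp_avian"]])
  expect_false(v[["hp_everywhere"]])
  expect_false(v[["hp_chicken_only"]])
  expect_error(lineage_verdicts(hps, panel, avian_set = "gga",
                                nonavian_set = c("hsa", "dre")),
               "neither")
})

test_that("presence calls are strand-symmetric and threshold-monotone", {
  set.seed(73)
  hp <- random_dna(1, 70)
  genome <- c(ctg = paste0(random_dna(1, 300), hp, random_dna(1, 300)))
  fwd <- search_presence(hp, genome)
  rev <- search_presence(hp, c(ctg = revcomp_dna(genome[["ctg"]])))
  expect_equal(fwd$present, rev$present)
  expect_equal(fwd$best_identity, rev$best_identity)
  expect_equal(fwd$best_coverage, rev$best_coverage)
  # monotonicity: raising thresholds never flips absent -> present
  ch <- strsplit(hp, "")[[1]]
  for (p in sample(70, 6)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  genome2 <- c(ctg = paste0(random_dna(1, 300), paste(ch, collapse = ""),
                            random_dna(1, 300)))
  grid <- expand.grid(id = c(0.85, 0.9, 0.95, 0.999),
                      cov = c(0.7, 0.8, 0.9, 0.999))
  calls <- mapply(function(i, c_) {
    search_presence(hp, genome2, identity_min = i, coverage_min = c_)$present
  }, grid$id, grid$cov)
  for (a in seq_len(nrow(grid))) {
    for (b in seq_len(nrow(grid))) {
      if (grid$id[b] >= grid$id[a] && grid$cov[b] >= grid$cov[a]) {
        expect_true(!calls[b] || calls[a])
      }
    }
  }
})
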