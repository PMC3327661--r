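test_that("match_exact finds published sequences, in either alphabet", {
  cat1 <- table1_catalog()
  expect_equal(match_exact("CAUCCCCAUUCCACUCCUAGCA", cat1), "gga-miR-2954")
  expect_equal(match_exact("CATCCCCATTCCACTCCTAGCA", cat1), "gga-miR-2954")
  mut <- "CAUCCCCAUUCCACUCCUAGCU"
  expect_length(match_exact(mut, cat1), 0L)
})

test_that("infer_star recovers the opposite arm and nothing else", {
  home <- tiny_home_catalog()
  hp <- home$hairpin$sequence[1]
  star_slice <- substr(hp, 38, 59)          # the planted 3' arm
  hit <- infer_star(star_slice, home)
  expect_equal(hit$star_name, "gga-test-miR-1-ukstar")
  expect_equal(hit$hairpin_id, "hp-test-1")
  # a shorter slice inside the opposite arm still hits
  expect_equal(infer_star(substr(hp, 40, 59), home)$star_name,
               "gga-test-miR-1-ukstar")
  # loop-spanning sequence (crosses the hairpin midpoint): no hit
  expect_null(infer_star(substr(hp, 20, 40), home))
  # the annotated mature itself is not a star hit
  expect_null(infer_star(substr(hp, 1, 22), home))
})

test_that("match_seed_preserving obeys the seed and mismatch budget", {
  home <- tiny_home_catalog()
  base <- "UUCGAUGCUUGUAUGCUACUCC"
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "U"), ch[p])[1]
    paste(ch, collapse = "")
  }
  hit <- match_seed_preserving(mutate_at(base, 15), home)
  expect_equal(hit$name, "gga-miR-1559")
  expect_equal(hit$mismatch_positions[[1]], 15L)
  # mismatch inside the seed (position 3) disqualifies
  expect_equal(nrow(match_seed_preserving(mutate_at(base, 3), home)), 0L)
  # three mismatches outside the seed exceed the budget
  expect_equal(nrow(match_seed_preserving(mutate_at(base, c(12, 15, 18)),
                                          home)), 0L)
  # two mismatches outside the seed are reported ascending
  hit2 <- match_seed_preserving(mutate_at(base, c(18, 11)), home)
  expect_equal(hit2$mismatch_positions[[1]], c(11L, 18L))

  # exhaustive-scan oracle over random mutated queries
  set.seed(21)
  for (rep in 1:40) {
    npos <- sample(1:3, 1)
    pos <- sample(nchar(base), npos)
    q <- mutate_at(base, pos)
    got <- match_seed_preserving(q, home)
    # oracle: per-mature naive comparison
    oracle <- list()
    for (i in seq_len(nrow(home$mature))) {
      r <- home$mature$sequence[i]
      if (nchar(r) != nchar(q)) next
      mm <- which(strsplit(q, "")[[1]] != strsplit(r, "")[[1]])
      if (length(mm) >= 1 && length(mm) <= 2 && !any(mm %in% 2:8)) {
        oracle[[home$mature$name[i]]] <- mm
      }
    }
    expect_equal(got$name,
                 if (length(oracle)) sort(names(oracle)) else character())
  }
})

test_that("map_genome reports exact full-length hits on both strands", {
  genome <- c(ctg = paste0(strrep("ACTG", 25),
                           "TGCAACGGGATCCATGGAACAC",
                           strrep("GTCA", 25)))
  hits <- map_genome("UGCAACGGGAUCCAUGGAACAC", genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 100L)
  expect_equal(hits$end, 122L)
  expect_equal(hits$strand, "+")
  # reverse complement planted: minus-strand location
  rc_hits <- map_genome(revcomp_dna("TGCAACGGGATCCATGGAACAC"), genome)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 100L)
  expect_equal(nrow(map_genome(strrep("AU", 11), genome)), 0L)
})

test_that("classify_contaminant follows the fixed precedence", {
  sets <- list(rrna = c(r = "AACCGGUUAACCGGUUAACCGGUUAACCGGUU"),
               "repeat" = c(p = "UAGGGUUAGGGUUAGGGUUAGGGUUAGGG"),
               mrna = c(m = "UAGGGUUAGGGUUAGGGUUAGGGUUAGGGAAAA"))
  expect_equal(classify_contaminant("CCGGUUAACCGGUUAACCGG", sets),
               "trna_rrna_snrna")
  # present in both repeat and mrna references: repeat wins
  expect_equal(classify_contaminant("UAGGGUUAGGGUUAGGGUUAGGG", sets),
               "repeat")
  expect_null(classify_contaminant(strrep("CA", 11), sets))
})

test_that("cascade assigns every read one category with correct priority", {
  rs <- tiny_rs()
  # a read matching both the home tier and (hypothetically) later tiers
  known <- rs$tiers$chicken$mature$sequence[2]
  lib <- as_library(c(known, rs$tiers$human$mature$sequence[1],
                      "UGCAACGGGAUCCAUGGAACAC", strrep("GA", 11)),
                    counts = c(5L, 3L, 2L, 1L))
  ann <- annotate_library(lib, rs)
  expect_equal(ann$records$category,
               c("known_mirna", "ortholog_exact", "genome_only",
                 "unannotated"))
  expect_equal(ann$summary$fractions[["known_mirna"]], 5 / 11)
  expect_equal(sum(ann$summary$fractions), 1, tolerance = 1e-12)
  expect_equal(ann$summary$mapped_reads, 10L)
  # annotating twice is idempotent
  ann2 <- annotate_library(lib, rs)
  expect_identical(ann$records, ann2$records)
  # empty library errors
  expect_error(annotate_library(as_library(character()), rs), "empty")
})

test_that("cascade equals the brute-force per-read comparator", {
  set.seed(31)
  sp <- sim_spec(depth = 4000L)
  ref <- make_reference_set(sp, seed = 5L)
  n_mat <- sum(vapply(ref$rs$tiers, function(t) nrow(t$mature), integer(1)))
  expect_lte(n_mat, 70L)
  dir <- withr::local_tempdir()
  sim <- simulate_libraries(sp, ref, dir, seed = 5L)
  lib <- preprocess_library(sim$files[[1]], "x", "gga", "HH20", sp$adapter)
  # spot-check; the full 500-insert comparison runs in the acceptance suite
  lib$reads <- head(lib$reads, 150L)
  ann <- annotate_library(lib, ref$rs)
  for (i in seq_len(nrow(ann$records))) {
    want <- naive_cascade_one(ann$records$insert[i], ref$rs)
    expect_identical(ann$records$category[i], want$category)
    if (!is.na(want$name)) {
      expect_identical(ann$records$assigned_name[i], want$name)
    }
  }
})

test_that("ortholog_mismatch never fires for reads with an exact hit", {
  sp <- sim_spec(depth = 4000L)
  ref <- make_reference_set(sp, seed = 6L)
  dir <- withr::local_tempdir()
  sim <- simulate_libraries(sp, ref, dir, seed = 6L)
  lib <- preprocess_library(sim$files[[1]], "x", "gga", "HH20", sp$adapter)
  ann <- annotate_library(lib, ref$rs)
  mm <- ann$records[category == "ortholog_mismatch"]
  for (tn in names(ref$rs$tiers)) {
    expect_false(any(mm$insert %in% ref$rs$tiers[[tn]]$mature$sequence))
  }
})
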