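test_that("packaged avian-candidate catalog loads with published sequences", {
  cat1 <- table1_catalog()
  expect_equal(nrow(cat1$mature), 6L)
  expect_equal(length(unique(cat1$mature$hairpin_id)), 5L)
  m2954 <- cat1$mature[name == "gga-miR-2954"]
  expect_equal(m2954$sequence, "CAUCCCCAUUCCACUCCUAGCA")
  expect_equal(nchar(m2954$sequence), 22L)
  # every mature slices its hairpin at the recorded interval
  hp <- setNames(cat1$hairpin$sequence, cat1$hairpin$id)
  for (i in seq_len(nrow(cat1$mature))) {
    m <- cat1$mature[i]
    expect_identical(substr(hp[[m$hairpin_id]], m$arm_start + 1L, m$arm_end),
                     m$sequence)
  }
})

test_that("load_catalog normalizes DNA input and rejects bad catalogs", {
  dir <- withr::local_tempdir()
  writeLines(c(">mir-a", "CATCCCCATTCCACTCCTAGCA"), file.path(dir, "m.fa"))
  writeLines(c("name\thairpin_id\tarm\tis_star\tannotated_species",
               "mir-a\t\tunknown\tFALSE\tgga"),
             file.path(dir, "side.tsv"))
  cat1 <- load_catalog(file.path(dir, "m.fa"), NULL, file.path(dir, "side.tsv"))
  expect_equal(cat1$mature$sequence, "CAUCCCCAUUCCACUCCUAGCA")

  # duplicate names are fatal and name the duplicate
  writeLines(c(">mir-a", "CAUCCCCAUUCCACUCCUAGCA", ">mir-a",
               "UGAGGUAGUAGGUUGUAUAGUU"), file.path(dir, "dup.fa"))
  expect_error(load_catalog(file.path(dir, "dup.fa"), NULL,
                            file.path(dir, "side.tsv")), "mir-a")

  # a mature that is not a slice of its hairpin is fatal
  expect_error(mir_catalog(
    data.frame(name = "m1", sequence = "UGAGGUAGUAGGUUGUAUAGUU",
               hairpin_id = "h1", arm = "five_prime", is_star = FALSE,
               annotated_species = "gga"),
    data.frame(id = "h1", species = "gga",
               sequence = strrep("ACGU", 15))), "not a slice")
})

test_that("validate_reference_set reports violations without throwing", {
  rs <- tiny_rs()
  expect_length(validate_reference_set(rs), 0L)

  # same mature name in two tiers
  rs_bad <- rs
  dup <- data.table::copy(rs$tiers$chicken$mature[1])
  dup[, `:=`(hairpin_id = "", arm = "unknown",
             arm_start = NA_integer_, arm_end = NA_integer_)]
  rs_bad$tiers$human$mature <- rbind(rs_bad$tiers$human$mature, dup,
                                     fill = TRUE)
  rep1 <- validate_reference_set(rs_bad)
  expect_true(any(grepl("present in tiers", rep1)))

  # arm interval beyond the hairpin end
  rs_bad2 <- tiny_rs()
  rs_bad2$tiers$chicken$mature[1, arm_end := 10000L]
  rep2 <- validate_reference_set(rs_bad2)
  expect_true(any(grepl("outside hairpin", rep2)))
})

test_that("reference set round-trips through disk byte-identically", {
  rs <- tiny_rs()
  dir <- withr::local_tempdir()
  write_reference_set(rs, dir)
  rs2 <- read_reference_set(dir)
  expect_identical(names(rs2$tiers), names(rs$tiers))
  for (tn in names(rs$tiers)) {
    expect_equal(rs2$tiers[[tn]]$mature$sequence, rs$tiers[[tn]]$mature$sequence)
    expect_equal(rs2$tiers[[tn]]$mature$name, rs$tiers[[tn]]$mature$name)
    expect_equal(rs2$tiers[[tn]]$mature$annotated_species,
                 rs$tiers[[tn]]$mature$annotated_species)
    expect_equal(rs2$tiers[[tn]]$hairpin$sequence, rs$tiers[[tn]]$hairpin$sequence)
  }
  expect_equal(lapply(rs2$contaminants, unname),
               lapply(rs$contaminants, unname))
  expect_equal(lapply(rs2$genome_panel, unname),
               lapply(rs$genome_panel, unname))
})

test_that("U/T normalization is idempotent on random sequences", {
  set.seed(11)
  x <- random_dna(50, 25)
  expect_identical(as_rna(as_rna(x)), as_rna(x))
  expect_identical(as_dna(as_dna(as_rna(x))), as_dna(x))
  expect_identical(revcomp_dna(revcomp_dna(x)), x)
})
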