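test_that("seed_of slices positions 2-8 of published matures", {
  expect_equal(seed_of("AUGCAGAAGUGCACGGAAACAGC"), "UGCAGAA")  # miR-2131
  expect_equal(seed_of("CAUCCCCAUUCCACUCCUAGCA"), "AUCCCCA")   # miR-2954
  expect_error(seed_of("UGCAGAA"), "shorter than 8")
})

test_that("find_sites locates seed complements and classifies site types", {
  # seed UGCAGAA -> DNA TGCAGAA -> site (revcomp) TTCTGCA
  hits <- find_sites("UGCAGAA", "GGTTCTGCAAGG")
  expect_equal(hits$start, 2L)
  expect_equal(hits$site_type, "eightmer")
  hits2 <- find_sites("UGCAGAA", "GGTTCTGCAGGG")
  expect_equal(hits2$site_type, "sevenmer_m8")
  expect_equal(nrow(find_sites("UGCAGAA", strrep("AC", 20))), 0L)
  # overlapping sites are all reported
  hits3 <- find_sites("UUUUUUU", strrep("A", 10))
  expect_equal(hits3$start, 0:3)
})

test_that("find_sites equals a brute-force sliding-window oracle", {
  set.seed(81)
  for (i in 1:200) {
    seed <- random_rna(1, 7)
    utr <- random_dna(1, sample(30:120, 1))
    got <- find_sites(seed, utr)
    site <- revcomp_dna(as_dna(seed))
    starts0 <- integer()
    types <- character()
    for (off in 0:(nchar(utr) - 7)) {
      if (substr(utr, off + 1, off + 7) == site) {
        starts0 <- c(starts0, off)
        types <- c(types, if (substr(utr, off + 8, off + 8) == "A")
          "eightmer" else "sevenmer_m8")
      }
    }
    expect_equal(got$start, starts0)
    expect_equal(got$site_type, types)
  }
})

test_that("every eightmer is a valid sevenmer_m8 at the same offset", {
  set.seed(82)
  site_of <- function(seed) revcomp_dna(as_dna(seed))
  for (i in 1:100) {
    seed <- random_rna(1, 7)
    utr <- random_dna(1, 80)
    hits <- find_sites(seed, utr)
    for (j in seq_len(nrow(hits))) {
      expect_equal(substr(utr, hits$start[j] + 1, hits$start[j] + 7),
                   site_of(seed))
    }
  }
})

test_that("predict_targets counts distinct transcripts with planted sites", {
  m <- "AUGCAGAAGUGCACGGAAACAGC"
  site <- paste0(revcomp_dna(as_dna(seed_of(m))), "A")
  set.seed(83)
  utr <- random_dna(5, 60)
  names(utr) <- paste0("TX", 1:5, "|G", 1:5)
  for (i in 1:3) substr(utr[i], 20, 27) <- site
  res <- predict_targets(m, utr)
  expect_equal(res$n_transcripts, 3L)
  expect_setequal(res$target_genes, c("G1", "G2", "G3"))
  expect_error(predict_targets(m, character()), "empty UTR set")
  # seed complement absent everywhere -> zero targets
  res0 <- predict_targets(m, c("TX9|G9" = strrep("AC", 30)))
  expect_equal(res0$n_transcripts, 0L)
})

test_that("enrich_terms matches the combinatorial oracle", {
  ann <- data.frame(term_id = c(rep("whole", 20), rep("hit5", 5)),
                    gene_id = c(paste0("g", 1:20), paste0("g", 1:5)))
  # term covering the whole universe: p = 1
  res <- enrich_terms(paste0("g", 1:5), ann)$results
  expect_equal(res[term_id == "whole"]$p_raw, 1)
  # N=20, K=5, n=5, k=5 -> C(5,5) C(15,0) / C(20,5)
  expect_equal(res[term_id == "hit5"]$p_raw, 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res[term_id == "hit5"]$p_adj,
               min(1, 2 / choose(20, 5)), tolerance = 1e-12)
  # k = 0 -> upper tail is 1
  res0 <- enrich_terms("g20", ann)$results
  expect_equal(res0[term_id == "hit5"]$p_raw, 1)
  # genes outside the universe are dropped and counted
  out <- enrich_terms(c("g1", "nowhere"), ann)
  expect_equal(out$n_dropped, 1L)
  expect_error(enrich_terms("g1", ann[0, ]), "empty annotation universe")
})

test_that("enrichment p is monotone non-increasing in the overlap", {
  p_at <- function(k, K = 8, n = 10, N = 40) {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  ps <- vapply(0:8, p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  # and the same ordering holds through enrich_terms on nested queries
  ann <- data.frame(term_id = rep("t", 8), gene_id = paste0("g", 1:8))
  ann <- rbind(ann, data.frame(term_id = "pad", gene_id = paste0("g", 1:40)))
  p_prev <- 1
  for (k in c(1, 3, 5, 8)) {
    q <- c(paste0("g", 1:k), paste0("g", 30:(39 - k)))   # n fixed at 10
    res <- enrich_terms(q, ann)$results
    p_now <- res[term_id == "t"]$p_raw
    expect_lte(p_now, p_prev + 1e-15)
    p_prev <- p_now
  }
})
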