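test_that("fold_change matches its definition and is antisymmetric", {
  # 30 vs 15 in the vanishing-pseudocount limit: exactly 2-fold
  expect_equal(fold_change(30, 15, pseudocount = 1e-12), 1, tolerance = 1e-9)
  expect_equal(fold_change(7, 7), 0)
  expect_equal(fold_change(0, 10, pseudocount = 0.5), log2(0.5 / 10.5))
  set.seed(61)
  a <- runif(50, 0, 100)
  b <- runif(50, 0, 100)
  expect_equal(fold_change(a, b), -fold_change(b, a))
})

test_that("fisher_exact_2x2 matches brute-force enumeration", {
  expect_equal(fisher_exact_2x2(0, 100, 0, 100), 1)
  # full enumeration oracle at fixed margins
  enum_p <- function(x_a, n_a, x_b, n_b) {
    k <- x_a + x_b
    xs <- max(0, k - n_b):min(k, n_a)
    pr <- choose(n_a, xs) * choose(n_b, k - xs) / choose(n_a + n_b, k)
    obs <- pr[match(x_a, xs)]
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(5, 10, 0, 10), enum_p(5, 10, 0, 10),
               tolerance = 1e-12)
  # symmetry under swapping libraries
  expect_equal(fisher_exact_2x2(5, 10, 0, 10), fisher_exact_2x2(0, 10, 5, 10))
  # random tables against both the oracle and stats::fisher.test
  set.seed(62)
  for (i in 1:50) {
    n_a <- sample(1:60, 1); n_b <- sample(1:60, 1)
    x_a <- sample(0:n_a, 1); x_b <- sample(0:n_b, 1)
    p <- fisher_exact_2x2(x_a, n_a, x_b, n_b)
    expect_equal(p, enum_p(x_a, n_a, x_b, n_b), tolerance = 1e-9)
    ft <- stats::fisher.test(matrix(c(x_a, n_a - x_a, x_b, n_b - x_b), 2,
                                    byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(0, 0, 1, 10), "positive")
})

test_that("bonferroni flags strictly below alpha/m", {
  expect_true(bonferroni(0.04, 0.05)$flags)
  b <- bonferroni(c(0.006, rep(0.5, 9)), 0.05)
  expect_equal(b$threshold, 0.005)
  expect_false(b$flags[1])
  expect_equal(bonferroni(rep(0.5, 2550))$threshold, 0.05 / 2550)
  expect_error(bonferroni(numeric()), "empty")
})

test_that("run_de combines fold change, detection and Fisher correctly", {
  # constructed table: m1 4-fold up, m2 flat, m3 below detection everywhere
  counts <- matrix(c(400L, 100L,
                     200L, 200L,
                     4L,   1L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("m1", "m2", "m3"), c("a", "b")))
  ct <- count_table(counts, c(a = 1000000L, b = 1000000L))
  de <- run_de(ct, data.frame(label = "AB", library_a = "a",
                              library_b = "b"))
  tab <- de$table
  expect_equal(tab[name == "m1"]$de_flag, TRUE)
  expect_equal(tab[name == "m1"]$significant, TRUE)
  expect_equal(tab[name == "m2"]$de_flag, FALSE)
  # m3: ~4-fold but never above 15 PMMR -> not DE
  expect_equal(tab[name == "m3"]$de_flag, FALSE)
  expect_gt(abs(tab[name == "m3"]$log2_fc), 1)
  expect_error(run_de(ct, data.frame(label = "x", library_a = "a",
                                     library_b = "zzz")), "unknown library")
})

test_that("planted fold changes in simulated data are flagged", {
  sp <- sim_spec(depth = 30000L)
  ref <- make_reference_set(sp, seed = 8L)
  dir <- withr::local_tempdir()
  sim <- simulate_libraries(sp, ref, dir, seed = 8L)
  anns <- lapply(seq_len(nrow(sim$libraries)), function(j) {
    m <- sim$libraries[j]
    annotate_library(preprocess_library(sim$files[[m$id]], m$id, m$species,
                                        m$stage, sp$adapter), ref$rs)
  })
  ct <- build_count_table(anns)
  de <- run_de(ct, standard_comparisons(ct$meta))
  pm <- normalize_pmmr(ct)
  ta <- ref$truth$trend_assign
  up3 <- ta[trend == "up_all3_HH25"]$name
  for (nm in up3) {
    for (sp3 in c("gga", "apl", "cja")) {
      row <- de$table[name == nm & label == paste0("ST-", sp3)]
      expect_true(row$de_flag)
      expect_gt(row$log2_fc, 1)
    }
  }
  # trend classification recovers the planted classes
  tr <- classify_trends(de)
  got <- merge(tr, ta, by = "name")
  expect_equal(got$class, got$trend)
})

test_that("classify_trends applies first-match rules on constructed input", {
  # directly constructed count table: 6 libraries, programmed patterns
  libs <- data.table::CJ(species = c("gga", "apl", "cja"),
                         stage = c("HH20", "HH25"), sorted = FALSE)
  libs[, id := paste(species, stage, sep = "-")]
  base <- 200L
  mk <- function(fold_by_lib) as.integer(round(base * fold_by_lib))
  f <- function(sp, st) paste(sp, st, sep = "-")
  ids <- libs$id
  counts <- rbind(
    up_all = mk(ifelse(grepl("HH25", ids), 4, 1)),
    cq_only = mk(ifelse(grepl("HH25", ids) & !grepl("apl", ids), 4, 1)),
    flat = mk(rep(1, 6)))
  colnames(counts) <- ids
  ct <- count_table(counts, setNames(rep(1000000L, 6), ids),
                    meta = libs)
  de <- run_de(ct, standard_comparisons(libs))
  tr <- classify_trends(de)
  expect_equal(tr[name == "up_all"]$class, "up_all3_HH25")
  expect_equal(tr[name == "cq_only"]$class, "up_chicken_quail_only")
  expect_equal(tr[name == "flat"]$class, "other")
  # missing comparisons are an error
  de2 <- run_de(ct, standard_comparisons(libs)[1:3])
  expect_error(classify_trends(de2), "missing comparison")
})
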