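# Pairwise differential expression on sequencing counts.
#
# The screen separates two notions deliberately: "differentially expressed"
# (de_flag) is the fold-change + detection rule (>2-fold on PMMR with a
# pseudocount, and >15 PMMR in at least one of the two libraries), while
# statistical significance is Fisher's exact test on raw counts against the
# mapped-read denominators, Bonferroni-corrected over every miRNA x
# comparison test in the run. Table-style outputs report both.

#' Log2 fold change between two PMMR values
#'
#' `log2((a + pseudocount) / (b + pseudocount))`. Antisymmetric in its
#' arguments by construction.
#'
#' @param pmmr_a,pmmr_b non-negative expression values (a relative to b).
#' @param pseudocount positive stabilizer for zero counts (default 0.5).
#' @return numeric log2 fold change.
#' @export
fold_change <- function(pmmr_a, pmmr_b, pseudocount = 0.5) {
  stopifnot(all(pmmr_a >= 0), all(pmmr_b >= 0), pseudocount > 0)
  log2((pmmr_a + pseudocount) / (pmmr_b + pseudocount))
}

#' Two-sided Fisher's exact test for a 2x2 sequencing-count table
#'
#' Tests the table `(x_a, n_a - x_a; x_b, n_b - x_b)` conditioning on both
#' margins: the two-sided p-value sums the hypergeometric point
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (with a `1e-7` relative slack, the
#' conventional tie rule).
#'
#' @param x_a,x_b miRNA read counts in libraries a and b.
#' @param n_a,n_b mapped-read denominators (totals) of the two libraries.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(x_a, n_a, x_b, n_b) {
  if (n_a <= 0L || n_b <= 0L) stop("library totals must be positive")
  stopifnot(x_a >= 0L, x_b >= 0L, x_a <= n_a, x_b <= n_b)
  k <- x_a + x_b
  support <- max(0L, k - n_b):min(k, n_a)
  probs <- stats::dhyper(support, n_a, n_b, k)
  p_obs <- probs[match(x_a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of raw p-values (the test family).
#' @param alpha family-wise error target in (0, 1).
#' @return list with `threshold` (`alpha / m`) and `flags`
#'   (`p < threshold`, strict).
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- length(p_values)
  if (m == 0L) stop("empty p-value family")
  thr <- alpha / m
  list(threshold = thr, flags = p_values < thr)
}

#' Standard pairwise comparisons for a species x stage design
#'
#' Builds the comparison sheet for libraries spanning species and stages:
#' one stage-within-species comparison per species (later stage relative to
#' earlier, label `ST-<species>`) and one species-at-stage comparison per
#' unordered species pair per stage (label `<AB>-<stage>` where A and B are
#' the upper-cased species initials, e.g. `DC-HH25` for duck relative to
#' chicken).
#'
#' @param meta data.table with columns `id`, `species`, `stage`.
#' @param stage_order character vector giving the stage order (earlier
#'   first); defaults to sorted unique stages.
#' @param species_initials named map from species code to the single
#'   letter used in species-comparison labels.
#' @param all_pairs if `TRUE`, also include the cross
#'   species-by-stage pairs so that every pair of libraries is compared.
#' @return data.table with columns `label`, `library_a`, `library_b`,
#'   `axis`, `species_a`, `species_b`, `stage_a`, `stage_b`.
#' @export
standard_comparisons <- function(meta,
                                 stage_order = NULL,
                                 species_initials = c(gga = "C", apl = "D",
                                                      cja = "Q"),
                                 all_pairs = FALSE) {
  meta <- data.table::as.data.table(meta)
  stages <- stage_order %||% sort(unique(meta$stage))
  species <- unique(meta$species)
  lib_of <- function(sp, st) {
    id <- meta[species == sp & stage == st]$id
    if (length(id) != 1L) stop("expected exactly one library for ", sp,
                               " at ", st)
    id
  }
  rows <- list()
  add <- function(label, a, b, axis, sa, sb, ta, tb) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      label = label, library_a = a, library_b = b, axis = axis,
      species_a = sa, species_b = sb, stage_a = ta, stage_b = tb)
  }
  # stage within species: later relative to earlier
  if (length(stages) >= 2L) {
    for (sp in species) {
      add(paste0("ST-", sp), lib_of(sp, stages[2]), lib_of(sp, stages[1]),
          "stage_within_species", sp, sp, stages[2], stages[1])
    }
  }
  # species at stage: label by initials, duck-relative conventions first
  initial <- function(sp) {
    if (sp %in% names(species_initials)) species_initials[[sp]]
    else toupper(substr(sp, 1, 1))
  }
  pair_label <- function(sa, sb) paste0(initial(sa), initial(sb))
  pref <- c("DC", "DQ", "QC")
  for (st in stages) {
    combs <- utils::combn(sort(species), 2L, simplify = FALSE)
    for (pr in combs) {
      sa <- pr[1]; sb <- pr[2]
      if (!(pair_label(sa, sb) %in% pref) && pair_label(sb, sa) %in% pref) {
        tmp <- sa; sa <- sb; sb <- tmp
      }
      add(paste0(pair_label(sa, sb), "-", st), lib_of(sa, st), lib_of(sb, st),
          "species_at_stage", sa, sb, st, st)
    }
  }
  if (all_pairs) {
    have <- data.table::rbindlist(rows)
    ids <- meta$id
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        done <- nrow(have[(library_a == ids[i] & library_b == ids[j]) |
                          (library_a == ids[j] & library_b == ids[i])]) > 0L
        if (!done) {
          ma <- meta[id == ids[i]]; mb <- meta[id == ids[j]]
          add(paste0(ma$id, "_vs_", mb$id), ma$id, mb$id, "cross",
              ma$species, mb$species, ma$stage, mb$stage)
        }
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Run pairwise differential expression
#'
#' For each miRNA and each comparison: the log2 fold change from PMMR (a
#' relative to b, with pseudocount), the Fisher exact p-value from raw
#' counts against the mapped denominators, Bonferroni significance over the
#' whole run's miRNA x comparison family, the per-comparison detection flag
#' (PMMR strictly above `detect_threshold` in at least one of the two
#' libraries), and the DE flag (detected and fold change strictly above
#' 2-fold in either direction).
#'
#' @param ct a `count_table`.
#' @param comparisons data.table as from [standard_comparisons()] (only
#'   `label`, `library_a`, `library_b` are required).
#' @param alpha family-wise error target for Bonferroni (default 0.05).
#' @param pseudocount PMMR pseudocount for fold changes (default 0.5).
#' @param detect_threshold PMMR detection threshold (default 15).
#' @param min_abs_log2_fc DE fold-change cut on |log2 FC|, strict
#'   (default 1, i.e. >2-fold).
#' @return object of class `de_result`: list with `table` (data.table:
#'   name, label, log2_fc, p_raw, significant, detected, de_flag),
#'   `bonferroni_threshold`, `n_tests`, and `params`.
#' @export
run_de <- function(ct, comparisons, alpha = 0.05, pseudocount = 0.5,
                   detect_threshold = 15, min_abs_log2_fc = 1) {
  comparisons <- data.table::as.data.table(comparisons)
  ids <- colnames(ct$counts)
  bad <- setdiff(unique(c(comparisons$library_a, comparisons$library_b)), ids)
  if (length(bad)) stop("unknown library id(s) in comparisons: ",
                        paste(bad, collapse = ", "))
  if (any(comparisons$library_a == comparisons$library_b)) {
    stop("a comparison pairs a library with itself")
  }
  pmmr <- normalize_pmmr(ct)
  rows <- list()
  for (ci in seq_len(nrow(comparisons))) {
    a <- comparisons$library_a[ci]
    b <- comparisons$library_b[ci]
    na <- ct$denominators[[a]]
    nb <- ct$denominators[[b]]
    p <- vapply(rownames(ct$counts), function(nm) {
      fisher_exact_2x2(ct$counts[nm, a], na, ct$counts[nm, b], nb)
    }, numeric(1))
    lfc <- fold_change(pmmr[, a], pmmr[, b], pseudocount)
    det <- pmmr[, a] > detect_threshold | pmmr[, b] > detect_threshold
    rows[[ci]] <- data.table::data.table(
      name = rownames(ct$counts), label = comparisons$label[ci],
      log2_fc = unname(lfc), p_raw = unname(p), detected = unname(det))
  }
  tab <- data.table::rbindlist(rows)
  bf <- bonferroni(tab$p_raw, alpha)
  tab[, significant := bf$flags]
  tab[, de_flag := detected & abs(log2_fc) > min_abs_log2_fc]
  data.table::setcolorder(tab, c("name", "label", "log2_fc", "p_raw",
                                 "significant", "detected", "de_flag"))
  structure(list(table = tab[], bonferroni_threshold = bf$threshold,
                 n_tests = nrow(tab),
                 params = list(alpha = alpha, pseudocount = pseudocount,
                               detect_threshold = detect_threshold,
                               min_abs_log2_fc = min_abs_log2_fc)),
            class = "de_result")
}

TREND_CLASSES <- c("down_all3_HH25", "up_all3_HH25", "up_chicken_quail_only",
                   "duck_high_HH25_only", "duck_high_both_stages",
                   "duck_low_both_stages", "other")

#' Classify expression trends across species and stages
#'
#' Applies a deterministic first-match rule set over the stage-within-
#' species comparisons (`ST-<species>`, later stage relative to earlier)
#' and the duck-relative species comparisons (`DC-*`, `DQ-*`): miRNAs down-
#' or up-regulated at the later stage in all three species, up only in the
#' two beaked species (chicken and quail), duck-high at the later stage
#' only, duck-high or duck-low at both stages, else `other`.
#'
#' @param de a `de_result` covering the required comparison labels.
#' @param species_codes named list with elements `chicken`, `duck`,
#'   `quail` giving the species codes used in `ST-` labels.
#' @param stages character length-2 vector, earlier stage first.
#' @return data.table with columns `name` and `class`.
#' @export
classify_trends <- function(de,
                            species_codes = list(chicken = "gga",
                                                 duck = "apl",
                                                 quail = "cja"),
                            stages = c("HH20", "HH25")) {
  tab <- de$table
  need <- c(paste0("ST-", unlist(species_codes)),
            paste0("DC-", stages), paste0("DQ-", stages))
  miss <- setdiff(need, unique(tab$label))
  if (length(miss)) stop("missing comparison(s) for trend classification: ",
                         paste(miss, collapse = ", "))
  names_all <- unique(tab$name)
  get <- function(nm, lab) tab[name == nm & label == lab]
  up <- function(r) nrow(r) == 1L && r$de_flag && r$log2_fc > 0
  down <- function(r) nrow(r) == 1L && r$de_flag && r$log2_fc < 0
  cls <- vapply(names_all, function(nm) {
    st_ch <- get(nm, paste0("ST-", species_codes$chicken))
    st_du <- get(nm, paste0("ST-", species_codes$duck))
    st_qu <- get(nm, paste0("ST-", species_codes$quail))
    dc20 <- get(nm, paste0("DC-", stages[1]))
    dc25 <- get(nm, paste0("DC-", stages[2]))
    dq20 <- get(nm, paste0("DQ-", stages[1]))
    dq25 <- get(nm, paste0("DQ-", stages[2]))
    if (down(st_ch) && down(st_du) && down(st_qu)) return(TREND_CLASSES[1])
    if (up(st_ch) && up(st_du) && up(st_qu)) return(TREND_CLASSES[2])
    if (up(st_ch) && up(st_qu) && !up(st_du)) return(TREND_CLASSES[3])
    if (up(dc25) && up(dq25) && !up(dc20) && !up(dq20))
      return(TREND_CLASSES[4])
    if (up(dc20) && up(dq20) && up(dc25) && up(dq25))
      return(TREND_CLASSES[5])
    if (down(dc20) && down(dq20) && down(dc25) && down(dq25))
      return(TREND_CLASSES[6])
    TREND_CLASSES[7]
  }, character(1))
  data.table::data.table(name = names_all, class = unname(cls))
}

#' Write DE results (and optionally trend classes) to TSV + JSON provenance
#'
#' @param de a `de_result`.
#' @param tsv results TSV path (or `NULL`).
#' @param trends optional data.table from [classify_trends()].
#' @param trends_tsv trend TSV path (or `NULL`).
#' @param provenance_json path for the run-parameter JSON (or `NULL`).
#' @return invisibly, `de`.
#' @export
write_de <- function(de, tsv = NULL, trends = NULL, trends_tsv = NULL,
                     provenance_json = NULL) {
  if (!is.null(tsv)) data.table::fwrite(de$table, tsv, sep = "\t")
  if (!is.null(trends) && !is.null(trends_tsv)) {
    data.table::fwrite(trends, trends_tsv, sep = "\t")
  }
  if (!is.null(provenance_json)) {
    writeLines(jsonlite::toJSON(
      c(de$params, list(n_tests = de$n_tests,
                        bonferroni_threshold = de$bonferroni_threshold)),
      auto_unbox = TRUE, digits = NA), provenance_json)
  }
  invisible(de)
}
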