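---
title: "Methods: annotation cascade, PMMR differential expression, and the synthetic stated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation cascade, PMMR differential expression, and the synthetic stated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avimir)
```

# The problem

Comparative small RNA-seq across related species (here: a chicken / duck /
quail design sampled at two embryonic stages, HH20 and HH25) cannot rely on
any single reference: the focal genome is gapped, its miRNA annotation is
incomplete, and orthologs of well-described miRNAs from better-annotated
genomes are routinely expressed but unannotated. `avimir` implements the
resulting analysis pattern as a reusable pipeline: a tiered annotation
cascade, per-million-mapped-reads quantification with an explicit detection
floor, count-based pairwise differential expression, a genome-panel
lineage-specificity screen, and seed-based target prediction — all
exercised end to end on synthetic libraries with planted ground truth.

# Preprocessing

Reads are `insert + 3′ adapter (+ tail)`. The insert ends at the first
position where the remainder of the read matches the adapter exactly — the
full adapter when it fits, otherwise an adapter prefix of at least
`min_overlap = 8` nt running off the read end. Three decisions are
deliberate:

* **Adapterless reads are discarded.** A mature miRNA insert is shorter
  than the read on this class of platform, so a read without a detectable
  adapter cannot be confirmed as a complete insert.
* **Adapter matching is exact.** No error tolerance is stated for the
  original trimming; exact matching keeps the stage deterministic. An
  internal 8-mer that happens to equal the adapter prefix is rejected
  unless its continuation also matches, so chance decoys do not truncate
  inserts.
* **Qualities are parsed, validated, and otherwise ignored** — no quality
  filtering is part of the procedure being modelled.

Size selection retains inserts of 20–40 nt inclusive. Collapsing is
order-stable (descending count, then lexicographic), so permuting the
input FASTQ cannot change any downstream result.

# The annotation cascade

Every collapsed read receives exactly one category by first hit:

| step | rule |
|---|---|
| `known_mirna` | exact equality with a home-tier mature (after U/T normalization) |
| `star_mirna` | exact substring of the hairpin arm *opposite* a single annotated mature arm; named `<mature>-ukstar` |
| `ortholog_exact` | exact equality in a later tier (tiers searched in declared order) |
| `ortholog_mismatch` | equal-length Hamming distance 1–2, **no mismatch in seed positions 2–8** (1-based) |
| `genome_only` | exact full-length occurrence in the home genome, either strand |
| `trna_rrna_snrna` / `repeat` / `degraded_mrna` | exact substring of a contaminant class sequence, fixed precedence |
| `unannotated` | none of the above |

Numerical/structural choices:

* **Tie-break.** Several matures can share one sequence. All tied names
  are retained in an `all_names` column; the lexicographically first is
  assigned. The procedure being modelled reports single assignments but is
  silent on ties.
* **Star regions.** Without annotated star coordinates, the opposite arm
  is operationalized as the hairpin half not containing the annotated
  mature (split at `floor(L/2)`). A read overlapping only the loop crosses
  the midpoint and therefore never matches within a single half.
* **Mismatch model.** Substitutions only, equal lengths. "Base mismatches"
  describes substitutions, and mature orthologs are length-matched; indels
  would require an alignment model the source procedure never states.
* **Mismatch tiers.** Ortholog rescue (exact and mismatch) searches the
  non-home tiers in declared order — human before zebrafinch. The original
  mismatch search was described against human miRNAs only; searching the
  zebrafinch tier afterwards is this package's generalization and cannot
  steal a hit from any earlier step.
* **Contaminant precedence** (`trna_rrna_snrna → repeat → degraded_mrna`)
  is fixed and logged; the classes were reported separately with no rule
  for overlaps.
* **Mapped denominator.** "Mapped" reads are all reads in any category
  except `unannotated`; this count is each library's PMMR denominator and
  is recorded alongside the count table.

The cascade is validated two ways: property tests (partition, idempotence,
`ortholog_mismatch` never fires on a read with an exact hit anywhere), and
a brute-force all-pairs comparator applying the same precedence one read
at a time through the public single-read operations.

# Quantification and detection

PMMR is `count × 10⁶ / mapped-reads`. Detection is **strict**:
PMMR > 15 in at least one library — the threshold below which trends could
not be independently verified in the study design this emulates, and the
comparison is written `>15` throughout, so 15.0 exactly is *not* detected.
Star strands are quantified as their own rows. Scaling counts and
denominator of a library by a common factor leaves its PMMR column
unchanged (tested), and raising the threshold can only shrink the detected
set (tested).

# Differential expression

Two notions are kept deliberately separate:

* **DE flag** — the screening rule: fold change strictly above 2-fold in
  either direction (|log2 FC| > 1 on PMMR with pseudocount 0.5) *and*
  PMMR > 15 in at least one of the two compared libraries.
* **Significance** — Fisher's exact test on the 2×2 table
  `(x_a, n_a − x_a; x_b, n_b − x_b)` of raw counts against mapped totals,
  two-sided by point-probability summation (probabilities ≤ the observed
  table's, with the conventional 1e-7 relative tie slack), Bonferroni
  corrected over **all** miRNA × comparison tests of the run (strict
  `p < α/m`).

The pseudocount (0.5) exists only to make fold changes finite at zero
counts; the source procedure is silent on zeros, and the tests that matter
(4-fold plants) are far from the boundary. Fold changes are antisymmetric
exactly: `log2_fc(a,b) = −log2_fc(b,a)`.

The family size `m` is the run's own test count and is reported in the
provenance block rather than matched to any externally printed threshold,
whose family size was never stated.

Trend classification applies a first-match rule list over the
stage-within-species comparisons (`ST-<species>`, later stage relative to
earlier) and the duck-relative species comparisons (`DC-*`, `DQ-*`):
down/up at the later stage in all three species, up only in the two beaked
species, duck-high at the later stage only, duck-high/duck-low at both
stages, else `other`. First match wins, making the classification total
and deterministic.

# Lineage screen

Candidates are matures whose annotation-status set is non-empty and
contained in the annotated avian genomes (chicken, zebrafinch), restricted
to detected names. Each candidate hairpin is scored against every panel
genome by local alignment in DNA space on both strands (match +1,
mismatch −1, gap open 5, extend 2); `present` requires identity ≥ 0.9 over
the aligned span *and* aligned coverage ≥ 0.8 of the hairpin. These
thresholds are package defaults — the original screen's alignment settings
were not stated — and both are arguments echoed in the output.
`avian_specific` is the conjunction: present in every avian panel member,
absent from every non-avian member. Presence calls are strand-symmetric
and monotone in both thresholds (tested).

# Target prediction and enrichment

The seed is mature positions 2–8 (1-based). A site is the exact DNA
reverse complement of the seed in a 3′UTR: `sevenmer_m8`, refined to
`eightmer` when an `A` follows (opposite mature position 1). 6mer sites
and context scoring are deliberately omitted: the procedure modelled names
only the seed. Genes aggregate over transcripts (`transcript|gene` FASTA
headers); enrichment is the hypergeometric upper tail `P[X ≥ k]` over a
universe of genes with ≥ 1 term annotation, Bonferroni over terms tested,
significant iff adjusted p < 0.05 strictly.

# The synthetic stated world

`sim_spec()` defaults *are* the stated conditions, chosen once:

* **Design**: 3 species × 2 stages, one library each; depth 1e5 reads per
  library for acceptance runs (scaled down from the 3.1–10.9M of the
  emulated study; every statistic involved scales with depth only through
  sampling noise).
* **Category fractions**: the published per-category read percentages
  (56.36% known, 1.02% star, 11.07% exact ortholog, 0.09% mismatch
  ortholog, 1.03% degraded mRNA, 6.71% repeat, 18.57% tRNA/rRNA/snRNA).
  The published residual of 5.16% is split into 3.61% genome-only and
  1.55% unmapped so that 98.45% of reads map, matching the printed mapped
  fraction.
* **Abundances**: within-category weights are log-uniform over two decades
  (10^U[−1,1]) — a realistic skew for miRNA libraries; the packaged
  candidate matures get a fixed high weight, as they were described as
  highly expressed.
* **Planted effects**: programmed log2 offsets of ±2 (4-fold) applied on
  the PMMR scale before multinomial sampling, covering every trend class;
  the realized fold change therefore carries sampling noise plus a small
  within-category renormalization drift (≪ 0.1 log2 units), which the
  acceptance tolerances absorb.
* **Error model**: uniform substitutions on insert bases, default rate 0
  (the acceptance condition). No indels, no quality-dependent profile —
  sufficient to exercise the mismatch-rescue stage, nothing more.
* **Planted features**: unannotated star arms (the 3′ arm of the first 8
  generated hairpins), mismatch orthologs (human matures mutated at two
  fixed positions outside the seed), orthologs absent from the home genome
  (emulating assembly gaps), avian-specific hairpins planted in all avian
  and no non-avian fixture genomes, one control hairpin planted
  everywhere, and one restricted hairpin planted in the home genome only —
  emulating the one candidate whose pan-avian conservation was not
  confirmed.

What a green test does establish: the pipeline recovers planted categories
essentially perfectly at zero error rate, flags every planted 4-fold
change above detection, and calls lineage specificity exactly as planted.
What it does not: performance on real error profiles, real multi-mapping
structure, isomiR heterogeneity, or real genome repeat content — the
generator's contaminants and genomes are random sequences, so
cross-category sequence collisions are (by construction) vanishingly rare,
whereas real data would exercise the precedence rules far harder.

# Degenerate inputs and edge semantics

* Empty libraries cannot be annotated (error, not an empty summary).
* A catalog with duplicate mature names, or a mature that is not an exact
  slice of its hairpin at its recorded interval, fails at load with the
  offending name.
* `validate_reference_set()` never throws; it returns one message per
  violation, and the constructor refuses to build an invalid set.
* Fisher's test requires positive library totals; Bonferroni requires a
  non-empty family; enrichment requires a non-empty universe; zero
  denominators refuse to normalize.
* All internal coordinates are 0-based half-open; only human-readable
  report columns are 1-based (mismatch positions on the mature reference).

# Known limitations

* Exact-substring contaminant and genome matching (no mismatches) —
  mirrors the stated rules, but real degraded fragments with errors would
  fall through to `unannotated`.
* The star-arm search assumes the precursor's two arms sit in opposite
  halves of the hairpin sequence; extremely asymmetric precursors would
  need annotated star coordinates.
* No novel-miRNA discovery (hairpin folding of unexplained reads is out of
  scope by design), no multi-mapping resolution, no FDR procedures beyond
  Bonferroni, no count-model (negative binomial) alternative to the exact
  test.
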