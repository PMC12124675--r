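---
title: "Methods: chromosome-Y disparity analysis for two-ancestry tumor cohorts"
author: "ycap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-Y disparity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ycap)
```

## The problem

The human Y chromosome is haploid, largely non-recombining, structurally
repetitive and hard to sequence, and it is routinely excluded from
genome-wide cancer studies. In a two-ancestry prostate-cancer cohort
(African and European patients, blood and tumor whole genomes), four
chrY questions drive the analysis: which germline copy-number variants
(CNVs) and somatic copy-number alterations (SCNAs) differ between the
ancestries; which germline small variants are potentially deleterious
(PDVs) and how their burden differs; whether tumors show mosaic loss of
the Y chromosome (LOY); and which variants travel with Y-haplogroup
clades rather than with disease.

`ycap` implements the full analysis as a reusable, tested pipeline and
pairs it with a seeded synthetic-cohort generator, so every stage runs —
and is validated — without access to the controlled-access patient data.

## Multi-caller CNV consensus

Single CNV callers are unreliable on chrY: most assume a diploid
baseline, and breakpoints disagree across tools. The consensus merge
therefore works at the granularity of *atoms*:

1. **Atomize.** For one sample and tissue, all callers' gain/loss
   segments are cut at the sorted union of their breakpoints
   (`atomize()`, backed by `IRanges::disjoin`). Each atom records which
   callers support it, per call type; a caller counts once per atom even
   if it emitted duplicate overlapping calls.
2. **Conflict removal.** Any atom carrying both gain and loss support is
   dropped (`resolve_conflicts()`), with *no* majority override — a
   2-vs-1 disagreement is still a disagreement. Conflict removal
   happens *before* the concurrence rule.
3. **Concurrence.** Atoms whose single present type has at least `k`
   supporting callers survive (`apply_concurrence()`): `k = 2` of 3
   callers in germline mode, `k = 2` of 2 (the intersection) in somatic
   mode.
4. **Merge.** Overlapping or bookended same-type atoms merge into
   maximal events (`merge_adjacent()`, `IRanges::reduce` semantics,
   `max_gap = 0` by default). A merged event's support is the minimum
   over its constituents (conservative; the maximum is available via
   `support = "max"`).

Conflict granularity is a genuine design choice: "conflicting calls are
filtered out" could be read per call or per base. We resolve conflicts
at atom level because it is the only reading consistent with also
keeping partial two-tool overlaps, and it is exactly what a
multi-intersect-then-filter computation produces. A whole-call reading
is noted as the alternative but not implemented as the default.

The pipeline is validated against an independent per-base oracle: on
random instances (10 kb genome, 3 callers, up to 50 calls each), a
brute-force per-base vote with the same rules must produce the identical
covered-base set and types as the interval pipeline. The suite also
checks conservation (every output base has ≥ k same-type and 0
opposite-type callers), idempotence at `k = 1`, and monotonicity in `k`.

## Gene-level annotation and ancestral events

Consensus events are projected onto gene models (`annotate_events()`)
under an any-overlap rule (≥ 1 bp, configurable): a sample is a carrier
of a gene × type column if any of its events of that type touches the
gene. Carrier percentages always use the full stratum size as
denominator, which is what makes printed figures such as 88/106 = 83.0%
reproducible as pure arithmetic.

Events fixed in a haplogroup clade reflect lineage history, not
individual variation. The original analysis excluded such events by
inspection; `flag_ancestral()` automates the judgment with a declared
proxy rule: a column is ancestral if within any clade of ≥ 5 samples
(haplogroup label, or its major-letter prefix) the carrier fraction
reaches 0.8. Both parameters are exposed; the rule is monotone in the
threshold by construction. Flagged columns stay in the matrix and are
only excluded from individual-event summaries.

Burden tables (`summarize_burden()`) report carrier-only means, sample
SD (n − 1; the convention of cohort reports), and ranges, with
single-carrier strata yielding an undefined SD rather than zero.

## The PDV cascade

Starting from a predictor-annotated variant table (ANNOVAR-style
columns), the cascade is:

1. keep nonsynonymous consequences (default whitelist: missense,
   stopgain, stoploss, nonstop);
2. keep rows called `damaging`/`possibly_damaging` by **at least one**
   of SIFT, SIFT4G, PolyPhen2 HDIV, PolyPhen2 HVAR;
3. remove rows InterVar classes Benign **and** Likely benign (the
   conservative clinical reading of "benign"; a benign-only mode is a
   switch);
4. classify rarity against a reference AF table: `unknown` if absent,
   else `rare` below max-AF 0.01, `common` at ≥ 0.05, `intermediate`
   between. The numeric rare cutoff is not stated by the source
   analysis; 0.01 is the package's default and is config-exposed.

Missing values are handled asymmetrically and deliberately: a missing
predictor verdict never counts as damaging (stage 2), and a missing
InterVar class never removes a row (stage 3). The first two stages are
row-local, so their order cannot change the result — a property the
suite asserts — and an audit trail guarantees
|input| = |output| + Σ removed.

The prevalence report counts carriers of rare-or-unknown PDVs per
ancestry and reports prevalence fold ratios to one decimal, the
convention behind "x-fold more likely" statements.

## Y ploidy and LOY

Ploidy is estimated as

$$\hat{p} \;=\; \frac{\overline{d}_{\mathrm{xdeg}}}{\tfrac12\, \overline{d}_{\mathrm{auto}}}$$

where \(\overline{d}_{\mathrm{xdeg}}\) is the **base-weighted** mean
depth over the union of the X-degenerate regions (single-copy,
depth-stable chrY segments) and \(\overline{d}_{\mathrm{auto}}\) the
sample's autosomal mean depth. Zero-depth bases are included; weighting
is per base, not per region ("mean coverage across the regions" read as
a per-base mean). The estimate is scale-invariant by construction and
exact (to < 1e-9) on noise-free depth.

LOY is screened on the tumor − blood ploidy delta: a sample is flagged
iff its delta lies strictly below the cohort mean minus 4 sample SDs.
Three choices are explicit: the rule is one-sided (only loss flags,
following the wording "ploidy loss"); it is single-pass (the outlier is
not excluded and the moments are not recomputed — whether the original
mean/SD included the outlier is unstated, so the simpler reading is
implemented); and it is strict, so a zero-SD cohort flags nothing. At
least 3 deltas are required, as the SD is unstable below that.

Ploidy-vs-age uses ordinary least squares (`stats::lm`) with a two-sided
t-test on the slope (n − 2 df); a constant-ploidy input returns the flat
fit (slope 0, R² = 0) rather than an undefined one.

## Association statistics

`fisher_exact_2x2()` is authored from the hypergeometric distribution:
the two-sided p-value sums, in log space, the point probabilities of all
tables with the observed margins that are no more probable than the
observed table (point-probability / minimum-likelihood convention). This
convention — not the tail-doubling one — is what reproduces the study's
printed p-values (0.2792 and 0.143). `fisher_exact_rxc()` extends this
by full enumeration over fixed margins, falling back past an enumeration
bound to a seeded Monte-Carlo estimate over `stats::r2dtable` draws
(reported with its standard error, and using the (1 + hits)/(B + 1)
estimator).

`wilcoxon_rank_sum()` computes the exact null distribution of the
Mann-Whitney U statistic by q-binomial polynomial convolution (exact
integer coefficients via multiply/synthetic-divide), used whenever both
samples have ≤ 50 observations and there are no ties; otherwise it
switches to the normal approximation with tie correction and continuity
correction. Two-sided p-values double the smaller tail and cap at 1 —
the same switching rule and conventions as the statistical environment
the original analysis used, which is what makes printed p-values
comparable. `stats::fisher.test` and `stats::wilcox.test` appear in the
test suite only as independent cross-checks, never as the
implementation.

`clade_marker_concordance()` replaces a phylogenetically corrected
association (treeWAS) with a declared, simpler screen: for each
haplogroup clade, variants carried by all members and no non-members
(perfect concordance), plus near-concordant variants up to a mismatch
budget. Cohort-fixed variants are flagged as concordant with the root
only. The screen's output is never labelled as a treeWAS result.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults encode the emulated study conditions:

* **Cohort**: 106 African and 57 European patients; high-risk (ISUP
  grade ≥ 3) fractions 88/106 and 50/57; ages ~N(66.9, 8.1) and
  N(61.7, 8.1); log-normal PSA with a much heavier African tail.
* **Haplogroups**: within-population compositions with E at 81.1%
  of Africans (80/106 E-V38), plus A (7) and B (13), and R at 58% of
  Europeans with a small European E-M215 clade. Counts are realized by
  largest-remainder apportionment, so the composition is exact.
* **SNV counts**: negative binomial per population with means 1010
  (African) and 332 (European). The spread contrast (narrow African,
  wide European) is emulated by the dispersion parameters: the African
  size parameter is effectively the Poisson limit, the European size is
  0.6. The observed African spread (IQR ≈ 15 at mean 1010) is
  *sub*-Poisson, which no count model with variance ≥ mean can reach;
  the contrast is therefore reproduced qualitatively (narrow ≪ wide),
  not at the exact IQR values.
* **Truth CNVs**: a catalog of germline events linked to haplogroup
  clades (a TTTY22-spanning loss fixed in clades A and E-V38, an
  adjacent lncRNA loss at slightly lower clade fractions, an RBMY-region
  gain/loss pair in clade A, one European-private multi-gene gain) and
  somatic events with risk- and ancestry-enriched carrier fractions.
  Carrier rules at fraction 1 are realized exactly.
* **Caller errors**: per caller, independent false negatives (default
  FNR 0.1), breakpoint jitter (rounded Gaussian, SD 200 bp, clamped to
  keep end > start), and spurious calls (Poisson per Mb, exponential
  lengths with mean 5 kb — the length law is unstated anywhere, so any
  heavy-tailed choice works and it is config-exposed).
* **Depth**: binned negative-binomial depth whose single-copy mean is
  `autosomal_mean × 0.5 × true_ploidy`; one African tumor (fraction
  1/106 of the African cohort) is implanted with true tumor ploidy 0.36,
  the partial-LOY outlier. Blood ploidy is 1.0, so the implanted delta
  is −0.64.
* **Variant table**: 19 annotated variants of which 13 are
  nonsynonymous and 8 survive the cascade; 5 of the 13 are absent from
  the reference AF table (3 on African, 2 on European carriers);
  clade-marker variants are fixed in clades A and B, and one USP9Y
  variant is fixed in all Africans while also present in the European
  E-M215 clade (making it clade-breaking for the concordance screen);
  rare PDVs are carried by five European high-risk and two African
  patients.

The chrY model is an abstract 25 Mb sequence with packaged toy gene,
callability-mask and X-degenerate BED files (labelled `synthetic_` under
`extdata`); real GRCh38 coordinates are accepted by every function but
never required.

What the generator does **not** model: sequence-level reads, coalescent
Y genealogy (the count model replaces lineage history), CNV-induced
depth changes in the X-degenerate regions, caller-specific error
signatures beyond the three-parameter model, and the correlation
structure of real predictor scores. Passing tests therefore demonstrate
the pipeline's correctness and its behavior under the modelled error
structure — not performance on real sequencing artifacts.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open everywhere in memory; VCF positions
  are converted on ingest (half-open membership is what makes the mask
  filter's boundary cases unambiguous).
* Integer copy numbers map to calls relative to a per-caller baseline
  (haploid baseline 1 by default; baseline 2 for diploid-style
  callers).
* A diploid genotype on the haploid Y takes the first allele with a
  warning — tolerant ingest, never a hard failure.
* Fisher point-probability comparisons use a relative tolerance of
  1e-7, matching the convention of reference implementations, and log
  space throughout for large counts.
* Degenerate 2×2 margins (an empty row or column) give p = 1; negative
  or non-integer counts are errors.
* The LOY rule errors below 3 deltas; zero-SD cohorts flag nothing.
* Empty gene sets annotate to an empty matrix with a warning; empty
  masks filter everything.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own trade-off between statistical resolution
and run time: oracle equivalence uses 500 random consensus instances on
a 10 kb genome and exhaustive Fisher/rank-sum enumeration to N = 12 and
n = 8; event recovery uses 500 replicates of a clade-A-like carrier's
four germline events (all ≥ 5 kb) under the default error model; LOY
flagging is checked across 100 seeded cohorts (25 in the faster
acceptance script) at 10 kb depth bins, where the background delta SD
is ≈ 0.01 — comfortably within the ≤ 0.05 regime the flag-rate claim
assumes; noise-free ploidy recovery uses 1 kb bins. The default
unit-test configurations shrink the cohort (8 + 4 samples, 100 kb bins)
without changing any generative parameter.

## Known limitations

* The consensus's call-level ("any-overlap between whole calls")
  alternative reading is not implemented; only atom-level.
* The ancestral-event rule is a proxy for a manual judgment; with small
  clades (< 5) it never fires, so lineage-fixed events in tiny clades
  pass through as individual events.
* The r × c exact test enumerates naively (with an abort bound) rather
  than via the network algorithm, so large-margin tables fall back to
  Monte Carlo.
* Mask-first variant ingest is a declared ordering decision; whether
  masking preceded annotation in the original analysis is unstated.
* The haplogroup × risk association is procedure-reproduced only; its
  original input table is not publicly available.
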