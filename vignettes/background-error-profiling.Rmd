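---
title: "Background error profiling for cfDNA targeted deep sequencing: methods and design"
author: "errprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background error profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(errprofiler)
```

## What is being measured, and why

Liquid-biopsy variant calling must separate somatic mutations present at
allele fractions of 0.1% or lower from the background of non-reference
bases that every deep-sequencing experiment contains. That background has
several origins with very different statistical signatures:

* **sequencer miscalls** — private to a single read, largely removable by
  quality filtering and by collapsing PCR duplicates that share a unique
  molecular identifier (UMI) to a consensus;
* **late-PCR errors** — present in a subset of a UMI family, also
  suppressed by consensus;
* **first-cycle PCR errors and template lesions** — carried by the
  molecule itself, hence inherited by *every* read of its UMI family and
  invisible to consensus. Cytosine deamination (C→U, read as T) produces
  C:G>T:A errors; 8-oxo-guanine from oxidative stress during acoustic
  shearing produces C:G>A:T errors concentrated within a few bases of the
  fragment breakpoint;
* **germline variation** — not an error at all, and removed by comparing
  each plasma sample against its donor-matched cellular gDNA.

The package quantifies this background per sample as rates over the 12
directional substitution classes, compares plasma cfDNA against matched
gDNA groups, localizes differences per genomic position and per position
relative to the DNA breakpoint, and provides a generator that plants each
error category with known truth so every analysis can be validated.

## The error model and its estimator

A base call enters the analysis only if it is A/C/G/T in both the read
and the reference, carries Phred quality ≥ `min_base_quality`, and lies at
a panel position whose post-filter depth reaches `min_depth` in the sample
*and* in every sample it is being compared with (joint eligibility; this
mirrors excluding positions where any sample fails the depth rule).
Alternate alleles whose allele fraction exceeds
`germline_af_threshold` in either member of a cfDNA/gDNA pair are treated
as germline variation and masked *in both members*; masking removes the
specific allele, not the site, so independent error classes at polymorphic
positions still count. Allele fractions for this rule are computed on the
same quality-filtered depths, before any masking — the only
self-consistent ordering.

The class rate is opportunity-normalized:
`rate[r>a] = errors[r>a] / eligible bases with reference r`. Whether the
original analyses normalized per reference-base opportunity or per total
sequenced base is not decidable from the source; opportunity normalization
is the default here because it makes classes comparable across panels of
different composition, and `denominator = "total"` switches to the
alternative for reporting. The masked allele depths stay in the
denominator (they are sequenced bases; only their error attribution is
void), which preserves the conservation identity tested in the suite:
errors + reference bases + masked bases = all retained bases.

Degenerate inputs are reported as missing rather than propagated as NaN:
a reference base with no eligible positions leaves its three classes `NA`,
an empty eligible set leaves the whole profile `NA`, and a zero raw rate
makes the corresponding DES reduction `NA`.

## Filter thresholds

| parameter | default | unit | why |
|---|---|---|---|
| `min_base_quality` | 30 | Phred | 1-in-1000 miscall ceiling; the conventional floor for error work |
| `min_depth` | 500 | × | below this, a single alt read exceeds 0.2% and rate estimates are dominated by shot noise |
| `germline_af_threshold` | 0.01 | fraction | heterozygous variants sit near 0.5, background near 1e-4; 1% separates them with orders of magnitude to spare |
| `variant_blacklist` | none | — | user-supplied (VCF/TSV) somatic or cohort-specific exclusions, applied like rule 4 |

## UMI consensus (digital error suppression)

Families are keyed by (UMI, chromosome, fragment start, fragment end,
strand of read 1). Including the strand keeps the two strands of one
original duplex molecule separate — the 4-bp index-read UMI scheme modeled
here is single-strand, not duplex. UMI sequencing errors are *not*
corrected by default (`umi_merge_hamming = 0`): at 4 bp, Hamming-1 merging
collides distinct UMIs easily; the merge is available behind a flag.

Within a family and position, every member base call votes (mates vote
independently where they overlap; a 1–1 mate disagreement in a
single-pair family is a tie). The consensus base must hold a strict
majority; ties and sub-majority pluralities drop the position from the
family, and singleton families pass through unchanged. This is the
simplest rule consistent with the modest reductions such data shows at a
mean family size of 2.79 — with most families of size 1 or 2, suppression
can only act where redundancy exists, and observed reductions around
20–30% of the total rate are expected rather than surprising. The
consensus quality is the maximum supporting member quality, and
`agreement_fraction` records the vote share.

## Breakpoint-distance analysis

`dist_from_breakpoint` is the base's 1-based offset from its read's 5′
end in original sequencing orientation (reversed for reverse-strand
alignments, soft-clipped cycles included). Read 5′ ends coincide with true
fragment breakpoints in both library types, so binning distances 1–50 in
ten 5-bp bins localizes end-proximal damage; positions beyond 50 bp are
outside the analysis. Bin contrasts (bin 1 vs pooled bins 2–10 per group;
bin 1 vs bin 2 per class; group difference of bin-1 rates per class) are
computed on counts pooled over a group's samples and compared as two
binomial rates with their eligible-base exposures, Bonferroni-corrected
across the 12 classes. A per-sample t-test is deliberately *not* used
here: at desk scale a single bin × class cell holds single-digit counts,
where sample-level variances are noise; at cohort scale the pooled test
converges to the same comparison. Pooling makes the test anti-conservative
if reads are duplicated copies of few molecules, so the bundled
fragment-end acceptance check runs duplication-free (see below).

## Group statistics

Class-wise comparisons are Welch (unequal-variance) t-tests on per-sample
rates, Bonferroni-corrected across the 12 (or 6 collapsed) class tests;
the total rate is tested separately and not counted in the correction.
Rates are compared untransformed, matching how such means are reported.

Per-position tests are Welch tests per (position, class) across samples,
corrected within each reference-base family (tests are enumerated per
source base — A>N, C>N, G>N, T>N — and a hit fraction of ~0.4% in the
original-scale analysis implies some correction was applied; Bonferroni
within family is the default, with `bh` and `none` available). Positions
where both groups are constant and equal are untestable and excluded from
the correction denominator; constant-but-different positions get a p = 0
sentinel and are counted in `n_degenerate` so they are visible rather than
silently dropped. Each hit carries its direction, and the
exclude-and-reprofile operation re-runs profiling on the complement of any
hit list, reporting per-class and total relative changes.

The null calibration of this machinery is itself part of the test suite:
over 1000 simulated null datasets the class-wise test's per-class hit
frequency at adjusted α = 0.05 sits slightly below nominal (the Welch
test is mildly conservative in the deep tail on Poisson-like rates) but
inside the binomial 99% interval, and the family-wise error rate stays
below α.

## The synthetic world

The generator's defaults encode the experimental magnitudes the analysis
is built around:

| quantity | default | where it acts |
|---|---|---|
| per-class background | 9e-6 (flat) | both presets; total 2.7e-5 (gDNA-like) |
| deamination elevation | C>T = G>A = 6.9e-5 | cfDNA-like preset; total 5.7e-5 |
| end effect | C>A ×5 in first 5 bp of each fragment end | gDNA-like preset (shearing oxidation) |
| depth | 1000× (counts mode) | panel-wide |
| UMI progeny | zero-truncated Poisson, mean 2.79 | reads mode |
| fragment length | 167 bp cfDNA-like / 450 bp gDNA-like | reads mode; 100 bp paired reads |
| base quality | 5% Q20, 15% Q33, 80% Q39 | reads mode (RTA-like binning) |
| germline | het AF 0.5 / hom AF 1.0, binomial sampling | both modes, shared across samples |

Counts mode draws alternate depths directly as
`Binomial(depth, rate)` — no reads, no families — and exists so that the
filtering and statistics can run at full panel scale in fractions of a
second. Reads mode builds template molecules, applies germline alleles,
then molecule-level damage (with the end multiplier), then first-cycle PCR
errors, expands each molecule to its family of read pairs, and finally
adds per-read sequencer errors; damage is applied *before* expansion
precisely so that it propagates family-wide and survives consensus, which
is the central topology the analysis assumes. Every planted non-reference
base is recorded in a ledger (germline / damage / pcr / seq), and the test
suite checks attribution completeness by exhaustive diff on small
instances.

What the generator does **not** emulate: sequence-context-dependent error
spectra (channels are uniform within a class), cycle-dependent quality
decay, homopolymer artifacts, fragment-length variation (lengths are
fixed per type), overlapping-gene panel structure, and donor-to-donor
germline differences (one genotype is shared by all samples). A green
test therefore establishes that the *pipeline machinery* — filtering,
consensus, estimation, testing — behaves correctly under the stated
statistical structure, not that any particular biological sample will
show these exact rates.

Simplifications worth knowing when reading the tests: all samples share
one genotype, so pairwise masking is exercised with identical planted
variant sets; two molecules can collide on the same (UMI, coordinates,
strand) key and legitimately merge into one family (tests aggregate the
ledger by key before comparing); and the fragment-end acceptance check
runs with mean progeny 1 and raised molecule counts — duplication is
orthogonal to breakpoint binning (family behaviour is covered by the
suppression criterion) and dropping it keeps that check within desk-scale
time and memory. Large read-level runs are streamed in 1-kb panel windows
for the same reason.

## Numerical and implementation choices

* Coordinates are 1-based closed internally (GRanges convention); BED
  input is 0-based half-open as usual.
* N or ambiguous bases are dropped from numerator and denominator alike.
* Mate-overlap bases are both counted in raw pileups (simple pileup
  semantics, reproducible without overlap-clipping conventions); in
  consensus output each family contributes once per position.
* MAPQ 0 alignments are always skipped; the threshold above that is
  configurable.
* Consensus tie-break: there is none — a tie is dropped by the strict
  majority rule, so no ordering-dependent behaviour exists.
* The signature refit minimizes squared error subject to non-negative
  weights via a small Lawson–Hanson active-set solver (no NNLS package is
  assumed), and reports weights as fractions of their sum plus the
  relative L2 residual. Errors whose ±1 bp context is unavailable are
  dropped and counted, never silently.
* Serialization: profiles round-trip through TSV + JSON sidecar exactly;
  denominators are integer base counts, which is what makes bit-identical
  round-trips possible.

## Known limitations

* The consensus rule is a reconstruction: the original "minor
  modification" of the published DES scheme is not described, so the
  strict-majority/tie-drop/keep-singletons rule documented above is a
  stated default, chosen as the simplest rule consistent with the reported
  effect sizes, not a reimplementation of an exact specification.
* Welch tests on per-sample rates are approximate for small groups and
  very low counts; the positional test refuses (and counts) degenerate
  positions rather than modeling them, and a count-based alternative is
  used only for the bin contrasts.
* The pooled bin test assumes independent bases; with heavy PCR
  duplication its p-values overstate evidence (see above) — run bin
  analyses on consensus observations or deduplicated data when family
  sizes are large.
* Panels are processed via per-window BAM queries; extremely fragmented
  panels (thousands of tiny intervals) will pay query overhead per
  interval.
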