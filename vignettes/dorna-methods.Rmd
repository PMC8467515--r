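---
title: "Detecting and quantifying dodecaRNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying dodecaRNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dornaseq)
```

## The biological model

DodecaRNAs (doRNAs) are 12-nt RNA fragments whose sequence coincides with
positions 2–13 of the 5.8S ribosomal RNA, together with a family of 5′
extended variants that all share one invariant property: their 3′ end falls
exactly on the G at 5.8S position 13, immediately upstream of a
2′-O-methylated U at position 14. The most abundant variant is the 13-nt
form carrying the one extra 5′ base that coincides with the mature 5.8S 5′
end — a cytosine in human and mouse (hence "C-doRNA"), an adenine in fly.
Longer family members are single-nucleotide 5′ extensions that walk into
the 3′ end of ITS1, up to 18 nt in total. Nothing extended on the 3′ side
belongs to the family.

`dornaseq` operationalises this model as:

* an **anchor** derived from a 5.8S-bearing reference record
  (`derive_anchor()`), which extracts the core, the +1 variant and the
  ladder windows and *validates* the signature (G at position 13, U/T at
  position 14) so that a mis-annotated reference fails loudly rather than
  silently producing nonsense calls;
* a **classifier** (`classify_reads()`, `tabulate_ladder()`) that assigns
  each collapsed read to exactly one of `dorna`, `c_dorna`,
  `extended_variant` or `non_dorna` by sequence identity to those windows.

Family membership is decided by identity to the anchored reference window,
not by genomic alignment. Mammalian genomes carry hundreds of rDNA operon
copies, so a read that matches the window cannot be attributed to a unique
locus anyway; identity to the anchor is both the biologically meaningful
criterion and a deterministic one.

### Naming the +1 variant across species

The fly 13-nt form begins with A rather than C. Rather than inventing a
species-specific category, the classifier labels offset −1 as `c_dorna`
for every species and the anchor records the actual 5′ base
(`five_prime_base`), so reports remain comparable across species while the
base identity stays visible.

### Mismatch tolerance

The default is strict identity (`allow_mismatches = 0`). Sequenced
variants with internal substitutions exist (rDNA copies differ), so
`allow_mismatches = 1` tolerates one internal substitution — but the 3′
terminal base must still be G, preserving the family's defining
invariant. There is no established tolerance rule beyond this, so anything
looser is left to the user.

## Upstream processing

Reads are trimmed by seed-and-extend: the first `min_overlap = 5` bases of
the 3′ adapter must occur exactly, the leftmost such seed wins, and the
full-adapter extension may carry at most a 10% mismatch rate over the
aligned span. This is deterministic and directly checkable against a
brute-force scan, which the test suite does. Inserts are kept only inside
the 8–30 nt window; at most one N is tolerated (N never matches during
classification). All sequences are canonicalized to DNA letters on ingest
(U → T).

Identical trimmed reads collapse to unique records ordered by count then
sequence; RPM uses the trimmed in-window read total as its denominator
(recorded in run metadata), so a library's RPM column sums to exactly one
million.

## The ultra-short mapper

BLAST-style seeded alignment is unreliable for 12-mers, so mapping is an
exhaustive ungapped scan: every offset of every record, both strands, with
at most 0 or 1 substitutions. This reproduces exactly the
100%-identity/100%-coverage semantics that ultra-short matches require.
Coordinates are 0-based half-open internally and 1-based inclusive in
human-readable labels; positions relative to the 5.8S 5′ end are signed
with no zero (…, −2, −1, 1, 2, …), so a 18-nt family member reads as
`-5..13`. Gapped alignment is deliberately unsupported: with queries of at
most 30 nt, an ungapped full-length hit is the only "100% coverage" event.

## Ratio estimation and uncertainty

The C-doRNA/doRNA ratio is the plain ratio of the two family counts.
Uncertainty comes from a percentile bootstrap (default 2000 resamples,
seeded): the two counts are resampled as a binomial split of their total
and the 2.5/97.5 percentiles of the resampled ratios form the interval.
The method is distribution-free and its coverage is itself testable — the
acceptance suite measures empirical coverage of the planted ratio over 200
simulated replicates and requires it to sit in the 93–97% band.

Two comparison routes are provided and clearly separated: a bootstrap test
on the difference of log ratios (`compare_ratios()`, with an add-one
corrected two-sided p-value, so the smallest attainable p is
`2/(n_bootstrap+1)`), and plain Welch t-test plumbing for per-replicate
ratios from independent cultures (`compare_ratio_replicates()`). Neither
is claimed to be canonical; they answer different questions (within-library
counting error vs between-culture variability).

## Partner filtering and quantitation

The proteomics filter is a literal reading of the published rule:
"more than 3 peptide matches" is strict (kept iff count ≥ 4, threshold
configurable) and "absent from the negative" means zero detected peptides,
not sub-threshold. Venn partition is exact set algebra. qPCR quantities
come from an OLS standard curve of Cq on log10(copies); efficiency is
`10^(-1/slope) - 1`, so the perfect-doubling slope is −3.3219. Copy
numbers invert the fitted line exactly. Compartment fractions, reporter
normalization (Fluc/Rluc as percent of control) and wound closure are the
obvious closed forms, with boundary handling (clamping of areas that
exceed the time-zero scratch with a warning, errors on zero denominators).

## The synthetic-data generators

`simulate_library()` emulates the statistical structure the analysis
assumes: a spiky length distribution concentrated at 12–13 nt, one
dominant sequence per family length class, a 5′-only extension ladder
anchored at the invariant 3′ position, species-specific ratios (presets
5.0 human, 1.0 mouse, 0.25 fly), miRNA-like background (random 19–24-mers
with a long-tailed abundance profile), random reference degradation
fragments, adapter ligation and substitution sequencing errors. Family
shares default to 0.60 (human), 0.74 (mouse) and 0.50 (fly) — chosen once
to sit inside the 22–74% range that the 12+13 nt window occupies across
real samples, with the mouse preset at the top as the most enriched cell
type, and 10% degradation + miRNA remainder as a realistic background mix.

The error model is substitutions only: inserts are at most 30 nt, the
classifier is exact-match, and indel artifacts in this size range are
dominated by substitution miscalls. This is a documented limitation —
passing tests say nothing about indel robustness, nor about realistic
quality-score profiles, ligation biases or multi-sample batch effects.
What exact recovery at error 0 *does* establish is that every counting
path (trim → collapse → classify → tabulate) is lossless and conservative.

The bundled references are synthetic 600-nt 45S-like records built in code
(`synthetic_reference()`): real flanking sequence is not required for any
computation, only the anchor region matters, and the human/mouse record
carries the well-known mammalian 5.8S 5′ terminus so the anchor sequences
are the real ones. The fly record is fully synthetic with the documented
properties (5′ A, core differing from the mammalian core at 2 positions,
G13/U14 intact). Real RefSeq records are drop-in replacements via
`reference_feature_set()`.

## Two denominators for the dominance statistic

The share of "the two sequences" (top 12-mer plus top 13-mer) can be
quoted against the 12+13 nt classes or against the whole 8–30 nt library;
both readings are defensible and they differ materially. The package
computes both (`combined_top_fraction()` returns `fraction_of_classes`
and `fraction_of_library`) and reports are explicit about which is used.
Per-length dominance fractions are computed within the length class on raw
counts (identical to RPM shares within one library).

## Numerical and degenerate-input choices

* Collapse ties break lexicographically; all orderings are deterministic.
* An empty library is not an error for the pipeline: it returns an empty
  report with a warning (stage errors, by contrast, abort with typed
  conditions such as `dorna_error_anchor_validation`).
* `estimate_ratio()` requires a nonzero core count; a zero C-variant count
  is legal and yields a ratio of 0 with a degenerate interval.
* Bootstrap resamples that drive the denominator to zero produce infinite
  ratios; percentile intervals handle them naturally and the log-ratio
  comparison drops non-finite resamples.
* All seeded code paths restore the caller's RNG state.

## Problem sizes used in the test and acceptance suites

Simulated libraries use 2×10⁴–3×10⁴ reads for unit checks and ~1.7×10⁵
reads (10⁵ expected family reads) for ratio-recovery and CI-calibration
runs, with 200 replicates for the coverage experiment and 1000 random
reference/query pairs for the mapper-vs-oracle comparison. These sizes
give binomial standard errors comfortably inside the asserted bands while
keeping a full run on a laptop-class single core in the minutes range.

## Known limitations

* Quality-based trimming, paired ends, UMIs and demultiplexing are out of
  scope; the trimmer assumes a single 3′ adapter.
* The mapper is for small reference sets (rRNA transcripts, contaminant
  panels), not genome-scale alignment.
* Cross-sample normalization beyond RPM, biogenesis inference and
  methylation calling are out of scope.
* Bootstrap intervals quantify counting error only; they do not model
  library-preparation variability between cultures (use the replicate
  t-test route for that).
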