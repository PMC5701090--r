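---
title: "Microsatellite risk classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite risk classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstrisk)
```

## The problem

Microsatellites (MSTs) are tracts of a short unit (1–6 bp) repeated in
tandem. Their lengths are polymorphic between individuals, and germline
repeat-length genotypes at specific loci can differ systematically between
cancer patients and healthy controls, making them candidate inherited risk
markers. `mstrisk` implements the full computational workflow for building
and validating such a marker panel:

1. **Catalog** perfect tandem repeats in reference sequence and assemble a
   target-enrichment panel from disease, other-cancer and control locus
   lists.
2. **Genotype** each sample at each panel locus from high-depth amplicon
   reads, by exact flank anchoring and allele-length histograms.
3. **Screen** loci whose genotype distributions separate cases from
   controls.
4. **Classify** samples by the fraction of signature loci carrying the risk
   genotype, with an ROC-derived cutoff, and estimate out-of-sample
   performance by leave-one-out cross-validation (LOOCV).
5. **Power** the validation cohort with a two-sample t-test calculation.

A first-class synthetic-data generator produces every input the pipeline
consumes, together with a truth manifest, so the whole chain is testable
without access to patient data.

## Genotypes and genotyping

A genotype at a locus is the unordered pair of repeat-tract lengths in bp,
written `"a1/a2"` with `a1 <= a2`; genotype equality is exact equality of
this pair. Reads are treated as *unaligned*: a locus is located in a read by
exact, unique matches of the `flank_len` (default 10 bp) reference bases on
each side of the tract, and the measurement is the number of bases strictly
between the two anchors, accepted only if it is a pure run of the locus
motif (any rotation). This sidesteps the well-known tendency of
repeat-spanning alignments to misplace indels; amplicon reads fully span the
short tracts targeted here, so anchoring loses little. A BAM ingestion path
is deliberately out of scope.

Per locus and sample the measurements form an allele-length histogram, and
`call_genotype()` applies two filters:

* `min_depth` (default 10 for discovery-like coverage, ~15x exome data; 30
  is a reasonable validation-mode choice at high depth): below it the call
  is missing.
* `min_allele_frac` (default 0.25): alleles supported by a smaller fraction
  of the locus reads are treated as PCR stutter and discarded. Stutter
  products sit ±1 unit off a true allele at per-read rates of a few
  percent, so at the depth regime this package targets (hundreds of reads
  per locus) fraction thresholding separates real heterozygous alleles
  (expected fraction ≈ 0.5) from stutter cleanly, and no probabilistic
  stutter model is attempted. Count ties resolve to the shorter length, a
  fixed and documented convention.

Quality control is a deterministic sliding-window trimmer
(`trim_reads()`): scanning 5'→3', a read is cut at the first base below
`min_q` inside the first window (default 4 bp) whose mean quality drops
below `min_q` (default Q20); reads shorter than `min_len` (default 36 bp)
are dropped. This is an intentionally simple, reproducible stand-in for the
usual external trimming tools, with the same intent.

## Repeat cataloging

`scan_tandem_repeats()` detects *perfect* (ungapped, mismatch-free) maximal
tandem tracts, truncated to whole copies of a primitive unit. Classical
repeat finders score impure repeats too; the markers this workflow targets
are short pure homopolymer/dinucleotide tracts, so the exact scanner is
sufficient and exactly testable against a brute-force oracle. Conventions
that keep catalogs consistent:

* motifs are canonicalized to the lexicographically minimal rotation
  (`"CA"` → `"AC"`), so rotated phases never create duplicate entries;
  strand is ignored.
* nested/overlapping candidates resolve to the smallest unit that explains
  a tract, then leftmost, then longest; catalogs are non-overlapping and
  sorted.
* internal coordinates are 0-based half-open; the textual form
  `"chrN:a-b"` is 1-based inclusive, matching how marker tables print
  spans (a 13 bp tract at `start=60918363,end=60918376` prints as
  `chr2:60918364-60918376`).
* `min_tract_bp` defaults to 10; this is a configurable detection floor,
  not an empirical constant. The parameter check requires only that the
  smallest unit can fit two copies, so the default unit range 1–6 remains
  usable; units whose two copies exceed the floor simply require longer
  tracts.

`assemble_panel()` unions lung-signature, other-cancer and control locus
lists with exact-coordinate de-duplication, keeps every source tag on
shared loci, and errors on motif conflicts at identical coordinates.

## Locus screening

For each locus with both cohorts called, the screen computes the **modal
genotype** (most frequent among called controls) and the **predominant
cancer genotype** (most frequent among called cases), each with a
predominance flag recording whether it exceeds half of its cohort. The
modal genotype is defined as "most frequent" so that it exists at every
locus, while the stricter >50% rule is enforced exactly where it matters:
a locus is *informative* in validation mode iff both top genotypes are
predominant **and** differ. Ties for the top genotype are broken to the
numerically smaller `(a1, a2)` pair and never satisfy predominance.
Missing calls leave both numerator and denominator of every frequency.

Discovery mode instead dichotomizes each cohort into modal vs non-modal
counts, tests the 2×2 table with a two-sided Fisher exact test (minimum
likelihood summation, with the conventional `1 + 1e-7` relative tolerance
so results are bit-for-bit reproducible), and controls the FDR with
Benjamini–Hochberg; the cutoff default `1e-4` reads the screening
convention "0.01%" literally as adjusted p < 0.0001 and is configurable.
A zero-margin table yields p = 1 by convention.

Per-locus odds ratios put the risk category in the case numerator —
non-modal in discovery, the predominant cancer genotype in validation —
with the Haldane–Anscombe +0.5 correction applied to all cells whenever
any cell is zero. Published per-locus odds ratios from real cohorts cannot
be regenerated here (the underlying genotype data are not public), so they
are not used as checks.

## Classification and cross-validation

A sample's risk score is the fraction of its *called* signature loci whose
genotype equals the locus risk genotype (validation) or differs from the
control modal genotype (discovery). A sample with no called signature
locus is unscorable and reported as such, distinct from a score of 0; a
sample with fewer than half its signature loci called is flagged
low-confidence.

Classification is `score >= cutoff` ("x% or more of the loci"), with
cutoff candidates restricted to observed scores and accuracy ties broken
toward the larger cutoff (higher specificity). On a 13-locus signature a
0.61 cutoff therefore means "8 or more risk genotypes". AUC is trapezoidal
integration of the ROC step curve, which equals the Mann–Whitney
concordance probability with 0.5 credit for ties; the equivalence is
asserted in the test suite against a pairwise-counting oracle and an
independent ROC library. The classifier odds ratio is `(TP/FP)/(FN/TN)`
with the same Haldane rule.

LOOCV refits *everything* per fold — modal/predominant genotypes,
informative-locus set and cutoff — because refitting only the cutoff while
keeping a signature chosen on the full data leaks the held-out sample into
marker selection. The optimistic variant is still available
(`fixed_signature = TRUE`) for comparison. With one held-out sample per
fold, "per-fold sensitivity" is ill-defined; the package therefore reports
both pooled held-out sensitivity/specificity (the honest summary) and
per-fold training metrics, and asserts neither as the historically used
variant. Folds whose refit produces an empty signature are surfaced as
unpredictable rather than dropped.

## Power calculation

`t_test_power()` computes the power of the classical pooled-variance
two-sided two-sample t-test from the noncentral t distribution
(`df = n1 + n2 - 2`, `ncp = diff / (sd * sqrt(1/n1 + 1/n2))`). "95%
confidence" is interpreted as two-sided `alpha = 0.05`. The computation is
units-agnostic; for classifier scores in percent, a mean difference of 30
with sd 15 at n = 30 vs 89 gives power > 0.99. A Welch variant
(Satterthwaite df under a common sd) is provided for comparison. The
implementation is verified against a vectorized Monte-Carlo oracle and
the analytic monotonicity properties.

## The synthetic-data generator

`simulation_config()` defaults *are* the study conditions the package
targets, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_loci` | 347 | enrichment-panel size (119 lung + 144 other-cancer + 84 control) |
| `n_informative` | 13 | validated lung signature size |
| `n_cases` / `n_controls` | 30 / 89 | validation cohort sizes |
| `depth_mean` / `depth_sd` / `depth_min` | 579 / 315 / 83 | per-locus amplicon depth: normal draw rounded, floored at 83 |
| `control_modal_freq` | 0.8 | modal-genotype share among controls; a clearly predominant mode with realistic minor-genotype mass |
| `case_shift_freq` | 0.7 | shifted top-genotype share among cases at informative loci; comfortably above the 0.5 predominance rule yet leaves sampling noise |
| `tract_len_range` | 12–26 bp | marker-table tract lengths (mono/di-nucleotide) |
| `unit_len_weights` | 1: 0.9, 2: 0.1 | validated markers are overwhelmingly homopolymers, occasionally dinucleotides |
| `allele_spread` | 2 units | alternative alleles within ±2 units of reference |
| `stutter_rate` | 0.05 | per-read ±1-unit slip probability, typical PCR stutter magnitude |
| `base_error_rate` | 0.001 | per-base substitution rate of modern short-read data |
| `read_len` | 150 | standard short-read length; validated to span tract + flanks |

The depth model floors (censors) the normal draw at `depth_min` rather
than resampling above it; this keeps the realized mean within a few
percent of `depth_mean`, matching the intended summary statistics, whereas
resampling would inflate the mean by ~7%.

Each locus lives on its own contig with random flanks constrained to be
locally non-repetitive; every contig is verified by *rescanning* — the
planted locus must be rediscovered at exact coordinates with its canonical
motif and unique anchors, or the flanks are redrawn. Controls draw
genotypes from a distribution with `control_modal_freq` on the modal
(homozygous-reference) genotype and the remainder uniform over four
alternative genotypes; at informative loci cases move `case_shift_freq`
onto one of those alternatives. Reads are built per sample × locus from
the two true alleles with equal probability, a per-read ±1-unit stutter
slip, and substitution errors that by default avoid the `flank_len`
anchoring bases next to the tract — the generator exercises the
genotyping logic, not flank-rescue alignment, which is out of scope
(`errors_in_flanks = TRUE` enables errors everywhere for robustness
testing). All outputs are byte-deterministic in `seed`, and a JSON truth
manifest records distributions, per-sample truth genotypes and the
informative flags, serving as the oracle for every recovery test.

What the generator does *not* emulate: locus-specific stutter and error
profiles, multi-unit stutter jumps, sequence-context-dependent error
rates, PCR/coverage bias correlated between loci, population structure or
covariates (age, smoking, ancestry), tumor contamination, and genome-scale
low-coverage discovery data. Passing recovery tests therefore demonstrate
the correctness of the algorithms under the stated statistical model, not
clinical performance on real cohorts.

## Numerical conventions and degenerate inputs

* Fisher exact: minimum-likelihood two-sided summation with relative
  tolerance `1 + 1e-7`; zero margins give p = 1.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`;
  significance is `adjusted < q_cutoff`, strictly.
* Genotype tie-breaks: numeric on `(a1, a2)`; allele count ties toward the
  shorter length; cutoff ties toward the larger cutoff.
* Empty histograms and sub-threshold depth are *missing calls*, not
  errors; loci whose flanks cannot be anchored are flagged uncallable, not
  fatal; all-missing or low-call-rate loci are excluded from screening and
  listed with reasons.
* Odds ratios use Haldane–Anscombe +0.5 only when some cell is zero, so
  tables without zeros reproduce the plain cross-ratio exactly.

## Problem sizes used in tests and the acceptance script

Statistical properties are checked at the default study conditions
(347-locus panel, 30/89 cohort) at the genotype level, where simulation is
cheap, averaging over 20–50 replicate cohorts; read-level end-to-end
checks (simulate reads → trim → genotype → screen → classify) use smaller
panels of 2–6 loci and cohorts of 4–10 samples, where exact identity with
the truth manifest is asserted in the noise-free setting. The LOOCV
demonstration uses a 60-locus panel with the full 119-sample cohort. These
sizes are the package's own choices for concise, deterministic checks;
all of them scale up by changing `simulation_config()` arguments.

## Known limitations

* Only perfect repeats are cataloged; impure/compound repeats are not
  modeled (nor present in the targeted marker class).
* Genotyping requires reads spanning tract plus both anchors; tracts
  approaching the read length are uncallable by design.
* The screen treats loci independently: no linkage, covariate adjustment
  or population-stratification correction.
* Validation-mode informativeness is a hard >0.5/differ rule; marginal
  loci flip in and out under resampling, which the LOOCV makes visible.
* The caller's thresholds are faithful-in-spirit defaults for the
  high-depth regime, not constants inherited from any prior pipeline.
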