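---
title: "Measuring transcription fidelity: the mismatch statistic and proofreading kinetics"
author: "rnafidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcription fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnafidelity)
```

# The problem

RNA polymerase makes mistakes, and most organisms deploy dedicated
proofreading factors (bacterial Gre, eukaryotic/archaeal TFIIS) to
excise them.  Cyanobacteria lack these factors, which raises two
measurable questions this package addresses:

1. **How error-prone is transcription in vivo?**  Answered by deep
   sequencing of total RNA: every mismatch between a sequenced read and
   the genome is a candidate transcription error, once sequencing
   errors and genomic variants are controlled for.
2. **How capable is the polymerase's own proofreading?**  Answered by
   in vitro kinetics of transcript hydrolysis: single-exponential
   cleavage time courses, their Mg²⁺ dependence (Michaelis–Menten),
   temperature dependence (Arrhenius) and pH dependence (log-linear
   versus general-base titration).

The package implements both estimators and a synthetic-data module that
generates inputs with known ground truth, so that every stage can be
validated by parameter recovery rather than by fiat.

# The mismatch statistic

## Definition

For reads aligned to a single reference, let p index positions **along
the read in sequencing direction** (the biologically meaningful axis:
base-calling error depends on cycle number).  A read base at position p
is *included* when

* neither the read base nor the reference base is `N`;
* its Phred quality is at least `qmin` (default 30, i.e. a nominal
  sequencing-error probability of 1e-3);
* its reference position is not in the variant mask.

Then

* `N(p)` — number of included bases at p (the denominator),
* `M(p)` — included bases that mismatch the reference,
* `M(p, s)` — those of substitution type `s` (12 types, written
  `ref>obs` in read orientation, so an RNA-level C-to-U error is
  `C>T`),

and the rates are percentages, `E(p) = 100 M(p)/N(p)` and
`E(p, s) = 100 M(p, s)/N(p)`.  A position with `N(p) = 0` has an
*undefined* rate, reported as `NA`, never as 0.

## Reading the thresholds

Three conventions required a decision, and each is exposed as a
parameter:

* **Quality threshold.**  Bases below Q30 are excluded from numerator
  *and* denominator.  The symmetric exclusion keeps `E(p)` a proper
  frequency over trustworthy base calls; excluding them from the
  numerator only would shrink rates by the fraction of low-quality
  bases, which varies along the read.  `qmin` is a parameter of every
  function that applies the predicate.
* **Denominator.**  "Reads" at position p means reads *covering* p
  whose base there passes the predicates — not all reads in the file.
  Short or trimmed reads therefore simply stop contributing beyond
  their length.
* **Ambiguity.**  `N` in read or reference removes the base from both
  counts.

## Alignment filters

Upstream of the statistic, reads are filtered the way the original
alignments were produced: at most `maxMismatches = 3` mismatches per
read and uniquely mapping reads only (the Bowtie `-n 3 -m 1`
convention).  Alignments are substitution-only (single-M CIGAR);
records with indels or clipping are skipped with a warning, because a
gapped alignment has no well-defined per-cycle mismatch axis in this
model.  Mismatch counts are always recomputed from the bases rather
than trusted from tags.  Reverse-strand alignments are
reverse-complemented into sequencing orientation on input, so
substitution types are reported at the RNA level for either strand.

## Variant masking

A fixed single-base difference between the sequenced strain and the
reference looks like a 100%-penetrant "error" and must be excluded.
The package uses a transparent frequency-consensus caller: a position
is masked iff qualifying coverage is at least `minCoverage` (default
10) and the most frequent non-reference base accounts for at least
`altFraction` (default 0.8) of qualifying bases.  The thresholds are
deliberately far above anything transcription or sequencing errors can
reach (~1e-3, uncorrelated across reads), and far below what a clonal
variant shows (~1), so the rule is insensitive to their exact values.
When two alternative bases tie at the top, the position is masked if
their combined fraction passes the threshold — conservative exclusion
protects the error statistic at the cost of a slightly larger mask.  A
known variant list (VCF/TSV) can be supplied instead via
`readVariantMask()`.

## Comparing samples

`compareSamples()` expresses one sample's `E(p, s)` relative to
another's as a percentage, with a binomial standard error propagated to
the ratio.  Rates can be pooled over several read positions: with the
uniform coverage of the synthetic data every position estimates the
same quantity, so pooling is a pure precision gain.  On real libraries
a single mid-read position (the default, position 7) avoids the
end-of-read artefacts that motivated the original choice of a mid-read
cycle.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the estimator is validated.

* **Genome**: i.i.d. bases at a target GC content (default 0.5); a
  configurable fraction of positions (default 0 unless set) carries a
  fixed single-base variant, giving a "sample genome" the reads are
  drawn from while analysis uses the reference — exactly the situation
  the mask must correct.
* **Reads**: uniform start positions, sense strand by default
  (strand-specific library; a `reverseStrandFraction` switch exists and
  is exercised in tests).  Per base, in order: a transcription error
  with the probability in a 4×4 substitution matrix; then a sequencing
  error with probability `10^(-Q/10)` for the sampled Phred score Q,
  uniform over the three alternative bases.  Both events at one site
  are both recorded, the sequencing error acting on the substituted
  base, so the truth table supports exact accounting.
* **Qualities**: per-position Gaussian Phred scores truncated to
  [2, `qualityMax`]; the default profile declines from mean 38 (first
  cycle) to 28 (last), s.d. 3, putting a realistic share of bases on
  both sides of the Q30 threshold.  Pinning the profile at the FASTQ
  ceiling of 93 makes the per-base error probability ~5e-10 and serves
  as the "sequencing channel off" configuration.
* **Outputs**: FASTA (reference and sample genome), FASTQ (Phred+33),
  SAM with the true placements (FLAG 0/16, single-M CIGAR), variant
  list (minimal VCF and TSV) and the truth table (TSV).  Identical
  configurations give byte-identical files.

What the generator does **not** emulate — and hence what passing tests
do not certify about real libraries: expression-level coverage
heterogeneity (uniform coverage isolates the statistic, which is
coverage-weighted by construction), indels, PCR duplicates, paired-end
structure, strand-bias artefacts, and reverse-transcription errors as a
separate channel (they are indistinguishable from sequencing errors at
the single-read level and are folded into that channel; the RT used in
the motivating experiments was chosen for maximal fidelity).

# Kinetic models

All fits are unweighted least squares — the source measurements carry
no variance model — with a per-series weight column accepted but
defaulting to 1 at the interface level.  The five model forms:

| model | form | parameters |
|---|---|---|
| exponential | y(t) = A(1 − e^(−kt)) | k (1/s), amplitude A |
| michaelis_menten | v(c) = kcat·c/(KM + c) | kcat (1/s), KM (mM) |
| arrhenius | ln k = ln A − (Ea/R)(1/T) | Ea (kJ/mol), ln A |
| ph_loglinear | log10 k = c0 + g·pH | gradient g, c0 |
| ph_titration | k = kmax/(1 + 10^(n(pKa − pH))) | kmax, pKa, n |

Numerical choices:

* **Initialisation** is deterministic and derivative-free: exponential
  k₀ from the initial slope over the plateau amplitude;
  Michaelis–Menten from the Lineweaver–Burk linearisation; titration
  pKa₀ from interpolating the half-maximal crossing.
* **Bounds**: rate-like parameters non-negative; exponential amplitude
  in (0, 1.1] (a fraction, with room for noise overshoot); titration
  slope n in [0.3, 3].  Bounded Levenberg–Marquardt via
  `minpack.lm::nlsLM`.
* **Failure is data, not an exception**: non-convergence, an all-zero
  time course, or a KM escaping 50-fold beyond the measured
  concentration range (effectively linear data) come back as a
  `FitResult` with `converged = FALSE` and a note.
* **Arrhenius is linear** and fitted by ordinary least squares exactly;
  Ea = −slope·R with R = 8.314 J mol⁻¹ K⁻¹, errors propagated from the
  slope.  Temperature input may be °C or K with an explicit unit flag;
  Kelvin internally.
* **pH model selection.**  The log-linear and titration shapes are
  non-nested, which rules out an F-test; they are compared by AICc
  (small-sample corrected AIC).  Both candidates are scored on the
  log10 rate — fitting one model on k and the other on log10 k would
  make the likelihoods incommensurable.  The titration fit is therefore
  performed in log space, which also matches the roughly multiplicative
  error of gel-quantified rates.  An AICc difference below 2 is flagged
  `ambiguous`; a flat profile (|g| < 0.05) is flagged `degenerate`.
* **Noise placement in the simulator** mirrors the fitted scale:
  additive on fractions (exponential, Michaelis–Menten), multiplicative
  (log-scale) for Arrhenius and the pH models.

`foldChange()` compares one parameter between two fits with a
first-order (delta-method) standard error; tests verify the propagation
against Monte-Carlo resampling.

# Validation design and problem sizes

Every operation is checked against an independent oracle rather than
against itself: exact double-loop recounts of `N(p)`, `M(p)`,
`M(p, s)`; truth-table resolution of per-read mismatch counts;
binomial 3-s.d. bands for each error channel in isolation; grid-search
SSE minimisers for the nonlinear fits; closed-form normal equations for
the linear ones.  The recovery experiments use the values reported for
the cyanobacterial and *E. coli* enzymes as generator settings —
misincorporation rates 0.016 and 0.012 s⁻¹, a 30-fold kcat difference
at shared Mg²⁺ KM, a 2-fold activation-energy difference, a pH
gradient of 0.9, an apparent pKa of 6.8, a 135-fold cleavage-rate
difference in correctly paired complexes, and a 125% between-sample
error-level ratio.

Synthetic sequencing runs in the test suite use genomes of 3–30 kb and
3·10⁴–1.5·10⁵ reads of 50 bp (up to ~7.5e6 bases, of which well over
10⁶ pass the Q30 predicate), sizes at which binomial expectations are
sharp while a full run of the suite stays comfortably interactive.
Calibration sweeps use 200 replicates per kinetic model and check both
median relative error (≤ 5%) and 1-s.e. interval coverage against the
Gaussian expectation (≈ 68%, accepted within [55%, 80%]).

# Known limitations

* The error statistic is read-level, not transcript-level: a hot-spot
  error transcribed many times counts many times.
* One reference sequence per alignment set; multi-chromosome input
  must be analysed per chromosome.
* The variant caller assumes a clonal haploid sample; heterogeneous
  populations with allele fractions near the threshold will be masked
  erratically (the threshold is a parameter for that reason).
* pH profiles with a pKa outside the measured range degenerate towards
  the log-linear shape; the comparison then flags ambiguity rather
  than inventing a pKa.

# End-to-end demonstration

`runDemo()` chains everything: two simulated read sets differing only
in transcription error rate (1.25e-3 vs 1.0e-3 C>T), masking, error
tables, the between-sample ratio, and one simulate-and-fit round per
kinetic model, writing a JSON report of recovered versus true values
with pass flags.  One global seed fans out to per-stage child seeds, so
stages can be re-run in isolation and identical seeds give
byte-identical reports.

```{r demo, eval = FALSE}
report <- runDemo(defaultRunConfig(seed = 1), outDir = "demo_out")
report$fidelity$ratioPercent   # ~125, the configured rate ratio
report$kinetics$exponential    # recovered k vs truth 0.016 1/s
```
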