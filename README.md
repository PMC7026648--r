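# rnafidelity

Estimating how often RNA polymerase makes mistakes, and how well it
proofreads them.

Most organisms proofread transcription with dedicated factors
(bacterial Gre, eukaryotic/archaeal TFIIS); cyanobacteria lack them,
yet keep their in-vivo error level almost as low as *E. coli*'s.
Quantifying that takes two measurements, and this package implements
the computation behind both:

1. **In-vivo transcription error rates from RNA-seq.**  Every mismatch
   between an aligned read and the genome is a candidate transcription
   error, contaminated by sequencing errors and genomic variants.  The
   statistic is computed per read position p (sequencing direction):

       E(p)    = 100 · M(p) / N(p)        (percent)
       E(p, s) = 100 · M(p, s) / N(p)

   where `N(p)` counts read bases at position p passing the inclusion
   predicates — non-`N` read and reference base, Phred quality ≥ 30,
   reference position not masked as a single-base variant — `M(p)`
   those that mismatch the reference, and `M(p, s)` those of one of
   the 12 substitution types `s` (read orientation, so an RNA C→U
   error is `C>T`).  Alignments are filtered to ≤ 3 mismatches and
   unique placements; variants are masked by a frequency-consensus
   caller (coverage ≥ 10, alternative-allele fraction ≥ 0.8) or an
   external VCF.  Samples are compared as `100·E_a/E_b` with binomial
   error propagation.

2. **Proofreading (transcript hydrolysis) kinetics.**  Least-squares
   fits of the four models used to characterise the reaction:
   single-exponential progress curves `y = A(1 − e^(−kt))`;
   Michaelis–Menten Mg²⁺ dependence `v = kcat·c/(KM + c)`; Arrhenius
   temperature dependence `ln k = ln A − (Ea/R)(1/T)` with
   R = 8.314 J mol⁻¹ K⁻¹; and pH–rate profiles, discriminating a
   log-linear shape (`log10 k = c0 + g·pH`, water ionisation) from a
   general-base titration (`k = kmax/(1 + 10^(n(pKa − pH)))`) by AICc.

A synthetic-data module generates reference genomes and
strand-specific reads carrying three independently controlled mismatch
channels — transcription errors (4×4 substitution matrix), sequencing
errors via the Phred identity `10^(−Q/10)`, and fixed genomic variants
— plus a complete truth table, so every estimator is validated by
parameter recovery.  See the vignette
(`vignettes/transcription-fidelity.Rmd`) for the model details and
design decisions.

## Worked example

Simulate a 20 kb genome with 0.5% single-base variants and 40 000
reads of 50 bp carrying C→U transcription errors at 2×10⁻³ per C, run
the full fidelity pipeline, and fit one misincorporation time course:

```r
library(rnafidelity)

cfg <- SimConfig(genomeLength = 20000, nReads = 40000, readLength = 50,
                 errorMatrix = makeErrorMatrix(c("C>T" = 2e-3)),
                 snvFraction = 0.005, seed = 1)
sim <- simulateReads(cfg)
sim
#> SimulatedReads: 40000 reads x 50 bp
#>   truth events: transcription_error=982, sequencing_error=1689, snv=10198

files <- writeSimulatedReads(sim, tempdir(), "demo")
reads <- filterAlignments(readAlignments(files["sam"], files["refFasta"]))
mask  <- callVariantMask(reads)
mask
#> VariantMask: 100 positions (minCoverage=10, altFraction=0.80)

tab <- computeErrorTable(reads, mask, qmin = 30)
specificErrorRate(tab, readPos = 7, substitution = "C>T")
#> [1] 0.02787492
#> attr(,"count")
#> [1] 11
#> attr(,"denominator")
#> [1] 39462

fit <- fitExponential(simulateKinetics("exponential", c(k = 0.016, A = 1),
                                       x = seq(30, 300, 30), noiseSd = 0.02,
                                       seed = 2)[[1]])
fit
#> FitResult: exponential (converged)
#>   k = 0.0156198 (se 0.000663)
#>   A = 1.01126 (se 0.0116)
#>   RSS 0.003245 on 10 points
```

Reading the output: the mask recovered all 100 planted variants; the
C>T rate at read position 7 is 0.028% from 11 events over 39 462
included bases — consistent with the configured 2×10⁻³ per-C rate
(C sites are ~25% of bases, so ~0.05% is expected, with ±0.02%
binomial scatter at this depth) plus a small Phred-predicted
sequencing residual; and the fitted misincorporation rate constant
0.0156 ± 0.0007 s⁻¹ recovers the generating 0.016 s⁻¹.
`runDemo(defaultRunConfig(seed = 1), outDir = "demo_out")` chains all
of this, plus all four kinetic fits, into one JSON report.

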