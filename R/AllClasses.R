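#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges IntegerList
#' @importClassesFrom Biostrings DNAString
NULL

#' Simulation configuration for synthetic RNA-seq data
#'
#' Holds every parameter of the read simulator: genome composition, read
#' geometry, the three independent mismatch channels (transcription errors,
#' quality-dependent sequencing errors, genomic single-base variants) and
#' the random seed.  Identical configurations produce byte-identical
#' outputs.
#'
#' @slot genomeLength Genome length in bp.
#' @slot gcContent Target GC fraction in (0, 1).
#' @slot nReads Number of reads to simulate.
#' @slot readLength Read length in bp (uniform across reads).
#' @slot errorMatrix 4x4 matrix of per-base transcription-error
#'   probabilities; rows are template (reference) bases, columns observed
#'   bases, diagonal ignored.  RNA-level substitutions are written in the
#'   DNA alphabet (a C-to-U error is the \code{["C","T"]} entry).
#' @slot snvFraction Fraction of reference positions carrying a fixed
#'   single-base variant in the sequenced strain.
#' @slot qualityMean Numeric vector of per-read-position mean Phred
#'   scores (length \code{readLength}).
#' @slot qualitySd Standard deviation of the sampled Phred scores.
#' @slot qualityMax Upper truncation bound for sampled Phred scores
#'   (default 41; at most 93, the FASTQ printable limit).  Setting the
#'   whole profile at 93 makes the sequencing-error probability
#'   negligible, switching that channel off.
#' @slot reverseStrandFraction Fraction of reads emitted as reverse-strand
#'   alignments; 0 (the default) models a strand-specific library.
#' @slot seed Integer random seed.
#'
#' @seealso \code{\link{SimConfig}} for the user constructor.
#' @export
setClass("SimConfig",
  representation(
    genomeLength = "integer",
    gcContent = "numeric",
    nReads = "integer",
    readLength = "integer",
    errorMatrix = "matrix",
    snvFraction = "numeric",
    qualityMean = "numeric",
    qualitySd = "numeric",
    qualityMax = "integer",
    reverseStrandFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@genomeLength < 100L)
    msg <- c(msg, "genomeLength must be >= 100")
  if (!(object@gcContent > 0 && object@gcContent < 1))
    msg <- c(msg, "gcContent must lie strictly inside (0, 1)")
  if (object@readLength > object@genomeLength)
    msg <- c(msg, "readLength must not exceed genomeLength")
  if (object@nReads < 0L) msg <- c(msg, "nReads must be non-negative")
  em <- object@errorMatrix
  if (!identical(dim(em), c(4L, 4L)) ||
      !identical(rownames(em), .BASES) || !identical(colnames(em), .BASES))
    msg <- c(msg, "errorMatrix must be 4x4 with A,C,G,T dimnames")
  else {
    off <- em; diag(off) <- 0
    if (any(off < 0) || any(off > 1))
      msg <- c(msg, "errorMatrix entries must be probabilities in [0, 1]")
    if (any(rowSums(off) > 1))
      msg <- c(msg, "per-base total error probability (row sum) must be <= 1")
  }
  if (object@snvFraction < 0 || object@snvFraction > 1)
    msg <- c(msg, "snvFraction must be in [0, 1]")
  if (length(object@qualityMean) != object@readLength)
    msg <- c(msg, "qualityMean must have one value per read position")
  if (object@qualitySd < 0) msg <- c(msg, "qualitySd must be >= 0")
  if (object@qualityMax < 2L || object@qualityMax > 93L)
    msg <- c(msg, "qualityMax must lie in [2, 93]")
  if (object@reverseStrandFraction < 0 || object@reverseStrandFraction > 1)
    msg <- c(msg, "reverseStrandFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Simulated genome pair: reference and sequenced-strain sample
#'
#' The reference sequence together with a "sample genome" that differs
#' from it at exactly the simulated single-base variant positions, plus
#' the variant list.  Reads are drawn from the sample genome but analysed
#' against the reference, so variants are a mismatch source the error
#' statistic must mask out.
#'
#' @slot reference \code{DNAString} reference sequence.
#' @slot sample \code{DNAString} sequenced-strain genome.
#' @slot variants \code{DataFrame} with columns \code{pos0} (0-based
#'   reference position), \code{ref} and \code{alt}.
#' @export
setClass("SimulatedGenome",
  representation(
    reference = "DNAString",
    sample = "DNAString",
    variants = "DataFrame"
  )
)

setValidity("SimulatedGenome", function(object) {
  if (length(object@reference) != length(object@sample))
    return("reference and sample genome must have equal length")
  v <- object@variants
  need <- c("pos0", "ref", "alt")
  if (!all(need %in% colnames(v)))
    return("variants must have columns pos0, ref, alt")
  if (nrow(v) && any(v$ref == v$alt))
    return("variant alt base must differ from ref")
  TRUE
})

#' Simulated read set with ground truth
#'
#' Reads simulated from a \code{\linkS4class{SimulatedGenome}} with every
#' injected event (transcription error, sequencing error, variant site)
#' enumerated in a truth table.  Sequences and qualities are stored in
#' sequencing orientation.
#'
#' @slot id Read identifiers.
#' @slot start0 0-based reference start of each alignment.
#' @slot strand \code{"+"} or \code{"-"} per read.
#' @slot seq Character vector of read sequences (sequencing orientation).
#' @slot qual Integer matrix of Phred scores, one row per read.
#' @slot truth \code{DataFrame} of injected events with columns
#'   \code{id}, \code{readPos} (1-based, sequencing direction),
#'   \code{refPos0} (0-based), \code{class}, \code{refBase},
#'   \code{obsBase} (bases in read orientation).
#' @slot genome The \code{\linkS4class{SimulatedGenome}} reads were drawn
#'   from.
#' @slot config The generating \code{\linkS4class{SimConfig}}.
#' @export
setClass("SimulatedReads",
  representation(
    id = "character",
    start0 = "integer",
    strand = "character",
    seq = "character",
    qual = "matrix",
    truth = "DataFrame",
    genome = "SimulatedGenome",
    config = "SimConfig"
  )
)

setValidity("SimulatedReads", function(object) {
  n <- length(object@id)
  if (length(object@start0) != n || length(object@strand) != n ||
      length(object@seq) != n || nrow(object@qual) != n)
    return("per-read slots must have equal length")
  if (n && !all(nchar(object@seq) == ncol(object@qual)))
    return("sequence length must match quality columns")
  TRUE
})

#' Aligned reads against a single reference
#'
#' The unit the mismatch statistic scans: each read's placement, bases and
#' Phred qualities, with sequences stored in sequencing orientation
#' (reverse-strand alignments are reverse-complemented on input).
#'
#' @slot id Read identifiers.
#' @slot refName Reference sequence name (single reference).
#' @slot start0 0-based reference start of each alignment.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot seq Character vector of read sequences, sequencing orientation.
#' @slot qual \code{IntegerList} of Phred qualities, sequencing
#'   orientation.
#' @slot unique Logical: alignment reported as unique.
#' @slot mismatches Integer mismatch count against the reference.
#' @slot reference \code{DNAString} reference sequence.
#' @export
setClass("AlignedReads",
  representation(
    id = "character",
    refName = "character",
    start0 = "integer",
    strand = "character",
    seq = "character",
    qual = "IntegerList",
    unique = "logical",
    mismatches = "integer",
    reference = "DNAString"
  )
)

setValidity("AlignedReads", function(object) {
  n <- length(object@id)
  if (length(object@start0) != n || length(object@strand) != n ||
      length(object@seq) != n || length(object@qual) != n ||
      length(object@unique) != n || length(object@mismatches) != n)
    return("per-read slots must have equal length")
  if (n && !all(nchar(object@seq) == lengths(object@qual)))
    return("sequence and quality lengths must agree per read")
  if (n && any(object@start0 + nchar(object@seq) > length(object@reference)))
    return("alignments must fit within the reference")
  if (n && !all(object@strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  TRUE
})

#' Mask of genomic single-base variant positions
#'
#' Reference positions excluded from the error-rate statistic because the
#' sequenced strain carries a fixed single-base difference there, with the
#' per-position evidence that triggered masking.
#'
#' @slot pos0 Sorted 0-based reference positions masked.
#' @slot evidence \code{DataFrame} with columns \code{pos0},
#'   \code{coverage}, \code{altBase}, \code{altFraction} for each masked
#'   position (empty for masks built from an external variant list).
#' @slot minCoverage Minimum coverage used by the caller.
#' @slot altFraction Minimum alternative-allele fraction used.
#' @export
setClass("VariantMask",
  representation(
    pos0 = "integer",
    evidence = "DataFrame",
    minCoverage = "integer",
    altFraction = "numeric"
  )
)

setValidity("VariantMask", function(object) {
  if (is.unsorted(object@pos0, strictly = TRUE))
    return("pos0 must be strictly increasing")
  if (nrow(object@evidence)) {
    if (any(object@evidence$coverage < object@minCoverage))
      return("every masked position must meet the minimum coverage")
    if (any(object@evidence$altFraction < object@altFraction))
      return("every masked position must meet the alt-fraction threshold")
  }
  TRUE
})

#' Per-read-position error-rate table
#'
#' For each read position p: the denominator N(p) (bases covering p that
#' pass the inclusion predicates: non-N read and reference base, Phred at
#' least \code{qmin}, reference position unmasked), the numerator M(p)
#' (those that mismatch the reference) and the 12 substitution-specific
#' counts M(p, s).  Rates are percentages: E(p) = 100 M(p)/N(p).
#'
#' @slot readPos 1-based read positions (sequencing direction).
#' @slot N Integer denominators.
#' @slot M Integer total mismatch numerators.
#' @slot subCounts Integer matrix, one column per substitution type in
#'   \code{substitutionTypes()} order.
#' @slot qmin Phred threshold applied.
#' @slot nMasked Number of reference positions that were masked.
#' @export
setClass("ErrorRateTable",
  representation(
    readPos = "integer",
    N = "integer",
    M = "integer",
    subCounts = "matrix",
    qmin = "integer",
    nMasked = "integer"
  )
)

setValidity("ErrorRateTable", function(object) {
  p <- length(object@readPos)
  if (length(object@N) != p || length(object@M) != p ||
      nrow(object@subCounts) != p)
    return("per-position slots must have equal length")
  if (ncol(object@subCounts) != 12L ||
      !identical(colnames(object@subCounts), .SUBTYPES))
    return("subCounts must have the 12 substitution-type columns")
  if (any(object@M > object@N))
    return("M(p) cannot exceed N(p)")
  if (any(rowSums(object@subCounts) != object@M))
    return("substitution counts must sum to M(p) at every position")
  TRUE
})

#' One measured kinetic series
#'
#' A single time-course or titration: x values (time in s, concentration
#' in mM, absolute temperature in K, or pH) and responses (fraction
#' reacted or rate in 1/s), with condition metadata.
#'
#' @slot x Numeric predictor values (sorted increasing).
#' @slot y Numeric responses.
#' @slot condition Condition label.
#' @slot replicate Replicate number.
#' @export
setClass("KineticSeries",
  representation(
    x = "numeric",
    y = "numeric",
    condition = "character",
    replicate = "integer"
  )
)

setValidity("KineticSeries", function(object) {
  if (length(object@x) != length(object@y))
    return("x and y must have equal length")
  if (anyNA(object@x) || anyNA(object@y))
    return("x and y must be finite")
  if (is.unsorted(object@x))
    return("x must be sorted increasing")
  TRUE
})

#' Result of a kinetic model fit
#'
#' Parameter estimates, standard errors, residual sum of squares and a
#' convergence flag for any of the kinetic models (exponential,
#' Michaelis-Menten, Arrhenius, pH log-linear, pH titration).
#'
#' @slot model Model identifier.
#' @slot estimates Named numeric parameter estimates.
#' @slot se Named numeric standard errors (NA when unavailable).
#' @slot rss Residual sum of squares on the fitted scale.
#' @slot nObs Number of observations.
#' @slot converged Logical convergence flag.
#' @slot note Diagnostic note ("" when clean).
#' @export
setClass("FitResult",
  representation(
    model = "character",
    estimates = "numeric",
    se = "numeric",
    rss = "numeric",
    nObs = "integer",
    converged = "logical",
    note = "character"
  )
)

setValidity("FitResult", function(object) {
  if (!identical(names(object@estimates), names(object@se)))
    return("estimates and se must share names")
  if (object@converged && any(!is.finite(object@se)))
    return("standard errors must be finite when the fit converged")
  TRUE
})

#' Comparison of candidate pH-profile models
#'
#' Both candidate fits (log-linear and titration), their small-sample
#' corrected information-criterion scores, the selected model and the
#' score difference.  A difference below 2 is flagged ambiguous.
#'
#' @slot fits Named list of \code{\linkS4class{FitResult}}s.
#' @slot scores Named numeric AICc scores.
#' @slot selected Identifier of the minimal-score model.
#' @slot delta Score difference (runner-up minus selected, >= 0).
#' @slot ambiguous Logical: score difference below 2.
#' @slot degenerate Logical: profile flat or a candidate failed.
#' @export
setClass("ModelComparison",
  representation(
    fits = "list",
    scores = "numeric",
    selected = "character",
    delta = "numeric",
    ambiguous = "logical",
    degenerate = "logical"
  )
)

setValidity("ModelComparison", function(object) {
  if (!object@selected %in% names(object@scores))
    return("selected model must be among the scored candidates")
  if (min(object@scores) != object@scores[[object@selected]])
    return("selected model must have the minimal score")
  if (object@delta < 0)
    return("score difference must be >= 0")
  TRUE
})
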