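#' Construct a simulation configuration
#'
#' User-facing constructor for \code{\linkS4class{SimConfig}}.  The
#' default quality profile declines linearly from a mean Phred of 38 at
#' the first read position to 28 at the last, with standard deviation 3
#' and scores truncated to [2, 41]; this places a realistic share of
#' bases on either side of the Q30 threshold the error statistic uses.
#'
#' @param genomeLength Genome length in bp (>= 100).
#' @param gcContent GC fraction, strictly inside (0, 1).
#' @param nReads Number of reads.
#' @param readLength Read length in bp.
#' @param errorMatrix 4x4 transcription-error probability matrix (rows =
#'   template base, columns = observed base); see
#'   \code{\link{makeErrorMatrix}}.
#' @param snvFraction Fraction of reference positions carrying a fixed
#'   single-base variant.
#' @param qualityMean Per-position mean Phred scores; a scalar is
#'   recycled, \code{NULL} uses the default declining profile.
#' @param qualitySd Phred score standard deviation.
#' @param qualityMax Upper truncation bound for Phred scores (2-93,
#'   default 41).  A profile pinned at 93 makes the sequencing-error
#'   probability negligible (about 5e-10 per base), effectively
#'   disabling that channel.
#' @param reverseStrandFraction Fraction of reads simulated on the
#'   reverse strand (default 0: strand-specific sense-only library).
#' @param seed Integer random seed.
#' @return A validated \code{SimConfig}.
#' @export
#' @examples
#' cfg <- SimConfig(genomeLength = 2000, nReads = 100, readLength = 50,
#'                  errorMatrix = makeErrorMatrix(c("C>T" = 1e-3)),
#'                  seed = 1)
#' cfg
SimConfig <- function(genomeLength = 10000L, gcContent = 0.5,
                      nReads = 1000L, readLength = 50L,
                      errorMatrix = makeErrorMatrix(),
                      snvFraction = 0, qualityMean = NULL, qualitySd = 3,
                      qualityMax = 41L, reverseStrandFraction = 0,
                      seed = 1L) {
  if (!(is.numeric(gcContent) && length(gcContent) == 1L &&
        gcContent > 0 && gcContent < 1))
    .stopf("gcContent must be a single value strictly inside (0, 1), got %s",
           paste(gcContent, collapse = ","))
  if (is.null(qualityMean))
    qualityMean <- seq(38, 28, length.out = readLength)
  else if (length(qualityMean) == 1L)
    qualityMean <- rep(qualityMean, readLength)
  new("SimConfig",
      genomeLength = as.integer(genomeLength), gcContent = gcContent,
      nReads = as.integer(nReads), readLength = as.integer(readLength),
      errorMatrix = errorMatrix, snvFraction = snvFraction,
      qualityMean = as.numeric(qualityMean), qualitySd = qualitySd,
      qualityMax = as.integer(qualityMax),
      reverseStrandFraction = reverseStrandFraction,
      seed = as.integer(seed))
}

#' Build a transcription-error probability matrix
#'
#' Creates the 4x4 per-base substitution probability matrix used by the
#' read simulator.  Entries are named \code{"ref>obs"} in the DNA
#' alphabet; an RNA-level C-to-U error is \code{"C>T"}.
#'
#' @param rates Named numeric vector of substitution probabilities, e.g.
#'   \code{c("C>T" = 2e-3)}.  Unnamed entries are an error.
#' @return 4x4 numeric matrix with zero diagonal.
#' @export
#' @examples
#' makeErrorMatrix(c("C>T" = 2e-3, "A>G" = 1e-3))
makeErrorMatrix <- function(rates = numeric()) {
  m <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  if (length(rates)) {
    if (is.null(names(rates)) || !all(names(rates) %in% .SUBTYPES))
      .stopf("rates must be named with substitution types such as \"C>T\"")
    parts <- strsplit(names(rates), ">", fixed = TRUE)
    for (i in seq_along(rates))
      m[parts[[i]][1], parts[[i]][2]] <- rates[[i]]
  }
  m
}

#' Uniform transcription-error matrix
#'
#' Every base errs with total probability \code{perBaseRate}, split
#' equally over the three alternative bases.
#'
#' @param perBaseRate Total per-base error probability.
#' @return 4x4 numeric matrix.
#' @export
uniformErrorMatrix <- function(perBaseRate) {
  m <- matrix(perBaseRate / 3, 4, 4, dimnames = list(.BASES, .BASES))
  diag(m) <- 0
  m
}

#' Simulate a reference genome and a variant-carrying sample genome
#'
#' Draws a random sequence at the configured GC content, then plants
#' exactly \code{round(genomeLength * snvFraction)} single-base variants
#' at uniformly sampled positions, each altered to one of the three other
#' bases chosen uniformly.  The returned object carries both genomes and
#' the variant list; reads are later drawn from the sample genome and
#' analysed against the reference, mimicking a sequenced strain that
#' differs from its reference assembly.
#'
#' @param config A \code{\linkS4class{SimConfig}}; uses its
#'   \code{genomeLength}, \code{gcContent}, \code{snvFraction} and
#'   \code{seed}.
#' @return A \code{\linkS4class{SimulatedGenome}}.
#' @export
#' @examples
#' g <- simulateGenome(SimConfig(genomeLength = 1000, snvFraction = 0.01,
#'                               seed = 1))
#' g
#' head(as.data.frame(variantTable(g)))
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  L <- config@genomeLength
  gc <- config@gcContent
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  refChars <- sample(.BASES, L, replace = TRUE, prob = probs)
  nSnv <- round(L * config@snvFraction)
  pos <- sort(sample.int(L, nSnv))
  sampleChars <- refChars
  if (nSnv) {
    refAt <- refChars[pos]
    # uniform draw over the three non-reference bases
    shift <- sample.int(3L, nSnv, replace = TRUE)
    altAt <- .BASES[(match(refAt, .BASES) - 1L + shift) %% 4L + 1L]
    sampleChars[pos] <- altAt
    variants <- DataFrame(pos0 = pos - 1L, ref = refAt, alt = altAt)
  } else {
    variants <- DataFrame(pos0 = integer(), ref = character(),
                          alt = character())
  }
  new("SimulatedGenome",
      reference = Biostrings::DNAString(paste(refChars, collapse = "")),
      sample = Biostrings::DNAString(paste(sampleChars, collapse = "")),
      variants = variants)
}
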