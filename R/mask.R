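#' Call a variant mask by frequency consensus
#'
#' Flags reference positions as genomic single-base variants using a
#' transparent frequency rule: a position is masked iff its coverage by
#' qualifying bases (non-N, Phred >= \code{qmin}) is at least
#' \code{minCoverage} and the single most frequent non-reference base
#' accounts for at least \code{altFraction} of those bases.  When two
#' alternative bases tie for the top count, the position is masked if
#' their combined fraction reaches the threshold (conservative
#' exclusion), with a message.  Alleles from reverse-strand reads are
#' complemented into reference orientation before counting.
#'
#' Transcription and sequencing errors are rare and uncorrelated across
#' reads, so they cannot push a position past a majority threshold; a
#' fixed variant is carried by essentially every covering read.
#'
#' @param reads Filtered \code{\linkS4class{AlignedReads}}.
#' @param minCoverage Minimum qualifying coverage (default 10).
#' @param altFraction Minimum alternative-allele fraction, in (0.5, 1]
#'   (default 0.8).
#' @param qmin Phred threshold for a base to count (default 30).
#' @return A \code{\linkS4class{VariantMask}}.
#' @export
callVariantMask <- function(reads, minCoverage = 10L, altFraction = 0.8,
                            qmin = 30L) {
  stopifnot(is(reads, "AlignedReads"))
  if (minCoverage < 1L) .stopf("minCoverage must be >= 1")
  if (!(altFraction > 0.5 && altFraction <= 1))
    .stopf("altFraction must lie in (0.5, 1]")
  Lref <- length(reads@reference)
  empty <- new("VariantMask", pos0 = integer(),
               evidence = DataFrame(pos0 = integer(), coverage = integer(),
                                    altBase = character(),
                                    altFraction = numeric()),
               minCoverage = as.integer(minCoverage),
               altFraction = altFraction)
  if (length(reads) == 0L) return(empty)

  ex <- .expandReads(reads)
  refOrientBase <- ex$readBase
  refOrientBase[!ex$fwd] <- .complement(refOrientBase[!ex$fwd])
  ok <- refOrientBase != "N" & ex$qual >= qmin
  pos1 <- ex$refPos0[ok] + 1L
  obs <- refOrientBase[ok]

  counts <- vapply(.BASES, function(b)
    tabulate(pos1[obs == b], nbins = Lref), integer(Lref))
  coverage <- rowSums(counts)

  refChars <- strsplit(as.character(reads@reference), "")[[1L]]
  refIdx <- match(refChars, .BASES)
  altCounts <- counts
  known <- !is.na(refIdx)
  altCounts[cbind(which(known), refIdx[known])] <- 0L

  ord <- t(apply(altCounts, 1L, sort, decreasing = TRUE))
  top1 <- ord[, 1L]
  top2 <- ord[, 2L]
  frac1 <- ifelse(coverage > 0, top1 / coverage, 0)
  tie <- top1 > 0 & top1 == top2
  fracTie <- ifelse(coverage > 0, (top1 + top2) / coverage, 0)
  masked <- coverage >= minCoverage &
    (frac1 >= altFraction | (tie & fracTie >= altFraction))
  if (any(tie & masked & frac1 < altFraction))
    message(sum(tie & masked & frac1 < altFraction),
            " position(s) masked on a tied alternative-base count")
  pos <- which(masked)
  if (!length(pos)) return(empty)

  topBase <- .BASES[max.col(altCounts[pos, , drop = FALSE],
                            ties.method = "first")]
  new("VariantMask", pos0 = pos - 1L,
      evidence = DataFrame(pos0 = pos - 1L,
                           coverage = as.integer(coverage[pos]),
                           altBase = topBase,
                           altFraction = pmax(frac1, fracTie * tie)[pos]),
      minCoverage = as.integer(minCoverage), altFraction = altFraction)
}

#' Build a variant mask from known positions
#'
#' Wraps an externally supplied exclusion list (e.g. a VCF or TSV of
#' known strain variants) as a \code{\linkS4class{VariantMask}} without
#' evidence rows.
#'
#' @param pos0 0-based reference positions to exclude.
#' @return A \code{\linkS4class{VariantMask}}.
#' @export
variantMaskFromPositions <- function(pos0) {
  new("VariantMask", pos0 = sort(unique(as.integer(pos0))),
      evidence = DataFrame(pos0 = integer(), coverage = integer(),
                           altBase = character(), altFraction = numeric()),
      minCoverage = 1L, altFraction = 1)
}

#' Read a variant mask from a VCF or TSV file
#'
#' Accepts either a minimal VCF (CHROM POS ID REF ALT; POS 1-based) or a
#' TSV with a \code{pos0} column as written by
#' \code{\link{writeSimulatedReads}}.
#'
#' @param path File path.
#' @return A \code{\linkS4class{VariantMask}}.
#' @export
readVariantMask <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    pos1 <- if (length(body))
      as.integer(vapply(strsplit(body, "\t"), `[[`, "", 2L))
    else integer()
    variantMaskFromPositions(pos1 - 1L)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t")
    if (!"pos0" %in% names(tab))
      .stopf("TSV mask file must have a pos0 column")
    variantMaskFromPositions(tab$pos0)
  }
}
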