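# The mismatch statistic: inclusion predicates, per-position counting,
# substitution-specific rates.

# Inclusion predicate shared by numerator and denominator: both bases
# called (non-N), Phred at or above the threshold, reference position
# not masked as a genomic variant.
.includedBases <- function(ex, mask, qmin) {
  inc <- ex$readBase != "N" & ex$refBase != "N" & ex$qual >= qmin
  if (!is.null(mask) && length(mask@pos0))
    inc <- inc & !(ex$refPos0 %in% mask@pos0)
  inc
}

#' Extract quality-thresholded mismatch events
#'
#' Emits one event per read base where the read differs from the
#' reference, subject to the inclusion predicates: neither base is N,
#' the base call has Phred >= \code{qmin}, and the reference position is
#' not in the variant mask.  Read positions are 1-based in sequencing
#' direction; bases are reported in read (RNA) orientation.
#'
#' @param reads Filtered \code{\linkS4class{AlignedReads}}.
#' @param mask A \code{\linkS4class{VariantMask}} or NULL.
#' @param qmin Phred threshold (default 30; bases below are excluded).
#' @return \code{DataFrame} with columns \code{id}, \code{readPos},
#'   \code{refPos0}, \code{refBase}, \code{readBase}, \code{qual}.
#' @export
extractMismatches <- function(reads, mask = NULL, qmin = 30L) {
  stopifnot(is(reads, "AlignedReads"))
  if (length(reads) == 0L)
    return(DataFrame(id = character(), readPos = integer(),
                     refPos0 = integer(), refBase = character(),
                     readBase = character(), qual = integer()))
  ex <- .expandReads(reads)
  sel <- .includedBases(ex, mask, qmin) & ex$readBase != ex$refBase
  DataFrame(id = reads@id[ex$readIdx[sel]],
            readPos = ex$readPos[sel],
            refPos0 = ex$refPos0[sel],
            refBase = ex$refBase[sel],
            readBase = ex$readBase[sel],
            qual = ex$qual[sel])
}

#' Compute the per-read-position error-rate table
#'
#' For every read position p, counts the denominator N(p) — reads
#' covering p whose base there passes the inclusion predicates (non-N
#' read and reference base, Phred >= \code{qmin}, unmasked reference
#' position) — and the numerator M(p), those whose base mismatches the
#' reference, split into the 12 substitution types.  The total rate is
#' E(p) = 100 M(p)/N(p) percent; positions with N(p) = 0 report an
#' undefined (NA) rate, distinct from 0.
#'
#' @inheritParams extractMismatches
#' @return An \code{\linkS4class{ErrorRateTable}}.
#' @export
#' @examples
#' cfg <- SimConfig(genomeLength = 2000, nReads = 200, readLength = 40,
#'                  errorMatrix = makeErrorMatrix(c("C>T" = 0.02)),
#'                  seed = 3)
#' files <- writeSimulatedReads(simulateReads(cfg), tempdir(), "et")
#' reads <- filterAlignments(readAlignments(files["sam"],
#'                                          files["refFasta"]))
#' tab <- computeErrorTable(reads)
#' head(as.data.frame(tab))
computeErrorTable <- function(reads, mask = NULL, qmin = 30L) {
  stopifnot(is(reads, "AlignedReads"))
  P <- if (length(reads)) max(nchar(reads@seq)) else 0L
  nMasked <- if (is.null(mask)) 0L else length(mask@pos0)
  if (P == 0L)
    return(new("ErrorRateTable", readPos = integer(), N = integer(),
               M = integer(),
               subCounts = matrix(0L, 0, 12,
                                  dimnames = list(NULL, .SUBTYPES)),
               qmin = as.integer(qmin), nMasked = nMasked))
  ex <- .expandReads(reads)
  inc <- .includedBases(ex, mask, qmin)
  mm <- inc & ex$readBase != ex$refBase
  N <- tabulate(ex$readPos[inc], nbins = P)
  M <- tabulate(ex$readPos[mm], nbins = P)
  sub <- factor(paste(ex$refBase[mm], ex$readBase[mm], sep = ">"),
                levels = .SUBTYPES)
  subCounts <- table(factor(ex$readPos[mm], levels = seq_len(P)), sub)
  subCounts <- matrix(as.integer(subCounts), P, 12,
                      dimnames = list(NULL, .SUBTYPES))
  new("ErrorRateTable", readPos = seq_len(P), N = as.integer(N),
      M = as.integer(M), subCounts = subCounts,
      qmin = as.integer(qmin), nMasked = nMasked)
}

#' @describeIn ErrorRateTable-class Total error rate E(p) in percent per
#'   read position; NA where the denominator is zero.
#' @param ... Ignored.
#' @export
setMethod("errorRate", "ErrorRateTable", function(x, ...) {
  ifelse(x@N > 0L, 100 * x@M / x@N, NA_real_)
})

#' Substitution-specific error rate at one read position
#'
#' Returns E(p, s) = 100 M(p, s)/N(p) percent, the rate of one specific
#' substitution (e.g. \code{"C>T"} for an RNA-level C-to-U error) at one
#' read position — by default position 7, a mid-read position where
#' base-calling artefacts of the read ends are avoided.
#'
#' @param table An \code{\linkS4class{ErrorRateTable}}.
#' @param readPos 1-based read position (default 7).  A vector of
#'   positions pools numerator and denominator counts across them.
#' @param substitution One of \code{substitutionTypes()}.
#' @return Rate in percent, with attribute \code{"count"} (M(p, s)) and
#'   \code{"denominator"} (N(p)).
#' @export
specificErrorRate <- function(table, readPos = 7L, substitution) {
  stopifnot(is(table, "ErrorRateTable"))
  if (!substitution %in% .SUBTYPES)
    .stopf("unknown substitution '%s'", substitution)
  i <- match(readPos, table@readPos)
  if (anyNA(i))
    .stopf("read position %d not in table", readPos[which(is.na(i))[1L]])
  n <- sum(table@N[i])
  if (n == 0L)
    .stopf("error rate undefined at read position(s) %s (N = 0)",
           paste(readPos, collapse = ","))
  m <- sum(table@subCounts[i, substitution])
  structure(100 * m / n, count = as.integer(m),
            denominator = as.integer(n))
}

#' Compare a substitution-specific rate between two samples
#'
#' Expresses sample a's rate relative to sample b's as a percentage,
#' 100 E_a(p, s) / E_b(p, s), with a binomial standard error propagated
#' to the ratio — the design used to compare in vivo error levels
#' between species at a fixed mid-read position.
#'
#' @param tableA,tableB \code{\linkS4class{ErrorRateTable}}s for the two
#'   samples.
#' @param readPos 1-based read position (default 7); a vector pools
#'   counts across positions.
#' @param substitution One of \code{substitutionTypes()}.
#' @return List with \code{ratioPercent}, \code{sePercent} (first-order
#'   propagated), and the two per-sample rates.
#' @export
compareSamples <- function(tableA, tableB, readPos = 7L, substitution) {
  ea <- specificErrorRate(tableA, readPos, substitution)
  eb <- specificErrorRate(tableB, readPos, substitution)
  if (eb == 0) .stopf("reference sample rate is zero; ratio undefined")
  ratio <- 100 * as.numeric(ea) / as.numeric(eb)
  relVar <- function(e) {
    m <- attr(e, "count"); n <- attr(e, "denominator")
    if (m == 0) return(Inf)
    (1 - m / n) / m   # binomial: var(p)/p^2 = (1-p)/(n p)
  }
  se <- ratio * sqrt(relVar(ea) + relVar(eb))
  list(ratioPercent = ratio, sePercent = se,
       ratePercentA = as.numeric(ea), ratePercentB = as.numeric(eb),
       readPos = readPos, substitution = substitution)
}

#' Write an error-rate table to TSV
#'
#' @param table An \code{\linkS4class{ErrorRateTable}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeErrorRateTable <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
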