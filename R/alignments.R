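#' Read substitution-only alignments from SAM + FASTA
#'
#' Loads mapped records from a SAM file (via Rsamtools) against a single
#' reference sequence from a FASTA file.  Only ungapped alignments
#' (single-M CIGAR) fit the substitution-only mismatch model; records
#' with any other CIGAR are skipped with a warning.  Reverse-strand
#' records (FLAG 16) are reverse-complemented into sequencing
#' orientation, so read positions count in sequencing direction for all
#' reads.  A record is flagged unique when it is neither secondary
#' (0x100) nor supplementary (0x800) and any NH tag equals 1.  Mismatch
#' counts against the reference are recomputed from the bases, never
#' trusted from tags.
#'
#' @param samPath Path to a SAM (or BAM) file.
#' @param fastaPath Path to the reference FASTA.
#' @return An \code{\linkS4class{AlignedReads}}.
#' @export
#' @examples
#' cfg <- SimConfig(genomeLength = 1000, nReads = 20, readLength = 40,
#'                  seed = 2)
#' files <- writeSimulatedReads(simulateReads(cfg), tempdir(), "ex")
#' readAlignments(files["sam"], files["refFasta"])
readAlignments <- function(samPath, fastaPath) {
  fa <- Biostrings::readDNAStringSet(fastaPath)
  if (length(fa) == 0L) .stopf("no sequence in %s", fastaPath)
  names(fa) <- sub("\\s.*$", "", names(fa))

  bam <- if (grepl("\\.bam$", samPath, ignore.case = TRUE)) samPath
         else Rsamtools::asBam(samPath, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  what <- c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = what, tag = "NH"))[[1L]]

  mapped <- !bitwAnd(res$flag, 0x4L)
  simpleM <- grepl("^[0-9]+M$", res$cigar)
  skip <- mapped & !simpleM
  if (any(skip))
    warning(sum(skip), " record(s) with non single-M CIGAR skipped ",
            "(substitution-only alignment model)")
  keep <- which(mapped & simpleM)

  refNames <- as.character(res$rname[keep])
  if (length(keep)) {
    un <- unique(refNames)
    if (length(un) > 1L)
      .stopf("alignments span %d reference sequences; one is supported",
             length(un))
    if (!un %in% names(fa))
      .stopf("reference '%s' not found in %s", un, fastaPath)
    refName <- un
  } else refName <- names(fa)[1L]
  reference <- fa[[refName]]

  seqs <- as.character(res$seq[keep])
  quals <- as(res$qual[keep], "IntegerList")
  flags <- res$flag[keep]
  revSel <- bitwAnd(flags, 0x10L) > 0L
  if (any(revSel)) {
    seqs[revSel] <- .revcompChar(seqs[revSel])
    quals[revSel] <- S4Vectors::endoapply(quals[revSel], rev)
  }
  nh <- res$tag$NH
  uniq <- !bitwAnd(flags, 0x100L) & !bitwAnd(flags, 0x800L)
  if (!is.null(nh)) {
    nhk <- nh[keep]
    uniq <- uniq & (is.na(nhk) | nhk == 1L)
  }

  ar <- new("AlignedReads",
            id = res$qname[keep], refName = refName,
            start0 = res$pos[keep] - 1L,
            strand = as.character(ifelse(revSel, "-", "+")),
            seq = seqs, qual = quals,
            unique = as.logical(uniq),
            mismatches = integer(length(keep)),
            reference = reference)
  ar@mismatches <- .countMismatches(ar)
  ar
}

# Expand an AlignedReads into parallel long vectors, one entry per read
# base, with bases expressed in read (sequencing) orientation and, for
# variant calling, also in reference orientation.
.expandReads <- function(ar) {
  widths <- nchar(ar@seq)
  total <- sum(widths)
  readIdx <- rep.int(seq_along(widths), widths)
  readPos <- sequence(widths)
  fwd <- (ar@strand == "+")[readIdx]
  w <- widths[readIdx]
  refPos0 <- ifelse(fwd, ar@start0[readIdx] + readPos - 1L,
                    ar@start0[readIdx] + w - readPos)
  refCharsGenome <- strsplit(as.character(ar@reference), "")[[1L]]
  refBase <- refCharsGenome[refPos0 + 1L]
  refBase[!fwd] <- .complement(refBase[!fwd])        # read orientation
  readBase <- unlist(strsplit(ar@seq, ""), use.names = FALSE)
  list(readIdx = readIdx, readPos = readPos, refPos0 = refPos0,
       refBase = refBase, readBase = readBase,
       qual = unlist(ar@qual, use.names = FALSE), fwd = fwd,
       total = total)
}

.countMismatches <- function(ar) {
  if (length(ar) == 0L) return(integer())
  ex <- .expandReads(ar)
  mm <- ex$readBase != ex$refBase
  as.integer(tabulate(ex$readIdx[mm], nbins = length(ar)))
}

#' Trim reads to a fixed window
#'
#' Drops the first \code{dropFirst} sequenced bases of every read and
#' keeps the next \code{keepFirst}, applied identically to sequence and
#' qualities; read positions downstream are renumbered from the trimmed
#' start.  Alignment coordinates are adjusted per strand so every
#' retained base keeps its original reference position.
#'
#' @param reads An \code{\linkS4class{AlignedReads}}.
#' @param keepFirst Number of bases to keep after dropping.
#' @param dropFirst Number of leading sequenced bases to drop.
#' @return A trimmed \code{AlignedReads} with recomputed mismatch counts.
#' @export
trimReads <- function(reads, keepFirst, dropFirst = 0L) {
  stopifnot(is(reads, "AlignedReads"))
  if (!.isCount(dropFirst) || dropFirst < 0)
    .stopf("dropFirst must be a non-negative integer")
  if (!.isCount(keepFirst) || keepFirst < 1)
    .stopf("keepFirst must be a positive integer")
  widths <- nchar(reads@seq)
  if (length(widths) && any(dropFirst + keepFirst > widths))
    .stopf("trim window (%d + %d) exceeds a read length (min %d)",
           dropFirst, keepFirst, min(widths))
  from <- dropFirst + 1L
  to <- dropFirst + keepFirst
  out <- reads
  out@seq <- substr(reads@seq, from, to)
  n <- length(widths)
  allQ <- unlist(reads@qual, use.names = FALSE)
  off <- cumsum(c(0L, widths[-n]))
  idx <- sequence(rep.int(keepFirst, n), from = off + from)
  out@qual <- IRanges::relist(
    allQ[idx], IRanges::PartitioningByWidth(rep.int(keepFirst, n)))
  fwdSel <- reads@strand == "+"
  # forward: dropping leading sequenced bases advances the start;
  # reverse: leading sequenced bases sit at the alignment end, so the
  # start moves by what is cut from the far (3'-reference) side.
  out@start0 <- as.integer(ifelse(fwdSel, reads@start0 + dropFirst,
                                  reads@start0 + widths - dropFirst -
                                    keepFirst))
  out@mismatches <- .countMismatches(out)
  validObject(out)
  out
}

#' Filter alignments by mismatch count and uniqueness
#'
#' Retains reads whose mismatch count against the reference is at most
#' \code{maxMismatches} and, if \code{uniqueOnly}, whose alignment is
#' unique — the read-level filters applied before the error statistic
#' (the aligner convention of at most three mismatches and unique
#' placements only).
#'
#' @param reads An \code{\linkS4class{AlignedReads}}.
#' @param maxMismatches Maximum allowed mismatches (default 3).
#' @param uniqueOnly Keep only uniquely aligned reads (default TRUE).
#' @return Filtered \code{AlignedReads}.
#' @export
filterAlignments <- function(reads, maxMismatches = 3L, uniqueOnly = TRUE) {
  stopifnot(is(reads, "AlignedReads"))
  keep <- reads@mismatches <= maxMismatches
  if (uniqueOnly) keep <- keep & reads@unique
  reads[which(keep)]
}
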