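#' Simulate strand-specific reads with three mismatch channels
#'
#' Draws reads from uniform start positions on the sample genome and
#' injects, per base and in this order: (1) a transcription error with
#' the probability given by the configured substitution matrix for the
#' template base; (2) a sequencing error with probability
#' \code{10^(-Q/10)} for that base's sampled Phred score Q, the erroneous
#' base drawn uniformly from the three alternatives of the current
#' (possibly already substituted) base.  Sites where the sample genome
#' differs from the reference contribute the third channel.  Every
#' injected event is enumerated in the truth table; when a transcription
#' and a sequencing error hit the same base both are recorded, the
#' sequencing error acting on the already-substituted base.
#'
#' Reads are sense-strand unless \code{reverseStrandFraction > 0}, in
#' which case that fraction of reads is emitted as reverse-strand
#' alignments (FLAG 16); their sequences and truth events are recorded in
#' sequencing (read) orientation.
#'
#' @param config A \code{\linkS4class{SimConfig}}.
#' @param genome A \code{\linkS4class{SimulatedGenome}}; defaults to
#'   \code{simulateGenome(config)}.
#' @return A \code{\linkS4class{SimulatedReads}}.
#' @seealso \code{\link{writeSimulatedReads}} to emit FASTA/FASTQ/SAM/TSV.
#' @export
#' @examples
#' cfg <- SimConfig(genomeLength = 2000, nReads = 50, readLength = 40,
#'                  errorMatrix = makeErrorMatrix(c("C>T" = 0.01)),
#'                  seed = 7)
#' rds <- simulateReads(cfg)
#' rds
simulateReads <- function(config, genome = simulateGenome(config)) {
  stopifnot(is(config, "SimConfig"), is(genome, "SimulatedGenome"))
  validObject(config)
  if (length(genome@reference) != config@genomeLength)
    .stopf("genome length (%d) does not match config (%d)",
           length(genome@reference), config@genomeLength)
  if (config@readLength > length(genome@reference))
    .stopf("reads longer than the genome cannot be simulated")
  set.seed(config@seed + 1L)

  n <- config@nReads
  L <- config@readLength
  G <- config@genomeLength
  refChars <- strsplit(as.character(genome@reference), "")[[1]]
  samChars <- strsplit(as.character(genome@sample), "")[[1]]

  start1 <- sample.int(G - L + 1L, n, replace = TRUE)
  rev <- rep(FALSE, n)
  if (config@reverseStrandFraction > 0)
    rev <- stats::runif(n) < config@reverseStrandFraction

  # reference position (1-based) of each read base, in sequencing order
  posMat <- matrix(rep(start1, L), n, L) +
    matrix(rep(0:(L - 1L), each = n), n, L)
  if (any(rev))
    posMat[rev, ] <- posMat[rev, L:1, drop = FALSE]

  take <- function(chars) {
    m <- matrix(chars[posMat], n, L)
    if (any(rev))
      m[rev, ] <- matrix(.complement(m[rev, , drop = FALSE]),
                         sum(rev), L)
    m
  }
  refMat <- take(refChars)   # reference base, read orientation
  baseMat <- take(samChars)  # template (sample genome) base

  events <- list()
  addEvents <- function(idx, class, refBase, obsBase) {
    if (!nrow(idx)) return()
    events[[length(events) + 1L]] <<- data.frame(
      readIdx = idx[, 1L], readPos = idx[, 2L],
      refPos0 = posMat[idx] - 1L, class = class,
      refBase = refBase, obsBase = obsBase,
      stringsAsFactors = FALSE)
  }

  # channel 3: fixed variants, visible wherever a read covers one
  snvIdx <- which(baseMat != refMat, arr.ind = TRUE)
  addEvents(snvIdx, "snv", refMat[snvIdx], baseMat[snvIdx])

  # channel 1: transcription errors at the matrix rate for the template base
  em <- config@errorMatrix
  rowRate <- rowSums(em)
  if (any(rowRate > 0)) {
    u <- matrix(stats::runif(n * L), n, L)
    errMask <- u < matrix(rowRate[match(baseMat, .BASES)], n, L)
    if (any(errMask)) {
      preBase <- baseMat
      for (b in .BASES) {
        sel <- which(errMask & preBase == b)
        if (!length(sel)) next
        alts <- setdiff(.BASES, b)
        p <- em[b, alts]
        baseMat[sel] <- if (sum(p) > 0)
          sample(alts, length(sel), replace = TRUE, prob = p)
        else preBase[sel]  # row rate 0 cannot fire; keep base
      }
      tIdx <- which(errMask & baseMat != preBase, arr.ind = TRUE)
      addEvents(tIdx, "transcription_error", preBase[tIdx], baseMat[tIdx])
    }
  }

  # Phred scores: per-position means, truncated to [2, 41]
  qMat <- matrix(stats::rnorm(n * L,
                              mean = rep(config@qualityMean, each = n),
                              sd = config@qualitySd), n, L)
  qMat <- matrix(as.integer(pmin(config@qualityMax, pmax(2, round(qMat)))),
                 n, L)

  # channel 2: sequencing errors at 10^(-Q/10), uniform over alternatives
  pErr <- 10^(-qMat / 10)
  sMask <- matrix(stats::runif(n * L), n, L) < pErr
  if (any(sMask)) {
    sel <- which(sMask)
    cur <- baseMat[sel]
    shift <- sample.int(3L, length(sel), replace = TRUE)
    baseMat[sel] <- .BASES[(match(cur, .BASES) - 1L + shift) %% 4L + 1L]
    sIdx <- which(sMask, arr.ind = TRUE)
    addEvents(sIdx, "sequencing_error", cur, baseMat[sIdx])
  }

  ids <- sprintf("read%06d", seq_len(n))
  truth <- if (length(events)) do.call(rbind, events)
           else data.frame(readIdx = integer(), readPos = integer(),
                           refPos0 = integer(), class = character(),
                           refBase = character(), obsBase = character())
  truth <- truth[order(truth$readIdx, truth$readPos), , drop = FALSE]
  truthDF <- DataFrame(id = ids[truth$readIdx],
                       readPos = as.integer(truth$readPos),
                       refPos0 = as.integer(truth$refPos0),
                       class = truth$class,
                       refBase = truth$refBase,
                       obsBase = truth$obsBase)

  seqs <- apply(baseMat, 1L, paste, collapse = "")
  if (n == 0L) seqs <- character()

  new("SimulatedReads",
      id = ids, start0 = start1 - 1L,
      strand = as.character(ifelse(rev, "-", "+")),
      seq = as.character(seqs), qual = qMat,
      truth = truthDF, genome = genome, config = config)
}

#' Write a simulated read set to standard file formats
#'
#' Emits the reference and sample genomes as FASTA, reads as FASTQ
#' (Phred+33), true placements as a substitution-only SAM (single-M
#' CIGAR, FLAG 0/16, 1-based POS), the truth table as TSV and the
#' variant list as both minimal VCF and TSV.  Output is deterministic:
#' the same \code{SimulatedReads} yields byte-identical files.
#'
#' @param sim A \code{\linkS4class{SimulatedReads}}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the paths written.
#' @export
writeSimulatedReads <- function(sim, dir, prefix = "sim") {
  stopifnot(is(sim, "SimulatedReads"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  refName <- "ref"

  ref <- Biostrings::DNAStringSet(as.character(sim@genome@reference))
  names(ref) <- refName
  Biostrings::writeXStringSet(ref, p(".ref.fasta"))
  smp <- Biostrings::DNAStringSet(as.character(sim@genome@sample))
  names(smp) <- paste0(refName, "_sample")
  Biostrings::writeXStringSet(smp, p(".sample.fasta"))

  n <- length(sim@id)
  qualStr <- vapply(seq_len(max(n, 0L)),
                    function(i) .phredToChar(sim@qual[i, ]), "")
  if (n == 0L) qualStr <- character()
  fq <- file(p(".fastq"), "wb")
  if (n) writeLines(paste0("@", sim@id, "\n", sim@seq, "\n+\n", qualStr),
                    fq, sep = "\n")
  close(fq)

  # SAM stores sequence/quality in reference orientation
  revSel <- sim@strand == "-"
  samSeq <- sim@seq
  samQual <- qualStr
  if (any(revSel)) {
    samSeq[revSel] <- .revcompChar(samSeq[revSel])
    samQual[revSel] <- vapply(samQual[revSel], function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), "",
      USE.NAMES = FALSE)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refName,
                   length(sim@genome@reference)),
           "@PG\tID:rnafidelity\tPN:rnafidelity")
  rec <- if (n) sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                        sim@id, ifelse(revSel, 16L, 0L), refName,
                        sim@start0 + 1L, nchar(sim@seq), samSeq, samQual)
         else character()
  con <- file(p(".sam"), "wb")
  writeLines(c(hdr, rec), con, sep = "\n")
  close(con)

  tt <- as.data.frame(sim@truth)
  utils::write.table(tt, p(".truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  v <- as.data.frame(sim@genome@variants)
  utils::write.table(v, p(".variants.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", refName,
                   length(sim@genome@reference)),
           "#CHROM\tPOS\tID\tREF\tALT")
  if (nrow(v))
    vcf <- c(vcf, sprintf("%s\t%d\t.\t%s\t%s", refName, v$pos0 + 1L,
                          v$ref, v$alt))
  con <- file(p(".variants.vcf"), "wb")
  writeLines(vcf, con, sep = "\n")
  close(con)

  c(refFasta = p(".ref.fasta"), sampleFasta = p(".sample.fasta"),
    fastq = p(".fastq"), sam = p(".sam"), truth = p(".truth.tsv"),
    variantsTsv = p(".variants.tsv"), variantsVcf = p(".variants.vcf"))
}
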