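# Fixture builders and independent oracles shared across test files.
# Oracles here are deliberately naive (explicit per-read loops) so they
# stay independent of the vectorised implementation they check.

# Simulate reads, round-trip through SAM/FASTA on disk, and return the
# pieces most tests need.
simFixture <- function(cfg) {
  sim <- simulateReads(cfg)
  dir <- tempfile("fix")
  files <- writeSimulatedReads(sim, dir)
  reads <- readAlignments(files[["sam"]], files[["refFasta"]])
  list(sim = sim, files = files, reads = reads, dir = dir)
}

# Hand-build an AlignedReads object without going through SAM.
makeAlignedReads <- function(seqs, starts0, quals, reference,
                             strand = rep("+", length(seqs)),
                             unique = rep(TRUE, length(seqs)),
                             ids = sprintf("r%03d", seq_along(seqs))) {
  if (is.numeric(quals))
    quals <- lapply(seqs, function(s) rep(quals, nchar(s)))
  ar <- new("AlignedReads",
            id = ids, refName = "ref",
            start0 = as.integer(starts0), strand = strand,
            seq = seqs, qual = IRanges::IntegerList(quals),
            unique = unique, mismatches = integer(length(seqs)),
            reference = Biostrings::DNAString(reference))
  ar@mismatches <- vapply(seq_along(seqs), function(i)
    naiveMismatchCount(seqs[i], starts0[i], strand[i], reference), 1L)
  ar
}

# Naive per-read mismatch count in read orientation.
naiveMismatchCount <- function(seq, start0, strand, reference) {
  rb <- strsplit(seq, "")[[1]]
  w <- length(rb)
  refb <- strsplit(as.character(reference), "")[[1]][start0 + seq_len(w)]
  if (strand == "-") refb <- rev(chartr("ACGTN", "TGCAN", refb))
  sum(rb != refb)
}

# Independent double-loop recount of N(p), M(p) and M(p, s) applying
# the stated inclusion predicates base by base.
bruteForceCounts <- function(reads, maskPos = integer(), qmin = 30) {
  refChars <- strsplit(as.character(reads@reference), "")[[1]]
  P <- max(nchar(reads@seq))
  types <- substitutionTypes()
  N <- integer(P); M <- integer(P)
  S <- matrix(0L, P, 12, dimnames = list(NULL, types))
  for (i in seq_along(reads@id)) {
    rb <- strsplit(reads@seq[i], "")[[1]]
    q <- reads@qual[[i]]
    w <- length(rb)
    for (p in seq_len(w)) {
      refPos0 <- if (reads@strand[i] == "+") reads@start0[i] + p - 1
                 else reads@start0[i] + w - p
      ref <- refChars[refPos0 + 1]
      if (reads@strand[i] == "-") ref <- chartr("ACGTN", "TGCAN", ref)
      if (rb[p] == "N" || ref == "N") next
      if (q[p] < qmin) next
      if (refPos0 %in% maskPos) next
      N[p] <- N[p] + 1L
      if (rb[p] != ref) {
        M[p] <- M[p] + 1L
        s <- paste0(ref, ">", rb[p])
        S[p, s] <- S[p, s] + 1L
      }
    }
  }
  list(N = N, M = M, S = S)
}

# Resolve the truth table to per-read effective mismatch counts against
# the reference: at each (read, position) the last event's observed base
# is compared with the first event's starting base (the reference).
truthMismatchCounts <- function(sim) {
  tt <- as.data.frame(truthTable(sim))
  n <- length(sim@id)
  out <- setNames(integer(n), sim@id)
  if (!nrow(tt)) return(out)
  key <- paste(tt$id, tt$readPos)
  first <- !duplicated(key)
  last <- !duplicated(key, fromLast = TRUE)
  eff <- tt$obsBase[last] != tt$refBase[first]
  cnt <- tapply(eff, tt$id[first], sum)
  out[names(cnt)] <- as.integer(cnt)
  out
}

# Two-pass grid-search minimiser of a two-parameter SSE surface; the
# independent oracle for the nonlinear least-squares fits.
gridSearchMin <- function(sse, r1, r2, n = 61, passes = 3) {
  for (pass in seq_len(passes)) {
    g1 <- seq(r1[1], r1[2], length.out = n)
    g2 <- seq(r2[1], r2[2], length.out = n)
    vals <- outer(g1, g2, Vectorize(sse))
    ij <- arrayInd(which.min(vals), dim(vals))
    s1 <- diff(r1) / (n - 1); s2 <- diff(r2) / (n - 1)
    r1 <- c(max(r1[1], g1[ij[1]] - 2 * s1), min(r1[2], g1[ij[1]] + 2 * s1))
    r2 <- c(max(r2[1], g2[ij[2]] - 2 * s2), min(r2[2], g2[ij[2]] + 2 * s2))
  }
  list(p1 = g1[ij[1]], p2 = g2[ij[2]], sse = min(vals))
}
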