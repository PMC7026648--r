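# Accessors, show methods and basic S4 plumbing.

#' @rdname SimulatedGenome-class
#' @export
setMethod("referenceSeq", "SimulatedGenome", function(x) x@reference)

#' @rdname SimulatedGenome-class
#' @export
setMethod("sampleSeq", "SimulatedGenome", function(x) x@sample)

#' @rdname SimulatedGenome-class
#' @export
setMethod("variantTable", "SimulatedGenome", function(x) x@variants)

#' @rdname SimulatedReads-class
#' @export
setMethod("truthTable", "SimulatedReads", function(x) x@truth)

#' @rdname SimulatedReads-class
#' @export
setMethod("length", "SimulatedReads", function(x) length(x@id))

#' @rdname AlignedReads-class
#' @export
setMethod("length", "AlignedReads", function(x) length(x@id))

#' @rdname AlignedReads-class
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "AlignedReads", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    id = x@id[i], start0 = x@start0[i], strand = x@strand[i],
    seq = x@seq[i], qual = x@qual[i], unique = x@unique[i],
    mismatches = x@mismatches[i])
})

#' @rdname VariantMask-class
#' @export
setMethod("maskedPositions", "VariantMask", function(x) x@pos0)

#' @rdname VariantMask-class
#' @export
setMethod("length", "VariantMask", function(x) length(x@pos0))

#' @rdname FitResult-class
#' @export
setMethod("estimates", "FitResult", function(x) x@estimates)

#' @rdname FitResult-class
#' @export
setMethod("stdErrors", "FitResult", function(x) x@se)

#' @rdname FitResult-class
#' @export
setMethod("converged", "FitResult", function(x) x@converged)

#' @rdname ModelComparison-class
#' @export
setMethod("selectedModel", "ModelComparison", function(x) x@selected)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@genomeLength, "bp genome (GC",
      object@gcContent, "),", object@nReads, "reads of",
      object@readLength, "bp\n")
  off <- object@errorMatrix; diag(off) <- 0
  cat("  transcription error (total):", sum(off) / 4,
      "| snvFraction:", object@snvFraction,
      "| seed:", object@seed, "\n")
})

setMethod("show", "SimulatedGenome", function(object) {
  cat("SimulatedGenome:", length(object@reference), "bp,",
      nrow(object@variants), "single-base variants\n")
})

setMethod("show", "SimulatedReads", function(object) {
  cls <- table(factor(object@truth$class,
                      c("transcription_error", "sequencing_error", "snv")))
  cat("SimulatedReads:", length(object@id), "reads x",
      ncol(object@qual), "bp\n")
  cat("  truth events:", paste(names(cls), as.integer(cls), sep = "=",
                               collapse = ", "), "\n")
})

setMethod("show", "AlignedReads", function(object) {
  cat("AlignedReads:", length(object@id), "reads on",
      object@refName, sprintf("(%d bp reference)\n",
                              length(object@reference)))
  if (length(object@id))
    cat("  mismatches per read: median",
        stats::median(object@mismatches),
        "| unique:", sum(object@unique), "\n")
})

setMethod("show", "VariantMask", function(object) {
  cat("VariantMask:", length(object@pos0), "positions",
      sprintf("(minCoverage=%d, altFraction=%.2f)\n",
              object@minCoverage, object@altFraction))
})

setMethod("show", "ErrorRateTable", function(object) {
  e <- errorRate(object)
  cat("ErrorRateTable:", length(object@readPos), "read positions,",
      "Q>=", object@qmin, ",", object@nMasked, "masked sites\n")
  cat(sprintf("  total rate: median %.4g%% (N median %d)\n",
              stats::median(e, na.rm = TRUE),
              as.integer(stats::median(object@N))))
})

setMethod("show", "KineticSeries", function(object) {
  cat(sprintf("KineticSeries '%s' (replicate %d): %d points, x in [%g, %g]\n",
              object@condition, object@replicate, length(object@x),
              min(object@x), max(object@x)))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", object@model,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  est <- object@estimates
  for (p in names(est))
    cat(sprintf("  %s = %.6g (se %.3g)\n", p, est[[p]], object@se[[p]]))
  cat(sprintf("  RSS %.4g on %d points", object@rss, object@nObs))
  if (nzchar(object@note)) cat("  [", object@note, "]")
  cat("\n")
})

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison: selected", object@selected,
      sprintf("(dAICc %.2f%s%s)\n", object@delta,
              if (object@ambiguous) ", ambiguous" else "",
              if (object@degenerate) ", degenerate" else ""))
})

#' Convert a KineticSeries to a data.frame
#'
#' @param x A \code{\linkS4class{KineticSeries}}.
#' @param ... Ignored.
#' @return data.frame with columns condition, x, y, replicate.
#' @export
setMethod("as.data.frame", "KineticSeries", function(x, ...) {
  data.frame(condition = x@condition, x = x@x, y = x@y,
             replicate = x@replicate)
})

#' Convert an ErrorRateTable to a data.frame
#'
#' One row per read position: \code{readPos}, \code{N}, \code{M},
#' \code{E_percent}, then the 12 substitution-count columns.
#'
#' @param x An \code{\linkS4class{ErrorRateTable}}.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "ErrorRateTable", function(x, ...) {
  cbind(data.frame(readPos = x@readPos, N = x@N, M = x@M,
                   E_percent = errorRate(x)),
        as.data.frame(x@subCounts))
})
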