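# Shared constants and small helpers.

.BASES <- c("A", "C", "G", "T")

# The 12 possible single-base substitutions, reference>observed, in read
# (RNA) orientation.  Column order used throughout ErrorRateTable.
.SUBTYPES <- as.vector(t(outer(.BASES, .BASES, paste, sep = ">")))[
  as.vector(t(outer(.BASES, .BASES, "!=")))]

#' Substitution type labels
#'
#' The twelve possible reference-to-observed single-base substitutions in
#' \code{"X>Y"} notation (read orientation), in the column order used by
#' \code{\linkS4class{ErrorRateTable}}.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' substitutionTypes()
substitutionTypes <- function() .SUBTYPES

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcompChar <- function(x) {
  vapply(x, function(s) .complement(paste(rev(strsplit(s, "")[[1]]),
                                          collapse = "")), "",
         USE.NAMES = FALSE)
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Phred integer vector -> FASTQ quality string (offset 33)
.phredToChar <- function(q) intToUtf8(q + 33L)

# quality string -> Phred integers
.charToPhred <- function(s) utf8ToInt(s) - 33L

# Small-sample corrected Akaike information criterion for a Gaussian fit.
.aicc <- function(fit, nObs) {
  k <- attr(stats::logLik(fit), "df")
  stats::AIC(fit) + 2 * k * (k + 1) / (nObs - k - 1)
}
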