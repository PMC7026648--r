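# End-to-end demonstration pipeline: simulate -> mask -> error table ->
# sample comparison, plus simulate -> fit for the four kinetic models,
# with a JSON report of recovered versus true parameters.

#' Default run configuration
#'
#' All thresholds and sizes of \code{\link{runDemo}} in one list:
#' simulation sizes, the two transcription error rates being compared,
#' the fidelity thresholds (qmin, maxMismatches, minCoverage,
#' altFraction, readPos) and the kinetic generator settings.  The list
#' round-trips losslessly through YAML via
#' \code{\link{writeRunConfig}} / \code{\link{readRunConfig}}.
#'
#' @param seed Global seed; per-stage child seeds are derived from it
#'   deterministically so stages can be re-run in isolation.
#' @return Named list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genomeLength = 20000L, nReads = 20000L, readLength = 50L,
    gcContent = 0.5,
    errorRateA = 1.25e-3, errorRateB = 1.0e-3, substitution = "C>T",
    snvFraction = 0.005,
    qmin = 30L, maxMismatches = 3L,
    minCoverage = 10L, altFraction = 0.8, readPos = 7L,
    kinetics = list(
      exponential = list(params = list(k = 0.016, A = 1),
                         x = as.numeric(seq(30, 300, by = 30)),
                         noiseSd = 0.02),
      michaelis_menten = list(params = list(kcat = 2, KM = 5),
                              x = c(1, 2, 5, 10, 20, 50),
                              noiseSd = 0.04),
      arrhenius = list(params = list(Ea = 60, A = 1e8),
                       x = as.numeric(273:318), noiseSd = 0.05),
      ph_titration = list(params = list(kmax = 1, pKa = 6.8, n = 1.3),
                          x = as.numeric(seq(5.5, 9.5, by = 0.25)),
                          noiseSd = 0.02)
    )
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config Run-configuration list.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: invisibly the path;
#'   \code{readRunConfig}: the configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ints <- c("seed", "genomeLength", "nReads", "readLength", "qmin",
            "maxMismatches", "minCoverage", "readPos")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("demo stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates two read sets differing only in their transcription error
#' rate, masks variants, computes error tables, compares the two samples
#' at the configured read position, then simulates and fits all four
#' kinetic models, and writes a single JSON report of recovered versus
#' true values with pass flags.  The report is deterministic for a given
#' configuration (no timestamps), so identical seeds give byte-identical
#' reports.
#'
#' @param config Run configuration, see \code{\link{defaultRunConfig}}.
#' @param outDir Output directory for \code{report.json}; NULL skips
#'   writing.
#' @return The report, invisibly as a list.
#' @export
runDemo <- function(config = defaultRunConfig(), outDir = NULL) {
  if (config$nReads <= 0L)
    .stopf("demo stage 'simulate' failed: nReads must be positive")
  sub <- config$substitution
  from <- strsplit(sub, ">")[[1L]][1L]

  simOne <- function(rate, seedOffset) .stage("simulate", {
    cfg <- SimConfig(genomeLength = config$genomeLength,
                     gcContent = config$gcContent,
                     nReads = config$nReads,
                     readLength = config$readLength,
                     errorMatrix = makeErrorMatrix(stats::setNames(rate, sub)),
                     snvFraction = config$snvFraction,
                     seed = config$seed * 100L + seedOffset)
    simulateReads(cfg)
  })
  simA <- simOne(config$errorRateA, 1L)
  simB <- simOne(config$errorRateB, 2L)

  analyse <- function(sim) {
    reads <- .stage("alignments", {
      files <- writeSimulatedReads(sim, tempfile("demo"))
      r <- filterAlignments(readAlignments(files[["sam"]],
                                           files[["refFasta"]]),
                            maxMismatches = config$maxMismatches)
      unlink(dirname(files[["sam"]]), recursive = TRUE)
      r
    })
    mask <- .stage("mask", callVariantMask(reads, config$minCoverage,
                                           config$altFraction, config$qmin))
    tab <- .stage("errorTable", computeErrorTable(reads, mask, config$qmin))
    list(reads = reads, mask = mask, table = tab)
  }
  a <- analyse(simA)
  b <- analyse(simB)

  # headline rates at the configured position; the between-sample ratio
  # pools all read positions for power at demonstration scale
  cmp <- .stage("comparison",
                compareSamples(a$table, b$table,
                               seq_len(config$readLength), sub))
  posRate <- function(tab) tryCatch(
    as.numeric(specificErrorRate(tab, config$readPos, sub)),
    error = function(e) NA_real_)
  trueRatio <- 100 * config$errorRateA / config$errorRateB
  maskRecall <- local({
    truePos <- variantTable(simA@genome)$pos0
    if (!length(truePos)) NA_real_
    else mean(truePos %in% maskedPositions(a$mask))
  })

  fidelity <- list(
    substitution = sub, readPos = config$readPos,
    ratePercentAtPosA = posRate(a$table), ratePercentAtPosB = posRate(b$table),
    ratePercentA = cmp$ratePercentA, ratePercentB = cmp$ratePercentB,
    ratioPercent = cmp$ratioPercent, ratioSePercent = cmp$sePercent,
    trueRatioPercent = trueRatio,
    ratioPass = abs(cmp$ratioPercent - trueRatio) <= 3 * cmp$sePercent,
    maskRecall = maskRecall, maskPass = is.na(maskRecall) || maskRecall >= 0.95)

  kin <- list()
  kseed <- config$seed * 100L + 10L
  for (model in names(config$kinetics)) {
    kc <- config$kinetics[[model]]
    kseed <- kseed + 1L
    series <- .stage("kineticsSimulate",
      simulateKinetics(model, unlist(kc$params), as.numeric(kc$x),
                       noiseSd = kc$noiseSd, seed = kseed)[[1L]])
    fit <- .stage("kineticsFit", switch(model,
      exponential = fitExponential(series),
      michaelis_menten = suppressWarnings(fitMichaelisMenten(series)),
      arrhenius = fitArrhenius(series),
      ph_titration = {
        mc <- analyzePhProfile(series)
        mc@fits[[selectedModel(mc)]]
      }))
    truth <- unlist(kc$params)
    primary <- names(truth)[1L]
    est <- estimates(fit)
    rel <- if (primary %in% names(est))
      abs(est[[primary]] - truth[[primary]]) / truth[[primary]]
    else NA_real_
    kin[[model]] <- list(
      model = fit@model, converged = converged(fit),
      truth = as.list(truth), estimates = as.list(est),
      primaryParameter = primary, relError = rel,
      pass = isTRUE(converged(fit)) && is.finite(rel) && rel <= 0.15)
  }

  report <- list(
    config = config,
    fidelity = fidelity,
    kinetics = kin,
    allPass = fidelity$ratioPass && fidelity$maskPass &&
      all(vapply(kin, function(k) isTRUE(k$pass), TRUE))
  )
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
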