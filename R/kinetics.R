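# Kinetic model fitting: single-exponential time courses,
# Michaelis-Menten titrations, Arrhenius temperature dependence.

#' Gas constant, J mol-1 K-1
#' @export
GAS_CONSTANT <- 8.314

#' Construct a kinetic series
#'
#' @param x Predictor values (time s, concentration mM, temperature K,
#'   or pH); sorted on construction.
#' @param y Responses (fraction reacted or rate in 1/s).
#' @param condition Condition label.
#' @param replicate Replicate number.
#' @return A \code{\linkS4class{KineticSeries}}.
#' @export
KineticSeries <- function(x, y, condition = "series", replicate = 1L) {
  o <- order(x)
  new("KineticSeries", x = as.numeric(x)[o], y = as.numeric(y)[o],
      condition = as.character(condition), replicate = as.integer(replicate))
}

#' Read kinetic series from a tidy CSV
#'
#' Expects columns \code{condition}, \code{x}, \code{y},
#' \code{replicate}; returns one \code{\linkS4class{KineticSeries}} per
#' (condition, replicate) pair.
#'
#' @param path CSV path.
#' @return Named list of \code{KineticSeries}.
#' @export
readKineticCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "x", "y", "replicate")
  if (!all(need %in% names(tab)))
    .stopf("kinetic CSV needs columns %s", paste(need, collapse = ", "))
  parts <- split(tab, interaction(tab$condition, tab$replicate,
                                  drop = TRUE, sep = "#"))
  out <- lapply(parts, function(d)
    KineticSeries(d$x, d$y, d$condition[1L], d$replicate[1L]))
  names(out) <- names(parts)
  out
}

#' Write kinetic series to a tidy CSV
#'
#' @param series A \code{KineticSeries} or list of them.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeKineticCSV <- function(series, path) {
  if (is(series, "KineticSeries")) series <- list(series)
  tab <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(tab[, c("condition", "x", "y", "replicate")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

.seriesXY <- function(series, minPoints = 3L) {
  if (is(series, "KineticSeries")) d <- as.data.frame(series)
  else if (is.data.frame(series)) d <- series
  else .stopf("series must be a KineticSeries or data.frame with x, y")
  if (!all(c("x", "y") %in% names(d)))
    .stopf("series needs x and y columns")
  if (nrow(d) < minPoints)
    .stopf("at least %d points are needed for this fit", minPoints)
  list(x = as.numeric(d$x), y = as.numeric(d$y))
}

.fitResult <- function(model, est, se, rss, nObs, converged, note = "") {
  if (converged && any(!is.finite(se))) {
    converged <- FALSE
    note <- paste(note, "non-finite standard error")
  }
  new("FitResult", model = model, estimates = est,
      se = stats::setNames(as.numeric(se), names(est)), rss = rss,
      nObs = as.integer(nObs), converged = converged,
      note = trimws(note))
}

.failedFit <- function(model, parNames, nObs, note) {
  est <- stats::setNames(rep(NA_real_, length(parNames)), parNames)
  .fitResult(model, est, est, NA_real_, nObs, FALSE, note)
}

# Bounded Levenberg-Marquardt fit with summary extraction.
.nlsFit <- function(model, formula, data, start, lower, upper, parNames,
                    note = "") {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(.failedFit(model, parNames, nrow(data), conditionMessage(fit)))
  co <- summary(fit)$coefficients
  est <- stats::setNames(co[parNames, "Estimate"], parNames)
  se <- co[parNames, "Std. Error"]
  res <- .fitResult(model, est, se, sum(stats::resid(fit)^2),
                    nrow(data), TRUE, note)
  attr(res, "fit") <- fit
  res
}

#' Fit a single-exponential time course
#'
#' Least-squares fit of y(t) = A (1 - exp(-k t)), the model for
#' single-turnover reaction progress (fraction of RNA cleaved or
#' elongated against time).  The rate is bounded non-negative and the
#' amplitude to (0, 1.1], allowing slight overshoot of a full-fraction
#' plateau under noise.  Starting values are derived from the data: the
#' amplitude from the final plateau, the rate from the initial slope
#' over the amplitude.
#'
#' @param series A \code{\linkS4class{KineticSeries}} (time in s,
#'   response a fraction) or data.frame with \code{x}, \code{y}.
#' @return A \code{\linkS4class{FitResult}} with parameters \code{k}
#'   (1/s) and \code{A}.  Non-convergence and degenerate (all-zero)
#'   input are flagged, not raised.
#' @export
#' @examples
#' s <- simulateKinetics("exponential", c(k = 0.5, A = 1),
#'                       x = seq(0.5, 5, 0.5), noiseSd = 0, seed = 1)[[1]]
#' fitExponential(s)
fitExponential <- function(series) {
  d <- .seriesXY(series, 3L)
  if (all(d$y == 0))
    return(.failedFit("exponential", c("k", "A"), length(d$x),
                      "degenerate: all-zero response, rate undefined"))
  A0 <- max(stats::quantile(d$y, 0.9), 1e-3)
  pos <- which(d$x > 0 & d$y > 0)
  k0 <- if (length(pos)) max((d$y[pos[1L]] / d$x[pos[1L]]) / A0, 1e-4)
        else 1e-2
  .nlsFit("exponential", y ~ A * (1 - exp(-k * x)),
          data = data.frame(x = d$x, y = d$y),
          start = list(k = k0, A = min(A0, 1.05)),
          lower = c(k = 0, A = 1e-6), upper = c(k = Inf, A = 1.1),
          parNames = c("k", "A"))
}

#' Fit the Michaelis-Menten equation
#'
#' Least-squares fit of v(c) = kcat c / (KM + c), used for the
#' magnesium dependence of the proofreading hydrolysis rate.  Starting
#' values come from the Lineweaver-Burk linearisation; both parameters
#' are bounded positive.  Data that do not span the half-saturation
#' point give a warning, and a KM escaping far beyond the measured
#' concentration range (monotone, effectively linear data) is flagged.
#'
#' @param series A \code{\linkS4class{KineticSeries}} (concentration in
#'   mM, rate in 1/s) or data.frame with \code{x}, \code{y}.
#' @return A \code{\linkS4class{FitResult}} with parameters \code{kcat}
#'   and \code{KM}.
#' @export
fitMichaelisMenten <- function(series) {
  d <- .seriesXY(series, 4L)
  if (any(d$x <= 0)) .stopf("concentrations must be positive")
  # Lineweaver-Burk seed: 1/v = 1/kcat + (KM/kcat) (1/c)
  ok <- d$y > 0
  seed <- c(kcat = max(d$y), KM = stats::median(d$x))
  if (sum(ok) >= 2) {
    lb <- stats::lm(I(1 / y) ~ I(1 / x),
                    data = data.frame(x = d$x[ok], y = d$y[ok]))
    b <- stats::coef(lb)
    if (is.finite(b[1L]) && b[1L] > 0) {
      kc <- unname(1 / b[1L])
      km <- unname(b[2L] * kc)
      if (is.finite(km) && km > 0) seed <- c(kcat = kc, KM = km)
    }
  }
  res <- .nlsFit("michaelis_menten", y ~ kcat * x / (KM + x),
                 data = data.frame(x = d$x, y = d$y),
                 start = as.list(seed),
                 lower = c(kcat = 1e-12, KM = 1e-12),
                 upper = c(kcat = Inf, KM = Inf),
                 parNames = c("kcat", "KM"))
  if (res@converged) {
    km <- res@estimates[["KM"]]
    if (km > 50 * max(d$x)) {
      res@converged <- FALSE
      res@note <- "KM far beyond measured range: data effectively linear"
    } else if (km < min(d$x) || km > max(d$x))
      warning("concentrations do not span the fitted half-saturation point")
  }
  res
}

#' Fit an Arrhenius plot
#'
#' Ordinary least squares of ln k on 1/T: ln k = ln A - (Ea/R) (1/T).
#' The activation energy is Ea = -slope * R with its standard error
#' propagated from the slope; R = 8.314 J mol-1 K-1 and Ea is reported
#' in kJ mol-1.  Being linear, this fit is exact (no iteration).
#'
#' @param series A \code{\linkS4class{KineticSeries}} or data.frame with
#'   \code{x} (temperature), \code{y} (rate in 1/s, all positive).
#' @param temperatureUnit \code{"K"} (default) or \code{"C"}; Celsius
#'   input is converted to Kelvin internally.
#' @return A \code{\linkS4class{FitResult}} with parameters \code{Ea}
#'   (kJ/mol) and \code{lnA}.
#' @export
fitArrhenius <- function(series, temperatureUnit = c("K", "C")) {
  temperatureUnit <- match.arg(temperatureUnit)
  d <- .seriesXY(series, 3L)
  if (any(d$y <= 0))
    .stopf("all rates must be positive for an Arrhenius fit (log taken)")
  TK <- if (temperatureUnit == "C") d$x + 273.15 else d$x
  if (any(TK <= 0)) .stopf("absolute temperatures must be positive")
  fit <- stats::lm(lnk ~ invT,
                   data = data.frame(invT = 1 / TK, lnk = log(d$y)))
  co <- summary(fit)$coefficients
  est <- c(Ea = -co["invT", "Estimate"] * GAS_CONSTANT / 1000,
           lnA = co["(Intercept)", "Estimate"])
  se <- c(Ea = co["invT", "Std. Error"] * GAS_CONSTANT / 1000,
          lnA = co["(Intercept)", "Std. Error"])
  .fitResult("arrhenius", est, se, sum(stats::resid(fit)^2),
             length(TK), TRUE)
}

#' Fold change between two fitted parameters
#'
#' Ratio of one parameter between two fits of the same model, with a
#' first-order (delta-method) standard error:
#' se(a/b) = (a/b) sqrt((se_a/a)^2 + (se_b/b)^2).
#'
#' @param resultA,resultB \code{\linkS4class{FitResult}}s of the same
#'   model.
#' @param parameter Parameter name present in both.
#' @return List with \code{ratio}, \code{se} and the inputs' values.
#' @export
foldChange <- function(resultA, resultB, parameter) {
  stopifnot(is(resultA, "FitResult"), is(resultB, "FitResult"))
  if (resultA@model != resultB@model)
    .stopf("fold change requires the same model (%s vs %s)",
           resultA@model, resultB@model)
  for (r in list(resultA, resultB))
    if (!parameter %in% names(r@estimates))
      .stopf("parameter '%s' absent from a %s fit", parameter, r@model)
  a <- resultA@estimates[[parameter]]
  b <- resultB@estimates[[parameter]]
  if (!is.finite(b) || b <= 0)
    .stopf("denominator parameter must be positive and finite")
  sa <- resultA@se[[parameter]]
  sb <- resultB@se[[parameter]]
  ratio <- a / b
  list(ratio = ratio,
       se = abs(ratio) * sqrt((sa / a)^2 + (sb / b)^2),
       parameter = parameter, valueA = a, valueB = b)
}
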