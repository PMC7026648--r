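#' Simulate noisy kinetic series from a named model
#'
#' Generates responses from one of the five kinetic models at the given
#' true parameters, adds i.i.d. Gaussian noise, and returns one
#' \code{\linkS4class{KineticSeries}} per replicate.  Model forms:
#' \describe{
#'   \item{exponential}{y(t) = A (1 - exp(-k t)); parameters \code{k},
#'     \code{A}; x = time (s, >= 0).}
#'   \item{michaelis_menten}{v(c) = kcat c / (KM + c); parameters
#'     \code{kcat}, \code{KM}; x = concentration (> 0).}
#'   \item{arrhenius}{k(T) = A exp(-Ea / (R T)) with R = 8.314
#'     J mol-1 K-1; parameters \code{Ea} (kJ/mol), \code{A}; x =
#'     absolute temperature (K, > 0).  Noise is applied to ln k
#'     (multiplicative), matching how rate errors behave.}
#'   \item{ph_loglinear}{log10 k = c0 + g pH; parameters \code{c0},
#'     \code{g}; noise applied to log10 k.}
#'   \item{ph_titration}{k(pH) = kmax / (1 + 10^(n (pKa - pH)));
#'     parameters \code{kmax}, \code{pKa}, \code{n}; noise applied to
#'     log10 k.}
#' }
#'
#' @param model Model name (one of the five above).
#' @param params Named numeric vector of true parameters.
#' @param x Design points (times, concentrations, temperatures in K, or
#'   pH values).
#' @param noiseSd Gaussian noise standard deviation (on the response
#'   scale noted per model above).
#' @param nReplicates Number of replicate series.
#' @param seed Integer seed.
#' @param condition Condition label stored in each series.
#' @return List of \code{nReplicates} \code{KineticSeries}.
#' @export
#' @examples
#' simulateKinetics("michaelis_menten", c(kcat = 2, KM = 5),
#'                  x = c(1, 2, 5, 10, 20, 50), noiseSd = 0,
#'                  seed = 1)[[1]]
simulateKinetics <- function(model, params, x, noiseSd = 0,
                             nReplicates = 1L, seed = 1L,
                             condition = model) {
  if (noiseSd < 0) .stopf("noiseSd must be >= 0")
  mu <- kineticModelValue(model, params, x)   # validates model and x
  logScale <- model %in% c("arrhenius", "ph_loglinear", "ph_titration")
  set.seed(as.integer(seed))
  lapply(seq_len(nReplicates), function(r) {
    eps <- stats::rnorm(length(x), 0, noiseSd)
    y <- if (model == "arrhenius") exp(log(mu) + eps)
         else if (logScale) 10^(log10(mu) + eps)
         else mu + eps
    KineticSeries(x, y, condition = condition, replicate = r)
  })
}

#' Evaluate a kinetic model at given parameters
#'
#' Noise-free model value; also validates the model name, required
#' parameters and design-point domain.
#'
#' @inheritParams simulateKinetics
#' @return Numeric vector of model values at \code{x}.
#' @export
kineticModelValue <- function(model, params, x) {
  p <- function(nm) {
    if (!nm %in% names(params))
      .stopf("model '%s' requires parameter '%s'", model, nm)
    params[[nm]]
  }
  switch(model,
    exponential = {
      if (any(x < 0)) .stopf("times must be >= 0")
      p("A") * (1 - exp(-p("k") * x))
    },
    michaelis_menten = {
      if (any(x <= 0)) .stopf("concentrations must be > 0")
      p("kcat") * x / (p("KM") + x)
    },
    arrhenius = {
      if (any(x <= 0)) .stopf("absolute temperatures must be > 0")
      p("A") * exp(-p("Ea") * 1000 / (GAS_CONSTANT * x))
    },
    ph_loglinear = 10^(p("c0") + p("g") * x),
    ph_titration = p("kmax") / (1 + 10^(p("n") * (p("pKa") - x))),
    .stopf("unknown kinetic model '%s'", model))
}
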