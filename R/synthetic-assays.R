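#' Simulate fluorescence-polarization binding titrations
#'
#' Draws replicate binding curves from the four-parameter logistic model
#' with additive Gaussian noise on the polarization signal. Defaults mirror
#' a typical splayed-duplex titration: 12 log-spaced protein concentrations
#' from 1 nM to 3 uM against a 10 nM probe, top 200 mP, bottom 50 mP,
#' hill 1, noise sd 2 mP.
#'
#' @param kd,top,bottom,hill generating parameters (kd in molar, signal in
#'   mP).
#' @param conc protein concentrations (molar).
#' @param noiseSd additive Gaussian noise sd (mP).
#' @param replicates number of curves.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param probeConc probe concentration (molar), recorded in the truth
#'   attribute.
#' @return list of data frames (`conc`, `signal`), with attribute `truth`
#'   holding the generating parameters and seed.
#' @export
simulateBindingCurves <- function(kd = 29e-9, top = 200, bottom = 50,
                                  hill = 1,
                                  conc = logSpaced(1e-9, 3e-6, 12),
                                  noiseSd = 2, replicates = 1, seed = 1,
                                  probeConc = 10e-9) {
  stopifnot(kd > 0, hill > 0, all(conc > 0), noiseSd >= 0, replicates >= 1)
  set.seed(seed)
  ideal <- fourPL(conc, kd, top, bottom, hill)
  out <- lapply(seq_len(replicates), function(i)
    data.frame(conc = conc,
               signal = ideal + stats::rnorm(length(conc), sd = noiseSd)))
  attr(out, "truth") <- list(model = "fourpl", kd = kd, top = top,
                             bottom = bottom, hill = hill,
                             noiseSd = noiseSd, probeConc = probeConc,
                             seed = seed)
  out
}

#' Simulate ATPase rate-versus-ATP curves
#'
#' Draws replicate Michaelis-Menten rate curves with proportional Gaussian
#' noise on the rates. Defaults mirror the coupled ATPase assay design:
#' 8 log-spaced ATP concentrations from 3 uM to 0.8 mM.
#'
#' @param kcat,km generating parameters (min^-1, molar).
#' @param substrate ATP concentrations (molar).
#' @param noiseCV proportional noise: sd of a rate is `noiseCV` times its
#'   ideal value.
#' @param replicates number of curves.
#' @param seed RNG seed.
#' @return list of data frames (`substrate`, `rate`), with attribute
#'   `truth`.
#' @export
simulateRateCurves <- function(kcat = 631, km = 43e-6,
                               substrate = logSpaced(3e-6, 8e-4, 8),
                               noiseCV = 0.05, replicates = 1, seed = 1) {
  stopifnot(kcat > 0, km > 0, all(substrate > 0), noiseCV >= 0,
            replicates >= 1)
  set.seed(seed)
  ideal <- michaelisMenten(substrate, kcat, km)
  out <- lapply(seq_len(replicates), function(i)
    data.frame(substrate = substrate,
               rate = ideal * (1 + stats::rnorm(length(ideal),
                                                sd = noiseCV))))
  attr(out, "truth") <- list(model = "mm", kcat = kcat, km = km,
                             noiseCV = noiseCV, seed = seed)
  out
}

#' Simulate NADH-absorbance progress traces
#'
#' Synthesizes linear-phase A340 traces for the coupled ATPase assay:
#' A340(t) = A0 - extinction * pathlength * \[E\] * v * t, where
#' v = turnover * \[E\] is the hydrolysis rate, plus additive Gaussian
#' absorbance noise. The default A0 of 1.25 corresponds to 0.2 mM NADH at
#' extinction 6250 over a 1 cm path.
#'
#' @param turnover generating turnover (min^-1).
#' @param enzymeConc enzyme concentration (molar).
#' @param extinction,pathlength Beer-Lambert constants (default 6250, 1).
#' @param duration trace length in seconds (default 600: a 10 min linear
#'   window).
#' @param dt sampling interval in seconds (default 15).
#' @param a0 starting absorbance.
#' @param noiseSd additive absorbance noise sd.
#' @param replicates number of traces.
#' @param seed RNG seed.
#' @return list of data frames (`time` in s, `a340`), with attribute
#'   `truth`.
#' @export
simulateAbsorbanceTraces <- function(turnover = 0.72, enzymeConc = 1e-6,
                                     extinction = 6250, pathlength = 1,
                                     duration = 600, dt = 15, a0 = 1.25,
                                     noiseSd = 0.002, replicates = 1,
                                     seed = 1) {
  stopifnot(turnover >= 0, enzymeConc > 0, extinction > 0, pathlength > 0,
            duration > 0, dt > 0, noiseSd >= 0, replicates >= 1)
  set.seed(seed)
  tGrid <- seq(0, duration, by = dt)
  slopePerSec <- extinction * pathlength * enzymeConc * turnover / 60
  ideal <- a0 - slopePerSec * tGrid
  out <- lapply(seq_len(replicates), function(i)
    data.frame(time = tGrid,
               a340 = ideal + stats::rnorm(length(tGrid), sd = noiseSd)))
  attr(out, "truth") <- list(model = "trace", turnover = turnover,
                             enzymeConc = enzymeConc,
                             extinction = extinction,
                             pathlength = pathlength, a0 = a0,
                             noiseSd = noiseSd, seed = seed)
  out
}

#' Generate an assay dataset from a declarative specification
#'
#' Dispatches to the binding-curve, rate-curve or absorbance-trace
#' simulator according to `spec$model` ("fourpl", "mm" or "trace"); all
#' other list entries are passed on as arguments.
#'
#' @param spec list with a `model` element and simulator arguments.
#' @return the corresponding simulator output (list of data frames with a
#'   `truth` attribute).
#' @examples
#' d <- makeAssayDataset(list(model = "mm", kcat = 600, km = 50e-6,
#'                            noiseCV = 0, seed = 1))
#' kcat(fitMichaelisMenten(d[[1]]))
#' @export
makeAssayDataset <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$model))
  model <- spec$model
  spec$model <- NULL
  fn <- switch(model,
               fourpl = simulateBindingCurves,
               mm = simulateRateCurves,
               trace = simulateAbsorbanceTraces,
               stop("unknown assay model: ", model))
  do.call(fn, spec)
}
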