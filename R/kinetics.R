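#' Model functions
#'
#' `michaelisMenten()` is the rate law v = kcat * S / (Km + S);
#' `fourPL()` is the four-parameter logistic binding model
#' FP(x) = bottom + (top - bottom) / (1 + (Kd / x)^hill).
#'
#' @param S,x substrate / titrant concentration.
#' @param kcat,km Michaelis-Menten parameters.
#' @param kd,top,bottom,hill four-parameter-logistic parameters.
#' @return model response, vectorised over `S`/`x`.
#' @export
michaelisMenten <- function(S, kcat, km) kcat * S / (km + S)

#' @rdname michaelisMenten
#' @export
fourPL <- function(x, kd, top, bottom, hill = 1)
  bottom + (top - bottom) / (1 + (kd / x)^hill)

#' Convert an NADH-absorbance progress trace to an ATP turnover rate
#'
#' In the pyruvate-kinase / lactate-dehydrogenase coupled assay each ATP
#' hydrolysed consumes one NADH, so the loss of absorbance at 340 nm
#' (extinction coefficient 6250 per molar per cm) reports the hydrolysis
#' rate. The initial rate is the least-squares slope over the stated initial
#' fraction of the trace, converted by Beer-Lambert to molar per minute and
#' divided by the enzyme concentration to give turnover per minute.
#'
#' @param trace data frame with columns `time` (seconds) and `a340`
#'   (absorbance units), time strictly increasing.
#' @param enzymeConc enzyme concentration (molar).
#' @param extinction NADH extinction coefficient (per molar per cm,
#'   default 6250).
#' @param pathlength optical path (cm). Default 1 cm, a nominal value: small
#'   assay volumes in microplate wells have shorter paths, so supply the
#'   calibrated value for quantitative work.
#' @param window fraction (0, 1] of the trace, from the start, treated as
#'   the initial linear phase (default 1: the whole trace).
#' @param r2Floor minimum R-squared of the linear fit below which a
#'   "poor-linearity" note is attached (default 0.9). The result is still
#'   returned; this is a data-quality flag, not an error.
#' @return turnover in min^-1 (numeric scalar) with attributes `slope`
#'   (absorbance/min), `r2` and `notes` (character vector; negative computed
#'   turnover is clipped to 0 and noted).
#' @examples
#' tr <- data.frame(time = 0:60, a340 = 1.25 - 0.00625 / 60 * (0:60))
#' traceToRate(tr, enzymeConc = 20e-9)  # 50 turnovers per minute
#' @export
traceToRate <- function(trace, enzymeConc, extinction = 6250,
                        pathlength = 1, window = 1, r2Floor = 0.9) {
  stopifnot(all(c("time", "a340") %in% names(trace)),
            extinction > 0, pathlength > 0, enzymeConc > 0,
            window > 0, window <= 1)
  if (any(diff(trace$time) <= 0)) stop("time must be strictly increasing")
  tmax <- min(trace$time) + window * diff(range(trace$time))
  w <- trace[trace$time <= tmax + 1e-12, , drop = FALSE]
  if (nrow(w) < 4) stop("fewer than 4 points in the linear window")
  fit <- stats::lm(a340 ~ time, data = w)
  slopePerMin <- unname(stats::coef(fit)["time"]) * 60
  r2 <- suppressWarnings(summary(fit)$r.squared)
  notes <- character()
  if (is.na(r2) || r2 < r2Floor)
    notes <- c(notes, sprintf("poor-linearity (R^2 = %.3f)", r2))
  turnover <- (-slopePerMin) / (extinction * pathlength) / enzymeConc
  if (turnover < 0) {
    if (turnover < -1e-12) {
      notes <- c(notes, "negative rate clipped to 0")
      warning("negative computed turnover clipped to 0", call. = FALSE)
    }
    turnover <- 0
  }
  structure(turnover, slope = slopePerMin, r2 = r2, notes = notes)
}

.nlsLMFit <- function(resFun, starts, lower, residArgs) {
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resFun, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  best
}

.lmSE <- function(fit, nObs) {
  np <- length(fit$par)
  tryCatch(
    suppressWarnings(unname(summary(fit)$coefficients[, "Std. Error"])),
    error = function(e) rep(NA_real_, np))
}

#' Fit the Michaelis-Menten model to a rate curve
#'
#' Nonlinear least squares of v = kcat * S / (Km + S) by
#' Levenberg-Marquardt, started from three deterministic initialisations
#' (the best residual sum of squares is kept). Rates are expected as
#' turnover (min^-1), so the fitted maximal rate is kcat directly.
#'
#' @param curve data frame with columns `substrate` (molar) and `rate`
#'   (min^-1), or two numeric vectors via `substrate=`/`rate=`.
#' @param substrate,rate alternative vector interface.
#' @return an [MMFit-class].
#' @examples
#' d <- data.frame(substrate = logSpaced(3e-6, 8e-4, 8))
#' d$rate <- michaelisMenten(d$substrate, kcat = 600, km = 50e-6)
#' fitMichaelisMenten(d)
#' @export
fitMichaelisMenten <- function(curve = NULL, substrate = NULL, rate = NULL) {
  if (!is.null(curve)) {
    substrate <- curve$substrate; rate <- curve$rate
  }
  stopifnot(length(substrate) == length(rate), all(substrate > 0),
            all(is.finite(rate)))
  if (length(unique(substrate)) < 4)
    stop("need >= 4 distinct substrate concentrations")
  resFun <- function(p) rate - michaelisMenten(substrate, p[1], p[2])
  v0 <- max(rate)
  starts <- list(c(kcat = v0, km = stats::median(substrate)),
                 c(kcat = 1.5 * v0, km = max(substrate) / 2),
                 c(kcat = v0, km = min(substrate) * 2))
  best <- .nlsLMFit(resFun, starts, lower = c(1e-12, 1e-15), residArgs = NULL)
  if (is.null(best))
    stop("fit-failure: Michaelis-Menten fit did not converge from any of ",
         length(starts), " starts (n = ", length(rate), " points, max rate ",
         signif(v0, 3), ")")
  p <- best$fit$par
  se <- .lmSE(best$fit, length(rate))
  names(se) <- c("kcat", "km")
  new("MMFit", kcat = unname(p[1]), km = unname(p[2]), se = se,
      rss = best$rss, nPoints = length(rate), converged = TRUE,
      notes = character())
}

.fourPLStarts <- function(conc, signal) {
  bottom0 <- min(signal); top0 <- max(signal)
  half <- (bottom0 + top0) / 2
  above <- which(signal >= half)
  kd0 <- if (length(above)) conc[above[1]] else stats::median(conc)
  lapply(c(0.3, 1, 3), function(f)
    c(kd = kd0 * f, top = top0, bottom = bottom0, hill = 1))
}

.extrapolationNote <- function(kdHat, conc) {
  if (kdHat > 10 * max(conc) || kdHat < min(conc) / 10)
    sprintf("extrapolated Kd (%.3g) outside measured range [%.3g, %.3g]",
            kdHat, min(conc), max(conc))
  else character()
}

#' Fit four-parameter-logistic binding curves
#'
#' Fits FP(x) = bottom + (top - bottom) / (1 + (Kd / x)^hill) to one or more
#' fluorescence-polarization titrations by Levenberg-Marquardt least squares
#' with three deterministic starts. With `shareTop = TRUE` a single top
#' (maximal signal) parameter is estimated jointly across all curves while
#' Kd, bottom and hill stay per-curve - the constrained fit used when
#' individual weak-binding curves do not reach saturation. Fixing
#' `hill = 1` reduces the model to a hyperbolic (single-site) isotherm; the
#' same routine can be applied to rate-versus-ATP data for fidelity checks
#' against the Michaelis-Menten fit.
#'
#' @param curves a data frame with columns `conc` (molar) and `signal` (mP),
#'   or a list of such data frames.
#' @param shareTop estimate one common top across curves (requires >= 2
#'   curves).
#' @param fixHill optional fixed Hill coefficient (e.g. 1); `NULL` fits it.
#' @return a list of [BindingFit-class] objects (one per curve, named after
#'   the list names when present). Kd estimates more than 10-fold outside
#'   the measured concentration range carry an extrapolation note.
#' @examples
#' d <- data.frame(conc = logSpaced(1e-9, 3e-6, 12))
#' d$signal <- fourPL(d$conc, kd = 29e-9, top = 200, bottom = 50)
#' fitBinding4PL(d)[[1]]
#' @export
fitBinding4PL <- function(curves, shareTop = FALSE, fixHill = NULL) {
  if (is.data.frame(curves)) curves <- list(curves)
  m <- length(curves)
  stopifnot(m >= 1)
  for (cv in curves) {
    stopifnot(all(c("conc", "signal") %in% names(cv)), all(cv$conc > 0))
    if (nrow(cv) < 5) stop("each curve needs >= 5 points")
  }
  if (shareTop && m < 2) stop("shared-top fitting requires >= 2 curves")
  fitHill <- is.null(fixHill)

  fitOne <- function(cv) {
    conc <- cv$conc; y <- cv$signal
    resFun <- function(p) {
      hill <- if (fitHill) p[4] else fixHill
      y - fourPL(conc, p[1], p[2], p[3], hill)
    }
    starts <- lapply(.fourPLStarts(conc, y), function(p)
      if (fitHill) p else p[1:3])
    lower <- if (fitHill) c(1e-15, -Inf, -Inf, 1e-6) else c(1e-15, -Inf, -Inf)
    best <- .nlsLMFit(resFun, starts, lower, NULL)
    if (is.null(best))
      stop("fit-failure: 4PL fit did not converge (n = ", length(y), ")")
    p <- best$fit$par
    se <- .lmSE(best$fit, length(y))
    names(se) <- c("kd", "top", "bottom", if (fitHill) "hill")
    if (!fitHill) se <- c(se, hill = 0)
    hill <- if (fitHill) unname(p[4]) else fixHill
    new("BindingFit", kd = unname(p[1]), top = unname(p[2]),
        bottom = unname(p[3]), hill = hill,
        se = se[c("kd", "top", "bottom", "hill")], rss = best$rss,
        nPoints = nrow(cv), sharedTopGroup = NA_character_,
        notes = .extrapolationNote(unname(p[1]), conc))
  }

  if (!shareTop) {
    fits <- lapply(curves, fitOne)
    names(fits) <- names(curves)
    return(fits)
  }

  # shared top: parameters [top, (kd_i, bottom_i, hill_i?) x m], started
  # from the independent per-curve fits
  indep <- lapply(curves, fitOne)
  perCurve <- if (fitHill) 3 else 2
  p0 <- c(mean(vapply(indep, topSignal, numeric(1))),
          unlist(lapply(indep, function(f)
            c(kd(f), bottomSignal(f), if (fitHill) hillCoefficient(f)))))
  lower <- c(-Inf, rep(c(1e-15, -Inf, if (fitHill) 1e-6), m))
  resFun <- function(p) {
    top <- p[1]
    unlist(lapply(seq_len(m), function(i) {
      q <- p[1 + (i - 1) * perCurve + seq_len(perCurve)]
      hill <- if (fitHill) q[3] else fixHill
      curves[[i]]$signal - fourPL(curves[[i]]$conc, q[1], top, q[2], hill)
    }))
  }
  nObs <- sum(vapply(curves, nrow, integer(1)))
  best <- .nlsLMFit(resFun, list(p0), lower, NULL)
  if (is.null(best)) stop("fit-failure: shared-top 4PL fit did not converge")
  p <- best$fit$par
  se <- .lmSE(best$fit, nObs)
  fits <- lapply(seq_len(m), function(i) {
    q <- p[1 + (i - 1) * perCurve + seq_len(perCurve)]
    qse <- se[1 + (i - 1) * perCurve + seq_len(perCurve)]
    hill <- if (fitHill) q[3] else fixHill
    hillSE <- if (fitHill) qse[3] else 0
    rssI <- sum((curves[[i]]$signal -
                   fourPL(curves[[i]]$conc, q[1], p[1], q[2], hill))^2)
    new("BindingFit", kd = unname(q[1]), top = unname(p[1]),
        bottom = unname(q[2]), hill = unname(hill),
        se = c(kd = unname(qse[1]), top = unname(se[1]),
               bottom = unname(qse[2]), hill = unname(hillSE)),
        rss = rssI, nPoints = nrow(curves[[i]]),
        sharedTopGroup = "shared",
        notes = .extrapolationNote(unname(q[1]), curves[[i]]$conc))
  })
  names(fits) <- names(curves)
  attr(fits, "totalRSS") <- best$rss
  fits
}

#' DNA-stimulation ratio of two ATPase fits
#'
#' Ratio of the stimulated to the basal turnover number, the fold activation
#' of ATP hydrolysis by single-stranded DNA.
#'
#' @param basal,stimulated [MMFit-class] objects (basal = DNA-free).
#' @return dimensionless ratio stimulated kcat / basal kcat.
#' @export
foldStimulation <- function(basal, stimulated) {
  stopifnot(is(basal, "MMFit"), is(stimulated, "MMFit"))
  if (kcat(basal) <= 0)
    stop("undefined-ratio: basal kcat must be positive")
  kcat(stimulated) / kcat(basal)
}
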