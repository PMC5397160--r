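test_that("trace-to-rate conversion follows Beer-Lambert arithmetic", {
  # slope -0.00625 A/min, eps 6250, 1 cm, 20 nM enzyme -> 50 turnovers/min
  tr <- data.frame(time = seq(0, 600, 15))
  tr$a340 <- 1.25 - 0.00625 / 60 * tr$time
  v <- traceToRate(tr, enzymeConc = 20e-9)
  expect_equal(as.numeric(v), 50, tolerance = 1e-9)

  flat <- data.frame(time = seq(0, 600, 15), a340 = 1.25)
  expect_equal(as.numeric(traceToRate(flat, enzymeConc = 20e-9)), 0)
})

test_that("turnover is linear in slope and inversely linear in enzyme concentration", {
  set.seed(50)
  for (i in 1:20) {
    slope <- runif(1, 1e-4, 1e-2)        # A/min
    eConc <- runif(1, 1e-9, 1e-6)
    eps <- runif(1, 4000, 8000)
    path <- runif(1, 0.2, 1)
    tr <- data.frame(time = seq(0, 300, 10))
    tr$a340 <- 2 - slope / 60 * tr$time
    v <- as.numeric(traceToRate(tr, enzymeConc = eConc, extinction = eps,
                                pathlength = path))
    expect_equal(v, slope / (eps * path) / eConc, tolerance = 1e-9)
  }
})

test_that("non-linear and rising traces are flagged, not rejected", {
  set.seed(51)
  garbage <- data.frame(time = seq(0, 600, 15))
  garbage$a340 <- 1.25 + rnorm(nrow(garbage), sd = 0.2)
  v <- suppressWarnings(traceToRate(garbage, enzymeConc = 1e-6))
  expect_true(any(grepl("poor-linearity", attr(v, "notes"))))

  rising <- data.frame(time = seq(0, 600, 15))
  rising$a340 <- 1 + 0.001 * rising$time
  expect_warning(v2 <- traceToRate(rising, enzymeConc = 1e-6), "clipped")
  expect_equal(as.numeric(v2), 0)

  short <- data.frame(time = 0:2, a340 = c(1, 0.9, 0.8))
  expect_error(traceToRate(short, enzymeConc = 1e-6), "4 points")
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  S <- logSpaced(3e-6, 8e-4, 8)
  d <- data.frame(substrate = S,
                  rate = michaelisMenten(S, kcat = 600, km = 50e-6))
  fit <- fitMichaelisMenten(d)
  expect_equal(kcat(fit), 600, tolerance = 1e-6)
  expect_equal(km(fit), 50e-6, tolerance = 1e-6)
  expect_lt(fitRSS(fit), 1e-12)
})

test_that("the MM fit beats a dense kcat x Km grid search", {
  d <- simulateRateCurves(kcat = 631, km = 43e-6, noiseCV = 0.05,
                          replicates = 1, seed = 52)[[1]]
  fit <- fitMichaelisMenten(d)
  grid <- expand.grid(kcat = seq(300, 1000, length.out = 200),
                      km = logSpaced(5e-6, 5e-4, 200))
  rssGrid <- vapply(seq_len(nrow(grid)), function(i)
    sum((d$rate - michaelisMenten(d$substrate, grid$kcat[i],
                                  grid$km[i]))^2), numeric(1))
  expect_lte(fitRSS(fit), min(rssGrid) + 1e-9)
})

test_that("MM fitting needs enough distinct substrate levels", {
  d <- data.frame(substrate = rep(c(1e-5, 1e-4), each = 3),
                  rate = rep(c(100, 400), each = 3))
  expect_error(fitMichaelisMenten(d), "4 distinct")
})

test_that("noiseless 4PL titrations are recovered exactly", {
  d <- data.frame(conc = logSpaced(1e-9, 3e-6, 12))
  d$signal <- fourPL(d$conc, kd = 29e-9, top = 200, bottom = 50, hill = 1)
  fit <- fitBinding4PL(d)[[1]]
  expect_equal(kd(fit), 29e-9, tolerance = 1e-6)
  expect_equal(topSignal(fit), 200, tolerance = 1e-6)
  expect_equal(bottomSignal(fit), 50, tolerance = 1e-6)
  expect_equal(hillCoefficient(fit), 1, tolerance = 1e-6)
})

test_that("sharing the top across correctly specified curves changes nothing", {
  conc <- logSpaced(1e-9, 3e-6, 12)
  curves <- list(
    a = data.frame(conc = conc,
                   signal = fourPL(conc, 29e-9, 200, 50, 1)),
    b = data.frame(conc = conc,
                   signal = fourPL(conc, 164e-9, 200, 60, 1)))
  indep <- fitBinding4PL(curves, shareTop = FALSE)
  shared <- fitBinding4PL(curves, shareTop = TRUE)
  for (nm in names(curves)) {
    expect_equal(kd(shared[[nm]]), kd(indep[[nm]]), tolerance = 1e-4)
    expect_equal(topSignal(shared[[nm]]), topSignal(indep[[nm]]),
                 tolerance = 1e-4)
    expect_equal(shared[[nm]]@sharedTopGroup, "shared")
  }
})

test_that("the shared-top fit is never better than the unconstrained fit", {
  set.seed(53)
  conc <- logSpaced(1e-9, 3e-6, 12)
  curves <- list(
    data.frame(conc = conc, signal = fourPL(conc, 29e-9, 200, 50, 1) +
                 rnorm(12, sd = 2)),
    data.frame(conc = conc, signal = fourPL(conc, 100e-9, 230, 55, 1) +
                 rnorm(12, sd = 2)))
  indep <- fitBinding4PL(curves)
  shared <- fitBinding4PL(curves, shareTop = TRUE)
  rssIndep <- sum(vapply(indep, fitRSS, numeric(1)))
  expect_gte(attr(shared, "totalRSS") + 1e-9, rssIndep)
})

test_that("fixing hill at 1 reduces the 4PL to a hyperbolic isotherm", {
  conc <- logSpaced(1e-9, 3e-6, 12)
  d <- data.frame(conc = conc, signal = fourPL(conc, 29e-9, 200, 50, 1))
  fit <- fitBinding4PL(d, fixHill = 1)[[1]]
  expect_equal(hillCoefficient(fit), 1)
  expect_equal(kd(fit), 29e-9, tolerance = 1e-6)
  hyper <- 50 + (200 - 50) * conc / (29e-9 + conc)
  expect_equal(fourPL(conc, 29e-9, 200, 50, 1), hyper, tolerance = 1e-12)
})

test_that("Kd far outside the measured range carries an extrapolation note", {
  conc <- logSpaced(1e-9, 1e-7, 8)
  d <- data.frame(conc = conc, signal = fourPL(conc, 5e-5, 200, 50, 1))
  fit <- fitBinding4PL(d)[[1]]
  expect_true(any(grepl("extrapolated", fitNotes(fit))))
})

test_that("fold stimulation is the kcat ratio", {
  S <- logSpaced(3e-6, 8e-4, 8)
  mkFit <- function(kc, kmv) fitMichaelisMenten(
    data.frame(substrate = S, rate = michaelisMenten(S, kc, kmv)))
  basal <- mkFit(1, 50e-6)
  stim <- mkFit(600, 50e-6)
  expect_equal(foldStimulation(basal, stim), 600, tolerance = 1e-6)
  expect_equal(foldStimulation(stim, stim), 1, tolerance = 1e-9)
  # arithmetic on a printed constant pair: 1146 / 0.72 ~ 1592, not ~600
  basal2 <- mkFit(0.72, 50e-6)
  stim2 <- mkFit(1146, 87e-6)
  expect_equal(foldStimulation(basal2, stim2), 1146 / 0.72,
               tolerance = 1e-6)
})
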