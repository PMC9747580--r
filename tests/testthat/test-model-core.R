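test_that("system propagator matches a scaled Taylor-series oracle", {
  tau <- 25e-9
  expect_equal(buildSystemPropagator(matrix(0, 3, 3), tau), diag(3))
  G <- rbind(c(-40, 40), c(40, -40))
  P <- buildSystemPropagator(G, tau)
  expect_equal(P, taylorExpm(tau * G), tolerance = 1e-12)
  expect_equal(P[1, 2], 40 * tau, tolerance = 1e-6)
  set.seed(11)
  for (M in 2:4) {
    G <- randomGenerator(M)
    P <- buildSystemPropagator(G, tau)
    expect_equal(unname(rowSums(P)), rep(1, M), tolerance = 1e-12)
    expect_equal(P, taylorExpm(tau * G), tolerance = 1e-10)
  }
  expect_error(buildSystemPropagator(matrix(1, 2, 3), tau), "square")
  expect_error(buildSystemPropagator(rbind(c(-1, 2), c(1, -1)), tau),
               "generator")
  expect_error(buildSystemPropagator(rbind(c(-1, 1), c(1, -1)), -1), "tau")
})

test_that("escape rates invert the propagator (matrix logarithm)", {
  tau <- 25e-9
  expect_equal(as.numeric(escapeRatesFromPropagator(diag(3), tau)),
               rep(0, 3))
  # printed two-state benchmark: both escape rates 40 1/s
  G <- rbind(c(-40, 40), c(40, -40))
  esc <- escapeRatesFromPropagator(buildSystemPropagator(G, tau), tau)
  expect_equal(as.numeric(esc), c(40, 40), tolerance = 1e-8)
  expect_false(attr(esc, "fallback"))
  # round trip on random generators
  set.seed(7)
  for (rep in 1:20) {
    M <- sample(2:4, 1)
    G <- randomGenerator(M)
    esc <- escapeRatesFromPropagator(buildSystemPropagator(G, tau), tau)
    expect_equal(as.numeric(esc), -diag(G), tolerance = 1e-8)
    expect_equal(attr(esc, "generator"), G, tolerance = 1e-6)
  }
})

test_that("escape rates agree with an independent matrix-logarithm route", {
  skip_if_not_installed("pracma")
  tau <- 25e-9
  set.seed(13)
  G <- randomGenerator(3, maxRate = 1e6)
  P <- buildSystemPropagator(G, tau)
  L <- pracma::logm(P) / tau
  expect_equal(as.numeric(escapeRatesFromPropagator(P, tau)), -diag(L),
               tolerance = 1e-6)
})

test_that("FRET efficiency is the transfer branching fraction", {
  lamD <- 1 / 3.5e-9
  expect_equal(fretEfficiency(0, lamD), 0)
  expect_equal(fretEfficiency(lamD, lamD), 0.5)
  # rates chosen to hit the benchmark ground truths
  expect_equal(fretEfficiency(0.22 / 0.78 * lamD, lamD), 0.22)
  expect_equal(fretEfficiency(0.59 / 0.41 * lamD, lamD), 0.59)
  expect_error(fretEfficiency(-1, lamD), "lambdaFret")
})

test_that("donor microtime density has the delta-IRF limit and unit mass", {
  params <- testParams(piEx = 0.2, tau = 100e-9)
  det0 <- DetectorModel(irfMean = 0, irfSigma = 0)
  mu <- seq(0, 20e-9, length.out = 50)
  lt <- params@lambdaD + params@lambdaFret[1]
  expect_equal(donorMicrotimeDensity(mu, 1, params, det0),
               params@piEx * params@lambdaD * exp(-lt * mu),
               tolerance = 1e-9)
  # integral over the pulse window = piEx * lambdaD / lambdaTot (quadrature)
  det <- DetectorModel(irfMean = 1e-9, irfSigma = 1e-10)
  for (s in 1:2) {
    lt <- params@lambdaD + params@lambdaFret[s]
    I <- integrate(donorMicrotimeDensity, 0, params@tau, stateIndex = s,
                   params = params, det = det, rel.tol = 1e-9,
                   subdivisions = 500L)$value
    expect_equal(I, params@piEx * params@lambdaD / lt, tolerance = 1e-6)
  }
})

test_that("acceptor microtime density: zero-FRET, unit mass, Erlang limit", {
  params <- testParams(piEx = 0.2, tau = 100e-9)
  det <- DetectorModel(irfMean = 1e-9, irfSigma = 1e-10)
  p0 <- params
  p0@lambdaFret <- c(0, p0@lambdaFret[2])
  expect_equal(acceptorMicrotimeDensity(seq(0, 50e-9, length.out = 20), 1,
                                        p0, det),
               rep(0, 20))
  for (s in 1:2) {
    lt <- params@lambdaD + params@lambdaFret[s]
    I <- integrate(acceptorMicrotimeDensity, 0, params@tau, stateIndex = s,
                   params = params, det = det, rel.tol = 1e-9,
                   subdivisions = 500L)$value
    expect_equal(I, params@piEx * params@lambdaFret[s] / lt, tolerance = 1e-6)
  }
  # continuity across the equal-rate degeneracy lambdaA -> lambdaD + lambdaFret
  lamD <- 1 / 3.5e-9
  lamF <- 1e8
  mu <- seq(0.5e-9, 30e-9, length.out = 40)
  mk <- function(lamA) PhotophysicsParams(lamD, lamA, lamF, 0.2, 100e-9)
  lt <- lamD + lamF
  dAbove <- acceptorMicrotimeDensity(mu, 1, mk(lt * (1 + 1e-9)), det)
  dBelow <- acceptorMicrotimeDensity(mu, 1, mk(lt * (1 - 1e-9)), det)
  dLimit <- acceptorMicrotimeDensity(mu, 1, mk(lt * (1 + 1e-10)), det)
  expect_equal(dAbove, dLimit, tolerance = 1e-6)
  expect_equal(dBelow, dLimit, tolerance = 1e-6)
})

test_that("per-pulse outcome measure is normalised and has analytic masses", {
  # no excitation, no background: every pulse is empty
  p0 <- testParams(piEx = 0)
  om <- pulseOutcomeModel(1, p0, idealDetector())
  expect_equal(om$pEmpty, 1)
  expect_equal(om$pDonor + om$pAcceptor + om$pBoth, 0)
  # identity route, no background, no IRF: photon probabilities are the
  # branching fractions of the donor-decay race
  p1 <- testParams(piEx = 0.3, tau = 100e-9)
  om <- pulseOutcomeModel(2, p1, idealDetector())
  lt <- p1@lambdaD + p1@lambdaFret[2]
  expect_equal(om$pDonor, 0.3 * p1@lambdaD / lt)
  expect_equal(om$pAcceptor, 0.3 * p1@lambdaFret[2] / lt)
  # full normalisation (mass + integrated densities) under random
  # calibrations, verified by quadrature
  set.seed(99)
  for (rep in 1:100) {
    tau <- 100e-9
    params <- PhotophysicsParams(
      lambdaD = 1 / runif(1, 1e-9, 5e-9), lambdaA = 1 / runif(1, 1e-9, 5e-9),
      lambdaFret = runif(1, 0, 8) / runif(1, 1, 5) * 1e8 + 1e6,
      piEx = runif(1, 0, 1), tau = tau)
    r1 <- c(runif(1, 0.1, 0.6), runif(1, 0, 0.2))
    det <- DetectorModel(routeMatrix = rbind(r1, c(runif(1, 0, 0.2),
                                                   runif(1, 0.2, 0.7))),
                         # keep the IRF offset >= ~5.5 sigma so the density
                         # mass below zero is negligible, as the model assumes
                         irfMean = runif(1, 1e-9, 2e-9),
                         irfSigma = runif(1, 0, 0.18e-9),
                         bgProb = runif(2, 0, 0.1))
    om <- pulseOutcomeModel(1, params, det)
    # split the window at the end of the decay peak so adaptive quadrature
    # resolves both the sharp signal and the flat background component
    intWin <- function(f) {
      integrate(f, 0, 3e-8, rel.tol = 1e-10, subdivisions = 500L)$value +
        integrate(f, 3e-8, tau, rel.tol = 1e-10, subdivisions = 500L)$value
    }
    iD <- intWin(om$densityDonor)
    iA <- intWin(om$densityAcceptor)
    iB <- intWin(function(muD) {
      vapply(muD, function(x) {
        integrate(function(muA) om$densityBoth(x, muA), 0, tau,
                  rel.tol = 1e-8)$value
      }, numeric(1))
    })
    expect_equal(om$pEmpty + iD + iA + iB, 1, tolerance = 1e-6)
    expect_equal(iD, om$pDonor, tolerance = 1e-6)
    expect_equal(iA, om$pAcceptor, tolerance = 1e-6)
    expect_equal(iB, om$pBoth, tolerance = 1e-6)
  }
})

test_that("detection matrices have constant rows and the right ordering", {
  params <- testParams()
  det <- testDetector()
  # empty observation with no excitation and no background: all ones
  p0 <- testParams(piEx = 0)
  D <- buildDetectionMatrix(PulseObservation(), p0, idealDetector())
  expect_equal(D, matrix(1, 2, 2))
  # single-state space degenerates to the outcome value
  p1 <- PhotophysicsParams(params@lambdaD, params@lambdaA,
                           params@lambdaFret[1], params@piEx, params@tau)
  om <- pulseOutcomeModel(1, p1, det)
  D <- buildDetectionMatrix(PulseObservation(muD = 2e-9), p1, det)
  expect_equal(dim(D), c(1L, 1L))
  expect_equal(D[1, 1], om$densityDonor(2e-9))
  # rows constant; stronger FRET means fewer early donor photons
  D <- buildDetectionMatrix(PulseObservation(muD = 1.5e-9), params, det)
  expect_true(all(D[, 1] == D[, 2]))
  expect_lt(D[2, 1], D[1, 1])
})

test_that("reduced propagator is the element-wise product", {
  set.seed(3)
  P <- matrix(runif(9), 3, 3)
  D <- matrix(runif(9), 3, 3)
  expect_identical(reducedPropagator(P, D), P * D)
  expect_equal(reducedPropagator(P, matrix(1, 3, 3)), P)
  D0 <- D
  D0[2, ] <- 0
  expect_equal(reducedPropagator(P, D0)[2, ], rep(0, 3))
  expect_error(reducedPropagator(P, matrix(1, 2, 2)), "dimensions")
})

test_that("grouped log likelihood equals the naive pulse-by-pulse oracle", {
  set.seed(17)
  params <- testParams(eff = c(0.2, 0.5, 0.75), piEx = 0.05)
  det <- testDetector()
  kin <- SystemKinetics(rateMatrix = randomGenerator(3, maxRate = 3e5),
                        tau = params@tau)
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 1000,
                                         seed = 5))
  llGrouped <- traceLogLikelihood(ds@trace, kin, params, det)
  llNaive <- naiveLogLik(ds@trace, kin, params, det)
  expect_equal(llGrouped, llNaive, tolerance = 1e-8)
  # scalar degenerate case: single state, single empty pulse
  p1 <- PhotophysicsParams(params@lambdaD, params@lambdaA, 1e8, 0.05,
                           params@tau)
  k1 <- SystemKinetics(transProb = matrix(1, 1, 1), rhoStart = 1)
  tr1 <- PhotonTrace(nPulses = 1, tau = params@tau)
  expect_equal(traceLogLikelihood(tr1, k1, p1, det),
               log(pulseOutcomeModel(1, p1, det)$pEmpty))
})

test_that("likelihood is invariant where it must be", {
  set.seed(23)
  det <- testDetector()
  # emission-identical states: likelihood cannot depend on the propagator
  paramsSame <- PhotophysicsParams(1 / 3.5e-9, 1 / 3e-9, c(2e8, 2e8), 0.05,
                                   25e-9)
  kinA <- SystemKinetics(transProb = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                         rhoStart = c(0.5, 0.5))
  kinB <- SystemKinetics(transProb = rbind(c(0.5, 0.5), c(0.7, 0.3)),
                         rhoStart = c(0.5, 0.5))
  ds <- generateDataset(SimulationConfig(kinA, paramsSame, det,
                                         nPulses = 500, seed = 8))
  expect_equal(traceLogLikelihood(ds@trace, kinA, paramsSame, det),
               traceLogLikelihood(ds@trace, kinB, paramsSame, det),
               tolerance = 1e-10)
  # consistent relabelling of states leaves the likelihood unchanged
  params <- testParams(eff = c(0.2, 0.5, 0.75), piEx = 0.05)
  kin <- SystemKinetics(rateMatrix = randomGenerator(3, maxRate = 3e5),
                        tau = params@tau, rhoStart = c(0.2, 0.3, 0.5))
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 800,
                                         seed = 9))
  perm <- c(3L, 1L, 2L)
  paramsP <- params
  paramsP@lambdaFret <- params@lambdaFret[perm]
  kinP <- SystemKinetics(transProb = kin@transProb[perm, perm],
                         rhoStart = kin@rhoStart[perm])
  expect_equal(traceLogLikelihood(ds@trace, kin, params, det),
               traceLogLikelihood(ds@trace, kinP, paramsP, det),
               tolerance = 1e-10)
})
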