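test_that("dense FFBS matches exhaustive trajectory enumeration", {
  set.seed(5)
  params <- testParams(eff = c(0.08, 0.75), piEx = 0.4)
  det <- testDetector()
  kin <- testKinetics2()
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 6,
                                         seed = 21))
  enum <- enumerateTrajectoryPosterior(ds@trace, kin, params, det)
  nd <- 1e5
  dr <- ffbsTrajectory(ds@trace, kin, params, det, nDraws = nd,
                       method = "dense")
  code <- as.vector(dr %*% 2^(0:5))
  codeRef <- as.vector(enum$trajectories %*% 2^(0:5))
  emp <- tabulate(match(code, codeRef), length(codeRef)) / nd
  expect_lt(0.5 * sum(abs(emp - enum$posterior)), 0.01)
})

test_that("grouped FFBS agrees with enumeration on trajectory summaries", {
  set.seed(6)
  params <- testParams(eff = c(0.08, 0.75), piEx = 0.3)
  det <- testDetector()
  kin <- testKinetics2()
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 8,
                                         seed = 31))
  enum <- enumerateTrajectoryPosterior(ds@trace, kin, params, det)
  key <- function(cnt, s1) paste(c(cnt), s1, collapse = "_")
  refKeys <- vapply(seq_len(nrow(enum$trajectories)), function(i) {
    key(countTransitions(enum$trajectories[i, ], 2),
        enum$trajectories[i, 1])
  }, "")
  ref <- tapply(enum$posterior, refKeys, sum)
  nd <- 1e5
  gr <- ffbsTrajectory(ds@trace, kin, params, det, nDraws = nd,
                       method = "grouped")
  empKeys <- vapply(seq_len(nd), function(d) key(gr$counts[, , d], gr$s1[d]),
                    "")
  emp <- table(empKeys) / nd
  expect_lt(tvDist(ref, c(emp)), 0.01)
  # bookkeeping identities: occupancy covers all pulses, counts all steps
  expect_equal(unique(rowSums(gr$occupancy)), 8)
  expect_equal(unique(apply(gr$counts, 3, sum)), 7)
})

test_that("FFBS degenerates correctly", {
  params <- testParams(piEx = 0.3)
  det <- testDetector()
  # single state: constant trajectory
  p1 <- PhotophysicsParams(params@lambdaD, params@lambdaA, 2e8, 0.3, 25e-9)
  k1 <- SystemKinetics(transProb = matrix(1, 1, 1), rhoStart = 1)
  ds <- generateDataset(SimulationConfig(k1, p1, det, nPulses = 50,
                                         seed = 2))
  dr <- ffbsTrajectory(ds@trace, k1, p1, det, nDraws = 5, method = "dense")
  expect_true(all(dr == 1L))
  # identity propagator: the chain freezes at a state drawn from the exact
  # conditional over the initial state
  kinI <- SystemKinetics(transProb = diag(2), rhoStart = c(0.5, 0.5))
  ds <- generateDataset(SimulationConfig(kinI, params, det, nPulses = 7,
                                         seed = 3))
  dr <- ffbsTrajectory(ds@trace, kinI, params, det, nDraws = 4000,
                       method = "dense")
  expect_true(all(dr == dr[, 1]))
  enum <- enumerateTrajectoryPosterior(ds@trace, kinI, params, det)
  pState1 <- sum(enum$posterior[enum$trajectories[, 1] == 1])
  phat <- mean(dr[, 1] == 1L)
  expect_lt(abs(phat - pState1), 3.5 * sqrt(pState1 * (1 - pState1) / 4000))
})

test_that("transition counting is exact", {
  expect_equal(countTransitions(rep(2L, 10), 3),
               matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3))
  expect_equal(countTransitions(c(1, 2, 1, 2), 2),
               rbind(c(0, 2), c(1, 0)))
  set.seed(9)
  s <- sample(1:3, 500, replace = TRUE)
  n <- countTransitions(s, 3)
  expect_equal(sum(n), 499)
  expect_equal(rowSums(n), tabulate(s[-500], 3))
})

test_that("conjugate updates match Dirichlet moments", {
  set.seed(10)
  prior <- PriorSpec(alpha = 1)
  # prior domination: huge symmetric concentration forces uniform rows
  priorBig <- PriorSpec(alpha = 1e6)
  P <- sampleTransitionMatrix(matrix(0, 3, 3), priorBig)
  expect_equal(P, matrix(1 / 3, 3, 3), tolerance = 1e-2)
  # likelihood domination: one huge count pins the row
  n <- matrix(0, 2, 2)
  n[1, 2] <- 1e8
  n[2, 1] <- 1e8
  P <- sampleTransitionMatrix(n, prior)
  expect_equal(P, rbind(c(0, 1), c(1, 0)), tolerance = 1e-3)
  # posterior mean of a row equals (n + alpha*beta) / sum within 3 sigma
  n <- rbind(c(20, 5, 2), c(1, 30, 4), c(3, 3, 40))
  draws <- replicate(1e4, sampleTransitionMatrix(n, prior)[1, ])
  shp <- n[1, ] + 1 / 3
  mExp <- shp / sum(shp)
  vExp <- mExp * (1 - mExp) / (sum(shp) + 1)
  expect_true(all(abs(rowMeans(draws) - mExp) < 3.5 * sqrt(vExp / 1e4)))
  # initial-probability update
  draws <- replicate(1e4, sampleRhoStart(2, prior, 3))
  shp <- c(1, 2, 1)
  mExp <- shp / sum(shp)
  vExp <- mExp * (1 - mExp) / (sum(shp) + 1)
  expect_true(all(abs(rowMeans(draws) - mExp) < 3.5 * sqrt(vExp / 1e4)))
  expect_gt(mean(draws[2, ]), max(rowMeans(draws)[-2]) - 1e-9)
  # concentration to infinity flattens the draw
  priorFlat <- PriorSpec(rhoConcentration = 1e7)
  expect_equal(sampleRhoStart(1, priorFlat, 4), rep(0.25, 4),
               tolerance = 1e-2)
})

test_that("MH rate updates behave at the degenerate-proposal limit", {
  set.seed(12)
  params <- testParams(piEx = 0.05)
  det <- testDetector()
  kin <- testKinetics2()
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 300,
                                         seed = 4))
  upd <- mhUpdateRates(kin, params, ds@trace, PriorSpec(), det,
                       proposalScales = c(lambdaD = 1e-12, lambdaA = 1e-12,
                                          lambdaFret = 1e-12, piEx = 1e-12))
  expect_true(all(upd$accepted))
  expect_equal(upd$params@lambdaD, params@lambdaD, tolerance = 1e-9)
  expect_equal(upd$params@lambdaFret, params@lambdaFret, tolerance = 1e-9)
})

test_that("with an all-dark detector the chain samples the prior", {
  # a route matrix of zeros and no background make every pulse empty with
  # probability one, so the posterior is the prior
  det0 <- DetectorModel(routeMatrix = matrix(0, 2, 2), irfMean = 0,
                        irfSigma = 0, bgProb = c(0, 0))
  trace <- PhotonTrace(nPulses = 100, tau = 25e-9)
  prior <- PriorSpec()
  ch <- runParametricChain(trace, 2, prior = prior, det = det0,
                           nSweeps = 6000, seed = 5, nTune = 500)
  lam <- ch@lambdaD[1001:6000]
  priorMean <- prior@lambdaDShape / prior@lambdaDRate
  priorSd <- sqrt(prior@lambdaDShape) / prior@lambdaDRate
  # generous Monte-Carlo bands to allow for chain autocorrelation
  expect_lt(abs(mean(lam) - priorMean), 0.15 * priorMean)
  expect_lt(abs(sd(lam) - priorSd), 0.2 * priorSd)
  pex <- ch@piEx[1001:6000]
  expect_lt(abs(mean(pex) - 0.5), 0.06)
})

test_that("single-block MH matches the quadrature posterior (1 photon)", {
  # one donor photon; only the FRET rate is updated, so its stationary law
  # is a 1-D posterior we can integrate numerically
  set.seed(14)
  lamD <- 1 / 3.5e-9
  params <- PhotophysicsParams(lamD, 1 / 3e-9, 2e8, 0.3, 25e-9)
  det <- idealDetector()
  kin <- SystemKinetics(transProb = matrix(1, 1, 1), rhoStart = 1)
  trace <- PhotonTrace(nPulses = 1, tau = 25e-9, pulseIndex = 1,
                       channel = 1, microtime = 2.1e-9)
  prior <- PriorSpec()
  loglik1 <- function(lf) {
    vapply(lf, function(x) {
      p <- params
      p@lambdaFret <- x
      traceLogLikelihood(trace, kin, p, det)
    }, numeric(1))
  }
  grid <- seq(1e6, 2.5e9, length.out = 3000)
  post <- exp(loglik1(grid) +
              dgamma(grid, prior@lambdaFretShape,
                     rate = prior@lambdaFretRate, log = TRUE))
  post <- post / sum(post)
  draws <- numeric(3e4)
  cur <- params
  ll <- traceLogLikelihood(trace, kin, cur, det)
  for (i in seq_len(3e4)) {
    upd <- mhUpdateRates(kin, cur, trace, prior, det,
                         proposalScales = c(lambdaD = 0, lambdaA = 0,
                                            lambdaFret = 1.2, piEx = 0),
                         blocks = "lambdaFret1", logLik = ll)
    cur <- upd$params
    ll <- upd$logLik
    draws[i] <- cur@lambdaFret[1]
  }
  breaks <- c(0, quantile(grid, seq(0.05, 0.95, by = 0.05)), Inf)
  refBin <- tapply(post, cut(grid, breaks), sum)
  refBin[is.na(refBin)] <- 0
  empBin <- table(cut(draws, breaks)) / length(draws)
  expect_lt(0.5 * sum(abs(refBin - empBin)), 0.05)
})

test_that("the chain driver is reproducible and well behaved", {
  lamD <- 1 / 3.5e-9
  eff <- c(0.25, 0.65)
  params <- PhotophysicsParams(lamD, 1 / 3e-9, eff / (1 - eff) * lamD,
                               piEx = 5e-3, tau = 25e-9)
  det <- benchmarkDetector()
  kin <- SystemKinetics(rateMatrix = rbind(c(-2000, 2000), c(1500, -1500)),
                        tau = params@tau)
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 3e5,
                                         seed = 42))
  ch1 <- runParametricChain(ds@trace, 2, det = det, nSweeps = 300, seed = 7)
  ch2 <- runParametricChain(ds@trace, 2, det = det, nSweeps = 300, seed = 7)
  expect_identical(ch1@lambdaFret, ch2@lambdaFret)
  expect_identical(ch1@transProb, ch2@transProb)
  expect_identical(ch1@logPost, ch2@logPost)
  expect_true(all(is.finite(ch1@logPost)))
  # acceptance rates of all blocks end up in a healthy band after tuning
  expect_true(all(ch1@acceptance > 0.1 & ch1@acceptance < 0.9))
  # and the posterior concentrates near the generating photophysics
  keep <- 151:300
  expect_lt(abs(mean(ch1@lambdaD[keep]) - lamD) / lamD, 0.05)
  effHat <- sort(colMeans(fretEfficiency(ch1@lambdaFret[keep, ],
                                         mean(ch1@lambdaD[keep]))))
  expect_lt(max(abs(effHat - eff)), 0.05)
})

test_that("propagator rows are calibrated where photons pin the chain", {
  # rank-uniformity check for the transition probabilities at a
  # photon-dense size (one photon every few pulses), where the
  # trajectory-propagator Gibbs pair mixes within the chain length
  set.seed(99)
  tau <- 100e-9
  prior <- PriorSpec(alpha = 2,
                     lambdaDShape = 25, lambdaDRate = 25 / 3e8,
                     lambdaAShape = 25, lambdaARate = 25 / 3e8,
                     lambdaFretShape = 2, lambdaFretRate = 2 / 3e8,
                     rhoConcentration = 1,
                     piExShape1 = 30, piExShape2 = 30)
  det <- DetectorModel(routeMatrix = rbind(c(0.55, 0.05), c(0, 0.6)),
                       irfMean = 1e-9, irfSigma = 1e-10,
                       bgProb = c(1e-5, 1e-5))
  R <- 150L
  ranks <- matrix(NA_integer_, R, 2, dimnames = list(NULL, c("pi11", "pi21")))
  for (r in seq_len(R)) {
    lamD <- rgamma(1, 25, rate = 25 / 3e8)
    lamA <- rgamma(1, 25, rate = 25 / 3e8)
    lamF <- rgamma(2, 2, rate = 2 / 3e8)
    piEx <- rbeta(1, 30, 30)
    p11 <- runif(1)
    p21 <- runif(1)
    Pi <- rbind(c(p11, 1 - p11), c(p21, 1 - p21))
    rho1 <- runif(1)
    params <- suppressWarnings(PhotophysicsParams(lamD, lamA, lamF, piEx, tau))
    kin <- SystemKinetics(transProb = Pi, rhoStart = c(rho1, 1 - rho1))
    ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 300,
                                           seed = 3000L + r))
    q11 <- runif(1)
    q21 <- runif(1)
    init <- list(lambdaD = rgamma(1, 25, rate = 25 / 3e8),
                 lambdaA = rgamma(1, 25, rate = 25 / 3e8),
                 lambdaFret = rgamma(2, 2, rate = 2 / 3e8),
                 piEx = rbeta(1, 30, 30),
                 transProb = rbind(c(q11, 1 - q11), c(q21, 1 - q21)),
                 rhoStart = rep(0.5, 2))
    ch <- runParametricChain(ds@trace, 2, prior = prior, det = det,
                             nSweeps = 1200, seed = 6000L + r, nTune = 200,
                             init = init)
    keep <- seq(250L, 1200L, by = 50L)
    ranks[r, "pi11"] <- sum(ch@transProb[1, 1, keep] < p11)
    ranks[r, "pi21"] <- sum(ch@transProb[2, 1, keep] < p21)
  }
  nD <- length(seq(250L, 1200L, by = 50L))
  pvals <- apply(ranks, 2, function(rk) {
    counts <- tabulate(rk + 1L, nD + 1L)
    suppressWarnings(chisq.test(counts, p = rep(1 / (nD + 1L),
                                                nD + 1L))$p.value)
  })
  expect_true(all(pvals > 0.01))
})

test_that("dense and grouped FFBS match enumeration with three states", {
  set.seed(15)
  # photon-dense instance: concentrated posterior keeps the Monte-Carlo
  # noise floor of the TV comparison well below the 0.01 tolerance
  params <- testParams(eff = c(0.1, 0.5, 0.8), piEx = 0.9)
  det <- testDetector()
  P <- rbind(c(0.7, 0.2, 0.1), c(0.15, 0.7, 0.15), c(0.05, 0.25, 0.7))
  kin <- SystemKinetics(transProb = P, rhoStart = c(0.3, 0.4, 0.3))
  ds <- generateDataset(SimulationConfig(kin, params, det, nPulses = 5,
                                         seed = 61))
  enum <- enumerateTrajectoryPosterior(ds@trace, kin, params, det)
  nd <- 2e5
  dr <- ffbsTrajectory(ds@trace, kin, params, det, nDraws = nd,
                       method = "dense")
  code <- as.vector(dr %*% 3^(0:4))
  codeRef <- as.vector(enum$trajectories %*% 3^(0:4))
  emp <- tabulate(match(code, codeRef), length(codeRef)) / nd
  expect_lt(0.5 * sum(abs(emp - enum$posterior)), 0.01)
  # grouped summaries on the same instance
  gr <- ffbsTrajectory(ds@trace, kin, params, det, nDraws = nd,
                       method = "grouped")
  key <- function(cnt, s1) paste(c(cnt), s1, collapse = "_")
  refKeys <- vapply(seq_len(nrow(enum$trajectories)), function(i)
    key(countTransitions(enum$trajectories[i, ], 3),
        enum$trajectories[i, 1]), "")
  ref <- tapply(enum$posterior, refKeys, sum)
  empKeys <- vapply(seq_len(nd), function(d) key(gr$counts[, , d], gr$s1[d]),
                    "")
  expect_lt(tvDist(ref, c(table(empKeys) / nd)), 0.01)
})
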