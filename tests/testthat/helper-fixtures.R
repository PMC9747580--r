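# Shared fixtures and oracles.  Everything is built in code at test time.

# photophysics resembling common organic dye pairs; two system states unless
# stated otherwise
testParams <- function(eff = c(0.25, 0.65), piEx = 0.05, tau = 25e-9,
                       lambdaD = 1 / 3.5e-9, lambdaA = 1 / 3e-9) {
  PhotophysicsParams(lambdaD = lambdaD, lambdaA = lambdaA,
                     lambdaFret = eff / (1 - eff) * lambdaD,
                     piEx = piEx, tau = tau)
}

# a deliberately messy detector: crosstalk both ways, losses, visible
# background, finite IRF
testDetector <- function() {
  DetectorModel(routeMatrix = rbind(c(0.5, 0.1), c(0.02, 0.55)),
                irfMean = 1e-9, irfSigma = 1e-10, bgProb = c(0.02, 0.03))
}

idealDetector <- function() {
  DetectorModel(routeMatrix = diag(2), irfMean = 0, irfSigma = 0,
                bgProb = c(0, 0))
}

testKinetics2 <- function(tau = 25e-9) {
  SystemKinetics(transProb = rbind(c(0.8, 0.2), c(0.35, 0.65)),
                 rhoStart = c(0.4, 0.6))
}

# naive pulse-by-pulse likelihood oracle: literal product of reduced
# propagators built from the R-level observation model
naiveLogLik <- function(trace, kin, params, det) {
  N <- trace@nPulses
  ph <- trace@photons
  f <- kin@rhoStart
  ll <- 0
  for (n in seq_len(N)) {
    rows <- ph[ph$pulseIndex == n, , drop = FALSE]
    muD <- if (any(rows$channel == 1L)) rows$microtime[rows$channel == 1L] else NA
    muA <- if (any(rows$channel == 2L)) rows$microtime[rows$channel == 2L] else NA
    D <- buildDetectionMatrix(PulseObservation(muD, muA), params, det)
    f <- f %*% reducedPropagator(kin@transProb, D)
    s <- sum(f)
    if (s <= 0) return(-Inf)
    ll <- ll + log(s)
    f <- f / s
  }
  ll
}

# scaled truncated power-series matrix exponential (30 terms after halving),
# independent of Matrix::expm
taylorExpm <- function(A, nTerms = 30L) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))))
  B <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(nTerms)) {
    term <- term %*% B / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# exhaustive trajectory posterior for tiny traces
enumerateTrajectoryPosterior <- function(trace, kin, params, det) {
  N <- as.integer(trace@nPulses)
  M <- nrow(kin@transProb)
  G <- matrix(0, N, M)
  ph <- trace@photons
  for (n in seq_len(N)) {
    rows <- ph[ph$pulseIndex == n, , drop = FALSE]
    muD <- if (any(rows$channel == 1L)) rows$microtime[rows$channel == 1L] else NA
    muA <- if (any(rows$channel == 2L)) rows$microtime[rows$channel == 2L] else NA
    G[n, ] <- buildDetectionMatrix(PulseObservation(muD, muA), params, det)[, 1]
  }
  traj <- as.matrix(expand.grid(rep(list(seq_len(M)), N)))
  w <- apply(traj, 1L, function(s) {
    p <- kin@rhoStart[s[1]] * prod(G[cbind(seq_len(N), s)])
    for (t in seq_len(N - 1)) p <- p * kin@transProb[s[t], s[t + 1]]
    p
  })
  list(trajectories = traj, posterior = w / sum(w))
}

# total-variation distance between two named discrete distributions
tvDist <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- setNames(numeric(length(keys)), keys)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  0.5 * sum(abs(pv - qv))
}

# random valid generator matrix for round-trip tests
randomGenerator <- function(M, maxRate = 1e4) {
  G <- matrix(runif(M * M) * maxRate, M, M)
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  G
}
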