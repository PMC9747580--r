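#' Single-pulse observation
#'
#' The observation attached to one pulse window: a donor-channel microtime,
#' an acceptor-channel microtime, both, or neither.  An absent microtime is
#' encoded as `NA`.
#'
#' @slot muD donor-channel microtime (s) or `NA`.
#' @slot muA acceptor-channel microtime (s) or `NA`.
#' @name PulseObservation-class
#' @rdname PulseObservation
#' @exportClass PulseObservation
setClass("PulseObservation",
         representation(muD = "numeric", muA = "numeric"))

setValidity("PulseObservation", function(object) {
  msg <- character()
  if (length(object@muD) != 1L || length(object@muA) != 1L) {
    msg <- c(msg, "'muD' and 'muA' must have length 1 (NA = absent)")
  }
  if ((!is.na(object@muD) && object@muD < 0) ||
      (!is.na(object@muA) && object@muA < 0)) {
    msg <- c(msg, "present microtimes must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @param muD,muA microtimes in seconds; `NA` for no photon in that channel.
#' @return a `PulseObservation`.
#' @rdname PulseObservation
#' @export
PulseObservation <- function(muD = NA_real_, muA = NA_real_) {
  new("PulseObservation", muD = as.numeric(muD), muA = as.numeric(muA))
}

#' Pulse-to-pulse system propagator
#'
#' Exponentiates the continuous-time system generator over one interpulse
#' period: `P = expm(tau * G)`.  Because system kinetics are far slower than
#' the interpulse period, the system state is treated as constant within a
#' pulse window and hops only between windows with these probabilities.
#'
#' @param rateMatrix MxM generator (1/s): non-negative off-diagonals, zero
#'   row sums.
#' @param tau interpulse period (s).
#' @return MxM row-stochastic matrix (rows sum to 1 within 1e-12).
#' @examples
#' buildSystemPropagator(rbind(c(-40, 40), c(40, -40)), 25e-9)
#' @export
buildSystemPropagator <- function(rateMatrix, tau) {
  G <- as.matrix(rateMatrix)
  if (!is.numeric(G) || nrow(G) != ncol(G) || any(!is.finite(G))) {
    stop("'rateMatrix' must be a finite square numeric matrix")
  }
  offd <- G
  diag(offd) <- 0
  scale <- max(1, max(abs(G)))
  if (any(offd < 0) || any(abs(rowSums(G)) > 1e-10 * scale)) {
    stop("'rateMatrix' must be a generator: off-diagonals >= 0, rows sum to 0")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("'tau' must be a single positive time (s)")
  }
  P <- as.matrix(Matrix::expm(tau * G))
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-13)) {
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- NULL
  P
}

#' Escape rates recovered from a propagator
#'
#' Inverts [buildSystemPropagator()]: takes the matrix logarithm
#' `G = logm(P) / tau` (via eigendecomposition) and returns the per-state
#' escape rates `-diag(G)`, i.e. the total rate of leaving each system state.
#' When the logarithm is not a valid real generator (possible for propagators
#' far from the identity or estimated with noise), the function falls back to
#' the diagonal approximation `-log(diag(P)) / tau` and flags it.
#'
#' @param transProb MxM row-stochastic matrix with strictly positive diagonal.
#' @param tau interpulse period (s).
#' @return numeric vector of escape rates (1/s) with attributes `generator`
#'   (the recovered rate matrix, or `NULL` under fallback) and `fallback`
#'   (logical).
#' @examples
#' P <- buildSystemPropagator(rbind(c(-40, 40), c(40, -40)), 25e-9)
#' escapeRatesFromPropagator(P, 25e-9)  # ~ c(40, 40)
#' @export
escapeRatesFromPropagator <- function(transProb, tau) {
  P <- as.matrix(transProb)
  M <- nrow(P)
  if (ncol(P) != M || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("'transProb' must be a row-stochastic square matrix")
  }
  if (any(diag(P) <= 0)) {
    stop("'transProb' must have strictly positive diagonal entries")
  }
  fallback <- function() {
    out <- -log(diag(P)) / tau
    warning("matrix logarithm did not yield a real generator; ",
            "using -log(diag)/tau")
    attr(out, "generator") <- NULL
    attr(out, "fallback") <- TRUE
    out
  }
  dec <- tryCatch(eigen(P), error = function(e) NULL)
  if (is.null(dec) || any(Mod(dec$values) < .Machine$double.eps)) {
    return(fallback())
  }
  Vi <- tryCatch(solve(dec$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(fallback())
  recon <- dec$vectors %*% diag(dec$values, M) %*% Vi
  if (max(abs(recon - P)) > 1e-8 * max(1, max(abs(P)))) return(fallback())
  L <- dec$vectors %*% diag(log(dec$values + 0i), M) %*% Vi
  if (max(abs(Im(L))) > 1e-8 * max(1, max(abs(Re(L))))) {
    return(fallback())
  }
  G <- Re(L) / tau
  offd <- G
  diag(offd) <- 0
  if (any(offd < -1e-8 * max(abs(G)))) {
    return(fallback())
  }
  out <- -diag(G)
  attr(out, "generator") <- G
  attr(out, "fallback") <- FALSE
  out
}

#' FRET efficiency from transfer and donor rates
#'
#' The probability that donor de-excitation proceeds through energy transfer
#' rather than donor photon emission: `lambdaFret / (lambdaFret + lambdaD)`.
#'
#' @param lambdaFret FRET transfer rate(s), 1/s (vectorised).
#' @param lambdaD donor relaxation rate, 1/s.
#' @return efficiency value(s) in `[0, 1]`.
#' @examples
#' fretEfficiency(8.06e7, 1 / 3.5e-9)  # ~ 0.22
#' @export
fretEfficiency <- function(lambdaFret, lambdaD) {
  if (any(lambdaFret < 0) || any(lambdaD <= 0)) {
    stop("'lambdaFret' must be >= 0 and 'lambdaD' > 0")
  }
  lambdaFret / (lambdaFret + lambdaD)
}

## Convolution of a unit-amplitude exponential decay exp(-lambda*t), t >= 0,
## with a Gaussian N(m, s^2): the exponentially modified Gaussian kernel.
## Evaluated through pnorm's log tail so it is stable for all arguments.
.expGaussDecay <- function(mu, lambda, m, s) {
  if (s <= 0) {
    out <- ifelse(mu >= m, exp(-lambda * (mu - m)), 0)
    return(out)
  }
  a <- lambda * (m - mu + 0.5 * lambda * s^2)
  u <- (m + lambda * s^2 - mu) / s
  exp(a + pnorm(u, lower.tail = FALSE, log.p = TRUE))
}

## Derivative form used in the equal-rate (Erlang) limit of the acceptor
## density: convolution of t*exp(-lambda*t) with the Gaussian IRF.
.expGaussDecayT <- function(mu, lambda, m, s) {
  g <- .expGaussDecay(mu, lambda, m, s)
  if (s <= 0) {
    return(pmax(mu - m, 0) * g)
  }
  (mu - m - lambda * s^2) * g + s^2 * dnorm(mu, mean = m, sd = s)
}

## relative gap below which the acceptor density switches to its Erlang limit
.EQUAL_RATE_TOL <- 1e-7

#' Microtime density of donor-band photons
#'
#' Emission-time density of a photon emitted in the donor spectral band while
#' the system is in state `stateIndex`: the donor decays in an exponential
#' race against FRET, so emission times follow
#' `lambdaD * exp(-(lambdaD + lambdaFret) * t)`, convolved with the Gaussian
#' IRF and scaled by the per-pulse excitation probability `piEx`.  The result
#' integrates (over the real line) to `piEx * lambdaD / (lambdaD + lambdaFret)`,
#' the probability that a pulse produces a donor-band photon.
#'
#' @param mu microtime(s), s (vectorised).
#' @param stateIndex system state index.
#' @param params a [PhotophysicsParams-class].
#' @param det a [DetectorModel-class] (provides the IRF).
#' @return density value(s), 1/s.
#' @export
donorMicrotimeDensity <- function(mu, stateIndex, params, det) {
  lt <- params@lambdaD + params@lambdaFret[stateIndex]
  params@piEx * params@lambdaD *
    .expGaussDecay(mu, lt, det@irfMean, det@irfSigma)
}

#' Microtime density of acceptor-band photons
#'
#' Emission-time density of a photon emitted in the acceptor band in system
#' state `stateIndex`: FRET transfer (rate `lambdaFret`, competing with donor
#' emission) followed by acceptor emission (rate `lambdaA`) gives a
#' hypoexponential arrival time, convolved with the Gaussian IRF and scaled
#' by `piEx`.  Integrates to `piEx * lambdaFret / (lambdaD + lambdaFret)`.
#' The `lambdaA -> lambdaD + lambdaFret` degeneracy is handled by the Erlang
#' limit.
#'
#' @inheritParams donorMicrotimeDensity
#' @return density value(s), 1/s.
#' @export
acceptorMicrotimeDensity <- function(mu, stateIndex, params, det) {
  lf <- params@lambdaFret[stateIndex]
  if (lf == 0) {
    return(rep(0, length(mu)))
  }
  lt <- params@lambdaD + lf
  la <- params@lambdaA
  m <- det@irfMean
  s <- det@irfSigma
  if (abs(la - lt) <= .EQUAL_RATE_TOL * lt) {
    dens <- lf * lt * .expGaussDecayT(mu, lt, m, s)
  } else {
    dens <- lf * la / (la - lt) *
      (.expGaussDecay(mu, lt, m, s) - .expGaussDecay(mu, la, m, s))
  }
  params@piEx * pmax(dens, 0)
}

#' Per-pulse outcome model for one system state
#'
#' Combines the band emission model with the detection path: crosstalk and
#' detection efficiency (`routeMatrix`), Gaussian IRF, and per-channel
#' background.  The outcome space of one pulse is
#' `{(empty, empty), (muD, empty), (empty, muA), (muD, muA)}`; photon
#' outcomes carry densities over microtimes, the empty outcome carries a
#' point mass, and the four pieces sum to exactly 1.  Signal and background
#' in the same channel enter as an additive mixture; the (tiny) probability
#' that both occur in one channel is folded into the empty-pulse mass rather
#' than the density shapes, and both-channel pulses are modelled as signal in
#' one channel times background in the other, symmetrised, since a single
#' excitation cannot emit in both bands.
#'
#' @param stateIndex system state index.
#' @param params a [PhotophysicsParams-class].
#' @param det a [DetectorModel-class].
#' @return a list with elements
#'   `pEmpty` (mass of the empty pulse),
#'   `pDonor`, `pAcceptor` (masses of the one-photon outcomes),
#'   `pBoth` (mass of the two-photon outcome),
#'   `densityDonor(mu)`, `densityAcceptor(mu)` (one-photon outcome
#'   densities, 1/s), and `densityBoth(muD, muA)` (two-photon density, 1/s^2).
#' @export
pulseOutcomeModel <- function(stateIndex, params, det) {
  r <- det@routeMatrix
  if (any(rowSums(r) > 1 + 1e-12)) {
    stop("'routeMatrix' rows must sum to at most 1")
  }
  lf <- params@lambdaFret[stateIndex]
  lt <- params@lambdaD + lf
  tau <- params@tau
  bg <- det@bgProb
  pBandD <- params@lambdaD / lt
  pBandA <- lf / lt
  pd <- params@piEx * (r[1, 1] * pBandD + r[2, 1] * pBandA)
  pa <- params@piEx * (r[1, 2] * pBandD + r[2, 2] * pBandA)
  q <- 1 - pd - pa
  sigD <- function(mu) {
    r[1, 1] * donorMicrotimeDensity(mu, stateIndex, params, det) +
      r[2, 1] * acceptorMicrotimeDensity(mu, stateIndex, params, det)
  }
  sigA <- function(mu) {
    r[1, 2] * donorMicrotimeDensity(mu, stateIndex, params, det) +
      r[2, 2] * acceptorMicrotimeDensity(mu, stateIndex, params, det)
  }
  list(
    pEmpty = q * (1 - bg[1]) * (1 - bg[2]) +
      pd * bg[1] * (1 - bg[2]) + pa * bg[2] * (1 - bg[1]),
    pDonor = (pd * (1 - bg[1]) + q * bg[1]) * (1 - bg[2]),
    pAcceptor = (pa * (1 - bg[2]) + q * bg[2]) * (1 - bg[1]),
    pBoth = pd * bg[2] + pa * bg[1] + q * bg[1] * bg[2],
    densityDonor = function(mu) {
      (sigD(mu) * (1 - bg[1]) + q * bg[1] / tau) * (1 - bg[2])
    },
    densityAcceptor = function(mu) {
      (sigA(mu) * (1 - bg[2]) + q * bg[2] / tau) * (1 - bg[1])
    },
    densityBoth = function(muD, muA) {
      sigD(muD) * bg[2] / tau + sigA(muA) * bg[1] / tau +
        q * bg[1] * bg[2] / tau^2
    }
  )
}

#' Detection matrix for one pulse observation
#'
#' Evaluates the per-pulse outcome model of every system state at one
#' observation and arranges the values as an MxM matrix whose row `i` is
#' constant and equal to `p(w | s = i)`: the observation probability does not
#' depend on the next state, so columns are identical.  Element-wise
#' multiplication with the system propagator (see [reducedPropagator()])
#' yields the per-pulse factor of the trace likelihood.
#'
#' @param obs a [PulseObservation-class].
#' @param params a [PhotophysicsParams-class].
#' @param det a [DetectorModel-class].
#' @return MxM matrix with constant rows.
#' @export
buildDetectionMatrix <- function(obs, params, det) {
  M <- length(params@lambdaFret)
  vals <- vapply(seq_len(M), function(i) {
    om <- pulseOutcomeModel(i, params, det)
    if (is.na(obs@muD) && is.na(obs@muA)) {
      om$pEmpty
    } else if (!is.na(obs@muD) && is.na(obs@muA)) {
      om$densityDonor(obs@muD)
    } else if (is.na(obs@muD) && !is.na(obs@muA)) {
      om$densityAcceptor(obs@muA)
    } else {
      om$densityBoth(obs@muD, obs@muA)
    }
  }, numeric(1))
  matrix(vals, nrow = M, ncol = M)
}

#' Reduced per-pulse propagator
#'
#' Element-wise product of the system propagator with a detection matrix:
#' the per-pulse factor `P * D` whose ordered product over pulses gives the
#' trace likelihood.
#'
#' @param transProb MxM system propagator.
#' @param detMatrix MxM detection matrix (see [buildDetectionMatrix()]).
#' @return MxM matrix `transProb * detMatrix` (element-wise).
#' @export
reducedPropagator <- function(transProb, detMatrix) {
  if (!identical(dim(as.matrix(transProb)), dim(as.matrix(detMatrix)))) {
    stop("'transProb' and 'detMatrix' must have identical dimensions")
  }
  as.matrix(transProb) * as.matrix(detMatrix)
}

## Convert a PhotonTrace into the photon-epoch representation consumed by the
## C++ core: one record per pulse that carries at least one photon, with the
## number of empty pulses preceding it and the empty tail after the last one.
.traceEpochs <- function(trace) {
  ph <- trace@photons
  if (!nrow(ph)) {
    return(list(gap = numeric(), muD = numeric(), muA = numeric(),
                hasD = integer(), hasA = integer(),
                tailGap = trace@nPulses))
  }
  pulses <- unique(ph$pulseIndex)
  idx <- match(ph$pulseIndex, pulses)
  muD <- rep(NA_real_, length(pulses))
  muA <- rep(NA_real_, length(pulses))
  isD <- ph$channel == 1L
  muD[idx[isD]] <- ph$microtime[isD]
  muA[idx[!isD]] <- ph$microtime[!isD]
  gap <- diff(c(0, pulses)) - 1
  list(gap = as.numeric(gap),
       muD = ifelse(is.na(muD), -1, muD),
       muA = ifelse(is.na(muA), -1, muA),
       hasD = as.integer(!is.na(muD)),
       hasA = as.integer(!is.na(muA)),
       tailGap = as.numeric(trace@nPulses - pulses[length(pulses)]))
}

## flatten model objects for the C++ core
.modelArgs <- function(params, det) {
  list(lambdaD = params@lambdaD, lambdaA = params@lambdaA,
       lambdaFret = params@lambdaFret, piEx = params@piEx, tau = params@tau,
       route = det@routeMatrix, irfMean = det@irfMean,
       irfSigma = det@irfSigma, bgProb = det@bgProb)
}

#' Log likelihood of a photon trace
#'
#' Evaluates the trace likelihood: the ordered product of reduced per-pulse
#' propagators contracted between the initial state distribution and the
#' all-ones summation vector, computed in a numerically scaled forward pass.
#' Runs of empty pulses are collapsed into matrix powers of the empty-pulse
#' propagator (cached dyadic powers with per-level rescaling), so the cost is
#' linear in the number of photons, not pulses.
#'
#' @param trace a [PhotonTrace-class].
#' @param kin a [SystemKinetics-class] (its `transProb` and `rhoStart` are
#'   used).
#' @param params a [PhotophysicsParams-class] with one FRET rate per system
#'   state.
#' @param det a [DetectorModel-class].
#' @return the log likelihood (`-Inf` for an impossible trace, with a
#'   diagnostic attribute `impossible = TRUE`).
#' @export
traceLogLikelihood <- function(trace, kin, params, det) {
  M <- nrow(kin@transProb)
  if (length(params@lambdaFret) != M) {
    stop("number of FRET rates must match the number of system states")
  }
  if (abs(params@tau - trace@tau) > 1e-15 + 1e-9 * params@tau) {
    stop("trace and params disagree on the interpulse period")
  }
  ep <- .traceEpochs(trace)
  ll <- cpp_trace_loglik(ep, kin@transProb, kin@rhoStart,
                         .modelArgs(params, det), trace@nPulses)
  if (!is.finite(ll)) {
    attr(ll, "impossible") <- TRUE
  }
  ll
}
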