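#' @useDynLib pulseFRET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats density dgamma dbeta rgamma rnorm runif rbeta quantile
#'   ks.test integrate setNames approxfun pnorm dnorm rexp qlogis plogis sd
#' @importFrom utils head tail
NULL

## Ratio of interpulse period to the slowest photophysical lifetime below which
## the discrete-pulse factorisation (fluorophores relax to the ground state
## between pulses) becomes questionable.  Constructors warn below this.
.LIFETIME_MARGIN <- 5

#' Per-state photophysical rates of a FRET pair under pulsed excitation
#'
#' Holds the donor and acceptor relaxation rates (inverse lifetimes), the
#' FRET transfer rate in each system (conformational) state, the per-pulse
#' donor excitation probability, and the interpulse period.  Together these
#' determine the per-pulse emission physics: with probability `piEx` a pulse
#' excites the donor, which then de-excites through an exponential race
#' between photon emission (rate `lambdaD`) and energy transfer to the
#' acceptor (rate `lambdaFret[s]` in system state `s`); after transfer the
#' acceptor emits with rate `lambdaA`.
#'
#' @slot lambdaD donor relaxation rate, 1/s (inverse donor lifetime).
#' @slot lambdaA acceptor relaxation rate, 1/s.
#' @slot lambdaFret numeric vector of FRET rates, 1/s, one per system state.
#' @slot piEx per-pulse donor excitation probability, in `[0, 1]`.
#' @slot tau interpulse period, s.
#' @name PhotophysicsParams-class
#' @rdname PhotophysicsParams
#' @exportClass PhotophysicsParams
setClass("PhotophysicsParams",
  representation(
    lambdaD = "numeric",
    lambdaA = "numeric",
    lambdaFret = "numeric",
    piEx = "numeric",
    tau = "numeric"
  )
)

setValidity("PhotophysicsParams", function(object) {
  msg <- character()
  if (length(object@lambdaD) != 1L || !is.finite(object@lambdaD) ||
      object@lambdaD <= 0) {
    msg <- c(msg, "'lambdaD' must be a single positive rate (1/s)")
  }
  if (length(object@lambdaA) != 1L || !is.finite(object@lambdaA) ||
      object@lambdaA <= 0) {
    msg <- c(msg, "'lambdaA' must be a single positive rate (1/s)")
  }
  if (length(object@lambdaFret) < 1L || any(!is.finite(object@lambdaFret)) ||
      any(object@lambdaFret < 0)) {
    msg <- c(msg, "'lambdaFret' must be non-negative rates, one per system state")
  }
  if (length(object@piEx) != 1L || is.na(object@piEx) ||
      object@piEx < 0 || object@piEx > 1) {
    msg <- c(msg, "'piEx' must be a probability in [0, 1]")
  }
  if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0) {
    msg <- c(msg, "'tau' must be a single positive time (s)")
  }
  if (length(msg)) msg else TRUE
})

#' @param lambdaD,lambdaA,lambdaFret,piEx,tau see slots.
#' @return a validated `PhotophysicsParams` object.
#' @examples
#' PhotophysicsParams(lambdaD = 1 / 3.5e-9, lambdaA = 1 / 3e-9,
#'                    lambdaFret = c(8.06e7, 4.11e8), piEx = 1e-3, tau = 25e-9)
#' @rdname PhotophysicsParams
#' @export
PhotophysicsParams <- function(lambdaD, lambdaA, lambdaFret, piEx, tau) {
  obj <- new("PhotophysicsParams", lambdaD = as.numeric(lambdaD),
             lambdaA = as.numeric(lambdaA),
             lambdaFret = as.numeric(lambdaFret),
             piEx = as.numeric(piEx), tau = as.numeric(tau))
  lifetime <- max(1 / obj@lambdaD, 1 / obj@lambdaA)
  if (obj@tau < .LIFETIME_MARGIN * lifetime) {
    warning(sprintf(paste0(
      "interpulse period tau = %.3g s is less than %d times the slowest ",
      "fluorophore lifetime (%.3g s); the assumption that dyes relax to the ",
      "ground state between pulses may be violated"),
      obj@tau, .LIFETIME_MARGIN, lifetime))
  }
  obj
}

#' Detection-path calibration: crosstalk, IRF, and background
#'
#' Describes everything that happens to an emitted photon between the molecule
#' and the recorded (channel, microtime) pair.  `routeMatrix[j, k]` is the
#' probability that a photon emitted in spectral band `j` (1 = donor band,
#' 2 = acceptor band) is detected in channel `k` (1 = donor channel,
#' 2 = acceptor channel); row sums at most 1, the deficit being photon loss
#' (detection inefficiency).  Detector timing jitter is Gaussian with mean
#' `irfMean` and width `irfSigma`.  Each channel independently registers a
#' background photon in a pulse window with probability `bgProb[k]`, uniformly
#' distributed over the window.
#'
#' @slot routeMatrix 2x2 crosstalk/detection-efficiency matrix.
#' @slot irfMean Gaussian IRF offset, s.
#' @slot irfSigma Gaussian IRF width, s.
#' @slot bgProb length-2 per-channel background probability per pulse.
#' @name DetectorModel-class
#' @rdname DetectorModel
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(
    routeMatrix = "matrix",
    irfMean = "numeric",
    irfSigma = "numeric",
    bgProb = "numeric"
  )
)

setValidity("DetectorModel", function(object) {
  msg <- character()
  rm_ <- object@routeMatrix
  if (!is.numeric(rm_) || !identical(dim(rm_), c(2L, 2L)) ||
      any(!is.finite(rm_)) || any(rm_ < 0)) {
    msg <- c(msg, "'routeMatrix' must be a non-negative 2x2 numeric matrix")
  } else if (any(rowSums(rm_) > 1 + 1e-12)) {
    msg <- c(msg, "'routeMatrix' rows must sum to at most 1")
  }
  if (length(object@irfMean) != 1L || !is.finite(object@irfMean)) {
    msg <- c(msg, "'irfMean' must be a single finite time (s)")
  }
  if (length(object@irfSigma) != 1L || !is.finite(object@irfSigma) ||
      object@irfSigma < 0) {
    msg <- c(msg, "'irfSigma' must be a single non-negative time (s)")
  }
  if (length(object@bgProb) != 2L || any(!is.finite(object@bgProb)) ||
      any(object@bgProb < 0) || any(object@bgProb >= 1)) {
    msg <- c(msg, "'bgProb' must be two probabilities in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @param routeMatrix,irfMean,irfSigma,bgProb see slots.
#' @return a validated `DetectorModel`.
#' @examples
#' DetectorModel(routeMatrix = rbind(c(0.55, 0.05), c(0, 0.6)),
#'               irfMean = 1e-9, irfSigma = 1e-10, bgProb = c(1e-5, 1e-5))
#' @rdname DetectorModel
#' @export
DetectorModel <- function(routeMatrix = diag(2), irfMean = 0, irfSigma = 0,
                          bgProb = c(0, 0)) {
  new("DetectorModel", routeMatrix = matrix(as.numeric(routeMatrix), 2L, 2L),
      irfMean = as.numeric(irfMean), irfSigma = as.numeric(irfSigma),
      bgProb = as.numeric(bgProb))
}

#' Sparse pulse-indexed single-photon trace
#'
#' The raw observations of a pulsed-illumination smFRET experiment: for each
#' of `nPulses` equally spaced laser pulses, at most one photon per detection
#' channel, recorded as `(pulseIndex, channel, microtime)` with the microtime
#' measured from the pulse.  Pulse indices are 1-based internally; the on-disk
#' CSV layout is 0-based (see [readTrace()]).
#'
#' @slot nPulses total number of pulses `N`.
#' @slot tau interpulse period, s.
#' @slot photons `data.frame` with columns `pulseIndex` (integer-valued, in
#'   `[1, nPulses]`), `channel` (1 = donor, 2 = acceptor), `microtime` (s,
#'   in `[0, tau)`), sorted by pulse index.
#' @name PhotonTrace-class
#' @rdname PhotonTrace
#' @exportClass PhotonTrace
setClass("PhotonTrace",
  representation(
    nPulses = "numeric",
    tau = "numeric",
    photons = "data.frame"
  )
)

setValidity("PhotonTrace", function(object) {
  msg <- character()
  if (length(object@nPulses) != 1L || !is.finite(object@nPulses) ||
      object@nPulses < 1 || object@nPulses != round(object@nPulses)) {
    msg <- c(msg, "'nPulses' must be a single positive integer count")
  }
  if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau <= 0) {
    msg <- c(msg, "'tau' must be a single positive time (s)")
  }
  ph <- object@photons
  need <- c("pulseIndex", "channel", "microtime")
  if (!all(need %in% names(ph))) {
    msg <- c(msg, sprintf("'photons' must have columns %s",
                          paste(need, collapse = ", ")))
    return(msg)
  }
  if (nrow(ph)) {
    if (any(ph$pulseIndex < 1) || any(ph$pulseIndex > object@nPulses) ||
        any(ph$pulseIndex != round(ph$pulseIndex))) {
      msg <- c(msg, "photon pulse indices must be integers in [1, nPulses]")
    }
    if (!all(ph$channel %in% c(1L, 2L))) {
      msg <- c(msg, "photon channels must be 1 (donor) or 2 (acceptor)")
    }
    if (any(ph$microtime < 0) || any(ph$microtime >= object@tau)) {
      msg <- c(msg, "microtimes must lie in [0, tau)")
    }
    if (anyDuplicated(ph[, c("pulseIndex", "channel")])) {
      msg <- c(msg, "at most one photon per (pulseIndex, channel)")
    }
    if (is.unsorted(ph$pulseIndex)) {
      msg <- c(msg, "'photons' must be sorted by pulseIndex")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param nPulses,tau see slots.
#' @param pulseIndex,channel,microtime photon record columns (equal length).
#' @return a validated `PhotonTrace`.
#' @examples
#' PhotonTrace(nPulses = 100, tau = 25e-9,
#'             pulseIndex = c(3, 40), channel = c(1, 2),
#'             microtime = c(2e-9, 5e-9))
#' @rdname PhotonTrace
#' @export
PhotonTrace <- function(nPulses, tau, pulseIndex = integer(),
                        channel = integer(), microtime = numeric()) {
  ph <- data.frame(pulseIndex = as.numeric(pulseIndex),
                   channel = as.integer(channel),
                   microtime = as.numeric(microtime))
  ph <- ph[order(ph$pulseIndex, ph$channel), , drop = FALSE]
  rownames(ph) <- NULL
  new("PhotonTrace", nPulses = as.numeric(nPulses), tau = as.numeric(tau),
      photons = ph)
}

#' System-state kinetics: rate matrix, pulse-to-pulse propagator, start vector
#'
#' The conformational dynamics of the labelled molecule.  Because typical
#' system kinetics (ms) are much slower than the interpulse period (tens of
#' ns), the system state is constant within a pulse window and evolves as a
#' discrete-time Markov chain with transition matrix
#' `transProb = expm(tau * rateMatrix)` between consecutive pulses.
#'
#' @slot rateMatrix Mx M continuous-time generator, 1/s (off-diagonals >= 0,
#'   rows sum to 0); may be a 0x0 matrix when only `transProb` is known.
#' @slot transProb MxM row-stochastic pulse-to-pulse transition matrix.
#' @slot rhoStart length-M initial state probability vector (sums to 1).
#' @name SystemKinetics-class
#' @rdname SystemKinetics
#' @exportClass SystemKinetics
setClass("SystemKinetics",
  representation(
    rateMatrix = "matrix",
    transProb = "matrix",
    rhoStart = "numeric"
  )
)

setValidity("SystemKinetics", function(object) {
  msg <- character()
  P <- object@transProb
  M <- nrow(P)
  if (!is.numeric(P) || M < 1L || ncol(P) != M || any(!is.finite(P)) ||
      any(P < 0)) {
    msg <- c(msg, "'transProb' must be a non-negative square matrix")
  } else if (any(abs(rowSums(P) - 1) > 1e-12)) {
    msg <- c(msg, "'transProb' rows must sum to 1 (within 1e-12)")
  }
  G <- object@rateMatrix
  if (length(G)) {
    if (nrow(G) != M || ncol(G) != M) {
      msg <- c(msg, "'rateMatrix' must match the dimension of 'transProb'")
    } else {
      offd <- G; diag(offd) <- 0
      if (any(offd < 0) || any(abs(rowSums(G)) > 1e-8 * max(1, max(abs(G))))) {
        msg <- c(msg, "'rateMatrix' must have non-negative off-diagonals and zero row sums")
      }
    }
  }
  r <- object@rhoStart
  if (length(r) != M || any(r < 0) || abs(sum(r) - 1) > 1e-8) {
    msg <- c(msg, "'rhoStart' must be a length-M probability vector")
  }
  if (length(msg)) msg else TRUE
})

#' @param rateMatrix optional generator (1/s); used with `tau` to build the
#'   propagator when `transProb` is not given.
#' @param tau interpulse period (s); required when `transProb` is derived from
#'   `rateMatrix`.
#' @param transProb optional row-stochastic propagator; computed from
#'   `rateMatrix` when missing.
#' @param rhoStart initial state probabilities; defaults to uniform.
#' @return a validated `SystemKinetics`.
#' @examples
#' G <- rbind(c(-40, 40), c(40, -40))
#' SystemKinetics(rateMatrix = G, tau = 25e-9)
#' @rdname SystemKinetics
#' @export
SystemKinetics <- function(rateMatrix = NULL, tau = NULL, transProb = NULL,
                           rhoStart = NULL) {
  if (is.null(transProb)) {
    if (is.null(rateMatrix) || is.null(tau)) {
      stop("supply either 'transProb' or both 'rateMatrix' and 'tau'")
    }
    transProb <- buildSystemPropagator(rateMatrix, tau)
  }
  transProb <- as.matrix(transProb)
  if (is.null(rhoStart)) rhoStart <- rep(1 / nrow(transProb), nrow(transProb))
  if (is.null(rateMatrix)) rateMatrix <- matrix(numeric(), 0L, 0L)
  new("SystemKinetics", rateMatrix = as.matrix(rateMatrix),
      transProb = transProb, rhoStart = as.numeric(rhoStart))
}

#' Ground-truth simulation configuration
#'
#' @slot kin `SystemKinetics` ground truth.
#' @slot params `PhotophysicsParams` ground truth.
#' @slot det `DetectorModel` calibration.
#' @slot nPulses number of pulses to simulate.
#' @slot seed integer RNG seed.
#' @name SimulationConfig-class
#' @rdname SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    kin = "SystemKinetics",
    params = "PhotophysicsParams",
    det = "DetectorModel",
    nPulses = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPulses < 1 || object@nPulses != round(object@nPulses)) {
    msg <- c(msg, "'nPulses' must be a positive integer count")
  }
  M <- nrow(object@kin@transProb)
  if (length(object@params@lambdaFret) != M) {
    msg <- c(msg, "length(lambdaFret) must equal the number of system states")
  }
  if (length(msg)) msg else TRUE
})

#' @param kin,params,det,nPulses,seed see slots.
#' @return a validated `SimulationConfig`.
#' @rdname SimulationConfig
#' @export
SimulationConfig <- function(kin, params, det, nPulses, seed = 1L) {
  new("SimulationConfig", kin = kin, params = params, det = det,
      nPulses = as.numeric(nPulses), seed = as.integer(seed))
}

#' Simulated dataset with its generating trajectory
#'
#' @slot trace the simulated `PhotonTrace`.
#' @slot trajectory run-length-encoded system state trajectory: `data.frame`
#'   with columns `state` and `length` whose lengths sum to `nPulses`.
#' @slot config the `SimulationConfig` that produced it.
#' @name GroundTruthDataset-class
#' @rdname GroundTruthDataset
#' @exportClass GroundTruthDataset
setClass("GroundTruthDataset",
  representation(
    trace = "PhotonTrace",
    trajectory = "data.frame",
    config = "SimulationConfig"
  )
)

setValidity("GroundTruthDataset", function(object) {
  msg <- character()
  if (!all(c("state", "length") %in% names(object@trajectory))) {
    msg <- c(msg, "'trajectory' needs columns 'state' and 'length'")
  } else if (sum(object@trajectory$length) != object@trace@nPulses) {
    msg <- c(msg, "trajectory run lengths must sum to nPulses")
  }
  if (length(msg)) msg else TRUE
})

#' Prior hyperparameters for the Gibbs sampler
#'
#' Dirichlet prior on each transition-matrix row (`Dirichlet(alpha * beta)`),
#' Gamma priors on all photophysical rates, a Dirichlet prior on the initial
#' state probabilities, and a Beta prior on the per-pulse excitation
#' probability.
#'
#' @slot alpha Dirichlet concentration for transition rows.
#' @slot beta base probability vector for transition rows; length 0 means
#'   uniform over however many states the sampler uses.
#' @slot lambdaDShape,lambdaDRate Gamma hyperparameters for the donor rate.
#' @slot lambdaAShape,lambdaARate Gamma hyperparameters for the acceptor rate.
#' @slot lambdaFretShape,lambdaFretRate Gamma hyperparameters for FRET rates.
#' @slot rhoConcentration Dirichlet concentration for `rhoStart`.
#' @slot piExShape1,piExShape2 Beta hyperparameters for `piEx`.
#' @name PriorSpec-class
#' @rdname PriorSpec
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(
    alpha = "numeric",
    beta = "numeric",
    lambdaDShape = "numeric", lambdaDRate = "numeric",
    lambdaAShape = "numeric", lambdaARate = "numeric",
    lambdaFretShape = "numeric", lambdaFretRate = "numeric",
    rhoConcentration = "numeric",
    piExShape1 = "numeric", piExShape2 = "numeric"
  )
)

setValidity("PriorSpec", function(object) {
  msg <- character()
  pos <- c(alpha = object@alpha,
           lambdaDShape = object@lambdaDShape, lambdaDRate = object@lambdaDRate,
           lambdaAShape = object@lambdaAShape, lambdaARate = object@lambdaARate,
           lambdaFretShape = object@lambdaFretShape,
           lambdaFretRate = object@lambdaFretRate,
           rhoConcentration = object@rhoConcentration,
           piExShape1 = object@piExShape1, piExShape2 = object@piExShape2)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    msg <- c(msg, sprintf("hyperparameters must be positive: %s",
                          paste(bad, collapse = ", ")))
  }
  if (length(object@beta)) {
    if (any(object@beta < 0) || abs(sum(object@beta) - 1) > 1e-8) {
      msg <- c(msg, "'beta' must be a probability vector summing to 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param alpha,beta,rhoConcentration see slots.
#' @param lambdaDShape,lambdaDRate,lambdaAShape,lambdaARate Gamma
#'   hyperparameters; defaults are exponential priors with mean 5e8 1/s,
#'   broad on the nanosecond-lifetime scale.
#' @param lambdaFretShape,lambdaFretRate Gamma hyperparameters for FRET rates.
#' @param piExShape1,piExShape2 Beta hyperparameters for `piEx`.
#' @return a validated `PriorSpec`.
#' @rdname PriorSpec
#' @export
PriorSpec <- function(alpha = 1, beta = numeric(),
                      lambdaDShape = 1, lambdaDRate = 2e-9,
                      lambdaAShape = 1, lambdaARate = 2e-9,
                      lambdaFretShape = 1, lambdaFretRate = 2e-9,
                      rhoConcentration = 1,
                      piExShape1 = 1, piExShape2 = 1) {
  new("PriorSpec", alpha = alpha, beta = as.numeric(beta),
      lambdaDShape = lambdaDShape, lambdaDRate = lambdaDRate,
      lambdaAShape = lambdaAShape, lambdaARate = lambdaARate,
      lambdaFretShape = lambdaFretShape, lambdaFretRate = lambdaFretRate,
      rhoConcentration = rhoConcentration,
      piExShape1 = piExShape1, piExShape2 = piExShape2)
}

#' Truncated hierarchical-Dirichlet-process configuration
#'
#' Settings for the infinite-HMM prior: the state space is truncated at
#' `mMax` states, the top-level Dirichlet process draws the base measure
#' `beta ~ Dirichlet(gamma/mMax, ..., gamma/mMax)` (or fixes it uniform when
#' `sampleBeta = FALSE`), and each transition row gets prior
#' `Dirichlet(alpha * beta)`.
#'
#' @slot mMax truncation level (number of candidate states).
#' @slot gamma top-level Dirichlet process concentration.
#' @slot alpha second-level concentration.
#' @slot sampleBeta resample `beta` by the auxiliary-table scheme (`TRUE`) or
#'   keep it fixed uniform (`FALSE`, the default simplification).
#' @name HDPConfig-class
#' @rdname HDPConfig
#' @exportClass HDPConfig
setClass("HDPConfig",
  representation(
    mMax = "integer",
    gamma = "numeric",
    alpha = "numeric",
    sampleBeta = "logical"
  )
)

setValidity("HDPConfig", function(object) {
  msg <- character()
  if (object@mMax < 2L) msg <- c(msg, "'mMax' must be at least 2")
  if (!is.finite(object@gamma) || object@gamma <= 0) {
    msg <- c(msg, "'gamma' must be positive")
  }
  if (!is.finite(object@alpha) || object@alpha <= 0) {
    msg <- c(msg, "'alpha' must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' @param mMax,gamma,alpha,sampleBeta see slots.
#' @return a validated `HDPConfig`.
#' @rdname HDPConfig
#' @export
HDPConfig <- function(mMax = 10L, gamma = 1, alpha = 1, sampleBeta = FALSE) {
  new("HDPConfig", mMax = as.integer(mMax), gamma = gamma, alpha = alpha,
      sampleBeta = sampleBeta)
}

#' MCMC output of the parametric or nonparametric sampler
#'
#' Per-sweep posterior samples.  State-indexed quantities have one column per
#' candidate state (M for the parametric sampler, `mMax` for the
#' nonparametric one).
#'
#' @slot nSweeps number of recorded sweeps.
#' @slot mMax number of candidate states carried by the sampler.
#' @slot nPulses,tau properties of the analysed trace.
#' @slot transProb `mMax x mMax x nSweeps` array of sampled propagators.
#' @slot lambdaD,lambdaA,piEx numeric vectors, one entry per sweep.
#' @slot lambdaFret,rhoStart,occupancy `nSweeps x mMax` matrices; `occupancy`
#'   counts pulses assigned to each state by the sampled trajectory.
#' @slot s1 sampled initial state per sweep.
#' @slot beta sampled base measure per sweep (0-row matrix when fixed).
#' @slot logLik,logPost per-sweep log likelihood and joint log posterior
#'   density (up to a constant).
#' @slot acceptance per-block Metropolis-Hastings acceptance rates after
#'   burn-in tuning.
#' @slot proposalScales final tuned proposal scales.
#' @slot seed RNG seed of the run.
#' @slot prior the `PriorSpec` used.
#' @slot hdp the `HDPConfig` used, or `NULL` for the parametric sampler.
#' @name PosteriorChain-class
#' @rdname PosteriorChain
#' @exportClass PosteriorChain
setClass("PosteriorChain",
  representation(
    nSweeps = "integer",
    mMax = "integer",
    nPulses = "numeric",
    tau = "numeric",
    transProb = "array",
    lambdaD = "numeric",
    lambdaA = "numeric",
    lambdaFret = "matrix",
    piEx = "numeric",
    rhoStart = "matrix",
    occupancy = "matrix",
    s1 = "integer",
    beta = "matrix",
    logLik = "numeric",
    logPost = "numeric",
    acceptance = "numeric",
    proposalScales = "numeric",
    seed = "integer",
    prior = "PriorSpec",
    hdp = "ANY"
  )
)

setValidity("PosteriorChain", function(object) {
  msg <- character()
  S <- object@nSweeps; M <- object@mMax
  if (!identical(dim(object@transProb), c(M, M, S))) {
    msg <- c(msg, "'transProb' must be an mMax x mMax x nSweeps array")
  }
  for (nm in c("lambdaD", "lambdaA", "piEx", "logLik", "logPost")) {
    if (length(slot(object, nm)) != S) {
      msg <- c(msg, sprintf("'%s' must have one entry per sweep", nm))
    }
  }
  for (nm in c("lambdaFret", "rhoStart", "occupancy")) {
    if (!identical(dim(slot(object, nm)), c(S, M))) {
      msg <- c(msg, sprintf("'%s' must be nSweeps x mMax", nm))
    }
  }
  acc <- object@acceptance
  if (any(!is.na(acc) & (acc < 0 | acc > 1))) {
    msg <- c(msg, "acceptance rates must lie in [0, 1] (NA = block never tried)")
  }
  if (length(msg)) msg else TRUE
})

#' Posterior summary of states, escape rates, and FRET efficiencies
#'
#' @slot stateTable per-state summary `data.frame` (MAP values, marginal KDE
#'   modes, and central credible-interval offsets).
#' @slot modalStateCount posterior modal number of occupied states.
#' @slot stateCountDistribution named table of the posterior over occupied
#'   state counts.
#' @slot intervalMass central credible mass used for intervals.
#' @slot samples the per-sweep `(escapeRate, fretEfficiency)` table the
#'   summary was computed from (see [bivariateSamples()]).
#' @name PosteriorSummary-class
#' @rdname PosteriorSummary-class
#' @exportClass PosteriorSummary
setClass("PosteriorSummary",
  representation(
    stateTable = "data.frame",
    modalStateCount = "integer",
    stateCountDistribution = "numeric",
    intervalMass = "numeric",
    samples = "data.frame"
  )
)
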