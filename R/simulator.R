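#' Simulate a system state trajectory over pulses
#'
#' Draws a discrete-time Markov chain over pulse windows: the initial state
#' from `rhoStart`, each subsequent state from the corresponding row of the
#' pulse-to-pulse propagator.
#'
#' @param kin a [SystemKinetics-class].
#' @param nPulses number of pulses.
#' @param asRle return the run-length encoding (`data.frame` with `state`,
#'   `length`) instead of the full integer vector; the full vector is only
#'   allowed for `nPulses <= 1e7`.
#' @return integer vector of states (1-based) or its run-length encoding.
#' @examples
#' set.seed(1)
#' kin <- SystemKinetics(rateMatrix = rbind(c(-40, 40), c(40, -40)),
#'                       tau = 25e-9)
#' head(simulateSystemTrajectory(kin, 1000))
#' @export
simulateSystemTrajectory <- function(kin, nPulses, asRle = FALSE) {
  rle_ <- cpp_simulate_trajectory(kin@transProb, kin@rhoStart,
                                  as.numeric(nPulses))
  if (asRle) {
    return(data.frame(state = rle_$state, length = rle_$length))
  }
  if (nPulses > 1e7) {
    stop("full trajectories above 1e7 pulses are not expanded; use asRle = TRUE")
  }
  rep(rle_$state, times = rle_$length)
}

#' Simulate per-pulse emission events for a fixed system state
#'
#' Vectorised draw of the pulse photophysics, with the pulse treated as
#' instantaneous: with probability `1 - piEx` nothing is emitted; otherwise
#' the excited donor either emits (donor band, probability
#' `lambdaD / (lambdaD + lambdaFret)`) or transfers to the acceptor, which
#' then emits in the acceptor band.  Emission times are the race time
#' `Exp(lambdaD + lambdaFret)` plus, for acceptor photons, an independent
#' `Exp(lambdaA)` delay.
#'
#' @param stateIndex system state index.
#' @param params a [PhotophysicsParams-class].
#' @param nPulses number of pulses to draw.
#' @return `data.frame` with columns `band` (`NA` = no emission, 1 = donor
#'   band, 2 = acceptor band) and `time` (emission time, s, `NA` when no
#'   emission).
#' @export
simulatePulsePhotophysics <- function(stateIndex, params, nPulses) {
  n <- as.integer(nPulses)
  lf <- params@lambdaFret[stateIndex]
  lt <- params@lambdaD + lf
  excited <- runif(n) < params@piEx
  band <- rep(NA_integer_, n)
  time <- rep(NA_real_, n)
  ne <- sum(excited)
  if (ne) {
    fret <- runif(ne) < lf / lt
    t0 <- stats::rexp(ne, rate = lt)
    t0[fret] <- t0[fret] + stats::rexp(sum(fret), rate = params@lambdaA)
    band[excited] <- ifelse(fret, 2L, 1L)
    time[excited] <- t0
  }
  data.frame(band = band, time = time)
}

#' Apply detector effects to emission events
#'
#' Routes each emitted photon to a detection channel (or loses it) according
#' to the crosstalk/efficiency matrix, adds Gaussian IRF jitter with the
#' microtime clamped into `[0, tau)`, and injects per-channel uniform
#' background photons; when a channel would receive two photons in one pulse
#' the earlier one is kept.
#'
#' @param events `data.frame` as returned by [simulatePulsePhotophysics()].
#' @param det a [DetectorModel-class].
#' @param tau interpulse period (s).
#' @return `data.frame` with columns `muD` and `muA` (microtimes, `NA` when
#'   no photon), one row per pulse.
#' @export
applyDetectorEffects <- function(events, det, tau) {
  n <- nrow(events)
  muD <- rep(NA_real_, n)
  muA <- rep(NA_real_, n)
  has <- !is.na(events$band)
  if (any(has)) {
    band <- events$band[has]
    p0 <- det@routeMatrix[band, 1]
    p1 <- det@routeMatrix[band, 2]
    u <- runif(sum(has))
    ch <- ifelse(u < p0, 1L, ifelse(u < p0 + p1, 2L, NA_integer_))
    t <- events$time[has] + det@irfMean
    if (det@irfSigma > 0) t <- t + rnorm(sum(has), sd = det@irfSigma)
    t <- pmin(pmax(t, 0), tau * (1 - 1e-12))
    idx <- which(has)
    dsel <- !is.na(ch) & ch == 1L
    asel <- !is.na(ch) & ch == 2L
    muD[idx[dsel]] <- t[dsel]
    muA[idx[asel]] <- t[asel]
  }
  bgD <- runif(n) < det@bgProb[1]
  bgA <- runif(n) < det@bgProb[2]
  if (any(bgD)) {
    tb <- runif(sum(bgD)) * tau
    muD[bgD] <- pmin(muD[bgD], tb, na.rm = TRUE)
  }
  if (any(bgA)) {
    tb <- runif(sum(bgA)) * tau
    muA[bgA] <- pmin(muA[bgA], tb, na.rm = TRUE)
  }
  data.frame(muD = muD, muA = muA)
}

#' Generate a complete synthetic ground-truth dataset
#'
#' Composes the trajectory, pulse-photophysics, and detector simulators in a
#' single pulse-by-pulse pass (in compiled code) and returns the photon trace
#' together with the generating state trajectory.  Deterministic given
#' `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruthDataset-class]; the per-photon generating states are
#'   attached to the photon table as column `state`.
#' @examples
#' cfg <- twoStateBenchmarkConfig(nPulses = 1e5, seed = 7)
#' ds <- generateDataset(cfg)
#' ds
#' @export
generateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed)
  sim <- cpp_simulate(config@kin@transProb, config@kin@rhoStart,
                      .modelArgs(config@params, config@det),
                      config@nPulses)
  trace <- PhotonTrace(nPulses = config@nPulses, tau = config@params@tau,
                       pulseIndex = sim$pulseIndex, channel = sim$channel,
                       microtime = sim$microtime)
  ord <- order(sim$pulseIndex, sim$channel)
  trace@photons$state <- sim$photonState[ord]
  new("GroundTruthDataset", trace = trace,
      trajectory = data.frame(state = sim$rleState, length = sim$rleLength),
      config = config)
}

#' Benchmark configuration: two slow system states
#'
#' The canonical slow-kinetics synthetic study: two system states with escape
#' rates of 40 1/s each, FRET efficiencies 0.22 and 0.59, interpulse period
#' 25 ns, and a 500 ms trace (2e7 pulses).  Donor and acceptor lifetimes are
#' 3.5 and 3.0 ns; the excitation probability of 1e-3 per pulse and a
#' detection path with realistic efficiencies (0.55/0.60) plus 5% donor-band
#' crosstalk yield roughly 1.2e4 detected photons, inside the 1e4-1e5
#' single-molecule photon budget.  Background is 1e-5 per channel per pulse
#' (about 400 counts/s) and the IRF is Gaussian with a 1 ns offset and 0.1 ns
#' width.
#'
#' @param nPulses trace length in pulses (default 2e7 = 500 ms).
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
twoStateBenchmarkConfig <- function(nPulses = 2e7, seed = 1L) {
  lambdaD <- 1 / 3.5e-9
  eff <- c(0.22, 0.59)
  params <- PhotophysicsParams(
    lambdaD = lambdaD, lambdaA = 1 / 3e-9,
    lambdaFret = eff / (1 - eff) * lambdaD,
    piEx = 1e-3, tau = 25e-9)
  kin <- SystemKinetics(rateMatrix = rbind(c(-40, 40), c(40, -40)),
                        tau = params@tau)
  SimulationConfig(kin = kin, params = params, det = benchmarkDetector(),
                  nPulses = nPulses, seed = seed)
}

#' Benchmark configuration: three fast-switching system states
#'
#' The fast-kinetics synthetic study: three system states connected in a
#' chain through the middle state, with escape rates 1200, 2400, and 1200
#' 1/s and FRET efficiencies 0.22, 0.53, and 0.70, interpulse period 25 ns,
#' and a 150 ms trace (6e6 pulses).  The excitation probability is raised to
#' 5e-3 per pulse (about 1.8e4 detected photons) so that each ~1 ms dwell
#' still carries enough photons to resolve; detector settings match
#' [twoStateBenchmarkConfig()].
#'
#' @param nPulses trace length in pulses (default 6e6 = 150 ms).
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
threeStateBenchmarkConfig <- function(nPulses = 6e6, seed = 1L) {
  lambdaD <- 1 / 3.5e-9
  eff <- c(0.22, 0.53, 0.70)
  params <- PhotophysicsParams(
    lambdaD = lambdaD, lambdaA = 1 / 3e-9,
    lambdaFret = eff / (1 - eff) * lambdaD,
    piEx = 5e-3, tau = 25e-9)
  G <- rbind(c(-1200, 1200, 0),
             c(1200, -2400, 1200),
             c(0, 1200, -1200))
  kin <- SystemKinetics(rateMatrix = G, tau = params@tau)
  SimulationConfig(kin = kin, params = params, det = benchmarkDetector(),
                  nPulses = nPulses, seed = seed)
}

#' Shared detector calibration of the benchmark configurations
#'
#' @return a [DetectorModel-class] with detection efficiencies 0.55 (donor)
#'   and 0.60 (acceptor), 5% donor-to-acceptor crosstalk, a Gaussian IRF with
#'   1 ns offset and 0.1 ns width, and 1e-5 background per channel per pulse.
#' @export
benchmarkDetector <- function() {
  DetectorModel(routeMatrix = rbind(c(0.55, 0.05), c(0, 0.60)),
                irfMean = 1e-9, irfSigma = 1e-10,
                bgProb = c(1e-5, 1e-5))
}
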