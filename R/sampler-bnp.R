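#' Draw from the truncated hierarchical-Dirichlet-process prior
#'
#' Samples the base probability vector `beta` over the truncated state space
#' (`Dirichlet(gamma/mMax, ..., gamma/mMax)`, or fixed uniform when
#' `sampleBeta = FALSE`) and one propagator row per candidate state from
#' `Dirichlet(alpha * beta)`.
#'
#' @param config an [HDPConfig-class].
#' @return list with `beta` (length `mMax`) and `transProb`
#'   (`mMax x mMax` row-stochastic matrix).
#' @examples
#' set.seed(1)
#' pr <- initHdpPrior(HDPConfig(mMax = 5))
#' rowSums(pr$transProb)
#' @export
initHdpPrior <- function(config) {
  M <- config@mMax
  beta <- if (config@sampleBeta) {
    g <- rgamma(M, shape = config@gamma / M, rate = 1)
    if (sum(g) <= 0) rep(1 / M, M) else g / sum(g)
  } else {
    rep(1 / M, M)
  }
  Pi <- t(vapply(seq_len(M), function(m) {
    g <- rgamma(M, shape = config@alpha * beta, rate = 1)
    if (sum(g) <= 0) rep(1 / M, M) else g / sum(g)
  }, numeric(M)))
  list(beta = beta, transProb = Pi)
}

#' Run the nonparametric (infinite-HMM) sampler
#'
#' Learns the number of system states together with all other parameters by
#' running the Gibbs sweep of [runParametricChain()] over a truncated state
#' space of `mMax` candidate states under a hierarchical-Dirichlet-process
#' prior on the propagator rows: `beta ~ Dirichlet(gamma/mMax, ...)` and
#' `pi_m ~ Dirichlet(alpha * beta)`.  With `sampleBeta = FALSE` (default)
#' the base measure is fixed uniform, the stated simplification of assigning
#' identical prior weights across the state space; with `sampleBeta = TRUE`
#' it is resampled each sweep through the auxiliary table-count scheme.
#' States carry their own FRET rates throughout; states not visited by the
#' sampled trajectory are informed only by their priors and drift over the
#' prior, so the number of system states is read off as the number of states
#' appreciably occupied by the trajectory (see [effectiveStateCount()]).
#'
#' @param trace a [PhotonTrace-class].
#' @param hdp an [HDPConfig-class].
#' @param prior a [PriorSpec-class] (its `alpha`/`beta` slots are ignored in
#'   favour of the HDP configuration).
#' @param det a [DetectorModel-class].
#' @param nSweeps,seed,init,nTune,verbose as in [runParametricChain()].
#' @return a [PosteriorChain-class] with `mMax` candidate states.
#' @export
runBnpChain <- function(trace, hdp = HDPConfig(), prior = PriorSpec(),
                        det = DetectorModel(), nSweeps = 3000L, seed = 1L,
                        init = NULL, nTune = nSweeps %/% 2L,
                        verbose = FALSE) {
  .runChain(trace, hdp@mMax, prior, det, nSweeps, seed, init, nTune,
            sampleBeta = hdp@sampleBeta, gammaConc = hdp@gamma,
            alphaConc = hdp@alpha, hdp = hdp, verbose = verbose)
}

#' Posterior distribution of the number of occupied system states
#'
#' For each recorded sweep, counts the candidate states whose trajectory
#' occupancy exceeds `threshold` (as a fraction of all pulses); the number
#' of system states is the mode of this distribution over post-burn-in
#' sweeps.
#'
#' @param chain a [PosteriorChain-class].
#' @param threshold minimum occupied fraction of pulses for a state to count
#'   as visited (default 1%).
#' @param burnInFraction fraction of initial sweeps to discard.
#' @return list with `perSweep` (integer vector of occupied-state counts),
#'   `distribution` (named proportions), and `mode` (modal count).
#' @export
effectiveStateCount <- function(chain, threshold = 0.01,
                                burnInFraction = 0.5) {
  keep <- seq.int(floor(chain@nSweeps * burnInFraction) + 1L, chain@nSweeps)
  occ <- chain@occupancy[keep, , drop = FALSE] / chain@nPulses
  counts <- as.integer(rowSums(occ > threshold))
  tab <- table(factor(counts, levels = sort(unique(counts))))
  dist <- as.numeric(tab) / sum(tab)
  names(dist) <- names(tab)
  list(perSweep = counts, distribution = dist,
       mode = as.integer(names(tab)[which.max(tab)]))
}
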