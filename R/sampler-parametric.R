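## dense per-pulse observation matrix (small traces only): row n holds
## p(w_n | s = m) for every candidate state m
.denseObsMatrix <- function(trace, params, det) {
  N <- as.integer(trace@nPulses)
  M <- length(params@lambdaFret)
  pEmpty <- vapply(seq_len(M),
                   function(m) pulseOutcomeModel(m, params, det)$pEmpty,
                   numeric(1))
  G <- matrix(pEmpty, nrow = N, ncol = M, byrow = TRUE)
  ph <- trace@photons
  if (nrow(ph)) {
    for (p in unique(ph$pulseIndex)) {
      rows <- ph[ph$pulseIndex == p, ]
      muD <- if (any(rows$channel == 1L)) rows$microtime[rows$channel == 1L] else NA_real_
      muA <- if (any(rows$channel == 2L)) rows$microtime[rows$channel == 2L] else NA_real_
      G[p, ] <- buildDetectionMatrix(PulseObservation(muD, muA), params, det)[, 1]
    }
  }
  G
}

## column-wise categorical sampling from an M x D weight matrix
.sampleCategoricalMatrix <- function(W) {
  M <- nrow(W)
  D <- ncol(W)
  u <- runif(D) * colSums(W)
  pick <- rep.int(M, D)
  acc <- rep.int(0, D)
  undecided <- rep.int(TRUE, D)
  for (s in seq_len(M - 1L)) {
    acc <- acc + W[s, ]
    hit <- undecided & (u <= acc)
    pick[hit] <- s
    undecided <- undecided & !hit
  }
  pick
}

#' Sample system state trajectories by forward filtering backward sampling
#'
#' Draws exact conditional samples of the full state trajectory
#' `p(s_1:N | trace, kinetics, rates)`.  Two implementations are exposed:
#' `"dense"` filters every pulse explicitly (exact reference, small traces
#' only) and returns complete trajectories; `"grouped"` is the production
#' path used inside the Gibbs samplers, which filters only photon epochs,
#' fills empty runs by exact Markov-bridge sampling with constant-run
#' shortcuts, and returns the trajectory summaries the samplers need
#' (transition counts, per-state occupancy, first and last state).
#'
#' @param trace a [PhotonTrace-class].
#' @param kin a [SystemKinetics-class].
#' @param params a [PhotophysicsParams-class].
#' @param det a [DetectorModel-class].
#' @param nDraws number of independent trajectory draws.
#' @param method `"dense"` or `"grouped"`.
#' @return for `"dense"`, an `nDraws x nPulses` integer matrix of states; for
#'   `"grouped"`, a list with `counts` (M x M x nDraws transition counts),
#'   `occupancy` (`nDraws x M` pulses per state), `s1`, `sN`, and `logLik`.
#' @export
ffbsTrajectory <- function(trace, kin, params, det, nDraws = 1L,
                           method = c("dense", "grouped")) {
  method <- match.arg(method)
  M <- nrow(kin@transProb)
  if (method == "grouped") {
    ep <- .traceEpochs(trace)
    return(cpp_ffbs_grouped(ep, kin@transProb, kin@rhoStart,
                            .modelArgs(params, det), trace@nPulses,
                            as.integer(nDraws)))
  }
  N <- as.integer(trace@nPulses)
  if (N > 5e4) stop("dense FFBS is for small traces; use method = \"grouped\"")
  G <- .denseObsMatrix(trace, params, det)
  Pi <- kin@transProb
  fwd <- matrix(0, N, M)
  f <- kin@rhoStart * G[1, ]
  if (sum(f) <= 0) stop("trace has zero likelihood under these parameters")
  fwd[1, ] <- f / sum(f)
  if (N > 1) {
    for (n in 2:N) {
      f <- as.vector(fwd[n - 1, ] %*% Pi) * G[n, ]
      if (sum(f) <= 0) stop("trace has zero likelihood under these parameters")
      fwd[n, ] <- f / sum(f)
    }
  }
  out <- matrix(0L, nDraws, N)
  out[, N] <- .sampleCategoricalMatrix(matrix(fwd[N, ], M, nDraws))
  if (N > 1) {
    for (n in (N - 1):1) {
      W <- Pi[, out[, n + 1], drop = FALSE] * fwd[n, ]
      out[, n] <- .sampleCategoricalMatrix(W)
    }
  }
  out
}

#' Count pulse-to-pulse transitions in a trajectory
#'
#' @param trajectory integer vector of states `s_1:N` (1-based).
#' @param nStates number of states M (defaults to the largest label seen).
#' @return MxM matrix `n` with `n[i, j]` the number of steps from `i` to `j`;
#'   entries sum to `N - 1`.
#' @examples
#' countTransitions(c(1, 2, 1, 2), 2)
#' @export
countTransitions <- function(trajectory, nStates = max(trajectory)) {
  s <- as.integer(trajectory)
  M <- as.integer(nStates)
  if (length(s) < 2L) return(matrix(0, M, M))
  from <- s[-length(s)]
  to <- s[-1L]
  matrix(tabulate((to - 1L) * M + from, nbins = M * M), M, M)
}

## row-prior vector alpha * beta, expanding an empty beta to uniform
.rowPrior <- function(prior, M) {
  beta <- prior@beta
  if (!length(beta)) beta <- rep(1 / M, M)
  if (length(beta) != M) stop("'beta' must have one entry per state")
  prior@alpha * beta
}

#' Conjugate draw of the transition matrix
#'
#' Samples each propagator row independently from its Dirichlet full
#' conditional `Dirichlet(n_m + alpha * beta)`, where `n_m` is the vector of
#' observed transition counts out of state `m`.
#'
#' @param counts MxM transition count matrix (see [countTransitions()]).
#' @param prior a [PriorSpec-class].
#' @return MxM row-stochastic matrix.
#' @export
sampleTransitionMatrix <- function(counts, prior) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("'counts' must be non-negative")
  M <- nrow(counts)
  ab <- .rowPrior(prior, M)
  t(apply(counts, 1L, function(n) {
    g <- rgamma(M, shape = n + ab, rate = 1)
    if (sum(g) <= 0) g <- rep(1, M)
    g / sum(g)
  }))
}

#' Conjugate draw of the initial state probabilities
#'
#' Samples `rhoStart ~ Dirichlet(rhoConcentration + indicator(s1))`.
#'
#' @param s1 sampled initial state (1-based index).
#' @param prior a [PriorSpec-class].
#' @param nStates number of states.
#' @return length-M probability vector.
#' @export
sampleRhoStart <- function(s1, prior, nStates) {
  conc <- rep(prior@rhoConcentration, nStates)
  conc[s1] <- conc[s1] + 1
  g <- rgamma(nStates, shape = conc, rate = 1)
  g / sum(g)
}

#' One Metropolis-Hastings pass over the photophysical rate blocks
#'
#' Updates `lambdaD`, `lambdaA`, each per-state FRET rate, and `piEx` one
#' block at a time with multiplicative log-normal random-walk proposals
#' (logit-normal for `piEx`), Gamma priors on rates and a Beta prior on
#' `piEx`, accepting on the marginal trace likelihood (trajectory summed
#' out) plus prior and proposal-asymmetry corrections.  The compiled chain
#' driver uses the equivalent update conditioned on the sampled trajectory
#' (whose factorised likelihood makes each block far cheaper); this
#' marginal variant is convenient for diagnostics and small-problem work,
#' and the two target the same posterior within the Gibbs sweep.
#'
#' @param kin a [SystemKinetics-class] (held fixed).
#' @param params current [PhotophysicsParams-class].
#' @param trace a [PhotonTrace-class].
#' @param prior a [PriorSpec-class].
#' @param det a [DetectorModel-class].
#' @param proposalScales named numeric: log-scale random-walk standard
#'   deviations for `lambdaD`, `lambdaA`, `lambdaFret` (shared across
#'   states), and `piEx`.
#' @param blocks which blocks to update.
#' @param logLik current log likelihood (recomputed when `NULL`).
#' @return list with updated `params`, logical `accepted` per block, and the
#'   updated `logLik`.
#' @export
mhUpdateRates <- function(kin, params, trace, prior, det,
                          proposalScales = c(lambdaD = 0.1, lambdaA = 0.1,
                                             lambdaFret = 0.3, piEx = 0.3),
                          blocks = c("lambdaD", "lambdaA",
                                     paste0("lambdaFret", seq_along(params@lambdaFret)),
                                     "piEx"),
                          logLik = NULL) {
  if (is.null(logLik)) logLik <- traceLogLikelihood(trace, kin, params, det)
  accepted <- setNames(logical(length(blocks)), blocks)
  for (b in blocks) {
    pp <- params
    if (b == "lambdaD") {
      nv <- params@lambdaD * exp(proposalScales[["lambdaD"]] * rnorm(1))
      pp@lambdaD <- nv
      dPrior <- dgamma(nv, prior@lambdaDShape, rate = prior@lambdaDRate, log = TRUE) -
        dgamma(params@lambdaD, prior@lambdaDShape, rate = prior@lambdaDRate, log = TRUE)
      jac <- log(nv / params@lambdaD)
    } else if (b == "lambdaA") {
      nv <- params@lambdaA * exp(proposalScales[["lambdaA"]] * rnorm(1))
      pp@lambdaA <- nv
      dPrior <- dgamma(nv, prior@lambdaAShape, rate = prior@lambdaARate, log = TRUE) -
        dgamma(params@lambdaA, prior@lambdaAShape, rate = prior@lambdaARate, log = TRUE)
      jac <- log(nv / params@lambdaA)
    } else if (b == "piEx") {
      x <- stats::qlogis(params@piEx) + proposalScales[["piEx"]] * rnorm(1)
      nv <- stats::plogis(x)
      pp@piEx <- nv
      dPrior <- dbeta(nv, prior@piExShape1, prior@piExShape2, log = TRUE) -
        dbeta(params@piEx, prior@piExShape1, prior@piExShape2, log = TRUE)
      jac <- log(nv * (1 - nv)) - log(params@piEx * (1 - params@piEx))
    } else {
      m <- as.integer(sub("lambdaFret", "", b))
      nv <- params@lambdaFret[m] * exp(proposalScales[["lambdaFret"]] * rnorm(1))
      pp@lambdaFret[m] <- nv
      dPrior <- dgamma(nv, prior@lambdaFretShape, rate = prior@lambdaFretRate, log = TRUE) -
        dgamma(params@lambdaFret[m], prior@lambdaFretShape,
               rate = prior@lambdaFretRate, log = TRUE)
      jac <- log(nv / params@lambdaFret[m])
    }
    llNew <- traceLogLikelihood(trace, kin, pp, det)
    la <- llNew - logLik + dPrior + jac
    if (is.finite(llNew) && log(runif(1)) < la) {
      params <- pp
      logLik <- llNew
      accepted[b] <- TRUE
    }
  }
  list(params = params, accepted = accepted, logLik = logLik)
}

## shared chain runner behind runParametricChain / runBnpChain
.runChain <- function(trace, M, prior, det, nSweeps, seed, init, nTune,
                      sampleBeta, gammaConc, alphaConc, hdp, verbose) {
  stopifnot(nSweeps >= 1)
  set.seed(seed)
  ep <- .traceEpochs(trace)
  rowPrior <- if (is.null(hdp)) .rowPrior(prior, M) else {
    rep(alphaConc / M, M)  # alpha * uniform beta at initialisation
  }
  if (is.null(init)) init <- list()
  nPhotons <- nrow(trace@photons)
  lamD0 <- init$lambdaD %||% (prior@lambdaDShape / prior@lambdaDRate)
  lamA0 <- init$lambdaA %||% (prior@lambdaAShape / prior@lambdaARate)
  lamF0 <- init$lambdaFret %||% {
    eff <- seq(0.1, 0.9, length.out = M)
    eff / (1 - eff) * lamD0
  }
  piEx0 <- init$piEx %||%
    min(0.5, max(2 * nPhotons / trace@nPulses, 1e-6))
  # near-static start, consistent with the slow-switching assumption; the
  # trajectory update forces transitions wherever photons demand them, so
  # the switching scale anneals up to the data quickly, whereas a diffuse
  # start mixes extremely slowly (empty-pulse counts just echo the current
  # propagator)
  Pi0 <- init$transProb %||% {
    P <- matrix(1e-5 / (M - 1), M, M)
    diag(P) <- 1 - 1e-5
    P
  }
  rho0 <- init$rhoStart %||% rep(1 / M, M)
  initList <- list(lambdaD = lamD0, lambdaA = lamA0,
                   lambdaFret = as.numeric(lamF0), piEx = piEx0,
                   transProb = Pi0, rhoStart = as.numeric(rho0))
  scales <- c(0.05, 0.05, rep(0.5, M), 0.3)
  params0 <- PhotophysicsParams(lambdaD = lamD0, lambdaA = lamA0,
                                lambdaFret = as.numeric(lamF0),
                                piEx = piEx0, tau = trace@tau)
  res <- cpp_run_chain(
    ep, trace@nPulses, as.integer(M), rowPrior,
    rep(prior@rhoConcentration, M),
    c(prior@lambdaDShape, prior@lambdaDRate,
      prior@lambdaAShape, prior@lambdaARate,
      prior@lambdaFretShape, prior@lambdaFretRate),
    c(prior@piExShape1, prior@piExShape2),
    initList, as.integer(nSweeps), as.integer(nTune), scales,
    isTRUE(sampleBeta), gammaConc, alphaConc,
    .modelArgs(params0, det),
    if (verbose) max(100L, nSweeps %/% 10L) else 0L)
  blockNames <- c("lambdaD", "lambdaA",
                  paste0("lambdaFret", seq_len(M)), "piEx")
  new("PosteriorChain",
      nSweeps = as.integer(nSweeps), mMax = as.integer(M),
      nPulses = trace@nPulses, tau = trace@tau,
      transProb = res$transProb,
      lambdaD = res$lambdaD, lambdaA = res$lambdaA,
      lambdaFret = res$lambdaFret, piEx = res$piEx,
      rhoStart = res$rhoStart, occupancy = res$occupancy,
      s1 = res$s1,
      beta = if (isTRUE(sampleBeta)) res$beta else matrix(numeric(), 0L, 0L),
      logLik = res$logLik, logPost = res$logPost,
      acceptance = setNames(as.numeric(res$acceptance), blockNames),
      proposalScales = setNames(as.numeric(res$proposalScales), blockNames),
      seed = as.integer(seed), prior = prior, hdp = hdp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the parametric Gibbs sampler (fixed number of states)
#'
#' Markov chain Monte Carlo over the posterior of a pulsed-illumination
#' smFRET trace with a known number of system states M.  Each sweep updates,
#' in order: (1) the photophysical rates and excitation probability by
#' Metropolis-Hastings blocks conditioned on the sampled trajectory (states
#' unvisited by the trajectory redraw their FRET rate from the prior
#' directly); (2) the propagator
#' rows by conjugate Dirichlet draws given the trajectory's transition
#' counts; (3) the state trajectory by grouped forward-filtering
#' backward-sampling; (4) the initial probabilities by a conjugate Dirichlet
#' draw.  Proposal scales are adapted toward 30% acceptance during the first
#' `nTune` sweeps only, so the post-tuning chain is a valid fixed-kernel
#' sampler.
#'
#' @param trace a [PhotonTrace-class].
#' @param nStates number of system states M.
#' @param prior a [PriorSpec-class].
#' @param det a [DetectorModel-class] (precalibrated input).
#' @param nSweeps number of Gibbs sweeps to record.
#' @param seed integer RNG seed.
#' @param init optional named list of initial values (`lambdaD`, `lambdaA`,
#'   `lambdaFret`, `piEx`, `transProb`, `rhoStart`); sensible defaults
#'   otherwise.
#' @param nTune number of initial sweeps with proposal adaptation (default
#'   half of `nSweeps`, matching the default burn-in fraction).
#' @param verbose print progress.
#' @return a [PosteriorChain-class].
#' @export
runParametricChain <- function(trace, nStates, prior = PriorSpec(),
                               det = DetectorModel(), nSweeps = 1000L,
                               seed = 1L, init = NULL,
                               nTune = nSweeps %/% 2L, verbose = FALSE) {
  .runChain(trace, as.integer(nStates), prior, det, nSweeps, seed, init,
            nTune, sampleBeta = FALSE, gammaConc = 1, alphaConc = prior@alpha,
            hdp = NULL, verbose = verbose)
}
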