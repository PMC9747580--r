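## marginal mode via kernel density estimation (Silverman bandwidth);
## degenerate samples fall back to their common value
.kdeMode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- density(x)
  d$x[which.max(d$y)]
}

## censor a row-stochastic matrix onto the index set `keep`: the stochastic
## complement P_OO + P_OJ (I - P_JJ)^-1 P_JO, i.e. the transition matrix of
## the chain watched only while it is in `keep`
.stochasticComplement <- function(P, keep) {
  M <- nrow(P)
  drop_ <- setdiff(seq_len(M), keep)
  if (!length(drop_)) {
    Peff <- P[keep, keep, drop = FALSE]
  } else {
    inv <- tryCatch(solve(diag(length(drop_)) - P[drop_, drop_, drop = FALSE]),
                    error = function(e) NULL)
    Peff <- if (is.null(inv)) {
      P[keep, keep, drop = FALSE]
    } else {
      P[keep, keep, drop = FALSE] +
        P[keep, drop_, drop = FALSE] %*% inv %*% P[drop_, keep, drop = FALSE]
    }
  }
  Peff / rowSums(Peff)
}

#' Per-sweep escape-rate / FRET-efficiency samples
#'
#' Maps every post-burn-in sweep of a chain to the physically reported
#' quantities: for each state occupied by the sampled trajectory (occupancy
#' above `threshold`), the FRET efficiency `lambdaFret / (lambdaFret +
#' lambdaD)` and the escape rate obtained from the matrix logarithm of the
#' sampled propagator censored onto the occupied states (its stochastic
#' complement), so that switches routed through transiently visited states
#' count while brief self-returning excursions do not.  Occupied states are
#' ranked by efficiency within each sweep, which is how label switching is
#' resolved in all reporting.
#'
#' @param chain a [PosteriorChain-class].
#' @param threshold occupancy fraction defining a visited state.
#' @param burnInFraction fraction of initial sweeps to discard.
#' @return `data.frame` with columns `sweep`, `nOccupied`, `stateRank`,
#'   `state` (candidate-state index), `escapeRate` (1/s), `fretEfficiency`,
#'   `logPost`.
#' @export
bivariateSamples <- function(chain, threshold = 0.01, burnInFraction = 0.5) {
  keep <- seq.int(floor(chain@nSweeps * burnInFraction) + 1L, chain@nSweeps)
  out <- vector("list", length(keep))
  tau <- chain@tau
  for (ii in seq_along(keep)) {
    s <- keep[ii]
    occFrac <- chain@occupancy[s, ] / chain@nPulses
    occ <- which(occFrac > threshold)
    if (!length(occ)) occ <- which.max(occFrac)
    eff <- fretEfficiency(chain@lambdaFret[s, occ], chain@lambdaD[s])
    ord <- order(eff)
    occ <- occ[ord]
    eff <- eff[ord]
    # Escape rates come from the matrix logarithm of the sampled propagator
    # censored onto the occupied states (the stochastic complement
    # P_OO + P_OJ (I - P_JJ)^-1 P_JO): a switch routed through a transiently
    # visited state still counts as a transition between occupied states,
    # while a brief excursion that returns to the same state does not.
    P <- chain@transProb[, , s]
    Peff <- .stochasticComplement(P, occ)
    esc <- suppressWarnings(as.numeric(escapeRatesFromPropagator(Peff, tau)))
    out[[ii]] <- data.frame(
      sweep = s, nOccupied = length(occ), stateRank = seq_along(occ),
      state = occ, escapeRate = esc, fretEfficiency = eff,
      logPost = chain@logPost[s])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' MAP estimates and credible intervals from posterior samples
#'
#' Restricts the sample table to sweeps whose occupied-state count equals
#' the posterior modal count, takes the sweep with the highest log posterior
#' as the joint MAP estimate, and attaches per-state central credible
#' intervals, reported as `-lower/+upper` offsets from the MAP values.
#' Marginal kernel-density modes are reported alongside (columns
#' `escapeRateMode`, `fretMode`); smoothing is never used for anything but
#' these marginal summaries.
#'
#' @param samples output of [bivariateSamples()].
#' @param intervalMass central credible mass (default 0.95).
#' @param minSweeps minimum number of usable sweeps required.
#' @return a [PosteriorSummary-class].
#' @export
mapAndIntervals <- function(samples, intervalMass = 0.95, minSweeps = 100L) {
  perSweep <- samples[!duplicated(samples$sweep),
                      c("sweep", "nOccupied", "logPost")]
  if (nrow(perSweep) < minSweeps) {
    stop(sprintf("only %d post-burn-in sweeps; at least %d required",
                 nrow(perSweep), minSweeps))
  }
  tab <- table(perSweep$nOccupied)
  K <- as.integer(names(tab)[which.max(tab)])
  dist <- as.numeric(tab) / sum(tab)
  names(dist) <- names(tab)
  sel <- samples[samples$nOccupied == K, , drop = FALSE]
  mapSweep <- sel$sweep[which.max(sel$logPost)]
  qlo <- (1 - intervalMass) / 2
  qhi <- 1 - qlo
  rows <- lapply(seq_len(K), function(r) {
    sr <- sel[sel$stateRank == r, , drop = FALSE]
    escMAP <- sr$escapeRate[sr$sweep == mapSweep]
    effMAP <- sr$fretEfficiency[sr$sweep == mapSweep]
    escQ <- quantile(sr$escapeRate, c(qlo, qhi), names = FALSE)
    effQ <- quantile(sr$fretEfficiency, c(qlo, qhi), names = FALSE)
    escQ <- c(min(escQ[1], escMAP), max(escQ[2], escMAP))
    effQ <- c(min(effQ[1], effMAP), max(effQ[2], effMAP))
    data.frame(
      state = r,
      escapeRateMAP = escMAP, escapeRateMode = .kdeMode(sr$escapeRate),
      escapeRateLowerOffset = escMAP - escQ[1],
      escapeRateUpperOffset = escQ[2] - escMAP,
      fretMAP = effMAP, fretMode = .kdeMode(sr$fretEfficiency),
      fretLowerOffset = effMAP - effQ[1],
      fretUpperOffset = effQ[2] - effMAP)
  })
  new("PosteriorSummary",
      stateTable = do.call(rbind, rows),
      modalStateCount = K,
      stateCountDistribution = dist,
      intervalMass = intervalMass,
      samples = samples)
}

#' One-call posterior summary of a chain
#'
#' Convenience wrapper: [bivariateSamples()] followed by
#' [mapAndIntervals()].
#'
#' @param chain a [PosteriorChain-class].
#' @param threshold,burnInFraction passed to [bivariateSamples()].
#' @param intervalMass passed to [mapAndIntervals()].
#' @return a [PosteriorSummary-class].
#' @export
summarizePosterior <- function(chain, threshold = 0.01,
                               burnInFraction = 0.5, intervalMass = 0.95) {
  mapAndIntervals(bivariateSamples(chain, threshold, burnInFraction),
                  intervalMass = intervalMass)
}

#' Plot the bivariate escape-rate / FRET-efficiency posterior
#'
#' Scatter of post-burn-in samples with kernel-density contours per occupied
#' state (smoothing is for display only) and optional ground-truth markers.
#'
#' @param summary a [PosteriorSummary-class] (or the `data.frame` from
#'   [bivariateSamples()]).
#' @param truth optional `data.frame` with columns `escapeRate` and
#'   `fretEfficiency` of ground-truth states.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted sample table.
#' @export
plotBivariatePosterior <- function(summary, truth = NULL, ...) {
  samples <- if (is(summary, "PosteriorSummary")) summary@samples else summary
  cols <- grDevices::hcl.colors(max(samples$stateRank), "Dark 3")
  graphics::plot(samples$escapeRate, samples$fretEfficiency,
                 col = grDevices::adjustcolor(cols[samples$stateRank], 0.25),
                 pch = 16, cex = 0.4, xlab = "escape rate (1/s)",
                 ylab = "FRET efficiency", ylim = c(0, 1), ...)
  for (r in unique(samples$stateRank)) {
    sr <- samples[samples$stateRank == r, ]
    if (nrow(sr) > 20 && stats::sd(sr$escapeRate) > 0 &&
        stats::sd(sr$fretEfficiency) > 0) {
      kd <- MASS::kde2d(sr$escapeRate, sr$fretEfficiency, n = 50)
      graphics::contour(kd, add = TRUE, col = cols[r], drawlabels = FALSE,
                        nlevels = 5)
    }
  }
  if (!is.null(truth)) {
    graphics::points(truth$escapeRate, truth$fretEfficiency, col = "red",
                     pch = 19, cex = 1.2)
  }
  invisible(samples)
}
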