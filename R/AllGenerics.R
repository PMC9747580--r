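#' Accessors for pulseFRET objects
#'
#' Small accessor family: number of pulses, interpulse period, photon records,
#' transition matrix, and initial state probabilities.
#'
#' @param object a pulseFRET S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nPulses", function(object) standardGeneric("nPulses"))

#' @rdname accessors
#' @export
setGeneric("interpulsePeriod",
           function(object) standardGeneric("interpulsePeriod"))

#' @rdname accessors
#' @export
setGeneric("photonRecords", function(object) standardGeneric("photonRecords"))

#' @rdname accessors
#' @export
setGeneric("transProb", function(object) standardGeneric("transProb"))

#' @rdname accessors
#' @export
setGeneric("rhoStart", function(object) standardGeneric("rhoStart"))

#' @rdname accessors
#' @export
setGeneric("stateTable", function(object) standardGeneric("stateTable"))

#' @rdname accessors
#' @export
setMethod("nPulses", "PhotonTrace", function(object) object@nPulses)

#' @rdname accessors
#' @export
setMethod("nPulses", "GroundTruthDataset",
          function(object) object@trace@nPulses)

#' @rdname accessors
#' @export
setMethod("interpulsePeriod", "PhotonTrace", function(object) object@tau)

#' @rdname accessors
#' @export
setMethod("interpulsePeriod", "PhotophysicsParams", function(object) object@tau)

#' @rdname accessors
#' @export
setMethod("photonRecords", "PhotonTrace", function(object) object@photons)

#' @rdname accessors
#' @export
setMethod("photonRecords", "GroundTruthDataset",
          function(object) object@trace@photons)

#' @rdname accessors
#' @export
setMethod("transProb", "SystemKinetics", function(object) object@transProb)

#' @rdname accessors
#' @export
setMethod("transProb", "PosteriorChain", function(object) object@transProb)

#' @rdname accessors
#' @export
setMethod("rhoStart", "SystemKinetics", function(object) object@rhoStart)

#' @rdname accessors
#' @export
setMethod("stateTable", "PosteriorSummary", function(object) object@stateTable)

setMethod("show", "PhotophysicsParams", function(object) {
  cat("PhotophysicsParams\n")
  cat(sprintf("  donor lifetime     : %.3g ns (lambdaD = %.4g 1/s)\n",
              1e9 / object@lambdaD, object@lambdaD))
  cat(sprintf("  acceptor lifetime  : %.3g ns (lambdaA = %.4g 1/s)\n",
              1e9 / object@lambdaA, object@lambdaA))
  cat(sprintf("  FRET rates (1/s)   : %s\n",
              paste(signif(object@lambdaFret, 4), collapse = ", ")))
  eff <- object@lambdaFret / (object@lambdaFret + object@lambdaD)
  cat(sprintf("  FRET efficiencies  : %s\n",
              paste(signif(eff, 3), collapse = ", ")))
  cat(sprintf("  piEx = %.3g ; tau = %.3g ns\n", object@piEx, 1e9 * object@tau))
})

setMethod("show", "DetectorModel", function(object) {
  cat("DetectorModel\n  route matrix (band -> channel):\n")
  m <- object@routeMatrix
  dimnames(m) <- list(c("donor band", "acceptor band"),
                      c("donor ch", "acceptor ch"))
  print(m)
  cat(sprintf("  IRF: mean %.3g ns, sigma %.3g ns\n",
              1e9 * object@irfMean, 1e9 * object@irfSigma))
  cat(sprintf("  background/pulse: donor %.3g, acceptor %.3g\n",
              object@bgProb[1], object@bgProb[2]))
})

setMethod("show", "PhotonTrace", function(object) {
  ph <- object@photons
  cat(sprintf("PhotonTrace: %g pulses, tau = %.3g ns, duration %.4g s\n",
              object@nPulses, 1e9 * object@tau, object@nPulses * object@tau))
  cat(sprintf("  %d photons (%d donor, %d acceptor); %.3g photons/pulse\n",
              nrow(ph), sum(ph$channel == 1L), sum(ph$channel == 2L),
              nrow(ph) / object@nPulses))
})

setMethod("show", "SystemKinetics", function(object) {
  M <- nrow(object@transProb)
  cat(sprintf("SystemKinetics with %d system state%s\n", M,
              if (M > 1) "s" else ""))
  if (length(object@rateMatrix)) {
    cat("  generator (1/s):\n")
    print(signif(object@rateMatrix, 4))
  }
  cat("  pulse-to-pulse transition matrix:\n")
  print(signif(object@transProb, 6))
  cat(sprintf("  rhoStart: %s\n",
              paste(signif(object@rhoStart, 3), collapse = ", ")))
})

setMethod("show", "GroundTruthDataset", function(object) {
  cat("GroundTruthDataset\n")
  show(object@trace)
  tr <- object@trajectory
  cat(sprintf("  trajectory: %d dwell segments over %d states; seed %d\n",
              nrow(tr), length(unique(tr$state)), object@config@seed))
})

setMethod("show", "PosteriorChain", function(object) {
  cat(sprintf("PosteriorChain: %d sweeps, %d candidate states (%s sampler)\n",
              object@nSweeps, object@mMax,
              if (is.null(object@hdp)) "parametric" else "nonparametric"))
  cat(sprintf("  trace: %g pulses, tau = %.3g ns ; seed %d\n",
              object@nPulses, 1e9 * object@tau, object@seed))
  cat(sprintf("  final log posterior: %.4g\n",
              object@logPost[object@nSweeps]))
  if (length(object@acceptance)) {
    cat("  MH acceptance rates:\n")
    print(signif(object@acceptance, 3))
  }
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: modal state count %d (%.0f%% intervals)\n",
              object@modalStateCount, 100 * object@intervalMass))
  st <- object@stateTable
  for (i in seq_len(nrow(st))) {
    cat(sprintf(
      "  state %d: escape rate %.3g -%.2g/+%.2g 1/s ; efficiency %.3g -%.2g/+%.2g\n",
      st$state[i], st$escapeRateMAP[i], st$escapeRateLowerOffset[i],
      st$escapeRateUpperOffset[i], st$fretMAP[i], st$fretLowerOffset[i],
      st$fretUpperOffset[i]))
  }
  invisible(NULL)
})
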