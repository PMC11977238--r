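#' @include AllClasses.R
NULL

#' Accessors for simulated fields and result objects
#'
#' Small accessor generics in the Bioconductor style; user code should
#' use these rather than reaching into slots with `@`.
#'
#' @param object an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("egfpChannel", function(object) standardGeneric("egfpChannel"))

#' @rdname accessors
#' @export
setGeneric("tomatoChannel", function(object) standardGeneric("tomatoChannel"))

#' @rdname accessors
#' @export
setGeneric("labelMask", function(object) standardGeneric("labelMask"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))

#' @rdname accessors
#' @export
setGeneric("hitCalls", function(object) standardGeneric("hitCalls"))

#' @rdname accessors
#' @export
setGeneric("hits", function(object) standardGeneric("hits"))

#' @rdname accessors
#' @export
setGeneric("hitRate", function(object, ...) standardGeneric("hitRate"))

#' @rdname accessors
#' @export
setGeneric("pctPositive", function(object) standardGeneric("pctPositive"))

#' @rdname accessors
#' @export
setGeneric("gateThreshold", function(object) standardGeneric("gateThreshold"))

#' @rdname accessors
#' @export
setGeneric("concAt50", function(object) standardGeneric("concAt50"))

#' @rdname accessors
setMethod("egfpChannel", "SimulatedField", function(object) object@egfp)

#' @rdname accessors
setMethod("tomatoChannel", "SimulatedField", function(object) object@tomato)

#' @rdname accessors
setMethod("labelMask", "SimulatedField", function(object) object@labelMask)

#' @rdname accessors
setMethod("groundTruth", "SimulatedField", function(object) object@truth)

#' @rdname accessors
setMethod("egfpChannel", "list", function(object) object$egfp)

#' @rdname accessors
setMethod("tomatoChannel", "list", function(object) object$tomato)

#' @rdname accessors
setMethod("ec50", "DoseResponseFit", function(object) object@ec50)

#' @rdname accessors
setMethod("hillSlope", "DoseResponseFit", function(object) object@hill)

#' @rdname accessors
setMethod("hitCalls", "ScreenResult", function(object) object@calls)

#' @rdname accessors
setMethod("hits", "ScreenResult", function(object) object@hits)

#' @rdname accessors
setMethod("pctPositive", "GateResult", function(object) object@pctPositive)

#' @rdname accessors
setMethod("gateThreshold", "GateResult", function(object) object@threshold)

#' @rdname accessors
setMethod("concAt50", "ChelationResult", function(object) object@concAt50)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:",
      sprintf("%dx%d field, %d nuclei/field",
              object@fieldShape[1], object@fieldShape[2],
              object@nNucleiPerField), "\n")
  cat(sprintf("  induction fold %.3g, responder fraction %.2f\n",
              object@inductionFold, object@responderFraction))
  cat(sprintf("  well CV %.3g (shared variance fraction %.2f)\n",
              object@wellCV, object@sharedCVFraction))
  cat(sprintf("  kinetics onset %.3g h, rate %.3g /h, plateau %.3g\n",
              object@kineticsOnsetH, object@kineticsRate,
              object@kineticsPlateau))
  cat(sprintf("  dose-response EC50 %.3g M, Hill %.3g, noise CV %.3g\n",
              object@ec50True, object@hillTrue, object@drNoiseCV))
  invisible(object)
})

setMethod("show", "SimulatedField", function(object) {
  cat(sprintf("SimulatedField: %dx%d px, %d planted nuclei (%s)\n",
              nrow(object@egfp), ncol(object@egfp), nrow(object@truth),
              if (isTRUE(object@induced)) "induced" else "uninduced"))
  if (nrow(object@truth) > 0) {
    cat(sprintf("  border %d, cluster %d, abnormal %d\n",
                sum(object@truth$border_flag),
                sum(object@truth$cluster_flag),
                sum(object@truth$abnormal_flag)))
  }
  invisible(object)
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult: %d compounds, z cut %.3g, EGFP cut %.3g\n",
              object@nCompounds, object@zCut, object@egfpCut))
  for (cl in names(object@hits)) {
    cat(sprintf("  %s hits: %d (%.1f%%)\n", cl, length(object@hits[[cl]]),
                object@hitRate[[cl]]))
  }
  nexcl <- sum(object@calls$class == "excluded_fluorescent")
  cat(sprintf("  excluded (EGFP artifact) compound-phase calls: %d\n", nexcl))
  invisible(object)
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit: EC50 %.4g, Hill %.3g, floor %.3g, ceiling %.3g\n",
              object@ec50, object@hill, object@floor, object@ceiling))
  cat(sprintf("  RSS %.4g over %d points; converged: %s\n",
              object@rss, object@nPoints, object@converged))
  invisible(object)
})

setMethod("show", "GateResult", function(object) {
  cat(sprintf(
    "GateResult: threshold %.4g (top %.1f%% of control), %.2f%% positive\n",
    object@threshold, 100 * object@topFraction, object@pctPositive))
  cat(sprintf("  MFI (%s) control %.4g, treated %.4g, fold %.3g\n",
              object@statistic, object@mfiControl, object@mfiTreated,
              object@foldMFI))
  invisible(object)
})

setMethod("show", "ChelationResult", function(object) {
  cat(sprintf("ChelationResult: slope %.4g, intercept %.4g (%s scale)\n",
              object@slope, object@intercept, object@scale))
  if (is.na(object@concAt50)) {
    cat("  50%-activity concentration: undefined\n")
  } else {
    cat(sprintf("  50%%-activity concentration: %.4g%s\n", object@concAt50,
                if (object@withinRange) "" else " (extrapolated; flagged)"))
  }
  invisible(object)
})
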