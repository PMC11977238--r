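#' @import methods
NULL

#' Simulation configuration for the synthetic reporter-assay generator
#'
#' An S4 container holding every tunable parameter of the synthetic data
#' generator: field geometry, nucleus morphology, per-cell lognormal
#' intensity models for the constitutive EGFP channel and the
#' signal-driven Tomato channel, the induction fold change, well-level
#' noise, kinetics, dose-response and flow-event parameters. The defaults
#' describe a well-behaved monoclonal dual-reporter line: ~10-fold
#' Tomato/EGFP induction, 10% well-to-well CV (of which most is shared
#' between channels and therefore cancelled by the ratio), and a
#' dose-response with EC50 = 0.2 nM.
#'
#' @slot seed integer, default RNG seed used when an operation is not
#'   given an explicit one.
#' @slot fieldShape integer(2), image field height and width in pixels.
#' @slot nNucleiPerField integer, nuclei placed per simulated field.
#' @slot nucleusRadiusMean,nucleusRadiusSD numeric, pixel radius
#'   distribution of normal nuclei (truncated normal, min 2 px).
#' @slot egfpMu,egfpSigma numeric, lognormal meanlog/sdlog of per-cell
#'   EGFP intensity (arbitrary units).
#' @slot basalTomMu,basalTomSigma numeric, lognormal meanlog/sdlog of
#'   uninduced per-cell Tomato intensity (AU).
#' @slot inductionFold numeric, multiplicative Tomato fold change in
#'   induced responder cells (default 10).
#' @slot responderFraction numeric in \[0,1\], fraction of cells that
#'   respond to induction (1 for clonal lines, ~0.5 for pools).
#' @slot backgroundLevel,noiseSD numeric, additive image background and
#'   Gaussian read-noise SD (AU).
#' @slot blurSigma numeric, optional Gaussian blur sigma in pixels
#'   applied to rendered fields (default 0: crisp pixel-resolution
#'   disks; optical PSF realism is deliberately not modelled).
#' @slot borderFraction,clusterFraction,abnormalFraction numeric in
#'   \[0,1\], fractions of nuclei planted touching the field edge,
#'   overlapping a neighbour, or oversized/abnormal.
#' @slot wellCV numeric, total coefficient of variation of well-level
#'   channel means (default 0.10).
#' @slot sharedCVFraction numeric in \[0,1\], fraction of the well-level
#'   variance shared between the two channels (cell density, seeding);
#'   shared variation cancels in the Tomato/EGFP ratio, which is the
#'   point of the internal control (default 0.85).
#' @slot kineticsOnsetH,kineticsRate,kineticsPlateau numeric, induction
#'   kinetics: onset time (h) at which the reporter departs baseline,
#'   first-order rise rate (1/h), and plateau fold change.
#' @slot ec50True numeric, true EC50 in molar units (default 2e-10,
#'   i.e. 0.2 nM).
#' @slot hillTrue numeric, true Hill slope (default 1).
#' @slot drNoiseCV numeric, multiplicative dose-response noise CV.
#'
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    fieldShape = "integer",
    nNucleiPerField = "integer",
    nucleusRadiusMean = "numeric",
    nucleusRadiusSD = "numeric",
    egfpMu = "numeric",
    egfpSigma = "numeric",
    basalTomMu = "numeric",
    basalTomSigma = "numeric",
    inductionFold = "numeric",
    responderFraction = "numeric",
    backgroundLevel = "numeric",
    noiseSD = "numeric",
    blurSigma = "numeric",
    borderFraction = "numeric",
    clusterFraction = "numeric",
    abnormalFraction = "numeric",
    wellCV = "numeric",
    sharedCVFraction = "numeric",
    kineticsOnsetH = "numeric",
    kineticsRate = "numeric",
    kineticsPlateau = "numeric",
    ec50True = "numeric",
    hillTrue = "numeric",
    drNoiseCV = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(
    nucleusRadiusMean = object@nucleusRadiusMean,
    egfpSigma = object@egfpSigma,
    basalTomSigma = object@basalTomSigma,
    inductionFold = object@inductionFold,
    kineticsPlateau = object@kineticsPlateau,
    ec50True = object@ec50True
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, paste0("scale parameters must be > 0: ",
                         paste(names(pos)[!(is.finite(pos) & pos > 0)],
                               collapse = ", ")))
  nonneg <- c(
    nucleusRadiusSD = object@nucleusRadiusSD,
    backgroundLevel = object@backgroundLevel,
    noiseSD = object@noiseSD,
    blurSigma = object@blurSigma,
    wellCV = object@wellCV,
    drNoiseCV = object@drNoiseCV,
    kineticsRate = object@kineticsRate
  )
  if (any(!is.na(nonneg) & nonneg < 0))
    msg <- c(msg, paste0("parameters must be >= 0: ",
                         paste(names(nonneg)[!is.na(nonneg) & nonneg < 0],
                               collapse = ", ")))
  frac <- c(
    responderFraction = object@responderFraction,
    borderFraction = object@borderFraction,
    clusterFraction = object@clusterFraction,
    abnormalFraction = object@abnormalFraction,
    sharedCVFraction = object@sharedCVFraction
  )
  if (any(frac < 0 | frac > 1))
    msg <- c(msg, paste0("fractions must lie in [0, 1]: ",
                         paste(names(frac)[frac < 0 | frac > 1],
                               collapse = ", ")))
  if (length(object@fieldShape) != 2L || any(object@fieldShape < 8L))
    msg <- c(msg, "fieldShape must be two integers >= 8")
  if (object@nNucleiPerField < 0L)
    msg <- c(msg, "nNucleiPerField must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A simulated two-channel image field with planted ground truth
#'
#' Co-registered EGFP and Tomato pixel matrices, the true per-nucleus
#' label mask (0 = background, k = nucleus k; labels contiguous from 1
#' and in bijection with the truth table rows), and a truth table with
#' one row per planted nucleus (centroid, radius, true per-channel
#' intensities, border/cluster/abnormal/induced flags).
#'
#' @slot egfp,tomato numeric matrices, the two channels (AU).
#' @slot labelMask integer matrix, planted nucleus labels.
#' @slot truth data.frame, one row per planted nucleus.
#' @slot induced logical, whether the field was simulated as induced.
#'
#' @seealso [simulateImageField()]
#' @export
setClass("SimulatedField",
  representation(
    egfp = "matrix",
    tomato = "matrix",
    labelMask = "matrix",
    truth = "data.frame",
    induced = "logical"
  )
)

setValidity("SimulatedField", function(object) {
  msg <- character()
  if (!identical(dim(object@egfp), dim(object@tomato)) ||
      !identical(dim(object@egfp), dim(object@labelMask)))
    msg <- c(msg, "egfp, tomato and labelMask must share dimensions")
  labs <- sort(unique(as.integer(object@labelMask[object@labelMask > 0])))
  if (!identical(labs, seq_len(nrow(object@truth))))
    msg <- c(msg, "label mask ids must be contiguous 1..n and match truth rows")
  if (length(msg)) msg else TRUE
})

#' Result of a bimodal compound-screen classification
#'
#' Per-compound z-scores and classes for one screening replicate:
#' phase 1 wells are unstimulated and scored in activator mode, phase 2
#' wells are pathway-stimulated and scored in inhibitor mode. Compounds
#' whose EGFP z-score falls outside +/- the EGFP cutoff are excluded as
#' fluorescence artifacts before any hit call.
#'
#' @slot calls data.frame with columns compound_id, phase, z_ratio,
#'   z_egfp, z_tom, class.
#' @slot hits list of character vectors of hit compound ids per class
#'   (activator, inhibitor).
#' @slot hitRate named numeric, percent of the screened library called
#'   per class.
#' @slot nCompounds integer, library size used as the hit-rate
#'   denominator.
#' @slot zCut,egfpCut numeric, thresholds used.
#' @export
setClass("ScreenResult",
  representation(
    calls = "data.frame",
    hits = "list",
    hitRate = "numeric",
    nCompounds = "integer",
    zCut = "numeric",
    egfpCut = "numeric"
  )
)

#' A fitted four-parameter logistic dose-response model
#'
#' Parameters of y = floor + (ceiling - floor) / (1 + (ec50/x)^hill),
#' fitted by least squares in log-dose space from a coarse grid search
#' (profiled linear floor/ceiling) followed by Levenberg-Marquardt
#' refinement.
#'
#' @slot floor,ceiling numeric, lower and upper response asymptotes.
#' @slot hill numeric, Hill slope (negative for decreasing curves).
#' @slot ec50 numeric, half-maximal concentration (same units as the
#'   doses; always > 0).
#' @slot rss numeric, residual sum of squares.
#' @slot converged logical, whether the fit converged.
#' @slot nPoints integer, number of fitted points.
#' @export
setClass("DoseResponseFit",
  representation(
    floor = "numeric",
    ceiling = "numeric",
    hill = "numeric",
    ec50 = "numeric",
    rss = "numeric",
    converged = "logical",
    nPoints = "integer"
  )
)

setValidity("DoseResponseFit", function(object) {
  if (isTRUE(object@converged) && (!is.finite(object@ec50) || object@ec50 <= 0))
    "converged fits must have ec50 > 0" else TRUE
})

#' Flow-cytometry gating summary
#'
#' Positivity threshold derived from the top fraction of a negative
#' control population, percent of treated events above it, and MFI fold
#' change.
#'
#' @slot threshold numeric, intensity threshold (AU).
#' @slot pctPositive numeric in \[0, 100\].
#' @slot mfiControl,mfiTreated,foldMFI numeric, per-sample MFI summary
#'   (median by default) and their ratio.
#' @slot nControl,nTreated integer, event counts after any EGFP
#'   pre-gate.
#' @slot topFraction numeric, gated control tail mass.
#' @slot statistic character, "median" or "mean".
#' @export
setClass("GateResult",
  representation(
    threshold = "numeric",
    pctPositive = "numeric",
    mfiControl = "numeric",
    mfiTreated = "numeric",
    foldMFI = "numeric",
    nControl = "integer",
    nTreated = "integer",
    topFraction = "numeric",
    statistic = "character"
  )
)

setValidity("GateResult", function(object) {
  if (object@pctPositive < 0 || object@pctPositive > 100)
    "pctPositive must lie in [0, 100]" else TRUE
})

#' Iron-chelation activity curve
#'
#' Per-concentration chelation activities (percent), the ordinary
#' least-squares line of activity against log10(concentration) (or raw
#' concentration), and the concentration at which the fitted line
#' crosses 50% activity.
#'
#' @slot table data.frame with columns concentration, activity.
#' @slot slope,intercept numeric, fitted line coefficients.
#' @slot concAt50 numeric, concentration at 50% activity (NA when the
#'   crossing is undefined or falls more than one decade outside the
#'   tested range).
#' @slot withinRange logical, whether the crossing lies within one
#'   decade of the tested concentrations.
#' @slot scale character, "log10" or "linear" predictor scale.
#' @export
setClass("ChelationResult",
  representation(
    table = "data.frame",
    slope = "numeric",
    intercept = "numeric",
    concAt50 = "numeric",
    withinRange = "logical",
    scale = "character"
  )
)
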