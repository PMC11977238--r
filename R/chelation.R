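#' @include AllClasses.R
NULL

#' Iron-chelation activity from paired absorbances
#'
#' `activity = 100 * (A_control - A_x) / A_control`, the percent loss
#' of the iron-ferrozine complex absorbance caused by the compound:
#' 0% when the compound leaves the complex untouched, 100% at complete
#' chelation. Values are negative when the compound absorbs more than
#' the control; these are reported but flagged.
#'
#' @param aControl control absorbance (no compound); must be > 0.
#' @param aX compound absorbance(s).
#' @return percent activities, with a logical `flagged` attribute
#'   marking negative values.
#' @examples
#' chelationActivity(1.0, c(1.0, 0.75, 0))  # 0, 25, 100
#' @export
chelationActivity <- function(aControl, aX) {
  if (!is.finite(aControl) || aControl <= 0)
    stop("control absorbance must be > 0")
  act <- 100 * (aControl - aX) / aControl
  if (any(act < 0))
    warning("compound absorbance exceeds control; negative activity flagged")
  attr(act, "flagged") <- act < 0
  act
}

#' Fit a chelation activity curve and read off the 50% concentration
#'
#' Ordinary least-squares line of activity against log10(concentration)
#' (the standard scale for series spanning decades; a linear scale is
#' available), inverted at 50% activity. The crossing is reported as
#' undefined (NA) when the slope is not positive-definite in practice
#' (near-flat line) or when it falls more than one decade outside the
#' tested concentration range.
#'
#' @param concentrations positive concentrations (any consistent unit).
#' @param activities percent activities, same length; at least 3 points
#'   with spread in the predictor.
#' @param scale "log10" (default) or "linear" predictor scale.
#' @return a [ChelationResult-class].
#' @examples
#' res <- chelationCurve(c(10, 100, 1000), c(25, 50, 75))
#' concAt50(res)  # 100
#' @export
chelationCurve <- function(concentrations, activities,
                           scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  stopifnot(length(concentrations) == length(activities))
  if (length(concentrations) < 3)
    stop("need at least 3 concentrations")
  if (any(concentrations <= 0) && scale == "log10")
    stop("concentrations must be > 0 on the log10 scale")
  x <- if (scale == "log10") log10(concentrations) else concentrations
  if (stats::var(x) == 0)
    stop("zero variance in the concentration predictor")
  fit <- stats::lm(activities ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  concAt50 <- NA_real_
  withinRange <- FALSE
  if (is.finite(slope) && abs(slope) > sqrt(.Machine$double.eps)) {
    x50 <- (50 - intercept) / slope
    conc50 <- if (scale == "log10") 10^x50 else x50
    lo <- min(concentrations); hi <- max(concentrations)
    withinRange <- conc50 >= lo / 10 & conc50 <= hi * 10
    if (withinRange) concAt50 <- conc50
  }
  new("ChelationResult",
      table = data.frame(concentration = concentrations,
                         activity = activities),
      slope = slope, intercept = intercept,
      concAt50 = concAt50, withinRange = withinRange, scale = scale)
}
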