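#' @include AllClasses.R
NULL

eventVector <- function(events, channel = "tomato") {
  if (is.data.frame(events)) events[[channel]] else events
}

#' Derive a positivity threshold from a negative control population
#'
#' The threshold is the empirical `1 - topFraction` quantile
#' (linear-interpolation quantile) of the control Tomato intensities:
#' by construction the top `topFraction` of control events sit above
#' it (top 1% by default).
#'
#' @param controlEvents numeric Tomato intensities, or a data.frame
#'   with a `tomato` column; needs at least `1 / topFraction` events.
#' @param topFraction control tail mass defining positivity (default
#'   0.01).
#' @return the intensity threshold.
#' @examples
#' derivePositiveThreshold(1:100)
#' @export
derivePositiveThreshold <- function(controlEvents, topFraction = 0.01) {
  x <- eventVector(controlEvents)
  if (topFraction <= 0 || topFraction >= 1)
    stop("topFraction must lie in (0, 1)")
  if (length(x) < 1 / topFraction)
    stop(sprintf("need at least %d control events for topFraction = %g",
                 ceiling(1 / topFraction), topFraction))
  unname(stats::quantile(x, 1 - topFraction, type = 7))
}

#' Gate a treated sample against its negative control
#'
#' Applies an optional EGFP-positive pre-gate to both samples, derives
#' the positivity threshold from the control's top `topFraction`, and
#' reports the percent of treated events above it plus the
#' treated/control MFI fold change (median MFI by default, robust on
#' log-scale data; arithmetic mean available).
#'
#' @param controlEvents,treatedEvents data.frames with `gfp` and
#'   `tomato` columns (bare Tomato vectors accepted when no pre-gate is
#'   used).
#' @param gfpGate optional EGFP intensity below which events are
#'   dropped before gating.
#' @param topFraction control tail mass (default 0.01).
#' @param statistic MFI statistic, "median" (default) or "mean".
#' @return a [GateResult-class].
#' @examples
#' cfg <- simConfig()
#' ctl <- simulateFlowEvents(cfg, 2000, responderFraction = 0, seed = 1)
#' trt <- simulateFlowEvents(cfg, 2000, responderFraction = 0.5, seed = 2)
#' gateSummary(ctl, trt)
#' @export
gateSummary <- function(controlEvents, treatedEvents, gfpGate = NULL,
                        topFraction = 0.01,
                        statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!is.null(gfpGate)) {
    if (!is.data.frame(controlEvents) || !is.data.frame(treatedEvents))
      stop("gfpGate requires event tables with a gfp column")
    controlEvents <- controlEvents[controlEvents$gfp >= gfpGate, ,
                                   drop = FALSE]
    treatedEvents <- treatedEvents[treatedEvents$gfp >= gfpGate, ,
                                   drop = FALSE]
    if (nrow(controlEvents) == 0 || nrow(treatedEvents) == 0)
      stop("all events removed by the EGFP pre-gate")
  }
  ctl <- eventVector(controlEvents)
  trt <- eventVector(treatedEvents)
  if (!length(ctl) || !length(trt)) stop("both samples must be non-empty")
  thr <- derivePositiveThreshold(ctl, topFraction)
  stat <- if (statistic == "median") stats::median else mean
  mfiC <- stat(ctl); mfiT <- stat(trt)
  new("GateResult",
      threshold = thr,
      pctPositive = 100 * mean(trt > thr),
      mfiControl = mfiC, mfiTreated = mfiT, foldMFI = mfiT / mfiC,
      nControl = length(ctl), nTreated = length(trt),
      topFraction = topFraction, statistic = statistic)
}

#' Mode-normalised log-intensity histogram
#'
#' Bins log10 intensities and scales counts so the modal bin equals 1,
#' the conventional display for flow histograms. Non-positive
#' intensities cannot be log-scaled; they are shifted to the smallest
#' positive intensity observed and the result is flagged.
#'
#' @param events numeric intensities or a data.frame with a `tomato`
#'   column.
#' @param bins number of histogram bins (default 64).
#' @return data.frame (mid, count, normalised) with attributes
#'   `flagged` (TRUE when non-positive intensities were floored) and
#'   `breaks`.
#' @examples
#' h <- modeNormalisedHistogram(rlnorm(1000))
#' max(h$normalised)  # 1
#' @export
modeNormalisedHistogram <- function(events, bins = 64) {
  x <- eventVector(events)
  if (!length(x)) stop("need at least one event")
  flagged <- any(x <= 0)
  if (flagged) {
    floorVal <- if (any(x > 0)) min(x[x > 0]) else 1
    x[x <= 0] <- floorVal
  }
  lx <- log10(x)
  rng <- range(lx)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  out <- data.frame(mid = h$mids, count = h$counts,
                    normalised = h$counts / max(h$counts))
  attr(out, "flagged") <- flagged
  attr(out, "breaks") <- breaks
  out
}
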