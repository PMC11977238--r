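#' @include AllClasses.R
NULL

#' Min/max normalisation within experiments
#'
#' `x' = (x - min) / (max - min)` applied per group, so each
#' experiment's minimum maps to 0 and its maximum to 1 with order
#' preserved.
#'
#' @param values numeric vector.
#' @param group optional grouping (experiment id); NULL treats all
#'   values as one group.
#' @return normalised values in the original order.
#' @examples
#' minmaxNormalise(c(2, 4, 6))  # 0, 0.5, 1
#' @export
minmaxNormalise <- function(values, group = NULL) {
  if (is.null(group)) group <- rep(1L, length(values))
  stopifnot(length(group) == length(values))
  out <- numeric(length(values))
  for (g in unique(group)) {
    i <- group == g
    lo <- min(values[i]); hi <- max(values[i])
    if (hi <= lo)
      stop("constant values in group '", g, "': min/max undefined")
    out[i] <- (values[i] - lo) / (hi - lo)
  }
  out
}

## Profiled linear fit of the floor/ceiling for fixed (hill, log ec50):
## the 4PL is linear in (floor, ceiling) given the logistic design.
profiledLimits <- function(logDose, y, hill, logEc50, fixLimits = NULL) {
  z <- 1 / (1 + exp(hill * (logEc50 - logDose)))
  if (!is.null(fixLimits)) {
    lims <- fixLimits
  } else {
    fit <- stats::lm.fit(cbind(1, z), y)
    lims <- c(fit$coefficients[1], sum(fit$coefficients))
  }
  pred <- lims[1] + (lims[2] - lims[1]) * z
  list(floor = unname(lims[1]), ceiling = unname(lims[2]),
       rss = sum((y - pred)^2))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' `y = floor + (ceiling - floor) / (1 + (ec50/x)^hill)` in log-dose
#' space. Initialisation is a coarse grid over log-spaced EC50
#' candidates across the dose range crossed with Hill slopes
#' (+/- 0.5, 1, 2), with floor and ceiling profiled out linearly; the
#' best grid point is refined by Levenberg-Marquardt. Decreasing curves
#' are captured by a negative Hill slope; the EC50 is positive by
#' construction. Fewer than 5 distinct doses, or refinement failure,
#' yields a flagged (`converged = FALSE`) fit rather than an error, and
#' the reported solution is never worse than the best grid
#' initialisation.
#'
#' @param dose positive concentrations (any consistent unit; the EC50
#'   is returned in the same unit).
#' @param response numeric responses, same length.
#' @param fixLimits optional numeric(2) to fix floor and ceiling
#'   (e.g. c(0, 1) after min/max normalisation) instead of fitting
#'   them.
#' @return a [DoseResponseFit-class].
#' @examples
#' d <- rep(10^seq(-11, -7, length.out = 9), 2)
#' y <- 1 / (1 + (2e-10 / d))
#' ec50(fit4PL(d, y))
#' @export
fit4PL <- function(dose, response, fixLimits = NULL) {
  stopifnot(length(dose) == length(response))
  if (any(dose <= 0)) stop("doses must be > 0")
  ok <- is.finite(dose) & is.finite(response)
  dose <- dose[ok]; response <- response[ok]
  ld <- log(dose)
  flagged <- length(unique(dose)) < 5
  grid <- expand.grid(
    hill = c(-2, -1, -0.5, 0.5, 1, 2),
    logEc50 = seq(min(ld), max(ld), length.out = 15))
  gridFits <- mapply(function(h, le)
    profiledLimits(ld, response, h, le, fixLimits)$rss,
    grid$hill, grid$logEc50)
  best <- which.min(gridFits)
  h0 <- grid$hill[best]; le0 <- grid$logEc50[best]
  lims0 <- profiledLimits(ld, response, h0, le0, fixLimits)
  sol <- list(floor = lims0$floor, ceiling = lims0$ceiling, hill = h0,
              logEc50 = le0, rss = lims0$rss)
  converged <- FALSE
  residFun <- function(p) {
    fl <- if (is.null(fixLimits)) p[["fl"]] else fixLimits[1]
    ce <- if (is.null(fixLimits)) p[["ce"]] else fixLimits[2]
    response - (fl + (ce - fl) / (1 + exp(p[["h"]] * (p[["le"]] - ld))))
  }
  start <- if (is.null(fixLimits))
    c(fl = lims0$floor, ce = lims0$ceiling, h = h0, le = le0)
  else c(h = h0, le = le0)
  refined <- if (length(response) <= length(start)) NULL else tryCatch({
    fit <- minpack.lm::nls.lm(
      par = start, fn = residFun,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!fit$info %in% 1:4) NULL else {
      p <- fit$par
      list(floor = if (is.null(fixLimits)) p[["fl"]] else fixLimits[1],
           ceiling = if (is.null(fixLimits)) p[["ce"]] else fixLimits[2],
           hill = p[["h"]], logEc50 = p[["le"]],
           rss = sum(fit$fvec^2))
    }
  }, error = function(e) NULL)
  if (!is.null(refined) && is.finite(refined$rss) &&
      refined$rss <= sol$rss + 1e-12) {
    sol <- refined
    converged <- TRUE
  }
  # canonical orientation: the model is invariant under swapping the
  # limits and negating the hill; report ceiling >= floor so the hill
  # sign encodes the curve direction
  if (sol$ceiling < sol$floor) {
    tmp <- sol$floor; sol$floor <- sol$ceiling; sol$ceiling <- tmp
    sol$hill <- -sol$hill
  }
  new("DoseResponseFit",
      floor = sol$floor, ceiling = sol$ceiling, hill = sol$hill,
      ec50 = exp(sol$logEc50), rss = sol$rss,
      converged = converged && !flagged,
      nPoints = length(response))
}

#' Predicted response of a fitted 4PL model
#'
#' @param object a [DoseResponseFit-class].
#' @param newdata positive doses at which to evaluate the curve.
#' @param ... ignored.
#' @return predicted responses.
#' @export
setMethod("predict", "DoseResponseFit", function(object, newdata, ...) {
  if (any(newdata <= 0)) stop("doses must be > 0")
  object@floor + (object@ceiling - object@floor) /
    (1 + (object@ec50 / newdata)^object@hill)
})
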