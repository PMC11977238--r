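#' @include AllClasses.R
NULL

#' Z-prime screening-window factor
#'
#' `Z' = 1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|`, the
#' standard separation-window statistic for assay robustness, with
#' sample SDs (n - 1 denominator). The score is at most 1; values above
#' 0.5 conventionally denote an excellent assay window.
#'
#' @param posValues,negValues numeric vectors of the reporter value in
#'   the positive and negative control wells (at least 2 each).
#' @return the Z-prime score.
#' @examples
#' zprime(c(9, 10, 11), c(0.9, 1.0, 1.1))
#' @export
zprime <- function(posValues, negValues) {
  if (length(posValues) < 2 || length(negValues) < 2)
    stop("need at least 2 values per control group")
  mp <- mean(posValues); mn <- mean(negValues)
  if (mp == mn) stop("zero separation: control means are equal")
  1 - 3 * (stats::sd(posValues) + stats::sd(negValues)) / abs(mp - mn)
}

#' Fold change between control groups
#'
#' Ratio of the positive-control mean to the negative-control mean.
#'
#' @param posValues,negValues numeric control values; the negative mean
#'   must be positive.
#' @return mean(pos) / mean(neg).
#' @examples
#' foldChange(c(9, 11), c(0.9, 1.1))
#' @export
foldChange <- function(posValues, negValues) {
  mn <- mean(negValues)
  if (!is.finite(mn) || mn <= 0)
    stop("negative-control mean must be > 0")
  mean(posValues) / mn
}

#' Per-plate screening QC (Z-prime and fold change)
#'
#' Computes control means, SDs, Z-prime and fold change of the reporter
#' value for each plate of a well table. The default reporter value is
#' the Tomato/EGFP ratio; `value = "tomato"` scores the raw Tomato MFI
#' instead. Wells failing their minimum-nucleus check are dropped with
#' a warning before control statistics are formed.
#'
#' @param wells well table with columns plate, role and the reporter
#'   column (`ratio` or `tom_mean`); an optional logical `sufficient_n`
#'   column marks under-sampled wells.
#' @param value reporter value: "ratio" (default) or "tomato".
#' @return data.frame with one row per plate: plate, mu_pos, mu_neg,
#'   sigma_pos, sigma_neg, zprime, fold_change, n_pos, n_neg.
#' @examples
#' wells <- simulatePlate(simConfig(), htsLayout(nPlates = 2), seed = 1)
#' plateQC(wells)
#' @export
plateQC <- function(wells, value = c("ratio", "tomato")) {
  value <- match.arg(value)
  col <- if (value == "ratio") "ratio" else "tom_mean"
  if (!all(c("plate", "role", col) %in% names(wells)))
    stop("well table must contain plate, role and ", col)
  if (!is.null(wells$sufficient_n) && any(!wells$sufficient_n)) {
    warning(sum(!wells$sufficient_n),
            " well(s) dropped for insufficient nucleus counts")
    wells <- wells[wells$sufficient_n, , drop = FALSE]
  }
  out <- lapply(split(wells, wells$plate), function(pw) {
    pos <- pw[[col]][pw$role == "positive"]
    neg <- pw[[col]][pw$role == "vehicle"]
    if (length(pos) < 2 || length(neg) < 2)
      stop("plate ", pw$plate[1],
           ": need at least 2 positive and 2 vehicle control wells")
    data.frame(plate = pw$plate[1],
               mu_pos = mean(pos), mu_neg = mean(neg),
               sigma_pos = stats::sd(pos), sigma_neg = stats::sd(neg),
               zprime = zprime(pos, neg),
               fold_change = foldChange(pos, neg),
               n_pos = length(pos), n_neg = length(neg))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plate), , drop = FALSE]
}

#' Summarise screening robustness across plates
#'
#' @param plates a [plateQC()] table (or a well table, which is passed
#'   through [plateQC()] first).
#' @param ... passed to [plateQC()] when `plates` is a well table.
#' @return list with `perPlate` (the per-plate QC table), `meanZprime`,
#'   `minZprime` and `meanFoldChange`.
#' @examples
#' wells <- simulatePlate(simConfig(), htsLayout(nPlates = 3), seed = 1)
#' robustnessSummary(wells)$minZprime
#' @export
robustnessSummary <- function(plates, ...) {
  if (!"zprime" %in% names(plates)) plates <- plateQC(plates, ...)
  list(perPlate = plates,
       meanZprime = mean(plates$zprime),
       minZprime = min(plates$zprime),
       meanFoldChange = mean(plates$fold_change))
}

#' Summarise an induction time course
#'
#' Mean, SEM and n of the reporter value per (group, timepoint), plus
#' an onset estimate: the earliest timepoint from which the induced
#' mean exceeds the vehicle mean + 3 vehicle SDs at that and all later
#' timepoints. The onset is NA when the separation is never sustained
#' or when either group is absent from the comparison pair.
#'
#' @param timeseries data.frame with columns group, timepoint_h and the
#'   reporter column (default `ratio`); at least 2 replicates per
#'   (group, timepoint).
#' @param groups character groups to summarise; all must be present.
#' @param inducedGroup,vehicleGroup group labels used for onset
#'   detection.
#' @param valueColumn reporter column name.
#' @return list with `series` (group, timepoint_h, mean, sem, n) and
#'   `onsetH`.
#' @examples
#' ts <- simulateKinetics(simConfig(), timepointsH = seq(0, 38, 2), seed = 1)
#' kineticsSummary(ts)$onsetH
#' @export
kineticsSummary <- function(timeseries, groups = unique(timeseries$group),
                            inducedGroup = "induced",
                            vehicleGroup = "vehicle",
                            valueColumn = "ratio") {
  missing <- setdiff(groups, unique(timeseries$group))
  if (length(missing))
    stop("group(s) absent from data: ", paste(missing, collapse = ", "))
  ts <- timeseries[timeseries$group %in% groups, , drop = FALSE]
  agg <- lapply(split(ts, list(ts$group, ts$timepoint_h), drop = TRUE),
                function(d) {
    if (nrow(d) < 2)
      stop("need at least 2 replicates per (group, timepoint)")
    v <- d[[valueColumn]]
    data.frame(group = d$group[1], timepoint_h = d$timepoint_h[1],
               mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
               sd = stats::sd(v), n = length(v))
  })
  series <- do.call(rbind, agg)
  series <- series[order(series$group, series$timepoint_h), , drop = FALSE]
  rownames(series) <- NULL
  onset <- NA_real_
  if (all(c(inducedGroup, vehicleGroup) %in% series$group)) {
    ind <- series[series$group == inducedGroup, ]
    veh <- series[series$group == vehicleGroup, ]
    tp <- sort(intersect(ind$timepoint_h, veh$timepoint_h))
    sep <- vapply(tp, function(t)
      ind$mean[ind$timepoint_h == t] >
        veh$mean[veh$timepoint_h == t] + 3 * veh$sd[veh$timepoint_h == t],
      logical(1))
    sustained <- rev(cumprod(rev(sep))) > 0
    if (any(sustained)) onset <- tp[which(sustained)[1]]
  }
  list(series = series, onsetH = onset)
}
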