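#' @include AllClasses.R
NULL

#' Isodata (iterative intermeans) threshold
#'
#' Computes the classic isodata threshold of a pixel intensity sample:
#' starting from the sample midrange, iterate
#' `T <- (mean(x <= T) + mean(x > T)) / 2` until the update moves by
#' less than 0.5 intensity units (or 100 iterations). The fixed point
#' lies midway between the background and foreground means.
#'
#' @param intensities numeric pixel sample with at least two distinct
#'   values.
#' @return the converged threshold.
#' @examples
#' isodataThreshold(c(rep(10, 50), rep(110, 50)))  # 60
#' @export
isodataThreshold <- function(intensities) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("degenerate histogram: need at least two distinct intensities")
  thr <- (min(x) + max(x)) / 2
  for (i in seq_len(100)) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    if (!length(lo) || !length(hi)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < 0.5) { thr <- new; break }
    thr <- new
  }
  thr
}

#' Segmentation and QC parameters
#'
#' Bundles the tunable nucleus QC parameters: area bounds (px),
#' minimum solidity, the unseparated-cluster area factor (components
#' larger than `clusterAreaFactor` times the median candidate area are
#' excluded as unresolvable clusters), and the per-well minimum nucleus
#' count.
#'
#' @param minArea,maxArea admissible component area in pixels.
#' @param solidityMin minimum solidity (area / convex hull area).
#' @param clusterAreaFactor multiple of the median candidate area above
#'   which a component is called unseparated.
#' @param minNuclei minimum included nuclei for a well to be deemed
#'   sufficiently sampled (default 2000, the conventional per-well
#'   floor for high-content reporter quantification).
#' @return a named list.
#' @export
segmentationParams <- function(minArea = 50, maxArea = 2500,
                               solidityMin = 0.85, clusterAreaFactor = 1.6,
                               minNuclei = 2000) {
  stopifnot(minArea > 0, maxArea > minArea,
            solidityMin > 0, solidityMin <= 1, clusterAreaFactor > 1,
            minNuclei >= 0)
  list(minArea = minArea, maxArea = maxArea, solidityMin = solidityMin,
       clusterAreaFactor = clusterAreaFactor, minNuclei = minNuclei)
}

## 8-connectivity labelling: EBImage::bwlabel is 4-connected, so merge
## labels that touch diagonally with a small union-find pass.
labelComponents8 <- function(fg) {
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  h <- nrow(lab); w <- ncol(lab)
  lab <- matrix(as.integer(round(lab)), h, w)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))  # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  newid <- match(root, sort(unique(root)))
  lab[lab > 0] <- newid[lab[lab > 0]]
  lab
}

#' Segment nuclei on the EGFP channel and apply QC exclusions
#'
#' Foreground is defined as EGFP at or above the isodata threshold of
#' the field; 8-connected components become nucleus candidates. Each
#' component receives exactly one QC status, applied in order of
#' precedence: `excluded_border` (any pixel on the image edge),
#' `excluded_abnormal` (area outside the configured bounds or solidity
#' below the minimum), `excluded_unseparated` (area above
#' `clusterAreaFactor` times the median area of the remaining
#' candidates), otherwise `included`. Per-channel MFIs are measured
#' over the component mask after subtracting the field background
#' (median of sub-threshold pixels per channel), floored at zero.
#'
#' @param field a [SimulatedField-class] or a list with `egfp` and
#'   `tomato` matrices.
#' @param params a [segmentationParams()] list.
#' @return list with `labelMap` (integer matrix of component labels),
#'   `nuclei` (data.frame: id, row, col, area, eccentricity, solidity,
#'   border_flag, egfp_mfi, tom_mfi, qc_status), `threshold`, and
#'   `background` (per-channel estimates). Zero foreground yields an
#'   empty (not erroneous) result.
#' @examples
#' fld <- simulateImageField(simConfig(nNucleiPerField = 8L), seed = 1)
#' seg <- segmentNuclei(fld)
#' table(seg$nuclei$qc_status)
#' @export
segmentNuclei <- function(field, params = segmentationParams()) {
  egfp <- egfpChannel(field); tom <- tomatoChannel(field)
  if (is.null(egfp)) stop("missing EGFP channel")
  if (is.null(tom)) stop("missing Tomato channel")
  thr <- isodataThreshold(as.vector(egfp))
  fg <- egfp >= thr
  empty <- list(
    labelMap = matrix(0L, nrow(egfp), ncol(egfp)),
    nuclei = data.frame(id = integer(), row = numeric(), col = numeric(),
                        area = numeric(), eccentricity = numeric(),
                        solidity = numeric(), border_flag = logical(),
                        egfp_mfi = numeric(), tom_mfi = numeric(),
                        qc_status = character()),
    threshold = thr,
    background = c(egfp = NA_real_, tom = NA_real_))
  if (!any(fg)) return(empty)
  bgE <- stats::median(egfp[!fg])
  bgT <- stats::median(tom[!fg])
  lab <- labelComponents8(fg)
  n <- max(lab)
  if (n == 0) return(empty)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rowsI <- (idx - 1L) %% nrow(lab) + 1L
  colsI <- (idx - 1L) %/% nrow(lab) + 1L
  pix <- split(seq_along(idx), labs)
  h <- nrow(lab); w <- ncol(lab)
  rec <- lapply(seq_len(n), function(k) {
    p <- pix[[as.character(k)]]
    pr <- rowsI[p]; pc <- colsI[p]
    area <- length(p)
    border <- any(pr == 1L | pr == h | pc == 1L | pc == w)
    data.frame(id = k, row = mean(pr), col = mean(pc), area = area,
               eccentricity = momentEccentricity(pr, pc),
               solidity = pixelSolidity(pr, pc),
               border_flag = border,
               egfp_mfi = max(0, mean(egfp[idx[p]]) - bgE),
               tom_mfi = max(0, mean(tom[idx[p]]) - bgT))
  })
  nuc <- do.call(rbind, rec)
  qc <- rep("included", n)
  qc[nuc$border_flag] <- "excluded_border"
  abn <- qc == "included" &
    (nuc$area < params$minArea | nuc$area > params$maxArea |
     nuc$solidity < params$solidityMin)
  qc[abn] <- "excluded_abnormal"
  cand <- qc == "included"
  if (any(cand)) {
    medArea <- stats::median(nuc$area[cand])
    qc[cand & nuc$area > params$clusterAreaFactor * medArea] <-
      "excluded_unseparated"
  }
  nuc$qc_status <- qc
  list(labelMap = lab, nuclei = nuc, threshold = thr,
       background = c(egfp = bgE, tom = bgT))
}

## Eccentricity from second central moments, as in standard regionprops.
momentEccentricity <- function(pr, pc) {
  if (length(pr) < 2) return(0)
  mrr <- stats::var(pr) * (length(pr) - 1) / length(pr) + 1 / 12
  mcc <- stats::var(pc) * (length(pc) - 1) / length(pc) + 1 / 12
  mrc <- stats::cov(pr, pc) * (length(pr) - 1) / length(pr)
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

## Solidity = pixel area / area of the convex hull of the pixel squares
## (hull taken over pixel corners so convex shapes score ~1, capped at 1).
pixelSolidity <- function(pr, pc) {
  n <- length(pr)
  if (n < 3) return(1)
  corners <- cbind(c(pr - 0.5, pr - 0.5, pr + 0.5, pr + 0.5),
                   c(pc - 0.5, pc + 0.5, pc - 0.5, pc + 0.5))
  hull <- grDevices::chull(corners)
  hp <- corners[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3) return(1)
  j <- c(2:m, 1)
  hullArea <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
  if (hullArea <= 0) return(1)
  min(1, n / hullArea)
}

#' Aggregate included nuclei into a well-level quantification
#'
#' Pools QC-included nuclei across one or more segmented fields of the
#' same well and computes the well EGFP mean, Tomato mean and reporter
#' ratio. The default reporter value is the ratio of well means
#' (Tomato mean / EGFP mean); the mean of per-nucleus ratios is
#' available as an option. Wells with no included nuclei are returned
#' flagged (ratio NA, `sufficient_n = FALSE`), not as errors.
#'
#' @param fields a single [segmentNuclei()] result or a list of them;
#'   a bare nucleus data.frame is also accepted.
#' @param minNuclei minimum included nuclei for `sufficient_n`
#'   (default 2000).
#' @param plate,well identifiers carried into the output row.
#' @param ratioMethod "ratio-of-means" (default) or "mean-of-ratios".
#' @return one-row data.frame (plate, well, n_included, egfp_mean,
#'   tom_mean, ratio, sufficient_n).
#' @examples
#' fld <- simulateImageField(simConfig(nNucleiPerField = 8L), seed = 1)
#' quantifyWell(segmentNuclei(fld), minNuclei = 5)
#' @export
quantifyWell <- function(fields, minNuclei = 2000, plate = NA, well = NA,
                         ratioMethod = c("ratio-of-means",
                                         "mean-of-ratios")) {
  ratioMethod <- match.arg(ratioMethod)
  if (is.data.frame(fields)) fields <- list(list(nuclei = fields))
  if (!is.null(fields$nuclei)) fields <- list(fields)
  if (length(fields) < 1) stop("need at least one segmented field")
  nuc <- do.call(rbind, lapply(fields, `[[`, "nuclei"))
  inc <- nuc[nuc$qc_status == "included", , drop = FALSE]
  n <- nrow(inc)
  if (n == 0) {
    return(data.frame(plate = plate, well = well, n_included = 0L,
                      egfp_mean = NA_real_, tom_mean = NA_real_,
                      ratio = NA_real_, sufficient_n = FALSE))
  }
  egfp <- mean(inc$egfp_mfi)
  tom <- mean(inc$tom_mfi)
  ratio <- if (ratioMethod == "ratio-of-means") {
    if (egfp > 0) tom / egfp else NA_real_
  } else {
    ok <- inc$egfp_mfi > 0
    if (any(ok)) mean(inc$tom_mfi[ok] / inc$egfp_mfi[ok]) else NA_real_
  }
  data.frame(plate = plate, well = well, n_included = n,
             egfp_mean = egfp, tom_mean = tom, ratio = ratio,
             sufficient_n = n >= minNuclei)
}
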