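#' @include AllClasses.R AllGenerics.R
NULL

#' Z-score well values against a reference population
#'
#' `z = (x - mean(ref)) / sd(ref)`. The screening default references
#' every compound well of the same phase and replicate; a robust mode
#' uses median and 1.4826 * MAD instead.
#'
#' @param values numeric values to score.
#' @param reference reference population (default: the values
#'   themselves); needs at least 3 values with positive spread.
#' @param robust use median/MAD location and scale.
#' @return numeric z-scores.
#' @examples
#' zscoreWells(c(1, 2, 3), c(0, 1, 2, 3, 4))
#' @export
zscoreWells <- function(values, reference = values, robust = FALSE) {
  if (length(reference) < 3)
    stop("reference population needs at least 3 values")
  if (robust) {
    ctr <- stats::median(reference)
    scl <- stats::mad(reference)  # 1.4826 * MAD, normal-consistent
  } else {
    ctr <- mean(reference)
    scl <- stats::sd(reference)
  }
  if (!is.finite(scl) || scl <= 0)
    stop("reference population has zero spread")
  (values - ctr) / scl
}

#' Classify screened compounds from ratio and EGFP z-scores
#'
#' EGFP-artifact exclusion takes precedence: any compound with
#' `|z_egfp| > egfpCut` is `excluded_fluorescent` regardless of its
#' ratio z-score. Otherwise, activator mode calls
#' `z_ratio >= zCut` an activator and inhibitor mode calls
#' `z_ratio <= -zCut` an inhibitor; everything else is inactive.
#' Boundaries are closed on the hit side so behaviour at exactly the
#' cutoff is defined.
#'
#' @param zRatio,zEgfp numeric z-scores of the Tomato/EGFP ratio and of
#'   the EGFP MFI.
#' @param mode "activator" or "inhibitor".
#' @param zCut,egfpCut thresholds in SD units (default 2).
#' @return character vector of classes.
#' @examples
#' classifyCompounds(c(2.5, 2.5, 0), c(0.3, 2.5, 0), "activator")
#' @export
classifyCompounds <- function(zRatio, zEgfp,
                              mode = c("activator", "inhibitor"),
                              zCut = 2, egfpCut = 2) {
  mode <- match.arg(mode)
  if (zCut <= 0 || egfpCut <= 0) stop("cutoffs must be positive")
  stopifnot(length(zRatio) == length(zEgfp))
  cls <- rep("inactive", length(zRatio))
  if (mode == "activator") cls[zRatio >= zCut] <- "activator"
  else cls[zRatio <= -zCut] <- "inhibitor"
  cls[abs(zEgfp) > egfpCut] <- "excluded_fluorescent"
  cls
}

#' Percent hit rate
#'
#' Hits as a percentage of the screened library,
#' `100 * nHits / nLibrary`, reported to one decimal as convention.
#'
#' @param object number of hits.
#' @param nLibrary library size.
#' @param digits decimals to report (default 1).
#' @return percent hit rate.
#' @examples
#' hitRate(8, 1595)  # 0.5
#' @rdname accessors
#' @export
setMethod("hitRate", "numeric", function(object, nLibrary, digits = 1) {
  if (nLibrary < 1) stop("library size must be >= 1")
  round(100 * object / nLibrary, digits)
})

#' @rdname accessors
setMethod("hitRate", "ScreenResult", function(object, ...) object@hitRate)

#' Run one replicate of a bimodal two-phase screen
#'
#' Z-scores both phases against their compound-well populations,
#' classifies phase 1 (unstimulated) in activator mode and phase 2
#' (stimulated) in inhibitor mode with EGFP-artifact exclusion, and
#' reports per-class hit lists and percent hit rates over the library.
#'
#' @param phase1,phase2 well tables with columns compound_id, role,
#'   egfp_mean, tom_mean and ratio; the two phases must cover the same
#'   compound set.
#' @param zCut,egfpCut classification thresholds (SD units).
#' @param robust robust (median/MAD) z-scoring.
#' @param reference "compounds" (default) z-scores against all compound
#'   wells of the phase; "controls" uses the plate control wells.
#' @return a [ScreenResult-class].
#' @examples
#' scr <- simulateScreen(simConfig(), nCompounds = 60, seed = 5)
#' runBimodalScreen(scr$replicates[[1]]$phase1, scr$replicates[[1]]$phase2)
#' @export
runBimodalScreen <- function(phase1, phase2, zCut = 2, egfpCut = 2,
                             robust = FALSE,
                             reference = c("compounds", "controls")) {
  reference <- match.arg(reference)
  c1 <- phase1[phase1$role == "compound", , drop = FALSE]
  c2 <- phase2[phase2$role == "compound", , drop = FALSE]
  extra1 <- setdiff(c1$compound_id, c2$compound_id)
  extra2 <- setdiff(c2$compound_id, c1$compound_id)
  if (length(extra1) || length(extra2))
    stop("phases screened different compound sets; only in phase 1: {",
         paste(utils::head(extra1, 5), collapse = ", "),
         "}, only in phase 2: {",
         paste(utils::head(extra2, 5), collapse = ", "), "}")
  c2 <- c2[match(c1$compound_id, c2$compound_id), , drop = FALSE]
  scorePhase <- function(cmp, full, mode) {
    ref <- if (reference == "compounds") cmp else
      full[full$role != "compound", , drop = FALSE]
    data.frame(
      compound_id = cmp$compound_id,
      phase = if (mode == "activator") 1L else 2L,
      z_ratio = zscoreWells(cmp$ratio, ref$ratio, robust),
      z_egfp = zscoreWells(cmp$egfp_mean, ref$egfp_mean, robust),
      z_tom = zscoreWells(cmp$tom_mean, ref$tom_mean, robust),
      stringsAsFactors = FALSE)
  }
  p1 <- scorePhase(c1, phase1, "activator")
  p2 <- scorePhase(c2, phase2, "inhibitor")
  p1$class <- classifyCompounds(p1$z_ratio, p1$z_egfp, "activator",
                                zCut, egfpCut)
  p2$class <- classifyCompounds(p2$z_ratio, p2$z_egfp, "inhibitor",
                                zCut, egfpCut)
  calls <- rbind(p1, p2)
  n <- nrow(c1)
  hits <- list(activator = p1$compound_id[p1$class == "activator"],
               inhibitor = p2$compound_id[p2$class == "inhibitor"])
  new("ScreenResult", calls = calls, hits = hits,
      hitRate = c(activator = hitRate(length(hits$activator), n),
                  inhibitor = hitRate(length(hits$inhibitor), n)),
      nCompounds = as.integer(n), zCut = zCut, egfpCut = egfpCut)
}

#' Intersect hit lists of two replicate screens
#'
#' Confirmed hits are the per-class set intersection of the two
#' replicates' hit lists; combined rates are reported over the library
#' size.
#'
#' @param rep1,rep2 [ScreenResult-class] objects over the same library.
#' @return list with `confirmed` (per-class id vectors) and `hitRate`
#'   (per-class combined percent rates).
#' @examples
#' cfg <- simConfig()
#' scr <- simulateScreen(cfg, nCompounds = 60, seed = 5)
#' r <- lapply(scr$replicates, function(s) runBimodalScreen(s$phase1, s$phase2))
#' intersectReplicates(r[[1]], r[[2]])$hitRate
#' @export
intersectReplicates <- function(rep1, rep2) {
  if (rep1@nCompounds != rep2@nCompounds)
    stop("replicates screened different library sizes")
  classes <- union(names(rep1@hits), names(rep2@hits))
  confirmed <- lapply(stats::setNames(classes, classes), function(cl)
    intersect(rep1@hits[[cl]], rep2@hits[[cl]]))
  list(confirmed = confirmed,
       hitRate = vapply(confirmed, function(ids)
         hitRate(length(ids), rep1@nCompounds), numeric(1)))
}

#' Pearson consistency between replicate screens
#'
#' Standard Pearson correlation (with two-sided p-value) between paired
#' compound activities of two replicate screens, optionally restricted
#' to a subset of compounds.
#'
#' @param z1,z2 paired numeric vectors (e.g. ratio z-scores).
#' @param subset optional logical or integer index selecting compounds.
#' @return list with `r`, `p.value` and `n`.
#' @examples
#' replicateCorrelation(1:10, (1:10) + rnorm(10, 0, 0.1))$r
#' @export
replicateCorrelation <- function(z1, z2, subset = NULL) {
  stopifnot(length(z1) == length(z2))
  if (!is.null(subset)) { z1 <- z1[subset]; z2 <- z2[subset] }
  if (length(z1) < 3) stop("need at least 3 paired values")
  if (stats::sd(z1) == 0 || stats::sd(z2) == 0)
    stop("zero variance in a replicate vector")
  ct <- stats::cor.test(z1, z2, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(z1))
}
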