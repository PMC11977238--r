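#' @include AllClasses.R
NULL

#' Construct a simulation configuration
#'
#' User-facing constructor for [SimConfig-class]. All arguments have
#' defaults describing a monoclonal dual-reporter line imaged at
#' desk-test scale; see the class documentation for slot meanings and
#' the methods vignette for how the defaults were chosen.
#'
#' @param seed default RNG seed used when an operation is not given one.
#' @param fieldShape integer(2) field height and width in pixels.
#' @param nNucleiPerField nuclei per field.
#' @param nucleusRadiusMean,nucleusRadiusSD nucleus radius (px).
#' @param egfpMu,egfpSigma lognormal meanlog/sdlog of per-cell EGFP.
#' @param basalTomMu,basalTomSigma lognormal meanlog/sdlog of basal
#'   Tomato.
#' @param inductionFold multiplicative Tomato induction (default 10).
#' @param responderFraction fraction of cells induced (default 1).
#' @param backgroundLevel,noiseSD additive background and read noise.
#' @param blurSigma optional Gaussian blur sigma (px, default 0).
#' @param borderFraction,clusterFraction,abnormalFraction planted QC
#'   fractions.
#' @param wellCV well-level coefficient of variation (default 0.10).
#' @param sharedCVFraction fraction of well-level variance shared
#'   between channels (default 0.85).
#' @param kineticsOnsetH,kineticsRate,kineticsPlateau induction
#'   kinetics parameters (h, 1/h, fold).
#' @param ec50True true EC50 in molar (default 2e-10 = 0.2 nM).
#' @param hillTrue true Hill slope (default 1).
#' @param drNoiseCV dose-response multiplicative noise CV (default
#'   0.05).
#'
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nNucleiPerField = 10L)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      fieldShape = c(192L, 192L),
                      nNucleiPerField = 40L,
                      nucleusRadiusMean = 6,
                      nucleusRadiusSD = 0.8,
                      egfpMu = log(500),
                      egfpSigma = 0.25,
                      basalTomMu = log(80),
                      basalTomSigma = 0.25,
                      inductionFold = 10,
                      responderFraction = 1,
                      backgroundLevel = 40,
                      noiseSD = 4,
                      blurSigma = 0,
                      borderFraction = 0.05,
                      clusterFraction = 0.05,
                      abnormalFraction = 0,
                      wellCV = 0.10,
                      sharedCVFraction = 0.85,
                      kineticsOnsetH = 10,
                      kineticsRate = 0.5,
                      kineticsPlateau = 10,
                      ec50True = 2e-10,
                      hillTrue = 1,
                      drNoiseCV = 0.05) {
  new("SimConfig",
      seed = as.integer(seed),
      fieldShape = as.integer(fieldShape),
      nNucleiPerField = as.integer(nNucleiPerField),
      nucleusRadiusMean = nucleusRadiusMean,
      nucleusRadiusSD = nucleusRadiusSD,
      egfpMu = egfpMu, egfpSigma = egfpSigma,
      basalTomMu = basalTomMu, basalTomSigma = basalTomSigma,
      inductionFold = inductionFold,
      responderFraction = responderFraction,
      backgroundLevel = backgroundLevel, noiseSD = noiseSD,
      blurSigma = blurSigma,
      borderFraction = borderFraction,
      clusterFraction = clusterFraction,
      abnormalFraction = abnormalFraction,
      wellCV = wellCV, sharedCVFraction = sharedCVFraction,
      kineticsOnsetH = kineticsOnsetH, kineticsRate = kineticsRate,
      kineticsPlateau = kineticsPlateau,
      ec50True = ec50True, hillTrue = hillTrue, drNoiseCV = drNoiseCV)
}

## Expected well-level channel means implied by the per-cell lognormal
## models; the tabular fast path draws around these.
expectedEgfp <- function(config) exp(config@egfpMu + config@egfpSigma^2 / 2)
expectedBasalTom <- function(config)
  exp(config@basalTomMu + config@basalTomSigma^2 / 2)

## Ratio CV implied by the channel-specific (non-shared) well noise.
ratioCV <- function(config)
  config@wellCV * sqrt(2 * (1 - config@sharedCVFraction))

#' Convert a target z-score effect into a multiplicative ratio effect
#'
#' Screens are z-scored against all compound wells, so a compound whose
#' true Tomato/EGFP effect multiplies the ratio by `1 + z * ratio CV`
#' lands (in expectation) z reference SDs from the inactive population.
#' Used to plant effects of calibrated strength in synthetic screens.
#'
#' @param config a [SimConfig-class].
#' @param z target z-score.
#' @return multiplicative effect on the reporter ratio.
#' @export
foldForZ <- function(config, z) 1 + z * ratioCV(config)

truncNorm <- function(n, mean, sd, lower) pmax(lower, stats::rnorm(n, mean, sd))

## Place nuclei on the field. Returns a data.frame of centres/radii with
## flags; errors if the requested density cannot be placed.
placeNuclei <- function(config) {
  h <- config@fieldShape[1]; w <- config@fieldShape[2]
  n <- config@nNucleiPerField
  if (n == 0L) {
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      radius = numeric(), border_flag = logical(),
                      cluster_flag = logical(), abnormal_flag = logical()))
  }
  nBorder <- round(config@borderFraction * n)
  nCluster <- round(config@clusterFraction * n)
  nAbnormal <- round(config@abnormalFraction * n)
  nNormal <- n - nBorder - nCluster - nAbnormal
  if (nNormal < 0)
    stop("border/cluster/abnormal fractions exceed the nucleus budget")
  radii <- truncNorm(n, config@nucleusRadiusMean, config@nucleusRadiusSD, 2)
  kind <- rep(c("normal", "abnormal", "border", "cluster"),
              c(nNormal, nAbnormal, nBorder, nCluster))
  # abnormal nuclei are oversized blobs (5x mean radius => area beyond any
  # plausible single-nucleus bound)
  radii[kind == "abnormal"] <- 5 * config@nucleusRadiusMean
  rows <- cols <- numeric(n)
  partnerUsed <- logical(n)  # each cluster pairs a distinct partner so
                             # merged blobs stay two-lobed
  maxTry <- 500L
  gap <- 3  # background gap so hard disks never touch under 8-connectivity
  for (i in seq_len(n)) {
    r <- radii[i]
    placed <- FALSE
    chosenPartner <- NA_integer_
    for (try in seq_len(maxTry)) {
      if (kind[i] == "border") {
        side <- sample.int(4L, 1L)
        d <- stats::runif(1, 1, max(1, r - 1))  # centre-to-edge distance < r
        along <- stats::runif(1, r + 1, c(w, w, h, h)[side] - r - 1)
        if (side == 1L) { rows[i] <- 1 + d; cols[i] <- along }
        else if (side == 2L) { rows[i] <- h - d; cols[i] <- along }
        else if (side == 3L) { cols[i] <- 1 + d; rows[i] <- along }
        else { cols[i] <- w - d; rows[i] <- along }
      } else if (kind[i] == "cluster" && i > 1L &&
                 any(kind[seq_len(i - 1L)] == "normal" &
                     !partnerUsed[seq_len(i - 1L)])) {
        candidates <- which(kind[seq_len(i - 1L)] == "normal" &
                            !partnerUsed[seq_len(i - 1L)])
        partner <- candidates[sample.int(length(candidates), 1L)]
        chosenPartner <- partner
        ang <- stats::runif(1, 0, 2 * pi)
        d <- 0.75 * (r + radii[partner])  # union area ~1.9x a single disk
        rows[i] <- rows[partner] + d * sin(ang)
        cols[i] <- cols[partner] + d * cos(ang)
        if (rows[i] < r + 2 || rows[i] > h - r - 1 ||
            cols[i] < r + 2 || cols[i] > w - r - 1) next
      } else {
        rows[i] <- stats::runif(1, r + 2, h - r - 1)
        cols[i] <- stats::runif(1, r + 2, w - r - 1)
      }
      # non-overlap with previously placed nuclei (clusters overlap their
      # partner on purpose; everyone else keeps a background gap)
      ok <- TRUE
      if (i > 1L) {
        j <- seq_len(i - 1L)
        dist <- sqrt((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2)
        need <- r + radii[j] + gap
        viol <- which(dist < need)
        # clusters may touch exactly their chosen partner, nobody else
        ok <- if (kind[i] == "cluster" && !is.na(chosenPartner))
          identical(viol, chosenPartner) else length(viol) == 0L
      }
      if (ok) { placed <- TRUE; break }
    }
    if (placed && !is.na(chosenPartner)) partnerUsed[chosenPartner] <- TRUE
    if (!placed)
      stop(sprintf(paste0("could not place nucleus %d after %d retries: ",
                          "%d nuclei of mean radius %.1f px are too dense ",
                          "for a %dx%d field"),
                   i, maxTry, n, config@nucleusRadiusMean, h, w))
  }
  data.frame(id = seq_len(n), row = rows, col = cols, radius = radii,
             border_flag = kind == "border",
             cluster_flag = kind == "cluster",
             abnormal_flag = kind == "abnormal")
}

gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

#' Simulate a two-channel image field with ground truth
#'
#' Renders a co-registered EGFP/Tomato pixel field. Nuclei are hard
#' (pixel-centre) disks of per-cell lognormal intensity over a uniform
#' background, with optional Gaussian blur and read noise. A configured
#' fraction of nuclei is planted touching the field edge, overlapping a
#' neighbour (so segmentation sees one unseparable component), or as an
#' oversized abnormal blob. When `induced = TRUE`, a `responderFraction`
#' of cells has its true Tomato intensity multiplied by the induction
#' fold.
#'
#' @param config a [SimConfig-class].
#' @param induced logical, simulate a stimulated field.
#' @param seed integer RNG seed (defaults to `config@seed`).
#' @return a [SimulatedField-class]; the truth table has one row per
#'   planted nucleus and is in bijection with the label mask.
#' @examples
#' fld <- simulateImageField(simConfig(nNucleiPerField = 6L), seed = 7)
#' fld
#' @export
simulateImageField <- function(config, induced = FALSE, seed = config@seed) {
  set.seed(seed)
  h <- config@fieldShape[1]; w <- config@fieldShape[2]
  nuc <- placeNuclei(config)
  n <- nrow(nuc)
  nuc$true_egfp <- stats::rlnorm(n, config@egfpMu, config@egfpSigma)
  nuc$true_tom <- stats::rlnorm(n, config@basalTomMu, config@basalTomSigma)
  nuc$induced_flag <- rep(FALSE, n)
  if (induced && n > 0) {
    nuc$induced_flag <- stats::runif(n) < config@responderFraction
    nuc$true_tom[nuc$induced_flag] <-
      nuc$true_tom[nuc$induced_flag] * config@inductionFold
  }
  egfp <- matrix(config@backgroundLevel, h, w)
  tom <- matrix(config@backgroundLevel, h, w)
  mask <- matrix(0L, h, w)
  depth <- matrix(-Inf, h, w)
  for (i in seq_len(n)) {
    r <- nuc$radius[i]
    rr <- max(1L, floor(nuc$row[i] - r)):min(h, ceiling(nuc$row[i] + r))
    cc <- max(1L, floor(nuc$col[i] - r)):min(w, ceiling(nuc$col[i] + r))
    d <- sqrt(outer((rr - nuc$row[i])^2, (cc - nuc$col[i])^2, "+"))
    inside <- d <= r
    dep <- r - d
    sub <- depth[rr, cc]
    take <- inside & dep > sub
    depth[rr, cc][take] <- dep[take]
    mask[rr, cc][take] <- i
    eg <- egfp[rr, cc]; to <- tom[rr, cc]
    eg[take] <- config@backgroundLevel + nuc$true_egfp[i]
    to[take] <- config@backgroundLevel + nuc$true_tom[i]
    egfp[rr, cc] <- eg; tom[rr, cc] <- to
  }
  egfp <- gaussianBlur(egfp, config@blurSigma)
  tom <- gaussianBlur(tom, config@blurSigma)
  if (config@noiseSD > 0) {
    egfp <- egfp + matrix(stats::rnorm(h * w, 0, config@noiseSD), h, w)
    tom <- tom + matrix(stats::rnorm(h * w, 0, config@noiseSD), h, w)
  }
  egfp[egfp < 0] <- 0
  tom[tom < 0] <- 0
  new("SimulatedField", egfp = egfp, tomato = tom, labelMask = mask,
      truth = nuc, induced = isTRUE(induced))
}

#' Build an HTS plate layout
#'
#' Convenience constructor for the plate-map table consumed by
#' [simulatePlate()]: `nVehicle` vehicle and `nPositive`
#' stimulated-control wells per plate, plus optional compound wells.
#'
#' @param nPlates number of plates.
#' @param nVehicle,nPositive control wells per plate.
#' @param nCompound compound wells per plate.
#' @param treatmentPositive label for the positive-control stimulus.
#' @return data.frame with columns plate, well, role, treatment,
#'   compound_id, dose, phase.
#' @examples
#' head(htsLayout(nPlates = 2))
#' @export
htsLayout <- function(nPlates = 10, nVehicle = 6, nPositive = 6,
                      nCompound = 0, treatmentPositive = "stimulated") {
  perPlate <- nVehicle + nPositive + nCompound
  if (perPlate > 96) stop("more than 96 wells requested per plate")
  rowsL <- rep(LETTERS[1:8], each = 12)
  colsL <- rep(1:12, times = 8)
  wellNames <- sprintf("%s%02d", rowsL, colsL)
  do.call(rbind, lapply(seq_len(nPlates), function(p) {
    role <- c(rep("vehicle", nVehicle), rep("positive", nPositive),
              rep("compound", nCompound))
    data.frame(
      plate = p,
      well = wellNames[seq_len(perPlate)],
      role = role,
      treatment = ifelse(role == "positive", treatmentPositive, "vehicle"),
      compound_id = ifelse(role == "compound",
                           sprintf("CPD%04d", seq_len(perPlate)), NA_character_),
      dose = NA_real_,
      phase = 1L
    )
  }))
}

roleExpectations <- function(config, roles, stimulated = NULL) {
  known <- c("vehicle", "positive", "compound")
  bad <- setdiff(unique(roles), known)
  if (length(bad))
    stop("unknown well role(s): ", paste(bad, collapse = ", "))
  egfp <- rep(expectedEgfp(config), length(roles))
  tom <- rep(expectedBasalTom(config), length(roles))
  tom[roles == "positive"] <- tom[roles == "positive"] * config@inductionFold
  if (!is.null(stimulated))
    tom[roles == "compound" & stimulated] <-
      tom[roles == "compound" & stimulated] * config@inductionFold
  list(egfp = egfp, tom = tom)
}

## Draw well-level channel values around expectations. Well-to-well
## variation decomposes into a factor shared by both channels (cell
## density, seeding; cancels in the ratio), a detection factor common
## to the well's optics, and a reporter-specific factor carried by the
## Tomato channel only — so the Tomato/EGFP ratio itself has Gaussian
## multiplicative noise, which is what the downstream z-scoring
## statistics assume. All factors are Gaussian with mean 1.
drawWells <- function(config, egfpExp, tomExp,
                      effectEgfp = 1, effectTom = 1) {
  nw <- length(egfpExp)
  sdShared <- config@wellCV * sqrt(config@sharedCVFraction)
  sdChan <- config@wellCV * sqrt(1 - config@sharedCVFraction)
  shared <- 1 + stats::rnorm(nw, 0, sdShared)
  det <- 1 + stats::rnorm(nw, 0, sdChan)
  rep <- 1 + stats::rnorm(nw, 0, sdChan * sqrt(2))
  egfp <- pmax(0, egfpExp * effectEgfp * shared * det)
  tom <- pmax(0, tomExp * effectTom * shared * det * rep)
  list(egfp = egfp, tom = tom)
}

#' Simulate a plate (or set of plates) of reporter wells
#'
#' In `"tabular"` mode each layout well directly receives EGFP/Tomato
#' well means drawn with the configured well-level CV around its
#' role-determined expectation (vehicle = basal, positive = basal times
#' the induction fold) — the fast path for statistics testing. In
#' `"image"` mode each well receives `fieldsPerWell` rendered
#' [SimulatedField-class] objects (vehicle wells uninduced, positive
#' wells induced).
#'
#' @param config a [SimConfig-class].
#' @param layout plate-map data.frame (see [htsLayout()]); roles must be
#'   vehicle, positive or compound.
#' @param mode `"tabular"` or `"image"`.
#' @param seed integer RNG seed.
#' @param fieldsPerWell fields rendered per well in image mode.
#' @return tabular mode: a well table (plate, well, role, treatment,
#'   compound_id, egfp_mean, tom_mean, ratio, n_included, sufficient_n).
#'   Image mode: list with `layout` and `fields` (named list of
#'   [SimulatedField-class] lists, one per well, named "plate_well").
#' @examples
#' wells <- simulatePlate(simConfig(), htsLayout(nPlates = 1), seed = 1)
#' head(wells)
#' @export
simulatePlate <- function(config, layout, mode = c("tabular", "image"),
                          seed = config@seed, fieldsPerWell = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  exps <- roleExpectations(config, layout$role)
  if (mode == "tabular") {
    eTom <- if (is.null(layout$effect_tom)) 1 else layout$effect_tom
    eEgfp <- if (is.null(layout$effect_egfp)) 1 else layout$effect_egfp
    vals <- drawWells(config, exps$egfp, exps$tom, eEgfp, eTom)
    out <- data.frame(
      plate = layout$plate, well = layout$well, role = layout$role,
      treatment = layout$treatment,
      compound_id = if (is.null(layout$compound_id)) NA_character_ else
        layout$compound_id,
      egfp_mean = vals$egfp, tom_mean = vals$tom,
      ratio = vals$tom / vals$egfp,
      n_included = config@nNucleiPerField * fieldsPerWell,
      sufficient_n = TRUE)
    rownames(out) <- NULL
    return(out)
  }
  fields <- vector("list", nrow(layout))
  names(fields) <- sprintf("%s_%s", layout$plate, layout$well)
  for (i in seq_len(nrow(layout))) {
    fields[[i]] <- lapply(seq_len(fieldsPerWell), function(f)
      simulateImageField(config, induced = layout$role[i] == "positive",
                         seed = sample.int(.Machine$integer.max, 1L)))
  }
  list(layout = layout, fields = fields)
}

#' Define the planted truth of a synthetic compound library
#'
#' Assigns each compound one of five true classes (inactive, activator,
#' inhibitor, artifact_egfp_up, artifact_egfp_down) and a multiplicative
#' effect: activators raise basal Tomato (phase 1), inhibitors attenuate
#' stimulated Tomato (phase 2), artifacts perturb EGFP in both phases.
#'
#' @param nCompounds library size (default 1595).
#' @param pActivator,pInhibitor,pArtifactUp,pArtifactDown class
#'   proportions (must sum to at most 1; the remainder is inactive).
#' @param activatorFold,inhibitorFold,artifactFold effect magnitudes
#'   (multiplicative; inhibitors divide stimulated Tomato by
#'   `inhibitorFold`).
#' @param seed RNG seed for the class assignment.
#' @return data.frame (compound_id, class, effect_tom_p1, effect_tom_p2,
#'   effect_egfp).
#' @examples
#' tr <- screenTruth(100, pActivator = 0.05, seed = 3)
#' table(tr$class)
#' @export
screenTruth <- function(nCompounds = 1595, pActivator = 0, pInhibitor = 0,
                        pArtifactUp = 0, pArtifactDown = 0,
                        activatorFold = 2, inhibitorFold = 2,
                        artifactFold = 1.5, seed = 1L) {
  p <- c(pActivator, pInhibitor, pArtifactUp, pArtifactDown)
  if (any(p < 0) || sum(p) > 1)
    stop("class proportions must be non-negative and sum to at most 1")
  if (nCompounds < 1) stop("nCompounds must be >= 1")
  set.seed(seed)
  counts <- round(p * nCompounds)
  classes <- rep(c("activator", "inhibitor", "artifact_egfp_up",
                   "artifact_egfp_down", "inactive"),
                 c(counts, nCompounds - sum(counts)))
  classes <- sample(classes)
  data.frame(
    compound_id = sprintf("CPD%05d", seq_len(nCompounds)),
    class = classes,
    effect_tom_p1 = ifelse(classes == "activator", activatorFold, 1),
    effect_tom_p2 = ifelse(classes == "inhibitor", 1 / inhibitorFold, 1),
    effect_egfp = ifelse(classes == "artifact_egfp_up", artifactFold,
                         ifelse(classes == "artifact_egfp_down",
                                1 / artifactFold, 1)))
}

screenPhaseTable <- function(config, truth, phase, controlVehicle,
                             controlPositive, wellsPerPlate = 80L) {
  n <- nrow(truth)
  nPlates <- ceiling(n / wellsPerPlate)
  plate <- rep(seq_len(nPlates), each = wellsPerPlate)[seq_len(n)]
  stim <- phase == 2L
  tomExp <- expectedBasalTom(config) *
    (if (stim) config@inductionFold else 1) *
    (if (stim) truth$effect_tom_p2 else truth$effect_tom_p1)
  egfpExp <- rep(expectedEgfp(config), n)
  vals <- drawWells(config, egfpExp, tomExp, truth$effect_egfp, 1)
  cmpd <- data.frame(
    plate = plate,
    well = sprintf("W%02d", (seq_len(n) - 1L) %% wellsPerPlate + 1L),
    role = "compound", compound_id = truth$compound_id,
    egfp_mean = vals$egfp, tom_mean = vals$tom,
    ratio = vals$tom / vals$egfp, phase = phase)
  ctrlRole <- rep(c("vehicle", "positive"),
                  c(controlVehicle, controlPositive))
  ctrl <- do.call(rbind, lapply(seq_len(nPlates), function(p) {
    ex <- roleExpectations(config, ctrlRole)
    v <- drawWells(config, ex$egfp, ex$tom)
    data.frame(plate = p,
               well = sprintf("C%02d", seq_along(ctrlRole)),
               role = ctrlRole, compound_id = NA_character_,
               egfp_mean = v$egfp, tom_mean = v$tom,
               ratio = v$tom / v$egfp, phase = phase)
  }))
  out <- rbind(cmpd, ctrl)
  rownames(out) <- NULL
  out
}

#' Simulate a bimodal two-phase compound screen
#'
#' Phase 1 wells are unstimulated (activators raise Tomato above
#' basal); phase 2 re-reads the same wells after pathway stimulation
#' (inhibitors attenuate the induced Tomato). EGFP-artifact compounds
#' perturb the EGFP channel in both phases. Replicate screens share the
#' planted true effects but draw independent well noise. Control wells
#' default to 4 vehicle + 4 stimulated per plate in phase 1 and
#' 4 vehicle + 8 stimulated in phase 2.
#'
#' @param config a [SimConfig-class].
#' @param truth a [screenTruth()] table (or `nCompounds` to build an
#'   all-inactive one).
#' @param nCompounds library size used when `truth` is NULL.
#' @param nReplicates number of replicate screens (default 2).
#' @param seed RNG seed.
#' @param controlsPhase1,controlsPhase2 integer(2), vehicle and
#'   positive control wells per plate for each phase.
#' @return list with `truth` and `replicates`: per replicate a list of
#'   `phase1` and `phase2` well tables.
#' @examples
#' scr <- simulateScreen(simConfig(), nCompounds = 50, seed = 2)
#' head(scr$replicates[[1]]$phase1)
#' @export
simulateScreen <- function(config, truth = NULL, nCompounds = 1595,
                           nReplicates = 2, seed = config@seed,
                           controlsPhase1 = c(4L, 4L),
                           controlsPhase2 = c(4L, 8L)) {
  if (is.null(truth)) truth <- screenTruth(nCompounds, seed = seed)
  if (nrow(truth) < 1) stop("nCompounds must be >= 1")
  set.seed(seed)
  reps <- lapply(seq_len(nReplicates), function(r) {
    list(phase1 = screenPhaseTable(config, truth, 1L,
                                   controlsPhase1[1], controlsPhase1[2]),
         phase2 = screenPhaseTable(config, truth, 2L,
                                   controlsPhase2[1], controlsPhase2[2]))
  })
  list(truth = truth, replicates = reps)
}

inductionCurve <- function(config, t) {
  dt <- pmax(0, t - config@kineticsOnsetH)
  rise <- ifelse(dt > 0, 1 - exp(-config@kineticsRate * dt), 0)
  rise[is.na(rise)] <- 1  # rate = Inf limit: full step past onset
  1 + (config@kineticsPlateau - 1) * rise
}

#' Simulate an induction time course
#'
#' Well-level reporter readings over time: the induced group's expected
#' Tomato/EGFP ratio stays at baseline until the onset time and then
#' rises with first-order kinetics to the plateau fold change; vehicle
#' stays flat. An infinite rate gives a step at the onset.
#'
#' @param config a [SimConfig-class].
#' @param timepointsH strictly ascending timepoints (hours).
#' @param groups character, subset of c("vehicle", "induced").
#' @param nReplicates replicate wells per group and timepoint.
#' @param seed RNG seed.
#' @return data.frame (group, timepoint_h, replicate, egfp_mean,
#'   tom_mean, ratio).
#' @examples
#' ts <- simulateKinetics(simConfig(), timepointsH = seq(0, 38, 2), seed = 1)
#' @export
simulateKinetics <- function(config, timepointsH,
                             groups = c("vehicle", "induced"),
                             nReplicates = 6, seed = config@seed) {
  if (length(timepointsH) == 0) stop("timepointsH must be non-empty")
  if (is.unsorted(timepointsH, strictly = TRUE))
    stop("timepointsH must be strictly ascending")
  groups <- match.arg(groups, several.ok = TRUE)
  set.seed(seed)
  grid <- expand.grid(group = groups, timepoint_h = timepointsH,
                      replicate = seq_len(nReplicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fold <- ifelse(grid$group == "induced",
                 inductionCurve(config, grid$timepoint_h), 1)
  vals <- drawWells(config, rep(expectedEgfp(config), nrow(grid)),
                    expectedBasalTom(config) * fold)
  grid$egfp_mean <- vals$egfp
  grid$tom_mean <- vals$tom
  grid$ratio <- vals$tom / vals$egfp
  grid[order(grid$group, grid$timepoint_h, grid$replicate), ]
}

## Four-parameter log-logistic response.
fourPL <- function(x, floor, ceiling, hill, ec50)
  floor + (ceiling - floor) / (1 + (ec50 / x)^hill)

#' Simulate a dose-response table
#'
#' Responses follow a four-parameter logistic with floor 0 and ceiling
#' 1 at the configured true EC50 and Hill slope, times multiplicative
#' Gaussian noise of CV `drNoiseCV`.
#'
#' @param config a [SimConfig-class].
#' @param doses positive molar concentrations.
#' @param nReps replicate wells per dose (default 8).
#' @param seed RNG seed.
#' @return data.frame (dose_molar, replicate, response, experiment).
#' @examples
#' dr <- simulateDoseResponse(simConfig(),
#'                            doses = 10^seq(-11, -7, length.out = 9))
#' nrow(dr)
#' @export
simulateDoseResponse <- function(config, doses, nReps = 8,
                                 seed = config@seed) {
  if (any(doses <= 0)) stop("doses must be > 0")
  set.seed(seed)
  grid <- expand.grid(dose_molar = doses, replicate = seq_len(nReps),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- fourPL(grid$dose_molar, 0, 1, config@hillTrue, config@ec50True)
  grid$response <- mu * (1 + stats::rnorm(nrow(grid), 0, config@drNoiseCV))
  grid$experiment <- 1L
  grid
}

#' Simulate flow-cytometry events
#'
#' Per-event EGFP and Tomato intensities for one sample. Control-like
#' samples (`responderFraction = 0`) are lognormal in both channels; a
#' responding sample is a two-component mixture in which a
#' `responderFraction` of events has Tomato shifted by the induction
#' fold.
#'
#' @param config a [SimConfig-class].
#' @param nEvents number of events (default 10000, the conventional
#'   minimum analysed per sample).
#' @param responderFraction overrides `config@responderFraction`.
#' @param seed RNG seed.
#' @return data.frame (gfp, tomato, responder).
#' @examples
#' ev <- simulateFlowEvents(simConfig(), nEvents = 1000,
#'                          responderFraction = 0.5, seed = 1)
#' mean(ev$responder)
#' @export
simulateFlowEvents <- function(config, nEvents = 10000,
                               responderFraction = config@responderFraction,
                               seed = config@seed) {
  if (nEvents < 1) stop("nEvents must be >= 1")
  set.seed(seed)
  resp <- stats::runif(nEvents) < responderFraction
  tom <- stats::rlnorm(nEvents, config@basalTomMu, config@basalTomSigma)
  tom[resp] <- tom[resp] * config@inductionFold
  data.frame(
    gfp = stats::rlnorm(nEvents, config@egfpMu, config@egfpSigma),
    tomato = tom,
    responder = resp)
}
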