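#' @include AllClasses.R synthetic-data.R image-quant.R plate-stats.R
#' @include hit-calling.R dose-response.R flow-gating.R chelation.R io.R
NULL

#' Default run configuration
#'
#' The resolved configuration consumed by [runPipeline()]: a nested
#' list with one block per stage plus a `sim` block of
#' [simConfig()] overrides. Desk-scale defaults (small plates, few
#' nuclei, reduced minimum-nucleus rule) so a full `all` run finishes
#' in seconds; production settings are reached by overriding fields
#' from a YAML file or the `overrides` argument.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    sim = list(nNucleiPerField = 30L, fieldShape = c(160L, 160L)),
    simulate = list(nPlates = 2L, nVehicle = 3L, nPositive = 3L,
                    mode = "image", fieldsPerWell = 1L),
    quantify = list(minNuclei = 10, minArea = 50, maxArea = 2500,
                    solidityMin = 0.85, clusterAreaFactor = 1.6,
                    ratioMethod = "ratio-of-means"),
    screen = list(nCompounds = 200L, nReplicates = 2L,
                  pActivator = 0.02, pInhibitor = 0.02,
                  pArtifactUp = 0.01, pArtifactDown = 0.01,
                  activatorFold = 1.5, inhibitorFold = 1.5,
                  zCut = 2, egfpCut = 2),
    dose = list(dosesMolar = 10^seq(log10(1e-11), log10(1e-7),
                                    length.out = 9),
                nReps = 8L, input = NULL),
    flow = list(nEvents = 5000L, responderFraction = 0.56,
                topFraction = 0.01, input = NULL),
    chelation = list(input = NULL)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

validateRunConfig <- function(config) {
  checkNum <- function(x, field, min = 0, strict = TRUE) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) ||
        (strict && any(x <= min)) || (!strict && any(x < min)))
      stop("invalid config field '", field, "': must be numeric",
           if (strict) paste0(" > ", min) else paste0(" >= ", min))
  }
  checkNum(config$screen$zCut, "screen.zCut")
  checkNum(config$screen$egfpCut, "screen.egfpCut")
  checkNum(config$quantify$minNuclei, "quantify.minNuclei", strict = FALSE)
  checkNum(config$simulate$nPlates, "simulate.nPlates")
  checkNum(config$flow$topFraction, "flow.topFraction")
  if (config$flow$topFraction >= 1)
    stop("invalid config field 'flow.topFraction': must be < 1")
  checkNum(config$dose$dosesMolar, "dose.dosesMolar")
  invisible(config)
}

#' Run the analysis pipeline end to end or stage by stage
#'
#' Thin orchestration over the package's stage functions. Each run
#' resolves its configuration (defaults, then an optional YAML file,
#' then in-memory overrides), validates it, serialises it verbatim to
#' `resolved_config.yaml` in the output directory, executes the
#' requested stage(s), writes the stage CSV outputs and appends to
#' `run_log.txt`. Reruns from a resolved config and the same seed are
#' bit-reproducible for the deterministic stages.
#'
#' @param subcommand one of "simulate", "quantify", "plate-stats",
#'   "screen", "dose", "flow", "chelation", "all".
#' @param outdir output directory (created if needed).
#' @param configFile optional YAML configuration file.
#' @param overrides optional nested list overriding config fields.
#' @param seed integer seed; overrides the config seed.
#' @param verbose print log lines to the console.
#' @return invisibly, the resolved config (with the output paths
#'   written attached as attribute `outputs`).
#' @examples
#' out <- file.path(tempdir(), "run1")
#' runPipeline("plate-stats", out, seed = 7)
#' list.files(out)
#' @export
runPipeline <- function(subcommand, outdir,
                        configFile = NULL, overrides = list(),
                        seed = NULL, verbose = FALSE) {
  stages <- c("simulate", "quantify", "plate-stats", "screen", "dose",
              "flow", "chelation", "all")
  subcommand <- match.arg(subcommand, stages)
  config <- defaultRunConfig()
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) stop("config file not found: ", configFile)
    config <- mergeConfig(config, yaml::read_yaml(configFile))
  }
  config <- mergeConfig(config, overrides)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validateRunConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outdir, "resolved_config.yaml"))
  logPath <- file.path(outdir, "run_log.txt")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = logPath, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  logLine("run: ", subcommand, " (seed ", config$seed, ")")
  cfg <- do.call(simConfig, c(list(seed = config$seed), config$sim))
  outputs <- character()
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    utils::write.csv(x, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    logLine("wrote ", name, " (", nrow(x), " rows)")
    p
  }

  doSimulate <- function() {
    sc <- config$simulate
    layout <- htsLayout(sc$nPlates, sc$nVehicle, sc$nPositive)
    writePlateMap(layout, file.path(outdir, "plate_map.csv"))
    outputs <<- c(outputs, file.path(outdir, "plate_map.csv"))
    if (identical(sc$mode, "tabular")) {
      wells <- simulatePlate(cfg, layout, "tabular", seed = config$seed)
      emit(wells, "wells_sim.csv")
    } else {
      sim <- simulatePlate(cfg, layout, "image", seed = config$seed,
                           fieldsPerWell = sc$fieldsPerWell)
      fdir <- file.path(outdir, "fields")
      dir.create(fdir, showWarnings = FALSE)
      for (wellName in names(sim$fields)) {
        flds <- sim$fields[[wellName]]
        for (f in seq_along(flds))
          writeFieldTIFF(flds[[f]],
                         file.path(fdir, sprintf("%s_f%d", wellName, f)))
      }
      logLine("wrote image fields for ", length(sim$fields), " wells")
    }
  }

  doQuantify <- function() {
    qc <- config$quantify
    layout <- readPlateMap(file.path(outdir, "plate_map.csv"))
    fdir <- file.path(outdir, "fields")
    params <- segmentationParams(qc$minArea, qc$maxArea, qc$solidityMin,
                                 qc$clusterAreaFactor, qc$minNuclei)
    nucAll <- list(); wellAll <- list()
    for (i in seq_len(nrow(layout))) {
      prefixes <- Sys.glob(file.path(
        fdir, sprintf("%s_%s_f*_egfp.tif", layout$plate[i], layout$well[i])))
      if (!length(prefixes))
        stop("no image fields found for plate ", layout$plate[i],
             " well ", layout$well[i])
      segs <- lapply(sub("_egfp\\.tif$", "", prefixes), function(p)
        segmentNuclei(readFieldTIFF(p), params))
      nuc <- do.call(rbind, lapply(segs, `[[`, "nuclei"))
      nuc$plate <- layout$plate[i]; nuc$well <- layout$well[i]
      nucAll[[i]] <- nuc
      wellAll[[i]] <- quantifyWell(segs, qc$minNuclei,
                                   plate = layout$plate[i],
                                   well = layout$well[i],
                                   ratioMethod = qc$ratioMethod)
      wellAll[[i]]$role <- layout$role[i]
      wellAll[[i]]$treatment <- layout$treatment[i]
    }
    emit(do.call(rbind, nucAll), "nuclei.csv")
    emit(do.call(rbind, wellAll), "wells.csv")
  }

  doPlateStats <- function() {
    wellsPath <- file.path(outdir, "wells.csv")
    if (!file.exists(wellsPath)) {
      # fall back to the tabular fast path so plate-stats is
      # self-contained on synthetic data
      layout <- htsLayout(config$simulate$nPlates, config$simulate$nVehicle,
                          config$simulate$nPositive)
      wells <- simulatePlate(cfg, layout, "tabular", seed = config$seed)
      emit(wells, "wells_sim.csv")
    } else {
      wells <- readWellTable(wellsPath)
    }
    qc <- plateQC(wells)
    emit(qc, "plate_qc.csv")
    rs <- robustnessSummary(qc)
    emit(data.frame(metric = c("mean_zprime", "min_zprime",
                               "mean_fold_change"),
                    value = c(rs$meanZprime, rs$minZprime,
                              rs$meanFoldChange)),
         "robustness.csv")
  }

  doScreen <- function() {
    sc <- config$screen
    truth <- screenTruth(sc$nCompounds, sc$pActivator, sc$pInhibitor,
                         sc$pArtifactUp, sc$pArtifactDown,
                         sc$activatorFold, sc$inhibitorFold,
                         seed = config$seed)
    scr <- simulateScreen(cfg, truth, nReplicates = sc$nReplicates,
                          seed = config$seed + 101L)
    results <- lapply(scr$replicates, function(rp)
      runBimodalScreen(rp$phase1, rp$phase2, sc$zCut, sc$egfpCut))
    calls <- do.call(rbind, lapply(seq_along(results), function(r)
      cbind(replicate = r, hitCalls(results[[r]]))))
    calls <- merge(calls, truth[c("compound_id", "class")],
                   by = "compound_id", suffixes = c("", "_true"))
    emit(calls, "screen_calls.csv")
    z1 <- hitCalls(results[[1]])
    zwide <- z1[c("compound_id", "phase", "z_ratio", "z_egfp")]
    if (length(results) > 1) {
      z2 <- hitCalls(results[[2]])
      zwide$z_ratio_rep2 <- z2$z_ratio[match(
        paste(zwide$compound_id, zwide$phase),
        paste(z2$compound_id, z2$phase))]
    }
    emit(zwide, "zscores.csv")
    summ <- do.call(rbind, lapply(seq_along(results), function(r)
      data.frame(replicate = r,
                 class = names(hits(results[[r]])),
                 n_hits = lengths(hits(results[[r]])),
                 hit_rate_pct = unname(hitRate(results[[r]])))))
    if (length(results) > 1) {
      conf <- intersectReplicates(results[[1]], results[[2]])
      summ <- rbind(summ, data.frame(
        replicate = 0, class = paste0("confirmed_", names(conf$confirmed)),
        n_hits = lengths(conf$confirmed),
        hit_rate_pct = unname(conf$hitRate)))
      for (ph in 1:2) {
        i1 <- hitCalls(results[[1]])$phase == ph
        pc <- replicateCorrelation(hitCalls(results[[1]])$z_ratio[i1],
                                   hitCalls(results[[2]])$z_ratio[i1])
        summ <- rbind(summ, data.frame(
          replicate = 0, class = sprintf("pearson_r_phase%d", ph),
          n_hits = pc$n, hit_rate_pct = pc$r))
      }
    }
    emit(summ, "screen_summary.csv")
  }

  doDose <- function() {
    dc <- config$dose
    dr <- if (!is.null(dc$input)) {
      utils::read.csv(dc$input, stringsAsFactors = FALSE)
    } else {
      simulateDoseResponse(cfg, dc$dosesMolar, dc$nReps,
                           seed = config$seed + 202L)
    }
    fit <- fit4PL(dr$dose_molar, dr$response)
    emit(data.frame(floor = fit@floor, ceiling = fit@ceiling,
                    hill = fit@hill, ec50_molar = fit@ec50,
                    rss = fit@rss, converged = fit@converged,
                    n_points = fit@nPoints),
         "fit.csv")
    curveDoses <- 10^seq(log10(min(dr$dose_molar)),
                         log10(max(dr$dose_molar)), length.out = 100)
    emit(data.frame(dose_molar = curveDoses,
                    response = predict(fit, curveDoses)),
         "fit_curve.csv")
  }

  doFlow <- function() {
    fc <- config$flow
    if (!is.null(fc$input)) {
      ev <- utils::read.csv(fc$input, stringsAsFactors = FALSE)
      ctl <- ev[ev$sample_id == "control", ]
      trt <- ev[ev$sample_id == "treated", ]
    } else {
      ctl <- simulateFlowEvents(cfg, fc$nEvents, responderFraction = 0,
                                seed = config$seed + 303L)
      trt <- simulateFlowEvents(cfg, fc$nEvents,
                                responderFraction = fc$responderFraction,
                                seed = config$seed + 304L)
    }
    gate <- gateSummary(ctl, trt, topFraction = fc$topFraction)
    emit(data.frame(threshold = gate@threshold,
                    pct_positive = gate@pctPositive,
                    mfi_control = gate@mfiControl,
                    mfi_treated = gate@mfiTreated,
                    fold_mfi = gate@foldMFI,
                    n_control = gate@nControl, n_treated = gate@nTreated),
         "gates.csv")
    hc <- modeNormalisedHistogram(ctl)
    ht <- modeNormalisedHistogram(trt)
    emit(rbind(cbind(sample = "control", hc), cbind(sample = "treated", ht)),
         "flow_histograms.csv")
  }

  doChelation <- function() {
    cc <- config$chelation
    if (!is.null(cc$input)) {
      ab <- utils::read.csv(cc$input, stringsAsFactors = FALSE)
    } else {
      # synthetic absorbance series: linear activity in log10(conc)
      conc <- c(1e-5, 1e-4, 1e-3)
      aCtl <- 1.0
      act <- pmin(95, pmax(5, 25 * (log10(conc) + 6)))
      ab <- data.frame(compound = "synthetic", concentration_molar = conc,
                       a562 = aCtl * (1 - act / 100), is_control = FALSE)
      ab <- rbind(ab, data.frame(compound = "control",
                                 concentration_molar = NA, a562 = aCtl,
                                 is_control = TRUE))
    }
    aCtl <- mean(ab$a562[ab$is_control])
    cmp <- ab[!ab$is_control, ]
    act <- chelationActivity(aCtl, cmp$a562)
    res <- chelationCurve(cmp$concentration_molar, as.numeric(act))
    emit(data.frame(compound = cmp$compound,
                    concentration_molar = cmp$concentration_molar,
                    activity_pct = as.numeric(act),
                    slope = res@slope, intercept = res@intercept,
                    conc_at_50 = res@concAt50),
         "chelation.csv")
  }

  runStage <- function(st) switch(st,
    "simulate" = doSimulate(), "quantify" = doQuantify(),
    "plate-stats" = doPlateStats(), "screen" = doScreen(),
    "dose" = doDose(), "flow" = doFlow(), "chelation" = doChelation())
  if (subcommand == "all") {
    for (st in c("simulate", "quantify", "plate-stats", "screen", "dose",
                 "flow", "chelation")) {
      if (st == "quantify" && identical(config$simulate$mode, "tabular"))
        next
      runStage(st)
    }
  } else {
    runStage(subcommand)
  }
  logLine("done: ", subcommand)
  attr(config, "outputs") <- outputs
  invisible(config)
}
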