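test_that("simConfig validates scales and fractions", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(inductionFold = -1), "> 0")
  expect_error(simConfig(ec50True = 0), "> 0")
  expect_error(simConfig(responderFraction = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(wellCV = -0.1), ">= 0")
})

test_that("image fields plant the requested nuclei with exact truth bookkeeping", {
  cfg <- exactFieldConfig(nNucleiPerField = 5L)
  fld <- simulateImageField(cfg, induced = FALSE, seed = 3)
  truth <- groundTruth(fld)
  expect_equal(nrow(truth), 5)
  # labels contiguous and in bijection with truth rows
  expect_equal(sort(unique(as.vector(labelMask(fld)[labelMask(fld) > 0]))),
               1:5)
  # per-nucleus channel means over the planted mask equal truth exactly
  # (noise-free hard disks over uniform background)
  for (k in 1:5) {
    pix <- labelMask(fld) == k
    expect_equal(mean(egfpChannel(fld)[pix]) - 40, truth$true_egfp[k],
                 tolerance = 1e-10)
    expect_equal(mean(tomatoChannel(fld)[pix]) - 40, truth$true_tom[k],
                 tolerance = 1e-10)
  }
})

test_that("empty fields and determinism contracts hold", {
  cfg <- exactFieldConfig(nNucleiPerField = 0L)
  fld <- simulateImageField(cfg, seed = 1)
  expect_equal(nrow(groundTruth(fld)), 0)
  expect_true(all(labelMask(fld) == 0))
  expect_true(all(egfpChannel(fld) == 40))

  cfg2 <- simConfig(nNucleiPerField = 15L)
  a <- simulateImageField(cfg2, induced = TRUE, seed = 11)
  b <- simulateImageField(cfg2, induced = TRUE, seed = 11)
  expect_identical(egfpChannel(a), egfpChannel(b))
  expect_identical(tomatoChannel(a), tomatoChannel(b))
  expect_identical(groundTruth(a), groundTruth(b))
})

test_that("overcrowded fields fail with an explicit density error", {
  cfg <- simConfig(fieldShape = c(48L, 48L), nNucleiPerField = 60L)
  expect_error(simulateImageField(cfg, seed = 1), "too dense")
})

test_that("induction multiplies responder Tomato truth by the configured fold", {
  cfg <- exactFieldConfig(nNucleiPerField = 10L, responderFraction = 1)
  ind <- simulateImageField(cfg, induced = TRUE, seed = 8)
  un <- simulateImageField(cfg, induced = FALSE, seed = 8)
  expect_true(all(groundTruth(ind)$induced_flag))
  expect_equal(groundTruth(ind)$true_tom, groundTruth(un)$true_tom * 10)
})

test_that("per-nucleus EGFP calibration matches the configured lognormal moments", {
  cfg <- simConfig(nNucleiPerField = 60L, fieldShape = c(256L, 256L))
  vals <- unlist(lapply(1:20, function(s)
    groundTruth(simulateImageField(cfg, seed = s))$true_egfp))
  expect_gte(length(vals), 1000)
  n <- length(vals)
  targetMean <- exp(log(500) + 0.25^2 / 2)
  targetSD <- targetMean * sqrt(exp(0.25^2) - 1)
  expect_lt(abs(mean(vals) - targetMean), 3 * stats::sd(vals) / sqrt(n))
  expect_lt(abs(stats::sd(vals) - targetSD), 3 * targetSD / sqrt(2 * n))
})

test_that("tabular plates reproduce the configured induction fold", {
  cfg <- simConfig()
  wells <- simulatePlate(cfg, htsLayout(nPlates = 10), seed = 21)
  fc <- mean(wells$ratio[wells$role == "positive"]) /
    mean(wells$ratio[wells$role == "vehicle"])
  expect_equal(fc, 10, tolerance = 0.05)
  # zero-variance limit: every vehicle well identical
  cfg0 <- simConfig(wellCV = 0)
  w0 <- simulatePlate(cfg0, htsLayout(nPlates = 2), seed = 1)
  expect_equal(length(unique(w0$ratio[w0$role == "vehicle"])), 1)
  expect_error(
    simulatePlate(cfg, data.frame(plate = 1, well = "A01", role = "mystery",
                                  treatment = "x"), seed = 1),
    "unknown well role")
})

test_that("screen truth proportions are validated and counted", {
  tr <- screenTruth(200, pActivator = 0.1, pInhibitor = 0.05, seed = 4)
  expect_equal(nrow(tr), 200)
  expect_equal(sum(tr$class == "activator"), 20)
  expect_equal(sum(tr$class == "inhibitor"), 10)
  expect_error(screenTruth(100, pActivator = 0.7, pInhibitor = 0.5), "sum")
  expect_error(screenTruth(0), ">= 1")
})

test_that("replicate screens share truth but draw independent noise", {
  cfg <- simConfig()
  scr <- simulateScreen(cfg, nCompounds = 50, nReplicates = 2, seed = 7)
  p1a <- scr$replicates[[1]]$phase1
  p1b <- scr$replicates[[2]]$phase1
  expect_identical(p1a$compound_id, p1b$compound_id)
  expect_false(any(p1a$ratio == p1b$ratio))
  # determinism of the whole object
  scr2 <- simulateScreen(cfg, nCompounds = 50, nReplicates = 2, seed = 7)
  expect_identical(scr, scr2)
})

test_that("kinetics follow the configured onset, plateau and step limit", {
  cfg <- simConfig(wellCV = 0)
  ts <- simulateKinetics(cfg, seq(0, 38, 2), seed = 1)
  ind <- ts[ts$group == "induced", ]
  veh <- ts[ts$group == "vehicle", ]
  r0 <- veh$ratio[1]
  # flat at baseline before onset
  expect_equal(ind$ratio[ind$timepoint_h <= 10], veh$ratio[veh$timepoint_h <= 10])
  # near plateau at 38 h (1 - exp(-0.5 * 28) ~ 1)
  expect_equal(max(ind$ratio) / r0, 10, tolerance = 1e-5)
  # infinite rate: step at onset
  cfgStep <- simConfig(wellCV = 0, kineticsRate = Inf)
  tsS <- simulateKinetics(cfgStep, c(8, 10, 12), seed = 1)
  indS <- tsS[tsS$group == "induced", ]
  expect_equal(unique(indS$ratio[indS$timepoint_h <= 10]) / r0, 1)
  expect_equal(unique(indS$ratio[indS$timepoint_h > 10]) / r0, 10)
  expect_error(simulateKinetics(cfg, numeric(0)), "non-empty")
  expect_error(simulateKinetics(cfg, c(4, 2)), "ascending")
})

test_that("dose-response tables follow the 4PL with configured truth", {
  cfg <- simConfig(drNoiseCV = 0)
  dr <- simulateDoseResponse(cfg, doses = cfg@ec50True, nReps = 3, seed = 1)
  expect_equal(dr$response, rep(0.5, 3))  # half-maximal at the true EC50
  tiny <- simulateDoseResponse(cfg, doses = 1e-18, nReps = 1, seed = 1)
  expect_lt(tiny$response, 1e-6)  # floor as dose -> 0
  dr9 <- simulateDoseResponse(simConfig(),
                              doses = 10^seq(-11, -7, length.out = 9))
  expect_equal(nrow(dr9), 72)
  expect_error(simulateDoseResponse(cfg, doses = c(1e-9, -1)), "> 0")
})

test_that("flow events honour the responder mixture and the default count", {
  cfg <- simConfig()
  expect_equal(formals(simulateFlowEvents)$nEvents, 10000)
  ctl <- simulateFlowEvents(cfg, 10000, responderFraction = 0, seed = 1)
  trt0 <- simulateFlowEvents(cfg, 10000, responderFraction = 0, seed = 2)
  expect_gt(stats::ks.test(ctl$tomato, trt0$tomato)$p.value, 0.01)
  full <- simulateFlowEvents(cfg, 10000, responderFraction = 1, seed = 3)
  expect_equal(stats::median(full$tomato) / stats::median(ctl$tomato), 10,
               tolerance = 0.05)
  expect_error(simulateFlowEvents(cfg, 0), ">= 1")
})
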