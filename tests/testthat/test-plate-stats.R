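test_that("zprime evaluates the separation-window formula", {
  # mu+ = 10, sd+ = 1, mu- = 1, sd- = 0.3: 1 - (3 + 0.9) / 9 = 0.56667
  pos <- twoPoint(10, 1)
  neg <- twoPoint(1, 0.3)
  expect_equal(zprime(pos, neg), 1 - 3.9 / 9, tolerance = 1e-10)
  # zero-variance limit
  expect_equal(zprime(c(10, 10), c(1, 1)), 1)
  expect_error(zprime(c(5, 5), c(5, 5)), "zero separation")
  expect_error(zprime(10, c(1, 2)), "at least 2")
})

test_that("zprime is scale/shift invariant and decreasing in control SDs", {
  pos <- c(9.1, 10.2, 10.7, 9.9)
  neg <- c(0.8, 1.1, 1.0, 1.2)
  z0 <- zprime(pos, neg)
  expect_equal(zprime(pos * 3.2, neg * 3.2), z0)
  expect_equal(zprime(pos + 5, neg + 5), z0)
  expect_lte(z0, 1)
  # widen the positive spread around its mean: Z' must drop
  wide <- mean(pos) + (pos - mean(pos)) * 2
  expect_lt(zprime(wide, neg), z0)
  wideN <- mean(neg) + (neg - mean(neg)) * 2
  expect_lt(zprime(pos, wideN), z0)
})

test_that("fold change is the ratio of control means", {
  expect_equal(foldChange(c(9, 11), c(0.9, 1.1)), 10)
  expect_equal(foldChange(c(2, 4), c(2, 4)), 1)
  expect_equal(foldChange(c(9, 11) * 7, c(0.9, 1.1) * 7), 10)
  expect_error(foldChange(c(1, 2), c(-1, 0)), "> 0")
})

test_that("plate QC summarises controls per plate and validates layout", {
  cfg <- simConfig(wellCV = 0)
  wells <- simulatePlate(cfg, htsLayout(nPlates = 3), seed = 1)
  qc <- plateQC(wells)
  expect_equal(nrow(qc), 3)
  expect_equal(qc$zprime, rep(1, 3))
  expect_equal(qc$fold_change, rep(10, 3))
  rs <- robustnessSummary(qc)
  expect_equal(rs$minZprime, 1)
  expect_equal(rs$meanFoldChange, 10)
  # Tomato-only reporter mode
  qcT <- plateQC(wells, value = "tomato")
  expect_equal(qcT$fold_change, rep(10, 3))
  # one control well only -> error naming the plate
  bad <- wells[!(wells$role == "vehicle" & duplicated(wells$plate)), ]
  expect_error(plateQC(bad[bad$plate == 1, ]), "plate 1")
  # insufficient wells are dropped with a warning
  wells$sufficient_n[1] <- FALSE
  expect_warning(plateQC(wells), "insufficient")
})

test_that("simulated default plates clear the excellent-assay window", {
  cfg <- simConfig()
  qc <- plateQC(simulatePlate(cfg, htsLayout(nPlates = 10), seed = 42))
  expect_gt(min(qc$zprime), 0.5)
  expect_equal(mean(qc$fold_change), 10, tolerance = 0.1)
})

test_that("kinetics summaries recover onset within one sampling interval", {
  cfg <- simConfig()
  ts <- simulateKinetics(cfg, seq(0, 38, 2), nReplicates = 6, seed = 5)
  ks <- kineticsSummary(ts)
  expect_true(all(ks$series$sem >= 0))
  expect_lte(abs(ks$onsetH - 10), 2)
  # vehicle-only input: onset undefined
  veh <- ts[ts$group == "vehicle", ]
  expect_true(is.na(kineticsSummary(veh, groups = "vehicle")$onsetH))
  # constant separation from t = 0: onset at the first timepoint
  cfg0 <- simConfig(kineticsOnsetH = 0, kineticsRate = Inf)
  tsS <- simulateKinetics(cfg0, c(0.1, 2, 4), seed = 2)
  expect_equal(kineticsSummary(tsS)$onsetH, 0.1)
  expect_error(kineticsSummary(ts, groups = "absent"), "absent")
})
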