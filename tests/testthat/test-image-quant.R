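test_that("isodata threshold reaches the intermeans fixed point", {
  # half at 10, half at 110: T = (10 + 110) / 2 = 60 is the fixed point
  expect_equal(isodataThreshold(c(rep(10, 50), rep(110, 50))), 60)
  expect_equal(isodataThreshold(c(0, 100)), 50)
  expect_error(isodataThreshold(rep(7, 10)), "degenerate histogram")
})

test_that("noise-free planted nuclei are recovered with exact counts and MFIs", {
  cfg <- exactFieldConfig(nNucleiPerField = 5L)
  fld <- simulateImageField(cfg, seed = 3)
  seg <- segmentNuclei(fld)
  expect_equal(nrow(seg$nuclei), 5)
  expect_true(all(seg$nuclei$qc_status == "included"))
  truth <- groundTruth(fld)
  idx <- matchToTruth(seg$nuclei, truth)
  expect_lt(max(abs(seg$nuclei$egfp_mfi - truth$true_egfp[idx]) /
                truth$true_egfp[idx]), 0.02)
  expect_lt(max(abs(seg$nuclei$tom_mfi - truth$true_tom[idx]) /
                truth$true_tom[idx]), 0.02)
})

test_that("border, cluster and abnormal exclusions match planted flags", {
  cfg <- exactFieldConfig(nNucleiPerField = 20L, borderFraction = 0.1,
                          clusterFraction = 0.1)
  for (s in 1:5) {
    fld <- simulateImageField(cfg, seed = s)
    seg <- segmentNuclei(fld)
    tab <- table(factor(seg$nuclei$qc_status,
                        levels = c("included", "excluded_border",
                                   "excluded_abnormal",
                                   "excluded_unseparated")))
    # 20 planted = 14 normal + 2 border + 2 clusters merged onto 2
    # partners => 18 components: 14 included, 2 border, 2 unseparated
    expect_equal(as.integer(tab), c(14L, 2L, 0L, 2L))
    # the border components really touch the edge; the unseparated ones
    # are the planted overlapping pairs (~1.9x area)
    truth <- groundTruth(fld)
    idx <- matchToTruth(seg$nuclei, truth)
    expect_true(all(truth$border_flag[
      idx[seg$nuclei$qc_status == "excluded_border"]]))
  }
  cfgA <- exactFieldConfig(nNucleiPerField = 10L, abnormalFraction = 0.1,
                           fieldShape = c(256L, 256L))
  segA <- segmentNuclei(simulateImageField(cfgA, seed = 2))
  expect_equal(sum(segA$nuclei$qc_status == "excluded_abnormal"), 1)
  expect_equal(sum(segA$nuclei$qc_status == "included"), 9)
})

test_that("every component receives exactly one QC status", {
  cfg <- simConfig(nNucleiPerField = 25L, borderFraction = 0.1,
                   clusterFraction = 0.1)
  seg <- segmentNuclei(simulateImageField(cfg, seed = 13))
  expect_equal(nrow(seg$nuclei), max(seg$labelMap))
  expect_true(all(seg$nuclei$qc_status %in%
                  c("included", "excluded_border", "excluded_abnormal",
                    "excluded_unseparated")))
  expect_equal(sum(seg$nuclei$qc_status == "included") +
               sum(seg$nuclei$qc_status != "included"),
               nrow(seg$nuclei))
})

test_that("the well ratio is invariant to a common intensity scaling", {
  cfg <- exactFieldConfig(nNucleiPerField = 8L)
  fld <- simulateImageField(cfg, seed = 5)
  w1 <- quantifyWell(segmentNuclei(fld), minNuclei = 5)
  scaled <- list(egfp = egfpChannel(fld) * 3.7,
                 tomato = tomatoChannel(fld) * 3.7)
  w2 <- quantifyWell(segmentNuclei(scaled), minNuclei = 5)
  expect_equal(w2$ratio, w1$ratio, tolerance = 1e-8)
  expect_equal(w2$n_included, w1$n_included)
})

test_that("segmentation handles missing channels and empty foreground", {
  expect_error(segmentNuclei(list(tomato = matrix(1, 4, 4))), "EGFP")
  expect_error(segmentNuclei(list(egfp = matrix(1, 4, 4))), "Tomato")
  # two-level image whose upper class sits below any nucleus: threshold
  # splits it but components of 1-2 px are sub-minArea, not errors
  m <- matrix(10, 32, 32); m[16, 16] <- 40
  seg <- segmentNuclei(list(egfp = m, tomato = m))
  expect_true(all(seg$nuclei$qc_status == "excluded_abnormal"))
})

test_that("wells pool included nuclei across fields and apply the n rule", {
  cfg <- exactFieldConfig(nNucleiPerField = 3L)
  segs <- lapply(1:2, function(s)
    segmentNuclei(simulateImageField(cfg, seed = s)))
  w <- quantifyWell(segs, minNuclei = 5)
  expect_equal(w$n_included, 6)
  expect_true(w$sufficient_n)
  wBig <- quantifyWell(segs, minNuclei = 2000)
  expect_false(wBig$sufficient_n)
  # default honours the 2000-nucleus convention
  expect_equal(formals(quantifyWell)$minNuclei, 2000)
  # all-excluded wells are flagged, not errors
  emptySeg <- list(nuclei = segs[[1]]$nuclei[0, ])
  w0 <- quantifyWell(list(emptySeg), minNuclei = 5)
  expect_equal(w0$n_included, 0)
  expect_true(is.na(w0$ratio))
  expect_false(w0$sufficient_n)
})
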