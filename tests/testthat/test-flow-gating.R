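test_that("the positivity threshold is the control top-fraction quantile", {
  expect_equal(derivePositiveThreshold(1:100),
               unname(stats::quantile(1:100, 0.99)))
  # symmetric data, top fraction 0.5: the median
  x <- c(1:50, 51:100)
  expect_equal(derivePositiveThreshold(x, 0.5),
               unname(stats::median(x)))
  expect_error(derivePositiveThreshold(1:50), "at least 100")
  expect_error(derivePositiveThreshold(1:100, 0), "topFraction")
})

test_that("control self-gating recovers the nominal top fraction", {
  cfg <- simConfig()
  ctl <- simulateFlowEvents(cfg, 10000, responderFraction = 0, seed = 1)
  thr <- derivePositiveThreshold(ctl$tomato)
  selfPos <- mean(ctl$tomato > thr)
  ci <- stats::qbinom(c(0.005, 0.995), 10000, 0.01) / 10000
  expect_gte(selfPos, ci[1])
  expect_lte(selfPos, ci[2])
})

test_that("gate summaries report percent positive and MFI fold change", {
  cfg <- simConfig()
  ctl <- simulateFlowEvents(cfg, 10000, responderFraction = 0, seed = 1)
  # treated identical to control: ~1% positive, fold exactly 1
  g0 <- gateSummary(ctl, ctl)
  expect_equal(pctPositive(g0), 1, tolerance = 0.5)
  expect_equal(g0@foldMFI, 1)
  # a 56% responder mixture at 10-fold separation gates at ~56%
  trt <- simulateFlowEvents(cfg, 10000, responderFraction = 0.56, seed = 2)
  g <- gateSummary(ctl, trt)
  expect_equal(pctPositive(g), 56, tolerance = 0.045)
  expect_gt(g@foldMFI, 1)
  # full responders: essentially everything above the gate
  full <- simulateFlowEvents(cfg, 10000, responderFraction = 1, seed = 3)
  expect_gt(pctPositive(gateSummary(ctl, full)), 99)
})

test_that("percent positive is monotone in the responder fraction", {
  cfg <- simConfig()
  ctl <- simulateFlowEvents(cfg, 8000, responderFraction = 0, seed = 4)
  pcts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f)
    pctPositive(gateSummary(
      ctl, simulateFlowEvents(cfg, 8000, responderFraction = f, seed = 7))),
    numeric(1))
  expect_true(all(diff(pcts) > 0))
})

test_that("the EGFP pre-gate drops dim events before gating", {
  cfg <- simConfig()
  ctl <- simulateFlowEvents(cfg, 5000, responderFraction = 0, seed = 5)
  trt <- simulateFlowEvents(cfg, 5000, responderFraction = 0.5, seed = 6)
  gate <- stats::median(ctl$gfp)
  g <- gateSummary(ctl, trt, gfpGate = gate)
  expect_lt(g@nControl, 5000)
  expect_error(gateSummary(ctl, trt, gfpGate = max(ctl$gfp) * 10),
               "removed")
})

test_that("mode-normalised histograms peak at exactly 1", {
  set.seed(8)
  h <- modeNormalisedHistogram(rlnorm(5000, 5, 0.4))
  expect_equal(max(h$normalised), 1)
  expect_false(attr(h, "flagged"))
  # single event: one occupied bin of height 1
  h1 <- modeNormalisedHistogram(42)
  expect_equal(sum(h1$count), 1)
  expect_equal(max(h1$normalised), 1)
  # duplicating all events leaves the normalised shape unchanged
  x <- rlnorm(2000, 4, 0.3)
  expect_equal(modeNormalisedHistogram(c(x, x))$normalised,
               modeNormalisedHistogram(x)$normalised)
  # non-positive intensities are floored and flagged
  hf <- modeNormalisedHistogram(c(-1, 0, rlnorm(100)))
  expect_true(attr(hf, "flagged"))
})
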