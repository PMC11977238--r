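test_that("z-scoring centres and scales against the reference population", {
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(zscoreWells(3, ref), 0)
  expect_equal(zscoreWells(mean(ref) + 2 * sd(ref), ref), 2)
  expect_error(zscoreWells(1, c(2, 2)), "at least 3")
  expect_error(zscoreWells(1, c(2, 2, 2)), "zero spread")
  # robust mode shrugs off a gross outlier
  set.seed(1)
  clean <- rnorm(5000)
  dirty <- c(clean, 500)
  zc <- zscoreWells(1.7, clean)
  zr <- zscoreWells(1.7, dirty, robust = TRUE)
  expect_lt(abs(zr - zc) / abs(zc), 0.05)
})

test_that("classification applies thresholds with EGFP exclusion precedence", {
  cases <- data.frame(
    z_ratio = c(2.5, 2.5, 2.0, 1.9, -2.5, -2.0, -2.5, 0),
    z_egfp = c(0.3, 2.5, 0.0, 0.0, 0.0, 0.0, -2.5, 0),
    mode = c("activator", "activator", "activator", "activator",
             "inhibitor", "inhibitor", "inhibitor", "activator"),
    expect = c("activator", "excluded_fluorescent", "activator", "inactive",
               "inhibitor", "inhibitor", "excluded_fluorescent", "inactive"))
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      classifyCompounds(cases$z_ratio[i], cases$z_egfp[i], cases$mode[i]),
      cases$expect[i], info = paste("case", i))
  }
  expect_error(classifyCompounds(1, 1, zCut = -2), "positive")
})

test_that("hit rates reproduce the printed-arithmetic convention", {
  expect_equal(hitRate(8, 1595), 0.5)
  expect_equal(hitRate(0, 1595), 0)
  expect_equal(hitRate(25, 1595), 1.6)
})

test_that("a planted-truth screen is classified with no artifact leakage", {
  cfg <- simConfig()
  truth <- screenTruth(1595,
                       pActivator = 20 / 1595, pInhibitor = 40 / 1595,
                       pArtifactUp = 5 / 1595, pArtifactDown = 5 / 1595,
                       activatorFold = foldForZ(cfg, 8),
                       inhibitorFold = 1 / foldForZ(cfg, -8),
                       artifactFold = 2, seed = 9)
  scr <- simulateScreen(cfg, truth, seed = 30)
  res <- lapply(scr$replicates, function(rp)
    runBimodalScreen(rp$phase1, rp$phase2))
  truthA <- truth$compound_id[truth$class == "activator"]
  truthI <- truth$compound_id[truth$class == "inhibitor"]
  artifacts <- truth$compound_id[grepl("artifact", truth$class)]
  for (r in 1:2) {
    calls <- hitCalls(res[[r]])
    # recovery before EGFP exclusion: every planted strong effect is
    # beyond the z threshold in the correct phase and direction
    p1 <- calls[calls$phase == 1, ]
    p2 <- calls[calls$phase == 2, ]
    expect_true(all(p1$z_ratio[match(truthA, p1$compound_id)] >= 2))
    expect_true(all(p2$z_ratio[match(truthI, p2$compound_id)] <= -2))
    # exclusion precedence: artifacts never reach a hit list
    expect_length(intersect(unlist(hits(res[[r]])), artifacts), 0)
    # and no called hit carries |z_egfp| > 2
    hitRows <- calls[calls$class %in% c("activator", "inhibitor"), ]
    expect_true(all(abs(hitRows$z_egfp) <= 2))
  }
  conf <- intersectReplicates(res[[1]], res[[2]])
  expect_true(all(conf$confirmed$activator %in% truthA))
  expect_true(all(conf$confirmed$inhibitor %in% truthI))
})

test_that("type-I calls before EGFP exclusion match the nominal 2SD tail mass", {
  cfg <- simConfig()
  set.seed(99)
  tails <- vapply(1:10, function(i) {
    s <- sample.int(1e6, 1)
    scr <- simulateScreen(cfg, nCompounds = 1595, nReplicates = 1, seed = s)
    cl <- hitCalls(runBimodalScreen(scr$replicates[[1]]$phase1,
                                    scr$replicates[[1]]$phase2))
    c(upper = mean(cl$z_ratio[cl$phase == 1] >= 2),
      lower = mean(cl$z_ratio[cl$phase == 2] <= -2))
  }, numeric(2))
  n <- 10 * 1595
  ci <- stats::qbinom(c(0.005, 0.995), n, stats::pnorm(-2)) / n
  expect_gte(mean(tails["upper", ]), ci[1])
  expect_lte(mean(tails["upper", ]), ci[2])
  expect_gte(mean(tails["lower", ]), ci[1])
  expect_lte(mean(tails["lower", ]), ci[2])
})

test_that("hit calls are invariant to compound row order", {
  cfg <- simConfig()
  scr <- simulateScreen(cfg, nCompounds = 120, nReplicates = 1, seed = 17)
  p1 <- scr$replicates[[1]]$phase1
  p2 <- scr$replicates[[1]]$phase2
  res <- runBimodalScreen(p1, p2)
  set.seed(5)
  resPerm <- runBimodalScreen(p1[sample(nrow(p1)), ], p2[sample(nrow(p2)), ])
  byId <- function(r, ph) {
    cl <- hitCalls(r); cl <- cl[cl$phase == ph, ]
    cl$class[order(cl$compound_id)]
  }
  expect_identical(byId(res, 1), byId(resPerm, 1))
  expect_identical(byId(res, 2), byId(resPerm, 2))
})

test_that("phase mismatch and replicate plumbing are validated", {
  cfg <- simConfig()
  scr <- simulateScreen(cfg, nCompounds = 20, nReplicates = 1, seed = 3)
  p1 <- scr$replicates[[1]]$phase1
  p2 <- scr$replicates[[1]]$phase2
  p2cut <- p2[p2$compound_id != "CPD00003" | is.na(p2$compound_id), ]
  expect_error(runBimodalScreen(p1, p2cut), "CPD00003")
})

test_that("replicate intersection is a per-class set intersection", {
  mk <- function(hitsA, hitsI) {
    new("ScreenResult", calls = data.frame(), nCompounds = 100L,
        hits = list(activator = hitsA, inhibitor = hitsI),
        hitRate = c(activator = 0, inhibitor = 0), zCut = 2, egfpCut = 2)
  }
  conf <- intersectReplicates(mk(c("A", "B", "C"), "X"),
                              mk(c("B", "C", "D"), "Y"))
  expect_equal(conf$confirmed$activator, c("B", "C"))
  expect_length(conf$confirmed$inhibitor, 0)
  expect_equal(unname(conf$hitRate), c(2, 0))
})

test_that("replicate correlation follows the variance-components arithmetic", {
  expect_equal(replicateCorrelation(1:10, 1:10)$r, 1)
  expect_equal(replicateCorrelation(1:10, -(1:10))$r, -1)
  expect_error(replicateCorrelation(1:2, 1:2), "at least 3")
  expect_error(replicateCorrelation(1:5, rep(1, 5)), "zero variance")
  # shared effect SD / noise SD = 2  =>  r = 4 / (4 + 1) = 0.8
  set.seed(42)
  e <- rnorm(4000, 0, 2)
  r <- replicateCorrelation(e + rnorm(4000), e + rnorm(4000))$r
  expect_equal(r, 0.8, tolerance = 0.03)
  expect_lt(replicateCorrelation(e + rnorm(4000), e + rnorm(4000))$p.value,
            1e-10)
})

test_that("strong planted effects are recovered in both replicates", {
  cfg <- simConfig()
  truth <- screenTruth(800, pActivator = 0.025,
                       activatorFold = foldForZ(cfg, 6), seed = 21)
  truthA <- truth$compound_id[truth$class == "activator"]
  misses <- 0L; trials <- 0L
  for (s in 1:5) {
    scr <- simulateScreen(cfg, truth, seed = 100 + s)
    for (r in 1:2) {
      p1 <- hitCalls(runBimodalScreen(scr$replicates[[r]]$phase1,
                                      scr$replicates[[r]]$phase2))
      p1 <- p1[p1$phase == 1, ]
      z <- p1$z_ratio[match(truthA, p1$compound_id)]
      misses <- misses + sum(z < 2)
      trials <- trials + length(z)
    }
  }
  expect_gt(1 - misses / trials, 0.99)
})
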