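# Shared fixtures for the test suite. Fields used for exact-recovery
# checks are noise-free with homogeneous radii and a tight per-cell
# intensity spread, so the isodata threshold separates every nucleus
# unambiguously and QC flags map one-to-one onto planted truth.

exactFieldConfig <- function(nNucleiPerField = 12L, borderFraction = 0,
                             clusterFraction = 0, ...) {
  simConfig(nNucleiPerField = nNucleiPerField, nucleusRadiusSD = 0,
            egfpSigma = 0.1, basalTomSigma = 0.1, noiseSD = 0,
            borderFraction = borderFraction,
            clusterFraction = clusterFraction, ...)
}

# Match segmented components to planted truth rows by nearest centroid.
matchToTruth <- function(nuclei, truth) {
  vapply(seq_len(nrow(nuclei)), function(i)
    which.min((truth$row - nuclei$row[i])^2 +
              (truth$col - nuclei$col[i])^2), integer(1))
}

# Two-point samples with exact mean m and sample sd s.
twoPoint <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
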