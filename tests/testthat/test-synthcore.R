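# Synthetic generators: determinism, ground-truth construction, rejection
# of invalid specifications.

test_that("CMR phantom is deterministic and labels follow the construction", {
  spec <- smallCMRSpec(noiseSD = 5)
  g1 <- generateCMR(spec)
  g2 <- generateCMR(spec)
  expect_identical(intensities(g1$volume), intensities(g2$volume))
  expect_identical(g1$labels, g2$labels)

  noScar <- generateCMR(smallCMRSpec(scar = FALSE))
  labs <- noScar$labels
  expect_true(all(labs %in% c(0L, 1L)))      # background or HM only
  expect_gt(sum(labs == 1L), 0)
})

test_that("noiseless scar voxels normalise to exactly the configured offset", {
  spec <- smallCMRSpec(offset = 4, noiseSD = 0)
  g <- generateCMR(spec)
  masks <- splitWallHalves(g$contours, g$volume)
  zv <- normalizeToSDUnits(g$volume, g$nominalRemote, masks)
  z <- zValues(zv)
  expect_equal(unique(z[g$labels == 3L]), 4)
  expect_equal(unique(z[g$labels == 1L]), 0)
})

test_that("invalid CMR geometry is rejected with a message", {
  expect_error(smallCMRSpec(endoRadius = 26, epiRadius = 26),
               "endocardial radius")
  expect_error(smallCMRSpec(offset = -1), "offsets")
})

test_that("optical ground truth follows plane-wave kinematics", {
  spec <- syntheticOpticalSpec(gridShape = c(24L, 24L), pixelSize = 0.5,
                               nBeats = 2L, noiseSD = 0, seed = 2L)
  syn <- generateOptical(spec)
  act <- mapValues(syn$activation)
  # pixel at column c is (c-1) * pixelSize mm from the left edge;
  # hmVelocity 50 cm/s = 0.5 mm/ms
  dmm <- (col(act) - 1) * 0.5
  expect_equal(act, dmm / 0.5, tolerance = 1e-12)
})

test_that("HT patch carries the configured velocity and APD ratios", {
  patch <- circularPatchMask(c(24L, 24L), c(12, 15), 5)
  spec <- syntheticOpticalSpec(gridShape = c(24L, 24L), nBeats = 2L,
                               htPatch = list(mask = patch,
                                              velocityRatio = 0.55,
                                              apdRatio = 1.4),
                               noiseSD = 0, seed = 2L)
  syn <- generateOptical(spec)
  expect_equal(unique(mapValues(syn$cv)[patch]), 27.5)
  expect_equal(unique(mapValues(syn$cv)[!patch]), 50)
  expect_equal(unique(mapValues(syn$apd)[patch]), 350)
})

test_that("optical movies are reproducible and reject bad patches", {
  spec <- syntheticOpticalSpec(gridShape = c(16L, 16L), nBeats = 2L,
                               noiseSD = 30, seed = 5L)
  expect_identical(frames(generateOptical(spec)$recording),
                   frames(generateOptical(spec)$recording))
  expect_error(syntheticOpticalSpec(gridShape = c(16L, 16L),
                                    htPatch = list(mask = matrix(TRUE, 8, 8),
                                                   velocityRatio = 0.5,
                                                   apdRatio = 1)),
               "mask")
  expect_error(syntheticOpticalSpec(cycleLength = 100, apd80 = 250),
               "cycleLength")
})

test_that("EAM generator covers the mesh and is deterministic", {
  spec <- syntheticEAMSpec(pointSpacing = 5, seed = 3L)
  g1 <- generateEAM(spec)
  g2 <- generateEAM(spec)
  expect_identical(g1$study@points, g2$study@points)
  nodes <- meshNodes(g1$study@mesh)
  P <- as.matrix(g1$study@points[, c("x", "y", "z")])
  mind <- vapply(seq_len(nrow(nodes)), function(i)
    min(sqrt(colSums((t(P) - nodes[i, ])^2))), numeric(1))
  expect_true(all(mind <= 5))                    # fill rule
  expect_error(syntheticEAMSpec(mesh = TriangleMesh(matrix(0, 0, 3),
                                                    matrix(0L, 0, 3))),
               "empty mesh")
})

test_that("histology generator is deterministic and rejects zero sections", {
  spec <- syntheticHistoSpec(seed = 9L)
  expect_identical(generateHistology(spec), generateHistology(spec))
  expect_error(syntheticHistoSpec(nSections = 0L), "zero sections")
  tab <- generateHistology(spec)
  expect_true(all(tab$ordinal_level %in% 1:5))
  expect_true(all(tab$ht_extent > 0))
})

test_that("noise never improves map recovery on the same geometry", {
  patch <- circularPatchMask(c(24L, 24L), c(12, 15), 5)
  mk <- function(ns) syntheticOpticalSpec(gridShape = c(24L, 24L),
    frameInterval = 2, nBeats = 2L,
    htPatch = list(mask = patch, velocityRatio = 0.6, apdRatio = 1.3),
    noiseSD = ns, seed = 11L)
  rmse <- vapply(c(0, 100, 400), function(ns) {
    syn <- generateOptical(mk(ns))
    maps <- computeOpticalMaps(syn$recording, k = 2L)
    ok <- validMask(maps$apd)
    sqrt(mean((mapValues(maps$apd)[ok] - mapValues(syn$apd)[ok])^2))
  }, numeric(1))
  expect_true(all(diff(rmse) >= 0))
})
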