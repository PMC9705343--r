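# Optical module: conditioning, beat handling, activation, APD80,
# isochrones, conduction velocity and regional summaries.

test_that("preprocessing corrects dye polarity and flags flat pixels", {
  spec <- syntheticOpticalSpec(gridShape = c(12L, 12L), nBeats = 2L,
                               noiseSD = 0, invertPolarity = TRUE, seed = 1L)
  rec <- generateOptical(spec)$recording
  pp <- preprocessOptical(rec)
  tm <- epiScarMap:::tracesMatrix(pp)
  tr <- tm[50, ]
  # upstroke positive-going: the max comes after a rise, not a fall
  expect_gt(max(tr) - tr[1], 0.9 * (max(tr) - min(tr)))
  win <- segmentBeats(stimulusTimes(rec), cycleLength(rec),
                      frameInterval(rec), dim(frames(rec))[3])
  ab <- epiScarMap:::averagedBeat(tm, win, frameInterval(rec), k = 2L)
  expect_equal(max(ab$beat[50, ]), 1.0)      # normalised peak exactly 1
  expect_equal(min(ab$beat[50, ]), 0.0)
  # constant pixel -> invalid
  tm2 <- tm; tm2[3, ] <- 42
  ab2 <- epiScarMap:::averagedBeat(tm2, win, frameInterval(rec), k = 2L)
  expect_false(ab2$valid[3])
  expect_true(ab2$valid[50])
})

test_that("beat segmentation counts windows and drops incomplete ones", {
  win <- segmentBeats(c(0, 600, 1200), 600, 1, 2000)
  expect_equal(nrow(win), 3L)
  expect_warning(w2 <- segmentBeats(c(0, 600, 1200), 600, 1, 1500),
                 "dropped")
  expect_equal(nrow(w2), 2L)
  expect_error(segmentBeats(1000, 600, 1, 100), "no complete beat")
  # averaging identical noiseless beats equals a single beat
  spec <- syntheticOpticalSpec(gridShape = c(10L, 10L), nBeats = 3L,
                               noiseSD = 0, seed = 1L)
  rec <- generateOptical(spec)$recording
  tm <- epiScarMap:::tracesMatrix(preprocessOptical(rec))
  w <- segmentBeats(stimulusTimes(rec), cycleLength(rec),
                    frameInterval(rec), dim(frames(rec))[3])
  a1 <- epiScarMap:::averagedBeat(tm, w, frameInterval(rec), k = 1L)
  a3 <- epiScarMap:::averagedBeat(tm, w, frameInterval(rec), k = 3L)
  expect_equal(a3$beat, a1$beat, tolerance = 1e-12)
})

test_that("activation detection interpolates ramps, ties and edges", {
  relTime <- 0:60
  ramp <- c(rep(0, 5), seq(0, 1, length.out = 11), rep(1, 20),
            seq(1, 0, length.out = 21), rep(0, 4))
  # linear upstroke from 5 to 15 ms: plateau of equal derivative -> midpoint
  res <- detectActivation(rbind(ramp), relTime)
  expect_equal(res$time, 10, tolerance = 1e-9)
  # two separated equal derivative maxima -> earlier one
  two <- rep(0, 61); two[11:30] <- 1; two[31:61] <- 2
  res2 <- detectActivation(rbind(two), relTime)
  expect_lt(res2$time, 15)
  # derivative max at the window edge -> invalid
  edge <- c(seq(0, 1, length.out = 10), rep(1, 51))
  res3 <- detectActivation(rbind(edge), relTime)
  expect_false(res3$valid[1])
})

test_that("APD80 is the 20%-amplitude crossing after the peak", {
  # triangle AP: instant rise at 0, linear fall to 0 at 100 ms
  relTime <- 0:120
  tri <- c(1, seq(1, 0, length.out = 100), rep(0, 20))
  apd <- computeAPD80(rbind(tri), relTime, activation = 0)
  expect_equal(apd$apd[1], 80, tolerance = 0.5)
  # amplitude-zero pixel -> no APD
  flat <- rep(0, 121)
  apd2 <- computeAPD80(rbind(flat), relTime, activation = 0)
  expect_false(apd2$valid[1])
  # template-constructed APD80 recovered within one frame
  spec <- syntheticOpticalSpec(gridShape = c(16L, 16L), frameInterval = 2,
                               nBeats = 2L, apd80 = 150, cycleLength = 400,
                               noiseSD = 0, seed = 1L)
  syn <- generateOptical(spec)
  maps <- computeOpticalMaps(syn$recording, k = 2L, spatialRadius = 0L,
                             temporalWindow = 0L)
  ok <- validMask(maps$apd)
  expect_true(all(abs(mapValues(maps$apd)[ok] - 150) <= 2))
})

test_that("isochrones follow the wave geometry", {
  px <- 0.5
  nr <- 20L
  plane <- matrix(rep((0:19) * px / 0.5, each = nr), nr, 20L)
  am <- new("ActivationMap", values = plane, valid = matrix(TRUE, nr, 20L),
            pixelSize = px)
  iso <- buildIsochrones(am, step = 2)
  expect_gt(length(iso), 2)
  # the wave travels along columns (y axis): isochrones are lines of
  # constant y
  spreads <- vapply(iso, function(cl) diff(range(cl$y)), numeric(1))
  expect_true(all(spreads < 1e-6))
  # point source: closed concentric contours
  r <- sqrt(outer((1:20 - 10)^2, (1:20 - 10)^2, "+"))
  am2 <- new("ActivationMap", values = r, valid = matrix(TRUE, 20L, 20L),
             pixelSize = px)
  iso2 <- buildIsochrones(am2, step = 2)
  expect_gt(length(iso2), 1)
  closed <- vapply(iso2, function(cl)
    sqrt((cl$x[1] - cl$x[length(cl$x)])^2 +
           (cl$y[1] - cl$y[length(cl$y)])^2) < 1e-6, logical(1))
  expect_true(any(closed))
  # step larger than the activation range -> at most one contour
  expect_lte(length(buildIsochrones(am, step = 100)), 1)
  # constant map -> empty set
  am3 <- new("ActivationMap", values = matrix(1, 10, 10),
             valid = matrix(TRUE, 10, 10), pixelSize = px)
  expect_length(buildIsochrones(am3, 2), 0)
})

test_that("plane-fit velocity recovers closed-form fields", {
  px <- 0.5
  # T(x, y) = x / 0.5 (ms, x in mm): speed 50 cm/s in +x
  xmm <- (matrix(1:30, 30, 30) - 1) * px
  am <- new("ActivationMap", values = xmm / 0.5,
            valid = matrix(TRUE, 30, 30), pixelSize = px)
  cv <- estimateCV(am)
  ok <- validMask(cv)
  expect_true(all(abs(mapValues(cv)[ok] - 50) < 1e-9))
  expect_true(all(abs(cv@dirX[ok] - 1) < 1e-9))
  expect_true(all(abs(cv@dirY[ok]) < 1e-9))
  # radial wave: |grad T| = 1/v away from the source
  v <- 0.4                                        # mm/ms
  ctr <- 15.5
  r <- sqrt((row(xmm) - ctr)^2 + (col(xmm) - ctr)^2) * px
  am2 <- new("ActivationMap", values = r / v, valid = matrix(TRUE, 30, 30),
             pixelSize = px)
  cv2 <- estimateCV(am2)
  far <- r > 10 * px & validMask(cv2)    # beyond the fit window's reach
  expect_true(all(abs(mapValues(cv2)[far] - 40) / 40 < 0.02))
  # spatial-scale covariance: doubling pixel size doubles speed
  am3 <- new("ActivationMap", values = xmm / 0.5,
             valid = matrix(TRUE, 30, 30), pixelSize = 2 * px)
  cv3 <- estimateCV(am3)
  expect_equal(stats::median(mapValues(cv3)[validMask(cv3)]), 100,
               tolerance = 1e-9)
})

test_that("regional relative difference follows (HT-HM)/HM", {
  v <- matrix(50, 10, 10); v[, 6:10] <- 40
  f <- new("CVField", values = v, valid = matrix(TRUE, 10, 10),
           pixelSize = 0.5, dirX = v, dirY = v)
  rois <- list(hm = col(v) <= 5, ht = col(v) > 5)
  expect_equal(regionalRelativeDifference(f, rois), -20)
  v2 <- matrix(200, 10, 10); v2[, 6:10] <- 280
  f2 <- new("APDMap", values = v2, valid = matrix(TRUE, 10, 10),
            pixelSize = 0.5)
  expect_equal(regionalRelativeDifference(f2, rois), 40)
  # identical regional statistics -> 0%
  v3 <- matrix(120, 10, 10)
  f3 <- new("APDMap", values = v3, valid = matrix(TRUE, 10, 10),
            pixelSize = 0.5)
  expect_equal(regionalRelativeDifference(f3, rois), 0)
  expect_error(regionalRelativeDifference(f2, list(hm = rois$hm,
                                                   ht = rois$hm)),
               "disjoint")
})

test_that("time-shifted stimuli leave activation, APD and CV unchanged", {
  mk <- function(t0) syntheticOpticalSpec(gridShape = c(20L, 20L),
    frameInterval = 2, nBeats = 2L, firstStimulus = t0, noiseSD = 0,
    seed = 4L)
  m1 <- computeOpticalMaps(generateOptical(mk(10))$recording, k = 2L)
  m2 <- computeOpticalMaps(generateOptical(mk(50))$recording, k = 2L)
  ok <- validMask(m1$activation) & validMask(m2$activation)
  expect_equal(mapValues(m1$activation)[ok], mapValues(m2$activation)[ok],
               tolerance = 1e-6)
  okA <- validMask(m1$apd) & validMask(m2$apd)
  expect_equal(mapValues(m1$apd)[okA], mapValues(m2$apd)[okA],
               tolerance = 1e-6)
})
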